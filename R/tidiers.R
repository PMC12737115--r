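# broom-style tidiers for the classed result tibbles

#' @method tidy panfam_occupancy
#' @export
tidy.panfam_occupancy <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance panfam_occupancy
#' @export
glance.panfam_occupancy <- function(x, ...) {
  cc <- attr(x, "category_counts")
  tibble(
    n_genes = nrow(x),
    n_genomes = x$n_genomes[1],
    n_core = as.integer(cc["core"]),
    n_near_core = as.integer(cc["near_core"]),
    n_dispensable = as.integer(cc["dispensable"]),
    n_private = as.integer(cc["private"]),
    near_core_min_frac = attr(x, "near_core_min_frac")
  )
}

#' @method tidy panfam_sv_regions
#' @export
tidy.panfam_sv_regions <- function(x, ...) {
  out <- as_tibble(x) |>
    mutate(carriers = map_chr(.data$carriers, paste, collapse = ","))
  class(out) <- class(tibble())
  out
}

#' @method glance panfam_sv_regions
#' @export
glance.panfam_sv_regions <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_deletion = sum(x$type == "deletion"),
    n_insertion = sum(x$type == "insertion"),
    min_share = attr(x, "min_share") %||% NA_integer_
  )
}

#' @method tidy panfam_selection
#' @export
tidy.panfam_selection <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance panfam_selection
#' @export
glance.panfam_selection <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_excluded = nrow(attr(x, "excluded") %||% tibble()),
    n_pairs_total = sum(x$n_pairs),
    mean_prop_omega_gt1 = mean(x$prop_omega_gt1, na.rm = TRUE)
  )
}

#' @method tidy panfam_assoc
#' @export
tidy.panfam_assoc <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance panfam_assoc
#' @export
glance.panfam_assoc <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_testable = sum(!is.na(x$p)),
    n_significant = sum(x$label %in% c("*", "**", "***"), na.rm = TRUE)
  )
}

#' @method tidy panfam_kaks
#' @export
tidy.panfam_kaks <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}
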