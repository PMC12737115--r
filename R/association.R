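# Presence/absence association testing: group samples by SV genotype (or any
# binary metadata), compare a per-sample scalar (expression) between groups
# with Student's t-test, and attach the conventional significance labels
# (* p < 0.05, ** p < 0.01, *** p < 0.001, ns otherwise).

significance_label <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Split sample values by SV presence/absence
#'
#' @param genotypes Wide genotype tibble from [genotype_sv()].
#' @param values Tibble `sample_id`, `value` (expression or any per-sample
#'   scalar).
#' @param region_id Region to split on.
#' @return List with numeric vectors `present` and `absent`, and `testable`
#'   (`TRUE` when both groups have at least 2 values). Samples without a
#'   value are dropped with a warning.
#' @export
split_by_genotype <- function(genotypes, values, region_id) {
  row <- genotypes[genotypes$region_id == region_id, , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("region not found: ", region_id))
  samples <- setdiff(names(genotypes), "region_id")
  present_ids <- samples[unlist(row[1, samples])]
  absent_ids <- setdiff(samples, present_ids)
  missing <- setdiff(samples, values$sample_id)
  if (length(missing) > 0) {
    warn(paste0("no value for sample(s) ", paste(missing, collapse = ", "),
                "; dropped from region ", region_id))
  }
  val <- setNames(values$value, values$sample_id)
  present <- unname(val[intersect(present_ids, values$sample_id)])
  absent <- unname(val[intersect(absent_ids, values$sample_id)])
  list(present = present, absent = absent,
       testable = length(present) >= 2 && length(absent) >= 2)
}

#' Two-sided Student's t-test with degenerate-case handling
#'
#' Classical pooled-variance Student's t by default (`equal_variance =
#' TRUE`, df = n_a + n_b - 2); Welch's correction by flag. Zero pooled
#' variance is handled explicitly: equal means give `t = 0, p = 1`,
#' different means give `p = 0` with a `degenerate` flag.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param equal_variance Pooled-variance Student's t when `TRUE` (default);
#'   Welch when `FALSE`.
#' @return List `t`, `p`, `df`, `degenerate`.
#' @export
t_test_two_sided <- function(group_a, group_b, equal_variance = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values")
  }
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                   sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = length(group_a) + length(group_b) - 2,
                degenerate = TRUE))
  }
  res <- stats::t.test(group_a, group_b, var.equal = equal_variance,
                       alternative = "two.sided")
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' Test every SV region for association with a per-sample value
#'
#' For each region, samples are grouped by SV presence/absence and the two
#' groups compared with a two-sided Student's t-test. Raw p-values drive the
#' significance labels; a Benjamini-Hochberg adjusted p-value is reported in
#' a separate column for reference. Regions with fewer than 2 samples in
#' either group are untestable and are skipped with a message.
#'
#' @inheritParams split_by_genotype
#' @param equal_variance Passed to [t_test_two_sided()].
#' @return A `panfam_assoc` tibble: `region_id`, `n_present`, `n_absent`,
#'   `mean_present`, `mean_absent`, `sd_present`, `sd_absent`, `t`, `p`,
#'   `p_bh`, `label`.
#' @export
associate_all <- function(genotypes, values, equal_variance = TRUE) {
  res <- map(genotypes$region_id, function(rid) {
    grp <- suppressWarnings(split_by_genotype(genotypes, values, rid))
    if (!grp$testable) {
      inform(paste0(rid, ": untestable (a genotype group has < 2 samples)"))
      return(tibble(
        region_id = rid,
        n_present = length(grp$present), n_absent = length(grp$absent),
        mean_present = if (length(grp$present)) mean(grp$present) else NA_real_,
        mean_absent = if (length(grp$absent)) mean(grp$absent) else NA_real_,
        sd_present = NA_real_, sd_absent = NA_real_,
        t = NA_real_, p = NA_real_
      ))
    }
    tt <- t_test_two_sided(grp$present, grp$absent,
                           equal_variance = equal_variance)
    tibble(
      region_id = rid,
      n_present = length(grp$present), n_absent = length(grp$absent),
      mean_present = mean(grp$present), mean_absent = mean(grp$absent),
      sd_present = sd(grp$present), sd_absent = sd(grp$absent),
      t = tt$t, p = tt$p
    )
  }) |> bind_rows()
  if (nrow(res) == 0) {
    inform("no testable regions")
  }
  res <- res |>
    mutate(p_bh = p.adjust(.data$p, method = "BH"),
           label = significance_label(.data$p))
  class(res) <- c("panfam_assoc", class(res))
  res
}

#' Group-vs-group comparison from a sample metadata column
#'
#' The same grouping + Student's t-test scheme applied to a binary sample
#' covariate (e.g. tropical vs temperate origin) instead of an SV genotype.
#'
#' @param values Tibble `sample_id`, `value`.
#' @param metadata Tibble with `sample_id` and the grouping column.
#' @param group_by Name of the metadata column (must have exactly 2 levels).
#' @param equal_variance Passed to [t_test_two_sided()].
#' @return One-row `panfam_assoc`-style tibble with the two level names in
#'   `group_a`/`group_b`.
#' @export
associate_by_metadata <- function(values, metadata, group_by,
                                  equal_variance = TRUE) {
  md <- metadata[, c("sample_id", group_by)]
  names(md)[2] <- "group"
  lv <- sort(unique(md$group))
  if (length(lv) != 2) {
    abort(paste0("grouping column '", group_by, "' must have exactly 2 levels"))
  }
  joined <- dplyr::inner_join(values, md, by = "sample_id")
  a <- joined$value[joined$group == lv[1]]
  b <- joined$value[joined$group == lv[2]]
  if (length(a) < 2 || length(b) < 2) abort("a group has < 2 samples")
  tt <- t_test_two_sided(a, b, equal_variance = equal_variance)
  tibble(
    group_a = lv[1], group_b = lv[2],
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    t = tt$t, p = tt$p, label = significance_label(tt$p)
  )
}
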