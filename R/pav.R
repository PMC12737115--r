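#' Build the gene-by-genome presence/absence (PAV) matrix
#'
#' Presence of pan-gene `g` in genome `G` means the pan-gene table records at
#' least one member of `g` annotated in `G`. Absence is meaningful only
#' relative to a complete genome panel, so the panel is an explicit argument.
#'
#' @param pan_genes Pan-gene table from [cluster_pan_genes()] (columns
#'   `pan_gene_id`, `genome_id`, `gene_id`).
#' @param genome_ids Character vector: the complete genome panel.
#' @return A `panfam_pav` tibble: one row per pan-gene, column `gene_id`
#'   followed by one logical column per genome (in `genome_ids` order).
#' @export
build_pav <- function(pan_genes, genome_ids) {
  genome_ids <- as.character(genome_ids)
  if (anyDuplicated(genome_ids)) abort("duplicate genome ids in panel")
  extra <- setdiff(unique(pan_genes$genome_id), genome_ids)
  if (length(extra) > 0) {
    abort(paste0("pan-gene table contains genomes missing from the panel: ",
                 paste(extra, collapse = ", ")))
  }
  genes <- sort(unique(pan_genes$pan_gene_id))
  mat <- matrix(FALSE, nrow = length(genes), ncol = length(genome_ids),
                dimnames = list(genes, genome_ids))
  if (nrow(pan_genes) > 0) {
    mat[cbind(pan_genes$pan_gene_id, pan_genes$genome_id)] <- TRUE
  }
  out <- as_tibble(mat, rownames = "gene_id")
  class(out) <- c("panfam_pav", class(out))
  attr(out, "genome_ids") <- genome_ids
  out
}

#' Construct a PAV matrix directly from presence vectors
#'
#' Convenience constructor for worked examples and fixtures: takes a named
#' list mapping each gene id to the character vector of genomes carrying it.
#'
#' @param presence Named list; names are gene ids, values are character
#'   vectors of carrier genomes (subset of `genome_ids`).
#' @param genome_ids Complete genome panel.
#' @return A `panfam_pav` tibble as from [build_pav()].
#' @export
pav_from_presence <- function(presence, genome_ids) {
  long <- tibble(
    pan_gene_id = rep(names(presence), lengths(presence)),
    genome_id = unlist(presence, use.names = FALSE),
    gene_id = rep(names(presence), lengths(presence))
  )
  build_pav(long, genome_ids)
}

pav_matrix <- function(pav) {
  m <- as.matrix(pav[, setdiff(names(pav), "gene_id")])
  rownames(m) <- pav$gene_id
  storage.mode(m) <- "logical"
  m
}

#' Classify pan-genes into occupancy categories
#'
#' Occupancy is the number of genomes a pan-gene is present in, out of the
#' `n` genomes of the panel. Categories partition the gene set:
#' * `core`: occupancy = n (present in all genomes);
#' * `near_core`: `near_core_min_frac * n <= occupancy < n`;
#' * `private`: occupancy = 1;
#' * `dispensable`: everything in between.
#'
#' @param pav A `panfam_pav` tibble from [build_pav()].
#' @param near_core_min_frac Fraction of the panel at or above which a
#'   non-core gene is near-core (default 0.90).
#' @return A `panfam_occupancy` tibble: `gene_id`, `occupancy`, `n_genomes`,
#'   `category` (factor core/near_core/dispensable/private). Category counts
#'   are in the `"category_counts"` attribute.
#' @examples
#' pav <- pav_from_presence(
#'   list(g1 = c("A", "B", "C"), g2 = "A"),
#'   genome_ids = c("A", "B", "C")
#' )
#' classify_occupancy(pav)
#' @export
classify_occupancy <- function(pav, near_core_min_frac = 0.90) {
  m <- pav_matrix(pav)
  n <- ncol(m)
  if (n < 2) abort("occupancy classification needs a panel of >= 2 genomes")
  occ <- rowSums(m)
  if (any(occ == 0)) {
    abort(paste0("gene(s) with zero occupancy violate the PAV invariant: ",
                 paste(rownames(m)[occ == 0], collapse = ", ")))
  }
  lvl <- c("core", "near_core", "dispensable", "private")
  category <- ifelse(
    occ == n, "core",
    ifelse(occ == 1, "private",
           ifelse(occ >= near_core_min_frac * n, "near_core", "dispensable"))
  )
  out <- tibble(
    gene_id = rownames(m),
    occupancy = as.integer(occ),
    n_genomes = n,
    category = factor(category, levels = lvl)
  )
  class(out) <- c("panfam_occupancy", class(out))
  attr(out, "category_counts") <- table(out$category)
  attr(out, "near_core_min_frac") <- near_core_min_frac
  out
}

#' Long-format PAV table for plotting
#'
#' @param pav A `panfam_pav` tibble.
#' @return Tibble `gene_id`, `genome_id`, `present` (0/1 integer), suitable
#'   for tile heatmaps or TSV export.
#' @export
pav_long <- function(pav) {
  pav |>
    tidyr::pivot_longer(-"gene_id", names_to = "genome_id",
                        values_to = "present") |>
    mutate(present = as.integer(.data$present))
}

#' Write PAV matrix and occupancy classification as TSV
#'
#' @param pav A `panfam_pav` tibble.
#' @param occupancy A `panfam_occupancy` tibble (optional).
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_pav <- function(pav, occupancy = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "pav_matrix.tsv")
  wide <- pav
  wide[-1] <- lapply(wide[-1], as.integer)
  utils::write.table(wide, paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long_path <- file.path(dir, "pav_long.tsv")
  utils::write.table(pav_long(pav), long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, long_path)
  if (!is.null(occupancy)) {
    cls_path <- file.path(dir, "occupancy.tsv")
    utils::write.table(occupancy, cls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, cls_path)
  }
  invisible(paths)
}
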