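#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the whitespace-separated per-domain output of `hmmsearch --domtblout`
#' into a tidy table of domain hits, one row per domain. Profile coverage of
#' each hit is computed on the profile (HMM) coordinates as
#' `(hmm_to - hmm_from + 1) / profile_len`.
#'
#' @param path Path to a domtblout file. Lines starting with `#` are ignored.
#' @param genome_id Genome the searched proteome belongs to. When `NULL`
#'   (default), target names of the form `"genome|gene"` are split into the
#'   two ids; otherwise the file's base name (without extension) is used.
#' @return A tibble with one row per domain hit: `genome_id`, `gene_id`,
#'   `profile_id`, `full_seq_evalue`, `profile_len`, `hmm_from`, `hmm_to`,
#'   `ali_from`, `ali_to`, `coverage`.
#' @examples
#' dom <- make_pangenome(n_genomes = 3, counts = c(1, 0, 1, 1), seed = 1)
#' path <- tempfile(fileext = ".domtblout")
#' write_domtblout(dom$hits, path)
#' parse_domtblout(path)
#' @export
parse_domtblout <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("domtblout file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(
      genome_id = character(), gene_id = character(), profile_id = character(),
      full_seq_evalue = numeric(), profile_len = integer(),
      hmm_from = integer(), hmm_to = integer(),
      ali_from = integer(), ali_to = integer(), coverage = numeric()
    ))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")

  parse_row <- function(fld, ln) {
    if (length(fld) < 22) {
      abort(paste0("malformed domtblout row at line ", ln,
                   ": expected >= 22 columns, found ", length(fld)))
    }
    ev <- suppressWarnings(as.numeric(fld[7]))
    if (is.na(ev)) {
      abort(paste0("malformed domtblout row at line ", ln,
                   ": non-numeric E-value '", fld[7], "'"))
    }
    num <- suppressWarnings(as.integer(fld[c(6, 16, 17, 18, 19)]))
    if (anyNA(num)) {
      abort(paste0("malformed domtblout row at line ", ln,
                   ": non-integer coordinate field"))
    }
    tibble(
      target = fld[1], profile_id = fld[4], full_seq_evalue = ev,
      profile_len = num[1], hmm_from = num[2], hmm_to = num[3],
      ali_from = num[4], ali_to = num[5]
    )
  }
  hits <- bind_rows(map2(fields, lineno, parse_row))

  if (is.null(genome_id)) {
    if (all(grepl("|", hits$target, fixed = TRUE))) {
      parts <- stringr::str_split_fixed(hits$target, stringr::fixed("|"), 2)
      hits$genome_id <- parts[, 1]
      hits$gene_id <- parts[, 2]
    } else {
      hits$genome_id <- sub("\\.[^.]*$", "", basename(path))
      hits$gene_id <- hits$target
    }
  } else {
    hits$genome_id <- genome_id
    hits$gene_id <- hits$target
  }
  hits |>
    mutate(coverage = (.data$hmm_to - .data$hmm_from + 1) / .data$profile_len) |>
    select("genome_id", "gene_id", "profile_id", "full_seq_evalue",
           "profile_len", "hmm_from", "hmm_to", "ali_from", "ali_to",
           "coverage")
}

#' Write domain hits as a HMMER3 domtblout file
#'
#' Inverse of [parse_domtblout()]: serializes a hit table in the 23-column
#' domtblout dialect (target names are `"genome|gene"`). Used by the
#' synthetic pangenome generator so fixtures round-trip through the parser.
#'
#' @param hits Tibble of hits as returned by [parse_domtblout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  header <- paste0("# target name accession tlen query name accession qlen ",
                   "E-value score bias # of c-Evalue i-Evalue score bias ",
                   "from to from to from to acc description")
  rows <- sprintf(
    "%s - %d %s PF_SYNTH %d %.3g 100.0 0.1 1 1 %.3g %.3g 99.0 0.1 %d %d %d %d %d %d 0.95 -",
    paste0(hits$genome_id, "|", hits$gene_id),
    hits$ali_to + 10L, hits$profile_id, hits$profile_len,
    hits$full_seq_evalue, hits$full_seq_evalue / 10, hits$full_seq_evalue,
    hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
    hits$ali_from, hits$ali_to
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter domain hits into per-genome family member sets
#'
#' A gene is designated a family member when at least one of its domain hits
#' passes both thresholds: full-sequence E-value strictly below `evalue_max`
#' and profile coverage strictly above `min_coverage`. Multiple qualifying
#' domains in one gene count once.
#'
#' @param hits Tibble of domain hits from [parse_domtblout()].
#' @param evalue_max Strict upper bound on the full-sequence E-value
#'   (default `1e-5`).
#' @param min_coverage Strict lower bound on profile coverage (default
#'   `0.70`).
#' @return A tibble with one row per retained (genome, gene): `genome_id`,
#'   `gene_id`, `best_evalue`, `best_coverage`; thresholds recorded in the
#'   `"thresholds"` attribute.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, min_coverage = 0.70) {
  stopifnot(evalue_max > 0, min_coverage > 0)
  passing <- if (nrow(hits) == 0) hits else {
    filter(hits, .data$full_seq_evalue < evalue_max,
           .data$coverage > min_coverage)
  }
  if (nrow(passing) == 0) {
    out <- tibble(genome_id = character(), gene_id = character(),
                  best_evalue = numeric(), best_coverage = numeric())
  } else {
    out <- passing |>
      group_by(.data$genome_id, .data$gene_id) |>
      summarise(best_evalue = min(.data$full_seq_evalue),
                best_coverage = max(.data$coverage), .groups = "drop") |>
      arrange(.data$genome_id, .data$gene_id)
  }
  attr(out, "thresholds") <- list(evalue_max = evalue_max,
                                  min_coverage = min_coverage)
  out
}

#' Group family members into pan-genes by protein identity
#'
#' Single-linkage clustering of member proteins on global pairwise identity:
#' two members join the same cluster when their global identity — computed
#' as `(max length - edit distance) / max length`, the unit-cost global
#' alignment identity — is at least `identity_min`. Each cluster becomes one
#' pan-gene. Pan-gene ids are assigned deterministically by the sorted
#' (genome, gene) key of each cluster's first member, so the result does not
#' depend on input order. An externally supplied pan-gene map bypasses
#' clustering.
#'
#' @param members Member table from [filter_hits()] (columns `genome_id`,
#'   `gene_id`).
#' @param proteins Named [Biostrings::AAStringSet] or named character vector
#'   of protein sequences; names are `"genome|gene"`.
#' @param identity_min Minimum global identity to link two members
#'   (default 0.90).
#' @param pan_map Optional data frame (`pan_gene_id`, `genome_id`, `gene_id`)
#'   giving a published pan-gene assignment; when provided it is validated
#'   and returned as-is.
#' @return A pan-gene table: tibble with `pan_gene_id`, `genome_id`,
#'   `gene_id`, one row per member.
#' @export
cluster_pan_genes <- function(members, proteins, identity_min = 0.90,
                              pan_map = NULL) {
  if (!is.null(pan_map)) {
    pan_map <- as_tibble(pan_map)
    stopifnot(all(c("pan_gene_id", "genome_id", "gene_id") %in%
                    names(pan_map)))
    dup <- pan_map |> count(.data$genome_id, .data$gene_id) |>
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort("pan_map assigns a (genome, gene) to more than one pan-gene")
    }
    return(pan_map |> select("pan_gene_id", "genome_id", "gene_id"))
  }
  if (is.character(proteins)) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  key <- paste0(members$genome_id, "|", members$gene_id)
  missing <- setdiff(key, names(proteins))
  if (length(missing) > 0) {
    abort(paste0("no protein sequence for member(s): ",
                 paste(missing, collapse = ", ")))
  }
  ord <- order(key)
  key <- key[ord]
  members <- members[ord, ]
  n <- length(key)
  if (n == 0) {
    return(tibble(pan_gene_id = character(), genome_id = character(),
                  gene_id = character()))
  }
  seqs <- as.character(proteins[key])

  # union-find over single-linkage edges; identities from one C-level
  # global edit-distance computation over all pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    d <- utils::adist(seqs)
    len <- nchar(seqs)
    maxlen <- outer(len, len, pmax)
    identity <- (maxlen - d) / maxlen
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (identity[i, j] >= identity_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # clusters named in the order of their smallest (sorted) member key
  cluster_first <- tapply(seq_len(n), root, min)
  cluster_order <- order(cluster_first)
  cluster_rank <- setNames(seq_along(cluster_order),
                           names(cluster_first)[cluster_order])
  pan_id <- sprintf("pan_%04d", cluster_rank[as.character(root)])
  tibble(pan_gene_id = unname(pan_id),
         genome_id = members$genome_id,
         gene_id = members$gene_id) |>
    arrange(.data$pan_gene_id, .data$genome_id, .data$gene_id)
}
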