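# Promoter window extraction and shared indel (SV) calling from a
# reference-anchored multiple alignment. Coordinates are reference-projected,
# 0-based, half-open (BED convention); insertions are anchored at the single
# reference position following the reference gap run.

#' Extract the upstream (promoter) window of a gene
#'
#' Strand-aware extraction of the `window` bases upstream of the annotated
#' gene start, oriented 5'->3' toward the gene: for a plus-strand gene on
#' genome interval `[s, e)` the window is `[max(0, s - window), s)` in
#' forward orientation; for a minus-strand gene it is `[e, e + window)`
#' reverse-complemented. Windows truncated at a contig edge are returned
#' shorter, with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a genome FASTA.
#' @param annotation A GFF3 file path, or a data frame with columns
#'   `seqid`, `start`, `end`, `strand`, `gene_id` (1-based inclusive
#'   coordinates, as in GFF3).
#' @param gene_id Gene to extract the promoter of.
#' @param window Window length in bp (default 2000).
#' @return One-row tibble: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open, genome-forward), `strand`, `length`, `truncated`, `seq`.
#' @export
extract_upstream <- function(genome, annotation, gene_id, window = 2000) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  ann <- load_annotation(annotation)
  row <- ann[ann$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0) {
    abort(paste0("gene id not found in annotation: ", gene_id))
  }
  row <- row[1, ]
  if (!row$seqid %in% names(genome)) {
    abort(paste0("annotation sequence ", row$seqid, " not in genome"))
  }
  contig_len <- Biostrings::width(genome[row$seqid])
  s <- row$start - 1L   # 0-based half-open gene interval [s, e)
  e <- row$end
  if (row$strand == "-") {
    w_start <- e
    w_end <- min(contig_len, e + window)
  } else {
    w_start <- max(0L, s - window)
    w_end <- s
  }
  if (w_end <= w_start) {
    abort(paste0("empty upstream window for gene ", gene_id,
                 " (gene abuts the contig edge)"))
  }
  truncated <- (w_end - w_start) < window
  if (truncated) {
    warn(paste0("upstream window of ", gene_id, " truncated to ",
                w_end - w_start, " bp at the contig edge"))
  }
  seq <- as.character(Biostrings::subseq(genome[[row$seqid]],
                                         start = w_start + 1, end = w_end))
  if (row$strand == "-") seq <- reverse_complement(seq)
  tibble(gene_id = gene_id, chrom = row$seqid,
         start = w_start, end = w_end, strand = row$strand,
         length = w_end - w_start, truncated = truncated, seq = seq)
}

load_annotation <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("seqid", "start", "end", "strand", "gene_id") %in%
                    names(annotation)))
    return(as_tibble(annotation))
  }
  gr <- rtracklayer::import(annotation)
  gr <- gr[gr$type %in% c("gene", "mRNA", "transcript")]
  ids <- gr$ID
  if (!is.null(gr$Name)) ids <- ifelse(is.na(ids), gr$Name, ids)
  tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids
  )
}

aln_to_matrix <- function(alignment) {
  if (inherits(alignment, "DNAStringSet") || inherits(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) return(alignment)
  if (length(unique(nchar(alignment))) != 1) {
    abort("ragged alignment: rows differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Call per-sample indel events against the reference row of an alignment
#'
#' For each non-reference row, maximal runs of alignment columns where the
#' sample is gapped but the reference is not become deletion events, and
#' maximal runs where the reference is gapped but the sample is not become
#' insertion events (anchored at the reference position following the run).
#' Columns gapped in both rows carry no length information and are skipped:
#' they neither break nor extend a run. Leading and trailing gap runs of a
#' sample are missing flanks, not deletions. Events shorter than `min_len`
#' are discarded.
#'
#' @param alignment Named character vector, [Biostrings::DNAStringSet], or
#'   character matrix of equal-length aligned sequences.
#' @param reference_id Name of the reference row.
#' @param min_len Minimum event length in bp (default 50).
#' @return Tibble of events: `sample_id`, `type` (`"deletion"`/
#'   `"insertion"`), `ref_start`, `ref_end` (0-based half-open; equal for
#'   insertions), `length`, `col_start`, `col_end` (1-based alignment
#'   columns), `seq` (deleted reference bases or inserted sample bases).
#' @export
detect_indels <- function(alignment, reference_id, min_len = 50) {
  m <- aln_to_matrix(alignment)
  if (!reference_id %in% rownames(m)) {
    abort(paste0("reference id not in alignment: ", reference_id))
  }
  ref <- m[reference_id, ]
  ref_has <- ref != "-"
  refpos_after <- cumsum(ref_has)       # ref bases consumed through column i

  events <- list()
  for (sample_id in setdiff(rownames(m), reference_id)) {
    s <- m[sample_id, ]
    s_has <- s != "-"
    if (!any(s_has)) next
    first <- which(s_has)[1]
    last <- tail(which(s_has), 1)

    # deletion runs: sample gapped / ref base, inside the sample's flanks
    del_col <- !s_has & ref_has
    del_col[seq_len(first - 1)] <- FALSE
    if (last < length(s)) del_col[seq(last + 1, length(s))] <- FALSE
    runs <- collapse_runs(del_col, breaker = s_has)
    for (r in runs) {
      len <- sum(del_col[r])
      if (len < min_len) next
      rs <- refpos_after[r[1]] - 1L
      events[[length(events) + 1]] <- tibble(
        sample_id = sample_id, type = "deletion",
        ref_start = rs, ref_end = rs + len, length = len,
        col_start = r[1], col_end = r[length(r)],
        seq = paste(ref[r][del_col[r]], collapse = "")
      )
    }

    # insertion runs: ref gapped / sample base; broken by reference bases
    ins_col <- s_has & !ref_has
    runs <- collapse_runs(ins_col, breaker = ref_has)
    for (r in runs) {
      len <- sum(ins_col[r])
      if (len < min_len) next
      anchor <- refpos_after[r[1]]      # ref position following the run
      events[[length(events) + 1]] <- tibble(
        sample_id = sample_id, type = "insertion",
        ref_start = anchor, ref_end = anchor, length = len,
        col_start = r[1], col_end = r[length(r)],
        seq = paste(s[r][ins_col[r]], collapse = "")
      )
    }
  }
  if (length(events) == 0) {
    return(tibble(sample_id = character(), type = character(),
                  ref_start = integer(), ref_end = integer(),
                  length = integer(), col_start = integer(),
                  col_end = integer(), seq = character()))
  }
  bind_rows(events) |> arrange(.data$ref_start, .data$sample_id)
}

# maximal runs of TRUE in `active`, where columns with breaker TRUE end a
# run and all other columns (e.g. gapped in both rows) are transparent
collapse_runs <- function(active, breaker) {
  runs <- list()
  first <- NA_integer_
  last <- NA_integer_
  for (i in seq_along(active)) {
    if (active[i]) {
      if (is.na(first)) first <- i
      last <- i
    } else if (breaker[i] && !is.na(first)) {
      runs[[length(runs) + 1]] <- seq(first, last)
      first <- NA_integer_
    }
  }
  if (!is.na(first)) runs[[length(runs) + 1]] <- seq(first, last)
  runs
}

#' Merge per-sample indel events into shared SV regions
#'
#' Single-linkage clustering of same-type events: two deletions link when
#' their reciprocal reference-interval overlap is at least `overlap_frac`;
#' two insertions link when their anchor points are within `anchor_tol` bp.
#' Events of different types never merge. Clusters carried by fewer than
#' `min_share` distinct samples are discarded; survivors become regions
#' numbered `Region1..k` left to right on the reference.
#'
#' @param events Event table from [detect_indels()].
#' @param min_share Minimum number of distinct carrier samples (default 5).
#' @param overlap_frac Reciprocal overlap fraction linking two deletions
#'   (default 0.5).
#' @param anchor_tol Anchor distance in bp linking two insertions
#'   (default 10).
#' @return A `panfam_sv_regions` tibble: `region_id`, `type`, `ref_start`,
#'   `ref_end`, `share_count`, `len_min`, `len_median`, `len_max`,
#'   `carriers` (list-column). Member events, tagged with `region_id`, are
#'   kept in `attr(, "events")`.
#' @export
merge_shared_sv <- function(events, min_share = 5, overlap_frac = 0.5,
                            anchor_tol = 10) {
  empty <- tibble(region_id = character(), type = character(),
                  ref_start = integer(), ref_end = integer(),
                  share_count = integer(), len_min = integer(),
                  len_median = double(), len_max = integer(),
                  carriers = list())
  class(empty) <- c("panfam_sv_regions", class(empty))
  attr(empty, "events") <- events
  if (nrow(events) == 0) return(empty)

  n <- nrow(events)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (events$type[i] != events$type[j]) next
      if (events$type[i] == "deletion") {
        ov <- min(events$ref_end[i], events$ref_end[j]) -
          max(events$ref_start[i], events$ref_start[j])
        if (ov > 0 &&
            ov / events$length[i] >= overlap_frac &&
            ov / events$length[j] >= overlap_frac) link(i, j)
      } else {
        if (abs(events$ref_start[i] - events$ref_start[j]) <= anchor_tol) {
          link(i, j)
        }
      }
    }
  }
  events$cluster <- vapply(seq_len(n), find, integer(1))
  regions <- events |>
    group_by(.data$cluster) |>
    summarise(
      type = .data$type[1],
      ref_start = min(.data$ref_start),
      ref_end = max(.data$ref_end),
      share_count = dplyr::n_distinct(.data$sample_id),
      len_min = min(.data$length),
      len_median = stats::median(.data$length),
      len_max = max(.data$length),
      carriers = list(sort(unique(.data$sample_id))),
      .groups = "drop"
    ) |>
    filter(.data$share_count >= min_share) |>
    arrange(.data$ref_start, .data$ref_end, .data$type) |>
    mutate(region_id = paste0("Region", row_number()))
  members <- events |>
    dplyr::inner_join(regions |> select("cluster", "region_id"),
                      by = "cluster") |>
    select(-"cluster")
  regions <- regions |>
    select("region_id", "type", "ref_start", "ref_end", "share_count",
           "len_min", "len_median", "len_max", "carriers")
  class(regions) <- c("panfam_sv_regions", class(regions))
  attr(regions, "events") <- members
  attr(regions, "min_share") <- min_share
  regions
}

#' Genotype all samples for the called SV regions
#'
#' @param regions A `panfam_sv_regions` tibble from [merge_shared_sv()].
#' @param samples Character vector: the full sample panel, including the
#'   reference (which is never a carrier — every SV is relative to it).
#' @return Tibble with `region_id` plus one logical column per sample.
#' @export
genotype_sv <- function(regions, samples) {
  samples <- as.character(samples)
  mat <- matrix(FALSE, nrow = nrow(regions), ncol = length(samples),
                dimnames = list(regions$region_id, samples))
  for (k in seq_len(nrow(regions))) {
    carr <- intersect(regions$carriers[[k]], samples)
    mat[k, carr] <- TRUE
  }
  out <- as_tibble(mat, rownames = "region_id")
  class(out) <- c("panfam_genotypes", class(out))
  out
}

#' Long-format genotype table
#'
#' @param genotypes Wide genotype tibble from [genotype_sv()].
#' @return Tibble `region_id`, `sample_id`, `present`.
#' @export
genotypes_long <- function(genotypes) {
  genotypes |>
    tidyr::pivot_longer(-"region_id", names_to = "sample_id",
                        values_to = "present")
}

#' Representative and per-carrier SV-region sequences
#'
#' For each region, returns the member-event sequences (inserted bases for
#' insertion regions, deleted reference bases for deletion regions); the
#' representative per region is the modal member sequence (ties broken by
#' sort order), suitable for motif scanning.
#'
#' @param regions A `panfam_sv_regions` tibble.
#' @param representative If `TRUE` (default), one row per region; otherwise
#'   one row per carrier event.
#' @return Tibble `region_id`, (`sample_id`,) `type`, `seq`.
#' @export
sv_region_sequences <- function(regions, representative = TRUE) {
  members <- attr(regions, "events")
  if (is.null(members) || nrow(members) == 0) {
    return(tibble(region_id = character(), type = character(),
                  seq = character()))
  }
  if (!representative) {
    return(members |>
             select("region_id", "sample_id", "type", "seq") |>
             arrange(.data$region_id, .data$sample_id))
  }
  members |>
    group_by(.data$region_id) |>
    summarise(
      type = .data$type[1],
      seq = names(sort(table(.data$seq), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    arrange(match(.data$region_id, regions$region_id))
}

#' Write SV regions as BED6
#'
#' Name is `RegionK_type`, score is the carrier count; insertion anchors are
#' written as 1-bp features so coordinates remain valid BED intervals.
#'
#' @param regions A `panfam_sv_regions` tibble.
#' @param path Output file.
#' @param chrom Chromosome/contig name for column 1 (default
#'   `"promoter_ref"`).
#' @return `path`, invisibly.
#' @export
write_sv_bed <- function(regions, path, chrom = "promoter_ref") {
  end <- ifelse(regions$ref_end > regions$ref_start,
                regions$ref_end, regions$ref_start + 1L)
  lines <- sprintf("%s\t%d\t%d\t%s_%s\t%d\t+",
                   chrom, regions$ref_start, end,
                   regions$region_id, regions$type, regions$share_count)
  writeLines(lines, path)
  invisible(path)
}
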