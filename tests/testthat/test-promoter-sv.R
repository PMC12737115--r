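test_that("upstream windows are strand-aware and edge-truncated", {
  genome <- Biostrings::DNAStringSet(c(chr1 = random_seq(9000, 1)))
  ann <- tibble::tibble(
    seqid = "chr1",
    start = c(5001L, 2001L, 1501L),   # 1-based GFF-style
    end = c(6000L, 3000L, 2500L),
    strand = c("+", "-", "+"),
    gene_id = c("plus_gene", "minus_gene", "edge_gene")
  )
  plus <- extract_upstream(genome, ann, "plus_gene", window = 2000)
  expect_equal(c(plus$start, plus$end), c(3000, 5000))
  expect_equal(plus$length, 2000)
  expect_equal(plus$seq,
               as.character(Biostrings::subseq(genome[["chr1"]], 3001, 5000)))

  minus <- extract_upstream(genome, ann, "minus_gene", window = 2000)
  expect_equal(c(minus$start, minus$end), c(3000, 5000))
  expect_equal(minus$seq, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[["chr1"]], 3001, 5000))))

  expect_warning(
    edge <- extract_upstream(genome, ann, "edge_gene", window = 2000),
    "truncated"
  )
  expect_equal(c(edge$start, edge$end), c(0, 1500))
  expect_equal(edge$length, 1500)

  expect_error(extract_upstream(genome, ann, "nope"), "not found")
  at_start <- tibble::tibble(seqid = "chr1", start = 1L, end = 100L,
                             strand = "+", gene_id = "g0")
  expect_error(extract_upstream(genome, at_start, "g0"), "empty upstream")
})

test_that("gap runs against the reference become typed indel events", {
  ref60 <- random_seq(60, 2)
  ref200 <- random_seq(200, 3)

  # 60-column deletion
  a1 <- aln(
    ref = paste0(ref200, ref60),
    s1 = paste0(substr(ref200, 1, 100), strrep("-", 60),
                substr(paste0(ref200, ref60), 161, 260))
  )
  ev <- detect_indels(a1, "ref", min_len = 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "deletion")
  expect_equal(c(ev$ref_start, ev$ref_end), c(100, 160))
  expect_equal(ev$length, 60)

  # 49-column run falls below the threshold
  a2 <- aln(
    ref = ref200,
    s1 = paste0(substr(ref200, 1, 100), strrep("-", 49),
                substr(ref200, 150, 200))
  )
  expect_equal(nrow(detect_indels(a2, "ref", min_len = 50)), 0)

  # 55-column insertion anchored after reference position 100
  ins <- random_seq(55, 4)
  a3 <- aln(
    ref = paste0(substr(ref200, 1, 100), strrep("-", 55),
                 substr(ref200, 101, 200)),
    s1 = paste0(substr(ref200, 1, 100), ins, substr(ref200, 101, 200))
  )
  ev3 <- detect_indels(a3, "ref", min_len = 50)
  expect_equal(ev3$type, "insertion")
  expect_equal(c(ev3$ref_start, ev3$ref_end), c(100, 100))
  expect_equal(ev3$length, 55)
  expect_equal(ev3$seq, ins)
})

test_that("terminal gaps are missing data and both-gap columns are transparent", {
  ref <- random_seq(300, 5)
  # leading and trailing gap runs are flanks, not deletions
  a <- aln(
    ref = ref,
    s1 = paste0(strrep("-", 80), substr(ref, 81, 220), strrep("-", 80))
  )
  expect_equal(nrow(detect_indels(a, "ref", min_len = 50)), 0)

  # a 60-col deletion split by 10 both-gap columns still merges: sample t
  # is deleted opposite ref bases 101-160, and a third row u carries an
  # unrelated insertion elsewhere creating both-gap columns for t
  ins <- random_seq(10, 6)
  ref_row <- paste0(substr(ref, 1, 130), strrep("-", 10),
                    substr(ref, 131, 300))
  t_row <- paste0(substr(ref, 1, 100), strrep("-", 30), strrep("-", 10),
                  strrep("-", 30), substr(ref, 161, 300))
  u_row <- paste0(substr(ref, 1, 130), ins, substr(ref, 131, 300))
  a2 <- aln(ref = ref_row, t = t_row, u = u_row)
  ev <- detect_indels(a2, "ref", min_len = 50)
  ev_t <- ev[ev$sample_id == "t", ]
  expect_equal(nrow(ev_t), 1)
  expect_equal(ev_t$type, "deletion")
  expect_equal(c(ev_t$ref_start, ev_t$ref_end), c(100, 160))

  expect_error(detect_indels(a, "absent"), "reference id")
  ragged <- c(ref = "ACGT", s1 = "ACG")
  expect_error(detect_indels(ragged, "ref"), "ragged")
})

test_that("shared-SV merging enforces carrier and overlap rules", {
  del_events <- function(samples, s, e) {
    tibble::tibble(sample_id = samples, type = "deletion",
                   ref_start = s, ref_end = e, length = e - s,
                   col_start = s + 1L, col_end = e,
                   seq = strrep("A", e - s))
  }
  five <- del_events(paste0("s", 1:5), 400L, 460L)
  reg <- merge_shared_sv(five, min_share = 5)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$type, "deletion")
  expect_equal(reg$share_count, 5)

  ins4 <- tibble::tibble(sample_id = paste0("s", 1:4), type = "insertion",
                         ref_start = 700L, ref_end = 700L, length = 80L,
                         col_start = 1L, col_end = 80L,
                         seq = strrep("C", 80))
  expect_equal(nrow(merge_shared_sv(ins4, min_share = 5)), 0)

  two_clusters <- dplyr::bind_rows(
    del_events(paste0("a", 1:6), 1500L, 1570L),
    del_events(paste0("b", 1:6), 100L, 160L)
  )
  regs <- merge_shared_sv(two_clusters, min_share = 5)
  expect_equal(regs$region_id, c("Region1", "Region2"))
  expect_equal(regs$ref_start, c(100L, 1500L))

  # reciprocal overlap below 0.5 does not link
  apart <- dplyr::bind_rows(
    del_events(paste0("a", 1:3), 100L, 200L),
    del_events(paste0("b", 1:3), 180L, 280L)   # overlap 20/100 = 0.2
  )
  expect_equal(nrow(merge_shared_sv(apart, min_share = 5)), 0)
  linked <- dplyr::bind_rows(
    del_events(paste0("a", 1:3), 100L, 200L),
    del_events(paste0("b", 1:3), 140L, 240L)   # overlap 60/100 = 0.6
  )
  expect_equal(merge_shared_sv(linked, min_share = 5)$share_count, 6)

  # mixed types never merge even when coordinates coincide
  mixed <- dplyr::bind_rows(
    del_events(paste0("a", 1:3), 100L, 160L),
    tibble::tibble(sample_id = paste0("b", 1:3), type = "insertion",
                   ref_start = 120L, ref_end = 120L, length = 60L,
                   col_start = 1L, col_end = 60L, seq = strrep("G", 60))
  )
  expect_equal(nrow(merge_shared_sv(mixed, min_share = 5)), 0)
})

test_that("genotyping marks carriers and never the reference", {
  ev <- tibble::tibble(sample_id = letters[1:5], type = "deletion",
                       ref_start = 10L, ref_end = 70L, length = 60L,
                       col_start = 11L, col_end = 70L,
                       seq = strrep("T", 60))
  reg <- merge_shared_sv(ev, min_share = 5)
  gt <- genotype_sv(reg, samples = c(letters[1:10], "ref"))
  row <- unlist(gt[1, letters[1:10]])
  expect_equal(sum(row), 5)
  expect_false(gt$ref[1])

  empty <- merge_shared_sv(ev[0, ], min_share = 5)
  expect_equal(nrow(genotype_sv(empty, letters[1:3])), 0)
})

test_that("the caller agrees exactly with a naive per-column oracle", {
  set.seed(21)
  for (rep in 1:8) {
    fx <- make_promoters(
      n_samples = 6, ref_len = 120,
      planted = tibble::tibble(
        type = sample(c("deletion", "insertion"), 2),
        position = c(20L, 70L),
        length = c(15L, 20L),
        carriers = list(3L, 4L)
      ),
      background_sub_rate = 0.02, seed = 300 + rep
    )
    expect_lte(max(nchar(fx$alignment)), 200)
    got <- detect_indels(fx$alignment, "ref", min_len = 10)
    want <- oracle_sv_events(fx$alignment, "ref", min_len = 10)
    got_df <- as.data.frame(got[, c("sample_id", "type", "ref_start",
                                    "ref_end", "length")])
    rownames(got_df) <- NULL
    rownames(want) <- NULL
    expect_equal(got_df, want)
  }
})

test_that("planted SVs are recovered as exactly one region each", {
  fx <- five_sv_promoters(seed = 101)
  ev <- detect_indels(fx$alignment, "B73like", min_len = 50)
  reg <- merge_shared_sv(ev, min_share = 5)
  expect_equal(nrow(reg), 5)
  expect_equal(reg$type,
               c("deletion", "insertion", "insertion", "deletion",
                 "insertion"))
  truth <- fx$truth$planted
  for (k in seq_along(truth)) {
    t <- truth[[k]]
    r <- reg[k, ]
    if (t$type == "deletion") {
      ov <- min(r$ref_end, t$position + t$length) - max(r$ref_start, t$position)
      expect_gte(ov / t$length, 0.9)
    } else {
      expect_equal(r$ref_start, t$position)
    }
    expect_setequal(r$carriers[[1]], t$carriers)
  }
  # thresholds are respected in every emitted object
  expect_true(all(attr(reg, "events")$length >= 50))
  expect_true(all(reg$share_count >= 5))

  # substitution-only backgrounds yield no events at all
  clean <- make_promoters(n_samples = 8, ref_len = 400, planted = NULL,
                          background_sub_rate = 0.02, seed = 9)
  expect_equal(nrow(detect_indels(clean$alignment, "ref", min_len = 50)), 0)
})

test_that("detection is invariant to sample order and numbering is positional", {
  fx <- five_sv_promoters(seed = 202)
  shuffled <- fx$alignment[c(1, rev(seq_along(fx$alignment))[-length(fx$alignment)])]
  ev1 <- detect_indels(fx$alignment, "B73like", min_len = 50)
  ev2 <- detect_indels(shuffled, "B73like", min_len = 50)
  key <- function(e) e[order(e$sample_id, e$ref_start, e$type),
                       c("sample_id", "type", "ref_start", "ref_end")]
  expect_equal(as.data.frame(key(ev1)), as.data.frame(key(ev2)),
               ignore_attr = TRUE)
  r1 <- merge_shared_sv(ev1)
  r2 <- merge_shared_sv(ev2)
  expect_equal(r1$ref_start, r2$ref_start)
  expect_equal(r1$region_id, r2$region_id)
})

test_that("BED export writes one valid line per region", {
  fx <- five_sv_promoters(seed = 101)
  reg <- merge_shared_sv(detect_indels(fx$alignment, "B73like"), min_share = 5)
  path <- tempfile(fileext = ".bed")
  write_sv_bed(reg, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(nrow(bed), 5)
  expect_true(all(bed$V3 > bed$V2))
  expect_equal(bed$V5, reg$share_count)
})
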