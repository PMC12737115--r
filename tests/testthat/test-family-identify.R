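test_that("domtblout rows parse with profile-based coverage", {
  path <- write_domtbl_fixture(
    domtblout_line("gA|g1", 2e-30, qlen = 200, hmm_from = 10, hmm_to = 180)
  )
  hits <- parse_domtblout(path)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$genome_id, "gA")
  expect_equal(hits$gene_id, "g1")
  expect_equal(hits$full_seq_evalue, 2e-30)
  expect_equal(hits$coverage, 171 / 200)
})

test_that("comment-only files parse to an empty hit table", {
  path <- write_domtbl_fixture(character(0),
                               comments = c("# header", "# another"))
  hits <- parse_domtblout(path)
  expect_equal(nrow(hits), 0)
})

test_that("malformed rows raise errors naming the line", {
  bad <- domtblout_line("gA|g1", 1e-10, 200, 10, 180)
  bad <- sub("1e-10", "NA", bad, fixed = TRUE)
  path <- tempfile()
  writeLines(bad, path)
  expect_error(parse_domtblout(path), "line 1")
  expect_error(parse_domtblout(tempfile()), "not found")
})

test_that("filtering applies both thresholds as strict inequalities", {
  hits <- dplyr::bind_rows(
    tibble::tibble(genome_id = "gA", gene_id = "keep", profile_id = "P",
                   full_seq_evalue = 1e-6, profile_len = 100L,
                   hmm_from = 11L, hmm_to = 90L, ali_from = 11L,
                   ali_to = 90L),           # coverage 0.80
    tibble::tibble(genome_id = "gA", gene_id = "bad_evalue", profile_id = "P",
                   full_seq_evalue = 1e-4, profile_len = 100L,
                   hmm_from = 1L, hmm_to = 95L, ali_from = 1L,
                   ali_to = 95L),           # coverage 0.95
    tibble::tibble(genome_id = "gA", gene_id = "bad_coverage", profile_id = "P",
                   full_seq_evalue = 1e-9, profile_len = 100L,
                   hmm_from = 16L, hmm_to = 85L, ali_from = 16L,
                   ali_to = 85L)            # coverage exactly 0.70
  ) |> dplyr::mutate(coverage = (hmm_to - hmm_from + 1) / profile_len)
  members <- filter_hits(hits)
  expect_equal(members$gene_id, "keep")

  # boundary cases: equality never passes
  at_evalue <- hits[1, ]
  at_evalue$full_seq_evalue <- 1e-5
  expect_equal(nrow(filter_hits(at_evalue)), 0)
})

test_that("duplicate qualifying domains collapse to one membership", {
  hit <- tibble::tibble(genome_id = "gA", gene_id = "g1", profile_id = "P",
                        full_seq_evalue = 1e-10, profile_len = 100L,
                        hmm_from = 1L, hmm_to = 90L, ali_from = 1L,
                        ali_to = 90L, coverage = 0.90)
  members <- filter_hits(dplyr::bind_rows(hit, hit, hit))
  expect_equal(nrow(members), 1)
})

test_that("filtering is monotone in both thresholds", {
  pg <- make_pangenome(n_genomes = 6, counts = c(2, 0, 2, 1), seed = 42)
  base <- filter_hits(pg$hits, evalue_max = 1e-5, min_coverage = 0.70)
  for (ev in c(1e-8, 1e-15, 1e-30)) {
    tighter <- filter_hits(pg$hits, evalue_max = ev, min_coverage = 0.70)
    expect_true(all(paste(tighter$genome_id, tighter$gene_id) %in%
                      paste(base$genome_id, base$gene_id)))
  }
  for (cov in c(0.8, 0.9, 0.99)) {
    tighter <- filter_hits(pg$hits, evalue_max = 1e-5, min_coverage = cov)
    expect_true(all(paste(tighter$genome_id, tighter$gene_id) %in%
                      paste(base$genome_id, base$gene_id)))
  }
})

test_that("pan-gene clustering follows single linkage on identity", {
  members <- tibble::tibble(genome_id = c("gA", "gB"),
                            gene_id = c("x", "y"))
  prot <- paste(rep("MKVLAT", 20), collapse = "")
  proteins <- c("gA|x" = prot, "gB|y" = prot)
  pan <- cluster_pan_genes(members, proteins)
  expect_equal(dplyr::n_distinct(pan$pan_gene_id), 1)

  set.seed(9)
  unrelated <- c("gA|x" = prot,
                 "gB|y" = paste(sample(c("A", "D", "E", "R", "W", "P"), 120,
                                       replace = TRUE), collapse = ""))
  pan2 <- cluster_pan_genes(members, unrelated)
  expect_equal(dplyr::n_distinct(pan2$pan_gene_id), 2)
})

test_that("a chain A~B~C joins one pan-gene even when A~C is below threshold", {
  # 100-aa base; B differs from A by 5, C from B by 5, A from C by 10:
  # identities 0.95, 0.95, 0.90 are all >= 0.90... push A~C to 0.88
  base <- strsplit(paste(rep("MKVLATSEQG", 10), collapse = ""), "")[[1]]
  b <- base; b[1:6] <- "W"
  c_ <- b; c_[7:12] <- "Y"
  members <- tibble::tibble(genome_id = c("g1", "g2", "g3"),
                            gene_id = c("a", "b", "c"))
  proteins <- c("g1|a" = paste(base, collapse = ""),
                "g2|b" = paste(b, collapse = ""),
                "g3|c" = paste(c_, collapse = ""))
  # verify the intended identity structure with an independent measure
  ident <- function(x, y) 1 - utils::adist(x, y) / max(nchar(x), nchar(y))
  expect_gte(ident(proteins[1], proteins[2]), 0.90)
  expect_gte(ident(proteins[2], proteins[3]), 0.90)
  expect_lt(ident(proteins[1], proteins[3]), 0.90)

  pan <- cluster_pan_genes(members, proteins)
  expect_equal(dplyr::n_distinct(pan$pan_gene_id), 1)
})

test_that("clustering is invariant to input order and needs every sequence", {
  pg <- make_pangenome(n_genomes = 5, counts = c(2, 0, 1, 1), seed = 5)
  members <- filter_hits(pg$hits)
  fwd <- cluster_pan_genes(members, pg$proteins)
  rev_members <- members[rev(seq_len(nrow(members))), ]
  bwd <- cluster_pan_genes(rev_members, pg$proteins)
  expect_equal(fwd, bwd)

  expect_error(
    cluster_pan_genes(members, pg$proteins[-1]),
    "no protein sequence"
  )
})

test_that("an external pan-gene map bypasses clustering", {
  map <- tibble::tibble(pan_gene_id = c("p1", "p1"),
                        genome_id = c("gA", "gB"),
                        gene_id = c("x", "y"))
  out <- cluster_pan_genes(NULL, NULL, pan_map = map)
  expect_equal(out, map)
  dup <- dplyr::bind_rows(map, tibble::tibble(pan_gene_id = "p2",
                                              genome_id = "gA",
                                              gene_id = "x"))
  expect_error(cluster_pan_genes(NULL, NULL, pan_map = dup),
               "more than one pan-gene")
})

test_that("synthetic domtblout files round-trip through the parser", {
  pg <- make_pangenome(n_genomes = 4, counts = c(1, 0, 1, 1), seed = 8)
  path <- tempfile(fileext = ".domtblout")
  write_domtblout(pg$hits, path)
  back <- parse_domtblout(path)
  expect_equal(back$genome_id, pg$hits$genome_id)
  expect_equal(back$gene_id, pg$hits$gene_id)
  expect_equal(back$hmm_from, pg$hits$hmm_from)
  expect_equal(back$hmm_to, pg$hits$hmm_to)
  expect_equal(back$coverage, pg$hits$coverage)
  # E-values survive at the printed precision
  expect_equal(back$full_seq_evalue, pg$hits$full_seq_evalue,
               tolerance = 1e-3)
})
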