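meme_fixture <- function(background = TRUE) {
  path <- tempfile(fileext = ".meme")
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", ""
  )
  if (background) {
    lines <- c(lines, "Background letter frequencies",
               "A 0.30 C 0.20 G 0.20 T 0.30", "")
  }
  lines <- c(lines,
    "MOTIF M1 testfam",
    "letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0",
    " 0.90 0.03 0.03 0.04",
    " 0.03 0.90 0.03 0.04",
    " 0.03 0.03 0.90 0.04",
    " 0.04 0.03 0.03 0.90",
    " 0.90 0.03 0.03 0.04",
    " 0.25 0.25 0.25 0.25",
    " 0.03 0.90 0.03 0.04",
    " 0.03 0.03 0.90 0.04",
    ""
  )
  writeLines(lines, path)
  path
}

test_that("MEME minimal files parse to normalized PWMs", {
  m <- read_meme_motifs(meme_fixture())
  expect_length(m, 1)
  expect_equal(m[[1]]$width, 8)
  expect_equal(m[[1]]$family, "testfam")
  expect_equal(unname(m[[1]]$background),
               c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(rowSums(m[[1]]$probs)), rep(1, 8), tolerance = 1e-9)

  nobg <- read_meme_motifs(meme_fixture(background = FALSE))
  expect_equal(unname(nobg[[1]]$background), rep(0.25, 4))

  # a row not summing to 1 still normalizes after the pseudocount
  path <- tempfile()
  writeLines(c("MEME version 4", "", "MOTIF M2",
               "letter-probability matrix: alength= 4 w= 4",
               " 0.5 0.2 0.1 0.1",
               " 0.25 0.25 0.25 0.25",
               " 1 0 0 0",
               " 0 0 0.4 0.5", ""), path)
  m2 <- read_meme_motifs(path)
  expect_equal(unname(rowSums(m2[[1]]$probs)), rep(1, 4), tolerance = 1e-9)

  bad <- tempfile()
  writeLines(c("MEME version 4", "", "MOTIF broken",
               "letter-probability matrix: alength= 4 w= 2",
               " 0.5 0.5 0.0", " 0.25 0.25 0.25 0.25"), bad)
  expect_error(read_meme_motifs(bad), "broken")
})

test_that("consensus PWMs place match_prob on the site base", {
  for (site in c("GAGATTCTGA", "GCATGTGC", "TTGTCATCAGCAACA",
                 "GCACATGC", "CCTCTGCCTTCTTCATGGCCA")) {
    pwm <- consensus_pwm(site)
    expect_equal(pwm$width, nchar(site))
    chars <- strsplit(site, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    expect_equal(unname(pwm$probs[cbind(seq_along(chars), idx)]),
                 rep(0.95, nchar(site)))
  }
  p4 <- consensus_pwm("ACGT")
  expect_equal(unname(diag(p4$probs)), rep(0.95, 4))
  expect_error(consensus_pwm("ACGN"), "non-ACGT")
})

test_that("DP p-values equal brute-force enumeration at the discretization", {
  set.seed(31)
  for (rep in 1:6) {
    w <- sample(4:6, 1)
    probs <- matrix(stats::rgamma(4 * w, 1), ncol = 4)
    probs <- probs / rowSums(probs)
    pwm <- panfam:::new_pwm("rand", "", probs,
                            c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), 0)
    tab <- pwm_pvalues(pwm)
    probe <- tab$score_int[seq(1, nrow(tab), length.out = min(12, nrow(tab)))]
    expect_equal(tab$p_value[match(probe, tab$score_int)],
                 unname(oracle_pwm_pvalue(pwm, probe)),
                 tolerance = 1e-12)
  }
})

test_that("p-values are monotone and thresholds behave set-wise", {
  pwm <- consensus_pwm("GCATGTGC")
  tab <- pwm_pvalues(pwm)
  expect_true(all(diff(tab$p_value) <= 1e-15))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))

  seq <- random_seq(400, 41)
  loose <- scan_sequence(seq, pwm, p_max = 1e-2)
  tight <- scan_sequence(seq, pwm, p_max = 1e-4)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("planted site strings are recovered at their planted offsets", {
  sites <- c("GCATGTGC", "GCACATGC", "CCTCTGCCTTCTTCATGGCCA",
             "GAGATTCTGA", "TTGTCATCAGCAACA")
  for (k in seq_along(sites)) {
    bg <- random_seq(200, 50 + k)
    planted <- plant_motifs(bg, tibble::tibble(site = sites[k], offset = 40))
    hits <- scan_sequence(planted$seq, consensus_pwm(sites[k]),
                          p_max = 1e-4)
    expect_true(40 %in% hits$start[hits$strand == "+"])
  }
})

test_that("reverse-strand hits mirror forward hits on the reverse complement", {
  pwm <- consensus_pwm("TTGTCATCAGCAACA")
  seq <- plant_motifs(random_seq(150, 77),
                      tibble::tibble(site = "TTGTCATCAGCAACA",
                                     offset = 60))$seq
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_sequence(seq, pwm, p_max = 1e-4)
  rev <- scan_sequence(rc, pwm, p_max = 1e-4)
  f_plus <- fwd[fwd$strand == "+", ]
  r_minus <- rev[rev$strand == "-", ]
  expect_equal(nrow(f_plus), nrow(r_minus))
  expect_setequal(nchar(seq) - pwm$width - f_plus$start, r_minus$start)
  expect_equal(sort(f_plus$p_value), sort(r_minus$p_value))
})

test_that("a background-identical PWM produces no hits", {
  flat <- panfam:::new_pwm("flat", "", matrix(0.25, nrow = 6, ncol = 4),
                           c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), 0)
  hits <- scan_sequence(random_seq(300, 99), flat, p_max = 1e-4)
  expect_equal(nrow(hits), 0)
})

test_that("non-ACGT windows are skipped, not fatal", {
  pwm <- consensus_pwm("GCATGTGC")
  seq <- paste0(substr(random_seq(60, 13), 1, 30), "NNNN",
                plant_motifs(random_seq(60, 14),
                             tibble::tibble(site = "GCATGTGC",
                                            offset = 10))$seq)
  expect_message(hits <- scan_sequence(seq, pwm, p_max = 1e-4), "non-ACGT")
  expect_true(any(hits$strand == "+"))
})

test_that("region annotation lists families and reports no-hit regions", {
  motifs <- list(consensus_pwm("GCATGTGC", family = "ERF"),
                 consensus_pwm("GCACATGC", family = "bHLH"))
  r1 <- plant_motifs(random_seq(120, 61),
                     tibble::tibble(site = c("GCATGTGC", "GCACATGC"),
                                    offset = c(20, 60)))$seq
  r2 <- random_seq(120, 62)
  ann <- annotate_sv_regions(
    tibble::tibble(region_id = c("Region1", "Region3"), seq = c(r1, r2)),
    motifs, p_max = 1e-4
  )
  fams <- ann$annotation$family[ann$annotation$region_id == "Region1"]
  expect_setequal(fams, c("ERF", "bHLH"))
  r3 <- ann$annotation[ann$annotation$region_id == "Region3", ]
  expect_equal(r3$n_hits, 0L)

  empty <- annotate_sv_regions(tibble::tibble(region_id = character(),
                                              seq = character()), motifs)
  expect_equal(nrow(empty$annotation), 0)
})

test_that("motif libraries round-trip through MEME serialization", {
  motifs <- list(consensus_pwm("GAGATTCTGA", family = "G2-like"),
                 consensus_pwm("TTGTCATCAGCAACA", family = "GATA"))
  path <- tempfile(fileext = ".meme")
  write_meme_motifs(motifs, path)
  back <- read_meme_motifs(path, pseudocount = 0)
  expect_equal(back[[1]]$width, 10)
  expect_equal(back[[2]]$family, "GATA")
  expect_equal(back[[1]]$probs, motifs[[1]]$probs, tolerance = 1e-5)
})
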