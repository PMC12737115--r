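# Pairwise Ka/Ks estimation: Nei-Gojobori (NG86) counting with Jukes-Cantor
# correction, and an approximate Yang-Nielsen (YN) estimator with F3x4
# codon frequencies, kappa-weighted site counting and K80-style corrections
# applied separately to the synonymous and nonsynonymous classes.

CODON_CHARS <- do.call(rbind, strsplit(CODONS, ""))

# Enumerate mutational pathways between two codons. Each path is one
# ordering of the differing positions; a path is valid when no intermediate
# codon is a stop. Returns per-path logical step vectors (synonymous?,
# transition?). Memoised: at most 64*64 pairs ever occur.
.path_cache <- new.env(parent = emptyenv())

codon_paths <- function(i, j) {
  key <- paste0(i, "_", j)
  hit <- .path_cache[[key]]
  if (!is.null(hit)) return(hit)
  diffs <- which(CODON_CHARS[i, ] != CODON_CHARS[j, ])
  perms <- switch(as.character(length(diffs)),
    "0" = list(),
    "1" = list(diffs),
    "2" = list(diffs, rev(diffs)),
    "3" = {
      p <- list()
      for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
        if (length(unique(c(a, b, cc))) == 3) {
          p[[length(p) + 1]] <- diffs[c(a, b, cc)]
        }
      }
      p
    }
  )
  build <- function(order, allow_stop) {
    cur <- i
    syn <- logical(length(order))
    ts <- logical(length(order))
    for (k in seq_along(order)) {
      p <- order[k]
      b <- match(CODON_CHARS[j, p], BASES)
      nxt <- MUT_TABLES$target[cur, p, b]
      ts[k] <- MUT_TABLES$ts[cur, p, b]
      aa_cur <- GENETIC_CODE_STD[cur]
      aa_nxt <- GENETIC_CODE_STD[nxt]
      if (aa_nxt == "*" && k < length(order) && !allow_stop) return(NULL)
      syn[k] <- aa_cur == aa_nxt && aa_cur != "*"
      cur <- nxt
    }
    list(syn = syn, ts = ts)
  }
  paths <- purrr::compact(map(perms, build, allow_stop = FALSE))
  if (length(paths) == 0 && length(perms) > 0) {
    # all orderings pass through a stop codon: fall back to counting them,
    # with stop-involving steps classified as nonsynonymous
    paths <- purrr::compact(map(perms, build, allow_stop = TRUE))
  }
  res <- list(ndiff = length(diffs), paths = paths)
  .path_cache[[key]] <- res
  res
}

kaks_result <- function(method, n_codons, N, S, Nd, Sd, Ka, Ks, omega,
                        kappa = NA_real_, flags = "") {
  out <- tibble(
    method = method, n_codons = n_codons,
    N = N, S = S, Nd = Nd, Sd = Sd,
    Ka = Ka, Ks = Ks, omega = omega, kappa = kappa, flags = flags
  )
  class(out) <- c("panfam_kaks", class(out))
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# K80 distance from transition proportion P and transversion proportion Q
k80_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous site fractions come from exhaustive enumeration of the nine
#' single-nucleotide changes per codon (changes to stop codons excluded from
#' numerator and denominator), averaged over the two sequences. Codons
#' differing at 2-3 positions contribute pathway-averaged synonymous and
#' nonsynonymous difference counts, all mutational orderings weighted
#' equally and orderings passing through a stop codon excluded. Proportions
#' are Jukes-Cantor corrected; a proportion at or beyond the correction
#' domain (p >= 0.75) leaves the corresponding rate undefined with a
#' `"saturated"` flag.
#'
#' @param aln A `codon_alignment`, or a codon sequence given with `seq_b`.
#' @param seq_b Optional second sequence when `aln` is a character string.
#' @return A one-row `panfam_kaks` tibble: `method`, `n_codons`, `N`, `S`,
#'   `Nd`, `Sd`, `Ka`, `Ks`, `omega`, `kappa` (NA for NG86), `flags`.
#'   `omega` is `NA` when `Ks` is undefined or zero.
#' @examples
#' kaks_ng86("TTTAAAGGG", "TTCAAAGGG")
#' @export
kaks_ng86 <- function(aln, seq_b = NULL) {
  aln <- as_codon_alignment(aln, seq_b)
  ia <- codon_index(split_codons(aln$seq_a))
  ib <- codon_index(split_codons(aln$seq_b))
  L <- length(ia)
  if (L == 0) abort("empty codon alignment")
  if (any(GENETIC_CODE_STD[ia] == "*") || any(GENETIC_CODE_STD[ib] == "*")) {
    abort("internal stop codon in codon alignment")
  }
  S <- (sum(NG86_SYN_FRAC[ia, , drop = FALSE]) +
          sum(NG86_SYN_FRAC[ib, , drop = FALSE])) / 2
  N <- 3 * L - S

  Sd <- 0; Nd <- 0
  for (k in which(ia != ib)) {
    pp <- codon_paths(ia[k], ib[k])
    sd_k <- mean(map_dbl(pp$paths, ~sum(.x$syn)))
    Sd <- Sd + sd_k
    Nd <- Nd + (pp$ndiff - sd_k)
  }
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  flags <- if (is.na(Ka) || is.na(Ks)) "saturated" else ""
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  kaks_result("NG86", L, N, S, Nd, Sd, Ka, Ks, omega, flags = flags)
}

# F3x4 position-specific base frequencies of the pair, lightly regularised
# so absent bases keep a small positive weight
f3x4_freqs <- function(ia, ib) {
  f <- matrix(0.5, nrow = 3, ncol = 4, dimnames = list(NULL, BASES))
  for (p in 1:3) {
    tab <- table(factor(c(CODON_CHARS[ia, p], CODON_CHARS[ib, p]),
                        levels = BASES))
    f[p, ] <- f[p, ] + as.numeric(tab)
  }
  f / rowSums(f)
}

# kappa from K80-corrected ts/tv proportions at fourfold-degenerate and
# nondegenerate codon positions (site class shared by both sequences)
estimate_kappa <- function(ia, ib) {
  ts_d <- c(`0` = 0, `4` = 0); tv_d <- c(`0` = 0, `4` = 0)
  Lcl <- c(`0` = 0, `4` = 0)
  for (p in 1:3) {
    da <- CODON_DEGENERACY[ia, p]
    db <- CODON_DEGENERACY[ib, p]
    for (cls in c(0L, 3L)) {           # 3 synonymous changes = fourfold
      key <- if (cls == 0L) "0" else "4"
      at <- which(da == cls & db == cls)
      Lcl[key] <- Lcl[key] + length(at)
      if (length(at) > 0) {
        ba <- CODON_CHARS[ia[at], p]
        bb <- CODON_CHARS[ib[at], p]
        d <- ba != bb
        if (any(d)) {
          tsv <- is_transition(ba[d], bb[d])
          ts_d[key] <- ts_d[key] + sum(tsv)
          tv_d[key] <- tv_d[key] + sum(!tsv)
        }
      }
    }
  }
  if (sum(Lcl) == 0 || sum(ts_d) + sum(tv_d) == 0) return(1)
  AB <- function(key) {
    L <- Lcl[[key]]
    if (L == 0) return(c(A = NA_real_, B = NA_real_, L = 0))
    P <- ts_d[[key]] / L
    Q <- tv_d[[key]] / L
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) return(c(A = NA_real_, B = NA_real_, L = L))
    A <- -0.5 * log(w1) + 0.25 * log(w2)   # transition distance
    B <- -0.5 * log(w2)                    # transversion distance
    c(A = A, B = B, L = L)
  }
  cls <- rbind(AB("4"), AB("0"))
  ok <- !is.na(cls[, "A"]) & cls[, "L"] > 0
  if (!any(ok)) return(1)
  A <- sum(cls[ok, "A"] * cls[ok, "L"]) / sum(cls[ok, "L"])
  B <- sum(cls[ok, "B"] * cls[ok, "L"]) / sum(cls[ok, "L"])
  if (!is.finite(A) || !is.finite(B) || B <= 0 || A <= 0) return(1)
  min(max(2 * A / B, 0.1), 99)
}

# kappa- and frequency-weighted synonymous site fraction per codon
yn_site_fracs <- function(kappa, freqs) {
  sfrac <- matrix(NA_real_, nrow = 64, ncol = 3)
  for (i in seq_len(64)) {
    if (GENETIC_CODE_STD[i] == "*") next
    for (p in 1:3) {
      syn <- MUT_TABLES$syn[i, p, ]
      ts <- MUT_TABLES$ts[i, p, ]
      w <- ifelse(ts, kappa, 1) * freqs[p, ]
      valid <- !is.na(syn)
      tot <- sum(w[valid])
      sfrac[i, p] <- if (tot > 0) sum(w[valid][syn[valid]]) / tot else 0
    }
  }
  sfrac
}

#' Approximate Yang-Nielsen (YN) Ka/Ks for a codon alignment
#'
#' An approximate counting estimator in the style of Yang & Nielsen (2000):
#' position-specific nucleotide frequencies (F3x4) of the pair weight
#' mutation targets; the transition/transversion ratio kappa is estimated
#' from K80-corrected difference proportions at fourfold-degenerate and
#' nondegenerate codon positions; synonymous/nonsynonymous site counts are
#' kappa- and frequency-weighted; multi-hit codons are resolved by weighting
#' each mutational ordering by kappa^(transitions) * omega^(nonsynonymous
#' steps); and K80-style corrections are applied separately to the
#' synonymous and nonsynonymous difference classes. The difference counting
#' is iterated on omega until Ka and Ks change by less than `tol`.
#'
#' @inheritParams kaks_ng86
#' @param tol Convergence tolerance on Ka and Ks (default 1e-6).
#' @param max_iter Iteration cap (default 100); hitting it flags the result
#'   `"nonconverged"` and returns the last iterate.
#' @return A one-row `panfam_kaks` tibble (see [kaks_ng86()]), with the
#'   estimated `kappa`. Fewer than 30 codons triggers a warning.
#' @export
kaks_yn <- function(aln, seq_b = NULL, tol = 1e-6, max_iter = 100) {
  aln <- as_codon_alignment(aln, seq_b)
  ia <- codon_index(split_codons(aln$seq_a))
  ib <- codon_index(split_codons(aln$seq_b))
  L <- length(ia)
  if (L == 0) abort("empty codon alignment")
  if (L < 30) {
    warn(paste0("YN estimation on ", L,
                " codons; fewer than 30 codons gives unstable estimates"))
  }
  if (any(GENETIC_CODE_STD[ia] == "*") || any(GENETIC_CODE_STD[ib] == "*")) {
    abort("internal stop codon in codon alignment")
  }
  freqs <- f3x4_freqs(ia, ib)
  kappa <- estimate_kappa(ia, ib)
  sfrac <- yn_site_fracs(kappa, freqs)
  S <- (sum(sfrac[ia, , drop = FALSE]) + sum(sfrac[ib, , drop = FALSE])) / 2
  N <- 3 * L - S

  diff_idx <- which(ia != ib)
  if (length(diff_idx) == 0) {
    return(kaks_result("YN", L, N, S, 0, 0, 0, 0, NA_real_, kappa = kappa))
  }
  path_info <- map(diff_idx, ~codon_paths(ia[.x], ib[.x]))

  count_diffs <- function(omega) {
    acc <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
    for (pp in path_info) {
      w <- map_dbl(pp$paths, function(pt) {
        prod(ifelse(pt$ts, kappa, 1)) * omega^sum(!pt$syn)
      })
      w <- w / sum(w)
      for (k in seq_along(pp$paths)) {
        pt <- pp$paths[[k]]
        acc["sd_ts"] <- acc["sd_ts"] + w[k] * sum(pt$syn & pt$ts)
        acc["sd_tv"] <- acc["sd_tv"] + w[k] * sum(pt$syn & !pt$ts)
        acc["nd_ts"] <- acc["nd_ts"] + w[k] * sum(!pt$syn & pt$ts)
        acc["nd_tv"] <- acc["nd_tv"] + w[k] * sum(!pt$syn & !pt$ts)
      }
    }
    acc
  }

  omega <- 1
  Ka_prev <- Inf; Ks_prev <- Inf
  flags <- character(0)
  Ka <- NA_real_; Ks <- NA_real_
  d <- count_diffs(omega)
  for (iter in seq_len(max_iter)) {
    Ks <- k80_distance(d[["sd_ts"]] / S, d[["sd_tv"]] / S)
    Ka <- k80_distance(d[["nd_ts"]] / N, d[["nd_tv"]] / N)
    if (is.na(Ka) || is.na(Ks)) {
      flags <- c(flags, "saturated")
      break
    }
    if (abs(Ka - Ka_prev) < tol && abs(Ks - Ks_prev) < tol) break
    Ka_prev <- Ka; Ks_prev <- Ks
    omega <- if (Ks > 0 && Ka >= 0) max(Ka / Ks, 1e-4) else 1
    if (iter == max_iter) flags <- c(flags, "nonconverged")
    d <- count_diffs(omega)
  }
  Sd <- d[["sd_ts"]] + d[["sd_tv"]]
  Nd <- d[["nd_ts"]] + d[["nd_tv"]]
  omega_out <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  kaks_result("YN", L, N, S, Nd, Sd, Ka, Ks, omega_out, kappa = kappa,
              flags = paste(unique(flags), collapse = ","))
}

#' Estimate Ka/Ks for every haplotype pair within each pan-gene
#'
#' All-vs-all pairing of the haplotypes (per-genome CDS copies) of each
#' pan-gene: each pair is protein-aligned, back-translated and passed to the
#' chosen estimator.
#'
#' @param cds Tibble with columns `gene_id`, `genome_id`, `cds` (one CDS per
#'   haplotype), e.g. read with [read_cds_fasta()].
#' @param method `"YN"` (default) or `"NG86"`.
#' @return Tibble of pairwise estimates: `gene_id`, `genome_a`, `genome_b`
#'   plus the [kaks_ng86()] columns.
#' @export
kaks_all_pairs <- function(cds, method = c("YN", "NG86")) {
  method <- match.arg(method)
  est_fun <- if (method == "YN") {
    function(a) suppressWarnings(kaks_yn(a))
  } else {
    kaks_ng86
  }
  res <- cds |>
    group_by(.data$gene_id) |>
    group_split() |>
    map(function(g) {
      n <- nrow(g)
      if (n < 2) return(NULL)
      pairs <- utils::combn(n, 2)
      map(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        aln <- align_codon_pair(g$cds[i], g$cds[j],
                                id_a = g$genome_id[i], id_b = g$genome_id[j])
        est_fun(aln) |>
          mutate(gene_id = g$gene_id[1],
                 genome_a = g$genome_id[i], genome_b = g$genome_id[j])
      }) |> bind_rows()
    }) |>
    bind_rows()
  if (nrow(res) == 0) {
    return(tibble(gene_id = character(), genome_a = character(),
                  genome_b = character()))
  }
  res |> select("gene_id", "genome_a", "genome_b", dplyr::everything())
}

#' Read per-haplotype CDS sequences from FASTA
#'
#' Headers follow the `genome_id|gene_id` convention.
#'
#' @param path FASTA file of CDS sequences.
#' @return Tibble `gene_id`, `genome_id`, `cds`.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 2)
  tibble(gene_id = parts[, 2], genome_id = parts[, 1],
         cds = as.character(seqs))
}

#' Summarise per-gene positive-selection signal
#'
#' Genes represented by fewer than `min_haplotypes` haplotypes cannot be
#' paired and are excluded (and listed in the `"excluded"` attribute); pairs
#' with undefined omega (saturated, or Ks = 0) are excluded from the
#' proportion denominator.
#'
#' @param estimates Pairwise estimate table from [kaks_all_pairs()].
#' @param haplotype_counts Optional tibble `gene_id`, `n_haplotypes` giving
#'   the haplotype count per gene (so single-haplotype genes, which produce
#'   no pairs, can still be reported as excluded). When omitted, counts are
#'   inferred from the genomes seen in `estimates`.
#' @param min_haplotypes Minimum haplotypes for a gene to be testable
#'   (default 2).
#' @return A `panfam_selection` tibble: `gene_id`, `n_haplotypes`,
#'   `n_pairs`, `n_pairs_omega_gt1`, `prop_omega_gt1`. Excluded genes are
#'   in `attr(, "excluded")`; omega values for density plots stay available
#'   in `estimates`.
#' @export
summarize_selection <- function(estimates, haplotype_counts = NULL,
                                min_haplotypes = 2) {
  inferred <- estimates |>
    tidyr::pivot_longer(c("genome_a", "genome_b"), values_to = "genome") |>
    distinct(.data$gene_id, .data$genome) |>
    count(.data$gene_id, name = "n_haplotypes")
  counts <- if (is.null(haplotype_counts)) inferred else {
    as_tibble(haplotype_counts)
  }
  excluded <- counts |> filter(.data$n_haplotypes < min_haplotypes)
  kept <- counts |> filter(.data$n_haplotypes >= min_haplotypes)
  summ <- estimates |>
    dplyr::semi_join(kept, by = "gene_id") |>
    group_by(.data$gene_id) |>
    summarise(
      n_pairs = sum(!is.na(.data$omega)),
      n_pairs_omega_gt1 = sum(.data$omega > 1, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(prop_omega_gt1 = ifelse(.data$n_pairs > 0,
                                   .data$n_pairs_omega_gt1 / .data$n_pairs,
                                   NA_real_)) |>
    left_join(kept, by = "gene_id") |>
    select("gene_id", "n_haplotypes", "n_pairs", "n_pairs_omega_gt1",
           "prop_omega_gt1")
  class(summ) <- c("panfam_selection", class(summ))
  attr(summ, "excluded") <- excluded
  attr(summ, "min_haplotypes") <- min_haplotypes
  summ
}
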