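# FIMO-style PWM scanning: log2-odds scores against a background model and
# exact p-values by dynamic programming over integer-discretized scores.
# Discretization granularity is 1/1000 bit, far below reporting precision.

PWM_GRANULARITY <- 1e-3

new_pwm <- function(motif_id, family, probs, background, pseudocount) {
  stopifnot(ncol(probs) == 4, nrow(probs) >= 1)
  colnames(probs) <- BASES
  names(background) <- BASES
  structure(
    list(motif_id = motif_id, family = family, width = nrow(probs),
         probs = probs, background = background, pseudocount = pseudocount),
    class = "panfam_pwm"
  )
}

#' @export
print.panfam_pwm <- function(x, ...) {
  cat("PWM", x$motif_id, if (nzchar(x$family)) paste0("(", x$family, ")"),
      "width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

apply_pseudocount <- function(probs, pseudocount, background) {
  p <- sweep(probs, 2, 0, "+") + pseudocount * rep(background, each = nrow(probs))
  p / rowSums(p)
}

#' Read a MEME minimal-format motif library
#'
#' Parses the MEME minimal text format (version line, optional ALPHABET and
#' background frequency lines, one letter-probability matrix per motif).
#' Matrices get a pseudocount of `pseudocount` (split by the background
#' frequencies) and are renormalized; a missing background line means the
#' uniform background.
#'
#' @param path Path to a MEME minimal motif file.
#' @param pseudocount Pseudocount added to each position (default 0.1, the
#'   FIMO default).
#' @return List of `panfam_pwm` objects. A motif's "family" is taken from
#'   the second word of its MOTIF line when present.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.1) {
  if (!file.exists(path)) abort(paste0("motif file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  i <- 1
  motifs <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "Background letter frequencies")) {
      fl <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fl[seq(2, length(fl), by = 2)]))
      names(vals) <- fl[seq(1, length(fl), by = 2)]
      background <- vals[BASES]
      background <- background / sum(background)
      i <- i + 2
    } else if (startsWith(ln, "MOTIF")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      motif_id <- parts[2]
      family <- if (length(parts) >= 3) parts[3] else ""
      # advance to the letter-probability header
      j <- i + 1
      while (j <= length(lines) &&
             !startsWith(trimws(lines[j]), "letter-probability")) {
        if (startsWith(trimws(lines[j]), "MOTIF")) {
          abort(paste0("motif ", motif_id, ": no letter-probability matrix"))
        }
        j <- j + 1
      }
      if (j > length(lines)) {
        abort(paste0("motif ", motif_id, ": no letter-probability matrix"))
      }
      rows <- list()
      j <- j + 1
      while (j <= length(lines)) {
        rl <- trimws(lines[j])
        if (!nzchar(rl)) { j <- j + 1; if (length(rows) > 0) break else next }
        if (startsWith(rl, "MOTIF") || startsWith(rl, "URL")) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
        if (length(vals) != 4 || anyNA(vals)) {
          abort(paste0("motif ", motif_id,
                       ": malformed probability row '", rl, "'"))
        }
        rows[[length(rows) + 1]] <- vals
        j <- j + 1
      }
      probs <- do.call(rbind, rows)
      probs <- apply_pseudocount(probs, pseudocount, background)
      motifs[[length(motifs) + 1]] <-
        new_pwm(motif_id, family, probs, background, pseudocount)
      i <- j
    } else {
      i <- i + 1
    }
  }
  motifs
}

#' Build a near-deterministic PWM from a binding-site string
#'
#' Each position gives probability `match_prob` to the site base and
#' `(1 - match_prob) / 3` to the other three bases — a convenient stand-in
#' when only the literal site string of a motif is known.
#'
#' @param site Binding-site string over A/C/G/T.
#' @param match_prob Probability of the consensus base (default 0.95).
#' @param motif_id,family Labels for the resulting PWM.
#' @param background Background distribution (default uniform).
#' @return A `panfam_pwm`.
#' @examples
#' consensus_pwm("GAGATTCTGA", family = "G2-like")
#' @export
consensus_pwm <- function(site, match_prob = 0.95,
                          motif_id = paste0("consensus_", site),
                          family = "",
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  chars <- strsplit(toupper(site), "")[[1]]
  if (!all(chars %in% BASES)) {
    abort("site string contains non-ACGT characters (ambiguity codes unsupported)")
  }
  probs <- matrix((1 - match_prob) / 3, nrow = length(chars), ncol = 4,
                  dimnames = list(NULL, BASES))
  probs[cbind(seq_along(chars), match(chars, BASES))] <- match_prob
  new_pwm(motif_id, family, probs, background, pseudocount = 0)
}

# integer-discretized per-position log2-odds scores (units of PWM_GRANULARITY)
pwm_int_scores <- function(pwm) {
  lo <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  round(lo / PWM_GRANULARITY)
}

# exact null distribution of the integer window score under the background:
# convolve per-position score distributions. Returns list(scores, probs).
pwm_score_distribution <- function(pwm) {
  ints <- pwm_int_scores(pwm)
  offset <- 0L
  dist <- 1   # probability vector over score - offset
  for (p in seq_len(pwm$width)) {
    row <- ints[p, ]
    lo <- min(row)
    span <- max(row) - lo
    step <- numeric(span + 1)
    for (b in seq_len(4)) {
      idx <- row[b] - lo + 1
      step[idx] <- step[idx] + pwm$background[b]
    }
    dist <- if (length(step) == 1) dist * step else convolve_dists(dist, step)
    offset <- offset + lo
  }
  list(min_score = offset, probs = dist)
}

convolve_dists <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (k in seq_along(b)) {
    if (b[k] == 0) next
    idx <- seq_along(a) + (k - 1)
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

#' Exact null distribution of PWM window scores
#'
#' The full dynamic-programming distribution of the integer-discretized
#' log2-odds window score under the background model, with the exact
#' p-value (upper tail, inclusive) at every achievable score.
#'
#' @param pwm A `panfam_pwm`.
#' @return Tibble `score_int` (units of 1/1000 bit), `score_bits`,
#'   `prob`, `p_value`, restricted to scores with nonzero probability.
#' @export
pwm_pvalues <- function(pwm) {
  dist <- pwm_score_distribution(pwm)
  scores <- dist$min_score + seq_along(dist$probs) - 1
  tail_probs <- rev(cumsum(rev(dist$probs)))
  tibble(score_int = scores,
         score_bits = scores * PWM_GRANULARITY,
         prob = dist$probs,
         p_value = pmin(tail_probs, 1)) |>
    filter(.data$prob > 0)
}

#' Scan a sequence with a PWM, FIMO-style
#'
#' Every window of length `width` is scored as the sum over positions of
#' `log2(pwm[pos, base] / background[base])`. The p-value of a window is the
#' exact probability that a background-distributed width-mer scores at least
#' as high, computed by dynamic programming over scores discretized at
#' 1/1000 bit. Hits with `p_value <= p_max` are returned; with
#' `both_strands` the reverse complement is scanned too and hit coordinates
#' are mapped back to the forward strand. Windows containing non-ACGT
#' characters are skipped (with a message).
#'
#' @param seq Nucleotide string, at least as long as the PWM width.
#' @param pwm A `panfam_pwm`.
#' @param p_max P-value threshold (default 1e-4, the FIMO default).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Tibble of hits: `motif_id`, `family`, `sequence_id`, `start`
#'   (0-based, forward strand), `strand`, `score_bits`, `p_value`, sorted
#'   by position.
#' @export
scan_sequence <- function(seq, pwm, p_max = 1e-4, both_strands = TRUE,
                          sequence_id = "seq") {
  seq <- toupper(seq)
  L <- nchar(seq)
  w <- pwm$width
  if (L < w) abort("sequence shorter than motif width")
  dist <- pwm_score_distribution(pwm)
  tailp <- rev(cumsum(rev(dist$probs)))
  lookup_p <- function(s_int) {
    idx <- s_int - dist$min_score + 1
    if (idx <= 1) return(1)
    if (idx > length(tailp)) return(0)
    min(tailp[idx], 1)
  }
  ints <- pwm_int_scores(pwm)
  lo_real <- log2(sweep(pwm$probs, 2, pwm$background, "/"))

  scan_strand <- function(s, strand) {
    chars <- strsplit(s, "")[[1]]
    base_idx <- match(chars, BASES)
    bad <- is.na(base_idx)
    if (any(bad)) {
      inform(paste0(sequence_id, ": skipping windows over ", sum(bad),
                    " non-ACGT position(s)"))
    }
    starts <- seq_len(L - w + 1)
    hits <- list()
    for (st in starts) {
      idx <- base_idx[st:(st + w - 1)]
      if (anyNA(idx)) next
      s_int <- sum(ints[cbind(seq_len(w), idx)])
      p <- lookup_p(s_int)
      if (p == 0) p <- .Machine$double.xmin  # p-values live in (0, 1]
      if (p <= p_max) {
        fwd_start <- if (strand == "+") st - 1L else L - (st - 1L) - w
        hits[[length(hits) + 1]] <- tibble(
          motif_id = pwm$motif_id, family = pwm$family,
          sequence_id = sequence_id, start = fwd_start, strand = strand,
          score_bits = sum(lo_real[cbind(seq_len(w), idx)]),
          p_value = p
        )
      }
    }
    hits
  }
  res <- scan_strand(seq, "+")
  if (both_strands) {
    res <- c(res, scan_strand(reverse_complement(seq), "-"))
  }
  if (length(res) == 0) {
    return(tibble(motif_id = character(), family = character(),
                  sequence_id = character(), start = integer(),
                  strand = character(), score_bits = numeric(),
                  p_value = numeric()))
  }
  bind_rows(res) |> arrange(.data$start, .data$strand)
}

#' Annotate SV regions with candidate TF families
#'
#' Scans each region sequence against every PWM in the library and
#' aggregates hits to (region, family, motif) counts. Regions with zero
#' hits are reported explicitly with `n_hits = 0`.
#'
#' @param region_seqs Tibble `region_id`, `seq` (e.g. from
#'   [sv_region_sequences()]), or a named character vector / FASTA path.
#' @param motifs List of `panfam_pwm` objects.
#' @param p_max Per-hit p-value threshold (default 1e-4).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return List with `hits` (per-hit tibble) and `annotation`: tibble
#'   `region_id`, `family`, `motif_id`, `n_hits`, where no-hit regions have
#'   one row with `family = NA` and `n_hits = 0`.
#' @export
annotate_sv_regions <- function(region_seqs, motifs, p_max = 1e-4,
                                both_strands = TRUE) {
  if (is.character(region_seqs) && length(region_seqs) == 1 &&
      file.exists(region_seqs)) {
    ss <- Biostrings::readDNAStringSet(region_seqs)
    region_seqs <- tibble(region_id = names(ss), seq = as.character(ss))
  } else if (is.character(region_seqs)) {
    region_seqs <- tibble(region_id = names(region_seqs),
                          seq = unname(region_seqs))
  }
  hits <- purrr::pmap(region_seqs[, c("region_id", "seq")],
                      function(region_id, seq) {
    map(motifs, function(pwm) {
      if (nchar(seq) < pwm$width) return(NULL)
      scan_sequence(seq, pwm, p_max = p_max, both_strands = both_strands,
                    sequence_id = region_id)
    }) |> bind_rows()
  }) |> bind_rows()

  if (nrow(hits) > 0) {
    counts <- hits |>
      count(region_id = .data$sequence_id, .data$family, .data$motif_id,
            name = "n_hits")
  } else {
    counts <- tibble(region_id = character(), family = character(),
                     motif_id = character(), n_hits = integer())
  }
  no_hit <- setdiff(region_seqs$region_id, counts$region_id)
  if (length(no_hit) > 0) {
    counts <- bind_rows(counts, tibble(
      region_id = no_hit, family = NA_character_,
      motif_id = NA_character_, n_hits = 0L
    ))
  }
  annotation <- counts |> arrange(match(.data$region_id, region_seqs$region_id))
  list(hits = hits, annotation = annotation)
}

#' Write a motif library in MEME minimal format
#'
#' @param motifs List of `panfam_pwm` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  bg <- motifs[[1]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    ""
  )
  for (m in motifs) {
    out <- c(out,
      paste("MOTIF", m$motif_id, m$family),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              m$width),
      apply(m$probs, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                            r[1], r[2], r[3], r[4])),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}
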