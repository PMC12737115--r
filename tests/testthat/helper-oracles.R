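# Independent oracles, deliberately written without reusing package
# internals: brute-force codon enumeration for NG86 quantities, full-window
# enumeration for PWM p-values, a restructured per-column SV scanner, and
# direct textbook formulas for the pooled t-test.

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)
oracle_bases <- c("A", "C", "G", "T")

# synonymous site count of one codon: enumerate all 9 single-base changes;
# changes to stop codons dropped from numerator and denominator
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(oracle_bases, chars[p])) {
      mut <- chars; mut[p] <- b
      mutc <- paste(mut, collapse = "")
      if (oracle_code[mutc] == "*") next
      valid <- valid + 1
      if (oracle_code[mutc] == oracle_code[codon]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# pathway-averaged (Sd, Nd) between two codons: enumerate substitution
# orders, drop orders whose intermediates are stops
oracle_pair_diff <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  orders <- if (length(diffs) == 1) list(diffs) else {
    perms <- combinat_perms(length(diffs))
    lapply(perms, function(p) diffs[p])
  }
  tallies <- list()
  for (ord in orders) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur; nxt[ord[k]] <- b[ord[k]]
      aa1 <- oracle_code[paste(cur, collapse = "")]
      aa2 <- oracle_code[paste(nxt, collapse = "")]
      if (aa2 == "*" && k < length(ord)) { ok <- FALSE; break }
      if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) tallies[[length(tallies) + 1]] <- c(sd = sd, nd = nd)
  }
  if (length(tallies) == 0) return(c(sd = NA, nd = NA))
  colMeans(do.call(rbind, tallies))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1)) {
      tail <- setdiff(seq_len(n), i)[rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

# brute-force exact PWM p-values: enumerate every width-mer, score with the
# same integer discretization, weight by the background
oracle_pwm_pvalue <- function(pwm, score_int) {
  w <- pwm$width
  ints <- round(log2(sweep(pwm$probs, 2, pwm$background, "/")) / 1e-3)
  all_idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(4)), w)))
  scores <- numeric(nrow(all_idx))
  probs <- rep(1, nrow(all_idx))
  for (p in seq_len(w)) {
    scores <- scores + ints[p, all_idx[, p]]
    probs <- probs * pwm$background[all_idx[, p]]
  }
  vapply(score_int, function(s) sum(probs[scores >= s]), numeric(1))
}

# independent per-column SV scanner: project each sample/reference pair onto
# columns informative for that pair (drop both-gap columns), classify the
# remainder with rle, and convert runs to events
oracle_sv_events <- function(alignment, reference_id, min_len) {
  rows <- lapply(alignment, function(s) strsplit(s, "")[[1]])
  ref <- rows[[reference_id]]
  out <- list()
  for (sid in setdiff(names(rows), reference_id)) {
    s <- rows[[sid]]
    keep <- !(ref == "-" & s == "-")
    r2 <- ref[keep]; s2 <- s[keep]
    state <- ifelse(r2 != "-" & s2 != "-", "M",
                    ifelse(s2 == "-", "D", "I"))
    # leading/trailing sample-gap runs are missing flanks
    has <- which(s2 != "-")
    if (length(has) == 0) next
    rl <- rle(state)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    refpos <- cumsum(r2 != "-")
    for (k in seq_along(rl$values)) {
      st <- rl$values[k]
      if (st == "M") next
      if (st == "D" && (ends[k] < has[1] || starts[k] > has[length(has)])) next
      len <- rl$lengths[k]
      if (len < min_len) next
      if (st == "D") {
        rs <- as.integer(refpos[starts[k]] - 1L)
        out[[length(out) + 1]] <- data.frame(
          sample_id = sid, type = "deletion",
          ref_start = rs, ref_end = rs + len, length = len)
      } else {
        anchor <- if (starts[k] == 1) 0L else
          as.integer(refpos[starts[k] - 1])
        out[[length(out) + 1]] <- data.frame(
          sample_id = sid, type = "insertion",
          ref_start = anchor, ref_end = anchor, length = len)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(), type = character(),
                      ref_start = integer(), ref_end = integer(),
                      length = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$ref_start, res$sample_id, res$type), , drop = FALSE]
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}
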