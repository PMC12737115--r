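# Codon-level lookup machinery shared by the NG86 and YN estimators and by
# the codon-pair evolution simulator. Everything is precomputed once at load
# into integer-indexed tables so per-pair work stays cheap.

BASES <- c("A", "C", "G", "T")

# 64 codons in fixed lexicographic order; index = codon_index(codon string)
CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
CODONS <- sort(CODONS)

GENETIC_CODE_STD <- local({
  aa <- as.character(Biostrings::GENETIC_CODE)
  names(aa) <- names(Biostrings::GENETIC_CODE)
  aa[CODONS]
})

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

codon_index <- function(codon) match(codon, CODONS)

#' Is a single-nucleotide change a transition?
#'
#' Transitions are A<->G and C<->T; all other base changes are transversions.
#'
#' @param from,to single bases among A, C, G, T.
#' @return Logical vector.
#' @keywords internal
is_transition <- function(from, to) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  from != to & purine[from] == purine[to]
}

# For each codon index i, position p (1..3) and alternative base b (1..4):
#   MUT_TARGET[i, p, b]  index of the mutated codon (NA if b is the current base)
#   MUT_SYN[i, p, b]     TRUE if the change is synonymous (stop targets NA)
#   MUT_TS[i, p, b]      TRUE if the change is a transition
MUT_TABLES <- local({
  target <- array(NA_integer_, dim = c(64, 3, 4))
  syn <- array(NA, dim = c(64, 3, 4))
  ts <- array(NA, dim = c(64, 3, 4))
  for (i in seq_len(64)) {
    cod <- strsplit(CODONS[i], "")[[1]]
    for (p in 1:3) {
      for (b in seq_len(4)) {
        if (BASES[b] == cod[p]) next
        mut <- cod
        mut[p] <- BASES[b]
        mutc <- paste(mut, collapse = "")
        j <- codon_index(mutc)
        target[i, p, b] <- j
        ts[i, p, b] <- is_transition(cod[p], BASES[b])
        if (GENETIC_CODE_STD[j] != "*" && GENETIC_CODE_STD[i] != "*") {
          syn[i, p, b] <- GENETIC_CODE_STD[j] == GENETIC_CODE_STD[i]
        }
      }
    }
  }
  list(target = target, syn = syn, ts = ts)
})

# Degeneracy class of each codon position: number of the three single-base
# changes that are synonymous, counting only non-stop targets. 4-fold = all
# 3 synonymous, 0-fold (nondegenerate) = none.
CODON_DEGENERACY <- local({
  deg <- matrix(NA_integer_, nrow = 64, ncol = 3)
  for (i in seq_len(64)) {
    if (GENETIC_CODE_STD[i] == "*") next
    for (p in 1:3) {
      deg[i, p] <- sum(MUT_TABLES$syn[i, p, ], na.rm = TRUE)
    }
  }
  deg
})

# NG86 per-position synonymous site fraction: synonymous changes over
# non-stop changes at that position (stop-producing changes are excluded
# from both numerator and denominator, so each position still contributes
# one full site split between S and N).
NG86_SYN_FRAC <- local({
  frac <- matrix(NA_real_, nrow = 64, ncol = 3)
  for (i in seq_len(64)) {
    if (GENETIC_CODE_STD[i] == "*") next
    for (p in 1:3) {
      syn <- MUT_TABLES$syn[i, p, ]
      valid <- !is.na(syn)
      frac[i, p] <- if (any(valid)) sum(syn[valid]) / sum(valid) else 0
    }
  }
  frac
})

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) {
    abort("sequence length must be divisible by 3")
  }
  substring(seq, seq(1, nchar(seq), by = 3), seq(3, nchar(seq), by = 3))
}

translate_cds <- function(seq) {
  paste(GENETIC_CODE_STD[split_codons(seq)], collapse = "")
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
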