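#' Back-translate an aligned protein pair into a codon alignment
#'
#' Maps each column of a pairwise protein alignment onto the corresponding
#' codon of each CDS, drops columns that are gapped in either protein (in
#' whole codon triplets), and validates that each CDS translates to its
#' ungapped protein. A terminal stop codon on either CDS is trimmed.
#'
#' @param prot_a,prot_b Aligned protein sequences (equal length, `-` gaps).
#' @param cds_a,cds_b Coding sequences (unaligned, no gaps).
#' @param id_a,id_b Optional sequence labels carried into the result.
#' @return A `codon_alignment` object: list with gap-free, equal-length,
#'   in-frame `seq_a`, `seq_b` and the ids.
#' @export
codon_align <- function(prot_a, prot_b, cds_a, cds_b,
                        id_a = "seq_a", id_b = "seq_b") {
  if (nchar(prot_a) != nchar(prot_b)) {
    abort("aligned proteins must have equal length")
  }
  prep <- function(cds, prot, label) {
    cds <- toupper(gsub("-", "", cds))
    ungapped <- gsub("-", "", prot)
    if (nchar(cds) == 3 * (nchar(ungapped) + 1)) {
      last <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (GENETIC_CODE_STD[last] == "*") {
        cds <- substr(cds, 1, nchar(cds) - 3)
      }
    }
    if (nchar(cds) != 3 * nchar(ungapped)) {
      abort(paste0(label, ": CDS length ", nchar(cds),
                   " is not 3x protein length ", nchar(ungapped)))
    }
    aa <- GENETIC_CODE_STD[split_codons(cds)]
    mism <- which(aa != strsplit(ungapped, "")[[1]])
    if (length(mism) > 0) {
      abort(paste0(label, ": CDS translation disagrees with protein at residue ",
                   mism[1]))
    }
    if (any(aa == "*")) {
      abort(paste0(label, ": internal stop codon at residue ",
                   which(aa == "*")[1]))
    }
    cds
  }
  cds_a <- prep(cds_a, prot_a, id_a)
  cds_b <- prep(cds_b, prot_b, id_b)

  cols_a <- strsplit(prot_a, "")[[1]]
  cols_b <- strsplit(prot_b, "")[[1]]
  keep <- cols_a != "-" & cols_b != "-"
  # residue index of each kept column within its own ungapped protein
  idx_a <- cumsum(cols_a != "-")[keep]
  idx_b <- cumsum(cols_b != "-")[keep]
  codons_a <- split_codons(cds_a)[idx_a]
  codons_b <- split_codons(cds_b)[idx_b]
  structure(
    list(seq_a = paste(codons_a, collapse = ""),
         seq_b = paste(codons_b, collapse = ""),
         id_a = id_a, id_b = id_b),
    class = "codon_alignment"
  )
}

#' Align a CDS pair via its proteins and return the codon alignment
#'
#' Convenience wrapper for pipelines starting from raw CDS: translates both
#' sequences, aligns the proteins globally (Needleman-Wunsch, BLOSUM62) and
#' back-translates with [codon_align()].
#'
#' @inheritParams codon_align
#' @return A `codon_alignment` object.
#' @export
align_codon_pair <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  trim_stop <- function(cds) {
    cds <- toupper(cds)
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (nchar(cds) %% 3 == 0 && GENETIC_CODE_STD[last] == "*") {
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    cds
  }
  cds_a <- trim_stop(cds_a)
  cds_b <- trim_stop(cds_b)
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  pal <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
  )
  codon_align(as.character(Biostrings::alignedPattern(pal)),
              as.character(Biostrings::alignedSubject(pal)),
              cds_a, cds_b, id_a = id_a, id_b = id_b)
}

as_codon_alignment <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) return(x)
  if (is.null(y)) abort("need a codon_alignment or two sequences")
  a <- toupper(x); b <- toupper(y)
  if (nchar(a) != nchar(b)) abort("codon sequences must have equal length")
  if (nchar(a) %% 3 != 0) abort("codon sequence length must be divisible by 3")
  structure(list(seq_a = a, seq_b = b, id_a = "seq_a", id_b = "seq_b"),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", nchar(x$seq_a) / 3, "codons\n")
  cat("  ", x$id_a, ": ", substr(x$seq_a, 1, 60),
      if (nchar(x$seq_a) > 60) "..." else "", "\n", sep = "")
  cat("  ", x$id_b, ": ", substr(x$seq_b, 1, 60),
      if (nchar(x$seq_b) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}
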