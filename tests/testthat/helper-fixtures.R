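# small in-code fixtures shared across test files

domtblout_line <- function(target, evalue, qlen, hmm_from, hmm_to,
                           query = "PF_TEST") {
  sprintf("%s - %d %s - %d %s 50.0 0.1 1 1 %s %s 49.0 0.1 %d %d %d %d %d %d 0.90 -",
          target, hmm_to + 10, query, qlen, format(evalue), format(evalue),
          format(evalue), hmm_from, hmm_to, hmm_from, hmm_to,
          hmm_from, hmm_to)
}

write_domtbl_fixture <- function(lines, comments = "# domtblout test fixture") {
  path <- tempfile(fileext = ".domtblout")
  writeLines(c(comments, lines), path)
  path
}

# an alignment as a named character vector from per-row strings
aln <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
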