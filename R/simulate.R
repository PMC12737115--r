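# Seeded generators for every input the pipeline consumes, each paired with
# a machine-readable truth record sufficient to score downstream stages
# without re-running generation. All generators restore the caller's RNG
# state, so fixing `seed` gives byte-identical output regardless of context.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic pangenome with known occupancy structure
#'
#' Produces, per planted pan-gene, an occupancy drawn from its category's
#' definition (core = all genomes; near-core uniform in
#' `[ceil(0.9 n), n - 1]`; dispensable uniform in `[2, ceil(0.9 n) - 1]`;
#' private = 1), a carrier set of that size, a domain-hit row per carrier
#' that passes the family filters, and a per-carrier protein copy (~2%
#' residues mutated from the pan-gene ancestor, so copies cluster together
#' at 90% identity while distinct pan-genes do not). Decoy hits failing
#' each filter are included for negative testing.
#'
#' @param n_genomes Panel size (default 26).
#' @param counts Planted category counts, in order (core, near_core,
#'   dispensable, private); default `c(9, 2, 5, 5)`.
#' @param seed Integer seed.
#' @param protein_len Ancestral protein length (default 200).
#' @param dir Optional directory: when given, writes `hits.domtblout`,
#'   `proteins.faa` and `truth.yaml` there.
#' @return List: `hits` (domain-hit tibble incl. decoys), `proteins`
#'   ([Biostrings::AAStringSet], names `genome|gene`), `pan_genes` (true
#'   pan-gene table), `genome_ids`, `truth`.
#' @export
make_pangenome <- function(n_genomes = 26,
                           counts = c(core = 9, near_core = 2,
                                      dispensable = 5, private = 5),
                           seed = 1, protein_len = 200, dir = NULL) {
  stopifnot(length(counts) == 4, all(counts >= 0), n_genomes >= 2)
  names(counts) <- c("core", "near_core", "dispensable", "private")
  nc_lo <- as.integer(ceiling(0.9 * n_genomes))
  if (counts["near_core"] > 0 && nc_lo > n_genomes - 1) {
    abort("near-core infeasible: ceil(0.9 n) exceeds n - 1")
  }
  if (counts["dispensable"] > 0 && nc_lo - 1 < 2) {
    abort("dispensable infeasible: no occupancy in [2, ceil(0.9 n) - 1]")
  }
  with_local_seed(seed, {
    genome_ids <- sprintf("genome%02d", seq_len(n_genomes))
    cats <- rep(names(counts), counts)
    n_genes <- length(cats)
    gene_ids <- sprintf("gene%02d", seq_len(n_genes))
    occ <- vapply(cats, function(cat) {
      switch(cat,
             core = n_genomes,
             near_core = if (nc_lo == n_genomes - 1) nc_lo else
               sample(seq(nc_lo, n_genomes - 1), 1),
             dispensable = if (nc_lo - 1 == 2) 2L else
               sample(seq(2, nc_lo - 1), 1),
             private = 1L)
    }, numeric(1))
    carriers <- map(occ, ~sort(sample(genome_ids, .x)))

    ancestors <- map_chr(gene_ids, function(g) {
      paste(sample(AA_ALPHABET20, protein_len, replace = TRUE),
            collapse = "")
    })
    prot <- list(); hit_rows <- list()
    for (k in seq_len(n_genes)) {
      anc <- strsplit(ancestors[k], "")[[1]]
      for (g in carriers[[k]]) {
        copy <- anc
        n_mut <- rpois(1, 0.02 * protein_len)
        if (n_mut > 0) {
          at <- sample(protein_len, min(n_mut, protein_len))
          copy[at] <- sample(AA_ALPHABET20, length(at), replace = TRUE)
        }
        prot[[paste0(g, "|", gene_ids[k])]] <- paste(copy, collapse = "")
        hmm_from <- sample(1:15, 1)
        hmm_to <- protein_len - sample(0:15, 1)
        hit_rows[[length(hit_rows) + 1]] <- tibble(
          genome_id = g, gene_id = gene_ids[k], profile_id = "SYNTH_DOM",
          full_seq_evalue = 10^-runif(1, 20, 60), profile_len = protein_len,
          hmm_from = hmm_from, hmm_to = hmm_to,
          ali_from = hmm_from, ali_to = hmm_to
        )
      }
    }
    # decoys: one gene failing the E-value filter, one failing coverage
    hit_rows[[length(hit_rows) + 1]] <- tibble(
      genome_id = genome_ids[1], gene_id = "decoy_evalue",
      profile_id = "SYNTH_DOM", full_seq_evalue = 1e-3,
      profile_len = protein_len, hmm_from = 1L, hmm_to = protein_len,
      ali_from = 1L, ali_to = protein_len
    )
    hit_rows[[length(hit_rows) + 1]] <- tibble(
      genome_id = genome_ids[1], gene_id = "decoy_coverage",
      profile_id = "SYNTH_DOM", full_seq_evalue = 1e-30,
      profile_len = protein_len, hmm_from = 1L,
      hmm_to = as.integer(floor(protein_len * 0.5)),
      ali_from = 1L, ali_to = as.integer(floor(protein_len * 0.5))
    )
    hits <- bind_rows(hit_rows) |>
      mutate(coverage = (.data$hmm_to - .data$hmm_from + 1) /
               .data$profile_len)
    pan_genes <- tibble(
      pan_gene_id = rep(gene_ids, lengths(carriers)),
      genome_id = unlist(carriers),
      gene_id = rep(gene_ids, lengths(carriers))
    )
    truth <- list(
      scenario = "pangenome", seed = seed, n_genomes = n_genomes,
      counts = as.list(counts),
      genes = map(seq_len(n_genes), function(k) {
        list(gene_id = gene_ids[k], category = cats[k],
             occupancy = as.integer(occ[k]), carriers = carriers[[k]])
      })
    )
    out <- list(hits = hits,
                proteins = Biostrings::AAStringSet(unlist(prot)),
                pan_genes = pan_genes, genome_ids = genome_ids,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_domtblout(hits, file.path(dir, "hits.domtblout"))
      Biostrings::writeXStringSet(out$proteins,
                                  file.path(dir, "proteins.faa"))
      yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
    }
    out
  })
}

#' Evolve a codon sequence pair at known omega and kappa
#'
#' Draws an ancestor of uniform sense codons and evolves two independent
#' descendant lineages by repeated single-nucleotide proposals, accepted
#' with relative rate `kappa` for transitions and `omega` for
#' nonsynonymous changes (stop-codon proposals always rejected). The total
#' expected divergence (`divergence` accepted substitutions per codon for
#' the pair) is split equally between the lineages, each lineage's realized
#' substitution count drawn Poisson.
#'
#' @param n_codons Number of codons.
#' @param omega True nonsynonymous/synonymous rate ratio.
#' @param kappa True transition/transversion rate ratio.
#' @param divergence Expected substitutions per codon for the pair.
#' @param seed Integer seed.
#' @return List: `alignment` (a `codon_alignment`), `truth`.
#' @export
evolve_codon_pair <- function(n_codons, omega, kappa, divergence, seed = 1) {
  stopifnot(n_codons >= 1, omega >= 0, kappa > 0, divergence >= 0)
  with_local_seed(seed, {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    m_rel <- max(kappa, 1) * max(omega, 1)
    evolve <- function(codons, n_subs) {
      idx <- codon_index(codons)
      accepted <- 0
      while (accepted < n_subs) {
        cp <- sample(n_codons, 1)
        p <- sample(3, 1)
        b <- sample(4, 1)
        tgt <- MUT_TABLES$target[idx[cp], p, b]
        if (is.na(tgt) || GENETIC_CODE_STD[tgt] == "*") next
        syn <- MUT_TABLES$syn[idx[cp], p, b]
        ts <- MUT_TABLES$ts[idx[cp], p, b]
        rate <- (if (ts) kappa else 1) * (if (!syn) omega else 1)
        if (runif(1) < rate / m_rel) {
          idx[cp] <- tgt
          accepted <- accepted + 1
        }
      }
      CODONS[idx]
    }
    n1 <- rpois(1, divergence / 2 * n_codons)
    n2 <- rpois(1, divergence / 2 * n_codons)
    seq_a <- paste(evolve(anc, n1), collapse = "")
    seq_b <- paste(evolve(anc, n2), collapse = "")
    list(
      alignment = structure(list(seq_a = seq_a, seq_b = seq_b,
                                 id_a = "lineage_a", id_b = "lineage_b"),
                            class = "codon_alignment"),
      truth = list(scenario = "codon_pair", seed = seed,
                   n_codons = n_codons, omega = omega, kappa = kappa,
                   divergence = divergence,
                   n_subs = c(lineage_a = n1, lineage_b = n2))
    )
  })
}

#' Generate promoter alignments with planted shared indels
#'
#' Builds a random reference promoter and per-sample copies carrying the
#' planted deletions (reference bases removed) and insertions (a shared
#' random insert of the stated length), plus background substitutions in
#' every sample. The multiple alignment is constructed exactly from the
#' known edit operations — no aligner is involved — so gap columns appear
#' only where edits were planted.
#'
#' @param n_samples Number of non-reference samples (default 24).
#' @param ref_len Reference promoter length in bp (default 2000).
#' @param planted Tibble of SV specs: `type` (`"deletion"`/`"insertion"`),
#'   `position` (0-based reference offset; deletion interval start or
#'   insertion anchor), `length` (bp), `carriers` (list-column of sample
#'   ids, or an integer count to sample at random). Deletion intervals and
#'   insertion anchors must not overlap on the reference.
#' @param background_sub_rate Per-base substitution probability in each
#'   sample (default 0.005).
#' @param seed Integer seed.
#' @param reference_id Name of the reference row (default `"ref"`).
#' @return List: `alignment` (named character vector, reference row first),
#'   `sequences` (unaligned, gaps removed), `sample_ids`, `truth`.
#' @export
make_promoters <- function(n_samples = 24, ref_len = 2000,
                           planted = NULL, background_sub_rate = 0.005,
                           seed = 1, reference_id = "ref") {
  with_local_seed(seed, {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    ref <- strsplit(random_dna(ref_len), "")[[1]]
    if (is.null(planted)) {
      planted <- tibble(type = character(), position = integer(),
                        length = integer(), carriers = list())
    }
    planted <- as_tibble(planted)
    if (nrow(planted) > 0) {
      planted$carriers <- map(planted$carriers, function(cv) {
        if (is.numeric(cv) && length(cv) == 1) {
          sort(sample(sample_ids, cv))
        } else sort(as.character(cv))
      })
      bad <- setdiff(unlist(planted$carriers), sample_ids)
      if (length(bad) > 0) {
        abort(paste0("planted carriers not in sample panel: ",
                     paste(bad, collapse = ", ")))
      }
      iv <- planted |>
        mutate(s = .data$position,
               e = ifelse(.data$type == "deletion",
                          .data$position + .data$length, .data$position)) |>
        arrange(.data$s)
      if (any(iv$e > ref_len) || any(iv$s < 0)) {
        abort("planted SV outside the reference")
      }
      if (nrow(iv) > 1 && any(iv$s[-1] < iv$e[-nrow(iv)])) {
        abort("planted SV intervals overlap on the reference")
      }
      planted$insert_seq <- map2(planted$type, planted$length,
                                 ~if (.x == "insertion") random_dna(.y)
                                  else NA_character_)
      planted$insert_seq <- map_chr(planted$insert_seq, ~.x[[1]])
    }

    # alignment columns: one per reference base, plus an insertion block at
    # each planted anchor. Column map: ref_col[i] gives the column of ref
    # base i (1-based).
    ins <- planted |> filter(.data$type == "insertion") |>
      arrange(.data$position)
    block_at <- setNames(ins$length, as.character(ins$position))
    total_cols <- ref_len + sum(ins$length)
    ref_row <- character(total_cols)
    col <- 1L
    ref_col <- integer(ref_len)
    ins_cols <- list()   # anchor -> column indices of the block
    for (i in 0:(ref_len - 1)) {
      key <- as.character(i)
      if (!is.na(block_at[key])) {
        len <- block_at[[key]]
        ins_cols[[key]] <- seq(col, col + len - 1)
        ref_row[seq(col, col + len - 1)] <- "-"
        col <- col + len
      }
      ref_col[i + 1] <- col
      ref_row[col] <- ref[i + 1]
      col <- col + 1L
    }
    key_end <- as.character(ref_len)
    if (!is.na(block_at[key_end])) {
      len <- block_at[[key_end]]
      ins_cols[[key_end]] <- seq(col, col + len - 1)
      ref_row[seq(col, col + len - 1)] <- "-"
      col <- col + len
    }

    rows <- list()
    rows[[reference_id]] <- ref_row
    for (s in sample_ids) {
      row <- ref_row
      # insertion blocks: carriers get the shared insert, others stay gapped
      if (nrow(ins) > 0) {
        for (k in seq_len(nrow(ins))) {
          if (s %in% ins$carriers[[k]]) {
            cols <- ins_cols[[as.character(ins$position[k])]]
            row[cols] <- strsplit(ins$insert_seq[k], "")[[1]]
          }
        }
      }
      dels <- planted |> filter(.data$type == "deletion")
      if (nrow(dels) > 0) {
        for (k in seq_len(nrow(dels))) {
          if (s %in% dels$carriers[[k]]) {
            cols <- ref_col[seq(dels$position[k] + 1,
                                dels$position[k] + dels$length[k])]
            row[cols] <- "-"
          }
        }
      }
      # background substitutions on the sample's own bases
      has_base <- row != "-"
      flip <- has_base & runif(total_cols) < background_sub_rate
      if (any(flip)) {
        row[flip] <- vapply(row[flip],
                            function(b) sample(setdiff(BASES, b), 1), "")
      }
      rows[[s]] <- row
    }
    alignment <- vapply(rows, paste, character(1), collapse = "")
    sequences <- vapply(alignment, gsub, character(1),
                        pattern = "-", replacement = "", fixed = TRUE)
    names(sequences) <- names(alignment)
    truth <- list(
      scenario = "promoters", seed = seed, n_samples = n_samples,
      ref_len = ref_len, background_sub_rate = background_sub_rate,
      reference_id = reference_id,
      planted = if (nrow(planted) == 0) list() else
        map(seq_len(nrow(planted)), function(k) {
          list(type = planted$type[k],
               position = as.integer(planted$position[k]),
               length = as.integer(planted$length[k]),
               carriers = planted$carriers[[k]],
               insert_seq = planted$insert_seq[k])
        })
    )
    list(alignment = alignment, sequences = sequences,
         sample_ids = sample_ids, truth = truth)
  })
}

#' Preset promoter fixture with five shared SVs
#'
#' A 24-sample, 2000-bp promoter panel with five planted shared indels laid
#' out left to right as deletion, insertion, insertion, deletion, insertion
#' (80/120/60/55/150 bp; 7/9/6/5/10 carriers), mirroring the five-region
#' configuration the SV caller is designed to recover: all events are at
#' least 50 bp long and carried by at least 5 samples.
#'
#' @param seed Integer seed (default 101).
#' @return As [make_promoters()].
#' @export
five_sv_promoters <- function(seed = 101) {
  planted <- tibble(
    type = c("deletion", "insertion", "insertion", "deletion", "insertion"),
    position = c(150L, 520L, 900L, 1300L, 1700L),
    length = c(80L, 120L, 60L, 55L, 150L),
    carriers = list(7L, 9L, 6L, 5L, 10L)
  )
  make_promoters(n_samples = 24, ref_len = 2000, planted = planted,
                 background_sub_rate = 0.005, seed = seed,
                 reference_id = "B73like")
}

#' Plant literal binding-site strings into a sequence
#'
#' @param seq Background nucleotide string.
#' @param sites Tibble `site`, `offset` (0-based), or a named list of
#'   offsets keyed by site string.
#' @return List: `seq` (modified), `truth` (placements).
#' @export
plant_motifs <- function(seq, sites) {
  if (!is.data.frame(sites)) {
    sites <- tibble(site = names(sites), offset = unlist(sites))
  }
  if (nrow(sites) == 0) {
    return(list(seq = seq, truth = list(scenario = "motif_plant",
                                        placements = list())))
  }
  sites <- sites |> arrange(.data$offset)
  ends <- sites$offset + nchar(sites$site)
  if (any(sites$offset < 0) || any(ends > nchar(seq))) {
    abort("planted site overruns the sequence")
  }
  if (nrow(sites) > 1 && any(sites$offset[-1] < ends[-nrow(sites)])) {
    abort("planted sites overlap")
  }
  chars <- strsplit(seq, "")[[1]]
  for (k in seq_len(nrow(sites))) {
    chars[seq(sites$offset[k] + 1, ends[k])] <-
      strsplit(sites$site[k], "")[[1]]
  }
  list(seq = paste(chars, collapse = ""),
       truth = list(scenario = "motif_plant",
                    placements = map(seq_len(nrow(sites)), function(k) {
                      list(site = sites$site[k],
                           offset = as.integer(sites$offset[k]))
                    })))
}

#' Simulate expression with additive SV-presence effects
#'
#' `value(sample) = baseline + sum_r effect_r * noise_sd * presence(r, s) +
#' Normal(0, noise_sd)`: effects are expressed in noise-SD units so power
#' calculations read directly off the effect size.
#'
#' @param genotypes Wide genotype tibble from [genotype_sv()].
#' @param effects Named numeric vector, region_id -> effect size in SD
#'   units (regions absent from `effects` have effect 0).
#' @param noise_sd Residual standard deviation (default 1).
#' @param baseline Intercept (default 10).
#' @param seed Integer seed.
#' @return List: `values` (tibble `sample_id`, `value`), `truth`.
#' @export
make_expression <- function(genotypes, effects = numeric(0), noise_sd = 1,
                            baseline = 10, seed = 1) {
  stopifnot(noise_sd > 0)
  bad <- setdiff(names(effects), genotypes$region_id)
  if (length(bad) > 0) {
    abort(paste0("effects refer to unknown region(s): ",
                 paste(bad, collapse = ", ")))
  }
  with_local_seed(seed, {
    samples <- setdiff(names(genotypes), "region_id")
    value <- rep(baseline, length(samples)) + rnorm(length(samples), 0, noise_sd)
    for (rid in names(effects)) {
      pres <- unlist(genotypes[genotypes$region_id == rid, samples])
      value <- value + effects[[rid]] * noise_sd * as.numeric(pres)
    }
    list(values = tibble(sample_id = samples, value = unname(value)),
         truth = list(scenario = "expression", seed = seed,
                      baseline = baseline, noise_sd = noise_sd,
                      effects = as.list(effects)))
  })
}

#' Write aligned or unaligned sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Serialize a generator truth record as YAML
#'
#' @param truth Truth list from any generator.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}
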