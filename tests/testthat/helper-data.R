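# Shared fixtures and independent oracles, all generated in code.

random_dna <- function(n, len_range = c(20, 200)) {
  vapply(seq_len(n), function(i) {
    L <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1, 1) - 1
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

seq_tibble <- function(sequences, labels = NA_character_,
                       ids = sprintf("s%03d", seq_along(sequences))) {
  tibble::tibble(id = ids, sequence = sequences,
                 label = rep_len(labels, length(sequences)),
                 length = nchar(sequences))
}

# dinucleotide count vector (16 cells, AA..TT) -- independent of the package
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(di, levels = lv))
}

# brute-force: all arrangements of s sharing its dinucleotide multiset and
# endpoints, via exhaustive permutation of the interior characters
brute_dinuc_arrangements <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  if (L <= 2) return(s)
  interior <- ch[2:(L - 1)]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  cand <- unique(vapply(perms(interior), function(p) {
    paste(c(ch[1], p, ch[L]), collapse = "")
  }, character(1)))
  ref <- dinuc_counts(s)
  cand[vapply(cand, function(x) all(dinuc_counts(x) == ref), logical(1))]
}

# tiny easily-learnable dataset shared by model tests
toy_motif_dataset <- function(n_per = 30, seed = 7) {
  spec <- synthetic_spec(
    n_families = 2, n_per_family = n_per,
    length_mean_range = c(28, 36), length_spread = 4,
    length_bounds = c(20, 48), n_motifs = 1, motif_length = 8,
    insertion_prob = 1, mutation_rate = 0, seed = seed
  )
  generate_family_dataset(spec)$data
}
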