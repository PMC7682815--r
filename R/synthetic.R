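#' Specification of a synthetic multi-family sequence dataset
#'
#' Emulates the statistical structure of a family-labeled short ncRNA
#' collection so the whole pipeline can be exercised offline: each family is
#' defined by a private set of sequence motifs planted into i.i.d.
#' background, family length distributions overlap by default (so length
#' alone cannot classify, mirroring the removal of length-predictable
#' classes from real data), and the background composition can optionally
#' be dinucleotide-biased to stress shuffle-based rejection tests.
#'
#' Defaults state a realistic desk-scale world: family mean lengths drawn
#' uniformly in \[60, 160\] nt with a common +/-30 nt spread, truncated to
#' \[20, 200\] nt (the short-ncRNA regime); 3 motifs of 10 nt per family,
#' inserted with probability 0.9 and mutated per position at rate 0.05.
#'
#' @param n_families Number of families (classes).
#' @param n_per_family Sequences per family.
#' @param length_mean_range Range the per-family mean lengths are drawn from.
#' @param length_spread Half-width of the uniform per-sequence length draw
#'   around the family mean.
#' @param length_bounds Hard truncation bounds on sequence length.
#' @param n_motifs Motifs per family.
#' @param motif_length Motif length (nt); must fit the shortest sequence.
#' @param insertion_prob Probability that a given motif is planted in a
#'   given sequence.
#' @param mutation_rate Per-position probability that a planted motif base
#'   is replaced by a random base.
#' @param background Either `"uniform"` or a 4x4 dinucleotide transition
#'   matrix (rows/cols A,C,G,T) for a first-order Markov background.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 8, n_per_family = 500,
                           length_mean_range = c(60, 160),
                           length_spread = 30,
                           length_bounds = c(20, 200),
                           n_motifs = 3, motif_length = 10,
                           insertion_prob = 0.9, mutation_rate = 0.05,
                           background = "uniform", seed = 1L) {
  if (motif_length >= length_bounds[1]) {
    abort("motif_length must be smaller than the minimum sequence length")
  }
  if (insertion_prob < 0 || insertion_prob > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    abort("insertion_prob and mutation_rate must lie in [0, 1]")
  }
  structure(
    list(n_families = as.integer(n_families),
         n_per_family = as.integer(n_per_family),
         length_mean_range = length_mean_range,
         length_spread = length_spread, length_bounds = length_bounds,
         n_motifs = as.integer(n_motifs),
         motif_length = as.integer(motif_length),
         insertion_prob = insertion_prob, mutation_rate = mutation_rate,
         background = background, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

random_background <- function(n, background) {
  if (identical(background, "uniform")) {
    paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
  } else {
    out <- integer(n)
    out[1] <- sample.int(4, 1)
    if (n > 1) {
      for (i in 2:n) out[i] <- sample.int(4, 1, prob = background[out[i - 1], ])
    }
    paste(DNA_ALPHABET[out], collapse = "")
  }
}

#' Generate a labeled multi-family dataset with planted motifs
#'
#' Each family gets `n_motifs` private random motifs. Every sequence is
#' i.i.d. (or Markov) background of a family-specific random length; each
#' family motif is planted at a uniform random position with probability
#' `insertion_prob`, after per-position mutation at `mutation_rate`.
#' Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (a labeled sequence tibble; family labels are
#'   `fam01`, `fam02`, ...), `motifs` (tibble: label, motif id, motif
#'   sequence) and `placements` (tibble: sequence id, motif id, start
#'   position of each planted, possibly mutated, motif copy).
#' @export
generate_family_dataset <- function(spec) {
  set.seed(spec$seed)
  fams <- sprintf("fam%02d", seq_len(spec$n_families))
  mean_len <- runif(spec$n_families, spec$length_mean_range[1],
                    spec$length_mean_range[2])
  motifs <- tibble::tibble(
    label = rep(fams, each = spec$n_motifs),
    motif = paste0(rep(fams, each = spec$n_motifs), "_m",
                   rep(seq_len(spec$n_motifs), spec$n_families)),
    motif_seq = vapply(seq_len(spec$n_families * spec$n_motifs), function(i) {
      paste(sample(DNA_ALPHABET, spec$motif_length, replace = TRUE),
            collapse = "")
    }, character(1))
  )
  n_total <- spec$n_families * spec$n_per_family
  ids <- character(n_total)
  seqs <- character(n_total)
  labels <- character(n_total)
  placements <- list()
  rec <- 0
  for (f in seq_len(spec$n_families)) {
    fam_motifs <- motifs[motifs$label == fams[f], ]
    for (j in seq_len(spec$n_per_family)) {
      rec <- rec + 1
      L <- round(runif(1, mean_len[f] - spec$length_spread,
                       mean_len[f] + spec$length_spread))
      L <- max(spec$length_bounds[1], min(spec$length_bounds[2], L))
      chars <- strsplit(random_background(L, spec$background), "")[[1]]
      id <- sprintf("%s_s%04d", fams[f], j)
      occupied <- logical(L)
      for (m in seq_len(nrow(fam_motifs))) {
        if (runif(1) > spec$insertion_prob) next
        mseq <- strsplit(fam_motifs$motif_seq[m], "")[[1]]
        mut <- runif(length(mseq)) < spec$mutation_rate
        if (any(mut)) {
          mseq[mut] <- sample(DNA_ALPHABET, sum(mut), replace = TRUE)
        }
        # avoid clobbering previously planted motifs when space permits
        start <- sample.int(L - length(mseq) + 1L, 1)
        for (try in 1:20) {
          if (!any(occupied[start:(start + length(mseq) - 1L)])) break
          start <- sample.int(L - length(mseq) + 1L, 1)
        }
        occupied[start:(start + length(mseq) - 1L)] <- TRUE
        chars[start:(start + length(mseq) - 1L)] <- mseq
        placements[[length(placements) + 1]] <-
          list(id = id, motif = fam_motifs$motif[m], start = start)
      }
      ids[rec] <- id
      seqs[rec] <- paste(chars, collapse = "")
      labels[rec] <- fams[f]
    }
  }
  data <- tibble::tibble(id = ids, sequence = seqs, label = labels,
                         length = nchar(seqs))
  placements <- if (length(placements) > 0) {
    tibble::tibble(id = vapply(placements, `[[`, character(1), "id"),
                   motif = vapply(placements, `[[`, character(1), "motif"),
                   start = vapply(placements, `[[`, numeric(1), "start"))
  } else {
    tibble::tibble(id = character(0), motif = character(0), start = numeric(0))
  }
  list(data = data, motifs = motifs, placements = placements)
}

#' Dinucleotide-preserving shuffled negatives
#'
#' Produces one non-functional counterpart per input record by
#' dinucleotide-preserving shuffling ([dinucleotide_shuffle()]): identical
#' length, nucleotide and dinucleotide composition, but scrambled higher-
#' order sequence. Combined with the originals this yields the "doubled
#' test set" used to evaluate rejection of non-functional sequences.
#'
#' @param data A sequence tibble.
#' @param seed Integer seed.
#' @return A tibble of the same size with ids suffixed `_shuf` and label
#'   `"non_functional"`; the `source_id` column pairs each negative with
#'   its original.
#' @export
make_negatives <- function(data, seed = 1L) {
  out <- dinucleotide_shuffle(data, seed = seed)
  out$source_id <- out$id
  out$id <- paste0(out$id, "_shuf")
  out$label <- "non_functional"
  out
}
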