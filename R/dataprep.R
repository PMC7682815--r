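#' Normalized Hamming similarity between two sequences
#'
#' Similarity is `1 - mismatches / longer_length`, where positions are
#' compared pairwise and every position beyond the shorter sequence counts
#' as a mismatch. Two identical sequences score 1; sequences of equal length
#' with no matching position score 0. The measure is symmetric and is the
#' criterion used by the homology-aware split: a validation/test sequence may
#' not be this similar (>= threshold) to any training sequence of its class.
#'
#' @param seq_a,seq_b Sequence strings (non-empty).
#' @return A number in \[0, 1\].
#' @examples
#' normalized_similarity("ACGT", "ACGT") # 1
#' normalized_similarity("AAAA", "AA")   # 0.5
#' @export
normalized_similarity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("normalized_similarity requires non-empty sequences")
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  long <- max(length(a), length(b))
  short <- min(length(a), length(b))
  mism <- sum(a[seq_len(short)] != b[seq_len(short)]) + (long - short)
  1 - mism / long
}

# pack sequences into a common integer matrix (rows = positions, 0 = beyond end)
pack_seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  L <- max(lens)
  M <- matrix(0L, nrow = L, ncol = length(seqs))
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(seqs)) {
    M[seq_len(lens[i]), i] <- match(chars[[i]], c(DNA_ALPHABET, PAD_SYMBOL),
                                    nomatch = 6L)
  }
  list(M = M, lens = lens)
}

# max similarity of each query column against all reference columns
max_sim_to_ref <- function(packed, query_idx, ref_idx) {
  M <- packed$M
  lens <- packed$lens
  vapply(query_idx, function(q) {
    mism <- colSums(M[, ref_idx, drop = FALSE] != M[, q])
    sims <- 1 - mism / pmax(lens[ref_idx], lens[q])
    if (length(sims) == 0) 0 else max(sims)
  }, numeric(1))
}

#' Configuration for the homology-aware split
#'
#' @param fractions Train/validation/test fractions; must sum to 1.
#' @param similarity_threshold Maximum allowed [normalized_similarity()]
#'   between a validation/test sequence and any same-class training sequence.
#' @param seed Integer seed controlling the random draw.
#' @return An object of class `split_config`.
#' @export
split_config <- function(fractions = c(train = 0.84, validation = 0.08, test = 0.08),
                         similarity_threshold = 0.50, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  if (similarity_threshold < 0 || similarity_threshold > 1) {
    abort("similarity_threshold must lie in [0, 1]")
  }
  structure(list(fractions = fractions,
                 similarity_threshold = similarity_threshold,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Homology-aware train/validation/test split
#'
#' Each class is split at random into train/validation/test at the requested
#' fractions (84/8/8 by default), then greedily repaired: any validation or
#' test sequence whose similarity to some training sequence of the same
#' class reaches the threshold is moved into train, and the repair is
#' iterated to a fixed point (moving a sequence into train can create new
#' violations). This limits the optimistic bias caused by near-identical
#' homologs landing on both sides of the split. Similarity is only
#' constrained within a class; classes with fewer than 3 records are placed
#' wholly in train with a warning.
#'
#' @param data A labeled sequence tibble (no missing labels).
#' @param config A [split_config()].
#' @return An object of class `split_result`: a list with tibbles `train`,
#'   `validation`, `test`, an `audit` tibble (id, label, split, and each
#'   validation/test record's maximum similarity to its class's training
#'   sequences), and the `config`. `tidy()` returns the audit table.
#' @export
similarity_aware_split <- function(data, config = split_config()) {
  if (anyNA(data$label)) abort("similarity_aware_split requires labeled records")
  set.seed(config$seed)
  assignment <- rep("train", nrow(data))
  max_sim <- rep(NA_real_, nrow(data))
  fr <- config$fractions
  thr <- config$similarity_threshold
  for (cl in dataset_classes(data)) {
    idx <- which(data$label == cl)
    n <- length(idx)
    if (n < 3) {
      warn(paste0("Class '", cl, "' has fewer than 3 records; placed wholly in train"))
      next
    }
    perm <- sample(idx)
    n_val <- round(fr[[2]] * n)
    n_test <- round(fr[[3]] * n)
    part <- rep("train", n)
    if (n_val > 0) part[seq_len(n_val)] <- "validation"
    if (n_test > 0) part[n_val + seq_len(n_test)] <- "test"
    packed <- pack_seq_matrix(data$sequence[idx])
    pos <- match(perm, idx) # column in packed for each permuted record
    repeat {
      train_pos <- pos[part == "train"]
      held <- which(part != "train")
      if (length(held) == 0) break
      sims <- max_sim_to_ref(packed, pos[held], train_pos)
      bad <- sims >= thr
      max_sim[perm[held]] <- sims
      if (!any(bad)) break
      part[held[bad]] <- "train"
      max_sim[perm[held[bad]]] <- NA_real_
    }
    assignment[perm] <- part
  }
  audit <- tibble::tibble(id = data$id, label = data$label,
                          split = assignment, max_sim_train = max_sim)
  structure(
    list(train = data[assignment == "train", , drop = FALSE],
         validation = data[assignment == "validation", , drop = FALSE],
         test = data[assignment == "test", , drop = FALSE],
         audit = audit, config = config),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> train ", nrow(x$train), " / validation ",
      nrow(x$validation), " / test ", nrow(x$test),
      " (similarity threshold ", x$config$similarity_threshold, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.split_result <- function(x, ...) x$audit

#' @export
glance.split_result <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$train), n_validation = nrow(x$validation),
    n_test = nrow(x$test),
    max_heldout_similarity = suppressWarnings(max(x$audit$max_sim_train,
                                                 na.rm = TRUE)),
    similarity_threshold = x$config$similarity_threshold
  )
}

base_markov_model <- function(chars) {
  init <- tabulate(match(chars, DNA_ALPHABET), 4)
  init <- init / sum(init)
  trans <- matrix(0, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  from <- match(chars[-length(chars)], DNA_ALPHABET)
  to <- match(chars[-1], DNA_ALPHABET)
  for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  rs <- rowSums(trans)
  for (r in 1:4) {
    trans[r, ] <- if (rs[r] > 0) trans[r, ] / rs[r] else init
  }
  list(init = init, trans = trans)
}

markov_flank <- function(model, m) {
  if (m == 0) return("")
  out <- integer(m)
  out[1] <- sample.int(4, 1, prob = model$init)
  if (m > 1) {
    for (i in 2:m) out[i] <- sample.int(4, 1, prob = model$trans[out[i - 1], ])
  }
  paste(DNA_ALPHABET[out], collapse = "")
}

#' Add boundary noise to sequence records
#'
#' Emulates uncertainty about where a transcript starts and ends (as arises
#' from sequencing read boundaries) by attaching random flanks to both ends
#' of each sequence. The total added length is `round(percent/100 * N)`
#' (round half up), split between the 5' and 3' flanks uniformly at random.
#' Flank bases are drawn from a first-order Markov chain fitted to the
#' record itself — initial distribution its nucleotide frequencies,
#' transitions its conditional dinucleotide frequencies — so the noise
#' preserves the sequence's nucleotide and dinucleotide composition. The
#' original sequence appears intact and contiguous inside the output.
#'
#' @param data A sequence tibble; every sequence must have length >= 2.
#' @param percent Noise level as a percentage of each sequence's length
#'   (the robustness experiments use 0, 25, ..., 200).
#' @param seed Integer seed.
#' @return The tibble with noised sequences and updated lengths.
#' @export
add_boundary_noise <- function(data, percent, seed = 1L) {
  if (percent < 0) abort("percent must be >= 0")
  if (percent == 0) return(data)
  if (any(nchar(data$sequence) < 2)) {
    abort("boundary noise requires sequences of length >= 2")
  }
  set.seed(seed)
  out <- data
  for (i in seq_len(nrow(data))) {
    s <- data$sequence[[i]]
    N <- nchar(s)
    total <- floor(percent / 100 * N + 0.5)
    five <- sample.int(total + 1L, 1) - 1L
    model <- base_markov_model(strsplit(s, "")[[1]])
    out$sequence[[i]] <- paste0(markov_flank(model, five), s,
                                markov_flank(model, total - five))
  }
  out$length <- nchar(out$sequence)
  out
}

dinucleotide_shuffle_one <- function(s) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  if (L < 2) return(s)
  v <- match(chars, DNA_ALPHABET)
  first <- v[1]; last <- v[L]
  succ <- split(v[-1], factor(v[-L], levels = 1:4)) # outgoing edge multisets
  outdeg <- lengths(succ)
  active <- which(outdeg > 0)
  # Altschul-Erickson: choose a random last-exit edge for every active vertex
  # except the terminal one; accept when those edges form paths into `last`.
  need <- setdiff(active, last)
  repeat {
    last_edge <- rep(NA_integer_, 4)
    for (vtx in need) last_edge[vtx] <- succ[[vtx]][sample.int(outdeg[vtx], 1)]
    ok <- TRUE
    for (vtx in need) {
      cur <- vtx; seen <- integer(0)
      while (cur != last && !is.na(last_edge[cur])) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[cur]
      }
      if (!ok || (cur != last && cur %in% need)) { ok <- FALSE }
      if (!ok) break
      }
    if (ok || length(need) == 0) break
  }
  order_edges <- vector("list", 4)
  for (vtx in active) {
    edges <- succ[[vtx]]
    if (vtx %in% need) {
      le <- last_edge[vtx]
      pos <- which(edges == le)[1]
      rest <- edges[-pos]
      order_edges[[vtx]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                              le)
    } else {
      order_edges[[vtx]] <- edges[sample.int(length(edges))]
    }
  }
  ptr <- rep(1L, 4)
  out <- integer(L)
  out[1] <- first
  cur <- first
  for (i in 2:L) {
    nxt <- order_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(DNA_ALPHABET[out], collapse = "")
}

#' Dinucleotide-preserving shuffle
#'
#' Permutes each sequence while keeping its exact multiset of adjacent base
#' pairs — hence also its length, nucleotide composition, and first and last
#' base. Shuffles are drawn via the Eulerian-path construction of Altschul
#' and Erickson: the dinucleotides form edges of a multigraph over the four
#' bases, a random last-exit edge per vertex is accepted when it spans an
#' arborescence into the final base, and remaining edges are consumed in
#' random order. Shuffled sequences serve as non-functional negatives whose
#' low-order composition matches the real sequences exactly.
#'
#' @param data A sequence tibble.
#' @param seed Integer seed.
#' @return The tibble with shuffled sequences.
#' @export
dinucleotide_shuffle <- function(data, seed = 1L) {
  set.seed(seed)
  out <- data
  out$sequence <- vapply(data$sequence, dinucleotide_shuffle_one, character(1),
                         USE.NAMES = FALSE)
  out
}

# ---- minimal 1D CART on a single numeric feature (gini impurity) ----

fit_length_tree <- function(x, y, max_depth = 8, min_split = 10, min_bucket = 5) {
  classes <- levels(y)
  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], length(classes))
    node <- list(leaf = TRUE, class = classes[which.max(counts)])
    if (depth >= max_depth || length(idx) < min_split || sum(counts > 0) < 2) {
      return(node)
    }
    ord <- idx[order(x[idx])]
    xs <- x[ord]
    Y <- outer(y[ord], classes, "==") * 1
    cumL <- apply(Y, 2, cumsum)
    n <- length(ord)
    nl <- seq_len(n)
    tot <- cumL[n, ]
    gl <- 1 - rowSums(cumL^2) / nl^2
    cumR <- sweep(-cumL, 2, tot, "+")
    nr <- n - nl
    gr <- 1 - rowSums(cumR^2) / pmax(nr, 1)^2
    score <- (nl * gl + nr * gr) / n
    valid <- nl >= min_bucket & nr >= min_bucket & xs != c(xs[-1], NA)
    if (!any(valid, na.rm = TRUE)) return(node)
    best <- which(valid & score == min(score[valid], na.rm = TRUE))[1]
    parent_gini <- 1 - sum((tot / n)^2)
    if (score[best] >= parent_gini - 1e-12) return(node)
    cut <- (xs[best] + xs[best + 1]) / 2
    left <- idx[x[idx] <= cut]
    right <- idx[x[idx] > cut]
    list(leaf = FALSE, cut = cut,
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  structure(list(root = grow(seq_along(x), 0), classes = classes),
            class = "length_tree")
}

predict_length_tree <- function(tree, x) {
  one <- function(node, v) {
    while (!node$leaf) node <- if (v <= node$cut) node$left else node$right
    node$class
  }
  vapply(x, function(v) one(tree$root, v), character(1))
}

#' Flag classes predictable from sequence length alone
#'
#' Some families have such narrow length distributions that a classifier
#' using only sequence length separates them; keeping them would let a model
#' "cheat" on length instead of sequence content. This screen runs k-fold
#' cross-validation of a decision tree whose sole feature is sequence length
#' and reports each class's mean F1 across folds; classes with mean F1 above
#' `f1_cutoff` should be removed by the caller.
#'
#' @param data A labeled sequence tibble (>= 2 classes).
#' @param f1_cutoff Mean-F1 threshold above which a class is flagged.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with columns `label`, `f1` (mean per-class F1 over the
#'   folds in which the class appears) and `flagged`.
#' @export
screen_length_predictable <- function(data, f1_cutoff = 0.80, folds = 10,
                                      seed = 1L) {
  classes <- dataset_classes(data)
  if (length(classes) < 2) abort("screen requires at least 2 classes")
  set.seed(seed)
  y <- factor(data$label, levels = classes)
  fold_id <- integer(nrow(data))
  for (cl in classes) {
    idx <- which(data$label == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f1 <- matrix(NA_real_, folds, length(classes),
               dimnames = list(NULL, classes))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    if (!any(te) || length(unique(y[tr])) < 2) next
    tree <- fit_length_tree(data$length[tr], droplevels(y[tr]))
    pred <- predict_length_tree(tree, data$length[te])
    truth <- as.character(y[te])
    for (cl in unique(truth)) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      if (tp + fp + fn > 0) f1[f, cl] <- 2 * tp / (2 * tp + fp + fn)
    }
  }
  mean_f1 <- colMeans(f1, na.rm = TRUE)
  mean_f1[is.nan(mean_f1)] <- NA_real_
  tibble::tibble(label = classes, f1 = unname(mean_f1),
                 flagged = !is.na(mean_f1) & mean_f1 > f1_cutoff)
}
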