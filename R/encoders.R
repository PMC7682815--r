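#' Describe how sequences become fixed-size channel arrays
#'
#' An encoding spec fixes everything needed to turn a set of sequences into
#' a dense one-hot array: the representation (non-overlapping k-mer vectors,
#' or a Hilbert / Morton / Snake space-filling-curve grid), the k-mer order,
#' the maximum sequence length the layout must accommodate, and the padding
#' scheme used to fill positions beyond the sequence payload.
#'
#' Padding schemes:
#' \describe{
#'   \item{`new`}{vacant positions are filled with a symbol outside the DNA
#'     alphabet (`E`), which gets its own one-hot channel;}
#'   \item{`constant`}{vacant positions are filled with one fixed DNA letter
#'     (`constant_symbol`);}
#'   \item{`random`}{vacant positions are filled with i.i.d. uniform draws
#'     from {A, C, G, T}, reproducible under `seed`.}
#' }
#'
#' @param representation One of `"kmer"`, `"hilbert"`, `"morton"`, `"snake"`.
#' @param k k-mer order, an integer in 1..3 (k-mer representation only).
#' @param max_len Maximum sequence length (nt) the encoding must hold.
#' @param padding One of `"random"`, `"constant"`, `"new"`.
#' @param constant_symbol DNA letter used by the constant scheme.
#' @param seed Integer seed used by the random scheme.
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(representation = c("kmer", "hilbert", "morton", "snake"),
                          k = 1, max_len = 200,
                          padding = c("new", "constant", "random"),
                          constant_symbol = "A", seed = 1L) {
  representation <- match.arg(representation)
  padding <- match.arg(padding)
  if (!(k %in% 1:3)) abort("k must be 1, 2 or 3")
  if (max_len < 1) abort("max_len must be >= 1")
  if (!(constant_symbol %in% DNA_ALPHABET)) {
    abort("constant_symbol must be one of A, C, G, T")
  }
  structure(
    list(representation = representation, k = as.integer(k),
         max_len = as.integer(max_len), padding = padding,
         constant_symbol = constant_symbol, seed = as.integer(seed)),
    class = "encoding_spec"
  )
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat("<encoding_spec> ", x$representation,
      if (x$representation == "kmer") paste0(" (k = ", x$k, ")"),
      ", max_len = ", x$max_len, ", padding = ", x$padding, "\n", sep = "")
  invisible(x)
}

#' Grid side (or 1D position count) for a representation
#'
#' Hilbert and Morton curves require a power-of-two grid, so the side is the
#' smallest power of two whose square holds `max_len` bases; the Snake curve
#' works on any square, so the side is `ceiling(sqrt(max_len))`. For the
#' k-mer representation the return value is the number of 1D positions,
#' `ceiling(max_len / k)`.
#'
#' @inheritParams encoding_spec
#' @param k k-mer order (k-mer representation only).
#' @return An integer: grid side for 2D representations, position count for
#'   k-mer. At `max_len = 200` this gives 16 (Hilbert/Morton) and 15 (Snake).
#' @export
grid_side_for <- function(representation, max_len, k = 1) {
  stopifnot(max_len >= 1)
  switch(representation,
    hilbert = ,
    morton = {
      s <- 1L
      while (s * s < max_len) s <- s * 2L
      s
    },
    snake = as.integer(ceiling(sqrt(max_len))),
    kmer = as.integer(ceiling(max_len / k)),
    abort(paste0("Unknown representation: ", representation))
  )
}

hilbert_d2xy <- function(side, d) {
  # classic iterative Hilbert decode: d = 0 -> (0,0), d = side^2-1 -> (side-1, 0)
  x <- 0L; y <- 0L; t <- d; s <- 1L
  while (s < side) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    if (ry == 0L) {
      if (rx == 1L) {
        x <- s - 1L - x
        y <- s - 1L - y
      }
      tmp <- x; x <- y; y <- tmp
    }
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- s * 2L
  }
  c(x, y)
}

interleave_bits <- function(row, col, nbits) {
  # Morton index with the row bit as the more significant of each pair
  d <- 0L
  for (b in (nbits - 1L):0) {
    d <- d * 4L +
      2L * bitwAnd(1L, bitwShiftR(row, b)) +
      bitwAnd(1L, bitwShiftR(col, b))
  }
  d
}

#' Space-filling-curve traversal of a square grid
#'
#' Returns the full, deterministic traversal order in which sequence bases
#' are laid onto the grid. Every cell is visited exactly once. Hilbert and
#' Snake traversals move between 4-neighbours at every step (locality
#' preserving); the Morton (Z-order) traversal, obtained by bit-interleaving
#' row and column indices, is not adjacency preserving.
#'
#' Conventions: all three curves start at cell (0, 0). The Hilbert curve is
#' the classic order-n construction ending at (side-1, 0); Morton interleaves
#' with the row bit more significant; Snake is a row-major boustrophedon with
#' even rows traversed left to right.
#'
#' @param representation `"hilbert"`, `"morton"` or `"snake"`.
#' @param side Grid side length; must be a power of two for Hilbert/Morton.
#' @return A tibble of class `curve_path` with columns `step` (1-based),
#'   `row`, `col` (0-based), and attributes `side`, `representation`.
#' @examples
#' curve_path("snake", 2)
#' @export
curve_path <- function(representation = c("hilbert", "morton", "snake"), side) {
  representation <- match.arg(representation)
  side <- as.integer(side)
  if (side < 1) abort("side must be >= 1")
  n <- side * side
  if (representation %in% c("hilbert", "morton")) {
    if (bitwAnd(side, side - 1L) != 0L) {
      abort(paste0(representation, " curve requires a power-of-two side, got ", side))
    }
  }
  cells <- switch(representation,
    snake = {
      rows <- rep(0:(side - 1L), each = side)
      cols <- ifelse(rows %% 2L == 0L,
                     rep(0:(side - 1L), times = side),
                     rep((side - 1L):0, times = side))
      cbind(rows, cols)
    },
    hilbert = t(vapply(0:(n - 1L), function(d) hilbert_d2xy(side, d),
                       integer(2))),
    morton = {
      nbits <- max(1L, as.integer(round(log2(side))))
      grid <- expand.grid(col = 0:(side - 1L), row = 0:(side - 1L))
      d <- mapply(interleave_bits, grid$row, grid$col,
                  MoreArgs = list(nbits = nbits))
      ord <- order(d)
      cbind(grid$row[ord], grid$col[ord])
    }
  )
  out <- tibble::tibble(step = seq_len(n),
                        row = as.integer(cells[, 1]),
                        col = as.integer(cells[, 2]))
  structure(out, side = side, representation = representation,
            class = c("curve_path", class(out)))
}

#' Pad a sequence to a target length under an encoding spec's scheme
#'
#' The original sequence is kept as an unchanged prefix; appended symbols
#' follow the spec's padding scheme (see [encoding_spec()]). The random
#' scheme consumes the current RNG stream, so batch encoders seed once from
#' `spec$seed` before padding all records.
#'
#' @param sequence A single sequence string.
#' @param target_len Total length after padding.
#' @param spec An [encoding_spec()].
#' @return The padded string.
#' @export
pad_sequence <- function(sequence, target_len, spec) {
  n <- nchar(sequence)
  if (n > target_len) {
    abort(paste0("Sequence of length ", n, " exceeds target length ",
                 target_len, "; truncate or reject it first"))
  }
  extra <- target_len - n
  if (extra == 0) return(sequence)
  pad <- switch(spec$padding,
    new = strrep(PAD_SYMBOL, extra),
    constant = strrep(spec$constant_symbol, extra),
    random = paste(sample(DNA_ALPHABET, extra, replace = TRUE), collapse = "")
  )
  paste0(sequence, pad)
}

kmer_channel_names <- function(k, with_pad) {
  words <- DNA_ALPHABET
  if (k >= 2) {
    for (i in 2:k) {
      words <- as.vector(t(outer(words, DNA_ALPHABET, paste0)))
    }
  }
  words <- sort(words) # lexicographic, A < C < G < T
  if (with_pad) c(words, strrep(PAD_SYMBOL, 1)) else words
}

seq_to_base_matrix <- function(padded, alphabet) {
  n <- length(padded)
  L <- nchar(padded[[1]])
  chars <- strsplit(padded, "", fixed = TRUE)
  idx <- match(unlist(chars), alphabet)
  if (anyNA(idx)) {
    abort("Sequence contains letters outside {A,C,G,T}; run filter_canonical() first")
  }
  matrix(idx, nrow = n, ncol = L, byrow = TRUE)
}

new_encoded_batch <- function(array, channel_names, payload_lengths,
                              seq_lengths, ids, spec, path = NULL) {
  structure(
    list(array = array, channel_names = channel_names,
         payload_lengths = as.integer(payload_lengths),
         seq_lengths = as.integer(seq_lengths),
         ids = ids, spec = spec, path = path),
    class = "encoded_batch"
  )
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat("<encoded_batch> ", paste(dim(x$array), collapse = " x "),
      " (", x$spec$representation, ", padding = ", x$spec$padding, ")\n",
      sep = "")
  invisible(x)
}

#' Encode sequences as non-overlapping k-mer one-hot vectors (1D)
#'
#' Each sequence is padded to `k * ceiling(max_len / k)` symbols and chunked
#' into consecutive non-overlapping k-letter words; each word becomes a
#' one-hot vector over the `4^k` canonical words, indexed lexicographically
#' with A < C < G < T. Under the `new` padding scheme, any word containing
#' the pad symbol maps to one extra dedicated pad channel. A 100-nt sequence
#' at k = 2 therefore yields 50 one-hot vectors of 16 canonical entries.
#'
#' @param data A sequence tibble (columns `id`, `sequence`).
#' @param spec An [encoding_spec()] with `representation = "kmer"`.
#' @return An `encoded_batch` whose `array` has shape
#'   (n_records, positions, channels), channels last.
#' @export
encode_kmer <- function(data, spec) {
  if (spec$representation != "kmer") abort("spec$representation must be 'kmer'")
  k <- spec$k
  positions <- grid_side_for("kmer", spec$max_len, k = k)
  total_len <- k * positions
  lens <- nchar(data$sequence)
  if (any(lens > spec$max_len)) {
    abort("All sequences must be <= spec$max_len; run filter_canonical() first")
  }
  n <- nrow(data)
  with_pad <- spec$padding == "new"
  channels <- kmer_channel_names(k, with_pad)
  C <- length(channels)
  if (n == 0) {
    return(new_encoded_batch(array(0, c(0, positions, C)), channels,
                             integer(0), integer(0), character(0), spec))
  }
  set.seed(spec$seed)
  padded <- vapply(data$sequence, pad_sequence, character(1),
                   target_len = total_len, spec = spec, USE.NAMES = FALSE)
  alphabet <- c(DNA_ALPHABET, PAD_SYMBOL)
  B <- seq_to_base_matrix(padded, alphabet) - 1L # 0..3 bases, 4 pad
  word_idx <- matrix(0L, n, positions)
  has_pad <- matrix(FALSE, n, positions)
  for (j in seq_len(k)) {
    col_j <- B[, seq(j, total_len, by = k), drop = FALSE]
    has_pad <- has_pad | (col_j == 4L)
    word_idx <- word_idx * 4L + pmin(col_j, 3L)
  }
  channel <- word_idx + 1L
  channel[has_pad] <- C # pad channel is last (only exists for 'new')
  X <- array(0, c(n, positions, C))
  X[cbind(rep(seq_len(n), positions),
          rep(seq_len(positions), each = n),
          as.vector(channel))] <- 1
  new_encoded_batch(X, channels, ceiling(lens / k), lens, data$id, spec)
}

#' Encode sequences onto a 2D space-filling-curve grid
#'
#' The i-th symbol of the padded sequence is written to the i-th cell of the
#' curve traversal ([curve_path()]); each cell carries a one-hot vector over
#' the four DNA letters, plus one pad channel under the `new` scheme. The
#' grid side follows [grid_side_for()] (16 x 16 for Hilbert/Morton and
#' 15 x 15 for Snake at `max_len = 200`).
#'
#' @param data A sequence tibble (columns `id`, `sequence`).
#' @param spec An [encoding_spec()] with a curve representation.
#' @return An `encoded_batch` whose `array` has shape
#'   (n_records, side, side, channels), channels last.
#' @export
encode_curve <- function(data, spec) {
  if (!(spec$representation %in% c("hilbert", "morton", "snake"))) {
    abort("spec$representation must be hilbert, morton or snake")
  }
  side <- grid_side_for(spec$representation, spec$max_len)
  capacity <- side * side
  lens <- nchar(data$sequence)
  if (any(lens > spec$max_len)) {
    abort("All sequences must be <= spec$max_len; run filter_canonical() first")
  }
  path <- curve_path(spec$representation, side)
  with_pad <- spec$padding == "new"
  channels <- if (with_pad) c(DNA_ALPHABET, PAD_SYMBOL) else DNA_ALPHABET
  C <- length(channels)
  n <- nrow(data)
  if (n == 0) {
    return(new_encoded_batch(array(0, c(0, side, side, C)), channels,
                             integer(0), integer(0), character(0), spec, path))
  }
  set.seed(spec$seed)
  padded <- vapply(data$sequence, pad_sequence, character(1),
                   target_len = capacity, spec = spec, USE.NAMES = FALSE)
  B <- seq_to_base_matrix(padded, channels) # n x capacity, values 1..C
  X <- array(0, c(n, side, side, C))
  i <- rep(seq_len(n), capacity)
  r <- rep(path$row, each = n) + 1L
  cc <- rep(path$col, each = n) + 1L
  ch <- as.vector(B)
  X[cbind(i, r, cc, ch)] <- 1
  new_encoded_batch(X, channels, lens, lens, data$id, spec, path)
}

#' Encode a sequence tibble under any representation
#'
#' Dispatches to [encode_kmer()] or [encode_curve()] according to the spec.
#'
#' @inheritParams encode_kmer
#' @return An `encoded_batch`.
#' @export
encode_sequences <- function(data, spec) {
  if (spec$representation == "kmer") encode_kmer(data, spec)
  else encode_curve(data, spec)
}

#' Decode an encoded batch back to sequence strings
#'
#' Inverts the one-hot encoding, reading grid cells back along the curve
#' traversal for 2D representations, and strips padding using the stored
#' original sequence lengths. For k-mer encodings under the `new` scheme a
#' trailing partial word is unrecoverable (it was mapped to the pad channel),
#' so exact round-trips hold when sequence length is a multiple of k.
#'
#' @param batch An `encoded_batch`.
#' @return Character vector of decoded sequences.
#' @export
decode_batch <- function(batch) {
  spec <- batch$spec
  n <- dim(batch$array)[1]
  if (n == 0) return(character(0))
  if (spec$representation == "kmer") {
    P <- dim(batch$array)[2]
    out <- character(n)
    for (i in seq_len(n)) {
      ch <- apply(batch$array[i, , , drop = FALSE][1, , ], 1, which.max)
      words <- batch$channel_names[ch]
      words <- words[!grepl(PAD_SYMBOL, words, fixed = TRUE)]
      s <- paste(words, collapse = "")
      out[i] <- substr(s, 1, min(nchar(s), batch$seq_lengths[i]))
    }
    out
  } else {
    path <- batch$path
    out <- character(n)
    for (i in seq_len(n)) {
      g <- batch$array[i, , , , drop = FALSE]
      dim(g) <- dim(batch$array)[-1]
      ch <- mapply(function(r, c) which.max(g[r + 1, c + 1, ]),
                   path$row, path$col)
      s <- paste(batch$channel_names[ch], collapse = "")
      out[i] <- substr(s, 1, batch$seq_lengths[i])
    }
    out
  }
}

#' @export
autoplot.curve_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0(attr(object, "representation"), " curve, side ",
                     attr(object, "side")),
      x = "column", y = "row"
    ) +
    ggplot2::theme_minimal()
}

#' Variable-length k-mer encoding for recurrent models
#'
#' Encodes each sequence as its own (positions x 4^k) one-hot matrix with no
#' padding, as consumed by the bidirectional LSTM family. Only complete
#' k-words are emitted: a trailing partial word (sequence length not a
#' multiple of k) is dropped, since without padding it has no canonical
#' channel.
#'
#' @param data A sequence tibble (columns `id`, `sequence`).
#' @param spec An [encoding_spec()] with `representation = "kmer"`; the
#'   padding scheme is ignored.
#' @return An object of class `ragged_batch`: a list of one-hot matrices
#'   (`seqs`), plus `channel_names`, `payload_lengths`, `seq_lengths`, `ids`.
#' @export
encode_kmer_ragged <- function(data, spec) {
  if (spec$representation != "kmer") abort("spec$representation must be 'kmer'")
  k <- spec$k
  channels <- kmer_channel_names(k, with_pad = FALSE)
  C <- length(channels)
  seqs <- vector("list", nrow(data))
  lens <- nchar(data$sequence)
  for (i in seq_len(nrow(data))) {
    L <- lens[i] %/% k
    if (L < 1) abort("Sequence shorter than k cannot be encoded without padding")
    s <- substr(data$sequence[[i]], 1, L * k)
    b <- match(strsplit(s, "")[[1]], DNA_ALPHABET) - 1L
    if (anyNA(b)) abort("Sequence contains letters outside {A,C,G,T}")
    word <- integer(L)
    for (j in seq_len(k)) word <- word * 4L + b[seq(j, L * k, by = k)]
    M <- matrix(0, L, C)
    M[cbind(seq_len(L), word + 1L)] <- 1
    seqs[[i]] <- M
  }
  structure(list(seqs = seqs, channel_names = channels,
                 payload_lengths = lens %/% k, seq_lengths = lens,
                 ids = data$id, spec = spec),
            class = "ragged_batch")
}

#' @export
print.ragged_batch <- function(x, ...) {
  cat("<ragged_batch> ", length(x$seqs), " sequences, ",
      length(x$channel_names), " channels (k = ", x$spec$k, ", no padding)\n",
      sep = "")
  invisible(x)
}
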