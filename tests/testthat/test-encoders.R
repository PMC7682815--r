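# independent Morton oracle: sort cells by bit-interleaved keys built from
# binary strings (no shared code with the package implementation)
morton_oracle <- function(side) {
  nbits <- ceiling(log2(max(side, 2)))
  grid <- expand.grid(row = 0:(side - 1), col = 0:(side - 1))
  key <- apply(grid, 1, function(g) {
    rb <- rev(as.integer(intToBits(g["row"]))[1:nbits])
    cb <- rev(as.integer(intToBits(g["col"]))[1:nbits])
    paste(rbind(rb, cb), collapse = "")
  })
  grid[order(key), c("row", "col")]
}

test_that("grid sizing matches the published maximum dimensions", {
  expect_equal(grid_side_for("hilbert", 200), 16)
  expect_equal(grid_side_for("morton", 200), 16)
  expect_equal(grid_side_for("snake", 200), 15)
  expect_equal(grid_side_for("hilbert", 4), 2)
  expect_equal(grid_side_for("kmer", 200, k = 1), 200)
  expect_equal(grid_side_for("kmer", 200, k = 2), 100)
  expect_equal(grid_side_for("kmer", 200, k = 3), 67)
  expect_error(grid_side_for("spiral", 200), "Unknown")
})

test_that("snake path follows the boustrophedon convention", {
  p <- curve_path("snake", 2)
  expect_equal(cbind(p$row, p$col),
               rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
})

test_that("all curves visit every cell exactly once (sides up to 16)", {
  for (side in 1:16) {
    reps <- if (side %in% c(1, 2, 4, 8, 16)) c("hilbert", "morton", "snake")
            else "snake"
    for (r in reps) {
      p <- curve_path(r, side)
      expect_equal(nrow(p), side^2)
      expect_equal(nrow(unique(p[, c("row", "col")])), side^2)
      expect_true(all(p$row >= 0 & p$row < side & p$col >= 0 & p$col < side))
    }
  }
  expect_error(curve_path("hilbert", 3), "power-of-two")
  expect_error(curve_path("morton", 12), "power-of-two")
})

test_that("hilbert and snake are 4-adjacent at every step; morton matches bit interleaving", {
  for (side in c(2, 4, 8, 16)) {
    for (r in c("hilbert", "snake")) {
      p <- curve_path(r, side)
      expect_true(all(abs(diff(p$row)) + abs(diff(p$col)) == 1),
                  info = paste(r, side))
    }
    m <- curve_path("morton", side)
    o <- morton_oracle(side)
    expect_equal(m$row, o$row)
    expect_equal(m$col, o$col)
  }
})

test_that("padding schemes behave as specified", {
  expect_equal(pad_sequence("ACG", 5, encoding_spec("kmer", padding = "new")),
               "ACGEE")
  expect_equal(pad_sequence("ACG", 5, encoding_spec("kmer", padding = "constant",
                                                    constant_symbol = "A")),
               "ACGAA")
  set.seed(1)
  p <- pad_sequence("ACG", 5, encoding_spec("kmer", padding = "random"))
  expect_equal(nchar(p), 5)
  expect_equal(substr(p, 1, 3), "ACG")
  expect_true(grepl("^[ACGT]{2}$", substr(p, 4, 5)))
  expect_error(pad_sequence("ACGTT", 3, encoding_spec("kmer")), "exceeds")
})

test_that("2-mer encoding of a 100-nt sequence gives 50 one-hot vectors of 16 entries", {
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  spec <- encoding_spec("kmer", k = 2, max_len = 100, padding = "constant")
  b <- encode_kmer(seq_tibble(s), spec)
  expect_equal(dim(b$array), c(1, 50, 16))
  expect_equal(b$payload_lengths, 50L)
  expect_true(all(apply(b$array[1, , ], 1, sum) == 1))
})

test_that("k-mer channels are indexed lexicographically with A<C<G<T", {
  b <- encode_kmer(seq_tibble("ACGT"),
                   encoding_spec("kmer", k = 2, max_len = 4))
  expect_equal(b$channel_names[1:16],
               sort(as.vector(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0))))
  expect_equal(which(b$array[1, 1, ] == 1), match("AC", b$channel_names))
  expect_equal(which(b$array[1, 2, ] == 1), match("GT", b$channel_names))
  expect_equal(match(c("AC", "GT"), b$channel_names), c(2, 12)) # 0-based 1, 11
})

test_that("k outside 1..3 is rejected", {
  expect_error(encoding_spec("kmer", k = 4), "k must be")
})

test_that("curve encoding fills payload cells and pads the rest", {
  s <- paste(rep("A", 47), collapse = "")
  spec <- encoding_spec("hilbert", max_len = 200, padding = "new")
  b <- encode_curve(seq_tibble(s), spec)
  expect_equal(dim(b$array), c(1, 16, 16, 5))
  pad_ch <- match("E", b$channel_names)
  expect_equal(sum(b$array[1, , , pad_ch]), 256 - 47)
  expect_equal(sum(b$array[1, , , -pad_ch]), 47)
  # full grid -> zero padding cells
  s2 <- paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = "")
  b2 <- encode_curve(seq_tibble(s2), encoding_spec("snake", max_len = 16))
  expect_equal(sum(b2$array[1, , , 5]), 0)
})

test_that("every position is one-hot under all representations and paddings", {
  set.seed(11)
  d <- seq_tibble(random_dna(5, c(10, 60)))
  for (rep_ in c("kmer", "hilbert", "morton", "snake")) {
    for (pad in c("new", "constant", "random")) {
      spec <- encoding_spec(rep_, k = 2, max_len = 64, padding = pad, seed = 3)
      b <- encode_sequences(d, spec)
      sums <- apply(b$array, seq_along(dim(b$array))[-length(dim(b$array))], sum)
      expect_true(all(sums == 1), info = paste(rep_, pad))
    }
  }
})

test_that("encode/decode round trip recovers the input", {
  set.seed(21)
  for (pad in c("new", "constant", "random")) {
    d <- seq_tibble(random_dna(6, c(10, 60)))
    for (rep_ in c("hilbert", "morton", "snake")) {
      spec <- encoding_spec(rep_, max_len = 64, padding = pad, seed = 5)
      expect_equal(decode_batch(encode_curve(d, spec)), d$sequence,
                   info = paste(rep_, pad))
    }
    for (k in 1:3) {
      # 'new' padding cannot recover a trailing partial word; use multiples of k
      lens <- k * sample(5:20, 6, replace = TRUE)
      dk <- seq_tibble(vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1)))
      spec <- encoding_spec("kmer", k = k, max_len = 60, padding = pad, seed = 5)
      expect_equal(decode_batch(encode_kmer(dk, spec)), dk$sequence,
                   info = paste("kmer", k, pad))
    }
  }
})

test_that("ragged k-mer encoding has no padding and 4^k channels", {
  d <- seq_tibble(c("ACGTACG", "TTAACC"))
  r <- encode_kmer_ragged(d, encoding_spec("kmer", k = 2, max_len = 200))
  expect_s3_class(r, "ragged_batch")
  expect_equal(nrow(r$seqs[[1]]), 3) # 7 nt -> 3 complete 2-words
  expect_equal(nrow(r$seqs[[2]]), 3)
  expect_equal(ncol(r$seqs[[1]]), 16)
  expect_true(all(rowSums(r$seqs[[1]]) == 1))
})

test_that("sequences longer than the layout are rejected", {
  d <- seq_tibble(strrep("A", 300))
  expect_error(encode_kmer(d, encoding_spec("kmer", max_len = 200)), "max_len")
  expect_error(encode_curve(d, encoding_spec("hilbert", max_len = 200)), "max_len")
})
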