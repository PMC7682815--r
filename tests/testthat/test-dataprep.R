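test_that("normalized similarity follows the unequal-length Hamming rule", {
  expect_equal(normalized_similarity("ACGT", "ACGT"), 1.0)
  expect_equal(normalized_similarity("AAAA", "TTTT"), 0.0)
  expect_equal(normalized_similarity("AAAA", "AA"), 0.5)
  set.seed(2)
  for (i in 1:20) {
    a <- random_dna(1, c(5, 40)); b <- random_dna(1, c(5, 40))
    expect_equal(normalized_similarity(a, b), normalized_similarity(b, a))
    expect_gte(normalized_similarity(a, b), 0)
    expect_lte(normalized_similarity(a, b), 1)
  }
  expect_error(normalized_similarity("", "ACGT"), "non-empty")
})

test_that("split partitions the data and honours fractions when the constraint is inactive", {
  set.seed(9)
  d <- seq_tibble(random_dna(200, c(60, 100)),
                  labels = rep(c("a", "b"), each = 100))
  res <- similarity_aware_split(d, split_config(seed = 3))
  expect_equal(sort(c(res$train$id, res$validation$id, res$test$id)),
               sort(d$id))
  # random 60-100 nt sequences rarely reach similarity 0.5: fractions hold
  expect_equal(nrow(res$train) / 200, 0.84, tolerance = 0.04)
  expect_equal(nrow(res$validation) / 200, 0.08, tolerance = 0.04)
  expect_equal(nrow(res$test) / 200, 0.08, tolerance = 0.04)
  aud <- tidy(res)
  expect_true(all(aud$max_sim_train[aud$split != "train"] < 0.5))
})

test_that("identical copies are forced into train by the repair rule", {
  d <- seq_tibble(rep(strrep("ACGT", 10), 50), labels = "a",
                  ids = sprintf("c%02d", 1:50))
  res <- suppressWarnings(similarity_aware_split(d, split_config(seed = 1)))
  expect_equal(nrow(res$train), 50)
  expect_equal(nrow(res$validation), 0)
  expect_equal(nrow(res$test), 0)
})

test_that("threshold 1 with distinct sequences gives a plain stratified split", {
  set.seed(5)
  d <- seq_tibble(random_dna(100, c(50, 60)), labels = "a")
  res <- similarity_aware_split(
    d, split_config(similarity_threshold = 1.0, seed = 2))
  expect_equal(nrow(res$validation), 8)
  expect_equal(nrow(res$test), 8)
})

test_that("no heldout record is similar to a same-class training record, with planted near-duplicates", {
  set.seed(31)
  base <- random_dna(30, c(60, 80))
  mutate_one <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
    s
  }
  d <- seq_tibble(c(base, vapply(base, mutate_one, character(1)),
                    random_dna(40, c(60, 80))),
                  labels = "fam", ids = sprintf("r%03d", 1:100))
  res <- similarity_aware_split(d, split_config(seed = 8))
  packed_train <- res$train$sequence
  for (s in c(res$validation$sequence, res$test$sequence)) {
    sims <- vapply(packed_train, function(t) normalized_similarity(s, t),
                   numeric(1))
    expect_true(all(sims < 0.5))
  }
})

test_that("tiny classes go wholly to train with a warning", {
  d <- seq_tibble(random_dna(52, c(30, 40)),
                  labels = rep(c("big", "small"), c(50, 2)))
  expect_warning(res <- similarity_aware_split(d, split_config(seed = 1)),
                 "fewer than 3")
  expect_true(all(res$train$label[res$train$label == "small"] == "small"))
  expect_equal(sum(c(res$validation$label, res$test$label) == "small"), 0)
})

test_that("boundary noise lengths are exact across the full percentage grid", {
  set.seed(13)
  d <- seq_tibble(random_dna(10, c(20, 120)), labels = "a")
  expect_identical(add_boundary_noise(d, 0, seed = 1), d)
  for (pct in c(25, 50, 75, 100, 125, 150, 175, 200)) {
    noised <- add_boundary_noise(d, pct, seed = 2)
    expect_equal(noised$length, d$length + floor(pct / 100 * d$length + 0.5))
    # original sequence intact and contiguous
    for (i in seq_len(nrow(d))) {
      expect_true(grepl(d$sequence[i], noised$sequence[i], fixed = TRUE))
    }
  }
  d100 <- seq_tibble(random_dna(1, c(100, 100)))
  expect_equal(add_boundary_noise(d100, 200, seed = 3)$length, 300)
  expect_error(add_boundary_noise(d, -5, seed = 1), "percent")
})

test_that("noise flanks reproduce the source dinucleotide frequencies", {
  set.seed(17)
  src <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                      prob = c(0.4, 0.1, 0.3, 0.2)), collapse = "")
  d <- seq_tibble(rep(src, 1000), ids = sprintf("n%04d", 1:1000))
  noised <- add_boundary_noise(d, 100, seed = 23)
  flanks <- vapply(noised$sequence, function(s) sub(src, "|", s, fixed = TRUE),
                   character(1), USE.NAMES = FALSE)
  five <- sub("\\|.*$", "", flanks)
  three <- sub("^.*\\|", "", flanks)
  flank_counts <- Reduce(`+`, lapply(c(five, three), function(s) {
    if (nchar(s) < 2) dinuc_counts("AA") * 0 else dinuc_counts(s)
  }))
  src_freq <- as.numeric(dinuc_counts(src)) / (nchar(src) - 1)
  flank_freq <- as.numeric(flank_counts) / sum(flank_counts)
  expect_true(all(abs(flank_freq - src_freq) < 0.05))
})

test_that("dinucleotide shuffle conserves counts and endpoints exactly", {
  set.seed(19)
  d <- seq_tibble(random_dna(200, c(20, 200)), ids = sprintf("q%03d", 1:200))
  sh <- dinucleotide_shuffle(d, seed = 7)
  for (i in seq_len(nrow(d))) {
    expect_equal(dinuc_counts(sh$sequence[i]), dinuc_counts(d$sequence[i]))
    expect_equal(substr(sh$sequence[i], 1, 1), substr(d$sequence[i], 1, 1))
    L <- nchar(d$sequence[i])
    expect_equal(substr(sh$sequence[i], L, L), substr(d$sequence[i], L, L))
  }
  expect_equal(dinucleotide_shuffle(seq_tibble("AAAA"), seed = 1)$sequence,
               "AAAA")
})

test_that("short-sequence shuffles stay within the brute-force arrangement set", {
  set.seed(23)
  for (s in c("ACGTGC", "AACGT", "ACACA", "TGCAT", "GGTACC")) {
    valid <- brute_dinuc_arrangements(s)
    outs <- vapply(1:40, function(seed) {
      dinucleotide_shuffle(seq_tibble(s), seed = seed)$sequence
    }, character(1))
    expect_true(all(outs %in% valid), info = s)
  }
})

test_that("shuffle and noise are reproducible under a fixed seed", {
  d <- seq_tibble(random_dna(10, c(30, 60)))
  expect_identical(dinucleotide_shuffle(d, seed = 5),
                   dinucleotide_shuffle(d, seed = 5))
  expect_identical(add_boundary_noise(d, 75, seed = 5),
                   add_boundary_noise(d, 75, seed = 5))
})

test_that("length screen flags a length-separable class and only that class", {
  set.seed(29)
  mk <- function(n, mean, sd) pmax(20, round(rnorm(n, mean, sd)))
  lens <- c(mk(120, 50, 2), mk(120, 100, 30), mk(120, 110, 30))
  d <- seq_tibble(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)), labels = rep(c("narrow", "wideA", "wideB"), each = 120),
  ids = sprintf("l%03d", seq_along(lens)))
  sc <- screen_length_predictable(d, f1_cutoff = 0.80, folds = 10, seed = 3)
  expect_true(sc$flagged[sc$label == "narrow"])
  expect_false(any(sc$flagged[sc$label != "narrow"]))
})

test_that("length screen flags nothing without signal or with an unattainable cutoff", {
  set.seed(37)
  d <- seq_tibble(random_dna(200, c(50, 150)),
                  labels = rep(c("a", "b"), 100))
  sc <- screen_length_predictable(d, f1_cutoff = 0.80, seed = 1)
  expect_false(any(sc$flagged))
  sc2 <- screen_length_predictable(d, f1_cutoff = 1.01, seed = 1)
  expect_false(any(sc2$flagged))
})
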