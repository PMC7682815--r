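test_that("standard CNN structure follows the architecture contract", {
  ms <- model_spec("cnn_standard", input_shape = c(16L, 16L, 5L),
                   n_classes = 7, n_conv_layers = 3, seed = 1)
  m <- build_standard_cnn(ms)
  ml <- model_layers(m)
  conv <- ml[ml$type == "conv2d", ]
  expect_equal(nrow(conv), 3)
  expect_equal(conv$units, c(64, 128, 256)) # 32 * 2^i, i = 1..3
  expect_equal(sum(ml$type == "dropout"), 3)
  expect_true(all(ml$type[ml$type %in% c("conv1d")] == character(0)))
  dense <- ml[ml$type == "dense", ]
  expect_equal(dense$units, c(1000, 500, 7))
  # 1D variant for k-mer input
  m1 <- build_standard_cnn(model_spec("cnn_standard", input_shape = c(200L, 5L),
                                      n_classes = 4, n_conv_layers = 2, seed = 1))
  expect_equal(sum(model_layers(m1)$type == "conv1d"), 2)
  # zero layers -> dense-only network
  m0 <- build_standard_cnn(model_spec("cnn_standard", input_shape = c(200L, 5L),
                                      n_classes = 4, n_conv_layers = 0, seed = 1))
  expect_false(any(grepl("conv", model_layers(m0)$type)))
  expect_equal(model_layers(m0)$units[model_layers(m0)$type == "dense"],
               c(1000, 500, 4))
})

test_that("improved CNN has 5 conv blocks, batch norm, two noise points, dense 128/64", {
  ms <- model_spec("cnn_improved", input_shape = c(100L, 4L), n_classes = 13,
                   seed = 1)
  expect_equal(ms$optimizer, "amsgrad")
  expect_equal(ms$learning_rate, 0.0005)
  m <- build_improved_cnn(ms)
  ml <- model_layers(m)
  expect_equal(sum(ml$type == "conv1d"), 5)
  expect_equal(sum(ml$type == "batchnorm"), 5)
  expect_equal(sum(ml$type == "gaussian_noise"), 2)
  expect_equal(sum(ml$type == "leaky_relu"), 5)
  expect_equal(sum(ml$type == "dropout"), 1)
  expect_equal(ml$units[ml$type == "dense"], c(128, 64, 13))
})

test_that("bilstm builds two bidirectional layers and accepts ragged batches", {
  ms <- model_spec("bilstm", input_shape = 4L, n_classes = 3, rnn_nodes = 150,
                   seed = 1)
  m <- build_bilstm(ms)
  ml <- model_layers(m)
  expect_equal(sum(ml$type == "bilstm"), 2)
  expect_equal(sum(ml$type == "dropout"), 2)
  bl <- which(vapply(m$layers, function(l) l$type, character(1)) == "bilstm")
  expect_equal(ncol(m$layers[[bl[1]]]$U), 4 * 150) # gates of 150 units
  expect_equal(nrow(m$layers[[bl[1]]]$U), 150)
  expect_equal(ml$units[ml$type == "dense"], 3)
  # curve-shaped input is rejected
  expect_error(build_bilstm(model_spec("bilstm", input_shape = c(16L, 16L, 5L),
                                       n_classes = 3)),
               "variable-length")
  # forward pass over mixed-length sequences yields one row per record
  set.seed(2)
  ragged <- lapply(c(5, 9, 7), function(L) {
    M <- matrix(0, L, 4); M[cbind(1:L, sample(4, L, TRUE))] <- 1; M
  })
  fw <- ncrnafam:::nn_forward(m, ragged, mode = "eval")
  expect_equal(dim(fw$out), c(3, 3))
})

test_that("a small toy set is memorized and reproduced by predict_proba", {
  d <- toy_motif_dataset(n_per = 25, seed = 5) # 50 records, 2 classes
  b <- encode_kmer(d, encoding_spec("kmer", k = 1, max_len = 48))
  ms <- model_spec("cnn_standard", input_shape = dim(b$array)[-1],
                   n_classes = 2, n_conv_layers = 1, batch_size = 16,
                   epochs = 40, patience = 40, seed = 4)
  tc <- train_classifier(build_standard_cnn(ms), b, d$label, b, d$label)
  expect_equal(max(tc$history$accuracy), 1)
  p <- predict_proba(tc, b)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(predict_classes(tc, b), d$label)
  # best-checkpoint validation losses improve monotonically
  best_so_far <- cummin(tc$history$val_loss)
  expect_true(all(diff(best_so_far) <= 0))
})

test_that("training is deterministic under a fixed seed", {
  d <- toy_motif_dataset(n_per = 15, seed = 2)
  b <- encode_kmer(d, encoding_spec("kmer", k = 1, max_len = 48))
  ms <- model_spec("cnn_standard", input_shape = dim(b$array)[-1],
                   n_classes = 2, n_conv_layers = 1, batch_size = 16,
                   epochs = 3, patience = 3, seed = 9)
  t1 <- train_classifier(build_standard_cnn(ms), b, d$label, b, d$label)
  t2 <- train_classifier(build_standard_cnn(ms), b, d$label, b, d$label)
  expect_identical(t1$history, t2$history)
})

test_that("a linearly separable toy task is solved on held-out data", {
  # class fully determined by a fixed-position prefix: linearly separable
  # from the one-hot encoding by construction
  set.seed(13)
  mk <- function(prefix, n) {
    vapply(seq_len(n), function(i) {
      paste0(prefix, paste(sample(c("A", "C", "G", "T"), 56, replace = TRUE),
                           collapse = ""))
    }, character(1))
  }
  d <- seq_tibble(c(mk("AAAA", 100), mk("TTTT", 100)),
                  labels = rep(c("a", "b"), each = 100),
                  ids = sprintf("t%03d", 1:200))
  spl <- similarity_aware_split(d, split_config(seed = 3))
  enc <- encoding_spec("kmer", k = 1, max_len = 60)
  btr <- encode_kmer(spl$train, enc)
  bva <- encode_kmer(spl$validation, enc)
  ms <- model_spec("cnn_standard", input_shape = dim(btr$array)[-1],
                   n_classes = 2, n_conv_layers = 1, batch_size = 32,
                   epochs = 30, patience = 6, seed = 1)
  tc <- train_classifier(build_standard_cnn(ms), btr, spl$train$label,
                         bva, spl$validation$label)
  expect_gt(max(tc$history$val_accuracy), 0.95)
  # duplicated record in a batch yields identical probability rows
  b2 <- encode_kmer(spl$validation[c(1, 1, 2), ], enc)
  p <- predict_proba(tc, b2)
  expect_equal(p[1, ], p[2, ])
})

test_that("input-shape and label mismatches are rejected", {
  d <- toy_motif_dataset(n_per = 10, seed = 1)
  b <- encode_kmer(d, encoding_spec("kmer", k = 1, max_len = 48))
  ms <- model_spec("cnn_standard", input_shape = c(30L, 5L), n_classes = 2,
                   n_conv_layers = 1, epochs = 1, seed = 1)
  m <- build_standard_cnn(ms)
  expect_error(train_classifier(m, b, d$label, b, d$label), "input_shape")
  ms_ok <- model_spec("cnn_standard", input_shape = dim(b$array)[-1],
                      n_classes = 2, n_conv_layers = 1, epochs = 1, seed = 1)
  m_ok <- build_standard_cnn(ms_ok)
  y_bad <- d$label
  y_bad[1] <- "fam99"
  expect_error(train_classifier(m_ok, b, d$label, b, y_bad),
               "absent from training")
})

test_that("improved CNN and bilstm train end to end on a tiny task", {
  d <- toy_motif_dataset(n_per = 15, seed = 6)
  b <- encode_kmer(d, encoding_spec("kmer", k = 1, max_len = 48))
  ms <- model_spec("cnn_improved", input_shape = dim(b$array)[-1],
                   n_classes = 2, batch_size = 16, epochs = 3, patience = 3,
                   seed = 2)
  tc <- train_classifier(build_improved_cnn(ms), b, d$label, b, d$label)
  expect_equal(nrow(tc$history), 3)
  expect_true(all(is.finite(tc$history$loss)))
  r <- encode_kmer_ragged(d, encoding_spec("kmer", k = 1, max_len = 48))
  msr <- model_spec("bilstm", input_shape = 4L, n_classes = 2, rnn_nodes = 12,
                    batch_size = 16, epochs = 8, patience = 8, seed = 2)
  tr <- train_classifier(build_bilstm(msr), r, d$label, r, d$label)
  expect_gt(max(tr$history$accuracy), 0.6)
  p <- predict_proba(tr, r)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})
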