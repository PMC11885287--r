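test_that("label encoding is sorted, idempotent and invertible", {
  enc <- label_encode(c("B", "A", "B"))
  expect_equal(enc, c(A = 0L, B = 1L))
  expect_equal(label_encode(names(enc)), enc)
  expect_equal(label_decode(enc, enc[c("B", "A")]), c("B", "A"))
  expect_error(label_encode(character(0)), class = "avifuse_invalid_input")
})

test_that("the feature MLP fits separable data deterministically", {
  set.seed(25)
  n <- 40
  labels <- rep(c("sp_a", "sp_b"), each = n / 2)
  X <- matrix(stats::rnorm(n * 21, 0, 0.3), n, 21)
  X[labels == "sp_b", 1:5] <- X[labels == "sp_b", 1:5] + 3

  cfg <- train_config("audio_mlp", seed = 31)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$epochs, 75L)

  m <- train_audio_mlp(X, labels, cfg)
  P <- predict_probs(m, X)
  expect_equal(colnames(P), c("sp_a", "sp_b"))
  expect_equal(mean(m$classes[max.col(P, ties.method = "first")] == labels), 1)
  # loss decreases over training
  expect_lt(m$loss_trace[cfg$epochs], m$loss_trace[1])

  m2 <- train_audio_mlp(X, labels, cfg)
  expect_identical(m$params, m2$params)

  expect_error(predict_probs(m, X[, 1:20]), class = "avifuse_schema_error")
})

test_that("the acoustic LSTM learns separable sequences", {
  set.seed(26)
  n_per <- 12
  mk_seq <- function(shift) {
    t <- seq(0, 1, length.out = 15)
    cbind(sin(2 * pi * t) + shift, cos(2 * pi * t) - shift) +
      matrix(stats::rnorm(30, 0, 0.05), 15, 2)
  }
  seqs <- c(lapply(1:n_per, function(i) mk_seq(0)),
            lapply(1:n_per, function(i) mk_seq(1.5)))
  labels <- rep(c("lo", "hi"), each = n_per)
  cfg <- train_config("acoustic_lstm", seed = 41, epochs = 15L,
                      hidden_size = 8L, embedding_dim = 8L)
  expect_equal(cfg$optimizer, "rmsprop")
  expect_equal(cfg$lr, 1e-3)
  m <- train_acoustic_lstm(seqs, labels, cfg)
  # loss decreases over the first epochs on separable data
  expect_lt(mean(m$loss_trace[11:15]), m$loss_trace[1])
  P <- predict_probs(m, seqs)
  expect_gte(mean(m$classes[max.col(P, ties.method = "first")] == labels), 0.9)
  m2 <- train_acoustic_lstm(seqs, labels, cfg)
  expect_identical(m$params, m2$params)
})

test_that("the acoustic LSTM identifies fully separated synthetic species", {
  ds <- fixture_dataset()                  # class_separation = 1
  items <- fixture("ds_items", function() {
    load_multimodal(ds$manifest, 32L, max_frames = 30L)
  })
  tr <- avifuse:::items_split(items, "train")
  held_out <- c(avifuse:::items_split(items, "val"),
                avifuse:::items_split(items, "test"))
  m <- train_acoustic_lstm(lapply(tr, `[[`, "seq"),
                           avifuse:::item_labels(tr),
                           train_config("acoustic_lstm", seed = 5,
                                        epochs = 20L, hidden_size = 16L,
                                        embedding_dim = 16L))
  P <- predict_probs(m, held_out)
  acc <- mean(m$classes[max.col(P, ties.method = "first")] ==
                avifuse:::item_labels(held_out))
  expect_gt(acc, 0.9)
})

test_that("evaluation metrics match the confusion-count oracle", {
  all_right <- evaluate(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$macro_precision, 1)
  expect_equal(all_right$macro_recall, 1)
  expect_equal(all_right$macro_f1, 1)

  all_wrong <- evaluate(c("b", "a"), c("a", "b"))
  expect_equal(all_wrong$accuracy, 0)

  set.seed(27)
  classes <- c("a", "b", "c")
  truth <- sample(classes, 60, replace = TRUE)
  pred <- ifelse(stats::runif(60) < 0.6, truth, sample(classes, 60, TRUE))
  got <- evaluate(pred, truth, classes = classes)
  want <- oracle_metrics(pred, truth, classes)
  expect_equal(unname(got$confusion), want$confusion,
               ignore_attr = TRUE)
  expect_lt(abs(got$accuracy - want$accuracy), 1e-12)
  expect_lt(abs(got$macro_precision - want$macro_precision), 1e-12)
  expect_lt(abs(got$macro_recall - want$macro_recall), 1e-12)
  expect_lt(abs(got$macro_f1 - want$macro_f1), 1e-12)
  expect_equal(unname(rowSums(got$confusion)),
               unname(table(factor(truth, classes))[classes]),
               ignore_attr = TRUE)

  # a class never predicted gets precision 0; AUC separable case is 1
  m <- evaluate(c("a", "a", "a"), c("a", "a", "b"),
                probs = matrix(c(0.9, 0.8, 0.4, 0.1, 0.2, 0.6), 3, 2))
  expect_equal(m$per_class$precision[m$per_class$class == "b"], 0)
  expect_equal(m$macro_auc, 1)
  expect_error(evaluate(c("a"), c("a", "b")), class = "avifuse_invalid_input")
})

test_that("models survive a save/load round trip bit-identically", {
  set.seed(28)
  X <- matrix(stats::rnorm(20 * 6), 20, 6)
  labels <- rep(c("x", "y"), 10)
  m <- train_audio_mlp(X, labels, train_config("audio_mlp", seed = 5,
                                               epochs = 5L))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict_probs(back, X), predict_probs(m, X))

  # kind mismatch is a type error
  expect_error(load_model(path, expect_kind = "late_fusion"),
               class = "avifuse_type_error")

  # tampering with the payload triggers the integrity warning
  txt <- readLines(path, warn = FALSE)
  tampered <- sub("\"classes\":\\[\"x\",\"y\"\\]", "\"classes\":[\"x\",\"z\"]",
                  txt)
  tampered <- sub("(\"data\":\")[A-Za-z0-9+/]{8}", "\\1AAAAAAAA", tampered)
  tpath <- tempfile(fileext = ".json")
  writeLines(tampered, tpath)
  expect_warning(load_model(tpath), regexp = "integrity")

  # version bump is an explicit unsupported-version error
  vpath <- tempfile(fileext = ".json")
  writeLines(sub("\"version\":1", "\"version\":99", txt), vpath)
  expect_error(load_model(vpath), class = "avifuse_version_error")
})

test_that("robustness with no degradation reproduces the clean metrics", {
  comp <- fixture_comp_dataset()
  cfg <- train_config("early_fusion", seed = 1, epochs = 6L)
  m <- train_fusion(comp$manifest, "early", cfg, items = comp$items)
  rc <- robustness_config(audio_snr_db = Inf, drop_modality = "none")
  res <- robustness_eval(m, comp$manifest, rc, items = comp$items)
  expect_equal(res$degraded$accuracy, res$clean$accuracy)
  expect_equal(res$degraded$confusion, res$clean$confusion)

  # dropping the only modality of a unimodal model is a config error
  lm <- train_fusion(comp$manifest, "late",
                     train_config("late_fusion", seed = 1, epochs = 2L),
                     items = comp$items)
  expect_error(
    robustness_eval(lm$visual, comp$manifest,
                    robustness_config(drop_modality = "visual"),
                    items = comp$items),
    class = "avifuse_invalid_config")
})

test_that("fusion training contracts hold on one seed", {
  comp <- fixture_comp_dataset()
  cfg <- train_config("early_fusion", seed = 2, epochs = 15L)
  em <- train_fusion(comp$manifest, "early", cfg, items = comp$items)
  # fused head input dim = visual dim + acoustic dim
  expect_equal(ncol(em$head$W_c), 2L * cfg$embedding_dim)
  lm <- train_fusion(comp$manifest, "late",
                     train_config("late_fusion", seed = 2, epochs = 15L),
                     items = comp$items)
  expect_true(lm$alpha %in% seq(0, 1, 0.05))
  te <- avifuse:::items_split(comp$items, "test")
  expect_gte(test_accuracy(em, te), 0.5)
})
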