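test_that("stage shape arithmetic and collapse errors", {
  shp <- cnn_shape(cnn_spec())
  expect_equal(shp$conv_len, c(252, 102, 43, 13))
  expect_equal(shp$pool_len, c(126, 51, 21, 6))
  expect_error(cnn_spec(input_len = 48), "stage 1")
  m <- cnn_build(cnn_spec(channels = c(2, 2, 2, 2), dense = c(8, 4)), seed = 1)
  p <- qrsvalid:::cnn_forward(m, matrix(rnorm(2 * 300), 2), training = FALSE)$p
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("learning-rate schedule steps at the prescribed epochs", {
  cfg <- cnn_train_config()
  expect_equal(sum(cfg$lr_schedule$epochs), cfg$epochs)   # 3+7+10+10 = 30
  expect_equal(cnn_learning_rate(1, cfg), 0.01)
  expect_equal(cnn_learning_rate(3, cfg), 0.01)
  expect_equal(cnn_learning_rate(4, cfg), 0.005)
  expect_equal(cnn_learning_rate(10, cfg), 0.005)
  expect_equal(cnn_learning_rate(11, cfg), 0.001)
  expect_equal(cnn_learning_rate(20, cfg), 0.001)
  expect_equal(cnn_learning_rate(21, cfg), 0.0001)
  expect_equal(cnn_learning_rate(30, cfg), 0.0001)
})

test_that("backpropagation matches numerical differentiation", {
  spec <- cnn_spec(input_len = 60, kernels = c(5, 3, 3, 3),
                   channels = c(2, 2, 2, 2), dense = c(4, 3), dropout = 0)
  m <- cnn_build(spec, seed = 1)
  set.seed(2)
  X <- matrix(rnorm(5 * 60), 5, 60)
  y <- c(1L, 2L, 1L, 2L, 1L)
  loss_at <- function(mm) {
    p <- qrsvalid:::cnn_forward(mm, X, training = FALSE)$p
    mean(-log(pmax(p[cbind(1:5, y)], 1e-12)))
  }
  fw <- qrsvalid:::cnn_forward(m, X, training = TRUE)
  gr <- qrsvalid:::cnn_backward(m, fw$p, y, fw$cache)
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (ii in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      m2 <- m
      m2$params[[nm]][ii] <- m$params[[nm]][ii] + eps
      up <- loss_at(m2)
      m2$params[[nm]][ii] <- m$params[[nm]][ii] - eps
      dn <- loss_at(m2)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

# One shared training run feeds the convergence, determinism, recall and
# prediction assertions below.
trained_fixture <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    recs <- synthetic_study_records(6, n_beats = 15, seed = 77, prefix = "fit")
    ts <- build_training_set(recs, aug_config(), model_len = 300L)
    cfg <- cnn_train_config(epochs = 10, batch_size = 128, seed = 0)
    model <- cnn_train(cnn_build(small_spec(), seed = 0), ts$x, ts$label, cfg,
                       strata = ts$meta$record_id)
    memo <<- list(model = model, ts = ts, cfg = cfg)
    memo
  }
})

test_that("the validator separates beats from between-beat windows", {
  fx <- trained_fixture()
  h <- fx$model$history
  expect_equal(nrow(h), 10)
  expect_lt(h$val_err[10], 0.05)
  # training loss decreases through any 5-epoch moving window
  mw <- stats::filter(h$train_loss, rep(1 / 5, 5), sides = 1)
  mw <- mw[!is.na(mw)]
  expect_true(all(diff(mw) <= 1e-8))
  # held-out synthetic records: both per-class recalls above 0.9
  held <- synthetic_study_records(3, n_beats = 12, seed = 991, prefix = "held")
  hts <- build_training_set(held, aug_config(), model_len = 300L)
  pr <- cnn_predict(fx$model, hts$x)
  beat <- hts$label == "beat"
  expect_gt(mean(pr[beat] >= 0.5), 0.9)
  expect_gt(mean(pr[!beat] < 0.5), 0.9)
})

test_that("training is reproducible and rejects degenerate inputs", {
  fx <- trained_fixture()
  sub <- sample(nrow(fx$ts$x), 220)
  cfg <- cnn_train_config(epochs = 2, batch_size = 64, seed = 5)
  m1 <- cnn_train(cnn_build(small_spec(), seed = 3), fx$ts$x[sub, ],
                  fx$ts$label[sub], cfg)
  m2 <- cnn_train(cnn_build(small_spec(), seed = 3), fx$ts$x[sub, ],
                  fx$ts$label[sub], cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  only_beats <- fx$ts$label == "beat"
  expect_error(cnn_train(cnn_build(small_spec(), seed = 0),
                         fx$ts$x[only_beats, ], fx$ts$label[only_beats], cfg),
               "both")
})

test_that("prediction contracts: lengths, softmax, identity inputs", {
  fx <- trained_fixture()
  expect_error(cnn_predict(fx$model, numeric(200)), "300")
  x <- fx$ts$x[1, ]
  expect_identical(cnn_predict(fx$model, global_attenuate(x, 0)),
                   cnn_predict(fx$model, x))
  p <- qrsvalid:::cnn_forward(fx$model, matrix(x, 1), training = FALSE)$p
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("model artifacts round-trip and reject foreign files", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  cnn_save(fx$model, path)
  back <- cnn_load(path)
  probe <- fx$ts$x[1:20, ]
  expect_identical(cnn_predict(back, probe), cnn_predict(fx$model, probe))
  expect_error(cnn_load(file.path(tempdir(), "nope.rds")), "not found")
  alien <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), alien)
  expect_error(cnn_load(alien), "format")
})
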