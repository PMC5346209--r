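lr_spec <- function(mode = "explicit", seed = 1)
  model_spec("logistic_regression", mode, 6, "morgan", seed)

test_that("encode_features passes pKi through explicitly or binarises it implicitly", {
  ex <- encode_features(0.8, 6.5, "explicit", 6)
  expect_equal(ex$activity, 6.5)
  im6 <- encode_features(c(0.8, 0.8), c(6.5, 5.9), "implicit", 6)
  expect_equal(im6$activity, c(1, 0))
  im5 <- encode_features(c(0.8, 0.8), c(6.5, 5.9), "implicit", 5)
  expect_equal(im5$activity, c(1, 1))
  expect_equal(ex$tc_most, 0.8)
})

test_that("training refuses degenerate single-class data", {
  feat <- encode_features(runif(20), runif(20, 4, 9), "explicit", 6)
  expect_error(most_train(feat, rep(1L, 20), lr_spec()), "single class")
  expect_error(most_train(feat, rep(0L, 20), lr_spec()), "single class")
})

test_that("implicit-mode models reject raw pKi features", {
  set.seed(1)
  feat <- data.frame(tc_most = runif(40), activity = rep(0:1, 20))
  m <- most_train(feat, rep(0:1, 20), lr_spec("implicit"))
  bad <- data.frame(tc_most = 0.5, activity = 7.2)
  expect_error(predict(m, bad), "0/1")
  expect_error(most_train(data.frame(tc_most = runif(4), activity = c(7, 5, 8, 4)),
                          c(1, 0, 1, 0), lr_spec("implicit")), "0/1")
})

test_that("all backends separate linearly separable data and emit complementary probabilities", {
  set.seed(42)
  n <- 200
  tc <- runif(n)
  act <- runif(n, 4, 9)
  lab <- as.integer(act > 6.5)          # separable on the activity feature
  feat <- encode_features(tc, act, "explicit", 6)
  for (method in c("logistic_regression", "naive_bayes", "random_forest")) {
    # separable data: the logistic fit legitimately warns about divergence
    m <- suppressWarnings(
      most_train(feat, lab, model_spec(method, "explicit", 6, "morgan", 7)))
    pred <- predict(m, feat)
    expect_gte(mean(pred$label == lab), 0.99)
    expect_true(all(abs(pred$p_a + pred$p_i - 1) < 1e-12))
    expect_identical(pred$p_value, pred$p_i)
    expect_true(all(pred$label == as.integer(pred$p_a > pred$p_i)))
  }
})

test_that("logistic predictions equal the closed-form sigmoid and recover planted coefficients", {
  dat <- simulate_feature_data(10000, c(-10, 6, 1), seed = 202)
  feat <- encode_features(dat$tc_most, dat$pki_most, "explicit", 6)
  m <- most_train(feat, dat$label, lr_spec(seed = 202))
  co <- coef(m)
  expect_true(all(abs(co - c(-10, 6, 1)) / abs(c(-10, 6, 1)) < 0.10))
  grid <- data.frame(tc_most = runif(50), activity = runif(50, 4, 9))
  pred <- predict(m, grid)
  expect_equal(pred$p_a,
               plogis(co[1] + co[2] * grid$tc_most + co[3] * grid$activity),
               tolerance = 1e-15)
})

test_that("a zero-coefficient logistic model predicts 0.5 and the tie goes to inactive", {
  m <- structure(list(spec = lr_spec(),
                      fit = list(coef = c(a0 = 0, a1 = 0, a2 = 0)),
                      n_train = 0L), class = "most_model")
  pred <- predict(m, data.frame(tc_most = 0.3, activity = 8))
  expect_equal(pred$p_a, 0.5)
  expect_identical(pred$label, 0L)
})

test_that("logistic probability is monotone in each feature when its weight is positive", {
  m <- structure(list(spec = lr_spec(),
                      fit = list(coef = c(a0 = -10, a1 = 10, a2 = 1)),
                      n_train = 0L), class = "most_model")
  tc_grid <- predict(m, data.frame(tc_most = seq(0, 1, 0.05), activity = 6))
  expect_true(all(diff(tc_grid$p_a) > 0))
  act_grid <- predict(m, data.frame(tc_most = 0.5, activity = seq(3, 10, 0.5)))
  expect_true(all(diff(act_grid$p_a) > 0))
  one <- predict(m, data.frame(tc_most = 1, activity = 9))
  expect_equal(one$p_a, 1 / (1 + exp(-9)), tolerance = 1e-12)
})

test_that("fitted slopes are positive when similarity and potency drive activity", {
  dat <- simulate_feature_data(4000, c(-8, 4, 1), seed = 31)
  feat <- encode_features(dat$tc_most, dat$pki_most, "explicit", 6)
  co <- coef(most_train(feat, dat$label, lr_spec(seed = 31)))
  expect_gt(co["a1"], 0)
  expect_gt(co["a2"], 0)
})

test_that("naive Bayes probabilities obey the Bayes identity of the fitted Gaussians", {
  set.seed(8)
  n <- 300
  tc <- runif(n); act <- runif(n, 4, 9)
  lab <- rbinom(n, 1, plogis(-6 + 3 * tc + act - 6))
  feat <- encode_features(tc, act, "explicit", 6)
  m <- most_train(feat, lab, model_spec("naive_bayes", "explicit", 6, "morgan", 8))
  tab <- m$fit$tables
  prior <- m$fit$apriori / sum(m$fit$apriori)
  grid <- expand.grid(tc_most = c(0.1, 0.5, 0.9), activity = c(4.5, 6, 8.5))
  pred <- predict(m, grid)
  lik <- function(cls, tc, a)
    dnorm(tc, tab$tc_most[cls, 1], tab$tc_most[cls, 2]) *
    dnorm(a, tab$activity[cls, 1], tab$activity[cls, 2])
  for (i in seq_len(nrow(grid))) {
    num <- prior["1"] * lik("1", grid$tc_most[i], grid$activity[i])
    den <- num + prior["0"] * lik("0", grid$tc_most[i], grid$activity[i])
    expect_equal(pred$p_a[i], unname(num / den), tolerance = 1e-6)
  }
})

test_that("retraining with the same seed reproduces predictions bit for bit", {
  set.seed(77)
  n <- 150
  tc <- runif(n); act <- runif(n, 4, 9)
  lab <- rbinom(n, 1, plogis(act - 6))
  feat <- encode_features(tc, act, "explicit", 6)
  newdata <- data.frame(tc_most = runif(20), activity = runif(20, 4, 9))
  for (method in c("logistic_regression", "naive_bayes", "random_forest")) {
    spec <- model_spec(method, "explicit", 6, "morgan", 123)
    p1 <- predict(most_train(feat, lab, spec), newdata)
    p2 <- predict(most_train(feat, lab, spec), newdata)
    expect_identical(p1, p2)
  }
})

test_that("model text artifacts round-trip through save and load", {
  set.seed(5)
  n <- 120
  tc <- runif(n); act <- runif(n, 4, 9)
  lab <- rbinom(n, 1, plogis(act - 6))
  feat <- encode_features(tc, act, "explicit", 6)
  newdata <- data.frame(tc_most = runif(10), activity = runif(10, 4, 9))
  for (method in c("logistic_regression", "naive_bayes", "random_forest")) {
    m <- most_train(feat, lab, model_spec(method, "explicit", 6, "morgan", 9))
    f <- withr::local_tempfile(fileext = ".txt")
    write_most_model(m, f)
    expect_false(any(grepl("[^[:print:][:space:]]", readLines(f))))  # text only
    back <- read_most_model(f)
    expect_identical(back$spec, m$spec)
    expect_equal(predict(back, newdata), predict(m, newdata))
  }
  expect_error(read_most_model(withr::local_tempfile(lines = "junk")), "artifact")
})
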