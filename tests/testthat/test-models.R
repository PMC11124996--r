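test_that("the 2:1 split is deterministic and spans the trait range", {
  set.seed(41)
  y <- runif(60, 32, 55)
  sp <- split_dataset(60, y)
  expect_length(sp$modeling, 40)
  expect_length(sp$validation, 20)
  expect_length(intersect(sp$modeling, sp$validation), 0)
  sp2 <- split_dataset(60, y)
  expect_identical(sp, sp2)
  # default picks the middle of each sorted triple: extremes stay in the
  # modelling set, so validation lies strictly inside the trait range
  expect_gt(min(y[sp$validation]), min(y))
  expect_lt(max(y[sp$validation]), max(y))
  # every sorted block of three contributes exactly one validation sample
  ord <- order(y)
  block <- (match(sp$validation, ord) - 1) %/% 3
  expect_equal(sort(block), 0:19)
  expect_error(split_dataset(5, runif(5)), "at least 6")
})

test_that("evaluate reproduces hand-computed metrics", {
  expect_equal(evaluate(c(2, 4), c(2, 4)), list(r2 = 1, rmse = 0, mre = 0))
  y <- c(1, 2, 3, 6)
  expect_equal(evaluate(y, rep(mean(y), 4))$r2, 0)
  m <- evaluate(c(2, 4), c(3, 3))
  expect_equal(m$rmse, 1)
  expect_equal(m$mre, 37.5)
  expect_true(is.na(evaluate(c(2, 2), c(2, 3))$r2))
  expect_error(evaluate(c(0, 2), c(1, 1)), "positive")
})

test_that("evaluate is permutation-invariant and MRE is scale-free", {
  set.seed(42)
  y <- runif(15, 1, 5); p <- y + rnorm(15, 0, 0.3)
  o <- sample(15)
  expect_equal(evaluate(y, p), evaluate(y[o], p[o]))
  expect_equal(evaluate(y, p)$mre, evaluate(10 * y, 10 * p)$mre,
               tolerance = 1e-12)
})

test_that("random forest interpolates a linear single-feature target", {
  set.seed(43)
  x <- matrix(runif(40, 0, 10), ncol = 1)
  colnames(x) <- "f"
  y <- 3 + 2 * x[, 1]
  cfg <- model_config(n_repeats = 3)
  pred <- fit_predict("rf", x, y, x, cfg)
  expect_gte(evaluate(y, pred$pred_model)$r2, 0.95)
})

test_that("a constant target is predicted exactly by the forest", {
  set.seed(44)
  x <- matrix(runif(30), ncol = 2)
  colnames(x) <- c("a", "b")
  pred <- suppressWarnings(  # forest warns on a degenerate response
    fit_predict("rf", x, rep(5, 15), x, model_config(n_repeats = 2)))
  expect_equal(pred$pred_model, rep(5, 15))
  expect_equal(pred$pred_valid, rep(5, 15))
})

test_that("repeated-run averaging is bit-reproducible under a fixed config", {
  set.seed(45)
  x <- matrix(runif(60), ncol = 3)
  colnames(x) <- c("a", "b", "c")
  y <- x[, 1] * 2 + rnorm(20, 0, 0.1) + 3
  xv <- matrix(runif(15), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  cfg <- model_config(n_repeats = 3)
  for (model in c("svm", "rf", "bpnn")) {
    p1 <- fit_predict(model, x, y, xv, cfg)
    p2 <- fit_predict(model, x, y, xv, cfg)
    expect_identical(p1, p2)
  }
  expect_error(fit_predict("rf", x * NA, y, xv, cfg), "non-finite")
})

test_that("the experiment grid covers traits x combinations x models x splits", {
  d <- run_pipeline(small_config(seed = 7, n_samples = 24),
                    model_config(n_repeats = 2),
                    models = c("svm", "rf", "bpnn"))
  m <- d$metrics
  expect_equal(nrow(m), 2 * 4 * 3 * 2)
  expect_setequal(unique(m$trait), c("lcc_area", "lcc_weight"))
  expect_setequal(unique(m$model), c("svm", "rf", "bpnn"))
  expect_setequal(unique(m$split), c("modeling", "validation"))
  expect_equal(unique(m$n[m$split == "modeling"]), 16)
  expect_equal(unique(m$n[m$split == "validation"]), 8)
  expect_true(all(m$r2 <= 1))
  expect_true(all(m$rmse >= 0) && all(m$mre >= 0))
  # every combination holds exactly 7 member features
  for (tr in d$selection$traits) {
    expect_true(all(vapply(tr$combinations, nrow, integer(1)) == 7L))
  }
})

test_that("red-edge two-band features beat empirical indices without noise", {
  synth <- synthetic_config(seed = 10, n_samples = 30, wl_start = 350,
                            wl_end = 900, noise_sd_additive = 0,
                            noise_sd_multiplicative = 0)
  res <- run_pipeline(synth, model_config(n_repeats = 3), models = "rf",
                      combinations = c("combination_1", "combination_3"))
  v <- subset(res$metrics, split == "validation" & trait == "lcc_area")
  r2_3 <- v$r2[v$combination == "combination_3"]
  r2_1 <- v$r2[v$combination == "combination_1"]
  expect_gt(r2_3, 0.9)
  expect_gte(r2_3, r2_1 - 0.05)
})
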