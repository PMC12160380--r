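# Diameter regression: transforms, OLS, diagnostics, VIF, elimination,
# prediction equation.

make_summaries <- function(ds) {
  data.frame(spore_conc = ds$spore_conc, agitation_rpm = ds$agitation,
             talc_g_per_l = ds$talc, baffled = ds$baffled,
             replicate_id = ds$replicate_id, median_ed_um = ds$median_ed_um,
             n_pellets = 100L, modality = "unimodal")
}

grid8 <- expand.grid(spore_conc = 5e6, agitation = c(150, 250),
                     talc = c(0, 1, 5, 10), baffled = FALSE)

test_that("dataset construction applies the ln transforms and exclusions", {
  sm <- data.frame(
    spore_conc = c(5e6, 5e4, 5e5, 5e6),
    agitation_rpm = c(250, 150, 150, 250),
    talc_g_per_l = c(0, 0, 5, 1),
    baffled = c(TRUE, FALSE, FALSE, TRUE),
    replicate_id = paste0("R", 1:4),
    median_ed_um = c(300, 2500, 800, 250),
    n_pellets = c(100L, 100L, 20L, 100L),
    modality = c("unimodal", "unimodal", "unimodal", "multimodal"))
  ds <- build_regression_dataset(sm)
  # the low-count and the multimodal rows are gone
  expect_equal(nrow(ds), 2)
  # printed transform conventions at the grid extremes
  expect_equal(round(ds$ln_spore[1], 2), 15.42)
  expect_equal(round(ds$ln_agitation[1], 2), 5.52)
  expect_equal(round(ds$ln_spore[2], 2), 10.82)
  expect_equal(round(ds$ln_agitation[2], 2), 5.01)
  expect_equal(ds$baffle, c(1L, 0L))

  sm$n_pellets <- 10L
  expect_error(build_regression_dataset(sm), "no admissible rows")
})

test_that("noiseless data reproduce the generating coefficients exactly", {
  ds <- gen_regression_dataset(grid8, replicates = 3, noise_sd_ln = 0,
                               seed = 1)
  fit <- fit_diameter_model(build_regression_dataset(make_summaries(ds)),
                            predictors = c("ln_agitation", "talc"))
  est <- fit$coefficients$estimate
  expect_lt(max(abs(est - c(15.863, -1.7769, -0.10856)) /
                  abs(c(15.863, -1.7769, -0.10856))), 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("degenerate and deficient designs are handled", {
  ds <- build_regression_dataset(make_summaries(
    gen_regression_dataset(grid8, replicates = 3, noise_sd_ln = 0.1,
                           seed = 2)))
  # constant response: zero slopes, zero R^2
  ds$ln_pd <- 3
  fit <- fit_diameter_model(ds, c("ln_agitation", "talc"))
  expect_equal(fit$coefficients$estimate[-1], c(0, 0), tolerance = 1e-12)
  expect_equal(fit$r2, 0)

  # rank deficiency is an error naming the aliased column
  ds$dup <- ds$ln_agitation
  expect_error(fit_diameter_model(ds, c("ln_agitation", "dup")),
               "rank-deficient")
})

test_that("least-squares residuals are orthogonal to the design", {
  ds <- build_regression_dataset(make_summaries(
    gen_regression_dataset(grid8, replicates = 3, noise_sd_ln = 0.15,
                           seed = 3)))
  fit <- fit_diameter_model(ds, c("ln_agitation", "talc"))
  X <- stats::model.matrix(fit$fit)
  r <- stats::residuals(fit$fit)
  expect_lt(max(abs(crossprod(X, r))), 1e-8 * nrow(X))
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("VIF matches its definition and the independent reference", {
  # orthogonal centred predictors: exactly 1
  X <- data.frame(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  expect_equal(unname(vif(X)), c(1, 1))

  # duplicated predictor: infinite, flagged
  Xd <- data.frame(a = rnorm(20), b = 0)
  Xd$b <- Xd$a
  expect_warning(v <- vif(Xd), "collinear")
  expect_true(all(is.infinite(v)))

  # near-collinear pair exceeds the conventional threshold of 10
  set.seed(4)
  x1 <- rnorm(50)
  Xn <- data.frame(x1 = x1, x2 = x1 + rnorm(50, 0, 0.05))
  expect_true(all(vif(Xn) > 10))

  # affine rescaling leaves VIF unchanged
  set.seed(5)
  Z <- data.frame(u = rnorm(40), v = rnorm(40), w = rnorm(40))
  Z$v <- Z$u * 0.4 + Z$v
  expect_equal(unname(vif(Z)),
               unname(vif(transform(Z, u = 10 * u - 3, v = 0.2 * v + 7))),
               tolerance = 1e-10)

  # independent cross-check against car::vif on a random design
  set.seed(6)
  df <- data.frame(y = rnorm(60), p = rnorm(60), q = rnorm(60), r = rnorm(60))
  df$q <- df$p * 0.5 + df$q
  ref <- car::vif(lm(y ~ p + q + r, data = df))
  expect_equal(unname(vif(df[, c("p", "q", "r")])), unname(ref),
               tolerance = 1e-10)
})

test_that("diagnostics quantify heteroscedasticity and normality", {
  n <- 1000
  set.seed(7)
  x <- runif(n, 0, 10)
  # homoscedastic normal residuals: score near zero
  d1 <- data.frame(ln_pd = 2 + 0.5 * x + rnorm(n), x = x)
  diag1 <- model_diagnostics(fit_diameter_model(d1, "x"))
  expect_lt(abs(diag1$heteroscedasticity_score), 0.08)
  expect_gt(diag1$normality_r, 0.99)

  # variance growing with the mean: pronounced funnel
  d2 <- data.frame(ln_pd = 2 + 0.5 * x + rnorm(n, 0, 0.05 + 0.3 * x), x = x)
  diag2 <- model_diagnostics(fit_diameter_model(d2, "x"))
  expect_gt(diag2$heteroscedasticity_score, 0.5)

  # perfect fit flagged as degenerate
  d3 <- data.frame(ln_pd = 1 + 2 * x, x = x)
  diag3 <- model_diagnostics(fit_diameter_model(d3, "x"))
  expect_true(diag3$degenerate)

  # qq data are sorted residuals against normal quantiles
  expect_equal(nrow(diag1$qq), n)
  expect_false(is.unsorted(diag1$qq$sample))
})

test_that("backward elimination drops null effects and keeps real ones", {
  # baffle has a true coefficient of zero: eliminated in >= 90% of runs
  grid_b <- expand.grid(spore_conc = c(5e4, 5e6), agitation = c(150, 250),
                        talc = c(0, 5), baffled = c(FALSE, TRUE))
  hits <- 0L
  n_rep <- 200L
  for (k in seq_len(n_rep)) {
    ds <- gen_regression_dataset(grid_b, replicates = 2, noise_sd_ln = 0.1,
                                 seed = 1000 + k)
    ds$median_ed_um <- ds$median_ed_um *
      exp(-0.2 * (log(ds$spore_conc) - mean(log(ds$spore_conc))))
    d <- build_regression_dataset(make_summaries(ds))
    m <- eliminate_nonsignificant(d)
    if (!"baffle" %in% m$predictors) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)

  # strong effects survive elimination
  ds <- gen_regression_dataset(grid8, replicates = 3, noise_sd_ln = 0.02,
                               seed = 11)
  d <- build_regression_dataset(make_summaries(ds))
  m <- eliminate_nonsignificant(d, c("ln_agitation", "talc"))
  expect_setequal(m$predictors, c("ln_agitation", "talc"))
  expect_equal(nrow(m$elimination_trace), 0)

  # alpha = 1 keeps the full model
  m1 <- eliminate_nonsignificant(d, c("ln_agitation", "talc"), alpha = 1)
  expect_setequal(m1$predictors, c("ln_agitation", "talc"))
})

test_that("the prediction equation back-transforms and flags its range", {
  b <- c(15.863, -1.7769, -0.10856)
  expect_equal(predict_diameter(150, 0),
               exp(b[1] + b[2] * log(150)), ignore_attr = TRUE)

  # each g/L of talc multiplies the prediction by exp(bT)
  p0 <- predict_diameter(200, 0)
  p1 <- predict_diameter(200, 1)
  expect_equal(as.numeric(p1 / p0), exp(b[3]))

  # doubling agitation multiplies by 2^bA
  expect_equal(as.numeric(predict_diameter(300, 2) / predict_diameter(150, 2)),
               2^b[2])

  # monotone decreasing in both inputs
  ag <- seq(150, 400, by = 50)
  expect_true(all(diff(as.numeric(predict_diameter(ag, 0))) < 0))
  tc <- 0:10
  expect_true(all(diff(as.numeric(predict_diameter(200, tc))) < 0))

  # validity flag: the model is trusted for 150-1200 um predictions
  expect_true(attr(predict_diameter(250, 0), "in_validity_range"))
  expect_false(attr(predict_diameter(600, 0), "in_validity_range"))
  expect_error(predict_diameter(0, 0), "positive")
  expect_error(predict_diameter(200, -1), ">= 0")
})

test_that("estimates converge to the truth as noise vanishes", {
  errs <- vapply(c(0.1, 0.01, 0), function(s) {
    ds <- gen_regression_dataset(grid8, replicates = 3, noise_sd_ln = s,
                                 seed = 21)
    fit <- fit_diameter_model(build_regression_dataset(make_summaries(ds)),
                              c("ln_agitation", "talc"))
    max(abs(fit$coefficients$estimate - c(15.863, -1.7769, -0.10856)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})
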