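make_clean_model <- function(seed = 1, noise_sd = 5, n_drugs = 4) {
  truth <- make_truth(small_panel(n_drugs),
                      linear = c(A = -15, B = -10),
                      interaction = c("A:B" = -12), noise_sd = noise_sd)
  d <- assemble_oacd(n_drugs)
  list(design = d, truth = truth,
       resp = simulate_screen(truth, d, seed = seed))
}

test_that("lack of fit is exactly zero when replicates sit on the surface", {
  f <- make_clean_model(noise_sd = 0)
  m <- tgmo_fit(f$design, f$resp)
  lof <- lack_of_fit_test(m)
  expect_equal(lof$ss_lof, 0, tolerance = 1e-18)
  expect_equal(lof$statistic, 0, tolerance = 1e-12)
})

test_that("residual SS decomposes exactly into lack-of-fit and pure error", {
  f <- make_clean_model(seed = 8)
  m <- tgmo_fit(f$design, f$resp)
  lof <- lack_of_fit_test(m)
  expect_equal(sum(m$residuals^2), lof$ss_lof + lof$ss_pe, tolerance = 1e-12)
  expect_equal(lof$df_lof + lof$df_pe,
               length(m$y) - length(coef(m)))
  expect_error(lack_of_fit_test(
    tgmo_fit(f$design, 100 - 10 * f$design$codes[, 1])),
    "pure error")
})

test_that("lack of fit detects a third-order truth missing from the model", {
  d <- assemble_oacd(4)
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    mu <- 100 - 12 * d$codes[, 1] - 8 * d$codes[, 2] -
      10 * d$codes[, 1] * d$codes[, 2] * d$codes[, 3]   # cubic term
    y <- matrix(rep(mu, 3) + rnorm(3 * length(mu), 0, 1), ncol = 3)
    m <- tgmo_fit(d, y)
    if (lack_of_fit_test(m)$p.value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, 25)                                    # majority of seeds
})

test_that("analytic Cook's distance equals the leave-one-out refit oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- assemble_oacd(2)                                 # 31 rows (< 50)
    y <- 100 - 10 * d$codes[, 1] - 5 * d$codes[, 2] + rnorm(31, 0, 4)
    m <- tgmo_fit(d, y, stepwise = FALSE)
    expect_lt(max(abs(cooks.distance(m) - cooks_loo_oracle(m))), 1e-10)
  }
})

test_that("Cook's distance flags a perturbed observation as most influential", {
  f <- make_clean_model(seed = 4)
  y <- f$resp
  i <- 57L
  y$viability[i] <- y$viability[i] + 50
  m <- tgmo_fit(f$design, y)
  expect_equal(which.max(cooks.distance(m)), i)
  # perfect fit: all distances zero
  d <- assemble_oacd(3)
  mz <- tgmo_fit(d, 100 - 10 * d$codes[, 1], stepwise = FALSE)
  expect_true(all(cooks.distance(mz) < 1e-16))
})

test_that("outlier-removed variants isolate a gross outlier and approach truth", {
  f <- make_clean_model(seed = 5)
  y <- f$resp
  # perturb an A=+1, B=+1 combination so the A:B estimate is biased upward
  i <- which(f$design$codes[, 1] == 1 & f$design$codes[, 2] == 1)[1]
  y$viability[i] <- y$viability[i] + 60
  v <- build_model_variants(f$design, y)
  expect_true(i %in% v$removed$high_cooks_removed)
  b_true <- -12
  err_full <- abs(coef(v$full)[["A:B"]] - b_true)
  err_rm <- abs(coef(v$high_cooks_removed)[["A:B"]] - b_true)
  expect_lt(err_rm, err_full)
})

test_that("clean data give concordant variants; no removals leaves full fit", {
  f <- make_clean_model(seed = 6)
  v <- build_model_variants(f$design, f$resp)
  sets <- lapply(list(v$full, v$max_outlier_removed, v$high_cooks_removed),
                 function(m) names(coef(m)))
  core <- c("(Intercept)", "A", "B", "A:B")
  for (s in sets) expect_true(all(core %in% s))
  stable <- robust_terms(v)
  expect_true(all(c("A", "B", "A:B") %in% stable))
  # degenerate: threshold above every distance reproduces the full fit
  v2 <- build_model_variants(f$design, f$resp, multiplier = 1e6)
  expect_identical(coef(v2$high_cooks_removed), coef(v2$full))
})

test_that("terms flipping sign or losing significance are not robust", {
  f <- make_clean_model(seed = 9)
  v <- build_model_variants(f$design, f$resp)
  # forge a variant disagreement: flip one term's coefficient sign
  v$max_outlier_removed$coefficients[["A"]] <-
    -v$max_outlier_removed$coefficients[["A"]]
  expect_false("A" %in% robust_terms(v))
  expect_true("B" %in% robust_terms(v))
})

test_that("diagnostics reports quantify residual behavior", {
  d <- assemble_oacd(3)
  mz <- tgmo_fit(d, 100 - 10 * d$codes[, 1])
  rep0 <- diagnostics_report(mz)
  expect_true(all(abs(rep0$qq$sample) < 1e-10))

  f <- make_clean_model(seed = 12, n_drugs = 11)         # 155-row screen
  m <- tgmo_fit(f$design, .subset2(f$resp, "viability")[1:155])
  repg <- diagnostics_report(m)
  expect_gte(repg$qq_correlation, 0.98)

  # heavy-tailed noise scores worse than Gaussian over the same seed set
  dg <- assemble_oacd(11)                                # 155-row screen
  mu <- 100 - 10 * dg$codes[, 1]
  cors <- vapply(1:10, function(s) {
    set.seed(s)
    y_g <- mu + rnorm(length(mu), 0, 5)
    y_t <- mu + 5 * rt(length(mu), df = 2)
    c(gauss = diagnostics_report(
        tgmo_fit(dg, y_g, stepwise = FALSE))$qq_correlation,
      t2 = diagnostics_report(
        tgmo_fit(dg, y_t, stepwise = FALSE))$qq_correlation)
  }, numeric(2))
  expect_lt(mean(cors["t2", ]), mean(cors["gauss", ]))
})
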