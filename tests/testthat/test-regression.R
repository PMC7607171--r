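test_that("the second-order basis has the right columns in a fixed order", {
  d2 <- assemble_oacd(2)
  X2 <- expand_second_order(d2)
  expect_equal(ncol(X2), 6)                       # 1 + 2 + 2 + 1
  d11 <- assemble_oacd(11)
  X11 <- expand_second_order(d11)
  expect_equal(ncol(X11), 78)                     # 1 + 11 + 11 + 55
  info <- attr(X11, "term_info")
  expect_equal(table(info$type)[["interaction"]], 55)
  # over the two-level part every squared column is identically one:
  # quadratic effects are estimable only through the three-level rows
  ff <- d11$part == "two_level_ff"
  expect_true(all(X11[ff, info$type == "quadratic"] == 1))
})

test_that("stepwise selection recovers exact truths on noise-free screens", {
  d <- assemble_oacd(4)
  y <- 100 - 20 * d$codes[, 1]
  m <- tgmo_fit(d, y)
  expect_setequal(names(coef(m)), c("(Intercept)", "A"))
  expect_equal(unname(coef(m)[["A"]]), -20, tolerance = 1e-10)
  expect_equal(m$r.squared, 1)

  y2 <- 80 - 10 * d$codes[, 1] - 8 * d$codes[, 2] -
    6 * d$codes[, 1] * d$codes[, 2]
  m2 <- tgmo_fit(d, y2)
  expect_true(all(c("A", "B", "A:B") %in% names(coef(m2))))
  oracle <- ols_oracle(d, y2, names(coef(m2)))
  expect_equal(coef(m2), oracle, tolerance = 1e-8)

  m3 <- tgmo_fit(d, rep(100, nrow(d$codes)))      # constant response
  expect_equal(names(coef(m3)), "(Intercept)")
  expect_equal(m3$r.squared, 0)
})

test_that("stepwise agrees with the OLS oracle on random sparse truths", {
  d <- assemble_oacd(5)
  drugs <- colnames(d$codes)
  X <- expand_second_order(d)
  info <- attr(X, "term_info")
  pool <- info$term[info$type != "intercept"]
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(1:4, 1)
    active <- sample(pool, k)
    beta <- stats::setNames(sample(c(-1, 1), k, TRUE) * runif(k, 8, 20), active)
    y <- 100 + as.numeric(X[, active, drop = FALSE] %*% beta)
    m <- tgmo_fit(d, y)
    expect_setequal(setdiff(names(coef(m)), "(Intercept)"), active)
    oracle <- ols_oracle(d, y, names(coef(m)))
    expect_equal(coef(m), oracle, tolerance = 1e-8)
  }
})

test_that("fitting is equivariant to drug column permutation", {
  truth <- make_truth(small_panel(5), linear = c(A = -12, C = -9),
                      interaction = c("A:C" = -10), noise_sd = 4)
  d <- assemble_oacd(5)
  resp <- simulate_screen(truth, d, seed = 11)
  m <- tgmo_fit(d, resp)
  perm <- c(3, 1, 5, 2, 4)
  dperm <- d
  dperm$codes <- d$codes[, perm]
  mperm <- tgmo_fit(dperm, resp)
  # canonicalize pair names: the basis orders pairs by column position
  canon <- function(cf) {
    nm <- vapply(strsplit(names(cf), ":", fixed = TRUE), function(p)
      paste(sort(p), collapse = ":"), character(1))
    stats::setNames(cf, nm)[order(nm)]
  }
  expect_equal(canon(coef(m)), canon(coef(mperm)), tolerance = 1e-10)
})

test_that("therapeutic-window fits model the normal-minus-tumor difference", {
  d <- assemble_oacd(4)
  same <- 100 - 10 * d$codes[, 1]
  tw0 <- fit_therapeutic_window(d, same, same)
  expect_equal(names(coef(tw0)), "(Intercept)")   # all-zero difference

  tum <- 100 - 20 * d$codes[, 1]
  tw1 <- fit_therapeutic_window(d, tum, rep(100, nrow(d$codes)))
  expect_equal(unname(coef(tw1)[["A"]]), 20, tolerance = 1e-10)

  # tumor-only synergy propagates into a positive TW interaction
  truth_t <- make_truth(small_panel(4), linear = c(A = -12, B = -10),
                        interaction = c("A:B" = -15), noise_sd = 0)
  truth_n <- make_truth(small_panel(4), noise_sd = 0)
  rt <- simulate_screen(truth_t, d, replicates = 1)
  rn <- simulate_screen(truth_n, d, replicates = 1)
  tw2 <- fit_therapeutic_window(d, rt, rn)
  expect_equal(unname(coef(tw2)[["A:B"]]), 15, tolerance = 1e-8)
  expect_error(fit_therapeutic_window(d, tum[-1], rep(100, 34)))
})

test_that("combined fits pool replicate datasets and tighten standard errors", {
  d <- assemble_oacd(4)
  y <- 100 - 15 * d$codes[, 1] - 8 * d$codes[, 1] * d$codes[, 2]
  cmb0 <- fit_combined(d, list(y, y, y))
  expect_equal(coef(cmb0$combined), coef(cmb0$per_dataset[[1]]),
               tolerance = 1e-10)

  truth <- make_truth(small_panel(4), linear = c(A = -15),
                      interaction = c("A:B" = -10), noise_sd = 5)
  sets <- lapply(1:3, function(s) simulate_screen(truth, d, seed = 100 + s))
  cmb <- fit_combined(d, sets)
  shared <- Reduce(intersect, c(list(names(coef(cmb$combined))),
                                lapply(cmb$per_dataset,
                                       function(m) names(coef(m)))))
  shared <- setdiff(shared, "(Intercept)")
  expect_gt(length(shared), 0)
  for (tm in shared) {
    for (m in cmb$per_dataset) expect_lt(cmb$combined$se[[tm]], m$se[[tm]])
  }
  expect_error(fit_combined(d, list(y)), "at least two")
})

test_that("predictions evaluate the surface, control lands near 100% CTRL", {
  truth <- make_truth(small_panel(4), linear = c(A = -15, B = -10),
                      interaction = c("A:B" = -12), noise_sd = 0)
  d <- assemble_oacd(4)
  m <- tgmo_fit(d, simulate_screen(truth, d, replicates = 1))
  ctrl <- stats::setNames(rep(-1, 4), small_panel(4))
  expect_equal(predict(m, ctrl), 100, tolerance = 1e-8)

  d1 <- assemble_oacd(4)
  m1 <- tgmo_fit(d1, 100 - 20 * d1$codes[, 1])
  codes <- stats::setNames(c(1, -1, -1, -1), small_panel(4))
  expect_equal(predict(m1, codes), 80, tolerance = 1e-10)

  # fractional-code surface grid for contour export
  g <- expand.grid(A = seq(-1, 1, length.out = 21),
                   B = seq(-1, 1, length.out = 21))
  codes_mat <- cbind(as.matrix(g), C = -1, D = -1)
  surf <- predict(m, codes_mat)
  expect_length(surf, 441)
  expect_error(predict(m, c(A = 1, B = 0, C = -1, Z = 0)), "unknown drug|missing")
})
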