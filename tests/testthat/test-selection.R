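# helper: fit noise-free models from a truth pair and return calls/models
fit_truth_models <- function(truth_t, truth_n, n = length(truth_t$drugs)) {
  d <- assemble_oacd(n, factor_names = truth_t$drugs)
  rt <- simulate_screen(truth_t, d, replicates = 1)
  rn <- simulate_screen(truth_n, d, replicates = 1)
  mt <- tgmo_fit(d, rt)
  tw <- fit_therapeutic_window(d, rt, rn)
  list(design = d, tumor = mt, tw = tw,
       calls = classify_interactions(mt, tw))
}

test_that("interaction calls follow the sign and significance rules", {
  truth_t <- make_truth(small_panel(4),
                        linear = c(A = -14, B = -10, C = 8),
                        quadratic = c(A = -5, B = 6),
                        interaction = c("A:B" = -12, "C:D" = 9),
                        noise_sd = 1)
  truth_n <- make_truth(small_panel(4), noise_sd = 1)
  d <- assemble_oacd(4)
  set.seed(2)
  f <- list(design = d)
  rt <- simulate_screen(truth_t, d, seed = 2)
  rn <- simulate_screen(truth_n, d, seed = 3)
  mt <- tgmo_fit(d, rt)
  tw <- fit_therapeutic_window(d, rt, rn)
  calls <- classify_interactions(mt, tw)
  lab <- function(tm) calls$label[calls$term == tm]
  expect_equal(lab("A:B"), "synergistic")        # negative pair term
  expect_equal(lab("C:D"), "antagonistic")       # positive pair term
  expect_equal(lab("A"), "efficacious")
  expect_equal(lab("C"), "stimulatory")
  expect_equal(lab("A^2"), "dose_dependent")     # negative quadratic
  expect_equal(lab("B^2"), "stable_over_range")  # positive quadratic
  # selective efficacy in tumor cells -> optimal flag (TW positive)
  expect_true(calls$optimal[calls$term == "A"])
})

test_that("non-significant terms get no call", {
  d <- assemble_oacd(4)
  set.seed(5)
  y <- 100 - 15 * d$codes[, 1] + rnorm(nrow(d$codes), 0, 5)
  m <- tgmo_fit(d, y)
  calls <- classify_interactions(m, alpha = 1e-12)
  expect_true(all(is.na(calls$label[calls$p > 1e-12])))
})

test_that("elimination keeps active and synergistic drugs, drops inert ones", {
  truth_t <- make_truth(small_panel(11),
                        linear = stats::setNames(rep(-12, 7),
                                                 small_panel(7)),
                        interaction = c("A:B" = -14),
                        noise_sd = 2)
  truth_n <- make_truth(small_panel(11), noise_sd = 2)
  d <- assemble_oacd(11)
  rt <- simulate_screen(truth_t, d, seed = 21)
  rn <- simulate_screen(truth_n, d, seed = 22)
  mt <- tgmo_fit(d, rt)
  tw <- fit_therapeutic_window(d, rt, rn)
  calls <- classify_interactions(mt, tw)
  kept <- eliminate_drugs(calls, small_panel(11), 7)
  expect_setequal(kept, small_panel(7))          # exactly the 7 active drugs
  expect_error(eliminate_drugs(calls, small_panel(11), 2), "at least 3")
  expect_error(eliminate_drugs(calls, small_panel(11), 11), "smaller")
})

test_that("the elimination score nets synergy against antagonism as documented", {
  calls <- structure(
    data.frame(term = c("A", "A:B", "A:C", "D"),
               type = c("linear", "interaction", "interaction", "linear"),
               estimate = c(-10, -12, 9, -8),
               p = c(0.01, 0.003, 0.04, 0.02),
               label = c("efficacious", "synergistic", "antagonistic",
                         "efficacious"),
               tw_estimate = NA_real_, tw_p = NA_real_,
               tw_label = NA_character_, optimal = FALSE,
               stringsAsFactors = FALSE),
    class = c("interaction_calls", "data.frame"))
  kept <- eliminate_drugs(calls, c("A", "B", "C", "D", "E"), 3)
  sc <- attr(kept, "scores")
  # A: +1 linear +2 synergy -2 antagonism = 1; B: +2; C: -2; D: +1; E(inert): -1
  expect_equal(sc$score[sc$drug == "A"], 1)
  expect_equal(sc$score[sc$drug == "B"], 2)
  expect_equal(sc$score[sc$drug == "C"], -2)
  expect_equal(sc$score[sc$drug == "D"], 1)
  expect_equal(sc$score[sc$drug == "E"], -1)
  expect_setequal(kept, c("A", "B", "D"))
})

test_that("the ODC contains the dominant synergistic pair", {
  truth_t <- make_truth(small_panel(4),
                        linear = c(A = -12, B = -10, C = -6, D = -5),
                        interaction = c("A:B" = -15), noise_sd = 0)
  truth_n <- make_truth(small_panel(4), noise_sd = 0)
  f <- fit_truth_models(truth_t, truth_n)
  odc <- select_odc(f$tumor, f$tw)
  expect_true(all(c("A", "B") %in% odc$drugs))
  expect_false(odc$warning)
  expect_lt(odc$predicted_viability, 60)
})

test_that("within the efficacy tie band the larger therapeutic window wins", {
  d <- assemble_oacd(4)
  # two equally efficacious subsets; only drugs C,D open the window
  tum <- 100 - 10 * rowSums(d$codes)
  nor <- 100 - 10 * d$codes[, 1] - 10 * d$codes[, 2]   # A,B hit normal cells too
  mt <- tgmo_fit(d, tum)
  tw <- fit_therapeutic_window(d, tum, nor)
  odc <- select_odc(mt, tw, tie_band = 50)
  expect_true(all(c("C", "D") %in% odc$drugs))
})

test_that("an all-inert model yields a warning-flagged result", {
  truth <- make_truth(small_panel(4), noise_sd = 0)
  f <- fit_truth_models(truth, truth)
  odc <- select_odc(f$tumor, f$tw)
  expect_true(odc$warning)
})

test_that("dose refinement exploits flat directions and monotone surfaces", {
  d <- assemble_oacd(4)
  # surface flat along C: refinement should spare C (lowest grid code)
  y <- 100 - 15 * d$codes[, 1] - 12 * d$codes[, 2] - 8 * d$codes[, 4]
  m <- tgmo_fit(d, y)
  odc <- select_odc(m)
  odc$drugs <- small_panel(4)[1:3]               # refine over A, B, C
  ref <- refine_doses(m, odc)
  expect_equal(unname(ref$codes[["C"]]), -1)     # dose sparing
  expect_equal(unname(ref$codes[["A"]]), 1)      # monotone: cap at top code
  expect_equal(unname(ref$codes[["B"]]), 1)
  expect_equal(nrow(ref$dose_sparing), 3)
})

test_that("refinement moves doses in the directions the surface rewards", {
  # benefit from lowering A and B (strong positive quadratic pulls the
  # optimum inside the range) while raising C and D
  d <- assemble_oacd(4)
  y <- 100 - 4 * d$codes[, 1] + 8 * d$codes[, 1]^2 -
    4 * d$codes[, 2] + 8 * d$codes[, 2]^2 -
    10 * d$codes[, 3] - 9 * d$codes[, 4]
  m <- tgmo_fit(d, y)
  odc <- select_odc(m)
  odc$drugs <- small_panel(4)
  ref <- refine_doses(m, odc, n_grid = 17)
  expect_lt(ref$codes[["A"]], 1)                 # interior optimum
  expect_lt(ref$codes[["B"]], 1)
  expect_equal(unname(ref$codes[["C"]]), 1)
  expect_equal(unname(ref$codes[["D"]]), 1)
  # refined concentrations respect the PCL cap
  dt <- dose_table(small_panel(4), dose1 = rep(1, 4), dose2 = rep(2, 4),
                   pcl = rep(2, 4))
  ref2 <- refine_doses(m, odc, doses = dt, n_grid = 9)
  expect_true(all(ref2$concentrations <= 2 + 1e-9))
})
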