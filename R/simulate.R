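# Seeded synthetic screens with known ground truth. Responses follow the
# second-order model exactly - mean-zero i.i.d. Gaussian noise on the
# % CTRL scale - so every downstream stage (selection, diagnostics,
# calibration) is testable against a known answer.

#' Define a ground-truth response surface
#'
#' Builds the true coefficient set of a simulated screen. The intercept is
#' chosen so that the vehicle control (all codes -1) sits exactly at
#' \code{control} % CTRL, which is how screen responses are normalized.
#'
#' @param drugs character vector of drug names.
#' @param linear named numeric vector of true linear coefficients (% CTRL
#'   per coded unit; negative = inhibitory). Unnamed drugs are inert.
#' @param quadratic named numeric vector of true quadratic coefficients.
#' @param interaction named list or numeric vector with names like
#'   \code{"A:B"}; negative = synergistic.
#' @param control viability at the vehicle control row (default 100).
#' @param noise_sd Gaussian noise standard deviation, % CTRL.
#' @param replicates default replicate count for [simulate_screen()].
#' @return object of class \code{tgmo_truth}.
#' @export
make_truth <- function(drugs, linear = NULL, quadratic = NULL,
                       interaction = NULL, control = 100,
                       noise_sd = 5, replicates = 3L) {
  stopifnot(is.character(drugs), length(drugs) >= 2L, noise_sd >= 0)
  lin <- stats::setNames(rep(0, length(drugs)), drugs)
  if (!is.null(linear)) {
    stopifnot(all(names(linear) %in% drugs))
    lin[names(linear)] <- linear
  }
  quad <- stats::setNames(rep(0, length(drugs)), drugs)
  if (!is.null(quadratic)) {
    stopifnot(all(names(quadratic) %in% drugs))
    quad[names(quadratic)] <- quadratic
  }
  inter <- unlist(interaction)
  if (length(inter)) {
    pairs <- strsplit(names(inter), ":", fixed = TRUE)
    ok <- vapply(pairs, function(p)
      length(p) == 2L && all(p %in% drugs) && p[1] != p[2], logical(1))
    if (!all(ok)) stop("interaction names must be 'drugA:drugB' over the panel")
    # canonical order: first drug earlier in the panel
    names(inter) <- vapply(pairs, function(p)
      paste(p[order(match(p, drugs))], collapse = ":"), character(1))
  } else inter <- stats::setNames(numeric(0), character(0))
  # anchor the control row: y(all -1) = b0 - sum(lin) + sum(quad) + sum(inter)
  b0 <- control + sum(lin) - sum(quad) - sum(inter)
  structure(list(drugs = drugs, b0 = b0, linear = lin, quadratic = quad,
                 interaction = inter, control = control,
                 noise_sd = noise_sd, replicates = as.integer(replicates)),
            class = "tgmo_truth")
}

#' @export
print.tgmo_truth <- function(x, ...) {
  cat("Ground-truth surface:", length(x$drugs), "drugs, noise sd",
      x$noise_sd, "% CTRL,", x$replicates, "replicates\n")
  act <- c(x$linear[x$linear != 0], x$quadratic[x$quadratic != 0],
           x$interaction)
  if (length(act)) print(round(act, 2)) else cat("  (all inert)\n")
  invisible(x)
}

# true mean response at a code matrix (columns named by truth drugs)
truth_mean <- function(truth, codes) {
  drugs <- truth$drugs
  stopifnot(all(drugs %in% colnames(codes)))
  y <- rep(truth$b0, nrow(codes))
  for (d in drugs) {
    y <- y + truth$linear[[d]] * codes[, d] + truth$quadratic[[d]] * codes[, d]^2
  }
  for (nm in names(truth$interaction)) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1]]
    y <- y + truth$interaction[[nm]] * codes[, p[1]] * codes[, p[2]]
  }
  y
}

# restrict a truth to a drug subset (eliminated drugs are fixed at code -1,
# i.e. absent; their contribution is folded into the intercept)
truth_subset <- function(truth, drugs) {
  drop <- setdiff(truth$drugs, drugs)
  b0 <- truth$b0
  for (d in drop) b0 <- b0 - truth$linear[[d]] + truth$quadratic[[d]]
  inter <- truth$interaction
  for (nm in names(inter)) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1]]
    both_out <- all(p %in% drop)
    one_out <- xor(p[1] %in% drop, p[2] %in% drop)
    if (both_out) b0 <- b0 + inter[[nm]]
  }
  lin <- truth$linear[drugs]
  for (nm in names(inter)) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (p[1] %in% drop && p[2] %in% drugs)
      lin[[p[2]]] <- lin[[p[2]]] - inter[[nm]]
    if (p[2] %in% drop && p[1] %in% drugs)
      lin[[p[1]]] <- lin[[p[1]]] - inter[[nm]]
  }
  keep_int <- vapply(names(inter), function(nm) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1]]
    all(p %in% drugs)
  }, logical(1))
  structure(list(drugs = drugs, b0 = b0, linear = lin,
                 quadratic = truth$quadratic[drugs],
                 interaction = inter[keep_int],
                 control = truth$control,
                 noise_sd = truth$noise_sd, replicates = truth$replicates),
            class = "tgmo_truth")
}

#' Simulate a drug-combination screen
#'
#' Evaluates the ground-truth surface at every design row and adds
#' independent Gaussian noise per replicate. Output is the long response
#' format [tgmo_fit()] accepts.
#'
#' @param truth a [make_truth()] surface.
#' @param design an [assemble_oacd()] design over (a superset of) the
#'   truth's drugs.
#' @param replicates,noise_sd override the truth's defaults.
#' @param seed integer seed; the simulation is a pure function of
#'   (truth, design, seed).
#' @param population label carried in the output.
#' @return data.frame with columns \code{row}, \code{replicate},
#'   \code{population}, \code{viability}.
#' @export
simulate_screen <- function(truth, design, replicates = truth$replicates,
                            noise_sd = truth$noise_sd, seed = NULL,
                            population = "tumor") {
  stopifnot(inherits(truth, "tgmo_truth"), inherits(design, "oacd_design"))
  if (noise_sd < 0) stop("noise sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- truth_mean(truth, design$codes)
  n <- nrow(design$codes)
  out <- data.frame(
    row = rep(seq_len(n), times = replicates),
    replicate = rep(seq_len(replicates), each = n),
    population = population,
    viability = rep(mu, times = replicates) +
      stats::rnorm(n * replicates, 0, noise_sd))
  out
}

#' Simulate single-drug dose-response data
#'
#' Seeded noisy samples of the forward four-parameter logistic curve, in
#' the dose-response CSV layout the fitting functions read.
#'
#' @param top,bottom,ec50,hill 4PL parameters.
#' @param doses positive concentrations to sample.
#' @param noise_sd Gaussian noise sd on the % CTRL scale.
#' @param replicates samples per dose.
#' @param seed integer seed.
#' @return data.frame with columns \code{dose}, \code{replicate},
#'   \code{viability}.
#' @export
simulate_dose_response <- function(top = 100, bottom = 0, ec50 = 1, hill = 1,
                                   doses = 10^seq(-2, 2, length.out = 8),
                                   noise_sd = 0, replicates = 1L,
                                   seed = NULL) {
  if (noise_sd < 0) stop("noise sd must be >= 0")
  stopifnot(ec50 > 0, all(doses > 0))
  if (!is.null(seed)) set.seed(seed)
  mu <- bottom + (top - bottom) / (1 + (doses / ec50)^hill)
  data.frame(
    dose = rep(doses, times = replicates),
    replicate = rep(seq_len(replicates), each = length(doses)),
    viability = rep(mu, times = replicates) +
      stats::rnorm(length(doses) * replicates, 0, noise_sd))
}

#' Named ground-truth scenario library
#'
#' Scenarios mirroring the qualitative behaviors a multidrug screen can
#' present, each a tumor/nonmalignant pair of [make_truth()] surfaces over
#' an 11-drug panel:
#' \describe{
#'   \item{one_synergistic_pair}{one synergistic pair (A:B) among active and
#'     inert drugs; the nonmalignant surface is mildly and uniformly
#'     affected.}
#'   \item{selective_synergy}{the interaction exists in tumor cells only, so
#'     the therapeutic-window model shows a positive interaction term.}
#'   \item{flat_surface_synergy}{a synergistic pair whose positive quadratic
#'     terms keep the effect stable over the dose range: activity robust to
#'     dose reduction.}
#'   \item{hormetic_single}{one drug stimulates tumor growth at low dose
#'     (positive linear term), as hormetic responses do.}
#'   \item{all_inert}{a null panel; the pipeline should flag its result.}
#' }
#'
#' @param noise_sd,replicates study conditions applied to every scenario.
#' @return named list; each element has \code{$tumor} and \code{$normal}
#'   truths.
#' @export
preset_scenarios <- function(noise_sd = 5, replicates = 3L) {
  drugs <- factor_letters(11)
  mk <- function(...) make_truth(drugs, ..., noise_sd = noise_sd,
                                 replicates = replicates)
  flat_normal <- mk()
  list(
    one_synergistic_pair = list(
      tumor = mk(linear = c(A = -15, B = -12, C = -10, D = -8, E = -8),
                 interaction = c("A:B" = -15)),
      normal = mk(linear = c(A = -4, B = -3, C = -3, D = -2, E = -2))),
    selective_synergy = list(
      tumor = mk(linear = c(A = -15, B = -12, C = -8),
                 interaction = c("A:B" = -15)),
      normal = flat_normal),
    flat_surface_synergy = list(
      tumor = mk(linear = c(A = -12, B = -10),
                 quadratic = c(A = 8, B = 7),
                 interaction = c("A:B" = -12)),
      normal = flat_normal),
    hormetic_single = list(
      tumor = mk(linear = c(A = 8, B = -12, C = -10),
                 interaction = c("B:C" = -10)),
      normal = flat_normal),
    all_inert = list(tumor = mk(), normal = flat_normal))
}
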