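# Single-drug dose-response fitting and clinically capped screen-dose
# selection. Screening doses are deliberately low (ED10/ED20) and never
# exceed the plasma concentration limit (PCL), the average clinical plasma
# concentration AUC_0-24h / 24 h.

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits viability (% of control) against dose with the standard 4PL model
#' \deqn{y = bottom + (top - bottom) / (1 + (d / ec50)^{hill})}
#' by Levenberg-Marquardt least squares. A positive hill slope gives a
#' decreasing (inhibitory) curve from \code{top} at zero dose to
#' \code{bottom} at high dose.
#'
#' A response that is flat over the tested range cannot identify ec50; such
#' fits are returned with \code{no_effect = TRUE} (top and bottom within 1%
#' of each other, or the fit fails to converge on a flat profile).
#'
#' @param doses positive concentrations, at least 4 distinct values.
#' @param responses viability, % CTRL, same length as \code{doses}
#'   (replicates may repeat doses).
#' @return object of class \code{dr_fit}: \code{top}, \code{bottom},
#'   \code{ec50}, \code{hill}, residuals, convergence info, \code{no_effect}.
#' @examples
#' d <- rep(10^seq(-2, 2, length.out = 8), each = 3)
#' y <- 100 / (1 + d / 1)            # top 100, bottom 0, ec50 1, hill 1
#' fit <- fit_four_param_logistic(d, y)
#' effective_dose(fit, 0.5)          # 1 (the EC50)
#' @export
fit_four_param_logistic <- function(doses, responses) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses to fit a 4PL")
  ybar <- tapply(responses, doses, mean)
  span <- max(ybar) - min(ybar)
  if (span < 1) {
    return(structure(list(top = mean(responses), bottom = mean(responses),
                          ec50 = NA_real_, hill = NA_real_,
                          residuals = responses - mean(responses),
                          doses = doses, responses = responses,
                          no_effect = TRUE, converged = FALSE),
                     class = "dr_fit"))
  }
  ld <- log(doses)
  fourpl_resid <- function(par)
    responses - (par[2] + (par[1] - par[2]) /
                   (1 + exp(par[4] * (ld - par[3]))))
  fourpl_jac <- function(par) {                  # d(residual)/d(par)
    e <- exp(par[4] * (ld - par[3]))
    g <- 1 / (1 + e)
    w <- (par[1] - par[2]) * e * g^2
    -cbind(g, 1 - g, par[4] * w, -(ld - par[3]) * w)
  }
  start <- c(max(ybar), min(ybar), unname(stats::median(ld)), 1)
  fit <- minpack.lm::nls.lm(start, fn = fourpl_resid, jac = fourpl_jac,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("4PL fit did not converge: ", fit$message)
  cf <- fit$par
  structure(list(top = cf[1], bottom = cf[2],
                 ec50 = exp(cf[3]), hill = cf[4],
                 residuals = fit$fvec,
                 doses = doses, responses = responses,
                 no_effect = abs(cf[1] - cf[2]) < 1,
                 converged = TRUE),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  if (x$no_effect) {
    cat("4PL dose-response fit: no effect over the tested range\n")
  } else {
    cat(sprintf(
      "4PL dose-response fit: top %.1f, bottom %.1f, ec50 %.4g, hill %.3f\n",
      x$top, x$bottom, x$ec50, x$hill))
  }
  invisible(x)
}

#' @export
predict.dr_fit <- function(object, newdoses, ...) {
  if (object$no_effect) return(rep(object$top, length(newdoses)))
  with(object, bottom + (top - bottom) / (1 + (newdoses / ec50)^hill))
}

#' Effective dose at a given inhibition level
#'
#' Inverts the fitted 4PL to the dose at which viability drops to
#' \code{top - level * (top - bottom)}; \code{level = 0.2} gives the ED20.
#' The level must be attainable within the fitted span: a curve whose
#' maximum inhibition is 10% has no ED20.
#'
#' @param fit a [fit_four_param_logistic()] result.
#' @param level inhibition fraction in (0, 1), relative to the full
#'   top-to-bottom span.
#' @return the effective dose (same units as the fitted doses).
#' @export
effective_dose <- function(fit, level) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!(level > 0 && level < 1)) stop("inhibition level must be in (0, 1)")
  if (fit$no_effect) stop("ED not attainable: curve shows no effect")
  # viability target measured from top on the % CTRL scale: the requested
  # absolute inhibition must not exceed the curve's span (top - bottom)
  span <- fit$top - fit$bottom
  target_drop <- level * fit$top
  if (target_drop >= span * (1 + 1e-9))
    stop("ED not attainable: maximum inhibition on this curve is ",
         round(100 * span / fit$top, 1), "% of control")
  frac <- target_drop / span          # position within the logistic span
  dose <- fit$ec50 * (frac / (1 - frac))^(1 / fit$hill)
  unname(dose)
}

#' Plasma concentration limit from clinical exposure
#'
#' The PCL is the time-averaged clinical plasma concentration,
#' \code{auc_0_24 / 24}, in the AUC's concentration unit (ug/mL for an AUC
#' in ug.h/mL). With a molecular weight it is additionally converted to
#' molar units (mol/L).
#'
#' @param auc_0_24 area under the plasma concentration-time curve over
#'   0-24 h, in ug.h/mL.
#' @param molecular_weight optional, g/mol; triggers molar conversion.
#' @return the PCL: ug/mL without a molecular weight, mol/L with one.
#' @examples
#' plasma_concentration_limit(24)        # 1 ug/mL
#' plasma_concentration_limit(24, 500)   # 2e-6 mol/L (2 uM)
#' @export
plasma_concentration_limit <- function(auc_0_24, molecular_weight = NULL) {
  if (!is.numeric(auc_0_24) || auc_0_24 <= 0)
    stop("AUC_0-24h must be a positive number")
  pcl <- auc_0_24 / 24                       # ug/mL
  if (!is.null(molecular_weight)) {
    stopifnot(molecular_weight > 0)
    pcl <- pcl * 1e-3 / molecular_weight     # ug/mL = mg/L -> mol/L
  }
  pcl
}

#' Select the two screening doses for a drug
#'
#' The high screening dose (dose 2) is the ED20 capped at the plasma
#' concentration limit; the low dose (dose 1) is always half of dose 2.
#' When the ED20 is not attainable (weak single-drug activity) the PCL
#' itself becomes dose 2 - the clinically relevant ceiling.
#'
#' @param fit a [fit_four_param_logistic()] result, or a bare ED20
#'   concentration.
#' @param pcl plasma concentration limit in the same units (NA for none).
#' @return named numeric vector \code{c(dose1, dose2)}.
#' @export
select_screen_doses <- function(fit, pcl = NA_real_) {
  ed20 <- if (inherits(fit, "dr_fit")) {
    tryCatch(effective_dose(fit, 0.2), error = function(e) NA_real_)
  } else as.numeric(fit)
  if (is.na(ed20) && is.na(pcl))
    stop("ED20 not attainable and no plasma concentration limit given")
  dose2 <- if (is.na(ed20)) pcl else if (is.na(pcl)) ed20 else min(ed20, pcl)
  if (dose2 <= 0) stop("selected dose must be positive")
  c(dose1 = dose2 / 2, dose2 = dose2)
}

#' Trapezoidal AUC and Cmax from a sampled concentration profile
#'
#' Computes the area under the concentration-time curve by the trapezoidal
#' rule over the observed interval only (no extrapolation beyond the last
#' sample) together with the maximum observed concentration.
#'
#' @param times sampling times in hours, strictly increasing, at least two.
#' @param concentrations measured concentrations (ug/mL), same length.
#' @return list with \code{auc} (ug.h/mL over \[first, last\] time),
#'   \code{c_max}, \code{t_max}, and the profile.
#' @export
auc_trapezoid <- function(times, concentrations) {
  times <- as.numeric(times); concentrations <- as.numeric(concentrations)
  stopifnot(length(times) == length(concentrations))
  if (length(times) < 2L) stop("need at least two time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  list(auc = pracma::trapz(times, concentrations),
       c_max = max(concentrations),
       t_max = times[which.max(concentrations)],
       times = times, concentrations = concentrations)
}
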