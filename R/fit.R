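# Stepwise second-order response-surface regression of screen viability.
#
# The model is y = b0 + sum_i bi xi + sum_i bii xi^2 + sum_{i<j} bij xi xj + e
# on coded dose levels xi in {-1, 0, +1}. Negative linear/interaction
# coefficients mean inhibitory/synergistic activity, positive mean
# stimulatory/antagonistic; quadratic terms describe the shape of the
# response over the dose range.

#' Second-order model matrix of a coded design
#'
#' Expands a coded design into the full second-order regression basis:
#' intercept, linear terms (panel order), quadratic terms, and all pairwise
#' products (lexicographic). Over the two-level rows (codes +/-1) every
#' squared column is identically 1, which is why quadratic effects are
#' estimable only through the three-level orthogonal-array part.
#'
#' @param design an [assemble_oacd()] design, or a bare code matrix with
#'   drug-named columns.
#' @return numeric matrix with a \code{term_info} attribute describing each
#'   column (type \code{intercept}/\code{linear}/\code{quadratic}/
#'   \code{interaction} and the drugs involved).
#' @export
expand_second_order <- function(design) {
  codes <- if (inherits(design, "oacd_design")) design$codes else as.matrix(design)
  drugs <- colnames(codes)
  if (is.null(drugs)) stop("design columns must be named")
  n <- ncol(codes)
  cols <- list(`(Intercept)` = rep(1, nrow(codes)))
  info <- data.frame(term = "(Intercept)", type = "intercept",
                     d1 = NA_character_, d2 = NA_character_,
                     stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    cols[[drugs[j]]] <- codes[, j]
    info <- rbind(info, data.frame(term = drugs[j], type = "linear",
                                   d1 = drugs[j], d2 = NA, stringsAsFactors = FALSE))
  }
  for (j in seq_len(n)) {
    nm <- paste0(drugs[j], "^2")
    cols[[nm]] <- codes[, j]^2
    info <- rbind(info, data.frame(term = nm, type = "quadratic",
                                   d1 = drugs[j], d2 = NA, stringsAsFactors = FALSE))
  }
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    nm <- paste0(drugs[a], ":", drugs[b])
    cols[[nm]] <- codes[, a] * codes[, b]
    info <- rbind(info, data.frame(term = nm, type = "interaction",
                                   d1 = drugs[a], d2 = drugs[b],
                                   stringsAsFactors = FALSE))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "term_info") <- info
  X
}

# Normalize the accepted response forms to (y, row_id, replicate):
# a vector (one value per design row), a rows x replicates matrix, or a
# long data frame with columns row, viability[, replicate].
.as_screen_obs <- function(design, response) {
  n_rows <- nrow(design$codes)
  if (is.data.frame(response)) {
    need <- c("row", "viability")
    if (!all(need %in% names(response)))
      stop("long responses need columns 'row' and 'viability'")
    row_id <- as.integer(response$row)
    if (any(row_id < 1L | row_id > n_rows))
      stop("response references design rows outside 1..", n_rows)
    rep_id <- if ("replicate" %in% names(response))
      as.integer(response$replicate) else rep(1L, nrow(response))
    list(y = as.numeric(response$viability), row_id = row_id,
         replicate = rep_id)
  } else if (is.matrix(response)) {
    if (nrow(response) != n_rows)
      stop("response matrix must have one row per design row")
    r <- ncol(response)
    list(y = as.numeric(response),
         row_id = rep(seq_len(n_rows), times = r),
         replicate = rep(seq_len(r), each = n_rows))
  } else {
    response <- as.numeric(response)
    if (length(response) != n_rows)
      stop("response vector must have one value per design row (",
           n_rows, ")")
    list(y = response, row_id = seq_len(n_rows),
         replicate = rep(1L, n_rows))
  }
}

#' Fit the stepwise second-order viability model
#'
#' Fits the second-order response-surface regression of viability (% of
#' control) on coded dose levels, with bidirectional stepwise term selection:
#' starting from the intercept-plus-linear model, terms enter on a partial-F
#' p-value below \code{p_enter} and leave above \code{p_remove}. Ties are
#' broken by smaller p-value, then by column order, so the fit is
#' deterministic. Any second-order term may enter whether or not its parent
#' linear terms are currently selected; parents are candidates, never forced.
#'
#' @param design an [assemble_oacd()] design.
#' @param response screen viability: a numeric vector (one value per design
#'   row), a rows-by-replicates matrix, or a long \code{data.frame} with
#'   columns \code{row}, \code{viability} and optionally \code{replicate}.
#' @param population label stored with the fit (\code{"tumor"},
#'   \code{"nonmalignant"}, \code{"tw"}, ...).
#' @param stepwise if \code{FALSE}, fit the full second-order model by
#'   ordinary least squares with no selection.
#' @param p_enter,p_remove partial-F entry/removal thresholds.
#' @param max_steps safety cap on selection steps.
#' @return an object of class \code{tgmo_model} with coefficients, standard
#'   errors, per-term p-values, \eqn{R^2}, fitted values, residuals and the
#'   selection trace. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{plot},
#'   \code{simulate}, \code{cooks.distance}.
#' @examples
#' d <- assemble_oacd(4)
#' y <- 100 - 20 * d$codes[, 1]          # one active drug, noise-free
#' m <- tgmo_fit(d, y)
#' coef(m)                               # intercept 100, A = -20
#' @export
tgmo_fit <- function(design, response, population = "tumor",
                     stepwise = TRUE, p_enter = 0.05, p_remove = 0.10,
                     max_steps = 500L) {
  stopifnot(inherits(design, "oacd_design"))
  obs <- .as_screen_obs(design, response)
  Xall <- expand_second_order(design)
  info <- attr(Xall, "term_info")
  X <- Xall[obs$row_id, , drop = FALSE]   # expand to observation level
  y <- obs$y
  n <- length(y)

  attr(X, "term_info") <- info            # row-subsetting drops attributes
  if (stepwise) {
    sel <- .stepwise_select(X, y, p_enter, p_remove, max_steps)
  } else {
    sel <- list(selected = seq_len(ncol(X)), trace = data.frame())
  }
  keep <- sel$selected                       # always includes column 1
  fit <- .ols(X[, keep, drop = FALSE], y)
  if (fit$rank < length(keep)) {
    aliased <- colnames(X)[keep][fit$aliased]
    stop("rank deficiency after selection; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-12) 0 else max(0, 1 - fit$rss / tss)

  structure(
    list(coefficients = fit$coef, se = fit$se, t = fit$t, p = fit$p,
         r.squared = r2, sigma2 = fit$s2, df.residual = fit$df,
         fitted.values = fit$fitted, residuals = fit$resid,
         term_info = info[keep, , drop = FALSE],
         trace = sel$trace,
         X = X[, keep, drop = FALSE], y = y,
         obs_rows = obs$row_id, obs_replicate = obs$replicate,
         design = design, population = population,
         control = list(stepwise = stepwise, p_enter = p_enter,
                        p_remove = p_remove),
         call = match.call()),
    class = "tgmo_model")
}

# plain OLS via QR, returning everything the model object needs
.ols <- function(X, y) {
  qr_x <- qr(X)
  rank <- qr_x$rank
  coefs <- qr.coef(qr_x, y)
  aliased <- is.na(coefs)
  fitted <- qr.fitted(qr_x, y)
  resid <- y - fitted
  rss <- sum(resid^2)
  df <- length(y) - rank
  s2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- tryCatch(chol2inv(qr.R(qr_x)), error = function(e) NULL)
  se <- if (!is.null(XtXinv) && !anyNA(s2)) sqrt(pmax(diag(XtXinv), 0) * s2)
        else rep(NA_real_, length(coefs))
  names(se) <- names(coefs)
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coef = coefs, se = se, t = tval, p = pval, fitted = fitted,
       resid = resid, rss = rss, df = df, s2 = s2, rank = rank,
       aliased = aliased, qr = qr_x)
}

# Bidirectional stepwise selection over the second-order term pool.
# Column 1 (intercept) is fixed. Degenerate (near-zero residual) states are
# resolved by sum-of-squares comparisons at a relative tolerance so that
# noise-free inputs select exactly the active terms.
.stepwise_select <- function(X, y, p_enter, p_remove, max_steps) {
  n <- length(y)
  m <- ncol(X)
  tss <- sum((y - mean(y))^2)
  eps <- 1e-10 * max(tss, 1)
  start <- intersect(seq_len(m),
                     c(1L, which(attr_type(X) == "linear")))
  sel <- start
  trace <- list()
  seen <- character(0)
  for (step in seq_len(max_steps)) {
    key <- paste(sort(sel), collapse = ",")
    if (key %in% seen) break            # selection revisited: stop
    seen <- c(seen, key)
    fit <- .ols(X[, sel, drop = FALSE], y)
    # --- removal ---
    if (length(sel) > 1L) {
      if (!is.na(fit$s2) && fit$s2 > eps / max(fit$df, 1)) {
        p_out <- fit$p[-1]
      } else {
        # residuals numerically zero: a term is removable iff dropping it
        # does not increase RSS beyond tolerance
        p_out <- vapply(seq_along(sel)[-1], function(k) {
          rss_wo <- .ols(X[, sel[-k], drop = FALSE], y)$rss
          if (rss_wo - fit$rss < eps) 1 else 0
        }, numeric(1))
        names(p_out) <- colnames(X)[sel[-1]]
      }
      p_out[is.na(p_out)] <- 1          # aliased terms explain nothing
      if (max(p_out) > p_remove) {
        k <- which.max(p_out)           # ties: first (panel order)
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "remove",
                     term = names(p_out)[k], p = p_out[[k]])
        sel <- sel[-(k + 1L)]
        next
      }
    }
    # --- addition ---
    cand <- setdiff(seq_len(m), sel)
    if (length(cand)) {
      Q <- qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]
      C <- X[, cand, drop = FALSE]
      Cp <- C - Q %*% crossprod(Q, C)
      den <- colSums(Cp^2)
      num <- as.numeric(crossprod(Cp, fit$resid))^2
      drss <- ifelse(den > 1e-9 * n, num / den, 0)
      rss_new <- fit$rss - drss
      df_new <- n - length(sel) - 1L
      p_in <- rep(1, length(cand))
      est <- den > 1e-9 * n & df_new > 0
      if (fit$rss < eps) {
        # nothing left to explain
      } else {
        f <- drss[est] / pmax(rss_new[est], eps) * df_new
        p_in[est] <- stats::pf(f, 1, df_new, lower.tail = FALSE)
        p_in[est][rss_new[est] < eps & drss[est] > eps] <- 0
      }
      if (min(p_in) < p_enter) {
        k <- which.min(p_in)            # ties: first (panel order)
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "add",
                     term = colnames(X)[cand[k]], p = p_in[k])
        sel <- sort(c(sel, cand[k]))
        next
      }
    }
    break
  }
  list(selected = sort(sel),
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), action = character(),
                    term = character(), p = numeric()))
}

attr_type <- function(X) attr(X, "term_info")$type

# OLS on a fixed, already-selected term set (no stepwise re-selection);
# used when refitting a model variant with its terms held constant.
.refit_terms <- function(design, response, terms, population) {
  obs <- .as_screen_obs(design, response)
  Xall <- expand_second_order(design)
  info <- attr(Xall, "term_info")
  keep <- match(terms, colnames(Xall))
  X <- Xall[obs$row_id, keep, drop = FALSE]
  y <- obs$y
  fit <- .ols(X, y)
  tss <- sum((y - mean(y))^2)
  structure(
    list(coefficients = fit$coef, se = fit$se, t = fit$t, p = fit$p,
         r.squared = if (tss < 1e-12) 0 else max(0, 1 - fit$rss / tss),
         sigma2 = fit$s2, df.residual = fit$df,
         fitted.values = fit$fitted, residuals = fit$resid,
         term_info = info[keep, , drop = FALSE],
         trace = data.frame(), X = X, y = y,
         obs_rows = obs$row_id, obs_replicate = obs$replicate,
         design = design, population = population,
         control = list(stepwise = FALSE),
         call = match.call()),
    class = "tgmo_model")
}

#' @export
print.tgmo_model <- function(x, ...) {
  cat("Stepwise second-order viability model (", x$population, ")\n", sep = "")
  cat("  observations:", length(x$y), " selected terms:",
      length(x$coefficients) - 1L, " R-squared:",
      formatC(x$r.squared, digits = 3, format = "f"), "\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
summary.tgmo_model <- function(object, ...) {
  tab <- data.frame(
    term = names(object$coefficients),
    type = object$term_info$type,
    estimate = unname(object$coefficients),
    se = unname(object$se),
    t = unname(object$t),
    p = unname(object$p),
    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, r.squared = object$r.squared,
                 sigma = sqrt(object$sigma2), df.residual = object$df.residual,
                 n = length(object$y), population = object$population),
            class = "summary.tgmo_model")
}

#' @export
print.summary.tgmo_model <- function(x, ...) {
  cat("Stepwise second-order viability model (", x$population, ")\n", sep = "")
  cat("  n =", x$n, "  residual df =", x$df.residual,
      "  sigma =", formatC(x$sigma, digits = 3, format = "f"),
      "  R-squared =", formatC(x$r.squared, digits = 3, format = "f"), "\n\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tgmo_model <- function(object, ...) object$coefficients

#' @export
residuals.tgmo_model <- function(object, ...) object$residuals

#' @export
fitted.tgmo_model <- function(object, ...) object$fitted.values

#' Predict viability at coded dose levels
#'
#' Evaluates the selected second-order terms at the given dose codes.
#' Fractional codes inside \[-1, +1\] are allowed (response-surface plotting
#' and dose refinement use them).
#'
#' @param object a fitted \code{tgmo_model}.
#' @param newcodes a named numeric vector of codes, or a matrix/data.frame
#'   with one column per drug of the model's design.
#' @param ... unused.
#' @return numeric vector of predicted viability (% CTRL, or TW percentage
#'   points for a therapeutic-window model).
#' @export
predict.tgmo_model <- function(object, newcodes, ...) {
  drugs <- colnames(object$design$codes)
  if (is.null(dim(newcodes))) {
    if (is.null(names(newcodes))) {
      if (length(newcodes) != length(drugs))
        stop("unnamed code vector must cover all ", length(drugs), " drugs")
      names(newcodes) <- drugs
    }
    newcodes <- matrix(newcodes, nrow = 1,
                       dimnames = list(NULL, names(newcodes)))
  }
  newcodes <- as.matrix(newcodes)
  missing <- setdiff(drugs, colnames(newcodes))
  if (length(missing))
    stop("codes missing for drug(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(newcodes), drugs)
  if (length(extra))
    stop("unknown drug(s) in codes: ", paste(extra, collapse = ", "))
  codes <- newcodes[, drugs, drop = FALSE]
  ti <- object$term_info
  out <- numeric(nrow(codes))
  for (k in seq_len(nrow(ti))) {
    v <- switch(ti$type[k],
                intercept = rep(1, nrow(codes)),
                linear = codes[, ti$d1[k]],
                quadratic = codes[, ti$d1[k]]^2,
                interaction = codes[, ti$d1[k]] * codes[, ti$d2[k]])
    out <- out + object$coefficients[k] * v
  }
  unname(out)
}

#' Simulate responses from a fitted viability model
#'
#' Draws new observations at the model's own design points with Gaussian
#' noise at the fitted residual standard deviation.
#'
#' @param object a fitted \code{tgmo_model}.
#' @param nsim number of simulated response sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with \code{nsim} columns.
#' @export
simulate.tgmo_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(object$sigma2)
  n <- length(object$fitted.values)
  out <- as.data.frame(
    matrix(rep(object$fitted.values, nsim) + stats::rnorm(n * nsim, 0, sd),
           ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted viability model
#'
#' \code{type = "coefficients"} draws the coefficient bar chart (selected
#' terms, significance-starred); \code{"qq"} a normal Q-Q plot of residuals;
#' \code{"residuals"} residuals against fitted values.
#'
#' @param x a fitted \code{tgmo_model}.
#' @param type one of \code{"coefficients"}, \code{"qq"}, \code{"residuals"}.
#' @param alpha significance level for starring coefficients.
#' @param ... passed to the underlying graphics call.
#' @export
plot.tgmo_model <- function(x, type = c("coefficients", "qq", "residuals"),
                            alpha = 0.05, ...) {
  type <- match.arg(type)
  if (type == "coefficients") {
    keep <- x$term_info$type != "intercept"
    est <- x$coefficients[keep]
    stars <- ifelse(x$p[keep] < 0.001, "***",
             ifelse(x$p[keep] < 0.01, "**",
             ifelse(x$p[keep] < alpha, "*", "")))
    bp <- graphics::barplot(est, las = 2, col = ifelse(est < 0, "tomato", "grey70"),
                            ylab = "estimated regression coefficient", ...)
    graphics::text(bp, est, stars, pos = ifelse(est < 0, 1, 3), xpd = NA)
    graphics::abline(h = 0)
  } else if (type == "qq") {
    stats::qqnorm(x$residuals, ...); stats::qqline(x$residuals)
  } else {
    graphics::plot(x$fitted.values, x$residuals,
                   xlab = "fitted", ylab = "residual", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
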