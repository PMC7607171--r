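# Model validation: lack-of-fit ANOVA, Cook's distance, outlier-removed
# model variants, and numeric residual diagnostics. A trustworthy screen
# model has a non-significant lack of fit, high R^2, well-behaved
# residuals, and terms that survive outlier removal.

#' ANOVA lack-of-fit test
#'
#' Splits the residual sum of squares into pure error (replicate scatter
#' within design rows) and lack of fit (systematic departure of row means
#' from the fitted surface). A non-significant result supports the chosen
#' model order; significance suggests terms beyond second order are needed.
#'
#' @param model a fitted \code{tgmo_model} whose observations include at
#'   least one design row with two or more replicates.
#' @return a list with the two sums of squares and degrees of freedom, the
#'   F statistic and its p-value.
#' @export
lack_of_fit_test <- function(model) {
  stopifnot(inherits(model, "tgmo_model"))
  y <- model$y
  g <- model$obs_rows
  counts <- table(g)
  if (!any(counts >= 2L))
    stop("pure error not estimable: no design row has replicate observations")
  means <- tapply(y, g, mean)
  ss_pe <- sum((y - means[as.character(g)])^2)
  df_pe <- length(y) - length(counts)
  rss <- sum(model$residuals^2)
  p <- length(model$coefficients)
  ss_lof <- max(rss - ss_pe, 0)
  df_lof <- length(counts) - p
  if (df_lof <= 0)
    stop("no lack-of-fit degrees of freedom: the model has as many terms ",
         "as distinct design rows")
  if (df_pe <= 0) stop("pure error not estimable")
  ms_pe <- ss_pe / df_pe
  f <- if (ms_pe > 0) (ss_lof / df_lof) / ms_pe else 0
  list(ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe, df_pe = df_pe,
       statistic = f,
       p.value = stats::pf(f, df_lof, df_pe, lower.tail = FALSE))
}

#' Cook's distances of a fitted viability model
#'
#' Standard Cook's distance per observation: the squared standardized
#' residual scaled by leverage, measuring how much the fitted surface moves
#' when that observation is dropped. Large values flag influential outliers.
#'
#' @param model a fitted \code{tgmo_model} with positive residual degrees of
#'   freedom.
#' @param ... unused.
#' @return numeric vector, one distance per observation.
#' @export
cooks.distance.tgmo_model <- function(model, ...) {
  if (model$df.residual <= 0)
    stop("saturated model: Cook's distance undefined with zero residual df")
  # an exact fit has no residual variance and hence no influential points
  if (sum(model$residuals^2) <
      1e-16 * max(sum((model$y - mean(model$y))^2), 1))
    return(numeric(length(model$y)))
  qr_x <- qr(model$X)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  h <- rowSums(Q^2)
  p <- qr_x$rank
  s2 <- model$sigma2
  r <- model$residuals
  d <- r^2 * h / (p * s2 * (1 - h)^2)
  d[h >= 1 - 1e-12] <- Inf
  d
}

#' Outlier-handling model variants
#'
#' Refits the screen model under the three outlier treatments used to judge
#' robustness: the model on all data, the model with the single most
#' influential observation removed, and the model with every observation
#' whose Cook's distance exceeds \code{multiplier} times the mean distance
#' removed (threshold computed on the full fit; rows removed simultaneously).
#' Stepwise term selection is re-run for each variant by default.
#'
#' @param design an [assemble_oacd()] design.
#' @param response a response set accepted by [tgmo_fit()].
#' @param multiplier Cook's-distance threshold multiplier (default 3).
#' @param reselect re-run stepwise selection per variant (\code{TRUE}) or
#'   refit the full model's terms unchanged (\code{FALSE}).
#' @param ... passed to [tgmo_fit()].
#' @return an object of class \code{tgmo_variants} with elements
#'   \code{full}, \code{max_outlier_removed}, \code{high_cooks_removed}
#'   (each a \code{tgmo_model}, or \code{NULL} with a reason if removal
#'   leaves too few observations) and \code{removed} (observation indices
#'   per variant).
#' @export
build_model_variants <- function(design, response, multiplier = 3,
                                 reselect = TRUE, ...) {
  full <- tgmo_fit(design, response, ...)
  d <- cooks.distance(full)
  i_max <- which.max(d)
  high <- which(d > multiplier * mean(d))
  obs_df <- data.frame(row = full$obs_rows, viability = full$y,
                       replicate = full$obs_replicate)
  refit <- function(drop_idx) {
    kept <- if (length(drop_idx)) obs_df[-drop_idx, , drop = FALSE] else obs_df
    if (nrow(kept) <= length(full$coefficients) + 1L)
      return(structure(list(reason = "too few observations after removal"),
                       class = "tgmo_variant_unavailable"))
    if (reselect) {
      tgmo_fit(design, kept, population = full$population, ...)
    } else {
      .refit_terms(design, kept, names(full$coefficients),
                   full$population)
    }
  }
  structure(
    list(full = full,
         max_outlier_removed = refit(i_max),
         high_cooks_removed = if (length(high)) refit(high) else full,
         removed = list(max_outlier_removed = i_max,
                        high_cooks_removed = high),
         threshold = multiplier * mean(d),
         cooks = d),
    class = "tgmo_variants")
}

#' @export
print.tgmo_variants <- function(x, ...) {
  cat("Outlier-handling model variants\n")
  cat("  Cook's threshold:", signif(x$threshold, 4),
      "-> removes", length(x$removed$high_cooks_removed), "observation(s)\n")
  for (v in c("full", "max_outlier_removed", "high_cooks_removed")) {
    m <- x[[v]]
    if (inherits(m, "tgmo_variant_unavailable"))
      cat(sprintf("  %-22s unavailable (%s)\n", v, m$reason))
    else
      cat(sprintf("  %-22s %d terms, R2 = %.3f\n", v,
                  length(m$coefficients) - 1L, m$r.squared))
  }
  invisible(x)
}

#' Terms stable under outlier removal
#'
#' Returns the terms selected in every available variant whose coefficient
#' keeps its sign and stays significant (p below \code{alpha}) throughout.
#' These are the most reliable effects and the ones used to guide drug
#' selection and elimination.
#'
#' @param variants a [build_model_variants()] result.
#' @param alpha per-term significance level.
#' @return character vector of stable term names (possibly empty).
#' @export
robust_terms <- function(variants, alpha = 0.05) {
  stopifnot(inherits(variants, "tgmo_variants"))
  models <- Filter(function(m) inherits(m, "tgmo_model"),
                   variants[c("full", "max_outlier_removed",
                              "high_cooks_removed")])
  if (length(models) < 2L)
    stop("need at least two available variants")
  per <- lapply(models, function(m) {
    keep <- m$term_info$type != "intercept" & m$p < alpha
    data.frame(term = names(m$coefficients)[keep],
               sign = sign(m$coefficients[keep]), stringsAsFactors = FALSE)
  })
  common <- Reduce(intersect, lapply(per, `[[`, "term"))
  stable <- common[vapply(common, function(tm) {
    signs <- vapply(per, function(p) p$sign[match(tm, p$term)], numeric(1))
    length(unique(signs)) == 1L
  }, logical(1))]
  unname(stable)
}

#' Numeric model diagnostics report
#'
#' Collects the quantities behind the usual validation graphics without any
#' rendering: R-squared, a residual five-number summary, normal Q-Q
#' quantile pairs with their correlation, and residual histogram bins.
#'
#' @param model a fitted \code{tgmo_model}.
#' @param bins number of histogram bins.
#' @return a list with components \code{r.squared}, \code{residual_summary},
#'   \code{qq} (theoretical/sample quantile pairs), \code{qq_correlation}
#'   and \code{histogram}.
#' @export
diagnostics_report <- function(model, bins = 15L) {
  r <- model$residuals
  qq_s <- sort(r)
  n <- length(r)
  qq_t <- stats::qnorm(stats::ppoints(n))
  qq_cor <- if (stats::sd(qq_s) > 0) stats::cor(qq_t, qq_s) else NA_real_
  h <- graphics::hist(r, breaks = bins, plot = FALSE)
  list(r.squared = model$r.squared,
       residual_summary = summary(r),
       qq = data.frame(theoretical = qq_t, sample = qq_s),
       qq_correlation = qq_cor,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
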