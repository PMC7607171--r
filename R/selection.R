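# Interaction classification, round-by-round drug elimination, final ODC
# selection and Search-4 dose refinement.
#
# Sign conventions on the viability model: negative linear/interaction
# coefficients are efficacious/synergistic, positive are stimulatory/
# antagonistic; negative quadratic terms are dose-dependent, positive are
# stable over the dose range. On the therapeutic-window model the desirable
# sign is reversed (positive = selectivity-enhancing).

.call_label <- function(type, estimate, p, alpha) {
  if (is.na(p) || p >= alpha) return(NA_character_)
  switch(type,
         linear = if (estimate < 0) "efficacious" else "stimulatory",
         quadratic = if (estimate < 0) "dose_dependent" else "stable_over_range",
         interaction = if (estimate < 0) "synergistic" else "antagonistic",
         NA_character_)
}

#' Classify drug-drug interactions and single-drug effects
#'
#' Labels every selected non-intercept term of the viability model by its
#' sign and significance, attaches the matching therapeutic-window term
#' where a TW model is given, and flags the most desirable pattern:
#' efficacy coefficient below zero with TW coefficient above zero.
#'
#' @param model tumor-cell \code{tgmo_model}.
#' @param tw optional therapeutic-window \code{tgmo_model} on the same
#'   design.
#' @param alpha significance level for calls.
#' @return data.frame of class \code{interaction_calls}: term, type,
#'   estimate, p, label, tw_estimate, tw_p, tw_label, optimal.
#' @export
classify_interactions <- function(model, tw = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "tgmo_model"))
  if (!is.null(tw)) {
    stopifnot(inherits(tw, "tgmo_model"))
    if (!identical(colnames(tw$design$codes), colnames(model$design$codes)))
      stop("efficacy and TW models must share the design")
  }
  keep <- model$term_info$type != "intercept"
  out <- data.frame(
    term = names(model$coefficients)[keep],
    type = model$term_info$type[keep],
    estimate = unname(model$coefficients[keep]),
    p = unname(model$p[keep]),
    stringsAsFactors = FALSE)
  out$label <- if (nrow(out)) {
    as.character(mapply(.call_label, out$type, out$estimate, out$p,
                        MoreArgs = list(alpha = alpha)))
  } else character(0)
  out$tw_estimate <- rep(NA_real_, nrow(out))
  out$tw_p <- rep(NA_real_, nrow(out))
  out$tw_label <- rep(NA_character_, nrow(out))
  if (!is.null(tw) && nrow(out)) {
    idx <- match(out$term, names(tw$coefficients))
    hit <- !is.na(idx)
    out$tw_estimate[hit] <- tw$coefficients[idx[hit]]
    out$tw_p[hit] <- tw$p[idx[hit]]
    if (any(hit)) out$tw_label[hit] <- vapply(which(hit), function(k) {
      ty <- out$type[k]; est <- out$tw_estimate[k]; p <- out$tw_p[k]
      if (is.na(p) || p >= alpha) return(NA_character_)
      if (ty == "interaction")
        return(if (est > 0) "synergistic" else "antagonistic")
      if (est > 0) "efficacious" else "stimulatory"
    }, character(1))
  }
  out$optimal <- !is.na(out$label) & out$estimate < 0 &
    !is.na(out$tw_estimate) & out$tw_estimate > 0 &
    !is.na(out$tw_p) & out$tw_p < alpha
  class(out) <- c("interaction_calls", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Default drug-elimination scoring weights
#'
#' Codifies "keep the most active and synergistic drugs, eliminate the most
#' inactive and antagonistic": membership in a significant synergistic pair
#' scores +2 per pair, a significant inhibitory linear term +1, a
#' significant selectivity-enhancing TW term +1, membership in a significant
#' antagonistic pair -2 per pair, and a drug with no significant term at all
#' -1.
#'
#' @return named numeric vector of weights.
#' @export
elimination_weights <- function() {
  c(synergy = 2, efficacy = 1, tw_positive = 1, antagonism = -2, inert = -1)
}

#' Score drugs and eliminate the weakest for the next search round
#'
#' Ranks the panel by the documented elimination score and keeps the top
#' \code{target_size} drugs. Ties are broken by the most negative
#' significant linear estimate, then by panel order, so the reduction is
#' deterministic.
#'
#' @param calls a [classify_interactions()] table.
#' @param panel character vector of the current round's drugs (panel
#'   order).
#' @param target_size number of drugs to advance (>= 3; final combinations
#'   are 3-4 drugs).
#' @param weights scoring weights, see [elimination_weights()].
#' @return character vector of retained drugs, with the score table as
#'   attribute \code{"scores"}.
#' @export
eliminate_drugs <- function(calls, panel, target_size,
                            weights = elimination_weights()) {
  stopifnot(inherits(calls, "data.frame"), is.character(panel))
  if (target_size >= length(panel))
    stop("target_size must be smaller than the current panel")
  if (target_size < 3L)
    stop("target_size must be at least 3: final combinations are 3-4 drugs")
  score <- stats::setNames(rep(0, length(panel)), panel)
  lin_est <- stats::setNames(rep(0, length(panel)), panel)
  any_sig <- stats::setNames(rep(FALSE, length(panel)), panel)
  for (k in seq_len(nrow(calls))) {
    lab <- calls$label[k]
    if (is.na(lab)) next
    drugs_in <- strsplit(calls$term[k], "[:^]")[[1]]
    drugs_in <- intersect(drugs_in, panel)
    any_sig[drugs_in] <- TRUE
    if (lab == "synergistic")
      score[drugs_in] <- score[drugs_in] + weights[["synergy"]]
    if (lab == "antagonistic")
      score[drugs_in] <- score[drugs_in] + weights[["antagonism"]]
    if (calls$type[k] == "linear" && lab == "efficacious") {
      score[drugs_in] <- score[drugs_in] + weights[["efficacy"]]
      lin_est[drugs_in] <- calls$estimate[k]
    }
    tw_lab <- calls$tw_label[k]
    if (!is.na(tw_lab) && tw_lab %in% c("efficacious", "synergistic") &&
        calls$tw_estimate[k] > 0)
      score[drugs_in] <- score[drugs_in] + weights[["tw_positive"]]
  }
  score[!any_sig] <- score[!any_sig] + weights[["inert"]]
  ord <- order(-score, lin_est, match(panel, panel))
  kept <- panel[ord][seq_len(target_size)]
  kept <- kept[order(match(kept, panel))]      # report in panel order
  attr(kept, "scores") <- data.frame(drug = panel, score = unname(score),
                                     linear = unname(lin_est),
                                     stringsAsFactors = FALSE)
  kept
}

#' Select the optimized drug combination from the final search round
#'
#' Enumerates every 3- and 4-drug subset of the final-round panel at the
#' available dose codes (dose 1 or dose 2 per selected drug, absent drugs at
#' code -1) and picks the candidate minimizing predicted tumor viability;
#' within \code{tie_band} percentage points of that optimum, the candidate
#' with the largest predicted therapeutic window wins (efficacy first, TW as
#' tie-break).
#'
#' @param model final-round tumor \code{tgmo_model}.
#' @param tw matching therapeutic-window model (optional; without it the
#'   tie-break is skipped).
#' @param drugs candidate drugs (defaults to the model's panel; at most 8
#'   for exhaustive enumeration).
#' @param tie_band efficacy band (percentage points) within which TW decides.
#' @param min_inhibition minimum predicted inhibition (percentage points
#'   below the control prediction) for a result without a warning flag.
#' @return object of class \code{odc_result}: drugs, codes, predicted
#'   viability, predicted TW, warning flag.
#' @export
select_odc <- function(model, tw = NULL, drugs = NULL, tie_band = 5,
                       min_inhibition = 10) {
  stopifnot(inherits(model, "tgmo_model"))
  panel <- colnames(model$design$codes)
  if (is.null(drugs)) drugs <- panel
  stopifnot(all(drugs %in% panel), length(drugs) >= 3L, length(drugs) <= 8L)
  control_pred <- predict(model, stats::setNames(rep(-1, length(panel)), panel))
  cands <- list()
  for (size in intersect(3:4, seq_len(length(drugs)))) {
    subs <- utils::combn(drugs, size, simplify = FALSE)
    for (s in subs) {
      grid <- as.matrix(expand.grid(rep(list(c(0, 1)), size)))
      for (g in seq_len(nrow(grid))) {
        codes <- stats::setNames(rep(-1, length(panel)), panel)
        codes[s] <- grid[g, ]
        cands[[length(cands) + 1L]] <- codes
      }
    }
  }
  codes_mat <- do.call(rbind, cands)
  eff <- predict(model, codes_mat)
  tw_pred <- if (!is.null(tw)) predict(tw, codes_mat) else rep(0, length(eff))
  best_eff <- min(eff)
  in_band <- eff <= best_eff + tie_band
  pick <- which(in_band)[order(-tw_pred[in_band], eff[in_band])][1]
  codes <- codes_mat[pick, ]
  chosen <- panel[codes > -1]
  structure(
    list(drugs = chosen, codes = codes,
         predicted_viability = eff[pick],
         predicted_tw = if (!is.null(tw)) tw_pred[pick] else NA_real_,
         control_prediction = control_pred,
         warning = (control_pred - eff[pick]) < min_inhibition,
         tie_band = tie_band),
    class = "odc_result")
}

#' @export
print.odc_result <- function(x, ...) {
  cat("Optimized drug combination:", paste(x$drugs, collapse = " + "), "\n")
  cat("  dose codes:", paste(names(x$codes)[x$codes > -1],
                             round(x$codes[x$codes > -1], 2),
                             sep = "=", collapse = ", "), "\n")
  cat(sprintf("  predicted viability %.1f%% CTRL (control %.1f)",
              x$predicted_viability, x$control_prediction))
  if (!is.na(x$predicted_tw))
    cat(sprintf(", predicted TW %+.1f pp", x$predicted_tw))
  cat("\n")
  if (isTRUE(x$warning))
    cat("  WARNING: predicted inhibition below the requested minimum\n")
  invisible(x)
}

#' Refine the doses of a selected combination on the fitted surface
#'
#' Grid-searches fractional dose codes in \[-1, +1\] for each combination
#' drug (non-combination drugs stay absent), minimizing predicted tumor
#' viability with the same therapeutic-window tie-band as [select_odc()].
#' The fitted surface is quadratic, so a modest grid is exact enough.
#' Refined codes are translated to concentrations capped by the dose
#' table's PCL, and predictions at 75% and 50% of the refined doses report
#' whether dose reduction preserves activity (dose sparing).
#'
#' @param model tumor \code{tgmo_model} (fractional-code prediction).
#' @param odc an [select_odc()] result.
#' @param doses optional [dose_table()] to express refined codes as
#'   concentrations.
#' @param tw optional TW model for the tie-break.
#' @param n_grid grid points per drug (default 9).
#' @param tie_band efficacy band in percentage points.
#' @return the \code{odc_result} with refined codes, concentrations (if
#'   doses given) and a \code{dose_sparing} table.
#' @export
refine_doses <- function(model, odc, doses = NULL, tw = NULL, n_grid = 9L,
                         tie_band = 5) {
  stopifnot(inherits(model, "tgmo_model"), inherits(odc, "odc_result"))
  panel <- colnames(model$design$codes)
  k <- length(odc$drugs)
  if (n_grid < 2L) stop("grid must have at least 2 points per drug")
  if (n_grid^k > 5e5) stop("grid infeasible: reduce n_grid or drugs")
  levels_ <- seq(-1, 1, length.out = n_grid)
  grid <- as.matrix(expand.grid(rep(list(levels_), k)))
  codes_mat <- matrix(-1, nrow(grid), length(panel),
                      dimnames = list(NULL, panel))
  codes_mat[, odc$drugs] <- grid
  eff <- predict(model, codes_mat)
  tw_pred <- if (!is.null(tw)) predict(tw, codes_mat) else rep(0, length(eff))
  best_eff <- min(eff)
  in_band <- eff <= best_eff + tie_band
  pick <- which(in_band)[order(-tw_pred[in_band], eff[in_band])][1]
  refined <- codes_mat[pick, ]
  out <- odc
  out$codes <- refined
  out$predicted_viability <- eff[pick]
  out$predicted_tw <- if (!is.null(tw)) tw_pred[pick] else NA_real_
  # dose sparing: scale the refined concentrations by 75% / 50%
  sparing <- lapply(c(1, 0.75, 0.5), function(fr) {
    codes <- refined
    conc_frac <- (refined[odc$drugs] + 1) / 2 * fr   # concentration-scale fraction
    codes[odc$drugs] <- conc_frac * 2 - 1
    data.frame(fraction = fr,
               predicted_viability = predict(model, codes))
  })
  out$dose_sparing <- do.call(rbind, sparing)
  if (!is.null(doses)) {
    stopifnot(inherits(doses, "dose_table"))
    idx <- match(odc$drugs, doses$drug)
    if (anyNA(idx))
      stop("dose table missing drug(s): ",
           paste(odc$drugs[is.na(idx)], collapse = ", "))
    conc <- codes_to_conc_matrix(matrix(refined[odc$drugs], nrow = 1),
                                 doses$dose1[idx], doses$dose2[idx])[1, ]
    over <- !is.na(doses$pcl[idx]) & conc > doses$pcl[idx] * (1 + 1e-9)
    if (any(over)) stop("refined dose exceeds PCL for: ",
                        paste(odc$drugs[over], collapse = ", "))
    out$concentrations <- stats::setNames(conc, odc$drugs)
    out$unit <- doses$unit[idx][1]
  }
  out
}
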