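# Therapeutic-window and combined (pooled-replicate) fits.

# per-design-row replicate means for any accepted response form
.row_means <- function(design, response) {
  obs <- .as_screen_obs(design, response)
  as.numeric(tapply(obs$y, factor(obs$row_id, levels = seq_len(nrow(design$codes))),
                    mean))
}

#' Fit the therapeutic-window model
#'
#' The therapeutic window (TW) is the per-combination difference between
#' nonmalignant and tumor cell viability; it is modelled with the same
#' stepwise second-order regression as the viability responses. With this
#' sign convention a positive TW coefficient is selectivity-enhancing, so
#' the most desirable pattern is an efficacy coefficient below zero paired
#' with a TW coefficient above zero.
#'
#' Replicates are averaged per design row in each population before the
#' difference is taken.
#'
#' @param design an [assemble_oacd()] design.
#' @param tumor_response,normal_response responses in any form accepted by
#'   [tgmo_fit()], covering the same design rows.
#' @param ... passed to [tgmo_fit()].
#' @return a \code{tgmo_model} with \code{population = "tw"}.
#' @export
fit_therapeutic_window <- function(design, tumor_response, normal_response,
                                   ...) {
  tum <- .row_means(design, tumor_response)
  nor <- .row_means(design, normal_response)
  if (anyNA(tum) || anyNA(nor))
    stop("tumor and nonmalignant responses must cover every design row")
  tgmo_fit(design, nor - tum, population = "tw", ...)
}

#' Fit replicate datasets separately and combined
#'
#' Fits the stepwise model to each replicate dataset and to all datasets
#' pooled (the combined model, the one reported graphically). Terms that
#' recur across the per-dataset fits and the combined fit are the most
#' reliable.
#'
#' @param design an [assemble_oacd()] design.
#' @param responses a list of two or more response sets on the same design.
#' @param ... passed to [tgmo_fit()].
#' @return an object of class \code{tgmo_combined}: \code{$combined} is the
#'   pooled \code{tgmo_model}, \code{$per_dataset} the individual fits.
#' @export
fit_combined <- function(design, responses, ...) {
  if (!is.list(responses) || length(responses) < 2L)
    stop("fit_combined needs a list of at least two replicate datasets")
  obs <- lapply(responses, .as_screen_obs, design = design)
  pooled <- data.frame(
    row = unlist(lapply(obs, `[[`, "row_id")),
    viability = unlist(lapply(obs, `[[`, "y")))
  per <- lapply(responses, function(r) tgmo_fit(design, r, ...))
  structure(
    list(combined = tgmo_fit(design, pooled, ...),
         per_dataset = per),
    class = "tgmo_combined")
}

#' @export
print.tgmo_combined <- function(x, ...) {
  cat("Combined model over", length(x$per_dataset), "datasets\n")
  print(x$combined)
  invisible(x)
}
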