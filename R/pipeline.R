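# End-to-end search driver: design -> screen -> fit (tumor, TW) ->
# classify -> eliminate, repeated over shrinking panels, then ODC
# selection and dose refinement.

#' Run the full multidrug optimization search on a simulated truth
#'
#' Executes consecutive search rounds against a known ground-truth surface:
#' each round assembles the composite design for the current panel,
#' simulates the tumor and nonmalignant screens, fits the stepwise models
#' and the therapeutic window, classifies interactions, and eliminates
#' drugs down to the next round's size. After the final round the optimized
#' drug combination is selected and its doses refined on the fitted
#' surface.
#'
#' The run is a pure function of \code{(truths, rounds, seed)}.
#'
#' @param truth_tumor,truth_normal [make_truth()] surfaces over the same
#'   panel.
#' @param rounds panel sizes of the successive elimination targets
#'   (default \code{c(7, 4)}: an 11-drug Search 1 feeding a 7-drug Search 2
#'   and a 4-drug Search 3).
#' @param seed integer seed for all simulated screens.
#' @param alpha significance level used for calls and elimination.
#' @param refine grid-refine the final doses (default \code{TRUE}).
#' @param ... passed to [tgmo_fit()].
#' @return object of class \code{tgmo_run}: per-round records (panel,
#'   models, calls, retained drugs) plus the final \code{odc}.
#' @export
tgmo_run <- function(truth_tumor, truth_normal, rounds = c(7, 4),
                     seed = 1L, alpha = 0.05, refine = TRUE, ...) {
  stopifnot(inherits(truth_tumor, "tgmo_truth"),
            inherits(truth_normal, "tgmo_truth"),
            identical(truth_tumor$drugs, truth_normal$drugs))
  if (any(diff(c(length(truth_tumor$drugs), rounds)) >= 0))
    stop("round sizes must strictly decrease from the panel size")
  set.seed(as.integer(seed))
  panel <- truth_tumor$drugs
  record <- list()
  for (r in seq_len(length(rounds) + 1L)) {
    tt <- truth_subset(truth_tumor, panel)
    tn <- truth_subset(truth_normal, panel)
    design <- assemble_oacd(length(panel), factor_names = panel)
    resp_t <- simulate_screen(tt, design, population = "tumor")
    resp_n <- simulate_screen(tn, design, population = "nonmalignant")
    fit_t <- tgmo_fit(design, resp_t, population = "tumor", ...)
    fit_tw <- fit_therapeutic_window(design, resp_t, resp_n, ...)
    calls <- classify_interactions(fit_t, fit_tw, alpha = alpha)
    kept <- if (r <= length(rounds))
      eliminate_drugs(calls, panel, rounds[r]) else panel
    record[[r]] <- list(search = r, panel = panel, design = design,
                        tumor = fit_t, tw = fit_tw, calls = calls,
                        retained = kept)
    panel <- kept
  }
  last <- record[[length(record)]]
  odc <- select_odc(last$tumor, last$tw)
  if (refine) odc <- refine_doses(last$tumor, odc, tw = last$tw)
  structure(list(rounds = record, odc = odc, seed = seed, alpha = alpha),
            class = "tgmo_run")
}

#' @export
print.tgmo_run <- function(x, ...) {
  cat("Multidrug optimization run (seed", x$seed, ")\n")
  for (r in x$rounds) {
    cat(sprintf("  Search %d: %d drugs -> kept %s\n", r$search,
                length(r$panel), paste(r$retained, collapse = ", ")))
  }
  print(x$odc)
  invisible(x)
}
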