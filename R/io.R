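# File formats: coded-design and response CSVs, dose tables, panel
# configuration (YAML) and JSON model reports. CSVs are UTF-8,
# comma-separated with a mandatory header; concentrations always carry an
# explicit unit column because published dose tables mix units.

#' Write / read a coded design as CSV
#'
#' The CSV holds one combination per row: a \code{part} column tagging the
#' design part, then one integer code column per drug.
#'
#' @param design an \code{oacd_design}.
#' @param file path.
#' @return \code{read_design} returns an \code{oacd_design} (generator
#'   metadata is not round-tripped; resolution queries need the in-memory
#'   object).
#' @export
write_design <- function(design, file) {
  stopifnot(inherits(design, "oacd_design"))
  df <- data.frame(part = design$part, design$codes, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_design
#' @export
read_design <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"part" %in% names(df)) stop("design CSV must have a 'part' column")
  codes <- as.matrix(df[setdiff(names(df), "part")])
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("design codes must be -1, 0 or +1")
  structure(list(codes = codes, part = df$part, generators = NULL,
                 n_base = NA_integer_, n_factors = ncol(codes)),
            class = "oacd_design")
}

#' Write / read screen responses as CSV
#'
#' Long format: \code{row}, \code{replicate}, \code{population},
#' \code{viability} (% CTRL).
#'
#' @param responses a long response data.frame ([simulate_screen()] output
#'   or equivalent).
#' @param file path.
#' @export
write_responses <- function(responses, file) {
  need <- c("row", "replicate", "population", "viability")
  stopifnot(all(need %in% names(responses)))
  utils::write.csv(responses[need], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_responses
#' @export
read_responses <- function(file) {
  df <- utils::read.csv(file)
  need <- c("row", "viability")
  if (!all(need %in% names(df)))
    stop("response CSV needs at least columns 'row' and 'viability'")
  df
}

#' Write / read a dose table as CSV
#'
#' Columns: drug, dose1, dose2, pcl, unit.
#'
#' @param doses a [dose_table()].
#' @param file path.
#' @export
write_dose_table <- function(doses, file) {
  stopifnot(inherits(doses, "dose_table"))
  utils::write.csv(as.data.frame(doses), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dose_table
#' @export
read_dose_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  dose_table(df$drug, df$dose1, df$dose2,
             pcl = if ("pcl" %in% names(df)) df$pcl else NA_real_,
             unit = if ("unit" %in% names(df)) df$unit else "uM")
}

#' Read a drug-panel configuration
#'
#' YAML with a \code{drugs} list (name, mw, auc_0_24, optional
#' override_dose1/override_dose2) and optional \code{thresholds} and
#' \code{rounds} entries. Screening doses are derived per drug: dose 2 is
#' the ED20 (when supplied) capped at the PCL computed from the clinical
#' AUC, dose 1 is half of it; explicit overrides win.
#'
#' @param file YAML path.
#' @return list with \code{panel} (data.frame), \code{thresholds},
#'   \code{rounds}.
#' @export
read_panel_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$drugs)) stop("panel config needs a 'drugs' list")
  panel <- do.call(rbind, lapply(cfg$drugs, function(d) {
    data.frame(drug = d$name,
               mw = d$mw %||% NA_real_,
               auc_0_24 = d$auc_0_24 %||% NA_real_,
               ed20 = d$ed20 %||% NA_real_,
               override_dose1 = d$override_dose1 %||% NA_real_,
               override_dose2 = d$override_dose2 %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(panel$drug)) stop("drug names must be unique")
  list(panel = panel,
       thresholds = cfg$thresholds %||% list(),
       rounds = cfg$rounds %||% c(7, 4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive the screening dose table from a panel configuration
#'
#' Applies the PCL cap per drug: dose 2 is \code{min(ED20, PCL)} where the
#' PCL comes from the clinical AUC (molar when a molecular weight is
#' given), dose 1 is half of dose 2; explicit overrides take precedence.
#'
#' @param config a [read_panel_config()] result.
#' @param unit unit label recorded in the dose table.
#' @return a [dose_table()].
#' @export
panel_dose_table <- function(config, unit = "M") {
  p <- config$panel
  d2 <- numeric(nrow(p)); pcl <- rep(NA_real_, nrow(p))
  for (k in seq_len(nrow(p))) {
    pcl_k <- if (!is.na(p$auc_0_24[k])) {
      plasma_concentration_limit(p$auc_0_24[k],
        if (!is.na(p$mw[k])) p$mw[k] else NULL)
    } else NA_real_
    pcl[k] <- pcl_k
    d2[k] <- if (!is.na(p$override_dose2[k])) p$override_dose2[k]
             else select_screen_doses(p$ed20[k], pcl_k)[["dose2"]]
  }
  d1 <- ifelse(!is.na(p$override_dose1), p$override_dose1, d2 / 2)
  dose_table(p$drug, d1, d2, pcl = pcl, unit = unit)
}

#' Write a fitted model report as JSON
#'
#' Versioned JSON with selected terms, coefficients, standard errors,
#' p-values, R-squared and the stepwise selection trace.
#'
#' @param model a \code{tgmo_model}.
#' @param file path.
#' @export
write_model_report <- function(model, file) {
  stopifnot(inherits(model, "tgmo_model"))
  rep_ <- list(
    schema = "tgmo_model_report/1",
    population = model$population,
    n = length(model$y),
    r_squared = model$r.squared,
    terms = data.frame(term = names(model$coefficients),
                       type = model$term_info$type,
                       estimate = unname(model$coefficients),
                       se = unname(model$se),
                       p = unname(model$p)),
    trace = model$trace)
  jsonlite::write_json(rep_, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
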