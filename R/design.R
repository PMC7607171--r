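# Orthogonal-array composite designs (OACD) for multidrug screens:
# a regular two-level fractional factorial (linear + interaction effects)
# joined to the 27-run three-level orthogonal array OA(27, 3^13)
# (quadratic effects). Dose-level codes: -1 = no drug, 0 = dose 1, +1 = dose 2.

# Default factor labels follow design-of-experiments convention (I is
# reserved for the identity and skipped).
factor_letters <- function(n) setdiff(LETTERS, "I")[seq_len(n)]

# Regular fractions with resolution >= IV, one per supported factor count.
# Each generator is a word over the base factors (the first k labels).
# Entries chosen from standard minimum-aberration tables; n = 11 gives the
# 2^(11-4) used for an 11-drug Search-1 screen (128 runs).
.ff_generator_table <- list(
  `2`  = character(0),                                  # full 2^2
  `3`  = character(0),                                  # full 2^3 (no res-IV half fraction exists)
  `4`  = c(D = "ABC"),                                  # 2^(4-1)_IV
  `5`  = c(E = "ABCD"),                                 # 2^(5-1)_V
  `6`  = c(E = "ABC", F = "BCD"),                       # 2^(6-2)_IV
  `7`  = c(F = "ABCD", G = "ABDE"),                     # 2^(7-2)_IV
  `8`  = c(F = "ABC", G = "ABD", H = "BCDE"),           # 2^(8-3)_IV
  `9`  = c(F = "BCDE", G = "ACDE", H = "ABDE", J = "ABCE"),            # 2^(9-4)_IV
  `10` = c(F = "ABCD", G = "ABCE", H = "ABDE", J = "ACDE", K = "BCDE"),# 2^(10-5)_IV
  `11` = c(H = "ABCD", J = "ABEF", K = "ACEG", L = "BDFG")             # 2^(11-4)_V
)

#' Construct a regular two-level fractional factorial design
#'
#' Builds the two-level part of an orthogonal-array composite design: a
#' regular \eqn{2^{k-p}} fraction with resolution at least IV, so that drug
#' main effects are not aliased with two-drug interactions. Codes are
#' \code{-1} (no drug) and \code{+1} (dose 2).
#'
#' @param n_factors number of drugs (2 to 11).
#' @param generators \code{"auto"} to use the generator words fixed in the
#'   package (minimum-aberration, resolution >= IV), or a character vector of
#'   defining words such as \code{c("D=ABC")} whose right-hand sides reference
#'   base factors only.
#' @param factor_names optional drug names for the columns; defaults to
#'   design-convention letters (I skipped).
#' @return an object of class \code{oacd_design} whose \code{codes} matrix
#'   holds one screened combination per row.
#' @seealso [assemble_oacd()], [resolution()]
#' @examples
#' d <- build_two_level_ff(4)     # 2^(4-1), I = ABCD
#' resolution(d)                  # 4
#' @export
build_two_level_ff <- function(n_factors, generators = "auto",
                               factor_names = NULL) {
  stopifnot(is.numeric(n_factors), length(n_factors) == 1L)
  n_factors <- as.integer(n_factors)
  if (n_factors < 2L || n_factors > 11L)
    stop("n_factors must be between 2 and 11; no resolution-IV regular ",
         "fraction is tabulated outside this range")
  labels <- factor_letters(n_factors)

  if (identical(generators, "auto")) {
    gen <- .ff_generator_table[[as.character(n_factors)]]
  } else {
    gen <- .parse_generators(generators, n_factors)
  }
  p <- length(gen)
  k <- n_factors - p
  if (k < 1L) stop("more generators than factors")

  # base full factorial 2^k, standard (Yates) order
  base <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))[, k:1, drop = FALSE]
  storage.mode(base) <- "integer"
  codes <- matrix(0L, nrow(base), n_factors)
  codes[, seq_len(k)] <- base
  if (p > 0L) {
    masks <- .generator_masks(gen, k, labels)
    for (j in seq_len(p)) {
      cols <- which(as.logical(masks[[j]]))
      codes[, k + j] <- as.integer(apply(base[, cols, drop = FALSE], 1L, prod))
    }
    res <- .resolution_from_masks(masks)
    if (res < 4L)
      stop("requested fraction has resolution ", res,
           " (< IV): main effects would be aliased with two-factor ",
           "interactions; no resolution-IV regular design exists for this ",
           "generator set")
  }
  if (!is.null(factor_names)) {
    stopifnot(length(factor_names) == n_factors)
    labels <- factor_names
  }
  colnames(codes) <- labels
  structure(
    list(codes = codes,
         part = rep("two_level_ff", nrow(codes)),
         generators = gen,
         n_base = k,
         n_factors = n_factors),
    class = "oacd_design")
}

# parse "D=ABC"-style words into logical masks over the k base factors
.parse_generators <- function(generators, n_factors) {
  words <- character(0)
  for (g in generators) {
    parts <- strsplit(gsub("\\s", "", g), "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("generator must look like 'D=ABC': ", g)
    words[parts[1]] <- parts[2]
  }
  words
}

.generator_masks <- function(gen, k, labels) {
  base_labels <- labels[seq_len(k)]
  lapply(gen, function(w) {
    letters_in <- strsplit(w, "")[[1]]
    bad <- setdiff(letters_in, base_labels)
    if (length(bad))
      stop("generator word '", w, "' references non-base factors: ",
           paste(bad, collapse = ", "))
    tabulate(match(letters_in, base_labels), nbins = k) %% 2L
  })
}

# shortest word in the defining relation: for every nonempty subset S of
# generators, word length = |S| + popcount(xor of base masks)
.resolution_from_masks <- function(masks) {
  p <- length(masks)
  if (p == 0L) return(Inf)
  shortest <- Inf
  for (s in seq_len(2L^p - 1L)) {
    members <- which(bitwAnd(s, 2L^(seq_len(p) - 1L)) > 0L)
    x <- Reduce(function(a, b) (a + b) %% 2L, masks[members])
    shortest <- min(shortest, length(members) + sum(x))
  }
  shortest
}

#' Resolution of the two-level part of a design
#'
#' The length of the shortest word in the defining relation of the regular
#' fraction. Resolution IV means main effects are clear of two-factor
#' interactions. A full factorial has no defining words and is reported as
#' \code{Inf}.
#'
#' @param design an \code{oacd_design} with a regular two-level part.
#' @return integer word length, or \code{Inf} for a full factorial.
#' @export
resolution <- function(design) {
  stopifnot(inherits(design, "oacd_design"))
  if (is.null(design$generators) && !any(design$part == "two_level_ff"))
    stop("design has no two-level fractional-factorial part")
  if (length(design$generators) == 0L) return(Inf)
  labels <- factor_letters(design$n_base)
  masks <- .generator_masks(design$generators, design$n_base, labels)
  .resolution_from_masks(masks)
}

#' Construct the 27-run three-level orthogonal array
#'
#' Returns OA(27, 3^13) of strength 2, restricted to the first
#' \code{n_factors} columns and recoded to dose-level codes
#' \{-1, 0, +1\} = \{no drug, dose 1, dose 2\}. This part of the composite
#' design makes quadratic (dose-range) effects estimable.
#'
#' The array is built over GF(3): runs are the 27 points of
#' \eqn{GF(3)^3} and each column is the inner product with one of the 13
#' projective direction vectors, which guarantees that every ordered pair of
#' levels appears equally often in any two columns.
#'
#' @param n_factors number of drugs (2 to 13).
#' @inheritParams build_two_level_ff
#' @return an \code{oacd_design} with 27 rows.
#' @export
build_three_level_oa <- function(n_factors, factor_names = NULL) {
  n_factors <- as.integer(n_factors)
  if (n_factors < 2L || n_factors > 13L)
    stop("OA(27, 3^13) supports at most 13 factors (got ", n_factors, ")")
  # 13 projective points of GF(3)^3, first nonzero coordinate = 1
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, 2, 0), c(1, 0, 1), c(1, 0, 2),
    c(0, 1, 1), c(0, 1, 2),
    c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2))
  runs <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  lev <- (runs %*% t(dirs[seq_len(n_factors), , drop = FALSE])) %% 3
  codes <- matrix(as.integer(lev - 1L), nrow = 27L)
  labels <- if (is.null(factor_names)) factor_letters(n_factors) else factor_names
  stopifnot(length(labels) == n_factors)
  colnames(codes) <- labels
  structure(
    list(codes = codes,
         part = rep("three_level_oa", 27L),
         generators = NULL,
         n_base = NA_integer_,
         n_factors = n_factors),
    class = "oacd_design")
}

#' Assemble the orthogonal-array composite design for one search round
#'
#' Concatenates the resolution-IV two-level fractional factorial and the
#' 27-run three-level orthogonal array. For 11 drugs this yields the
#' 128 + 27 = 155 screened combinations of a Search-1 round. A vehicle-only
#' control row (all codes -1) is guaranteed to be present; the orthogonal
#' array always contains it, so no row is appended in practice.
#'
#' @inheritParams build_two_level_ff
#' @return an \code{oacd_design}; \code{$part} tags each row as
#'   \code{"two_level_ff"} or \code{"three_level_oa"}.
#' @examples
#' nrow(assemble_oacd(11)$codes)  # 155
#' @export
assemble_oacd <- function(n_factors, generators = "auto", factor_names = NULL) {
  ff <- build_two_level_ff(n_factors, generators, factor_names)
  oa <- build_three_level_oa(n_factors, factor_names)
  codes <- rbind(ff$codes, oa$codes)
  part <- c(ff$part, oa$part)
  if (!any(rowSums(codes == -1L) == ncol(codes))) {   # ensure control row
    codes <- rbind(codes, rep(-1L, ncol(codes)))
    part <- c(part, "control")
  }
  rownames(codes) <- NULL
  structure(
    list(codes = codes, part = part,
         generators = ff$generators, n_base = ff$n_base,
         n_factors = ff$n_factors),
    class = "oacd_design")
}

#' @export
print.oacd_design <- function(x, ...) {
  cat("Orthogonal-array composite design:", x$n_factors, "drugs,",
      nrow(x$codes), "combinations\n")
  tab <- table(x$part)
  cat(paste0("  ", names(tab), ": ", tab, " rows", collapse = "\n"), "\n")
  if (length(x$generators))
    cat("  generators:",
        paste(names(x$generators), x$generators, sep = "="), "\n")
  invisible(x)
}

#' Screening dose table
#'
#' Per-drug screening concentrations: \code{dose1} (low, ED10-like) and
#' \code{dose2} (high, ED20-like), optionally with the plasma concentration
#' limit (PCL) each dose must respect.
#'
#' @param drug character drug names (unique).
#' @param dose1,dose2 concentrations, \code{0 < dose1 < dose2}.
#' @param pcl optional plasma concentration limit; where given,
#'   \code{dose2 <= pcl} is enforced.
#' @param unit concentration unit label, recorded with the table.
#' @return a \code{data.frame} of class \code{dose_table}.
#' @export
dose_table <- function(drug, dose1, dose2, pcl = NA_real_, unit = "uM") {
  stopifnot(is.character(drug), !anyDuplicated(drug),
            length(dose1) == length(drug), length(dose2) == length(drug))
  pcl <- rep_len(pcl, length(drug))
  if (any(!(dose1 > 0 & dose2 > dose1)))
    stop("doses must satisfy 0 < dose1 < dose2 for every drug")
  over <- !is.na(pcl) & dose2 > pcl * (1 + 1e-12)
  if (any(over))
    stop("dose2 exceeds the plasma concentration limit for: ",
         paste(drug[over], collapse = ", "))
  structure(
    data.frame(drug = drug, dose1 = dose1, dose2 = dose2, pcl = pcl,
               unit = unit, stringsAsFactors = FALSE),
    class = c("dose_table", "data.frame"))
}

#' Translate dose-level codes to plate concentrations
#'
#' Maps each code to a concentration: -1 (no drug) to 0, 0 to \code{dose1},
#' +1 to \code{dose2}. Fractional codes (used when refining doses on the
#' fitted surface) interpolate linearly between the bracketing levels.
#'
#' @param design an \code{oacd_design}.
#' @param doses a [dose_table()] covering every design column.
#' @return numeric matrix of concentrations, same shape and row order as the
#'   design codes; the unit is attached as attribute \code{"unit"}.
#' @export
code_to_concentration <- function(design, doses) {
  stopifnot(inherits(design, "oacd_design"), inherits(doses, "dose_table"))
  drugs <- colnames(design$codes)
  missing <- setdiff(drugs, doses$drug)
  if (length(missing))
    stop("no dose entry for drug(s): ", paste(missing, collapse = ", "))
  idx <- match(drugs, doses$drug)
  conc <- codes_to_conc_matrix(design$codes, doses$dose1[idx], doses$dose2[idx])
  colnames(conc) <- drugs
  attr(conc, "unit") <- doses$unit[idx][1]
  conc
}

# piecewise-linear code -> concentration map, vectorized over a code matrix
codes_to_conc_matrix <- function(codes, dose1, dose2) {
  n <- ncol(codes)
  conc <- matrix(0, nrow(codes), n)
  for (j in seq_len(n)) {
    x <- codes[, j]
    conc[, j] <- ifelse(x <= 0, (x + 1) * dose1[j],
                        dose1[j] + x * (dose2[j] - dose1[j]))
  }
  conc
}
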