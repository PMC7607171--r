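# shared fixtures and independent oracles

# alias check by exhaustive enumeration: TRUE if no product of `upto` or
# fewer columns is constant (+/-1) over the rows, i.e. resolution > upto
no_alias_up_to <- function(codes, upto) {
  n <- ncol(codes)
  for (k in seq_len(upto)) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      prods <- apply(codes[, s, drop = FALSE], 1, prod)
      if (abs(sum(prods)) == nrow(codes)) return(FALSE)
    }
  }
  TRUE
}

# strength-2 orthogonal-array check: every ordered level pair equally often
oa_strength2_ok <- function(codes) {
  n <- ncol(codes)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    tab <- table(codes[, a], codes[, b])
    if (!all(dim(tab) == c(3, 3)) || length(unique(as.vector(tab))) != 1L)
      return(FALSE)
  }
  TRUE
}

# independent OLS oracle on a named term set (lm on explicit columns)
ols_oracle <- function(design, y, terms) {
  X <- expand_second_order(design)
  fit <- stats::lm.fit(X[, terms, drop = FALSE], y)
  fit$coefficients
}

# leave-one-out Cook's distance oracle
cooks_loo_oracle <- function(model) {
  X <- model$X; y <- model$y
  p <- ncol(X); s2 <- model$sigma2
  yh <- as.numeric(X %*% model$coefficients)
  vapply(seq_along(y), function(i) {
    fi <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    sum((yh - as.numeric(X %*% fi$coefficients))^2) / (p * s2)
  }, numeric(1))
}

small_panel <- function(n) tgmo:::factor_letters(n)
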