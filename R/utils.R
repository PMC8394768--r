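# internal helpers shared across modules

# Set the RNG locally when a seed is given; leaves the caller's RNG state
# untouched either way (no seed -> use and advance the global stream).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict) "(" else "[", lower, upper, if (strict) ")" else "]", x
    ))
  }
  invisible(x)
}

# modal value of a numeric vector after rounding to a fixed precision;
# used to infer the frame interval from consecutive time differences
modal_value <- function(x, digits = 9) {
  r <- round(x, digits)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

# least-squares line through (log10 x, log10 y); returns c(slope, intercept, r2)
loglog_ls <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  lx <- log10(x[keep])
  ly <- log10(y[keep])
  if (length(lx) < 2) abort("need at least 2 positive points for a log-log fit")
  fit <- lm(ly ~ lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), r2 = r2)
}
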