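# Internal helpers shared across modules.

# z-score a numeric vector; errors on zero variance unless `allow_constant`.
zscore <- function(x, allow_constant = FALSE) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop("cannot standardize a constant variable", call. = FALSE)
  }
  (x - m) / s
}

# Coerce a factor-of-interest column to numeric: numerics pass through,
# logicals become 0/1, two-level character/factor becomes 0/1 by sorted level.
coerce_factor_numeric <- function(x, name = "factor") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) > 2) {
      stop(sprintf("column '%s' has %d levels; only binary categorical factors are supported",
                   name, length(lev)), call. = FALSE)
    }
    return(as.numeric(match(x, lev) - 1))
  }
  stop(sprintf("column '%s' has unsupported type '%s'", name, class(x)[1]), call. = FALSE)
}

# Simple OLS slope/intercept by closed form; used where a full lm() is overkill.
ols_line <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) stop("predictor has zero variance", call. = FALSE)
  slope <- stats::cov(x, y) / vx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
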