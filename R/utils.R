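# Internal helpers: condition classes, RNG scoping, small numerics.

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("oxikin_domain_error", "oxikin_error")))
}

stop_analysis <- function(msg) {
  stop(errorCondition(msg, class = c("oxikin_analysis_error", "oxikin_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("oxikin_format_error",
                                     "oxikin_domain_error", "oxikin_error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(sprintf("'%s' must be a single strictly positive number", name))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_domain(sprintf("'%s' must be a single non-negative number", name))
  invisible(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centred moving average; shrinks the window at the edges.
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Least-squares slope/intercept/r2 of y on x without lm() overhead.
ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop_analysis("degenerate regression window (zero time spread)")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ssr <- sum((y - (intercept + slope * x))^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Kinetic-chain-length display convention: integers at/above 10, one decimal
# below (Table-style reporting).
format_nu <- function(nu) {
  if (is.null(nu) || !is.finite(nu)) return(NA_character_)
  if (nu >= 10) sprintf("%d", round(nu)) else sprintf("%.1f", nu)
}

fmt_rate_nM <- function(rate) {
  if (is.null(rate) || !is.finite(rate)) return(NA_character_)
  formatC(signif(rate * 1e9, 3), format = "fg", flag = "#")
}
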