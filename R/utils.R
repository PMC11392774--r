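# Internal helpers shared across the package.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded generators do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' OLS slope and R^2 of y against x
#' @noRd
ols_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(slope = unname(fit$coefficients[2L]), intercept = unname(fit$coefficients[1L]), r2 = r2)
}

#' Sample standard deviation (n - 1 denominator), vector-safe
#' @noRd
sample_sd <- function(x) stats::sd(x)

# Relative guard used when assigning event times to counting windows: protects
# exact-multiple window boundaries against floating-point round-off without
# moving any event by a physically meaningful amount (< 1 ns at 1 s scale).
.boundary_guard <- 1e-9
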