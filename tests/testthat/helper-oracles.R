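# Independent oracles and tiny fixtures used across the suite.

# Brute-force per-dimension comparator: number of shared feature values.
oracle_shared_count <- function(a, b) sum(unlist(a) == unlist(b))

# Exhaustive sliding-window scan for the learning criterion.
oracle_trials_to_criterion <- function(outcomes, window = 10, threshold = 0.7) {
  x <- as.numeric(outcomes)
  if (length(x) < window) return(NA_integer_)
  for (t in window:length(x)) {
    if (mean(x[(t - window + 1):t]) >= threshold) return(as.integer(t))
  }
  NA_integer_
}

oracle_plateau <- function(outcomes, crit) {
  rest <- as.numeric(outcomes)[-seq_len(crit)]
  if (length(rest) == 0) return(NA_real_)
  sum(rest) / length(rest)
}

# Normal-equations OLS solver, independent of stats::lm.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(s2 * solve(t(X) %*% X))))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       intercept_se = se[1], slope_se = se[2],
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# A 2x2x2 toy space for fast property tests.
toy_space <- function() {
  feature_space(list(
    shape = list(values = c("sph", "cub"), neutral = "sph"),
    color = list(values = c("gray", "red", "blue"), neutral = "gray"),
    arms  = list(values = c("blunt", "spike"), neutral = "blunt")
  ))
}

# Agent that errors on trial `fail_at` — used for crash-safety tests.
crashing_agent <- function(fail_at, rt_s = 1) {
  structure(list(fail_at = fail_at, rt_s = rt_s, n = 0L),
            class = c("crashing_agent"))
}
respond.crashing_agent <- function(agent, spec) {
  if (spec$trial_index >= agent$fail_at) stop("simulated crash")
  list(choice = spec$target_index %||% 1L, rt = agent$rt_s)
}
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# register the S3 method for the helper class in the testthat environment
registerS3method("respond", "crashing_agent", respond.crashing_agent,
                 envir = asNamespace("kiosksim"))
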