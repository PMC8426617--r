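#' Per-session visual-search summary
#'
#' Summarizes the test trials of a search-session log: per set size, the
#' mean reaction time of *correct* trials (timeouts, aborts and errors are
#' excluded from RT means but count in the accuracy denominator), plus the
#' session's overall accuracy. Initialization trials are excluded from both.
#'
#' @param log A session log (data.frame of trial records, as produced by
#'   [run_session()] or [read_session_log()]).
#' @return A list of class `search_summary` with elements `by_set_size`
#'   (data.frame: `set_size`, `mean_rt_s`, `n_correct`, `n_total`) and
#'   `accuracy`.
#' @export
search_summary <- function(log) {
  test <- log[log$task_kind == "search_test", , drop = FALSE]
  if (nrow(test) == 0L) stop("log contains no search test trials", call. = FALSE)
  sizes <- sort(unique(test$set_size))
  by <- do.call(rbind, lapply(sizes, function(ss) {
    sub <- test[test$set_size == ss, , drop = FALSE]
    ok <- sub$outcome == "correct"
    data.frame(set_size = ss,
               mean_rt_s = if (any(ok)) mean(sub$reaction_time_s[ok]) else NA_real_,
               n_correct = sum(ok), n_total = nrow(sub))
  }))
  structure(list(by_set_size = by,
                 accuracy = sum(test$outcome == "correct") / nrow(test)),
            class = "search_summary")
}

#' @export
print.search_summary <- function(x, ...) {
  cat(sprintf("Search session: accuracy %.1f%%\n", 100 * x$accuracy))
  print(x$by_set_size, row.names = FALSE)
  invisible(x)
}

#' Set-size regression (slope = set-size effect, intercept = baseline speed)
#'
#' Ordinary least squares of per-set-size mean reaction time on set size
#' (distractor count). The slope indexes the set-size effect (seconds of
#' slowing per added distractor); the intercept indexes the baseline speed
#' of processing (RT extrapolated to zero distractors).
#'
#' @param summary A [search_summary()], or a data.frame with columns
#'   `set_size` and `mean_rt_s`.
#' @return A list of class `set_size_fit`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r_squared`, `n_points`.
#' @export
fit_set_size_regression <- function(summary) {
  df <- if (inherits(summary, "search_summary")) summary$by_set_size else summary
  df <- df[!is.na(df$mean_rt_s), , drop = FALSE]
  if (length(unique(df$set_size)) < 2L) {
    stop("need >= 2 distinct set sizes with defined mean RT", call. = FALSE)
  }
  fit <- stats::lm(mean_rt_s ~ set_size, data = df)
  # an exactly linear input (e.g. a noise-free agent) is legitimate here
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  co <- s$coefficients
  structure(list(slope = unname(co["set_size", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 slope_se = unname(co["set_size", "Std. Error"]),
                 intercept_se = unname(co["(Intercept)", "Std. Error"]),
                 r_squared = s$r.squared,
                 n_points = nrow(df)), class = "set_size_fit")
}

#' @export
print.set_size_fit <- function(x, ...) {
  cat(sprintf(
    "Set-size fit (%d points): slope %.4f s/distractor (SE %.4f), intercept %.3f s (SE %.3f), R2 %.3f\n",
    x$n_points, x$slope, x$slope_se, x$intercept, x$intercept_se,
    x$r_squared))
  invisible(x)
}

#' Trials to criterion (sliding-window learning-speed statistic)
#'
#' The smallest 1-based trial index `t >= window` such that the accuracy
#' over the trailing window `outcomes[(t - window + 1):t]` reaches the
#' criterion threshold; `NA` (censored) if no window qualifies. The default
#' 70% over 10 trials is the standard criterion; 75% is also in common use —
#' `threshold` is a parameter.
#'
#' @param outcomes Binary vector (1/TRUE = correct; incorrect, timeout and
#'   abort count as 0).
#' @param window Window length (default 10).
#' @param threshold Criterion accuracy (default 0.70).
#' @return Integer index of the criterion trial, or `NA_integer_` if
#'   censored (including when the sequence is shorter than the window).
#' @export
trials_to_criterion <- function(outcomes, window = 10L, threshold = 0.70) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  x <- as.numeric(outcomes)
  n <- length(x)
  if (n < window) return(NA_integer_)
  cs <- cumsum(x)
  sums <- cs[window:n] - c(0, cs)[seq_len(n - window + 1L)]
  hit <- which(sums / window >= threshold)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(hit[1] + window - 1L)
}

#' Plateau performance after the learning criterion
#'
#' Mean accuracy across the trials strictly after the criterion trial to the
#' end of the block; `NA` when the criterion fell on the final trial (empty
#' window).
#'
#' @param outcomes Binary outcome vector of the block.
#' @param criterion_index Output of [trials_to_criterion()]; must not be
#'   censored.
#' @return Fraction in `[0, 1]`, or `NA_real_` for an empty plateau.
#' @export
plateau_performance <- function(outcomes, criterion_index) {
  if (is.na(criterion_index)) {
    stop("criterion_index is censored; no plateau defined", call. = FALSE)
  }
  rest <- as.numeric(outcomes)[-seq_len(criterion_index)]
  if (length(rest) == 0L) return(NA_real_)
  mean(rest)
}

#' Summarize learning blocks from a session log
#'
#' Splits a learning-session log by block and computes, per block, the
#' trials-to-criterion and plateau accuracy.
#'
#' @param log A learning-session log.
#' @param window,threshold Passed to [trials_to_criterion()].
#' @return Data.frame: `block_id`, `n_trials`, `n_varied`,
#'   `trials_to_criterion` (NA = censored), `plateau_accuracy`.
#' @export
block_learning_summary <- function(log, window = 10L, threshold = 0.70) {
  lrn <- log[log$task_kind == "learning", , drop = FALSE]
  if (nrow(lrn) == 0L) stop("log contains no learning trials", call. = FALSE)
  out <- do.call(rbind, lapply(split(lrn, lrn$block_id), function(b) {
    b <- b[order(b$trial_index), , drop = FALSE]
    oc <- as.numeric(b$outcome == "correct")
    ttc <- trials_to_criterion(oc, window, threshold)
    data.frame(block_id = b$block_id[1], n_trials = nrow(b),
               n_varied = b$n_varied[1],
               trials_to_criterion = ttc,
               plateau_accuracy = if (is.na(ttc)) NA_real_ else
                 plateau_performance(oc, ttc))
  }))
  out <- out[order(out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trial-position learning curve across blocks
#'
#' Mean accuracy (and SEM) at each within-block trial position, averaging
#' over the blocks long enough to contribute at that position.
#'
#' @param blocks List of binary outcome vectors (one per block).
#' @param max_len Curve length (default: longest block).
#' @return Data.frame: `trial`, `mean_accuracy`, `sem`, `n_blocks`.
#' @export
learning_curve <- function(blocks, max_len = NULL) {
  if (length(blocks) == 0L) stop("need >= 1 block", call. = FALSE)
  lens <- lengths(blocks)
  if (is.null(max_len)) max_len <- max(lens)
  do.call(rbind, lapply(seq_len(max_len), function(t) {
    vals <- vapply(blocks[lens >= t], function(b) as.numeric(b[t]), numeric(1))
    data.frame(trial = t, mean_accuracy = mean(vals),
               sem = if (length(vals) > 1L)
                 stats::sd(vals) / sqrt(length(vals)) else 0,
               n_blocks = length(vals))
  }))
}

#' Weekly (grouped) aggregation of per-session values
#'
#' Pools consecutive sessions into non-overlapping groups of
#' `group_size` (five sessions = one testing week, by default); a trailing
#' partial group is kept with its own `n`. SEM uses the sample SD
#' (n - 1 denominator).
#'
#' @param values Numeric per-session values, ordered by session index.
#' @param group_size Sessions per group (default 5).
#' @return Data.frame: `group`, `mean`, `sem`, `n`.
#' @export
weekly_aggregate <- function(values, group_size = 5L) {
  if (length(values) == 0L) stop("no session values", call. = FALSE)
  grp <- (seq_along(values) - 1L) %/% group_size + 1L
  out <- do.call(rbind, lapply(split(values, grp), function(v) {
    data.frame(mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
  out <- cbind(group = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Session profile report
#'
#' Bundles the headline statistics of one or more analyzed sessions into a
#' list suitable for JSON export: the set-size fit, search accuracy, and
#' mean trials-to-criterion / plateau accuracy split by difficulty (number
#' of varied dimensions). Censored blocks are excluded from the
#' trials-to-criterion mean (the default convention; see
#' [block_learning_summary()]).
#'
#' @param search_fit Optional [fit_set_size_regression()] result.
#' @param search_acc Optional accuracy fraction.
#' @param block_summary Optional [block_learning_summary()] data.frame.
#' @return A list (class `profile_report`).
#' @export
profile_report <- function(search_fit = NULL, search_acc = NULL,
                           block_summary = NULL) {
  rep <- list()
  if (!is.null(search_fit)) {
    rep$search <- list(slope_s_per_distractor = search_fit$slope,
                       intercept_s = search_fit$intercept,
                       slope_se = search_fit$slope_se,
                       intercept_se = search_fit$intercept_se,
                       r_squared = search_fit$r_squared,
                       accuracy = search_acc)
  }
  if (!is.null(block_summary)) {
    rep$learning <- lapply(split(block_summary, block_summary$n_varied),
      function(b) {
        done <- b[!is.na(b$trials_to_criterion), , drop = FALSE]
        list(n_blocks = nrow(b),
             n_censored = sum(is.na(b$trials_to_criterion)),
             mean_trials_to_criterion =
               if (nrow(done)) mean(done$trials_to_criterion) else NA_real_,
             mean_plateau_accuracy =
               if (any(!is.na(done$plateau_accuracy)))
                 mean(done$plateau_accuracy, na.rm = TRUE) else NA_real_)
      })
    names(rep$learning) <- paste0("varied_", names(rep$learning))
  }
  structure(rep, class = "profile_report")
}
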