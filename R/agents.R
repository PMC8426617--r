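#' Agent generics
#'
#' Agents are synthetic subjects. `respond()` maps a trial spec to a choice
#' (`list(choice = index or NA, rt = seconds)`); `learn()` lets stateful
#' agents update after feedback and returns the (possibly updated) agent.
#'
#' @param agent An agent object.
#' @param spec A trial spec.
#' @param result A `trial_result` (for `learn`).
#' @return `respond`: `list(choice, rt)`. `learn`: the updated agent.
#' @export
respond <- function(agent, spec) UseMethod("respond")

#' @rdname respond
#' @export
learn <- function(agent, spec, result) UseMethod("learn")

#' @export
learn.default <- function(agent, spec, result) agent

#' Reaction-time agent for visual search
#'
#' A stationary responder emulating the classical set-size effect: with
#' probability `lapse_rate` it times out; otherwise it picks the target with
#' probability `p_correct` (a uniformly random distractor otherwise) and
#' reports a reaction time
#' `b0 + b1 * set_size + Normal(0, sigma)`, clamped to the interval
#' (`choice_hold_s`, `response_window_s`]. With the default noise scale the
#' clamp is hit with negligible probability, so sample means track the linear
#' model.
#'
#' @param p_correct Probability of choosing the target on non-lapse trials.
#' @param b0 Baseline RT in seconds (regression intercept, speed of
#'   processing).
#' @param b1 RT increment per distractor in seconds (regression slope, the
#'   set-size effect). Presets spanning the range observed in rhesus monkeys
#'   are in [agent_presets()] (0.049--0.072 s/distractor).
#' @param sigma RT noise SD in seconds.
#' @param lapse_rate Probability of a timeout.
#' @return An object of class `rt_agent`.
#' @export
rt_agent <- function(p_correct = 0.9, b0 = 0.9, b1 = 0.06, sigma = 0.15,
                     lapse_rate = 0.02) {
  stopifnot(p_correct >= 0, p_correct <= 1, lapse_rate >= 0, lapse_rate <= 1,
            sigma >= 0, b0 > 0)
  structure(list(p_correct = p_correct, b0 = b0, b1 = b1, sigma = sigma,
                 lapse_rate = lapse_rate), class = "rt_agent")
}

#' @export
respond.rt_agent <- function(agent, spec) {
  if (stats::runif(1) < agent$lapse_rate) {
    return(list(choice = NA_integer_, rt = NA_real_))
  }
  n <- nrow(spec$stimuli)
  choice <- if (n == 1L || stats::runif(1) < agent$p_correct) {
    spec$target_index
  } else {
    sample_one(setdiff(seq_len(n), spec$target_index))
  }
  ss <- if (is.na(spec$set_size)) 0L else spec$set_size
  rt <- agent$b0 + agent$b1 * ss + stats::rnorm(1, 0, agent$sigma)
  rt <- max(min(rt, spec$timing$response_window_s),
            spec$timing$choice_hold_s + 1e-6)
  list(choice = choice, rt = rt)
}

#' Feature-based reinforcement-learning agent
#'
#' A delta-rule learner over feature values, emulating trial-and-error
#' feature-reward learning. Each (dimension, value) feature carries a value
#' `V`, initialized at `v0`. An object's value is the *mean* of `V` over its
#' features (so the value scale does not grow with the number of
#' dimensions); choices are softmax in the object values with inverse
#' temperature `beta`. After feedback, only the chosen object's features are
#' updated: `V <- V + alpha * (reward - V)`.
#'
#' @param alpha Learning rate in (0, 1].
#' @param beta Softmax inverse temperature, >= 0 (0 = uniform choice).
#' @param v0 Initial feature value (default 0).
#' @param rt_s Constant reaction time reported on every trial (default 1).
#' @param reset_between_blocks Reset `V` when the block id changes
#'   (default FALSE; carrying values across blocks produces the proactive
#'   interference that makes multi-dimension blocks harder).
#' @return An object of class `rl_agent` with a mutable value table.
#' @export
rl_agent <- function(alpha = 0.3, beta = 5, v0 = 0, rt_s = 1,
                     reset_between_blocks = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, beta >= 0)
  structure(list(alpha = alpha, beta = beta, v0 = v0, rt_s = rt_s,
                 reset_between_blocks = reset_between_blocks,
                 V = numeric(0), last_block = NA_integer_,
                 n_trials = 0L), class = "rl_agent")
}

feature_keys <- function(stimuli, row) {
  paste(names(stimuli), unlist(stimuli[row, , drop = FALSE]), sep = ":")
}

object_values <- function(agent, stimuli) {
  vapply(seq_len(nrow(stimuli)), function(i) {
    keys <- feature_keys(stimuli, i)
    v <- agent$V[keys]
    v[is.na(v)] <- agent$v0
    mean(v)
  }, numeric(1))
}

softmax <- function(x, beta) {
  z <- beta * (x - max(x))
  p <- exp(z)
  p / sum(p)
}

#' @export
respond.rl_agent <- function(agent, spec) {
  vals <- object_values(agent, spec$stimuli)
  p <- softmax(vals, agent$beta)
  list(choice = sample.int(length(p), 1L, prob = p), rt = agent$rt_s)
}

#' @export
learn.rl_agent <- function(agent, spec, result) {
  if (agent$reset_between_blocks && !is.na(agent$last_block) &&
      !identical(agent$last_block, spec$block_id)) {
    agent$V <- numeric(0)
  }
  agent$last_block <- spec$block_id
  agent$n_trials <- agent$n_trials + 1L
  if (is.na(result$chosen_index)) return(agent)
  keys <- feature_keys(spec$stimuli, result$chosen_index)
  v <- agent$V[keys]
  v[is.na(v)] <- agent$v0
  names(v) <- keys
  agent$V[keys] <- v + agent$alpha * (as.numeric(result$rewarded) - v)
  agent
}

#' Stand-alone delta-rule update (pure form)
#'
#' Functional form of the `rl_agent` update, exposed for testing and for
#' building custom learners: for each feature of the chosen object,
#' `V(f) <- V(f) + alpha * (reward - V(f))`; all other entries untouched.
#'
#' @param V Named numeric vector of feature values (`"dim:value"` keys);
#'   missing keys are treated as `v0`.
#' @param chosen_features Character vector of the chosen object's feature
#'   keys.
#' @param reward 0 or 1.
#' @param alpha Learning rate.
#' @param v0 Default value for unseen features.
#' @return Updated named numeric vector.
#' @export
rl_value_update <- function(V, chosen_features, reward, alpha, v0 = 0) {
  v <- V[chosen_features]
  v[is.na(v)] <- v0
  names(v) <- chosen_features
  V[chosen_features] <- v + alpha * (reward - v)
  V
}

#' Omniscient oracle agent
#'
#' Always chooses the target (search) or the object carrying the rewarded
#' feature (learning), at a constant RT. Used as a test oracle: a session
#' run against it must be 100% correct and rewarded on every trial.
#'
#' @param rt_s Constant reaction time (default 1 s).
#' @return An object of class `oracle_agent`.
#' @export
oracle_agent <- function(rt_s = 1) {
  structure(list(rt_s = rt_s), class = "oracle_agent")
}

#' @export
respond.oracle_agent <- function(agent, spec) {
  choice <- if (spec$task_kind %in% c("search_init", "search_test")) {
    spec$target_index
  } else {
    which(spec$stimuli[[spec$rewarded_dim]] == spec$rewarded_value)[1]
  }
  list(choice = choice, rt = agent$rt_s)
}

#' Subject-like agent presets
#'
#' Parameter sets for the RT and RL agents tuned so that simulated sessions
#' land in the performance ranges reported for trained rhesus monkeys
#' (set-size slopes ~0.049--0.072 s/distractor, intercepts ~0.77--0.91 s,
#' accuracies ~81--90%; learning criterion reached around trials 12--19 with
#' plateau accuracy ~75--80%). These are presets emulating realistic
#' behavior, not fits to any animal's data. Shipped as a plain-text table in
#' `inst/extdata/agent_presets.csv`.
#'
#' @return Data.frame with one row per preset (`subject_1` ... `subject_4`)
#'   and columns for both agent families.
#' @export
agent_presets <- function() {
  path <- system.file("extdata", "agent_presets.csv", package = "kiosksim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
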