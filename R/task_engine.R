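#' Default configuration for a visual-search session
#'
#' A session comprises `n_runs` runs; each run opens with `n_init`
#' initialization trials (the target shown alone, defining it for the run)
#' followed by `n_test` test trials in which the target appears among 3, 6,
#' 9, or 12 distractors placed at random intersections of a virtual grid.
#'
#' @param n_runs Runs per session (default 2).
#' @param n_init Initialization trials per run (default 10).
#' @param n_test Test trials per run (default 100).
#' @param set_sizes Distractor-count menu (default `c(3, 6, 9, 12)`).
#' @param set_size_policy `"stratified"` (exact equal counts per set size,
#'   order shuffled; default) or `"iid_uniform"` (each trial draws a set size
#'   independently).
#' @param n_shared Menu of shared-feature counts between each distractor and
#'   the target; one value is drawn per test trial (default `1:3`).
#' @param target_k_nonneutral Non-neutral dimensions of the target
#'   (default 3).
#' @param target_forced_neutral Dimensions of the target pinned to neutral
#'   (default `"body_shape"`, the spherical body).
#' @param timing,grid See [trial_timing()] and [grid_config()].
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_runs = 2L, n_init = 10L, n_test = 100L,
                          set_sizes = c(3L, 6L, 9L, 12L),
                          set_size_policy = c("stratified", "iid_uniform"),
                          n_shared = 1:3,
                          target_k_nonneutral = 3L,
                          target_forced_neutral = "body_shape",
                          timing = trial_timing(),
                          grid = grid_config()) {
  set_size_policy <- match.arg(set_size_policy)
  if (!all(set_sizes %in% c(0L, 3L, 6L, 9L, 12L))) {
    stop("set-size menu must be a subset of {0, 3, 6, 9, 12}", call. = FALSE)
  }
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  structure(list(
    task_kind = "search", n_runs = as.integer(n_runs),
    n_init = as.integer(n_init), n_test = as.integer(n_test),
    set_sizes = as.integer(set_sizes), set_size_policy = set_size_policy,
    n_shared = as.integer(n_shared),
    target_k_nonneutral = as.integer(target_k_nonneutral),
    target_forced_neutral = target_forced_neutral,
    timing = timing, grid = grid), class = "search_config")
}

#' Default configuration for a feature-reward learning session
#'
#' A session presents `n_blocks` blocks of 45--60 trials. Within a block one
#' non-neutral feature value of one dimension is rewarded; the rewarded
#' (dimension, value) pair switches between blocks and never repeats the
#' immediately preceding pair. On every trial `n_objects` objects appear on a
#' ring 4.1 inches from the display center; they vary in `n_varied_dims`
#' dimensions (1 = easy, 2--3 = difficult) and are neutral elsewhere.
#'
#' @param n_blocks Blocks per session (default 40).
#' @param block_len_range Integer range for block lengths (default
#'   `c(45, 60)`).
#' @param n_objects Objects per trial (default 3).
#' @param n_varied_dims Number of varied dimensions per block (default 1);
#'   may be a vector, sampled uniformly per block.
#' @param eligible_dims Dimensions eligible to carry the rewarded feature
#'   (default: all).
#' @param timing,grid See [trial_timing()] and [grid_config()].
#' @return A list of class `learning_config`.
#' @export
learning_config <- function(n_blocks = 40L, block_len_range = c(45L, 60L),
                            n_objects = 3L, n_varied_dims = 1L,
                            eligible_dims = NULL,
                            timing = trial_timing(),
                            grid = grid_config()) {
  if (length(block_len_range) != 2L || block_len_range[1] > block_len_range[2]) {
    stop("block_len_range must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (any(n_varied_dims < 1L)) stop("n_varied_dims must be >= 1", call. = FALSE)
  structure(list(
    task_kind = "learning", n_blocks = as.integer(n_blocks),
    block_len_range = as.integer(block_len_range),
    n_objects = as.integer(n_objects),
    n_varied_dims = as.integer(n_varied_dims),
    eligible_dims = eligible_dims,
    timing = timing, grid = grid), class = "learning_config")
}

#' Trial timing parameters
#'
#' @param initiation_hold_s Hold duration on the central blue square (s).
#' @param delay_range_s Uniform range for the square-offset-to-array delay.
#' @param response_window_s Maximum time to choose an object (s).
#' @param choice_hold_s Hold duration required on the chosen object (s).
#' @return A list.
#' @export
trial_timing <- function(initiation_hold_s = 0.2,
                         delay_range_s = c(0.3, 0.5),
                         response_window_s = 5.0,
                         choice_hold_s = 0.2) {
  list(initiation_hold_s = initiation_hold_s,
       delay_range_s = delay_range_s,
       response_window_s = response_window_s,
       choice_hold_s = choice_hold_s)
}

#' Virtual placement grid for a 19.5-inch touchscreen
#'
#' Stimuli land on intersections of a virtual grid spanning the screen with a
#' margin; the paper-style learning display instead constrains positions to a
#' ring of fixed eccentricity around the center.
#'
#' @param cols,rows Grid intersections (default 5 x 3).
#' @param width_in,height_in Usable screen size in inches (defaults match a
#'   19.5-inch 16:9 display: 17.0 x 9.5).
#' @param margin_in Margin kept free at each edge (default 1).
#' @param ring_radius_in Eccentricity of the learning-task ring (default 4.1).
#' @param ring_slots Number of equally spaced slots on the ring (default 8).
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(cols = 5L, rows = 3L, width_in = 17.0,
                        height_in = 9.5, margin_in = 1.0,
                        ring_radius_in = 4.1, ring_slots = 8L) {
  list(cols = as.integer(cols), rows = as.integer(rows),
       width_in = width_in, height_in = height_in, margin_in = margin_in,
       ring_radius_in = ring_radius_in, ring_slots = as.integer(ring_slots))
}

grid_intersections <- function(grid) {
  xs <- seq(-grid$width_in / 2 + grid$margin_in,
            grid$width_in / 2 - grid$margin_in, length.out = grid$cols)
  ys <- seq(-grid$height_in / 2 + grid$margin_in,
            grid$height_in / 2 - grid$margin_in, length.out = grid$rows)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Place stimuli on the virtual grid or eccentricity ring
#'
#' Samples `n_items` distinct positions without replacement: grid mode draws
#' from the grid intersections, ring mode from `ring_slots` equally spaced
#' points at radius `ring_radius_in` from the center (the learning-task
#' geometry).
#'
#' @param n_items Number of positions.
#' @param grid A [grid_config()].
#' @param mode `"grid"` or `"ring"`.
#' @return Data.frame with columns `x`, `y` (inches, display-centered).
#' @export
place_on_grid <- function(n_items, grid = grid_config(),
                          mode = c("grid", "ring")) {
  mode <- match.arg(mode)
  pts <- if (mode == "grid") {
    grid_intersections(grid)
  } else {
    ang <- 2 * pi * (seq_len(grid$ring_slots) - 1L) / grid$ring_slots
    data.frame(x = grid$ring_radius_in * cos(ang),
               y = grid$ring_radius_in * sin(ang))
  }
  if (n_items > nrow(pts)) {
    stop(sprintf("%d positions requested but only %d available",
                 n_items, nrow(pts)), call. = FALSE)
  }
  out <- pts[sample.int(nrow(pts), n_items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule so that block `k` of a session is
#' reproducible in isolation: `child = (master * 48271 + k) mod (2^31 - 1)`
#' (a Lehmer-style mix; constants documented, no statistical claims beyond
#' decorrelation of nearby indices).
#'
#' @param master Integer master seed.
#' @param k Integer index (>= 0).
#' @return Integer child seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, k) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(k)) %% m)
}

draw_delay <- function(timing) {
  stats::runif(1, timing$delay_range_s[1], timing$delay_range_s[2])
}

new_trial_spec <- function(task_kind, block_id, trial_index, stimuli,
                           positions, target_index = NA_integer_,
                           rewarded_dim = NA_character_,
                           rewarded_value = NA_character_,
                           set_size = NA_integer_, n_shared = NA_integer_,
                           varied_dims = character(0), timing, delay_s) {
  structure(list(
    task_kind = task_kind, block_id = block_id, trial_index = trial_index,
    stimuli = stimuli, positions = positions, target_index = target_index,
    rewarded_dim = rewarded_dim, rewarded_value = rewarded_value,
    set_size = set_size, n_shared = n_shared, varied_dims = varied_dims,
    timing = timing, delay_s = delay_s), class = "trial_spec")
}

#' Generate a visual-search session plan
#'
#' Deterministic given `(config, seed)`. Each run draws one fixed target
#' (non-neutral in `target_k_nonneutral` dimensions, neutral in the forced
#' dimensions), schedules `n_init` single-object initialization trials and
#' `n_test` test trials whose set sizes follow the configured policy, and
#' builds every distractor array with [sample_search_array()]. Run `r` uses
#' child seed [derive_seed()]`(seed, r)`.
#'
#' @param config A [search_config()].
#' @param seed Integer master seed.
#' @param space A [feature_space()] (default the canonical Quaddle space).
#' @return A `session_plan`: list with `trials` (list of trial specs),
#'   `config`, `seed`, `task_kind`, `space`.
#' @export
generate_search_session <- function(config = search_config(), seed = 1L,
                                    space = default_feature_space()) {
  stopifnot(inherits(config, "search_config"))
  trials <- list()
  idx <- 0L
  for (r in seq_len(config$n_runs)) {
    set.seed(derive_seed(seed, r))
    target <- sample_target(space, config$target_k_nonneutral,
                            config$target_forced_neutral)
    sizes <- switch(config$set_size_policy,
      stratified = {
        per <- config$n_test %/% length(config$set_sizes)
        rem <- config$n_test %% length(config$set_sizes)
        s <- rep(config$set_sizes, per)
        if (rem > 0) s <- c(s, sample(config$set_sizes, rem))
        sample(s)
      },
      iid_uniform = sample(config$set_sizes, config$n_test, replace = TRUE))
    for (i in seq_len(config$n_init)) {
      idx <- idx + 1L
      pos <- place_on_grid(1L, config$grid, "grid")
      trials[[idx]] <- new_trial_spec(
        task_kind = "search_init", block_id = r, trial_index = idx,
        stimuli = descriptor_frame(list(target), space), positions = pos,
        target_index = 1L, set_size = 0L, timing = config$timing,
        delay_s = draw_delay(config$timing))
    }
    for (i in seq_len(config$n_test)) {
      idx <- idx + 1L
      ss <- sizes[i]
      sh <- sample_one(config$n_shared)
      if (ss > 0L) {
        distr <- sample_search_array(space, target, ss, sh)
        stim <- rbind(descriptor_frame(list(target), space), distr)
        ord <- sample.int(nrow(stim))
        stim <- stim[ord, , drop = FALSE]
        rownames(stim) <- NULL
        t_idx <- which(ord == 1L)
      } else {
        stim <- descriptor_frame(list(target), space)
        t_idx <- 1L
      }
      pos <- place_on_grid(nrow(stim), config$grid, "grid")
      trials[[idx]] <- new_trial_spec(
        task_kind = "search_test", block_id = r, trial_index = idx,
        stimuli = stim, positions = pos, target_index = t_idx,
        set_size = ss, n_shared = sh, timing = config$timing,
        delay_s = draw_delay(config$timing))
    }
  }
  structure(list(task_kind = "search", trials = trials, config = config,
                 seed = as.integer(seed), space = space),
            class = "session_plan")
}

#' Generate a feature-reward learning session plan
#'
#' Deterministic given `(config, seed)`. Draws `n_blocks` block definitions:
#' length uniform over `block_len_range`, rewarded dimension uniform over
#' eligible dimensions, rewarded value uniform over that dimension's
#' non-neutral values, with the constraint that consecutive blocks never
#' repeat the same (dimension, value) pair. Every trial's object array comes
#' from [sample_learning_array()] and its positions from the eccentricity
#' ring. Block `b` uses child seed [derive_seed()]`(seed, b)`.
#'
#' @inheritParams generate_search_session
#' @param config A [learning_config()].
#' @return A `session_plan` with an extra `blocks` element (data.frame of
#'   block definitions).
#' @export
generate_learning_session <- function(config = learning_config(), seed = 1L,
                                      space = default_feature_space()) {
  stopifnot(inherits(config, "learning_config"))
  dims <- config$eligible_dims
  if (is.null(dims)) dims <- dimension_names(space)
  n_feat <- sum(vapply(dims, function(d) length(non_neutral_values(space, d)),
                       integer(1)))
  if (n_feat < 2L) stop("need >= 2 candidate rewarded features", call. = FALSE)
  trials <- list()
  blocks <- data.frame(block_id = integer(0), rewarded_dim = character(0),
                       rewarded_value = character(0), n_trials = integer(0),
                       n_varied = integer(0), stringsAsFactors = FALSE)
  idx <- 0L
  prev <- c(NA_character_, NA_character_)
  for (b in seq_len(config$n_blocks)) {
    set.seed(derive_seed(seed, b))
    repeat {
      rd <- sample_one(dims)
      rv <- sample_one(non_neutral_values(space, rd))
      if (!identical(c(rd, rv), prev)) break
    }
    prev <- c(rd, rv)
    len <- sample_one(seq(config$block_len_range[1], config$block_len_range[2]))
    nv <- sample_one(config$n_varied_dims)
    varied <- union(rd, sample(setdiff(dims, rd), max(0L, nv - 1L)))
    blocks <- rbind(blocks, data.frame(
      block_id = b, rewarded_dim = rd, rewarded_value = rv, n_trials = len,
      n_varied = length(varied), stringsAsFactors = FALSE))
    for (i in seq_len(len)) {
      idx <- idx + 1L
      stim <- sample_learning_array(space, rd, rv,
                                    n_objects = config$n_objects,
                                    varied_dims = varied)
      pos <- place_on_grid(nrow(stim), config$grid, "ring")
      trials[[idx]] <- new_trial_spec(
        task_kind = "learning", block_id = b, trial_index = idx,
        stimuli = stim, positions = pos,
        rewarded_dim = rd, rewarded_value = rv,
        varied_dims = varied, timing = config$timing,
        delay_s = draw_delay(config$timing))
    }
  }
  structure(list(task_kind = "learning", trials = trials, blocks = blocks,
                 config = config, seed = as.integer(seed), space = space),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %s task, %d trials, seed %d\n",
              x$task_kind, length(x$trials), x$seed))
  if (!is.null(x$blocks)) {
    cat(sprintf("  %d blocks, lengths %d-%d\n", nrow(x$blocks),
                min(x$blocks$n_trials), max(x$blocks$n_trials)))
  }
  invisible(x)
}

is_target_choice <- function(spec, choice) {
  if (spec$task_kind %in% c("search_init", "search_test")) {
    choice == spec$target_index
  } else {
    spec$stimuli[[spec$rewarded_dim]][choice] == spec$rewarded_value
  }
}

#' Run one trial against an agent
#'
#' The discrete-event trial state machine. The agent is asked to respond to
#' the spec; the outcome is classified as:
#' * `timeout` — no choice within the response window (RT logged as the
#'   window length and excluded from RT statistics downstream);
#' * `abort_neutral` — the chosen object is the fully neutral Quaddle
#'   (never rewarded; aborts the trial);
#' * `correct` (rewarded) — the chosen object is the target (search) or
#'   carries the block's rewarded feature (learning);
#' * `incorrect` — anything else.
#'
#' @param spec A trial spec from a session plan.
#' @param agent An agent object; see [rt_agent()], [rl_agent()],
#'   [oracle_agent()].
#' @param abort_on_neutral Enable the all-neutral abort rule (default TRUE).
#' @return A `trial_result`: list with `outcome`, `chosen_index`,
#'   `reaction_time_s`, `rewarded`, `delay_s`.
#' @export
run_trial <- function(spec, agent, abort_on_neutral = TRUE) {
  resp <- respond(agent, spec)
  rw <- spec$timing$response_window_s
  if (is.null(resp$choice) || is.na(resp$choice)) {
    return(structure(list(outcome = "timeout", chosen_index = NA_integer_,
                          reaction_time_s = rw, rewarded = FALSE,
                          delay_s = spec$delay_s), class = "trial_result"))
  }
  choice <- as.integer(resp$choice)
  if (choice < 1L || choice > nrow(spec$stimuli)) {
    stop(sprintf("agent chose index %d out of 1..%d", choice,
                 nrow(spec$stimuli)), call. = FALSE)
  }
  rt <- resp$rt
  if (is.null(rt) || is.na(rt) || rt < 0) stop("agent reported invalid RT", call. = FALSE)
  rt <- min(rt, rw)
  chosen <- spec$stimuli[choice, , drop = FALSE]
  space <- attr(spec, "space")
  if (abort_on_neutral && all(unlist(chosen) ==
        unlist(chosen_neutrals(spec)))) {
    outcome <- "abort_neutral"
    rewarded <- FALSE
  } else if (is_target_choice(spec, choice)) {
    outcome <- "correct"
    rewarded <- TRUE
  } else {
    outcome <- "incorrect"
    rewarded <- FALSE
  }
  structure(list(outcome = outcome, chosen_index = choice,
                 reaction_time_s = rt, rewarded = rewarded,
                 delay_s = spec$delay_s), class = "trial_result")
}

# neutral values in the order of the spec's stimulus columns; specs carry no
# space pointer, so neutrality is resolved against the canonical labels used
# when the plan was generated (stored on the session and threaded by
# run_session); fall back to the default space.
chosen_neutrals <- function(spec) {
  space <- attr(spec, "space")
  if (is.null(space)) space <- default_feature_space()
  as.list(neutral_values(space)[names(spec$stimuli)])
}

#' Run a full session, flushing each trial to a sink
#'
#' Executes the plan's trials in order against an agent, writing one log
#' record to `sink` immediately after each trial completes (incremental
#' persistence: interrupting after trial *k* leaves exactly *k* complete
#' records on disk). Learning agents are updated between trials via
#' [learn()].
#'
#' @param plan A session plan.
#' @param agent An agent object.
#' @param sink Optional path to a JSON-Lines log file (see
#'   [open_log_sink()]), an open sink, or `NULL` for in-memory only.
#' @param session_id Identifier stamped into each record.
#' @return Data.frame of trial records (class `session_log`), one row per
#'   executed trial.
#' @export
run_session <- function(plan, agent, sink = NULL,
                        session_id = paste0("s", plan$seed)) {
  stopifnot(inherits(plan, "session_plan"))
  own_sink <- is.character(sink)
  if (own_sink) sink <- open_log_sink(sink)
  if (!is.null(sink)) on.exit(if (own_sink) close_log_sink(sink), add = TRUE)
  records <- vector("list", length(plan$trials))
  for (i in seq_along(plan$trials)) {
    spec <- plan$trials[[i]]
    attr(spec, "space") <- plan$space
    res <- run_trial(spec, agent)
    agent <- learn(agent, spec, res)
    rec <- trial_record(spec, res, session_id, plan$seed)
    if (!is.null(sink)) write_trial_record(sink, rec)
    records[[i]] <- rec
  }
  out <- do.call(rbind, records)
  class(out) <- c("session_log", class(out))
  attr(out, "agent") <- agent
  out
}

#' Touch-Hold-Release difficulty ladder
#'
#' Ordered shaping levels: the blue square shrinks, its position
#' randomizes, and the hold/release windows tighten as the subject is
#' promoted. Defaults follow the standard shaping endpoint: hold 200--300 ms,
#' release within 500 ms of touch onset.
#'
#' @param square_in Square side lengths per level (inches, non-increasing).
#' @param randomize_position Logical per level.
#' @param hold_min_ms,hold_max_ms,release_max_ms Per-level windows (recycled).
#' @param window Rolling window of recent trials used for level decisions.
#' @param promote_at,demote_at Accuracy thresholds over the window.
#' @return A list of class `thr_ladder`.
#' @export
thr_ladder <- function(square_in = c(4, 3, 2.5, 2, 1.5, 1.2, 1),
                       randomize_position = c(FALSE, rep(TRUE, 6)),
                       hold_min_ms = c(0, 0, 50, 100, 150, 200, 200),
                       hold_max_ms = c(Inf, Inf, 1000, 800, 500, 300, 300),
                       release_max_ms = c(Inf, Inf, 2000, 1500, 1000, 500, 500),
                       window = 10L, promote_at = 0.8, demote_at = 0.5) {
  n <- length(square_in)
  if (n < 1L) stop("empty ladder", call. = FALSE)
  if (any(diff(square_in) > 0)) {
    stop("square size must be non-increasing with level", call. = FALSE)
  }
  structure(list(
    levels = data.frame(
      level = seq_len(n), square_in = square_in,
      randomize_position = rep_len(randomize_position, n),
      hold_min_ms = rep_len(hold_min_ms, n),
      hold_max_ms = rep_len(hold_max_ms, n),
      release_max_ms = rep_len(release_max_ms, n)),
    window = as.integer(window),
    promote_at = promote_at, demote_at = demote_at), class = "thr_ladder")
}

#' Initial THR state
#'
#' @param ladder A [thr_ladder()].
#' @param level Starting level (default 1).
#' @return A list of class `thr_state` with the current level's parameters
#'   and a `touch_ready` flag.
#' @export
thr_state <- function(ladder = thr_ladder(), level = 1L) {
  lv <- ladder$levels[level, ]
  structure(list(level = as.integer(level),
                 square_in = lv$square_in,
                 randomize_position = lv$randomize_position,
                 hold_min_ms = lv$hold_min_ms, hold_max_ms = lv$hold_max_ms,
                 release_max_ms = lv$release_max_ms,
                 touch_ready = level == nrow(ladder$levels)),
            class = "thr_state")
}

#' Advance the THR ladder given recent outcomes
#'
#' Promotes one level when rolling accuracy over the ladder's window meets
#' the promote threshold, demotes one level when it falls below the demote
#' threshold, and otherwise stays. Levels are clamped to the ladder; reaching
#' the top level with sustained accuracy sets `touch_ready`. Level moves by
#' at most 1 per update (monotone lattice walk).
#'
#' @param state A [thr_state()].
#' @param recent_outcomes Logical/0-1 vector of recent trial outcomes,
#'   most recent last.
#' @param ladder The [thr_ladder()].
#' @return Updated `thr_state`.
#' @export
thr_next_level <- function(state, recent_outcomes, ladder = thr_ladder()) {
  n_lv <- nrow(ladder$levels)
  w <- min(ladder$window, length(recent_outcomes))
  if (w == 0L) return(state)
  acc <- mean(as.numeric(utils::tail(recent_outcomes, w)))
  lv <- state$level
  if (acc >= ladder$promote_at) lv <- min(lv + 1L, n_lv)
  else if (acc < ladder$demote_at) lv <- max(lv - 1L, 1L)
  thr_state(ladder, lv)
}

#' Classify a raw touch trace
#'
#' Implements the Touch-Hold-Release contact rules: a valid response is a
#' touch that lands inside the object bounds, stays within them (up to a
#' tolerance), is held between `hold_min_ms` and `hold_max_ms`, and is
#' released within `release_max_ms` of touch onset. Undesired strategies are
#' named: brief taps, overlong holds, late releases, swipes (the contact path
#' exits the bounds before release), and off-target touches.
#'
#' @param trace Data.frame with columns `t_ms` (ascending), `x`, `y`
#'   (inches), `down` (logical contact state at that sample).
#' @param bounds Named list/vector `xmin`, `xmax`, `ymin`, `ymax`.
#' @param hold_min_ms,hold_max_ms,release_max_ms Contact windows
#'   (defaults 200, 300, 500).
#' @param tol_in Excursion tolerance outside the bounds before a contact
#'   counts as a swipe (default 0.1).
#' @return One of `"valid"`, `"tap_too_short"`, `"hold_too_long"`,
#'   `"late_release"`, `"swipe"`, `"off_target"`, `"no_touch"`.
#' @export
classify_touch <- function(trace, bounds, hold_min_ms = 200,
                           hold_max_ms = 300, release_max_ms = 500,
                           tol_in = 0.1) {
  if (is.unsorted(trace$t_ms, strictly = FALSE)) {
    stop("touch trace timestamps must be non-decreasing", call. = FALSE)
  }
  down <- which(trace$down)
  if (length(down) == 0L) return("no_touch")
  onset <- down[1]
  after_up <- which(!trace$down & seq_len(nrow(trace)) > onset)
  release_t <- if (length(after_up)) trace$t_ms[after_up[1]] else
    trace$t_ms[nrow(trace)]
  contact <- trace[trace$down & trace$t_ms >= trace$t_ms[onset] &
                     trace$t_ms <= release_t, , drop = FALSE]
  inside <- function(x, y, pad = 0) {
    x >= bounds$xmin - pad & x <= bounds$xmax + pad &
      y >= bounds$ymin - pad & y <= bounds$ymax + pad
  }
  if (!inside(contact$x[1], contact$y[1])) return("off_target")
  if (any(!inside(contact$x, contact$y, pad = tol_in))) return("swipe")
  dur <- release_t - trace$t_ms[onset]
  if (dur < hold_min_ms) return("tap_too_short")
  if (dur > release_max_ms) return("late_release")
  if (dur > hold_max_ms) return("hold_too_long")
  "valid"
}
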