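test_that("search sessions have the canonical run structure", {
  plan <- generate_search_session(seed = 11)
  kinds <- vapply(plan$trials, `[[`, character(1), "task_kind")
  runs <- vapply(plan$trials, `[[`, integer(1), "block_id")
  for (r in 1:2) {
    expect_equal(sum(kinds == "search_init" & runs == r), 10)
    expect_equal(sum(kinds == "search_test" & runs == r), 100)
  }
  # stratified policy: exactly 25 trials per set size per run
  ss <- vapply(plan$trials, `[[`, integer(1), "set_size")
  for (r in 1:2) {
    expect_equal(as.integer(table(ss[kinds == "search_test" & runs == r])),
                 rep(25L, 4))
  }
  # one fixed target per run, shown alone on initialization trials
  for (r in 1:2) {
    tr <- plan$trials[runs == r]
    tgt <- vapply(tr, function(t)
      paste(unlist(t$stimuli[t$target_index, ]), collapse = "|"),
      character(1))
    expect_equal(length(unique(tgt)), 1L)
    init <- tr[vapply(tr, `[[`, character(1), "task_kind") == "search_init"]
    expect_true(all(vapply(init, function(t) nrow(t$stimuli) == 1L,
                           logical(1))))
  }
})

test_that("search trial arrays respect set size and sharing", {
  plan <- generate_search_session(
    search_config(n_runs = 1L, n_test = 20L, n_shared = 2L), seed = 3)
  fs <- plan$space
  for (t in plan$trials) {
    if (t$task_kind != "search_test") next
    expect_equal(nrow(t$stimuli), t$set_size + 1L)
    tgt <- t$stimuli[t$target_index, ]
    for (i in setdiff(seq_len(nrow(t$stimuli)), t$target_index)) {
      expect_equal(oracle_shared_count(t$stimuli[i, ], tgt), 2L)
    }
    expect_equal(anyDuplicated(t$positions), 0L)
  }
})

test_that("session generation is deterministic given (config, seed)", {
  expect_identical(generate_search_session(seed = 42),
                   generate_search_session(seed = 42))
  expect_identical(generate_learning_session(seed = 42),
                   generate_learning_session(seed = 42))
  expect_false(identical(generate_search_session(seed = 1),
                         generate_search_session(seed = 2)))
})

test_that("learning sessions have 40 blocks within the length range", {
  plan <- generate_learning_session(seed = 5)
  expect_equal(nrow(plan$blocks), 40)
  expect_true(all(plan$blocks$n_trials >= 45 & plan$blocks$n_trials <= 60))
  expect_equal(length(plan$trials), sum(plan$blocks$n_trials))
  # rewarded value is always non-neutral
  neu <- neutral_values(plan$space)
  expect_false(any(plan$blocks$rewarded_value ==
                     neu[plan$blocks$rewarded_dim]))
})

test_that("consecutive blocks never repeat the rewarded feature", {
  for (seed in c(2, 9, 17, 101, 555)) {
    b <- generate_learning_session(
      learning_config(n_blocks = 20L, block_len_range = c(2L, 3L)),
      seed = seed)$blocks
    key <- paste(b$rewarded_dim, b$rewarded_value)
    expect_false(any(key[-1] == key[-length(key)]))
  }
  # two-feature space: the rewarded feature must strictly alternate
  two <- feature_space(list(
    d = list(values = c("n", "a", "b"), neutral = "n")))
  b2 <- generate_learning_session(
    learning_config(n_blocks = 10L, block_len_range = c(2L, 2L),
                    n_objects = 2L), seed = 1, space = two)$blocks
  expect_equal(unique(b2$rewarded_value[c(TRUE, FALSE)]),
               b2$rewarded_value[1])
  expect_equal(length(unique(b2$rewarded_value)), 2L)
})

test_that("every learning trial has exactly one rewarded object", {
  plan <- generate_learning_session(
    learning_config(n_blocks = 6L, block_len_range = c(5L, 8L),
                    n_varied_dims = 1:3), seed = 8)
  for (t in plan$trials) {
    hits <- sum(t$stimuli[[t$rewarded_dim]] == t$rewarded_value)
    expect_equal(hits, 1L)
  }
})

test_that("run_trial classifies outcomes and rewards soundly", {
  plan <- generate_search_session(
    search_config(n_runs = 1L, n_test = 5L), seed = 2)
  spec <- plan$trials[[15]]
  attr(spec, "space") <- plan$space
  # fixed-choice stub agents
  pick <- function(idx, rt = 1) {
    structure(list(idx = idx, rt = rt), class = "stub_agent")
  }
  registerS3method("respond", "stub_agent",
                   function(agent, spec) list(choice = agent$idx, rt = agent$rt),
                   envir = asNamespace("kiosksim"))
  res <- run_trial(spec, pick(spec$target_index))
  expect_equal(res$outcome, "correct")
  expect_true(res$rewarded)
  expect_equal(res$reaction_time_s, 1)
  wrong <- setdiff(seq_len(nrow(spec$stimuli)), spec$target_index)[1]
  res <- run_trial(spec, pick(wrong))
  expect_equal(res$outcome, "incorrect")
  expect_false(res$rewarded)
  res <- run_trial(spec, pick(NA_integer_))
  expect_equal(res$outcome, "timeout")
  expect_equal(res$reaction_time_s, spec$timing$response_window_s)
  expect_error(run_trial(spec, pick(99L)), "out of")
  expect_error(run_trial(spec, pick(1L, rt = -1)), "invalid RT")
})

test_that("choosing the fully neutral object aborts the trial", {
  fs <- default_feature_space()
  stim <- rbind(
    as.data.frame(as.list(neutral_object(fs)), stringsAsFactors = FALSE),
    within(as.data.frame(as.list(neutral_object(fs)),
                         stringsAsFactors = FALSE), color <- "red"))
  spec <- structure(list(
    task_kind = "learning", block_id = 1L, trial_index = 1L,
    stimuli = stim, positions = data.frame(x = c(0, 1), y = c(0, 1)),
    target_index = NA_integer_, rewarded_dim = "color",
    rewarded_value = "red", set_size = NA_integer_,
    varied_dims = "color", timing = trial_timing(), delay_s = 0.4),
    class = "trial_spec")
  attr(spec, "space") <- fs
  pick1 <- structure(list(), class = "pick_first")
  registerS3method("respond", "pick_first",
                   function(agent, spec) list(choice = 1L, rt = 0.5),
                   envir = asNamespace("kiosksim"))
  res <- run_trial(spec, pick1)
  expect_equal(res$outcome, "abort_neutral")
  expect_false(res$rewarded)
  # with the rule disabled the same choice is just incorrect
  expect_equal(run_trial(spec, pick1, abort_on_neutral = FALSE)$outcome,
               "incorrect")
})

test_that("run_session conserves trials and rewards are sound", {
  plan <- generate_search_session(
    search_config(n_runs = 1L, n_test = 40L), seed = 21)
  set.seed(1)
  log <- run_session(plan, rt_agent(lapse_rate = 0.1))
  expect_equal(nrow(log), length(plan$trials))
  levels <- c("correct", "incorrect", "abort_neutral", "timeout",
              "broken_hold")
  expect_equal(sum(table(factor(log$outcome, levels))), nrow(log))
  # reward soundness against an independent scan of the arrays
  for (i in seq_len(nrow(log))) {
    spec <- plan$trials[[i]]
    ch <- log$chosen_index[i]
    if (is.na(ch)) { expect_false(log$rewarded[i]); next }
    is_target <- ch == spec$target_index
    expect_equal(log$rewarded[i], is_target)
    expect_equal(log$outcome[i] == "correct", is_target)
  }
  # omniscient agent: 100% correct and rewarded
  log2 <- run_session(generate_learning_session(
    learning_config(n_blocks = 3L, block_len_range = c(5L, 6L)), seed = 4),
    oracle_agent())
  expect_true(all(log2$outcome == "correct"))
  expect_true(all(log2$rewarded))
})

test_that("grid placement yields distinct in-bound positions", {
  g <- grid_config()
  set.seed(3)
  for (i in 1:20) {
    p <- place_on_grid(13, g, "grid")
    expect_equal(anyDuplicated(p), 0L)
    expect_true(all(abs(p$x) <= g$width_in / 2 & abs(p$y) <= g$height_in / 2))
  }
  # exhaustive draw returns every intersection exactly once
  all15 <- place_on_grid(15, g, "grid")
  expect_equal(nrow(unique(all15)), 15)
  expect_error(place_on_grid(16, g, "grid"), "only 15")
  # learning ring: all positions at the configured eccentricity
  p <- place_on_grid(3, g, "ring")
  expect_equal(sqrt(p$x^2 + p$y^2), rep(4.1, 3), tolerance = 0.01)
})

test_that("THR ladder promotes, demotes, clamps and flags touch-ready", {
  lad <- thr_ladder()
  s <- thr_state(lad, 3)
  up <- thr_next_level(s, rep(1, 10), lad)
  expect_equal(up$level, 4L)
  expect_lte(up$square_in, s$square_in)
  down <- thr_next_level(s, rep(0, 10), lad)
  expect_equal(down$level, 2L)
  expect_equal(thr_next_level(thr_state(lad, 1), rep(0, 10), lad)$level, 1L)
  top <- thr_state(lad, nrow(lad$levels))
  top2 <- thr_next_level(top, rep(1, 10), lad)
  expect_equal(top2$level, nrow(lad$levels))
  expect_true(top2$touch_ready)
  # lattice walk: level moves by at most one per update
  set.seed(6)
  s <- thr_state(lad, 4)
  for (i in 1:50) {
    nxt <- thr_next_level(s, stats::rbinom(10, 1, runif(1)), lad)
    expect_lte(abs(nxt$level - s$level), 1L)
    s <- nxt
  }
  expect_error(thr_ladder(square_in = numeric(0)), "empty")
  expect_error(thr_ladder(square_in = c(1, 2)), "non-increasing")
})

test_that("classify_touch names the contact failure modes", {
  b <- list(xmin = -1, xmax = 1, ymin = -1, ymax = 1)
  trace <- function(times, xs, ys, downs) {
    data.frame(t_ms = times, x = xs, y = ys, down = downs)
  }
  # 250 ms stationary hold inside bounds -> valid
  tr <- trace(c(0, 100, 250, 260), c(0, 0, 0, 0), c(0, 0, 0, 0),
              c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(classify_touch(tr, b), "valid")
  # 50 ms contact -> tap_too_short
  tr <- trace(c(0, 50), c(0, 0), c(0, 0), c(TRUE, FALSE))
  expect_equal(classify_touch(tr, b), "tap_too_short")
  # held 400 ms (within release window) -> hold_too_long
  tr <- trace(c(0, 400), c(0, 0), c(0, 0), c(TRUE, FALSE))
  expect_equal(classify_touch(tr, b), "hold_too_long")
  # released after 600 ms -> late_release
  tr <- trace(c(0, 600), c(0, 0), c(0, 0), c(TRUE, FALSE))
  expect_equal(classify_touch(tr, b), "late_release")
  # geometric containment oracle: any path leaving bounds + tol is a swipe
  set.seed(9)
  for (i in 1:50) {
    xs <- cumsum(c(0, stats::rnorm(5, 0, 0.6)))
    tr <- trace(seq(0, 250, length.out = 6), xs, rep(0, 6), rep(TRUE, 6))
    tr <- rbind(tr, data.frame(t_ms = 260, x = xs[6], y = 0, down = FALSE))
    leaves <- any(abs(xs) > 1 + 0.1)
    got <- classify_touch(tr, b)
    if (leaves) expect_equal(got, "swipe") else expect_false(got == "swipe")
  }
  # first contact outside bounds -> off_target
  tr <- trace(c(0, 250), c(5, 5), c(0, 0), c(TRUE, FALSE))
  expect_equal(classify_touch(tr, b), "off_target")
  expect_error(classify_touch(trace(c(10, 0), c(0, 0), c(0, 0),
                                    c(TRUE, FALSE)), b), "timestamps")
})
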