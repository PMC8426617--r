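LOG_SCHEMA_VERSION <- "1.0"

OUTCOME_LEVELS <- c("correct", "incorrect", "abort_neutral", "timeout",
                    "broken_hold")

# Flatten one (spec, result) pair into a single-row data.frame record.
trial_record <- function(spec, result, session_id, seed) {
  desc_str <- function(row) {
    if (is.null(row) || (length(row) == 1 && is.na(row))) return(NA_character_)
    paste(unlist(row), collapse = "|")
  }
  chosen <- if (is.na(result$chosen_index)) NA_character_ else
    desc_str(spec$stimuli[result$chosen_index, , drop = FALSE])
  target <- if (is.na(spec$target_index)) NA_character_ else
    desc_str(spec$stimuli[spec$target_index, , drop = FALSE])
  data.frame(
    schema_version = LOG_SCHEMA_VERSION,
    session_id = session_id,
    task_kind = spec$task_kind,
    block_id = spec$block_id,
    trial_index = spec$trial_index,
    set_size = spec$set_size,
    n_varied = if (length(spec$varied_dims)) length(spec$varied_dims) else
      NA_integer_,
    varied_dims = if (length(spec$varied_dims))
      paste(spec$varied_dims, collapse = "|") else NA_character_,
    target_descriptor = target,
    rewarded_dim = spec$rewarded_dim,
    rewarded_value = spec$rewarded_value,
    chosen_index = result$chosen_index,
    chosen_descriptor = chosen,
    outcome = result$outcome,
    reaction_time_s = result$reaction_time_s,
    rewarded = result$rewarded,
    delay_s = result$delay_s,
    timestamp_ordinal = spec$trial_index,
    seed_path = paste0(seed, "/", spec$block_id),
    stringsAsFactors = FALSE)
}

#' Open / close an append-only JSON-Lines log sink
#'
#' The trial log is newline-delimited JSON, one schema-stamped record per
#' trial, flushed to disk after every write so that an interrupted session
#' loses nothing beyond the trial in flight.
#'
#' @param path Log file path (created or appended to).
#' @param sink An open sink (for `close_log_sink` / [write_trial_record()]).
#' @return `open_log_sink`: a sink object of class `log_sink`.
#' @export
open_log_sink <- function(path) {
  con <- file(path, open = "a")
  structure(list(con = con, path = path), class = "log_sink")
}

#' @rdname open_log_sink
#' @export
close_log_sink <- function(sink) {
  close(sink$con)
  invisible(NULL)
}

#' Write one trial record to a sink
#'
#' Validates the record against the log schema, serializes it as a single
#' JSON line, and flushes. Errors never leave a partial record behind: the
#' line is only written after validation succeeds.
#'
#' @param sink A [open_log_sink()] sink.
#' @param record A one-row data.frame trial record.
#' @return The sink, invisibly.
#' @export
write_trial_record <- function(sink, record) {
  validate_record(record)
  line <- jsonlite::toJSON(as.list(record[1, , drop = FALSE]),
                           auto_unbox = TRUE, na = "null", digits = NA)
  writeLines(line, sink$con)
  flush(sink$con)
  invisible(sink)
}

validate_record <- function(record) {
  needed <- c("session_id", "task_kind", "trial_index", "outcome",
              "reaction_time_s", "rewarded")
  missing <- setdiff(needed, names(record))
  if (length(missing)) {
    stop("trial record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!record$outcome %in% OUTCOME_LEVELS) {
    stop(sprintf("invalid value '%s' in field 'outcome'", record$outcome),
         call. = FALSE)
  }
  invisible(record)
}

#' Read a JSON-Lines session log
#'
#' Parses and schema-validates every line. A truncated (unparseable) final
#' line — the signature of a crash mid-write — is tolerated: it is skipped
#' with a warning and the preceding complete records are returned. An
#' unparseable line anywhere else is an error.
#'
#' @param path Log file path.
#' @return Data.frame of trial records (class `session_log`).
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such log file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec)) {
      if (i == length(lines)) {
        warning(sprintf("truncated final line skipped in %s", path),
                call. = FALSE)
        recs[[i]] <- NULL
        break
      }
      stop(sprintf("corrupt record at line %d of %s", i, path), call. = FALSE)
    }
    rec <- lapply(rec, function(x) if (is.null(x)) NA else x)
    validate_record(as.data.frame(rec, stringsAsFactors = FALSE))
    recs[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- do.call(rbind, recs)
  class(out) <- c("session_log", class(out))
  out
}

#' Export a session log to CSV
#'
#' @param log A session log data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration file
#'
#' A run configuration is a JSON file naming the task kind, the session
#' parameters, the agent preset (or explicit parameters), and the seed. It
#' is validated before any simulation starts; unknown task kinds and
#' malformed fields fail fast with the offending field named.
#'
#' @param config A list as returned by `read_run_config`, or hand-built with
#'   fields `task` (`"search"` or `"learning"`), optional `agent` (preset
#'   name or list of parameters), optional `seed`, and optional overrides of
#'   [search_config()] / [learning_config()] arguments under `params`.
#' @param path File path.
#' @return `read_run_config`: validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$task) || !cfg$task %in% c("search", "learning")) {
    stop("config field 'task' must be \"search\" or \"learning\"",
         call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

build_session_config <- function(cfg) {
  params <- if (is.null(cfg$params)) list() else cfg$params
  if (cfg$task == "search") do.call(search_config, params)
  else do.call(learning_config, params)
}

build_agent <- function(cfg) {
  a <- cfg$agent
  if (is.null(a)) a <- "subject_2"
  if (is.character(a)) {
    pre <- agent_presets()
    row <- pre[pre$preset == a, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop(sprintf("unknown agent preset '%s'", a), call. = FALSE)
    }
    if (cfg$task == "search") {
      rt_agent(p_correct = row$p_correct, b0 = row$b0, b1 = row$b1,
               sigma = row$sigma, lapse_rate = row$lapse_rate)
    } else {
      rl_agent(alpha = row$alpha, beta = row$beta, rt_s = row$rl_rt_s)
    }
  } else {
    if (cfg$task == "search") do.call(rt_agent, a) else do.call(rl_agent, a)
  }
}

#' Command-line entry points
#'
#' Programmatic equivalents of the shipped CLI script
#' (`system.file("cli", "kiosksim", package = "kiosksim")`):
#' * `cli_simulate` — read a run configuration, generate the session plan,
#'   run the configured agent, and write the JSON-Lines trial log (and a CSV
#'   copy) into `out_dir`;
#' * `cli_analyze` — read a trial log and write per-session summary tables
#'   and a JSON profile report;
#' * `cli_report` — pool per-session summary JSONs into weekly aggregates.
#'
#' All three validate inputs before acting and signal classed errors; the
#' CLI script maps these to distinct non-zero exit codes. Simulation is
#' fully deterministic given `(config, seed)`.
#'
#' @param config_path Path to a run-config JSON ([read_run_config()]).
#' @param seed Master seed (overrides the config's seed if given).
#' @param out_dir Output directory (created if needed).
#' @param log_path Path of a trial log (for `cli_analyze`).
#' @param criterion,window Learning-criterion parameters.
#' @param summary_paths Character vector of `profile.json` paths, in session
#'   order (for `cli_report`).
#' @param sessions_per_week Group size for [weekly_aggregate()].
#' @return `cli_simulate`: the log path, invisibly. `cli_analyze` /
#'   `cli_report`: the profile/report path, invisibly.
#' @export
cli_simulate <- function(config_path, seed = NULL, out_dir = ".") {
  cfg <- read_run_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- if (!is.null(cfg$feature_space_file)) {
    read_feature_space(cfg$feature_space_file)
  } else default_feature_space()
  scfg <- build_session_config(cfg)
  plan <- if (cfg$task == "search") {
    generate_search_session(scfg, seed = cfg$seed, space = space)
  } else {
    generate_learning_session(scfg, seed = cfg$seed, space = space)
  }
  agent <- build_agent(cfg)
  set.seed(derive_seed(cfg$seed, 0L))
  log_path <- file.path(out_dir,
                        sprintf("%s_seed%d.jsonl", cfg$task, cfg$seed))
  if (file.exists(log_path)) file.remove(log_path)
  log <- run_session(plan, agent, sink = log_path,
                     session_id = sprintf("%s_%d", cfg$task, cfg$seed))
  write_log_csv(log, sub("\\.jsonl$", ".csv", log_path))
  invisible(log_path)
}

#' @rdname cli_simulate
#' @export
cli_analyze <- function(log_path, out_dir = ".", criterion = 0.70,
                        window = 10L) {
  log <- read_session_log(log_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  has_search <- any(log$task_kind == "search_test")
  has_learning <- any(log$task_kind == "learning")
  if (!has_search && !has_learning) {
    stop("no analyzable trials in log (classed: kiosksim_no_data)",
         call. = FALSE)
  }
  fit <- NULL; acc <- NULL; bs <- NULL
  if (has_search) {
    ss <- search_summary(log)
    fit <- fit_set_size_regression(ss)
    acc <- ss$accuracy
    utils::write.csv(ss$by_set_size,
                     file.path(out_dir, "search_by_set_size.csv"),
                     row.names = FALSE)
  }
  if (has_learning) {
    bs <- block_learning_summary(log, window = window, threshold = criterion)
    utils::write.csv(bs, file.path(out_dir, "block_summary.csv"),
                     row.names = FALSE)
  }
  rep <- profile_report(fit, acc, bs)
  path <- file.path(out_dir, "profile.json")
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname cli_simulate
#' @export
cli_report <- function(summary_paths, out_dir = ".",
                       sessions_per_week = 5L) {
  if (length(summary_paths) == 0L) stop("no summaries given", call. = FALSE)
  profs <- lapply(summary_paths, function(p)
    jsonlite::read_json(p, simplifyVector = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  slopes <- vapply(profs, function(p)
    if (!is.null(p$search)) p$search$slope_s_per_distractor else NA_real_,
    numeric(1))
  if (any(!is.na(slopes))) {
    out$slope_by_week <- weekly_aggregate(slopes[!is.na(slopes)],
                                          sessions_per_week)
  }
  ttcs <- vapply(profs, function(p) {
    if (is.null(p$learning)) return(NA_real_)
    m <- vapply(p$learning, function(l)
      as.numeric(l$mean_trials_to_criterion), numeric(1))
    mean(m, na.rm = TRUE)
  }, numeric(1))
  if (any(!is.na(ttcs))) {
    out$trials_to_criterion_by_week <-
      weekly_aggregate(ttcs[!is.na(ttcs)], sessions_per_week)
  }
  path <- file.path(out_dir, "weekly_report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
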