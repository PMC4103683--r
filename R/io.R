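#' Read and write dual-channel traces
#'
#' CSV with mandatory header `time_s,green,red,green_bg,red_bg`, comma
#' separated, `.` decimal. Malformed files are rejected with the offending
#' line number (header = line 1).
#'
#' @param path file path.
#' @return [read_trace()] returns a [dual_channel_trace()].
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "green", "red", "green_bg", "red_bg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!complete.cases(df[need]) |
                 Reduce(`|`, lapply(df[need], function(x) !is.finite(x))))
  if (length(bad))
    stop("non-numeric or missing values in ", path, " at line ",
         bad[1] + 1L, call. = FALSE)
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono))
    stop("time_s not strictly increasing in ", path, " at line ",
         nonmono[1] + 2L, call. = FALSE)
  dual_channel_trace(df$time_s, df$green, df$red, df$green_bg, df$red_bg)
}

#' @rdname read_trace
#' @param trace a [dual_channel_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read and write event logs
#'
#' JSON object mapping event names to arrays of times in seconds, e.g.
#' `{"insertion": [5.0], "retraction": [38.2]}`. An empty object is a valid
#' (eventless) log.
#'
#' @param path file path.
#' @return [read_events()] returns an [event_log()].
#' @export
read_events <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(ev) == 0) return(event_log())
  event_log(as.list(ev))
}

#' @rdname read_events
#' @param events an [event_log()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  jsonlite::write_json(lapply(unclass(events), as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read and write mating-trial tables
#'
#' Long-format CSV, one row per scored event, with header
#' `male_id,group,event,start_s,end_s,value`. `event` is one of `placed`,
#' `commence`, `vulva_contact`, `vulva_passes`, `insertion`, `sperm_release`,
#' `outcome`, `ectopic_protraction`, `progeny`. Interval events use
#' `start_s`/`end_s`; scalar scores use `value` (for `outcome`, the category
#' label; for `progeny`, the count for insertion index `start_s`).
#'
#' @param path file path.
#' @return [read_trials()] returns a `mating_trial_set`.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, colClasses = c(
    male_id = "character", group = "character", event = "character",
    start_s = "numeric", end_s = "numeric", value = "character"))
  need <- c("male_id", "group", "event", "start_s", "end_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trials <- lapply(split(df, df$male_id), .trial_from_rows)
  structure(unname(trials[unique(df$male_id)]), class = "mating_trial_set")
}

.trial_from_rows <- function(rows) {
  get_iv <- function(ev) {
    sel <- rows[rows$event == ev, , drop = FALSE]
    lapply(seq_len(nrow(sel)), function(i)
      c(sel$start_s[i], sel$end_s[i]))
  }
  rel <- get_iv("sperm_release")
  prog_rows <- rows[rows$event == "progeny", , drop = FALSE]
  progeny <- NULL
  if (nrow(prog_rows)) {
    progeny <- as.numeric(prog_rows$value)[order(prog_rows$start_s)]
  }
  out_row <- rows$value[rows$event == "outcome"]
  mating_trial(
    male_id = rows$male_id[1], group = rows$group[1],
    placed_s = if (any(rows$event == "placed"))
      rows$start_s[rows$event == "placed"][1] else 0,
    commence_s = rows$start_s[rows$event == "commence"],
    vulva_contacts = get_iv("vulva_contact"),
    vulva_passes = if (any(rows$event == "vulva_passes"))
      as.integer(rows$value[rows$event == "vulva_passes"][1]) else NA_integer_,
    insertions = get_iv("insertion"),
    sperm_release = if (length(rel)) rel[[1]] else NULL,
    outcome = if (length(out_row)) out_row[1] else "neither",
    ectopic_protraction = any(rows$event == "ectopic_protraction" &
                                rows$value == "TRUE"),
    progeny = progeny)
}

#' @rdname read_trials
#' @param trials a `mating_trial_set` or list of [mating_trial()] objects.
#' @export
write_trials <- function(trials, path) {
  rows <- do.call(rbind, lapply(trials, .trial_to_rows))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

.trial_to_rows <- function(tr) {
  row <- function(event, start_s = NA_real_, end_s = NA_real_, value = "")
    data.frame(male_id = tr$male_id, group = tr$group, event = event,
               start_s = start_s, end_s = end_s, value = value)
  out <- row("placed", tr$placed_s)
  for (cm in tr$commence_s) out <- rbind(out, row("commence", cm))
  for (v in tr$vulva_contacts)
    out <- rbind(out, row("vulva_contact", v[1], v[2]))
  if (!is.na(tr$vulva_passes))
    out <- rbind(out, row("vulva_passes", value = as.character(tr$vulva_passes)))
  for (v in tr$insertions) out <- rbind(out, row("insertion", v[1], v[2]))
  if (!is.null(tr$sperm_release))
    out <- rbind(out, row("sperm_release", tr$sperm_release[1],
                          tr$sperm_release[2]))
  out <- rbind(out, row("outcome", value = tr$outcome))
  if (tr$ectopic_protraction)
    out <- rbind(out, row("ectopic_protraction", value = "TRUE"))
  if (!is.null(tr$progeny))
    for (k in seq_along(tr$progeny))
      out <- rbind(out, row("progeny", start_s = k,
                            value = as.character(tr$progeny[k])))
  out
}

#' Pipeline configuration
#'
#' All tunable parameters of the trace pipeline in one round-trippable
#' object: sample interval, baseline-window rule, onset rule (`k` SDs
#' sustained for `m` samples), peak search and post-peak windows, refractory
#' bin boundaries, Mann-Whitney mode, and the master seed.
#'
#' @param dt_s sample interval (s).
#' @param f0_pre_insertion_s baseline window length before insertion (s).
#' @param onset_k,onset_m onset-detection parameters.
#' @param peak_window_s peak search window after insertion (s).
#' @param post_peak_window_s post-peak slope window (s).
#' @param refractory_bins_s numeric `c(lo, split, hi)` bin boundaries (s).
#' @param mw_mode Mann-Whitney mode.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dt_s = 0.05, f0_pre_insertion_s = 2,
                            onset_k = 2, onset_m = 3, peak_window_s = 30,
                            post_peak_window_s = 15,
                            refractory_bins_s = c(180, 540, 1800),
                            mw_mode = "auto", seed = 1) {
  if (any(c(dt_s, f0_pre_insertion_s, peak_window_s, post_peak_window_s) <= 0))
    stop("all windows must be positive", call. = FALSE)
  structure(list(dt_s = dt_s, f0_pre_insertion_s = f0_pre_insertion_s,
                 onset_k = onset_k, onset_m = onset_m,
                 peak_window_s = peak_window_s,
                 post_peak_window_s = post_peak_window_s,
                 refractory_bins_s = refractory_bins_s,
                 mw_mode = mw_mode, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path file path for the JSON representation.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full trace pipeline on a set of bouts
#'
#' For each bout: background subtraction, mDsRed bleach fit and correction,
#' ratiometric percent dF/F0 against the pre-insertion baseline, and
#' event-aligned kinetic feature extraction; then a cohort summary in the
#' shape of a transient-kinetics summary table. Deterministic given its inputs
#' and config.
#'
#' @param bouts list of `sim_bout` objects, or of lists with elements
#'   `trace` (a [dual_channel_trace()]) and `events` (an [event_log()]).
#' @param config a [pipeline_config()].
#' @param group cohort label for the summary row.
#' @param biphasic search for second rises.
#' @param out_dir optional directory: writes `features.csv`,
#'   `cohort_summary.csv` and `run_log.json` (config, seed, package version).
#' @return list with `features` (data frame, one row per bout), `summary`
#'   (one-row data frame), `config`.
#' @export
run_pipeline <- function(bouts, config = pipeline_config(),
                         group = "cohort", biphasic = FALSE, out_dir = NULL) {
  if (!length(bouts)) stop("empty input set", call. = FALSE)
  feats <- vector("list", length(bouts))
  for (i in seq_along(bouts)) {
    b <- bouts[[i]]
    feats[[i]] <- tryCatch(
      process_bout(b$trace, b$events, config, biphasic = biphasic),
      error = function(e)
        stop("pipeline failed on bout ", i, ": ", conditionMessage(e),
             call. = FALSE))
  }
  feat_df <- do.call(rbind, lapply(seq_along(feats), function(i)
    data.frame(bout = i, as.data.frame(unclass(feats[[i]])))))
  summ <- summarize_cohort(feats, group = group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(feat_df, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(summ, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("spicula")),
           n_bouts = length(bouts)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  list(features = feat_df, summary = summ, config = config)
}

#' Process one bout through the trace pipeline
#'
#' @param trace a raw [dual_channel_trace()].
#' @param events an [event_log()] with at least an `insertion` event.
#' @param config a [pipeline_config()].
#' @param biphasic search for a second rise.
#' @return a `kinetic_features` object.
#' @export
process_bout <- function(trace, events, config = pipeline_config(),
                         biphasic = FALSE) {
  sub <- subtract_background(trace)
  model <- fit_bleach_decay(sub$red, sub$time_s)
  ins <- events[["insertion"]][1]
  if (is.null(ins) || is.na(ins)) stop("no insertion event", call. = FALSE)
  dff <- ratiometric_dff(
    sub, model,
    f0_window = c(max(sub$time_s[1], ins - config$f0_pre_insertion_s), ins),
    events = events)
  extract_kinetics(dff, insertion_s = ins,
                   search_window_s = config$peak_window_s,
                   k = config$onset_k, m = config$onset_m,
                   biphasic = biphasic)
}
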