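#' A scored mating trial
#'
#' One male's hand-scored behavioral record for a mating assay: placement
#' time, commencement times, vulva contacts and passes, spicule insertions,
#' sperm release, outcome category and per-insertion progeny counts. All
#' times are seconds on the trial clock; intervals are half-open
#' `[start, end)` and durations are `end - start`.
#'
#' @param male_id,group identifiers.
#' @param placed_s time the male was placed on the mating lawn.
#' @param commence_s times backward locomotion along a mate commenced.
#' @param vulva_contacts list of `c(start_s, end_s)` vulva stays.
#' @param vulva_passes count of passes over the vulva without stopping.
#' @param insertions list of `c(insert_s, retract_s)` spicule insertions.
#' @param sperm_release optional `c(start_s, end_s)` sperm transfer interval.
#' @param outcome one of `"uterine_ejaculation"`, `"insert_no_ejaculation"`,
#'   `"ectopic_ejaculation"`, `"neither"`.
#' @param ectopic_protraction logical: spicules protruded before any insertion.
#' @param progeny optional numeric vector of progeny sired per insertion.
#' @return an object of class `mating_trial`.
#' @export
mating_trial <- function(male_id, group = "control", placed_s = 0,
                         commence_s = numeric(0), vulva_contacts = list(),
                         vulva_passes = NA_integer_, insertions = list(),
                         sperm_release = NULL,
                         outcome = c("uterine_ejaculation",
                                     "insert_no_ejaculation",
                                     "ectopic_ejaculation", "neither"),
                         ectopic_protraction = FALSE, progeny = NULL) {
  outcome <- match.arg(outcome)
  chk_iv <- function(iv, what) {
    for (v in iv) if (length(v) != 2 || v[2] < v[1])
      stop("malformed ", what, " interval", call. = FALSE)
    starts <- vapply(iv, `[`, numeric(1), 1)
    if (is.unsorted(starts)) stop(what, " intervals out of order", call. = FALSE)
  }
  chk_iv(vulva_contacts, "vulva contact")
  chk_iv(insertions, "insertion")
  if (!is.null(sperm_release) &&
      (length(sperm_release) != 2 || sperm_release[2] < sperm_release[1]))
    stop("malformed sperm_release interval", call. = FALSE)
  has_ins <- length(insertions) > 0
  has_rel <- !is.null(sperm_release)
  ok <- switch(outcome,
    uterine_ejaculation = has_ins && has_rel,
    insert_no_ejaculation = has_ins && !has_rel,
    ectopic_ejaculation = !has_ins,
    neither = !has_ins && !has_rel)
  if (!ok)
    stop("outcome '", outcome, "' inconsistent with recorded insertions/",
         "release", call. = FALSE)
  structure(list(male_id = male_id, group = group,
                 placed_s = unname(placed_s),
                 commence_s = unname(sort(commence_s)),
                 vulva_contacts = lapply(vulva_contacts, function(v)
                   unname(v[1:2])),
                 vulva_passes = vulva_passes,
                 insertions = lapply(insertions, function(v) unname(v[1:2])),
                 sperm_release = if (is.null(sperm_release)) NULL else
                   unname(sperm_release[1:2]),
                 outcome = outcome,
                 ectopic_protraction = isTRUE(ectopic_protraction),
                 progeny = if (is.null(progeny)) NULL else
                   unname(as.numeric(progeny))),
            class = "mating_trial")
}

first_insert_time <- function(trial) {
  if (!length(trial$insertions)) return(NA_real_)
  trial$insertions[[1]][1]
}

#' Sperm-transfer ranking
#'
#' Composite success score for a 5-minute mating opportunity. A male scores
#' 0 if he ejaculated into the uterus, 1 if he inserted without ejaculating,
#' 2 if he ejaculated ectopically without inserting, and 3 if he neither
#' inserted nor ejaculated; his time to insert (capped at `cap_s`) divided by
#' `cap_s` is added to that category. Males that never inserted contribute
#' the full `cap_s / cap_s = 1` time term (censored at the cap), so lower
#' scores mean faster, more complete sperm transfer.
#'
#' @param trial a [mating_trial()].
#' @param cap_s observation cap in seconds (default 300, i.e. 5 min).
#' @return numeric score in `[0, 4]`.
#' @export
rank_sperm_transfer <- function(trial, cap_s = 300) {
  stopifnot(inherits(trial, "mating_trial"))
  category <- switch(trial$outcome,
    uterine_ejaculation = 0, insert_no_ejaculation = 1,
    ectopic_ejaculation = 2, neither = 3)
  t_ins <- first_insert_time(trial)
  time_term <- if (is.na(t_ins)) 1 else
    min(t_ins - trial$placed_s, cap_s) / cap_s
  category + time_term
}

#' Refractory period
#'
#' The interval from a male's first spicule insertion to his second.
#'
#' @param trial a [mating_trial()].
#' @return seconds, or `NA` when fewer than two insertions were scored.
#' @export
refractory_period <- function(trial) {
  stopifnot(inherits(trial, "mating_trial"))
  if (length(trial$insertions) < 2) return(NA_real_)
  trial$insertions[[2]][1] - trial$insertions[[1]][1]
}

#' Mating drive metrics
#'
#' First commencement: time from placement on the lawn to first backward
#' locomotion along a mate. Second commencement: time from the first spicule
#' retraction to the next commencement.
#'
#' @param trial a [mating_trial()].
#' @return list with `first_commencement_s` and `second_commencement_s`
#'   (either may be `NA` when the defining events are missing).
#' @export
drive_metrics <- function(trial) {
  stopifnot(inherits(trial, "mating_trial"))
  first <- if (length(trial$commence_s))
    trial$commence_s[1] - trial$placed_s else NA_real_
  second <- NA_real_
  if (length(trial$insertions)) {
    retract1 <- trial$insertions[[1]][2]
    nxt <- trial$commence_s[trial$commence_s >= retract1]
    if (length(nxt)) second <- nxt[1] - retract1
  }
  list(first_commencement_s = first, second_commencement_s = second)
}

#' Vulva metrics
#'
#' Total time spent at the hermaphrodite vulva before the first insertion
#' (individual stays summed; a stay spanning the insertion is truncated at
#' it), and the number of vulva passes.
#'
#' @param trial a [mating_trial()].
#' @return list with `total_time_at_vulva_s` and `passes`.
#' @export
vulva_metrics <- function(trial) {
  stopifnot(inherits(trial, "mating_trial"))
  iv <- trial$vulva_contacts
  if (length(iv) > 1) {
    ends <- vapply(iv, `[`, numeric(1), 2)
    starts <- vapply(iv, `[`, numeric(1), 1)
    if (any(starts[-1] < ends[-length(ends)]))
      stop("overlapping vulva contacts", call. = FALSE)
  }
  cut_at <- first_insert_time(trial)
  total <- 0
  for (v in iv) {
    s <- v[1]; e <- v[2]
    if (!is.na(cut_at)) { if (s >= cut_at) next; e <- min(e, cut_at) }
    total <- total + (e - s)
  }
  list(total_time_at_vulva_s = total, passes = trial$vulva_passes)
}

#' Insertion metrics
#'
#' Duration of the first insertion; total inserted time within the 30 s
#' after the second insertion (operated males insert and retract repeatedly,
#' so inserted intervals are clipped to `[2nd insert, 2nd insert + 30 s]`
#' and summed); and counts of insertions and retractions in the 60 s after
#' the second insertion.
#'
#' @param trial a [mating_trial()].
#' @return list with `first_total_s`, `second_window_total_s`,
#'   `inserts_in_60s`, `retracts_in_60s` (NA where no second insertion).
#' @export
insertion_metrics <- function(trial) {
  stopifnot(inherits(trial, "mating_trial"))
  ins <- trial$insertions
  if (!length(ins))
    return(list(first_total_s = NA_real_, second_window_total_s = NA_real_,
                inserts_in_60s = NA_integer_, retracts_in_60s = NA_integer_))
  first_total <- ins[[1]][2] - ins[[1]][1]
  if (length(ins) < 2)
    return(list(first_total_s = first_total,
                second_window_total_s = NA_real_,
                inserts_in_60s = NA_integer_, retracts_in_60s = NA_integer_))
  t2 <- ins[[2]][1]
  w30 <- c(t2, t2 + 30)
  tot30 <- 0
  for (v in ins) {
    s <- max(v[1], w30[1]); e <- min(v[2], w30[2])
    if (e > s) tot30 <- tot30 + (e - s)
  }
  later <- ins[-(1:2)]
  starts <- vapply(later, `[`, numeric(1), 1)
  retracts <- vapply(ins[-1], `[`, numeric(1), 2)
  list(first_total_s = first_total,
       second_window_total_s = tot30,
       inserts_in_60s = sum(starts > t2 & starts <= t2 + 60),
       retracts_in_60s = sum(retracts > t2 & retracts <= t2 + 60))
}

#' Sustained sperm transfer
#'
#' Wild-type males transfer sperm for about 17 s; a male is classified as
#' showing wild-type (sustained) transfer when his release interval lasted
#' at least 10 s.
#'
#' @param trial a [mating_trial()].
#' @return logical.
#' @export
classify_sustained_transfer <- function(trial) {
  stopifnot(inherits(trial, "mating_trial"))
  if (is.null(trial$sperm_release)) return(FALSE)
  (trial$sperm_release[2] - trial$sperm_release[1]) >= 10
}

#' Bin males by refractory period
#'
#' Partition into a short-refractory group (re-copulated between 3 min and
#' 8 min 59 s after the first insertion) and a long-refractory group (9 to
#' 30 min), with the boundary as a half-open split at 540 s: short is
#' `[180, 540)`, long is `[540, 1800]`. Values outside `[180, 1800]` are
#' flagged `out_of_range`; undefined refractory periods are `NA`.
#'
#' @param trials a list of [mating_trial()] objects (or a
#'   `mating_trial_set`), or a numeric vector of refractory periods.
#' @return factor with levels `short`, `long`, `out_of_range`.
#' @export
bin_refractory <- function(trials) {
  rp <- if (is.numeric(trials)) trials else
    vapply(trials, refractory_period, numeric(1))
  out <- rep(NA_character_, length(rp))
  out[!is.na(rp) & rp >= 180 & rp < 540] <- "short"
  out[!is.na(rp) & rp >= 540 & rp <= 1800] <- "long"
  out[!is.na(rp) & (rp < 180 | rp > 1800)] <- "out_of_range"
  factor(out, levels = c("short", "long", "out_of_range"))
}

#' Mating potency by insertion index
#'
#' Fraction of males that sired progeny at each successive insertion
#' (progeny count > 0). Trials with no progeny record are excluded with a
#' warning.
#'
#' @param trials a list of [mating_trial()] objects.
#' @return named numeric vector, one entry per insertion index, with
#'   attribute `n` (males scored per index).
#' @export
potency <- function(trials) {
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  has <- vapply(trials, function(tr) !is.null(tr$progeny), logical(1))
  if (any(!has))
    warning(sum(!has), " trial(s) without progeny records excluded",
            call. = FALSE)
  trials <- trials[has]
  if (!length(trials)) stop("no trials with progeny records", call. = FALSE)
  kmax <- max(vapply(trials, function(tr) length(tr$progeny), integer(1)))
  frac <- numeric(kmax)
  n <- integer(kmax)
  for (k in seq_len(kmax)) {
    vals <- unlist(lapply(trials, function(tr)
      if (length(tr$progeny) >= k) tr$progeny[k] else NULL))
    n[k] <- length(vals)
    frac[k] <- mean(vals > 0)
  }
  names(frac) <- paste0("insertion_", seq_len(kmax))
  structure(frac, n = n)
}
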