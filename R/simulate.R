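#' Simulate one dual-channel calcium bout
#'
#' Generates a dual-channel ROI time series and its behavioral event log for a
#' single insertion-aligned mating bout, from a [make_preset()] kinetic
#' preset. The green channel carries the calcium transient,
#' `green(t) = background + F0g * (1 + transient(t)/100) + noise`;
#' the red reference channel bleaches mono-exponentially,
#' `red(t) = background + F0r * (floor + (1-floor) * exp(-t/tau)) * (1 + noise)`.
#' Noise is additive Gaussian, sd = `noise_sd`% of F0, independent per sample
#' and per channel. Background ROIs carry the same relative noise about
#' `background_level`.
#'
#' Per-bout ground truth (sampled latency, slope, amplitude, event times) is
#' attached as `$truth`, so recovery of every downstream statistic can be
#' checked against what the generator actually drew.
#'
#' @param preset a `kinetic_preset`.
#' @param insertion_time_s time of spicule insertion (s from recording start).
#' @param duration_s total recording length (s).
#' @param dt_s sample interval (s); default 0.05 (20 Hz).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return a list of class `sim_bout` with elements `trace`
#'   (a [dual_channel_trace()]), `events` (an [event_log()]) and `truth`.
#' @examples
#' b <- simulate_bout(make_preset("spc"), insertion_time_s = 5,
#'                    duration_s = 40, seed = 1)
#' b$truth$insertion_to_peak_s
#' @export
simulate_bout <- function(preset, insertion_time_s = 5, duration_s = 45,
                          dt_s = 0.05, seed = 1) {
  validate_preset(preset)
  if (dt_s <= 0) stop("dt_s must be positive", call. = FALSE)
  if (dt_s >= duration_s) stop("dt_s must be smaller than duration_s", call. = FALSE)
  if (insertion_time_s + preset$time_to_peak_s >= duration_s)
    stop("duration_s too short: transient peak at ",
         insertion_time_s + preset$time_to_peak_s,
         " s would fall outside the recording", call. = FALSE)

  with_seed(seed, {
    tt <- seq(0, duration_s, by = dt_s)
    n <- length(tt)

    ## --- draw per-bout kinetics (ground truth) -------------------------
    flat <- preset$peak_amplitude == 0
    rise_dur <- if (flat) preset$time_to_peak_s - preset$onset_delay_s else
      rlnorm_ms(1, preset$time_to_peak_s - preset$onset_delay_s,
                preset$time_to_peak_sd_s)
    slope <- if (flat) 0 else
      rlnorm_ms(1, preset$rise_slope, preset$rise_slope_sd)
    onset_t <- insertion_time_s + preset$onset_delay_s
    peak_t <- onset_t + rise_dur
    amp <- slope * rise_dur

    transient <- .transient_wave(tt, onset_t, peak_t, amp, preset$decay_rate,
                                 preset$rise_shape, preset$sustained_frac)

    truth <- list(
      onset_s = onset_t, peak_time_s = peak_t,
      insertion_to_peak_s = peak_t - insertion_time_s,
      rise_slope = slope, amplitude = amp, decay_rate = preset$decay_rate
    )

    ## --- behavioral events --------------------------------------------
    ev <- list(insertion = insertion_time_s)
    valve_t <- insertion_time_s +
      rlnorm_ms(1, preset$valve_open_delay[["mean"]],
                preset$valve_open_delay[["sd"]])
    rel_start <- insertion_time_s +
      rlnorm_ms(1, preset$release_start_delay[["mean"]],
                preset$release_start_delay[["sd"]])
    rel_end <- rel_start + rlnorm_ms(1, preset$release_duration[["mean"]],
                                     preset$release_duration[["sd"]])
    ev$valve_open <- min(valve_t, duration_s)
    ev$sperm_release_start <- min(rel_start, duration_s)
    ev$sperm_release_end <- min(rel_end, duration_s)
    ev$retraction <- min(rel_end + 2, duration_s)
    truth$valve_open_s <- ev$valve_open

    ## --- optional second rise ------------------------------------------
    if (!is.null(preset$second_rise)) {
      sr <- preset$second_rise
      sr_onset <- insertion_time_s + sr$onset_s
      sr_dur <- rlnorm_ms(1, sr$time_to_peak_s - sr$onset_s, sr$time_to_peak_sd_s)
      sr_slope <- rlnorm_ms(1, sr$slope, sr$slope_sd)
      sr_amp <- sr_slope * sr_dur
      transient <- transient + .transient_wave(
        tt, sr_onset, sr_onset + sr_dur, sr_amp, sr_slope / 2, "linear", 0)
      truth$second_rise <- list(
        onset_s = sr_onset, peak_time_s = sr_onset + sr_dur,
        insertion_to_peak_s = sr_onset + sr_dur - insertion_time_s,
        rise_slope = sr_slope, amplitude = sr_amp)
    }

    ## --- optional damped oscillation after a named event ----------------
    if (!is.null(preset$oscillation)) {
      osc <- preset$oscillation
      t0 <- ev[[osc$start_event]]
      if (!is.null(t0)) {
        rel <- tt - t0
        w <- rel >= 0
        transient[w] <- transient[w] + osc$amplitude *
          exp(-rel[w] / osc$damp_tau_s) * sin(2 * pi * rel[w] / osc$period_s)
      }
    }

    ## --- channels -------------------------------------------------------
    nz <- preset$noise_sd / 100
    bleach <- preset$red_bleach_floor +
      (1 - preset$red_bleach_floor) * exp(-tt / preset$red_bleach_tau_s)
    green <- preset$background_level +
      preset$f0_green * (1 + rnorm(n, 0, nz) + transient / 100)
    red <- preset$background_level +
      preset$f0_red * bleach * (1 + rnorm(n, 0, nz))
    green_bg <- preset$background_level * (1 + rnorm(n, 0, nz))
    red_bg <- preset$background_level * (1 + rnorm(n, 0, nz))

    trace <- dual_channel_trace(tt, green, red, green_bg, red_bg)
    structure(list(trace = trace, events = event_log(ev), truth = truth,
                   preset = preset$name, seed = seed),
              class = "sim_bout")
  })
}

# Piecewise transient: 0 before onset, rise (linear or smooth sigmoidal) to
# `amp` at `peak_t`, then linear decline at `decay` %/s down to
# `sustained_frac * amp`.
.transient_wave <- function(tt, onset_t, peak_t, amp, decay, rise_shape,
                            sustained_frac) {
  out <- numeric(length(tt))
  if (amp <= 0) return(out)
  dur <- peak_t - onset_t
  rising <- tt >= onset_t & tt < peak_t
  frac <- (tt[rising] - onset_t) / dur
  if (identical(rise_shape, "sigmoidal")) frac <- frac^2 * (3 - 2 * frac)
  out[rising] <- amp * frac
  after <- tt >= peak_t
  out[after] <- pmax(amp - decay * (tt[after] - peak_t), sustained_frac * amp)
  out
}

#' Simulate a cohort of calcium bouts
#'
#' Runs [simulate_bout()] `n` times with per-bout seeds drawn from the
#' master-seeded stream (so bout `i` is reproducible given the master seed
#' and `i`), and insertion times jittered uniformly over
#' `insertion_window_s`.
#'
#' @param preset a `kinetic_preset`.
#' @param n number of bouts (>= 1).
#' @param dt_s,duration_s as in [simulate_bout()].
#' @param seed master seed.
#' @param insertion_window_s length-2 numeric: insertion time drawn uniformly
#'   in this interval, per bout.
#' @return a list of `sim_bout` objects, with attribute `"seed"`.
#' @export
simulate_cohort <- function(preset, n, dt_s = 0.05, duration_s = 45,
                            seed = 1, insertion_window_s = c(4, 6)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  sub <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    ins = runif(n, insertion_window_s[1], insertion_window_s[2])))
  bouts <- lapply(seq_len(n), function(i)
    simulate_bout(preset, insertion_time_s = sub$ins[i],
                  duration_s = duration_s, dt_s = dt_s,
                  seed = sub$seeds[i]))
  attr(bouts, "seed") <- seed
  bouts
}

#' Simulate a 2x2 contingency outcome
#'
#' Draws successes for two groups from independent binomials and returns the
#' success/failure table, for exercising [fisher_exact()] on ablation-style
#' yes/no outcomes.
#'
#' @param n1,n2 group sizes (>= 1).
#' @param p1,p2 per-group success probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param labels length-2 character group labels.
#' @return a `contingency_2x2` (see [contingency_2x2()]).
#' @export
simulate_contingency <- function(n1, p1, n2, p2, seed = 1,
                                 labels = c("group1", "group2")) {
  if (n1 < 1 || n2 < 1) stop("group counts must be >= 1", call. = FALSE)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    s1 <- rbinom(1, n1, p1)
    s2 <- rbinom(1, n2, p2)
    contingency_2x2(s1, n1 - s1, s2, n2 - s2, labels = labels)
  })
}

#' Specify a simulated mating-trial population
#'
#' Parameter shell for [simulate_trials()]: group-level success probabilities
#' for insertion, valve opening and sperm release, plus lognormal
#' distributions (arithmetic mean/sd, seconds) for commencement latency,
#' insertion latency, refractory period and transfer duration. Defaults
#' emulate an intact wild-type cohort: commencement within ~34 s, first
#' insertion within ~2 min, a ~12 min (SD ~6.5 min) refractory period, and
#' ~17 s of sperm transfer.
#'
#' `progeny_rate` is the mean progeny count sired by a full first ejaculation;
#' at the second mating the rate scales with `min(1, refractory/720)`,
#' encoding sperm-stock recovery over the refractory period.
#'
#' @param group_label cohort label.
#' @param n_males number of males (>= 1).
#' @param p_insert,p_valve_open,p_release stage success probabilities.
#' @param commence_mean_s,commence_sd_s commencement latency (s).
#' @param insert_mean_s,insert_sd_s placement-to-first-insertion latency (s).
#' @param refractory_mean_s,refractory_sd_s first-to-second insertion (s).
#' @param transfer_mean_s,transfer_sd_s sperm transfer duration (s).
#' @param progeny_rate mean progeny per successful first ejaculation.
#' @param seed integer seed.
#' @return a list of class `trial_spec`.
#' @export
trial_spec <- function(group_label = "control", n_males = 20,
                       p_insert = 1, p_valve_open = 0.92, p_release = 0.71,
                       commence_mean_s = 34, commence_sd_s = 15,
                       insert_mean_s = 120, insert_sd_s = 60,
                       refractory_mean_s = 720, refractory_sd_s = 390,
                       transfer_mean_s = 17, transfer_sd_s = 4,
                       progeny_rate = 30, seed = 1) {
  if (any(c(p_insert, p_valve_open, p_release) < 0 |
          c(p_insert, p_valve_open, p_release) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_males < 1) stop("n_males must be >= 1", call. = FALSE)
  if (any(c(commence_mean_s, insert_mean_s, refractory_mean_s,
            transfer_mean_s) <= 0) ||
      any(c(commence_sd_s, insert_sd_s, refractory_sd_s, transfer_sd_s) < 0))
    stop("distribution means must be > 0 and sds >= 0", call. = FALSE)
  structure(as.list(environment()), class = "trial_spec")
}

#' Simulate a population of scored mating trials
#'
#' One [mating_trial()] per male: commencement and insertion latencies,
#' refractory period (males are given two insertion opportunities), transfer
#' duration, outcome category and per-insertion progeny counts, all sampled
#' from the [trial_spec()] distributions. Deterministic under the spec's seed.
#'
#' @param spec a [trial_spec()].
#' @return a list of `mating_trial` objects (class `mating_trial_set`).
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  sub_seeds <- derive_seeds(spec$seed, spec$n_males)
  trials <- lapply(seq_len(spec$n_males), function(i) {
    with_seed(sub_seeds[i], .simulate_one_trial(spec, i))
  })
  structure(trials, class = "mating_trial_set", group = spec$group_label)
}

.simulate_one_trial <- function(spec, i) {
  placed <- 0
  commence1 <- rlnorm_ms(1, spec$commence_mean_s, spec$commence_sd_s)
  inserted <- runif(1) < spec$p_insert
  insertions <- list()
  release <- NULL
  progeny <- numeric(0)
  outcome <- "neither"

  if (inserted) {
    ins1 <- commence1 + rlnorm_ms(1, spec$insert_mean_s, spec$insert_sd_s)
    dur1 <- rlnorm_ms(1, 94, 30)   # first insertions last ~94 s on average
    released <- runif(1) < spec$p_valve_open && runif(1) < spec$p_release
    if (released) {
      rel_start <- ins1 + rlnorm_ms(1, 15, 3)
      rel_dur <- rlnorm_ms(1, spec$transfer_mean_s, spec$transfer_sd_s)
      release <- c(start_s = rel_start, end_s = rel_start + rel_dur)
      outcome <- "uterine_ejaculation"
      progeny[1] <- rpois(1, spec$progeny_rate)
    } else {
      outcome <- "insert_no_ejaculation"
      progeny[1] <- 0
    }
    insertions[[1]] <- c(insert_s = ins1, retract_s = ins1 + dur1)
    # second opportunity after the refractory period
    rp <- rlnorm_ms(1, spec$refractory_mean_s, spec$refractory_sd_s)
    ins2 <- ins1 + rp
    commence <- commence1
    if (ins2 > ins1 + dur1) {
      dur2 <- rlnorm_ms(1, 40, 15)
      # re-commencement sits between first retraction and second insertion
      commence <- c(commence1,
                    ins1 + dur1 + 0.7 * (ins2 - ins1 - dur1))
      insertions[[2]] <- c(insert_s = ins2, retract_s = ins2 + dur2)
      # sperm stocks recover over the refractory period: both the odds of a
      # successful second release and the progeny count scale with rp/720
      recov <- min(1, rp / 720)
      released2 <- runif(1) < spec$p_valve_open * spec$p_release * recov
      progeny[2] <- if (released2)
        rpois(1, spec$progeny_rate * recov) else 0
    }
  } else {
    commence <- commence1
  }

  mating_trial(
    male_id = sprintf("%s_%03d", spec$group_label, i),
    group = spec$group_label,
    placed_s = placed,
    commence_s = commence,
    vulva_contacts = list(),
    vulva_passes = NA_integer_,
    insertions = insertions,
    sperm_release = release,
    outcome = outcome,
    ectopic_protraction = FALSE,
    progeny = if (length(progeny)) progeny else NULL
  )
}
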