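# Deterministic preset: no measurement noise, no per-bout kinetic
# variability. Used wherever an exact waveform is needed.
noiseless_preset <- function(name) {
  p <- make_preset(name)
  p$noise_sd <- 0
  p$time_to_peak_sd_s <- 0
  p$rise_slope_sd <- 0
  if (!is.null(p$second_rise)) {
    p$second_rise$time_to_peak_sd_s <- 0
    p$second_rise$slope_sd <- 0
  }
  p$valve_open_delay["sd"] <- 0
  p$release_start_delay["sd"] <- 0
  p$release_duration["sd"] <- 0
  p
}

# Plain dff_trace from a numeric series (baseline window = full series by
# default handled per test).
make_dff <- function(time_s, dff_percent, events = NULL) {
  structure(data.frame(time_s = time_s, dff_percent = dff_percent),
            f0 = 1, events = events,
            class = c("dff_trace", "data.frame"))
}

# Brute-force two-sided Fisher oracle: enumerate every admissible table with
# the observed margins, computing point probabilities from binomial
# coefficients directly (independent of dhyper).
fisher_bruteforce <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Full-permutation Mann-Whitney oracle (no ties): distribution of U over all
# assignments of the pooled values to sample 1.
mw_bruteforce <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(rk[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}
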