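trial_uterine <- function(ins = 150, release = c(165, 182), placed = 0,
                          progeny = c(25, 10)) {
  mating_trial("m1", placed_s = placed, commence_s = placed + 30,
               insertions = list(c(ins, ins + 94)),
               sperm_release = release, outcome = "uterine_ejaculation",
               progeny = progeny)
}

test_that("sperm-transfer ranking combines category and capped latency", {
  expect_equal(rank_sperm_transfer(trial_uterine(150)), 0.5)
  no_ejac <- mating_trial("m2", insertions = list(c(300, 320)),
                          outcome = "insert_no_ejaculation")
  expect_equal(rank_sperm_transfer(no_ejac), 2.0)
  neither <- mating_trial("m3", outcome = "neither")
  expect_equal(rank_sperm_transfer(neither), 4.0)
  ectopic <- mating_trial("m4", outcome = "ectopic_ejaculation")
  expect_equal(rank_sperm_transfer(ectopic), 3.0)
  # inconsistent outcome/evidence is rejected at construction
  expect_error(mating_trial("m5", outcome = "uterine_ejaculation"),
               "inconsistent")
  expect_error(mating_trial("m6", insertions = list(c(10, 20)),
                            outcome = "neither"), "inconsistent")
})

test_that("ranking is monotone in insertion time and category", {
  # fixed category: later insertion means strictly larger score
  s <- vapply(c(50, 100, 200, 299), function(t)
    rank_sperm_transfer(trial_uterine(t)), numeric(1))
  expect_true(all(diff(s) > 0))
  # category k at the cap scores below category k+1 at the cap
  at_cap_0 <- rank_sperm_transfer(trial_uterine(300))
  no_ejac_cap <- mating_trial("m", insertions = list(c(300, 310)),
                              outcome = "insert_no_ejaculation")
  expect_lt(at_cap_0, rank_sperm_transfer(no_ejac_cap))
  expect_lt(rank_sperm_transfer(no_ejac_cap), 3 + 1)
})

test_that("refractory period is the first-to-second insertion interval", {
  tr <- mating_trial("m", insertions = list(c(100, 150), c(820, 860)),
                     outcome = "insert_no_ejaculation")
  expect_equal(refractory_period(tr), 720)
  single <- mating_trial("m", insertions = list(c(100, 150)),
                         outcome = "insert_no_ejaculation")
  expect_true(is.na(refractory_period(single)))
})

test_that("simulated refractory periods match the generator median", {
  trs <- simulate_trials(trial_spec(n_males = 200, refractory_mean_s = 720,
                                    refractory_sd_s = 390, seed = 3))
  rp <- vapply(trs, refractory_period, numeric(1))
  gen_median <- 720 / sqrt(1 + (390 / 720)^2)   # lognormal closed form
  expect_lt(abs(median(rp, na.rm = TRUE) - gen_median) / gen_median, 0.10)
})

test_that("drive metrics split first and post-retraction commencement", {
  tr <- mating_trial("m", placed_s = 0, commence_s = c(34, 500),
                     insertions = list(c(100, 200)),
                     outcome = "insert_no_ejaculation")
  d <- drive_metrics(tr)
  expect_equal(d$first_commencement_s, 34)
  expect_equal(d$second_commencement_s, 300)
  no2 <- mating_trial("m", commence_s = 34,
                      insertions = list(c(100, 200)),
                      outcome = "insert_no_ejaculation")
  expect_true(is.na(drive_metrics(no2)$second_commencement_s))
})

test_that("vulva metrics sum pre-insertion stays and clip at insertion", {
  tr <- mating_trial("m", vulva_contacts = list(c(10, 20), c(30, 45)),
                     vulva_passes = 3L, insertions = list(c(60, 90)),
                     outcome = "insert_no_ejaculation")
  v <- vulva_metrics(tr)
  expect_equal(v$total_time_at_vulva_s, 25)
  expect_equal(v$passes, 3L)
  none <- mating_trial("m", outcome = "neither")
  expect_equal(vulva_metrics(none)$total_time_at_vulva_s, 0)
  spanning <- mating_trial("m", vulva_contacts = list(c(50, 80)),
                           insertions = list(c(60, 90)),
                           outcome = "insert_no_ejaculation")
  expect_equal(vulva_metrics(spanning)$total_time_at_vulva_s, 10)
  expect_error(
    vulva_metrics(mating_trial("m", vulva_contacts = list(c(1, 5), c(4, 8)),
                               outcome = "neither")), "overlapping")
})

test_that("insertion metrics handle repeated short insertions", {
  tr <- mating_trial("m", insertions = list(c(0, 94)),
                     outcome = "insert_no_ejaculation")
  expect_equal(insertion_metrics(tr)$first_total_s, 94)
  multi <- mating_trial("m", insertions = list(
    c(0, 94), c(200, 205), c(210, 215), c(222, 227), c(290, 295)),
    outcome = "insert_no_ejaculation")
  m <- insertion_metrics(multi)
  expect_equal(m$second_window_total_s, 15)   # 3 x 5 s inside [200, 230]
  expect_equal(m$inserts_in_60s, 2L)          # re-inserts at 210 and 222
  expect_equal(m$retracts_in_60s, 3L)         # retracts at 205, 215, 227
  cont <- mating_trial("m", insertions = list(c(0, 94), c(200, 400)),
                       outcome = "insert_no_ejaculation")
  expect_equal(insertion_metrics(cont)$second_window_total_s, 30)
})

test_that("sustained transfer uses the 10 s wild-type rule", {
  expect_true(classify_sustained_transfer(trial_uterine(10, c(30, 47))))
  expect_false(classify_sustained_transfer(trial_uterine(10, c(30, 39.9))))
  none <- mating_trial("m", insertions = list(c(1, 5)),
                       outcome = "insert_no_ejaculation")
  expect_false(classify_sustained_transfer(none))
})

test_that("refractory binning splits at 540 s half-open", {
  b <- bin_refractory(c(539, 540, 180, 1800, 2000, 100, NA))
  expect_equal(as.character(b),
               c("short", "long", "short", "long", "out_of_range",
                 "out_of_range", NA))
})

test_that("potency reports the progeny-siring fraction per insertion", {
  trs <- c(
    lapply(1:8, function(i) trial_uterine(progeny = c(20, 0))),
    lapply(1:4, function(i) trial_uterine(progeny = c(0, 5))))
  p <- potency(trs)
  expect_equal(unname(p["insertion_1"]), 8 / 12, tolerance = 1e-12)
  expect_equal(unname(p["insertion_2"]), 4 / 12, tolerance = 1e-12)
  zero <- lapply(1:3, function(i) trial_uterine(progeny = 0))
  expect_equal(unname(potency(zero)["insertion_1"]), 0)
  expect_error(potency(list()), "no trials")
  mixed <- c(trs[1:2], list(mating_trial("x", outcome = "neither")))
  expect_warning(potency(mixed), "without progeny")
})

test_that("interval metrics are invariant under a global time shift", {
  base <- mating_trial("m", placed_s = 0, commence_s = c(34, 500),
                       vulva_contacts = list(c(40, 60)),
                       insertions = list(c(100, 194), c(820, 860)),
                       sperm_release = c(110, 130),
                       outcome = "uterine_ejaculation")
  shift <- 1000
  shifted <- mating_trial("m", placed_s = shift,
                          commence_s = c(34, 500) + shift,
                          vulva_contacts = list(c(40, 60) + shift),
                          insertions = list(c(100, 194) + shift,
                                            c(820, 860) + shift),
                          sperm_release = c(110, 130) + shift,
                          outcome = "uterine_ejaculation")
  expect_equal(refractory_period(base), refractory_period(shifted))
  expect_equal(drive_metrics(base), drive_metrics(shifted))
  expect_equal(vulva_metrics(base), vulva_metrics(shifted))
  expect_equal(insertion_metrics(base), insertion_metrics(shifted))
  expect_equal(rank_sperm_transfer(base), rank_sperm_transfer(shifted))
})

test_that("longer refractory periods buy more second-mating progeny", {
  # pooled over seeds: males binned long sire progeny at the 2nd insertion
  # more often than males binned short
  short_hits <- short_n <- long_hits <- long_n <- 0
  for (s in 1:30) {
    trs <- simulate_trials(trial_spec(n_males = 20, refractory_mean_s = 540,
                                      refractory_sd_s = 250, seed = s))
    bins <- bin_refractory(trs)
    p2 <- vapply(trs, function(tr)
      if (length(tr$progeny) >= 2) as.numeric(tr$progeny[2] > 0)
      else NA_real_, numeric(1))
    ok <- !is.na(p2) & !is.na(bins)
    short_hits <- short_hits + sum(p2[ok & bins == "short"])
    short_n <- short_n + sum(ok & bins == "short")
    long_hits <- long_hits + sum(p2[ok & bins == "long"])
    long_n <- long_n + sum(ok & bins == "long")
  }
  expect_gt(long_hits / long_n, short_hits / short_n)
})
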