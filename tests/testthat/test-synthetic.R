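# Synthetic-data generator: determinism, conservation, schedule shape and
# stimulation-effect semantics.

test_that("planning and rendering are deterministic given the seed", {
  p <- gen_params(duration_s = 150)
  pl1 <- plan_session(p, 2, seed = 5)
  pl2 <- plan_session(p, 2, seed = 5)
  expect_identical(pl1$events, pl2$events)
  b1 <- generate_session(p, 2, seed = 5)
  b2 <- generate_session(p, 2, seed = 5)
  expect_identical(b1$lfp, b2$lfp)
  expect_identical(lapply(b1$units, `[[`, "spike_times_s"),
                   lapply(b2$units, `[[`, "spike_times_s"))
  b3 <- generate_session(p, 2, seed = 6)
  expect_false(identical(b1$lfp, b3$lfp))
})

test_that("coupling draws are conserved and links are bijective", {
  p <- gen_params(duration_s = 600, p_couple = 1, hc_ied_rate_min = 6)
  pl <- plan_session(p, 1, seed = 9)
  ev <- pl$events
  n_hc <- sum(ev$origin == "hc_ied")
  expect_gt(n_hc, 20)
  expect_equal(sum(ev$origin == "coupled_down"), n_hc)
  expect_equal(sum(ev$origin == "coupled_spindle"), n_hc)
  # each coupled pair links to a distinct existing hippocampal IED
  hc_ids <- ev$id[ev$origin == "hc_ied"]
  for (orig in c("coupled_down", "coupled_spindle")) {
    links <- ev$link[ev$origin == orig]
    expect_true(all(links %in% hc_ids))
    expect_false(anyDuplicated(links) > 0)
  }
  # no IEDs at zero rates
  p0 <- gen_params(duration_s = 300, hc_ied_rate_min = 0,
                   ind_mpfc_rate_min = 0)
  expect_equal(sum(plan_session(p0, 1, 1)$events$kind == "IED"), 0)
})

test_that("injected amplitudes respect the configured range and SNR", {
  b <- fixture_short()
  ev <- b$ground_truth$events
  amps <- ev$amplitude_uv[ev$origin == "hc_ied"]
  expect_true(all(amps >= 500 & amps <= 2500))
  expect_gt(b$ground_truth$snr_peak_over_sd, 5)
})

test_that("kindling schedules are deterministic with the documented shape", {
  s1 <- make_kindling_schedule("KINDLED_ONLY", 20, seed = 3)
  s2 <- make_kindling_schedule("KINDLED_ONLY", 20, seed = 3)
  expect_identical(s1, s2)
  pc <- vapply(s1$days, function(d) d$overrides$p_couple, 0)
  expect_gt(pc[5], pc[18])
  expect_equal(pc[1], 0.7)
  expect_equal(pc[20], 0.2)
  rate <- vapply(s1$days, function(d) d$overrides$hc_ied_rate_min, 0)
  expect_true(all(diff(rate) > 0))
  expect_gt(rate[10] / rate[1], 3)
  # one-day schedule: baseline-like, no independent cortical IEDs yet
  sch1 <- make_kindling_schedule("KINDLED_ONLY", 1, seed = 1,
                                 duration_s = 150)
  co <- generate_cohort(sch1)
  expect_length(co, 1)
  expect_equal(sum(co[[1]]$ground_truth$events$origin == "ind_ied"), 0)
})

test_that("cohorts reproduce and hippocampal burden rises across kindling", {
  sch <- make_kindling_schedule("KINDLED_ONLY", 3, seed = 4,
                                duration_s = 150)
  c1 <- generate_cohort(sch)
  c2 <- generate_cohort(sch)
  expect_identical(c1[[2]]$ground_truth$events, c2[[2]]$ground_truth$events)
  expect_equal(vapply(c1, function(b) b$meta$day_index, 0L), 1:3)
  # day-15 vs day-2 HC IED counts compared across 5 seeds (plan level)
  n_at_day <- function(day, seed) {
    sch <- make_kindling_schedule("KINDLED_ONLY", day, seed,
                                  duration_s = 600)
    ov <- sch$days[[day]]$overrides
    pl <- plan_session(do.call(gen_params, ov), day, derive_seed(seed, day))
    sum(pl$events$origin == "hc_ied")
  }
  wins <- vapply(1:5, function(s) n_at_day(15, s) > n_at_day(2, s), TRUE)
  expect_true(all(wins))
})

test_that("stimulation cancels coupled responses with probability p_eff", {
  p <- gen_params(duration_s = 600, p_couple = 1, hc_ied_rate_min = 6)
  pl <- plan_session(p, 1, seed = 31)
  hc_t <- pl$events$t_peak_s[pl$events$origin == "hc_ied"]
  # p_eff = 1, stimulation at every IED -> all coupled responses cancelled
  pl1 <- attach_stim_effect(pl, hc_t + 0.02, p_eff = 1)
  expect_equal(sum(pl1$events$origin == "coupled_spindle" &
                     pl1$events$cancelled == 0L), 0)
  # p_eff = 0 -> identical surviving injections
  pl0 <- attach_stim_effect(pl, hc_t + 0.02, p_eff = 0)
  expect_identical(pl0$events$cancelled, pl$events$cancelled)
  # p_eff = 0.5 -> binomial survival within 3 SD
  pl5 <- attach_stim_effect(pl, hc_t + 0.02, p_eff = 0.5)
  n <- sum(pl$events$origin == "coupled_spindle")
  surv <- sum(pl5$events$origin == "coupled_spindle" &
                pl5$events$cancelled == 0L)
  expect_lt(abs(surv - 0.5 * n), 3 * sqrt(n * 0.25) + 1)
  # stimulation beyond the session end is ignored with a warning
  expect_warning(attach_stim_effect(pl, c(hc_t[1] + 0.02, 1e5), 1),
                 "beyond")
})

test_that("cancellation only affects planned activity after stimulation", {
  p <- gen_params(duration_s = 300, p_couple = 1)
  pl <- plan_session(p, 1, seed = 15)
  hc_t <- pl$events$t_peak_s[pl$events$origin == "hc_ied"]
  # stimulation placed long after each IED cancels nothing
  pl_late <- attach_stim_effect(pl, hc_t + 1.0, p_eff = 1)
  expect_equal(sum(pl_late$events$cancelled), 0)
})

test_that("flat cohorts show no systematic detected-rate trend", {
  # scaled down (10 seeds x 8 days x 4 min sessions); the criterion is
  # >= 80% of seeds without a Mann-Kendall trend at alpha = 0.05
  flat_trend <- function(seed) {
    rates <- vapply(1:8, function(d) {
      b <- generate_session(gen_params(duration_s = 240), d,
                            derive_seed(seed, d))
      occurrence_rate(detect_ied(b, "HC"), b$states)
    }, 0)
    mann_kendall(rates)$p
  }
  ps <- vapply(1:10, flat_trend, 0)
  expect_gte(mean(ps > 0.05), 0.8)
})
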