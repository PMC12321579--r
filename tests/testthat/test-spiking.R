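# Spiking analysis: population rate, peri-event modulation (statistic,
# exclusion rule, calibration), categorization and correlations.

test_that("population rate is mass-conserving and correctly normalized", {
  set.seed(20)
  dur <- 400
  u <- spike_unit("u1", "MPFC", "PYR", sort(runif(10 * dur, 0, dur)))
  pr <- population_rate(list(u), dur)
  interior <- pr$times_s > 2 & pr$times_s < dur - 2
  expect_equal(mean(pr$rate_hz[interior]), 10, tolerance = 0.5)
  expect_equal(sum(pr$rate_hz) * pr$bin_s, length(u$spike_times_s),
               tolerance = 0.001 * length(u$spike_times_s))
  st <- state_intervals(0, dur, "NREM")
  prn <- population_rate(list(u), dur, normalize = TRUE, states = st)
  expect_equal(mean(prn$rate_hz[in_intervals(prn$times_s, st)]), 1,
               tolerance = 1e-6)
  expect_error(population_rate(list(), dur), "at least one")
  expect_warning(population_rate(list(spike_unit("e", "MPFC", "PYR",
                                                 numeric(0))), 10),
                 "no spikes")
})

test_that("peri-event modulation detects gain and respects exclusion", {
  set.seed(4)
  dur <- 600
  ev <- sort(runif(100, 5, dur - 5))
  base <- sort(runif(rpois(1, 5 * dur), 0, dur))
  extra <- unlist(lapply(ev, function(t) {
    t + runif(rpois(1, 4 * 5 * 0.05), 0, 0.05)
  }))
  u <- spike_unit("u1", "MPFC", "PYR", sort(unique(c(base, extra))))
  r <- peri_event_modulation(u, ev, dur, n_perm = 500, seed = 7)
  expect_true(r$significant)
  expect_lt(r$p_value, 0.05)
  expect_gte(r$ifr_peak_norm, 3.5)
  expect_lte(r$ifr_peak_norm, 6.5)
  expect_gte(r$latency_s, 0)
  expect_lte(r$latency_s, 0.08)
  r19 <- peri_event_modulation(u, ev[1:19], dur)
  expect_true(r19$excluded)
  expect_true(is.na(r19$significant))
  # events at the session edge are dropped with a warning
  expect_warning(peri_event_modulation(u, c(1, ev), dur), "edge")
})

test_that("the permutation test is calibrated under the null", {
  # reduced replicate count; acceptance runs the 200-seed version
  rej <- vapply(1:60, function(s) {
    set.seed(s)
    dur <- 400
    u <- spike_unit("x", "MPFC", "PYR", sort(runif(rpois(1, 5 * dur),
                                                   0, dur)))
    ee <- sort(runif(100, 5, dur - 5))
    peri_event_modulation(u, ee, dur, n_perm = 199,
                          seed = s + 1000)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.12)
})

test_that("modulation categories form a true partition", {
  mk <- function(id, sig_i, sig_d, sig_u) {
    mr <- function(sig) {
      structure(list(unit_id = id, significant = sig, excluded = FALSE,
                     ifr_peak_norm = 2, p_value = 0.01),
                class = "modulation_result")
    }
    list(i = mr(sig_i), d = mr(sig_d), u = mr(sig_u))
  }
  units <- list(mk("a", TRUE, FALSE, FALSE), mk("b", TRUE, TRUE, FALSE),
                mk("c", TRUE, TRUE, TRUE), mk("d", FALSE, TRUE, TRUE),
                mk("e", FALSE, FALSE, FALSE))
  cat3 <- categorize_modulation(lapply(units, `[[`, "i"),
                                lapply(units, `[[`, "d"),
                                lapply(units, `[[`, "u"))
  expect_equal(unname(cat3$categories),
               c("IED only", "IED+DOWN", "IED+DOWN+UP", "DOWN+UP only",
                 "unmodulated"))
  expect_equal(cat3$n_modulated, 4)
  expect_equal(sum(cat3$proportions), 1, tolerance = 1e-9)
  expect_error(categorize_modulation(lapply(units[1:4], `[[`, "i"),
                                     lapply(units, `[[`, "d"),
                                     lapply(units, `[[`, "u")),
               "same units")
  expect_equal(modulated_percentage(617, 2733), 100 * 617 / 2733)
})

test_that("transition windows quantify suppression and rebound", {
  # constructed normalized population rate: baseline 1, a DOWN dip to 0.1
  # at 10-10.3 s, and a 2x rebound for 0.5 s after the peak
  bin <- 0.001
  n <- 20000
  rate <- rep(1, n)
  rate[10000:10300] <- 0.1
  rate[10150:10650] <- c(rep(0.1, 151), rep(2, 350))
  pop <- list(rate_hz = rate, times_s = (seq_len(n) - 0.5) * bin,
              bin_s = bin)
  downs <- data.frame(t_start = 10.0, t_peak = 10.15, t_end = 10.3,
                      z_peak = 2.5, z_end = -2, mua_validated = TRUE,
                      pathological = TRUE)
  tw <- transition_firing_windows(pop, downs)
  expect_equal(tw$up_pre, 1, tolerance = 0.01)
  expect_equal(tw$down_min, 0.1, tolerance = 0.01)
  expect_equal(tw$up_post, (0.1 * 150 + 2 * 350) / 500, tolerance = 0.05)
  expect_gt(tw$up_post, tw$up_pre)
  expect_equal(nrow(transition_firing_windows(pop, downs[0, ])), 0)
  # transitions too close to the session end are dropped
  late <- downs
  late$t_start <- 19.8; late$t_peak <- 19.9; late$t_end <- 19.95
  expect_equal(nrow(transition_firing_windows(pop, late)), 0)
})

test_that("pathological transitions carry suppressed DOWNs and hot UPs", {
  fx <- fixture_recovery()
  b <- fx$bundle
  pop <- population_rate(b$units, session_duration(b), normalize = TRUE,
                         states = b$states)
  tw <- transition_firing_windows(pop, fx$downs[fx$downs$mua_validated %in%
                                                  TRUE, ])
  expect_gt(nrow(tw), 10)
  expect_lt(mean(tw$down_min), 0.5)
  if (sum(tw$pathological) >= 5 && sum(!tw$pathological) >= 5) {
    wt <- stats::wilcox.test(tw$up_post[tw$pathological],
                             tw$up_post[!tw$pathological],
                             alternative = "greater")
    expect_lt(wt$p.value, 0.05)
  }
})

test_that("modulation correlation is exact on identical inputs and null", {
  mk <- function(id, v) {
    structure(list(unit_id = id, ifr_peak_norm = v, excluded = FALSE),
              class = "modulation_result")
  }
  a <- lapply(1:30, function(i) mk(paste0("u", i), i + runif(1)))
  expect_equal(modulation_correlation(a, a)$rho, 1)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    x <- lapply(1:200, function(i) mk(paste0("u", i), rnorm(1)))
    y <- lapply(1:200, function(i) mk(paste0("u", i), rnorm(1)))
    modulation_correlation(x, y)$rho
  }, 0)
  expect_lt(mean(abs(rhos)), 0.15)
  expect_error(modulation_correlation(a[1:3], a[1:3]), "fewer than 5")
})

test_that("shared per-unit gains couple IED and independent-IED responses", {
  b <- generate_session(gen_params(duration_s = 1800, ind_mpfc_rate_min = 4,
                                   hc_ied_rate_min = 6),
                        10, seed = 77)
  gt <- b$ground_truth$events
  dur <- session_duration(b)
  hc_t <- gt$t_peak_s[gt$origin == "hc_ied"]
  ind_t <- gt$t_peak_s[gt$origin == "ind_ied"]
  ra <- suppressWarnings(
    lapply(b$units, peri_event_modulation, events = hc_t,
           duration_s = dur, states = b$states, n_perm = 99, seed = 5))
  rb <- suppressWarnings(
    lapply(b$units, peri_event_modulation, events = ind_t,
           duration_s = dur, states = b$states, n_perm = 99, seed = 6))
  mc <- modulation_correlation(ra, rb)
  expect_gt(mc$rho, 0.4)
  expect_lt(mc$p, 0.05)
})
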