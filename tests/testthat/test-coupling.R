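# Coupling statistics: CCG oracle equality, Poisson-bound calibration,
# modulation formula, independence classification, trajectory fits,
# composite score and Mann-Kendall.

brute_ccg <- function(ref, tgt, bin_s = 0.01, window_s = 1) {
  half <- round(window_s / bin_s)
  lag <- as.vector(outer(tgt, ref, `-`))
  k <- round(lag / bin_s) + half + 1
  k <- k[k >= 1 & k <= 2 * half + 1]
  tabulate(k, 2 * half + 1)
}

test_that("CCG counts equal the brute-force oracle bin for bin", {
  set.seed(10)
  ref <- sort(runif(300, 0, 500))
  tgt <- sort(runif(1000, 0, 500))
  cc <- ccg_convolution(ref, tgt)
  expect_equal(cc$counts, brute_ccg(ref, tgt))
  # conservation: total counts = pairs within the lag window
  lag <- as.vector(outer(tgt, ref, `-`))
  expect_equal(sum(cc$counts), sum(abs(lag) <= 1 + 0.005))
  # symmetry: ccg(ref, tgt) at +l equals ccg(tgt, ref) at -l
  cc_r <- ccg_convolution(tgt, ref)
  expect_equal(cc$counts, rev(cc_r$counts))
  # pointwise Poisson bounds bracket the baseline
  expect_true(all(cc$ci_low <= cc$baseline_b + 1e-9))
  expect_true(all(cc$baseline_b <= cc$ci_high + 1e-9))
  expect_error(ccg_convolution(numeric(0), tgt), "empty")
  expect_warning(ccg_convolution(ref[1:5], tgt), "reference")
})

test_that("a shifted train yields a single dominant significant peak", {
  set.seed(3)
  ref <- sort(runif(400, 0, 800))
  cc <- ccg_convolution(ref, sort(ref + 0.15))
  expect_equal(cc$lags_s[which.max(cc$counts)], 0.15)
  m <- coupling_modulation(cc, c(0.05, 0.3))
  expect_true(m$significant)
  expect_equal(m$lag_s, 0.15)
  expect_gt(m$M, 5)
})

test_that("coupling modulation follows the (a - b)/b formula", {
  fake <- structure(list(lags_s = seq(-0.1, 0.1, 0.01),
                         counts = rep(10, 21), baseline_b = rep(10, 21),
                         ci_low = rep(4, 21), ci_high = rep(17, 21),
                         bin_s = 0.01), class = "ccg_result")
  expect_equal(coupling_modulation(fake)$M, 0)   # a = b, nothing significant
  fake$counts[11] <- 20                          # a = 2b above the bound
  m <- coupling_modulation(fake)
  expect_equal(m$M, 1)
  expect_equal(m$a, 20)
  fake$baseline_b[] <- 0
  fake$ci_high[] <- 0
  expect_error(coupling_modulation(fake), "degenerate")
})

test_that("null CCGs stay inside the Poisson bounds at the nominal rate", {
  frac <- m_abs <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    r <- sort(runif(rpois(1, 0.2 * 7200), 0, 7200))
    t <- sort(runif(rpois(1, 0.2 * 7200), 0, 7200))
    cc <- ccg_convolution(r, t)
    frac[s] <- mean(cc$counts > cc$ci_high)
    # null M at the zero-lag bin (the literal reading; the widened peak
    # search is meant for jittered true couplings and pays an uncorrected
    # multiplicity cost under the null)
    m_abs[s] <- abs(coupling_modulation(cc, test_window_s = 0)$M)
  }
  expect_lte(mean(frac), 0.075)
  expect_lte(mean(m_abs), 0.2)
})

test_that("independence classification is exact on constructed mixtures", {
  ref <- seq(5, 995, by = 10)
  expect_equal(classify_independent(ref, ref)$fraction, 0)
  expect_equal(classify_independent(ref + 0.2, ref)$fraction, 1)
  # 30/70 mixture
  tgt <- sort(c(ref[1:70] + 0.05, seq(2000, 2990, by = 34)))
  expect_equal(classify_independent(tgt, ref)$fraction, 0.3)
  # piecewise-constant in the radius with breakpoints at event distances
  f1 <- classify_independent(ref + 0.2, ref, radius_s = 0.19)$fraction
  f2 <- classify_independent(ref + 0.2, ref, radius_s = 0.21)$fraction
  expect_equal(f1, 1)
  expect_equal(f2, 0)
})

test_that("independence matrix matches hand computation on a toy set", {
  soz <- c(10, 20, 30, 40)
  f2 <- c(10.05, 20.05, 100, 200)              # 2 of 4 co-occurring
  f3 <- c(300, 400, 500)                        # fully disjoint
  foci <- list(soz = soz, f2 = f2, f3 = f3)
  tab <- independence_matrix(foci, "soz")
  expect_equal(tab$independent_ratio[tab$focus == "soz"], 0)
  expect_equal(tab$independent_ratio[tab$focus == "f2"], 0.5)
  expect_equal(tab$independent_ratio[tab$focus == "f3"], 1)
  expect_error(independence_matrix(foci, "nope"), "unknown")
  expect_error(independence_matrix(foci["soz"], "soz"), "two foci")
})

test_that("occurrence rate counts events inside the requested state", {
  st <- state_intervals(c(0, 1800), c(1800, 3600), c("NREM", "WAKE"))
  ev <- seq(10, 1790, length.out = 60)
  expect_equal(occurrence_rate(ev, st), 2)
  expect_equal(occurrence_rate(numeric(0), st), 0)
  expect_equal(occurrence_rate(seq(1900, 3500, 100), st, "NREM"), 0)
  expect_error(occurrence_rate(ev, st, "REM"), "zero time")
})

test_that("cubic trajectory fits recover curves and compare them", {
  x <- 1:12
  y <- 2 + 0.5 * x - 0.2 * x^2 + 0.01 * x^3
  ft <- fit_occurrence_trajectories(list(a = y, b = y))
  expect_lt(ft$comparisons$F[1], 1e-6)
  expect_gt(ft$comparisons$p[1], 0.99)
  # noiseless cubic recovered exactly (in the standardized coordinate)
  fit <- ft$fits$a
  xs <- (x - mean(x)) / sd(x)
  expect_equal(unname(cbind(1, xs, xs^2, xs^3) %*% fit$coef)[, 1], y,
               tolerance = 1e-6)
  # genuinely different cubics are detected at alpha = 0.01
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    y1 <- 1 + 2 * x - 0.1 * x^2 + rnorm(12, sd = 0.5)
    y2 <- 8 - 1 * x + 0.15 * x^2 + rnorm(12, sd = 0.5)
    fit_occurrence_trajectories(list(a = y1, b = y2))$comparisons$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(fit_occurrence_trajectories(list(a = 1:5, b = 1:5)),
               "8 days")
})

test_that("composite responsiveness is the mean of session z-scores", {
  m <- data.frame(M_spindle = c(1, 2, 3), M_down = c(2, 4, 6),
                  mua_modulation = c(0, 1, 2))
  z <- composite_responsiveness(m)
  expect_equal(z[2], 0)
  expect_equal(z[3], -z[1])
  expect_equal(z[3], 1, tolerance = 1e-9)
  m$M_down <- 5
  expect_warning(z2 <- composite_responsiveness(m), "zero-variance")
  expect_equal(z2[2], 0)
  expect_error(composite_responsiveness(m[1:2, ]), "3 sessions")
})

test_that("Mann-Kendall matches exact enumeration and is calibrated", {
  r <- mann_kendall(1:10)
  expect_equal(r$tau, 1)
  expect_lt(r$p, 0.01)
  expect_equal(mann_kendall(rep(3, 5))$tau, 0)
  expect_error(mann_kendall(1:3), "at least 4")
  # exact small-n p against brute-force permutation enumeration (n = 6)
  s_stat <- function(x) {
    d <- outer(x, x, `-`)
    sum(sign(d[lower.tri(d)]))
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  allp <- perms(1:6)
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(6)
    s0 <- s_stat(x)
    p_exact <- mean(vapply(allp, function(p) abs(s_stat(x[p])) >= abs(s0),
                           TRUE))
    expect_equal(mann_kendall(x)$p, p_exact, tolerance = 1e-12)
  }
  # null calibration at n = 20 (reduced replicate count; the acceptance
  # suite runs the full 1000-seed version)
  rej <- vapply(1:300, function(s) {
    set.seed(s)
    mann_kendall(rnorm(20))$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("spindle-band power z-scores are centred on NREM background", {
  b <- fixture_short()
  nrem <- slice_by_state(b, "NREM")
  set.seed(5)
  starts <- runif(100, nrem$start_s[1], nrem$end_s[1] - 0.5)
  z <- spindle_band_power(b, "MPFC", data.frame(start_s = starts,
                                                end_s = starts + 0.5))
  expect_lt(abs(mean(z)), 0.25)
  # windows centred on injected spindles carry more band power
  gt <- b$ground_truth$events
  sp <- gt[gt$kind == "SPINDLE", ]
  zs <- spindle_band_power(b, "MPFC",
                           data.frame(start_s = sp$t_start_s,
                                      end_s = sp$t_start_s + 0.5))
  expect_gt(mean(zs), mean(z) + 0.5)
  expect_error(spindle_band_power(b, "MPFC",
                                  data.frame(start_s = 1, end_s = 1.1)),
               "0.25")
})

test_that("multitaper coherence has the correct limits", {
  set.seed(6)
  n <- 1250 * 420
  bun <- noise_bundle(rnorm(n), rnorm(n))
  c_id <- multitaper_coherence(bun, "hc1", "hc1", n_segments = 20, seed = 2)
  expect_lt(max(abs(c_id$coherence - 1)), 1e-6)
  c_in <- multitaper_coherence(bun, "hc1", "mpfc1", n_segments = 40,
                               seed = 2)
  expect_lt(mean(c_in$coherence), 0.2)
  # a shared narrowband component raises coherence at its frequency
  t <- (0:(n - 1)) / 1250
  sh <- 30 * sin(2 * pi * 10 * t)
  bun2 <- noise_bundle(rnorm(n, sd = 30) + sh, rnorm(n, sd = 30) + sh)
  c_sh <- multitaper_coherence(bun2, "hc1", "mpfc1", n_segments = 30,
                               seed = 2)
  at <- function(f) c_sh$coherence[which.min(abs(c_sh$freqs_hz - f))]
  expect_gt(at(10), at(40))
  # normalization by the 1-100 Hz mean
  c_nm <- multitaper_coherence(bun2, "hc1", "mpfc1", n_segments = 10,
                               seed = 2, normalize = "MEAN_1_100")
  expect_equal(mean(c_nm$coherence), 1, tolerance = 1e-9)
  expect_error(multitaper_coherence(noise_bundle(rnorm(1250 * 30),
                                                 rnorm(1250 * 30)),
                                    "hc1", "mpfc1"),
               "fewer than 5")
})
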