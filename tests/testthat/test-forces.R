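test_that("active force is 1 at the optimal length and follows the Ia=1 branch", {
  expect_identical(active_force(1, 1, 1), 1)
  expect_identical(active_force(0.25, 0.25, 1), 1)
  # direct evaluation oracle at 10% stretch
  expect_equal(active_force(1.1, 1, 1), exp(-2.727 * log(1.1)^2),
               tolerance = 1e-15)
  expect_equal(active_force(1.1, 1, 1), 0.9755313, tolerance = 1e-6)
  # symmetry of the parallel branch in log length
  for (lam in c(1.1, 1.3, 1.7))
    expect_equal(active_force(lam, 1, 1), active_force(1 / lam, 1, 1),
                 tolerance = 1e-12)
  expect_error(active_force(0, 1, 1), "positive")
  expect_error(active_force(1, 1, 0), "Ia")
  expect_error(active_force(1, 1, 1.2), "Ia")
})

test_that("both active-force branches are unimodal with maximum 1 at L0", {
  lam <- seq(0.5, 1.5, by = 0.01)
  for (Ia in c(0.1, 0.25, 0.5, 0.9, 1)) {
    f <- active_force(lam, 1, Ia)
    expect_true(all(f > 0 & f <= 1))
    peak <- which.max(f)
    expect_equal(lam[peak], 1)
    expect_equal(f[peak], 1, tolerance = 1e-12)
    # rises before the peak, falls after
    expect_true(all(diff(f[seq_len(peak)]) > 0))
    expect_true(all(diff(f[peak:length(f)]) < 0))
  }
})

test_that("passive force is an exponential of relative stretch", {
  # the exponent vanishes at the optimal length for any Ia
  for (Ia in c(0.2, 0.7, 1))
    expect_equal(passive_force(1, 1, Ia), 0.0195, tolerance = 1e-15)
  # direct evaluation oracle at 10% stretch, parallel muscle
  expect_equal(passive_force(1.1, 1, 1),
               0.0195 * exp((2.933 + 4.911) * 0.1), tolerance = 1e-12)
  expect_equal(passive_force(1.1, 1, 1), 0.0427263, tolerance = 1e-5)
  # strictly increasing in L on the stretch side
  lam <- seq(1, 1.6, by = 0.01)
  for (Ia in c(0.1, 0.5, 1))
    expect_true(all(diff(passive_force(lam, 1, Ia)) > 0))
  # larger architecture index stiffens the response beyond L0
  expect_gt(passive_force(1.2, 1, 0.9), passive_force(1.2, 1, 0.3))
})

test_that("cycle-offset shifting is circular and forward", {
  base <- cycle_waveform()
  p <- force_profile("toy", base, rep(0.01, 101))
  expect_equal(apply_cycle_offset(p, 0)$active, base)
  # a peak at 10% moves to 35% after a 25% shift
  peaked <- exp(-((0:100 - 10) / 5)^2)
  pp <- force_profile("toy", peaked, rep(0, 101))
  shifted <- apply_cycle_offset(pp, 25)
  expect_equal(which.max(shifted$active) - 1L, 35L)
  # passive is untouched; offset recorded
  expect_equal(shifted$passive, pp$passive)
  expect_equal(shifted$applied_offset_pct, 25)
  # circularity: a then 100 - a returns the original series
  rt <- apply_cycle_offset(apply_cycle_offset(p, 37), 63)
  expect_equal(rt$active[1:100], base[1:100], tolerance = 1e-12)
  expect_error(apply_cycle_offset(p, 100), "offset")
  expect_error(apply_cycle_offset(p, -1), "offset")
})

test_that("cycle-offset estimation recovers planted circular shifts", {
  base <- cycle_waveform()
  expect_equal(estimate_cycle_offset(base, base), 0)
  for (k in c(5, 20, 61, 99)) {
    shifted <- force_profile("toy", base, rep(0, 101))
    shifted <- apply_cycle_offset(shifted, k)
    expect_equal(estimate_cycle_offset(base, shifted$active), k)
    # round trip: applying the recovered offset aligns the peaks
    realigned <- apply_cycle_offset(
      force_profile("toy", base, rep(0, 101)),
      estimate_cycle_offset(base, shifted$active))
    expect_equal(which.max(realigned$active),
                 which.max(shifted$active))
  }
  expect_error(estimate_cycle_offset(rep(1, 101), base), "constant")
})

test_that("offset estimation tolerates noise at moderate SNR", {
  set.seed(101)
  base <- cycle_waveform()
  sig_sd <- stats::sd(base)
  for (k in c(10, 40, 80)) {
    clean <- apply_cycle_offset(force_profile("t", base, rep(0, 101)),
                                k)$active
    noisy <- clean + stats::rnorm(101, sd = sig_sd / sqrt(10))  # SNR 10
    rec <- estimate_cycle_offset(base, noisy)
    d <- min(abs(rec - k), 100 - abs(rec - k))
    expect_lte(d, 2)
  }
})

test_that("profile normalization divides by the maximum", {
  expect_equal(normalize_profile(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalize_profile(rep(3, 5)), rep(1, 5))
  v <- cycle_waveform()
  expect_equal(normalize_profile(normalize_profile(v)),
               normalize_profile(v))
  expect_error(normalize_profile(c(-2, -1)), "positive")
  expect_error(normalize_profile(rep(0, 4)), "positive")
})

test_that("the packaged cycle-offset table matches its column means", {
  tab <- cycle_offset_table()
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$muscle %in% c("Glut_Max1", "TFL", "Iliacus",
                                    "Pectineus", "Vas_Int", "Med_Gas",
                                    "Tib_Ant", "Tib_Post", "Soleus")))
  conds <- setdiff(names(tab), "muscle")
  expect_setequal(conds, c("esp_free", "esnd_rfast", "esnd_free",
                           "esnd_slow", "esnd_xslow"))
  for (cond in conds) {
    expect_true(all(tab[[cond]] >= 0 & tab[[cond]] < 100))
    expect_equal(mean_cycle_offset(tab, cond), mean(tab[[cond]]),
                 tolerance = 1e-12)
  }
  expect_equal(lookup_cycle_offset("Glut_Max1", "esnd_xslow"), 16.03)
  expect_error(mean_cycle_offset(tab, "sprint"), "condition")
  tab$esnd_free[3] <- NA
  expect_error(mean_cycle_offset(tab, "esnd_free"), "Iliacus")
})
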