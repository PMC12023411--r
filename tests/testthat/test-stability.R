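test_that("two-state signal hits midpoint, step limit and hand value", {
  p <- list(alpha_N = 2, beta_N = 0, alpha_D = 0.4, beta_D = 0,
            m_DN = 3 * RT25, u50 = 1.5, RT = RT25)
  expect_equal(two_state_signal(1.5, p), (2 + 0.4) / 2)
  # huge m-value gives a step between baselines
  ps <- utils::modifyList(p, list(m_DN = 1e6))
  expect_equal(two_state_signal(1.4, ps), 2)
  expect_equal(two_state_signal(1.6, ps), 0.4)
  # hand arithmetic: m/RT = 2 per M, u50 = 0.66, u = 1.16
  ph <- list(alpha_N = 1, beta_N = 0, alpha_D = 0, beta_D = 0,
             m_DN = 2 * RT25, u50 = 0.66, RT = RT25)
  expect_equal(two_state_signal(1.16, ph), 1 / (1 + 10), tolerance = 1e-10)
})

test_that("signals stay inside the baseline envelope; fraction folded is monotone", {
  u <- seq(0, 8, length.out = 100)
  p <- list(alpha_N = 1, beta_N = -0.02, alpha_D = 0.2, beta_D = 0.01,
            m_DN = 2.5 * RT25, u50 = 3, RT = RT25)
  s <- two_state_signal(u, p)
  top <- pmax(1 - 0.02 * u, 0.2 + 0.01 * u)
  bot <- pmin(1 - 0.02 * u, 0.2 + 0.01 * u)
  expect_true(all(s <= top + 1e-12 & s >= bot - 1e-12))
  expect_true(all(diff(two_state_fraction_folded(u, p)) <= 0))
  p3 <- list(alpha_N = 1, beta_N = 0, alpha_I = 0.5, beta_I = 0,
             alpha_D = 0, beta_D = 0, m_IN = 3 * RT25, m_DI = 3 * RT25,
             u50_I = 0.6, u50_D = 4, RT = RT25)
  s3 <- three_state_signal(u, p3)
  expect_true(all(s3 <= 1 + 1e-12 & s3 >= -1e-12))
})

test_that("three-state model reduces to two-state in the degenerate limit", {
  u <- seq(0, 8, length.out = 50)
  p2 <- list(alpha_N = 1, beta_N = 0.01, alpha_D = 0.1, beta_D = -0.005,
             m_DN = 2 * RT25, u50 = 0.66, RT = RT25)
  p3 <- list(alpha_N = 1, beta_N = 0.01, alpha_I = 0.1, beta_I = -0.005,
             alpha_D = 0.1, beta_D = -0.005, m_IN = 2 * RT25,
             m_DI = 2 * RT25, u50_I = 0.66, u50_D = 1e6, RT = RT25)
  expect_equal(three_state_signal(u, p3), two_state_signal(u, p2),
               tolerance = 1e-9)
  # native plateau and intermediate plateau with separated transitions
  p3b <- utils::modifyList(p3, list(alpha_I = 0.5, beta_I = 0, u50_D = 4,
                                    m_IN = 3 * RT25, m_DI = 3 * RT25,
                                    beta_N = 0))
  expect_equal(three_state_signal(0, p3b), 1, tolerance = 0.01)
  expect_equal(three_state_signal(2, p3b), 0.5, tolerance = 1e-3)
})

test_that("thermal signal is half-unfolded at tm and steps for huge dH", {
  p <- list(tm = 310, dH_vH = 1e5, aN = 1, bN = 0, aD = 0, bD = 0)
  expect_equal(thermal_signal(310, p), 0.5)
  pstep <- utils::modifyList(p, list(dH_vH = 1e9))
  expect_equal(thermal_signal(309.5, pstep), 1)
  expect_equal(thermal_signal(310.5, pstep), 0)
})

test_that("a remote second transition collapses the two-step model to one step", {
  T <- seq(280, 330, 0.5)
  p1 <- list(tm = 300, dH_vH = 9e4, aN = 1, bN = 0, aD = 0.3, bD = 0)
  p2 <- list(tm1 = 300, dH1 = 9e4, tm2 = 450, dH2 = 5e5,
             aN = 1, bN = 0, aI = 0.3, bI = 0, aD = -5, bD = 0)
  expect_equal(thermal_signal(T, p2, 2), thermal_signal(T, p1, 1),
               tolerance = 1e-9)
})

test_that("two-step thermal fit recovers both melting temperatures to 0.01 K", {
  th <- gen_thermal(2, params = list(tm1 = 296.45, tm2 = 307.15))
  f <- fit_thermal(th, init = list(tm1 = 295, dH1 = 7e4, tm2 = 308,
                                   dH2 = 1e5, aN = 1.05, bN = 0, aI = 0.55,
                                   bI = 0, aD = 0.05, bD = 0),
                   n_transitions = 2)
  expect_equal(coef(f)[["tm1"]], 296.45, tolerance = 0.01 / 296.45)
  expect_equal(coef(f)[["tm2"]], 307.15, tolerance = 0.01 / 307.15)
})

test_that("DSF inflection point matches the generating tm", {
  # symmetric baselines: the derivative extremum sits at tm
  dsf <- gen_thermal(1, preset = "ailac-dsf-ip",
                     temps = celsius_to_kelvin(seq(20, 60, by = 0.25)))
  ip <- dsf_inflection(dsf)
  expect_true(ip$transition)
  expect_equal(kelvin_to_celsius(ip$ip), 40.9, tolerance = 0.1 / 40.9)
  # increasing-ratio curves work too
  dsf_up <- gen_thermal(1, params = list(tm = celsius_to_kelvin(40.9),
                                         aN = 0, aD = 1),
                        temps = celsius_to_kelvin(seq(20, 60, by = 0.25)))
  ip_up <- dsf_inflection(dsf_up)
  expect_equal(kelvin_to_celsius(ip_up$ip), 40.9, tolerance = 0.1 / 40.9)
})

test_that("a linear scan yields a no-transition result, not an error", {
  T <- seq(290, 330, 0.5)
  flat <- titration_series(T, 0.2 + 0.001 * T)
  ip <- dsf_inflection(flat)
  expect_false(ip$transition)
  expect_true(is.na(ip$ip))
})

test_that("sigmoid midpoint fit recovers its own forward curve", {
  x <- 10^seq(-2, 1, length.out = 15)
  truth <- list(S_min = 0.1, S_max = 2, A50 = 0.8, S_f = 2.5)
  d <- titration_series(x, sigmoid_signal(x, truth))
  f <- sigmoid_midpoint_fit(d, "increasing")
  expect_equal(coef(f)[["A50"]], 0.8, tolerance = 1e-5)
  expect_equal(sigmoid_signal(truth$A50, truth), (0.1 + 2) / 2)
  # slope-factor sign flips monotonicity
  set.seed(7)
  for (i in 1:10) {
    p <- list(S_min = runif(1), S_max = 1 + runif(1), A50 = runif(1, .1, 5),
              S_f = runif(1, 0.5, 5))
    up <- sigmoid_signal(x, p)
    dn <- sigmoid_signal(x, utils::modifyList(p, list(S_f = -p$S_f)))
    expect_true(all(diff(up) > -1e-12))
    expect_true(all(diff(dn) < 1e-12))
  }
})

test_that("stabilization slopes are recovered exactly on noiseless lines", {
  conc <- c(0, 0.25, 0.5, 0.75, 1)
  for (sl in c(10.2, 6.15, 0)) {
    s <- stabilization_slope(titration_series(conc, 35 + sl * conc))
    expect_equal(s$slope, sl, tolerance = 1e-10)
  }
  expect_error(stabilization_slope(titration_series(c(0, 1), c(1, 2))),
               "3 points")
})

test_that("recovery fraction is a guarded percentage with propagation", {
  expect_equal(recovery_fraction(5, 5)$percent, 100)
  expect_equal(recovery_fraction(0, 5)$percent, 0)
  r <- recovery_fraction(15.1, 100, sigma_refolded = 0.6, sigma_native = 0)
  expect_equal(r$percent, 15.1)
  expect_equal(r$percent_se, 0.6, tolerance = 1e-6)
  expect_error(recovery_fraction(1, 0), "non-zero")
})

test_that("median midpoint error stays below 0.05 M across noisy replicates", {
  # 200 synthetic two-state curves, sigma = 2% of span, 25 points on 0-8 M
  errs <- vapply(1:200, function(i) {
    d <- gen_denaturation(2, params = list(u50 = 2.2, m_DN = 2.5 * RT25),
                          urea = seq(0, 8, length.out = 25),
                          noise_sd = 0.02, seed = 1000 + i)
    f <- fit_two_state(d, init = list(alpha_N = 0.9, alpha_D = 0.1,
                                      m_DN = 2 * RT25, u50 = 1.8),
                       fix = c(beta_N = 0, beta_D = 0))
    abs(coef(f)[["u50"]] - 2.2)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("decadic m-values convert to the natural-log convention", {
  expect_equal(m10_to_mln(1000), log(10))
})
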