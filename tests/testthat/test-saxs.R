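test_that("Debye scattering matches closed forms for one and two beads", {
  q <- seq(0.01, 0.6, length.out = 30)
  one <- bead_structure(matrix(c(0, 0, 0), 1), w = 2.5)
  expect_equal(debye_intensity(one, q, scale = 3, background = 0.1)$I,
               rep(3 * 2.5^2 + 0.1, 30))
  two <- bead_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  I <- debye_intensity(two, q)$I
  expect_equal(I, 2 * (1 + sin(q * 10) / (q * 10)), tolerance = 1e-12)
  expect_error(bead_structure(matrix(numeric(0), 0, 3)))
})

test_that("Debye scattering is invariant under rigid motion", {
  set.seed(3)
  st <- bead_structure(matrix(rnorm(90, sd = 15), 30, 3))
  q <- seq(0.01, 0.4, length.out = 25)
  I0 <- debye_intensity(st, q)$I
  R <- coldlac:::.rot_mat(c(1, 2, 3), 1.1)
  st2 <- st
  st2$xyz <- sweep(st$xyz %*% t(R), 2, c(100, -50, 7), "+")
  I1 <- debye_intensity(st2, q)$I
  expect_lt(max(abs(I1 - I0) / I0), 1e-10)
})

test_that("Guinier analysis inverts exact Gaussian curves and sphere models", {
  qg <- seq(0.002, 0.05, length.out = 60)
  g <- guinier_fit(saxs_curve(qg, 7 * exp(-qg^2 * 43^2 / 3)))
  expect_equal(g$Rg, 43, tolerance = 1e-6)
  expect_equal(g$I0, 7, tolerance = 1e-6)
  # solid sphere of beads: Rg = sqrt(3/5) R within 2%
  grid <- seq(-20, 20, by = 3)
  lat <- as.matrix(expand.grid(grid, grid, grid))
  sph <- bead_structure(lat[rowSums(lat^2) <= 400, ])
  cur <- debye_intensity(sph, seq(0.005, 0.08, length.out = 40))
  gs <- guinier_fit(cur)
  expect_equal(gs$Rg, sqrt(3 / 5) * 20, tolerance = 0.02)
  expect_false(g$aggregation)
})

test_that("p(r) inversion recovers distances, sizes and forward intensity", {
  two <- bead_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  cur <- debye_intensity(two, seq(0.02, 2.5, length.out = 150))
  pr <- pr_invert(cur, Dmax = 15)
  sel <- pr$r > 3
  expect_equal(pr$r[sel][which.max(pr$pr[sel])], 10, tolerance = 0.1)
  expect_true(all(pr$pr >= -1e-12))
  expect_equal(pr$pr[1], 0)
  expect_equal(pr$pr[length(pr$pr)], 0)
  # sphere: Rg within 3%, I0 within 2% of the Debye I(0)
  grid <- seq(-20, 20, by = 4)
  lat <- as.matrix(expand.grid(grid, grid, grid))
  sph <- bead_structure(lat[rowSums(lat^2) <= 400, ])
  curs <- debye_intensity(sph, seq(0.01, 0.25, length.out = 80))
  prs <- pr_invert(curs, Dmax = 45)
  expect_equal(prs$Rg, sqrt(3 / 5) * 20, tolerance = 0.03)
  I0_debye <- sum(sph$w)^2
  expect_equal(prs$I0, I0_debye, tolerance = 0.02)
  gI0 <- guinier_fit(curs)$I0
  expect_equal(gI0, I0_debye, tolerance = 0.02)
  # all-zero intensity yields a zero distribution
  z <- pr_invert(saxs_curve(seq(0.01, 0.3, length.out = 40),
                            rep(0, 40), sigma = 1), Dmax = 40)
  expect_true(all(abs(z$pr) < 1e-8))
})

test_that("forward-intensity masses invert the printed worked examples", {
  m <- mass_from_i0(0.1612, mgml_to_gcm3(1.15), monomer_mass = 119130)
  expect_equal(m$M / 1000, 211, tolerance = 0.005)
  expect_equal(m$n_monomers, 1.7, tolerance = 0.2 / 1.7)
  m2 <- mass_from_i0(1.15 * 1e-3 * 2e10^2 * 1994000 / 6.02214076e23,
                     mgml_to_gcm3(1.15), monomer_mass = 119130)
  expect_equal(round(m2$n_monomers), 17)
  # exactly linear in I0, inversely linear in c
  a <- mass_from_i0(0.2, 1e-3)$M
  expect_equal(mass_from_i0(0.4, 1e-3)$M, 2 * a)
  expect_equal(mass_from_i0(0.2, 2e-3)$M, a / 2)
  expect_error(mass_from_i0(0.1, 0), "positive")
})

test_that("q-window summaries are linear and flag the aggregation signature", {
  q <- seq(0.005, 0.3, length.out = 120)
  flat <- saxs_curve(q, rep(2, 120))
  s <- q_window_summary(flat)
  expect_equal(s$low_q, s$mid_q)
  dbl <- q_window_summary(saxs_curve(q, rep(4, 120)))
  expect_equal(dbl$low_q, 2 * s$low_q)
  # growing mass with loss of internal structure: low-q up, mid-q down
  grid <- seq(-20, 20, by = 5)
  lat <- as.matrix(expand.grid(grid, grid, grid))
  small <- bead_structure(lat[rowSums(lat^2) <= 15^2, ])
  big <- bead_structure(2.2 * lat[rowSums(lat^2) <= 20^2, ])
  cs <- debye_intensity(small, q)
  cb0 <- debye_intensity(big, q)
  # normalize the aggregate curve to partially lose mid-q features
  cb <- saxs_curve(q, cb0$I * (sum(small$w)^2 / sum(big$w)^2) * 3 * 0.999 +
                     0.001 * mean(cs$I))
  ss <- q_window_summary(cs)
  sb <- q_window_summary(cb)
  expect_gt(sb$low_q, ss$low_q)
  expect_lt(sb$mid_q / sb$low_q, ss$mid_q / ss$low_q)
  expect_error(q_window_summary(flat, low_window = c(2, 3)), "empty q window")
})

test_that("chi-squared fitting recovers its own forward model", {
  # default lattice spacing so that interior beads are buried and the
  # hydration contribution is identifiable alongside the scale
  bd <- gen_bead_dimer(q_grid = seq(0.01, 0.25, length.out = 40))
  st <- bd$structure
  truth <- list(scale = 2.5, background = 0.05, rho = 0.8)
  cur <- debye_intensity(st, bd$curve$q, scale = truth$scale,
                         background = truth$background,
                         rho_hydration = truth$rho)
  cur$sigma <- 0.01 * cur$I
  f <- chi2_fit(st, cur)
  expect_equal(f$scale, truth$scale, tolerance = 1e-4)
  expect_equal(f$background, truth$background, tolerance = 1e-3)
  expect_equal(f$rho_hydration, truth$rho, tolerance = 1e-3)
  expect_lt(f$redchi2, 1e-6)
})

test_that("reduced chi-squared is ~1 for unit-sigma noise around the model", {
  bd <- gen_bead_dimer(spacing = 12,
                       q_grid = seq(0.01, 0.25, length.out = 400))
  st <- bd$structure
  cur <- debye_intensity(st, bd$curve$q, scale = 2)
  set.seed(99)
  noisy <- saxs_curve(cur$q, cur$I + rnorm(400), sigma = 1)
  f <- chi2_fit(st, noisy)
  expect_equal(f$redchi2, 1, tolerance = 0.2)
})

test_that("the generating structure beats perturbed structures in chi-squared", {
  bd <- gen_bead_dimer(spacing = 12, q_grid = seq(0.01, 0.25,
                                                  length.out = 30))
  st <- bd$structure
  cur <- bd$curve
  cur$sigma <- 0.01 * cur$I
  chi_true <- chi2_fit(st, cur)$redchi2
  set.seed(5)
  for (i in 1:20) {
    pert <- rotate_part(st, part = sample(c(1, 3), 1),
                        axis = rnorm(3), deg = runif(1, 5, 25))
    expect_gt(chi2_fit(pert, cur)$redchi2, chi_true)
  }
})

test_that("missing sigmas fall back to an unweighted fit with a warning", {
  bd <- gen_bead_dimer(spacing = 12, q_grid = seq(0.01, 0.2,
                                                  length.out = 25))
  expect_warning(chi2_fit(bd$structure, bd$curve), "unweighted")
})

test_that("rigid-body MC does not drift uphill from the true structure", {
  bd <- small_dimer(spacing = 12, nq = 30)
  mc <- rigid_body_mc(bd$structure, bd$curve, attr(bd$structure, "anchors"),
                      cfg = mc_config(n_steps = 30, n_runs = 2, seed = 3))
  start_chi <- chi2_fit(bd$structure, bd$curve)$redchi2
  for (r in mc$runs) {
    expect_lte(r$chi2, start_chi + 1e-6)
    # best-so-far bookkeeping is non-increasing
    expect_true(all(diff(r$best_trace) <= 1e-12))
  }
})

test_that("MC refinement recovers a rotated part, cutting chi-squared >= 5x", {
  bd <- small_dimer(spacing = 10, nq = 40)
  st <- bd$structure
  pert <- rotate_part(st, part = 3, deg = 10)
  chi_start <- chi2_fit(pert, bd$curve)$redchi2
  expect_gt(chi_start, 1)
  mc <- rigid_body_mc(pert, bd$curve, attr(st, "anchors"),
                      cfg = mc_config(n_steps = 100, n_runs = 10, seed = 7,
                                      tau = 0.05))
  red <- chi_start / vapply(mc$runs, `[[`, numeric(1), "chi2")
  expect_gte(sum(red >= 5), 8)
  expect_true(is.finite(mc$chi2_mean) && is.finite(mc$chi2_sd))
  # seeded rerun is bit-identical
  mc2 <- rigid_body_mc(pert, bd$curve, attr(st, "anchors"),
                       cfg = mc_config(n_steps = 100, n_runs = 10, seed = 7,
                                       tau = 0.05))
  expect_identical(mc$best$xyz, mc2$best$xyz)
  expect_identical(mc$chi2_mean, mc2$chi2_mean)
})

test_that("MC rejects anchors within one part and incomplete part labels", {
  bd <- small_dimer(spacing = 12, nq = 20)
  st <- bd$structure
  i2 <- which(st$part == 1)[1:2]
  expect_error(rigid_body_mc(st, bd$curve,
                             list(list(i = i2[1], j = i2[2], rest = 5))),
               "same part")
  st$part[1] <- NA
  expect_error(rigid_body_mc(st, bd$curve, attr(bd$structure, "anchors")),
               "part label")
})

test_that("superposition RMSD is zero under rigid motion and scales as d/sqrt(N)", {
  set.seed(11)
  A <- bead_structure(matrix(rnorm(300, sd = 20), 100, 3))
  expect_equal(superpose_rmsd(A, A), 0, tolerance = 1e-10)
  R <- coldlac:::.rot_mat(c(0, 1, 0), pi / 2)
  B <- A
  B$xyz <- sweep(A$xyz %*% t(R), 2, c(30, -10, 2), "+")
  expect_equal(superpose_rmsd(A, B), 0, tolerance = 1e-8)
  # one of 100 beads displaced 10 A -> RMSD ~ sqrt(100/N) = 1.0 A
  C <- A
  C$xyz[7, ] <- C$xyz[7, ] + c(10, 0, 0)
  expect_equal(superpose_rmsd(A, C), 1.0, tolerance = 0.05)
  expect_error(superpose_rmsd(A, bead_structure(A$xyz[1:10, ])),
               "equal bead counts")
})
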