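#' SAXS curve container
#'
#' Small-angle scattering curve on an absolute scale. q is the modulus of
#' the scattering vector, q = 4*pi*sin(theta)/lambda (1/Angstrom), where
#' 2*theta is the scattering angle.
#'
#' @param q Strictly increasing positive scattering vector grid, 1/Angstrom.
#' @param I Intensities, 1/cm.
#' @param sigma Optional per-point uncertainties, 1/cm (> 0 where used).
#' @param wavelength X-ray wavelength in Angstrom (default 1.34, a gallium
#'   metal-jet source line).
#' @return Data frame of class `"saxs_curve"`.
#' @export
saxs_curve <- function(q, I, sigma = NA_real_, wavelength = 1.34) {
  stopifnot(all(q > 0), !is.unsorted(q, strictly = TRUE),
            length(q) == length(I))
  structure(data.frame(q = q, I = I, sigma = rep_len(sigma, length(q))),
            class = c("saxs_curve", "data.frame"), wavelength = wavelength)
}

#' Read a 3-column SAXS text file
#'
#' Whitespace-delimited columns q (1/Angstrom), I, sigma (sigma optional);
#' `#` starts a comment.
#'
#' @param path File path.
#' @return A [saxs_curve()].
#' @export
read_saxs <- function(path) {
  d <- utils::read.table(path, comment.char = "#")
  if (ncol(d) < 2) stop("expected at least 2 columns (q, I) in ", path)
  if (is.unsorted(d[[1]], strictly = TRUE))
    stop("q grid must be strictly increasing in ", path)
  saxs_curve(d[[1]], d[[2]],
             sigma = if (ncol(d) >= 3) d[[3]] else NA_real_)
}

#' Coarse-grained bead structure
#'
#' One bead per residue (or any coarse-grained site) with a scattering
#' weight; beads may carry residue numbers, chain identifiers and rigid-part
#' labels for refinement.
#'
#' @param xyz N x 3 matrix of coordinates, Angstrom (finite).
#' @param w Per-bead scattering weights (>= 0; recycled, default 1).
#' @param part Optional integer/character part labels (rigid-body units).
#' @param resno,chain Optional residue numbers and chain ids.
#' @return Object of class `"bead_structure"`.
#' @export
bead_structure <- function(xyz, w = 1, part = NA, resno = NULL,
                           chain = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1, all(is.finite(xyz)))
  w <- rep_len(w, nrow(xyz))
  stopifnot(all(w >= 0))
  structure(list(xyz = xyz, w = w,
                 part = rep_len(part, nrow(xyz)),
                 resno = resno %||% seq_len(nrow(xyz)),
                 chain = chain %||% rep("A", nrow(xyz))),
            class = "bead_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bead_structure <- function(x, ...) {
  cat("bead structure:", nrow(x$xyz), "beads,",
      length(unique(x$chain)), "chain(s)")
  if (!all(is.na(x$part)))
    cat(",", length(unique(stats::na.omit(x$part))), "part(s)")
  cat("\n")
  invisible(x)
}

#' Read a PDB file as a one-bead-per-residue structure
#'
#' Parses ATOM records and places one bead at each C-alpha (uniform unit
#' weights). Chain identifiers are preserved so dimers can be handled.
#'
#' @param path PDB file path.
#' @return A [bead_structure()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, "calpha")
  at <- pdb$atom[ca$atom, ]
  bead_structure(cbind(at$x, at$y, at$z), w = 1,
                 resno = at$resno, chain = at$chain)
}

#' Assign rigid-part labels by residue interval
#'
#' @param structure A [bead_structure()].
#' @param parts Named list of residue ranges, e.g.
#'   `list(`1` = c(1, 326), `2` = c(327, 626), `3` = c(627, 1041))`; ranges
#'   apply to every chain.
#' @return The structure with `part` filled in.
#' @export
assign_parts <- function(structure, parts) {
  lbl <- rep(NA_integer_, nrow(structure$xyz))
  for (i in seq_along(parts)) {
    rng <- parts[[i]]
    lbl[structure$resno >= rng[1] & structure$resno <= rng[2]] <- i
  }
  structure$part <- lbl
  structure
}

# sinc(x) = sin(x)/x with sinc(0) = 1
.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Effective bead weights with a hydration-layer contribution
#'
#' The hydration layer is modeled as a uniform multiplicative weight
#' increment on solvent-exposed beads: beads whose neighbor count within
#' `radius` falls below `burial` get weight
#' `w * (1 + coef * (rho_hydration - rho_ref))`. `rho_hydration` is the
#' dimensionless hydration contribution, bounded in [0.2, 1.3].
#'
#' @param structure A [bead_structure()].
#' @param rho_hydration Hydration contribution in [0.2, 1.3].
#' @param rho_ref Reference level at which the layer vanishes (default 0.2).
#' @param coef Weight increment per unit rho (default 0.1).
#' @param radius Neighbor-count radius, Angstrom (default 11).
#' @param burial Neighbor count at/above which a bead counts as buried
#'   (default 16).
#' @return Numeric vector of effective weights.
#' @export
hydration_weights <- function(structure, rho_hydration, rho_ref = 0.2,
                              coef = 0.1, radius = 11, burial = 16,
                              exposed = NULL) {
  stopifnot(rho_hydration >= 0.2, rho_hydration <= 1.3)
  if (is.null(exposed)) exposed <- exposed_beads(structure, radius, burial)
  structure$w * (1 + coef * (rho_hydration - rho_ref) * exposed)
}

#' @rdname hydration_weights
#' @return `exposed_beads`: logical vector, TRUE for solvent-exposed beads.
#' @export
exposed_beads <- function(structure, radius = 11, burial = 16) {
  d <- as.matrix(stats::dist(structure$xyz))
  nb <- rowSums(d < radius) - 1
  nb < burial
}

#' Debye forward scattering of a bead structure
#'
#' Pairwise Debye sum over beads:
#' I(q) = scale * sum_ij w_i w_j sinc(q * r_ij) + background,
#' with the hydration layer entering through the effective weights of
#' [hydration_weights()]. I(0) = scale*(sum w)^2 + background.
#'
#' @param structure A [bead_structure()] with at least one bead.
#' @param q_grid Scattering vector grid, 1/Angstrom.
#' @param scale Concentration-proportional scale factor (> 0, default 1).
#' @param background Constant background, 1/cm (default 0).
#' @param rho_hydration Optional hydration contribution in [0.2, 1.3];
#'   `NULL` uses the bare weights.
#' @return A [saxs_curve()].
#' @export
debye_intensity <- function(structure, q_grid, scale = 1, background = 0,
                            rho_hydration = NULL) {
  stopifnot(inherits(structure, "bead_structure"), scale > 0)
  if (nrow(structure$xyz) < 1) stop("empty structure")
  w <- if (is.null(rho_hydration)) structure$w else
    hydration_weights(structure, rho_hydration)
  I <- scale * .debye_sum(structure$xyz, w, q_grid) + background
  saxs_curve(q_grid, I)
}

# unscaled Debye sum S(q) = sum_ij w_i w_j sinc(q r_ij)
.debye_sum <- function(xyz, w, q_grid) {
  n <- nrow(xyz)
  self <- sum(w^2)
  if (n == 1) return(rep(self, length(q_grid)))
  dvec <- as.numeric(stats::dist(xyz))
  # pair weights in the same (column-major lower-triangle) order as dist()
  wp <- numeric(length(dvec))
  k <- 1
  for (i in seq_len(n - 1)) {
    m <- n - i
    wp[k:(k + m - 1)] <- w[i] * w[(i + 1):n]
    k <- k + m
  }
  vapply(q_grid, function(q) self + 2 * sum(wp * .sinc(q * dvec)),
         numeric(1))
}

#' Guinier fit
#'
#' Linear fit of ln I against q^2 on a self-consistent low-q window
#' (iteratively restricted to q*Rg < `qmax_rg`). Rg = sqrt(-3*slope) and
#' I(0) = exp(intercept). Upward curvature at the lowest q beyond the noise
#' raises an aggregation flag.
#'
#' @param curve A [saxs_curve()].
#' @param qmax_rg Window limit in units of q*Rg (default 1.3).
#' @param min_points Minimum number of points in the window (default 5).
#' @return List with `Rg` (Angstrom), `I0` (1/cm), standard errors,
#'   `window` (logical index of used points), `aggregation` flag and the
#'   underlying `lm`.
#' @export
guinier_fit <- function(curve, qmax_rg = 1.3, min_points = 5) {
  d <- as.data.frame(curve)
  d <- d[d$I > 0, ]
  use <- seq_len(max(min_points, min(15, nrow(d))))
  Rg <- NA_real_
  for (it in 1:30) {
    fit <- stats::lm(log(I) ~ I(q^2), data = d[use, ])
    sl <- stats::coef(fit)[[2]]
    if (sl >= 0) break
    Rg <- sqrt(-3 * sl)
    new <- which(d$q * Rg < qmax_rg)
    if (length(new) < min_points) new <- seq_len(min_points)
    if (identical(new, use)) break
    use <- new
  }
  fit <- stats::lm(log(I) ~ I(q^2), data = d[use, ])
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  Rg <- sqrt(max(-3 * cf[[2]], 0))
  res <- stats::residuals(fit)
  k <- max(3, floor(length(res) / 5))
  aggregation <- mean(res[seq_len(k)]) > 2 * stats::sd(res) &&
    stats::sd(res) > 0
  list(Rg = Rg,
       Rg_se = if (Rg > 0) 3 * se[[2]] / (2 * Rg) else NA_real_,
       I0 = exp(cf[[1]]), I0_se = exp(cf[[1]]) * se[[1]],
       window = use, aggregation = isTRUE(aggregation), lm = fit)
}

#' Indirect Fourier transformation to the pair-distance distribution
#'
#' Regularized non-negative least squares inversion of
#' I(q) = 4*pi * integral p(r) sinc(q r) dr on a fixed r grid in
#' [0, Dmax], with a second-difference smoothness penalty and the boundary
#' conditions p(0) = p(Dmax) = 0. Rg and I(0) follow from the moments of
#' p(r): Rg^2 = integral r^2 p dr / (2 * integral p dr).
#'
#' @param curve A [saxs_curve()] extending to roughly q*Dmax >= pi.
#' @param Dmax Maximum particle dimension, Angstrom (> 0).
#' @param alpha Smoothness weight (dimensionless, default 0.01).
#' @param n_r Number of r-grid points (default 101).
#' @return List of class `"pr_result"`: `r`, `pr`, `Dmax`, `Rg`, `I0`,
#'   `fitted` (intensity reproduced from p(r)), `flagged_dmax` (TRUE when a
#'   systematic residual trend suggests Dmax is too small).
#' @export
pr_invert <- function(curve, Dmax, alpha = 0.01, n_r = 101) {
  stopifnot(Dmax > 0)
  d <- as.data.frame(curve)
  q <- d$q; I <- d$I
  sig <- d$sigma
  if (all(is.na(sig))) sig <- rep(max(abs(I)) * 0.01 + 1e-30, length(I))
  r <- seq(0, Dmax, length.out = n_r)
  dr <- r[2] - r[1]
  inner <- 2:(n_r - 1)  # p = 0 at both ends
  A <- 4 * pi * dr * outer(q, r[inner], function(qq, rr) .sinc(qq * rr))
  Aw <- A / sig
  Iw <- I / sig
  np <- length(inner)
  L <- diff(diag(np), differences = 2)
  lam <- alpha * mean(diag(crossprod(Aw))) / mean(diag(crossprod(L)))
  H <- crossprod(Aw) + lam * crossprod(L)
  g <- crossprod(Aw, Iw)
  obj <- function(p) 0.5 * sum(p * (H %*% p)) - sum(g * p)
  grad <- function(p) as.numeric(H %*% p - g)
  p0 <- rep(max(mean(I), 0) / (4 * pi * Dmax), np)
  op <- stats::optim(p0, obj, grad, method = "L-BFGS-B", lower = 0,
                     control = list(maxit = 2000, factr = 1e7))
  pr <- c(0, op$par, 0)
  ip <- sum(pr) * dr
  I0 <- 4 * pi * ip
  Rg <- if (ip > 0) sqrt(sum(r^2 * pr) * dr / (2 * ip)) else 0
  fitted <- as.numeric(A %*% op$par)
  res <- (I - fitted) / sig
  # long runs of same-signed residuals indicate a truncated p(r)
  runs <- rle(sign(res[res != 0]))
  flagged <- length(runs$lengths) > 0 &&
    max(runs$lengths) > max(8, length(res) / 3)
  structure(list(r = r, pr = pr, Dmax = Dmax, Rg = Rg, I0 = I0,
                 fitted = fitted, flagged_dmax = flagged),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("p(r) on [0, %.1f] A: Rg = %.2f A, I(0) = %.4g /cm%s\n",
              x$Dmax, x$Rg, x$I0,
              if (x$flagged_dmax) " [Dmax possibly too small]" else ""))
  invisible(x)
}

#' Molar mass from forward scattering
#'
#' M = I(0) * N_A / (c * drho_m^2), with I(0) in 1/cm, concentration c in
#' g/cm^3 and the scattering contrast per mass drho_m in cm/g (2.0e10 for a
#' typical protein). The monomer count is M / monomer_mass.
#'
#' @param I0 Forward intensity, 1/cm (> 0).
#' @param c Mass concentration, g/cm^3 (> 0); use [mgml_to_gcm3()] for
#'   mg/mL inputs.
#' @param drho_m Scattering contrast per mass, cm/g (default 2.0e10).
#' @param monomer_mass Optional monomer molar mass, g/mol, to report a
#'   monomer count.
#' @return List with `M` (g/mol) and, if requested, `n_monomers`.
#' @export
#' @examples
#' mass_from_i0(0.1612, mgml_to_gcm3(1.15), monomer_mass = 119130)
mass_from_i0 <- function(I0, c, drho_m = 2.0e10, monomer_mass = NULL) {
  if (c <= 0) stop("concentration must be positive")
  stopifnot(I0 > 0, drho_m > 0)
  M <- I0 * .const$N_A / (c * drho_m^2)
  out <- list(M = M)
  if (!is.null(monomer_mass)) out$n_monomers <- M / monomer_mass
  out
}

#' Convert mg/mL to g/cm^3
#' @param x Concentration in mg/mL.
#' @return Concentration in g/cm^3 (x * 1e-3).
#' @export
mgml_to_gcm3 <- function(x) x * 1e-3

#' Low-q / mid-q window summaries
#'
#' Mean background-subtracted intensity in a low-q window (proportional to
#' particle mass) and a mid-q window (sensitive to tertiary structure).
#'
#' @param curve A [saxs_curve()].
#' @param low_window,mid_window q intervals, 1/Angstrom (defaults
#'   c(0.01, 0.025) and c(0.07, 0.20)).
#' @param background Constant background to subtract (default 0).
#' @return List with `low_q` and `mid_q`.
#' @export
q_window_summary <- function(curve, low_window = c(0.01, 0.025),
                             mid_window = c(0.07, 0.20), background = 0) {
  d <- as.data.frame(curve)
  pick <- function(win) {
    i <- d$q >= win[1] & d$q <= win[2]
    if (!any(i)) stop("empty q window [", win[1], ", ", win[2], "]")
    mean(d$I[i] - background)
  }
  list(low_q = pick(low_window), mid_q = pick(mid_window))
}

# profile (scale, background) analytically for a fixed model shape S(q):
# minimize sum ((I - a*S - b)/sigma)^2 over a, b
.profile_scale_bg <- function(S, I, sig, fit_background = TRUE) {
  w <- 1 / sig^2
  if (fit_background) {
    X <- cbind(S, 1)
    XtWX <- crossprod(X * sqrt(w))
    XtWy <- crossprod(X, w * I)
    ab <- tryCatch(solve(XtWX, XtWy), error = function(e) rbind(1, 0))
    a <- ab[1]; b <- ab[2]
  } else {
    a <- sum(w * S * I) / sum(w * S^2)
    b <- 0
  }
  if (!is.finite(a) || a <= 0) { a <- sum(w * S * I) / sum(w * S^2); b <- 0 }
  chi2 <- sum(w * (I - a * S - b)^2)
  list(scale = a, background = b, chi2 = chi2)
}

#' Fit a bead model to a measured curve (scale, hydration, background)
#'
#' Minimizes the reduced chi-squared
#' (1/(N_q - 3)) * sum(((I_exp - I_model)/sigma)^2) over the
#' concentration-proportional scale, the hydration contribution
#' rho_hydration in [0.2, 1.3] and a constant background. Scale and
#' background are profiled analytically at each rho value; rho is found by
#' 1-D minimization, so the fit is deterministic. Missing sigmas trigger an
#' unweighted fit with a warning.
#'
#' @param structure A [bead_structure()].
#' @param curve A [saxs_curve()] with uncertainties.
#' @param rho_bounds Bounds for rho_hydration (default c(0.2, 1.3)).
#' @return List with `scale`, `rho_hydration`, `background`, `redchi2`,
#'   `fitted` (model curve), `n_obs`.
#' @export
chi2_fit <- function(structure, curve, rho_bounds = c(0.2, 1.3)) {
  d <- as.data.frame(curve)
  sig <- d$sigma
  if (all(is.na(sig))) {
    warning("curve has no uncertainties; performing unweighted fit")
    sig <- rep(1, nrow(d))
  }
  stopifnot(all(sig > 0))
  expo <- exposed_beads(structure)
  prof <- function(rho) {
    S <- .debye_sum(structure$xyz,
                    hydration_weights(structure, rho, exposed = expo), d$q)
    .profile_scale_bg(S, d$I, sig)
  }
  op <- stats::optimize(function(r) prof(r)$chi2, rho_bounds, tol = 1e-6)
  best <- prof(op$minimum)
  dof <- nrow(d) - 3
  S <- .debye_sum(structure$xyz,
                  hydration_weights(structure, op$minimum, exposed = expo),
                  d$q)
  list(scale = best$scale, rho_hydration = op$minimum,
       background = best$background,
       redchi2 = best$chi2 / dof,
       fitted = saxs_curve(d$q, best$scale * S + best$background),
       n_obs = nrow(d))
}

# rotation matrix about unit axis u by angle a (Rodrigues)
.rot_mat <- function(u, a) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Monte Carlo configuration for rigid-body refinement
#'
#' @param n_steps Steps per run (default 100).
#' @param n_runs Independent runs (default 10).
#' @param max_rot_deg Maximum proposal rotation angle, degrees (default 5).
#' @param max_trans Maximum proposal translation per axis, Angstrom
#'   (default 2).
#' @param spring Weight of the soft anchor restraints (default 1).
#' @param clash_cutoff Inter-part bead clash distance, Angstrom (default 3).
#' @param clash_weight Penalty per clashing pair (default 0.1).
#' @param tau Metropolis acceptance temperature in objective units
#'   (default 0.5); `tau = 0` gives a greedy walk.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List of class `"mc_config"`.
#' @export
mc_config <- function(n_steps = 100, n_runs = 10, max_rot_deg = 5,
                      max_trans = 2, spring = 1, clash_cutoff = 3,
                      clash_weight = 0.1, tau = 0.5, seed = 1) {
  stopifnot(n_steps >= 1, n_runs >= 1, spring >= 0, clash_weight >= 0)
  structure(list(n_steps = n_steps, n_runs = n_runs,
                 max_rot_deg = max_rot_deg, max_trans = max_trans,
                 spring = spring, clash_cutoff = clash_cutoff,
                 clash_weight = clash_weight, tau = tau, seed = seed),
            class = "mc_config")
}

#' Rigid-body Monte Carlo refinement against a SAXS curve
#'
#' The structure's labeled parts move as rigid bodies in a Metropolis walk.
#' The objective is
#' reduced chi2 + spring * sum(max(0, d_anchor - d_rest)^2)
#'              + clash_weight * (number of inter-part bead pairs closer
#'                than the clash cutoff),
#' where scale and constant background are re-fitted analytically at every
#' step (profile objective) and the hydration contribution is held at
#' `rho_hydration` throughout (fit it first with [chi2_fit()]). Per run the
#' best-objective structure is kept; the summary reports the mean and
#' standard deviation of the best reduced chi2 across runs.
#'
#' @param structure A [bead_structure()] whose `part` labels are complete.
#' @param curve Target [saxs_curve()] with uncertainties.
#' @param anchors List of anchor restraints, each
#'   `list(i = bead index, j = bead index, rest = rest length in Angstrom)`;
#'   anchors must connect beads of different parts (the backbone
#'   connections between consecutive parts).
#' @param cfg An [mc_config()].
#' @param rho_hydration Hydration contribution held fixed during the walk
#'   (default 0.2, i.e. no hydration increment).
#' @return List with `best` (overall best [bead_structure()]), `runs` (per
#'   run: best structure, best chi2, best objective, objective trace,
#'   best-so-far trace, acceptance rate), `chi2_mean`, `chi2_sd`.
#' @export
rigid_body_mc <- function(structure, curve, anchors, cfg = mc_config(),
                          rho_hydration = 0.2) {
  stopifnot(inherits(structure, "bead_structure"))
  if (any(is.na(structure$part))) stop("all beads must carry a part label")
  parts <- sort(unique(structure$part))
  for (a in anchors) {
    if (structure$part[a$i] == structure$part[a$j])
      stop("anchor connects beads of the same part; anchors must link ",
           "different parts")
  }
  d <- as.data.frame(curve)
  sig <- d$sigma
  if (all(is.na(sig))) sig <- rep(1, nrow(d))
  w <- hydration_weights(structure, rho_hydration)
  dof <- nrow(d) - 3

  objective <- function(xyz) {
    S <- .debye_sum(xyz, w, d$q)
    pr <- .profile_scale_bg(S, d$I, sig)
    chi2 <- pr$chi2 / dof
    pen <- 0
    for (a in anchors) {
      da <- sqrt(sum((xyz[a$i, ] - xyz[a$j, ])^2))
      pen <- pen + cfg$spring * max(0, da - a$rest)^2
    }
    nclash <- 0
    if (cfg$clash_weight > 0) {
      dm <- as.matrix(stats::dist(xyz))
      inter <- outer(structure$part, structure$part, "!=")
      nclash <- sum(dm < cfg$clash_cutoff & inter) / 2
    }
    list(obj = chi2 + pen + cfg$clash_weight * nclash, chi2 = chi2)
  }

  runs <- vector("list", cfg$n_runs)
  for (run in seq_len(cfg$n_runs)) {
    set.seed(cfg$seed + run - 1)
    xyz <- structure$xyz
    cur <- objective(xyz)
    best <- list(xyz = xyz, obj = cur$obj, chi2 = cur$chi2)
    trace <- numeric(cfg$n_steps)
    best_trace <- numeric(cfg$n_steps)
    acc <- 0
    for (step in seq_len(cfg$n_steps)) {
      p <- sample(parts, 1)
      idx <- which(structure$part == p)
      prop <- xyz
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, 0, cfg$max_rot_deg) * pi / 180
      shift <- stats::runif(3, -cfg$max_trans, cfg$max_trans)
      ctr <- colMeans(xyz[idx, , drop = FALSE])
      R <- .rot_mat(axis, ang)
      prop[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, ctr) %*% t(R),
                           2, ctr + shift, "+")
      cand <- objective(prop)
      du <- cand$obj - cur$obj
      if (du < 0 || (cfg$tau > 0 && stats::runif(1) < exp(-du / cfg$tau))) {
        xyz <- prop
        cur <- cand
        acc <- acc + 1
        if (cur$obj < best$obj)
          best <- list(xyz = xyz, obj = cur$obj, chi2 = cur$chi2)
      }
      trace[step] <- cur$obj
      best_trace[step] <- best$obj
    }
    st <- structure
    st$xyz <- best$xyz
    runs[[run]] <- list(structure = st, chi2 = best$chi2,
                        objective = best$obj, trace = trace,
                        best_trace = best_trace,
                        acceptance = acc / cfg$n_steps)
  }
  chis <- vapply(runs, `[[`, numeric(1), "chi2")
  ibest <- which.min(vapply(runs, `[[`, numeric(1), "objective"))
  list(best = runs[[ibest]]$structure, runs = runs,
       chi2_mean = mean(chis), chi2_sd = stats::sd(chis))
}

#' RMSD after optimal superposition
#'
#' Least-squares rigid superposition (Kabsch algorithm, reflections
#' excluded) of B onto A followed by the root-mean-square deviation over
#' corresponding beads. Invariant to rigid motions of either input.
#'
#' @param A,B [bead_structure()]s (or N x 3 matrices) with equal bead
#'   counts in corresponding order.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(A, B) {
  xa <- if (inherits(A, "bead_structure")) A$xyz else as.matrix(A)
  xb <- if (inherits(B, "bead_structure")) B$xyz else as.matrix(B)
  if (!all(dim(xa) == dim(xb))) stop("structures must have equal bead counts")
  ca <- colMeans(xa); cb <- colMeans(xb)
  pa <- sweep(xa, 2, ca); pb <- sweep(xb, 2, cb)
  s <- svd(crossprod(pb, pa))
  dsign <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  pb_rot <- pb %*% R
  sqrt(mean(rowSums((pa - pb_rot)^2)))
}
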