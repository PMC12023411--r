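#' Dimer speciation at equilibrium
#'
#' For the association 2M <-> D with dissociation constant KD = [M]^2/[D]
#' and total monomer-equivalent concentration M0 = [M] + 2[D], the dimer
#' concentration is the physical root of the mass-action quadratic:
#'
#' D = ((4*M0 + KD) - sqrt((4*M0 + KD)^2 - 16*M0^2)) / 8
#'
#' @param M0 Total monomer-equivalent concentration, mol/L (>= 0).
#' @param KD Dissociation constant of the dimer, mol/L (> 0).
#' @return List with `M0`, `M` (free monomer), `D` (dimer), all mol/L.
#'   Mass conservation (M + 2D = M0) and mass action (M^2/D = KD) hold to
#'   floating-point accuracy.
#' @export
#' @examples
#' s <- dimer_concentration(1e-6, 1e-6)
#' s$M^2 / s$D  # = KD
dimer_concentration <- function(M0, KD) {
  if (any(M0 < 0)) stop("M0 must be non-negative")
  stopifnot(KD > 0)
  b <- 4 * M0 + KD
  disc <- b^2 - 16 * M0^2
  D <- (b - sqrt(pmax(disc, 0))) / 8
  # one Newton polish of the quadratic 4D^2 - b D + M0^2 = 0 against
  # cancellation at M0 >> KD
  D <- D - (4 * D^2 - b * D + M0^2) / (8 * D - b)
  D[M0 == 0] <- 0
  list(M0 = M0, M = M0 - 2 * D, D = D)
}

#' Concentration-dependent observable under a monomer-dimer equilibrium
#'
#' Maps an observable measured across a concentration titration (a
#' hydrodynamic radius, or an apparent melting temperature) onto the
#' monomer-dimer speciation:
#'
#' obs(M0) = obs_mono + (2*D/M0) * (obs_dimer - obs_mono)
#'
#' where 2D/M0 is the fraction of monomer units residing in dimers. The
#' curve is continuous, monotone in M0, and bounded by the two endpoint
#' observables; at M0 = 0 it returns the monomer endpoint (limit).
#'
#' @param M0 Total monomer-equivalent concentration, mol/L.
#' @param p Named vector/list `KD` (mol/L), `obs_mono`, `obs_dimer`.
#' @return Observable values.
#' @export
association_observable <- function(M0, p) {
  s <- dimer_concentration(M0, p[["KD"]])
  frac <- ifelse(M0 > 0, 2 * s$D / M0, 0)
  p[["obs_mono"]] + frac * (p[["obs_dimer"]] - p[["obs_mono"]])
}

register_model("association", function(p, x)
  association_observable(x, list(KD = 10^p[["logKD"]],
                                 obs_mono = p[["obs_mono"]],
                                 obs_dimer = p[["obs_dimer"]])))

#' Fit the monomer-dimer association model to a titration
#'
#' Weighted least squares over (KD, obs_mono, obs_dimer), with KD fitted as
#' log10(KD) bounded in [-12, -2]. If no initialization is given, KD starts
#' at the concentration where the observable crosses the half-transition
#' and the endpoints at the extremes of the data. A design spanning fewer
#' than two decades in M0, or fewer than 5 concentrations, triggers a
#' warning; data without any transition leave KD unidentifiable, which is
#' flagged via an infinite/failed standard error rather than an error.
#'
#' @param series Series of observable vs M0 (mol/L).
#' @param init Optional named list `KD`, `obs_mono`, `obs_dimer`.
#' @return A `"coldlac_fit"` with coefficients `logKD`, `obs_mono`,
#'   `obs_dimer`. Use [association_params()] for the natural scale.
#' @export
fit_association <- function(series, init = NULL) {
  d <- as.data.frame(series)
  o <- order(d$x)
  d <- d[o, ]
  if (nrow(d) < 5) warning("fewer than 5 concentrations in the titration")
  if (diff(log10(range(d$x[d$x > 0]))) < 2)
    warning("titration spans less than 2 decades in concentration")
  if (is.null(init)) {
    lowend <- d$y[1]; highend <- d$y[nrow(d)]
    half <- (lowend + highend) / 2
    i <- which.min(abs(d$y - half))
    init <- list(KD = d$x[i], obs_mono = lowend, obs_dimer = highend)
  }
  p0 <- c(logKD = log10(init$KD), obs_mono = init$obs_mono,
          obs_dimer = init$obs_dimer)
  fit_curve("association", d, p0,
            lower = c(logKD = -12), upper = c(logKD = -2))
}

#' Natural-scale parameters of an association fit
#'
#' @param fit A fit from [fit_association()].
#' @return List with `KD` (mol/L), `KD_se` (delta-method, mol/L),
#'   `obs_mono`, `obs_dimer` and their standard errors.
#' @export
association_params <- function(fit) {
  p <- coef(fit)
  KD <- 10^p[["logKD"]]
  list(KD = KD,
       KD_se = KD * log(10) * fit$se[["logKD"]],
       obs_mono = p[["obs_mono"]], obs_mono_se = fit$se[["obs_mono"]],
       obs_dimer = p[["obs_dimer"]], obs_dimer_se = fit$se[["obs_dimer"]])
}

#' n-mer association observable
#'
#' Generalizes the dimer model to n M <-> M_n with
#' KD_n = [M]^n / [M_n] (units M^(n-1)). The free-unit concentration is
#' found by bisection on the conservation relation
#' M + n*M^n/KD_n = M0 (relative tolerance 1e-12), the assembled fraction
#' is n*[M_n]/M0, and the observable interpolates linearly between the two
#' endpoints by that subunit-weighted fraction. With n = 2 this reproduces
#' [association_observable()] exactly. The "unit" may itself be a preformed
#' dimer, in which case n = 2 with dimer/tetramer endpoint observables
#' describes a dimer-of-dimers (2 -> 4) assembly.
#'
#' @param M0 Total unit-equivalent concentration, mol/L (> 0 elementwise,
#'   0 allowed and returns `obs_low`).
#' @param KD_n Dissociation constant, M^(n-1) (> 0).
#' @param n Association order (integer >= 2).
#' @param obs_low Observable of the free unit.
#' @param obs_high Observable of the assembled n-mer.
#' @return Observable values.
#' @export
nmer_observable <- function(M0, KD_n, n = 2, obs_low, obs_high) {
  stopifnot(n >= 2, KD_n > 0, all(M0 >= 0))
  frac <- vapply(M0, function(m0) {
    if (m0 == 0) return(0)
    g <- function(M) M + n * M^n / KD_n - m0
    lo <- 0; hi <- m0
    # g is strictly increasing; g(0) = -m0 < 0, g(m0) >= 0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-12 * m0) break
    }
    M <- (lo + hi) / 2
    Mn <- M^n / KD_n
    n * Mn / m0
  }, numeric(1))
  obs_low + frac * (obs_high - obs_low)
}

register_model("nmer2", function(p, x)
  nmer_observable(x, 10^p[["logKD"]], 2, p[["obs_low"]], p[["obs_high"]]))

#' Fit the n-mer association model
#'
#' @param series Series of observable vs total unit concentration (mol/L).
#' @param n Association order (currently fitted for n = 2 units, where a
#'   "unit" may be a preformed dimer for a 2 -> 4 assembly).
#' @param init Named list `KD`, `obs_low`, `obs_high`.
#' @return A `"coldlac_fit"` with `logKD`, `obs_low`, `obs_high`.
#' @export
fit_nmer <- function(series, n = 2, init) {
  stopifnot(n == 2)
  p0 <- c(logKD = log10(init$KD), obs_low = init$obs_low,
          obs_high = init$obs_high)
  fit_curve("nmer2", series, p0, lower = c(logKD = -12),
            upper = c(logKD = -2))
}
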