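#' Two-state isothermal denaturation signal
#'
#' Signal of a protein unfolding N <-> D in a denaturant, with linear
#' baselines for both states and a base-10 denaturant dependence of the
#' equilibrium constant (log K_DN linear in [urea] with slope m_DN/RT):
#'
#' S(u) = (aN + bN*u + (aD + bD*u) * 10^(m_DN*(u - u50)/RT)) /
#'        (1 + 10^(m_DN*(u - u50)/RT))
#'
#' Note the base-10 convention: the m-value here multiplies a decadic
#' exponent. [m10_to_mln()] converts to the conventional natural-log
#' kcal/(mol M) m-value.
#'
#' @param u Denaturant concentration, M (>= 0).
#' @param p Named vector/list: `alpha_N`, `beta_N`, `alpha_D`, `beta_D`
#'   (baseline intercepts and slopes), `m_DN` (cal/(mol M), decadic
#'   convention), `u50` (midpoint, M), `RT` (cal/mol).
#' @return Signal values.
#' @export
two_state_signal <- function(u, p) {
  stopifnot(p[["RT"]] > 0)
  e <- 10^(p[["m_DN"]] * (u - p[["u50"]]) / p[["RT"]])
  (p[["alpha_N"]] + p[["beta_N"]] * u +
      (p[["alpha_D"]] + p[["beta_D"]] * u) * e) / (1 + e)
}

#' Three-state isothermal denaturation signal
#'
#' Sequential N <-> I <-> D unfolding with an intermediate baseline. The
#' state populations follow K_IN = 10^(m_IN*(u - u50_I)/RT) and
#' K_DI = 10^(m_DI*(u - u50_D)/RT), with the denatured population weighted
#' by the product K_IN*K_DI so that the model reduces exactly to
#' [two_state_signal()] when the second transition is pushed to infinite
#' denaturant and the I and D baselines coincide.
#'
#' @param u Denaturant concentration, M.
#' @param p Named vector/list: baselines `alpha_N`, `beta_N`, `alpha_I`,
#'   `beta_I`, `alpha_D`, `beta_D`; m-values `m_IN`, `m_DI` (decadic
#'   convention); midpoints `u50_I` <= `u50_D`; `RT`.
#' @return Signal values.
#' @export
three_state_signal <- function(u, p) {
  stopifnot(p[["RT"]] > 0)
  kIN <- 10^(p[["m_IN"]] * (u - p[["u50_I"]]) / p[["RT"]])
  kDI <- 10^(p[["m_DI"]] * (u - p[["u50_D"]]) / p[["RT"]])
  wD <- kIN * kDI
  (p[["alpha_N"]] + p[["beta_N"]] * u +
      (p[["alpha_I"]] + p[["beta_I"]] * u) * kIN +
      (p[["alpha_D"]] + p[["beta_D"]] * u) * wD) / (1 + kIN + wD)
}

#' Fraction folded from the two-state model
#'
#' @param u Denaturant concentration, M.
#' @param p As in [two_state_signal()] (only `m_DN`, `u50`, `RT` are used).
#' @return Native population, monotone non-increasing in `u`.
#' @export
two_state_fraction_folded <- function(u, p) {
  e <- 10^(p[["m_DN"]] * (u - p[["u50"]]) / p[["RT"]])
  1 / (1 + e)
}

#' Convert a decadic m-value to the natural-log convention
#'
#' The denaturation equations use base-10 exponents, so their m-value obeys
#' log10 K = m10*(u - u50)/RT. The conventional m-value (d dG / d[urea]) is
#' m_ln = m10 * ln(10), returned in kcal/(mol M).
#'
#' @param m10 Decadic m-value, cal/(mol M).
#' @return Conventional m-value, kcal/(mol M).
#' @export
m10_to_mln <- function(m10) m10 * log(10) / 1000

register_model("two_state", function(p, x)
  two_state_signal(x, as.list(p)))
register_model("three_state", function(p, x)
  three_state_signal(x, as.list(p)))

#' Fit the two-state denaturation model
#'
#' @param data Series of signal vs denaturant (M).
#' @param init Named starting values (see [two_state_signal()]); `RT` is
#'   held fixed.
#' @param RT Thermal energy, cal/mol (default 298.15 K worth).
#' @param fix Optional named vector of additional parameters to hold fixed
#'   (e.g. `c(beta_N = 0, beta_D = 0)` for flat baselines).
#' @return A `"coldlac_fit"`.
#' @export
fit_two_state <- function(data, init, RT = .const$R_cal * 298.15,
                          fix = NULL) {
  pars <- c("alpha_N", "beta_N", "alpha_D", "beta_D", "m_DN", "u50")
  free <- setdiff(pars, names(fix))
  fit_curve("two_state", data, unlist(init)[free],
            lower = c(u50 = 0)[intersect("u50", free)],
            fixed = c(fix, RT = RT))
}

#' Fit the three-state denaturation model
#'
#' The midpoint ordering u50_I <= u50_D is enforced by box constraints to
#' prevent label switching.
#'
#' @param data Series of signal vs denaturant (M).
#' @param init Named starting values (see [three_state_signal()]).
#' @param RT Thermal energy, cal/mol.
#' @param fix Optional named vector of parameters to hold fixed.
#' @return A `"coldlac_fit"`.
#' @export
fit_three_state <- function(data, init, RT = .const$R_cal * 298.15,
                            fix = NULL) {
  pars <- c("alpha_N", "beta_N", "alpha_I", "beta_I", "alpha_D", "beta_D",
            "m_IN", "m_DI", "u50_I", "u50_D")
  free <- setdiff(pars, names(fix))
  mid <- mean(c(init[["u50_I"]], init[["u50_D"]]))
  lo <- c(u50_I = 0, u50_D = mid)
  hi <- c(u50_I = mid)
  fit_curve("three_state", data, unlist(init)[free],
            lower = lo[intersect(names(lo), free)],
            upper = hi[intersect(names(hi), free)],
            fixed = c(fix, RT = RT))
}

#' Thermal transition signal (van 't Hoff two-state, one or two steps)
#'
#' Single transition: K(T) = exp(-(dH_vH/R)*(1/T - 1/tm)), fraction
#' unfolded f = K/(1+K), and the signal interpolates the two linear
#' baselines. With `n_transitions = 2` the model is sequential N -> I -> D
#' with independent (tm, dH_vH) per step and an intermediate baseline; the
#' denatured population carries the product K1*K2.
#'
#' @param T Absolute temperature, K (> 0).
#' @param p Named vector/list. One transition: `tm`, `dH_vH` (cal/mol),
#'   baselines `aN`, `bN`, `aD`, `bD` (intercept and slope vs T). Two
#'   transitions: `tm1`, `dH1`, `tm2`, `dH2`, baselines `aN`, `bN`, `aI`,
#'   `bI`, `aD`, `bD`.
#' @param n_transitions 1 or 2.
#' @return Signal values.
#' @export
thermal_signal <- function(T, p, n_transitions = 1) {
  stopifnot(all(T > 0))
  R <- .const$R_cal
  if (n_transitions == 1) {
    # f = K/(1+K) computed in logistic form so huge dH_vH cannot overflow
    lK <- -(p[["dH_vH"]] / R) * (1 / T - 1 / p[["tm"]])
    f <- stats::plogis(lK)
    (1 - f) * (p[["aN"]] + p[["bN"]] * T) + f * (p[["aD"]] + p[["bD"]] * T)
  } else if (n_transitions == 2) {
    # populations via log-sum-exp for numerical safety at steep transitions
    a <- -(p[["dH1"]] / R) * (1 / T - 1 / p[["tm1"]])   # log K1
    b <- -(p[["dH2"]] / R) * (1 / T - 1 / p[["tm2"]])   # log K2
    m <- pmax(0, a, a + b)
    wN <- exp(0 - m); wI <- exp(a - m); wD <- exp(a + b - m)
    z <- wN + wI + wD
    (wN * (p[["aN"]] + p[["bN"]] * T) + wI * (p[["aI"]] + p[["bI"]] * T) +
       wD * (p[["aD"]] + p[["bD"]] * T)) / z
  } else stop("n_transitions must be 1 or 2")
}

register_model("thermal1", function(p, x) thermal_signal(x, as.list(p), 1))
register_model("thermal2", function(p, x) thermal_signal(x, as.list(p), 2))

#' Fit one- or two-step thermal transitions
#'
#' @param data Series of signal vs absolute temperature (K).
#' @param init Named starting values (see [thermal_signal()]).
#' @param n_transitions 1 or 2.
#' @param fix Optional named vector of parameters to hold fixed.
#' @return A `"coldlac_fit"`.
#' @export
fit_thermal <- function(data, init, n_transitions = 1, fix = NULL) {
  pars <- if (n_transitions == 1)
    c("tm", "dH_vH", "aN", "bN", "aD", "bD")
  else c("tm1", "dH1", "tm2", "dH2", "aN", "bN", "aI", "bI", "aD", "bD")
  free <- setdiff(pars, names(fix))
  lo <- c(tm = 1, dH_vH = 0, tm1 = 1, dH1 = 0, tm2 = 1, dH2 = 0)
  fit_curve(if (n_transitions == 1) "thermal1" else "thermal2",
            data, unlist(init)[free],
            lower = lo[intersect(names(lo), free)], fixed = fix)
}

#' Melting midpoint from a scanning-fluorimetry curve
#'
#' The inflection point (IP) of a 350/330 nm ratio-vs-temperature scan, read
#' as the extremum of the Savitzky-Golay smoothed first derivative, refined
#' by parabolic interpolation around the discrete peak. A curve whose
#' derivative peak is indistinct (prominence below `prominence` times the
#' derivative range) yields a no-transition result (`NA` with
#' `transition = FALSE`), not an error.
#'
#' @param curve Series of ratio vs temperature (same unit in, same unit
#'   out; at least 11 points on a monotone temperature grid).
#' @param smooth_window Savitzky-Golay window length (odd, default 11).
#' @param smooth_order Polynomial order (default 3).
#' @param prominence Minimal derivative-peak prominence as a fraction of
#'   the derivative range (default 0.05).
#' @return List with `ip` (temperature of the inflection point, or `NA`),
#'   `transition` (logical), `derivative` (data frame T, dSdT).
#' @export
dsf_inflection <- function(curve, smooth_window = 11, smooth_order = 3,
                           prominence = 0.05) {
  d <- as.data.frame(curve)
  stopifnot(nrow(d) >= 11)
  T <- d$x
  if (is.unsorted(T, strictly = TRUE)) stop("temperature grid must be monotone")
  s <- signal::sgolayfilt(d$y, p = smooth_order, n = smooth_window)
  dT <- diff(T)
  dS <- diff(s) / dT
  Tm <- (T[-1] + T[-length(T)]) / 2
  # drop the filter's edge artefacts
  k <- (smooth_window - 1) / 2
  keep <- seq_len(length(dS))
  keep <- keep[keep > k & keep <= length(dS) - k]
  dSk <- dS[keep]; Tk <- Tm[keep]
  rng <- diff(range(dSk))
  sgn <- if (max(dSk) >= -min(dSk)) 1 else -1   # increasing vs decreasing ratio
  dd <- sgn * dSk
  i <- which.max(dd)
  prom <- dd[i] - stats::median(dd)
  # indistinct when the derivative barely varies relative to its own level
  # (flat or purely linear signal) or the peak lacks prominence
  if (rng == 0 || rng < 0.05 * max(abs(dSk)) || prom < prominence * rng) {
    return(list(ip = NA_real_, transition = FALSE,
                derivative = data.frame(T = Tk, dSdT = dSk)))
  }
  ip <- Tk[i]
  if (i > 1 && i < length(dd)) {
    y1 <- dd[i - 1]; y2 <- dd[i]; y3 <- dd[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom != 0) {
      delta <- 0.5 * (y1 - y3) / denom
      ip <- Tk[i] + delta * (Tk[i + 1] - Tk[i])
    }
  }
  list(ip = ip, transition = TRUE,
       derivative = data.frame(T = Tk, dSdT = dSk))
}

#' Sigmoid (Hill-type) transition signal
#'
#' S(x) = S_min + (S_max - S_min) / (1 + (A50/x)^S_f). The slope factor S_f
#' sets both steepness and direction (a sign flip reverses monotonicity).
#'
#' @param x Independent variable (> 0).
#' @param p Named vector/list `S_min`, `S_max`, `A50`, `S_f`.
#' @return Signal values.
#' @export
sigmoid_signal <- function(x, p) {
  p[["S_min"]] + (p[["S_max"]] - p[["S_min"]]) /
    (1 + (p[["A50"]] / x)^p[["S_f"]])
}

register_model("sigmoid", function(p, x) sigmoid_signal(x, as.list(p)))

#' Fit a sigmoid midpoint
#'
#' Generic four-parameter sigmoid fit used e.g. for aggregation midpoints
#' (A50) as a function of a perturbant.
#'
#' @param series Series of signal vs positive x (at least 5 points).
#' @param direction `"increasing"` or `"decreasing"`; sets the sign of the
#'   initial slope factor.
#' @param init Optional named starting values; sensible defaults are
#'   derived from the data.
#' @return A `"coldlac_fit"`; the midpoint is `coef(fit)[["A50"]]`.
#' @export
sigmoid_midpoint_fit <- function(series,
                                 direction = c("increasing", "decreasing"),
                                 init = NULL) {
  direction <- match.arg(direction)
  d <- as.data.frame(series)
  stopifnot(nrow(d) >= 5, all(d$x > 0))
  if (is.null(init)) {
    init <- c(S_min = min(d$y), S_max = max(d$y),
              A50 = stats::median(d$x),
              S_f = if (direction == "increasing") 2 else -2)
  }
  fit_curve("sigmoid", d, unlist(init), lower = c(A50 = 1e-12))
}

#' Cosolute stabilization slope
#'
#' Ordinary least-squares slope of melting temperature against cosolute
#' concentration (e.g. degrees C per M trehalose), with its standard error.
#'
#' @param tm_series Series of tm vs cosolute concentration (M), at least 3
#'   points.
#' @return List with `slope`, `slope_se`, `intercept` and the `lm` fit.
#' @export
stabilization_slope <- function(tm_series) {
  d <- as.data.frame(tm_series)
  if (nrow(d) < 3) stop("need at least 3 points for a stabilization slope")
  fit <- stats::lm(y ~ x, data = d)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  list(slope = cf[[2]], slope_se = se[[2]], intercept = cf[[1]], lm = fit)
}

#' Refolding recovery fraction
#'
#' 100 * refolded / native, with first-order uncertainty propagation when
#' standard deviations are supplied.
#'
#' @param refolded_signal,native_signal Signal values (native non-zero).
#' @param sigma_refolded,sigma_native Optional standard deviations.
#' @return List with `percent` and `percent_se` (`NA` without sigmas).
#' @export
recovery_fraction <- function(refolded_signal, native_signal,
                              sigma_refolded = NA, sigma_native = NA) {
  if (any(native_signal == 0)) stop("native signal must be non-zero")
  pct <- 100 * refolded_signal / native_signal
  se <- NA_real_
  if (!is.na(sigma_refolded) && !is.na(sigma_native)) {
    se <- abs(pct) * sqrt((sigma_refolded / refolded_signal)^2 +
                            (sigma_native / native_signal)^2)
  } else if (!is.na(sigma_refolded)) {
    se <- 100 * sigma_refolded / abs(native_signal)
  }
  list(percent = pct, percent_se = se)
}
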