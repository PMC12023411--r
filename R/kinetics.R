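#' Extinction coefficient of ortho-nitrophenol as a function of pH
#'
#' Only the deprotonated phenolate (ONP-) absorbs at 420 nm, so the
#' effective extinction coefficient follows the Henderson-Hasselbalch
#' ionization fraction:
#' eps(pH) = eps_ONP- * 10^(pH - pKa) / (1 + 10^(pH - pKa)).
#' With the standard eps_ONP- = 4600 /M/cm and pKa = 7.2 this evaluates to
#' 1779.6 /M/cm at pH 7.0. (A value of 1741 /M/cm is sometimes quoted for
#' the same inputs; it is not consistent with the formula, which this
#' function follows.)
#'
#' @param pH Numeric pH values.
#' @param eps_deprotonated Extinction coefficient of ONP- (/M/cm), > 0.
#' @param pKa Acid dissociation constant of ONP (default 7.2).
#' @return Extinction coefficient(s) in /M/cm, strictly increasing in pH and
#'   bounded by (0, eps_deprotonated).
#' @export
#' @examples
#' onp_extinction(7.0)  # 1779.6
onp_extinction <- function(pH, eps_deprotonated = 4600, pKa = 7.2) {
  stopifnot(eps_deprotonated > 0, pKa > 0, pKa < 14)
  f <- 10^(pH - pKa) / (1 + 10^(pH - pKa))
  eps_deprotonated * f
}

#' Specific activity from an absorbance slope
#'
#' Beer-Lambert conversion of an initial absorbance slope (AU/min at 420 nm)
#' to specific activity in U/mg, i.e. micromol product per minute per mg of
#' enzyme: slope/(eps*path) gives mol/L/min of product, which is scaled to
#' micromol/min per mg of enzyme present per mL.
#'
#' @param abs_slope Absorbance slope, AU/min (>= 0).
#' @param extinction Extinction coefficient, /M/cm (> 0).
#' @param path_cm Optical path length, cm (> 0).
#' @param enzyme_conc Enzyme concentration in the cuvette, mg/mL (> 0).
#' @return Specific activity, U/mg.
#' @export
#' @examples
#' specific_activity(0.1741, 1741, 1, 0.001)  # 100 U/mg
specific_activity <- function(abs_slope, extinction, path_cm, enzyme_conc) {
  if (any(extinction <= 0) || any(path_cm <= 0) || any(enzyme_conc <= 0))
    stop("extinction, path_cm and enzyme_conc must be positive")
  molar_per_min <- abs_slope / (extinction * path_cm)  # mol/L/min
  umol_per_min_per_ml <- molar_per_min * 1e6 / 1000    # umol/min per mL
  umol_per_min_per_ml / enzyme_conc
}

#' Biphasic sequential-binding rate law
#'
#' Observed turnover for the scheme E + 2S <-> E:S + S <-> E:S2 with
#' dissociation constants K1, K2 and turnover numbers kcat1 (from E:S) and
#' kcat2 (from E:S2):
#' k_obs = (kcat1 + kcat2*S/K2) / (1 + K1/S + S/K2).
#' The S -> 0 limit is 0 and S -> Inf saturates at kcat2. With K2 -> Inf the
#' law reduces to classical Michaelis-Menten kcat1*S/(K1+S).
#'
#' @param S Substrate concentration, mol/L (>= 0).
#' @param p Named vector/list with `kcat1`, `kcat2`, `K1`, `K2` (K's in
#'   mol/L, > 0; kcat's >= 0, any consistent rate unit).
#' @return Observed rate in the units of the kcat's.
#' @export
biphasic_rate <- function(S, p) {
  stopifnot(p[["K1"]] > 0, p[["K2"]] > 0, all(S >= 0))
  out <- numeric(length(S))
  pos <- S > 0
  s <- S[pos]
  out[pos] <- (p[["kcat1"]] + p[["kcat2"]] * s / p[["K2"]]) /
    (1 + p[["K1"]] / s + s / p[["K2"]])
  out
}

#' Two-site magnesium activation rate law
#'
#' Three-state ladder for an enzyme with zero, one or two Mg2+ ions bound
#' (rates kcat_a, kcat_b, kcat_c; stepwise dissociation constants KA, KB):
#' k_obs = (kcat_a*KA/Mg + kcat_b + kcat_c*Mg/KB) / (KA/Mg + 1 + Mg/KB),
#' with limits kcat_a as Mg -> 0 and kcat_c as Mg -> Inf.
#'
#' @param mg Free Mg2+ concentration, mol/L (>= 0).
#' @param p Named vector/list with `kcat_a`, `kcat_b`, `kcat_c`, `KA`, `KB`.
#' @return Observed rate.
#' @export
mg_activation_rate <- function(mg, p) {
  stopifnot(p[["KA"]] > 0, p[["KB"]] > 0, all(mg >= 0))
  out <- numeric(length(mg))
  out[mg == 0] <- p[["kcat_a"]]
  pos <- mg > 0
  m <- mg[pos]
  out[pos] <- (p[["kcat_a"]] * p[["KA"]] / m + p[["kcat_b"]] +
                 p[["kcat_c"]] * m / p[["KB"]]) /
    (p[["KA"]] / m + 1 + m / p[["KB"]])
  out
}

register_model("biphasic", function(p, x)
  biphasic_rate(x, list(kcat1 = p[["kcat1"]], kcat2 = p[["kcat2"]],
                        K1 = 10^p[["logK1"]], K2 = 10^p[["logK2"]])))

register_model("mg", function(p, x)
  mg_activation_rate(x, list(kcat_a = p[["kcat_a"]], kcat_b = p[["kcat_b"]],
                             kcat_c = p[["kcat_c"]],
                             KA = 10^p[["logKA"]], KB = 10^p[["logKB"]])))

#' Fit the biphasic sequential-binding rate law
#'
#' Dissociation constants are fitted in log10 space to enforce positivity;
#' the multimodal loss surface can optionally be attacked with a seeded
#' multi-start around the supplied initialization.
#'
#' @param data Series of observed rate vs substrate concentration (mol/L).
#' @param init Named list/vector `kcat1`, `kcat2`, `K1`, `K2` (K's in
#'   mol/L).
#' @param n_start Number of multi-start replicates (1 = single start).
#' @param seed Seed for the multi-start perturbations.
#' @return A `"coldlac_fit"`; `coef()` names are `kcat1`, `kcat2`, `logK1`,
#'   `logK2`. Use [biphasic_params()] to recover natural-scale parameters in
#'   both parameterizations.
#' @export
fit_biphasic <- function(data, init, n_start = 1, seed = 1) {
  p0 <- c(kcat1 = init[["kcat1"]], kcat2 = init[["kcat2"]],
          logK1 = log10(init[["K1"]]), logK2 = log10(init[["K2"]]))
  lo <- c(kcat1 = 0, kcat2 = 0, logK1 = -12, logK2 = -12)
  hi <- c(kcat1 = Inf, kcat2 = Inf, logK1 = 2, logK2 = 2)
  best <- fit_curve("biphasic", data, p0, lower = lo, upper = hi)
  if (n_start > 1) {
    set.seed(seed)
    for (i in seq_len(n_start - 1)) {
      pi <- p0 * stats::runif(4, 0.5, 2)
      pi <- pmin(pmax(pi, lo), hi)
      f <- fit_curve("biphasic", data, pi, lower = lo, upper = hi)
      if (is.finite(f$redchi2) && (!is.finite(best$redchi2) ||
                                   f$redchi2 < best$redchi2)) best <- f
    }
  }
  best
}

#' Natural-scale parameters of a biphasic fit
#'
#' Returns both the dissociation-constant parameterization (kcat1, kcat2,
#' K1, K2) and the equivalent Michaelis-Menten style labels (Vmax1 = kcat1,
#' Km1 = K1, Vmax2 = kcat2, Km2 = K2) used when the two phases are reported
#' as two Michaelis constants with their maximal velocities.
#'
#' @param fit A fit from [fit_biphasic()].
#' @return Named list with both parameter sets.
#' @export
biphasic_params <- function(fit) {
  p <- coef(fit)
  list(
    kcat1 = p[["kcat1"]], kcat2 = p[["kcat2"]],
    K1 = 10^p[["logK1"]], K2 = 10^p[["logK2"]],
    Vmax1 = p[["kcat1"]], Km1 = 10^p[["logK1"]],
    Vmax2 = p[["kcat2"]], Km2 = 10^p[["logK2"]]
  )
}

#' Fit the two-site magnesium activation law
#'
#' @param data Series of observed rate vs Mg2+ concentration (mol/L).
#' @param init Named list/vector `kcat_a`, `kcat_b`, `kcat_c`, `KA`, `KB`.
#' @return A `"coldlac_fit"` with `kcat_a`, `kcat_b`, `kcat_c`, `logKA`,
#'   `logKB`.
#' @export
fit_mg <- function(data, init) {
  p0 <- c(kcat_a = init[["kcat_a"]], kcat_b = init[["kcat_b"]],
          kcat_c = init[["kcat_c"]],
          logKA = log10(init[["KA"]]), logKB = log10(init[["KB"]]))
  fit_curve("mg", data, p0,
            lower = c(kcat_a = 0, kcat_b = 0, kcat_c = 0,
                      logKA = -12, logKB = -12),
            upper = c(kcat_a = Inf, kcat_b = Inf, kcat_c = Inf,
                      logKA = 2, logKB = 2))
}

#' Eyring activation analysis
#'
#' Linear regression of ln(k/T) on 1/T. Slope = -dH_act/R and intercept =
#' ln(kappa*kB/h) + dS_act/R (transmission coefficient kappa defaults to 1).
#' Optionally fits two linear segments around a user-supplied breakpoint
#' (default 300 K), as used when the plot shows a kink near room
#' temperature.
#'
#' @param temps Absolute temperatures, K (> 0), at least 3 per segment.
#' @param rates Positive rate constants in any consistent unit.
#' @param breakpoint Optional breakpoint in K. `NULL` fits one segment.
#' @param kappa Transmission coefficient (> 0), default 1.
#' @return List of class `"eyring_fit"`: one element per segment, each with
#'   `dH_act` (cal/mol), `dS_act` (cal/(mol K)), standard errors and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' k <- eyring_rate(seq(283.15, 298.15, 5), dH_act = 8030, dS_act = 25)
#' eyring_fit(seq(283.15, 298.15, 5), k)
eyring_fit <- function(temps, rates, breakpoint = NULL, kappa = 1) {
  stopifnot(all(temps > 0), kappa > 0)
  if (any(rates <= 0)) stop("rates must be positive")
  seg <- if (is.null(breakpoint)) list(seq_along(temps)) else
    list(which(temps <= breakpoint), which(temps > breakpoint))
  seg <- Filter(length, seg)
  out <- lapply(seg, function(idx) {
    if (length(idx) < 3) stop("need at least 3 points per Eyring segment")
    T <- temps[idx]
    yl <- log(rates[idx] / T)
    fit <- stats::lm(yl ~ I(1 / T))
    cf <- stats::coef(fit)
    sd <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    R <- .const$R_cal
    list(
      dH_act = -cf[[2]] * R,
      dS_act = (cf[[1]] - log(kappa * .const$kB / .const$h)) * R,
      dH_se = sd[[2]] * R,
      dS_se = sd[[1]] * R,
      kappa = kappa,
      temps = T,
      lm = fit
    )
  })
  structure(out, class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  for (i in seq_along(x)) {
    s <- x[[i]]
    cat(sprintf(
      "segment %d (%.1f-%.1f K): dH_act = %.3g +/- %.2g kcal/mol, dS_act = %.3g +/- %.2g cal/(mol K)\n",
      i, min(s$temps), max(s$temps), s$dH_act / 1000, s$dH_se / 1000,
      s$dS_act, s$dS_se))
  }
  invisible(x)
}

#' Eyring rate law (forward evaluation)
#'
#' k(T) = kappa*(kB*T/h) * exp(-dH_act/(R*T) + dS_act/R).
#'
#' @param temps Absolute temperatures, K.
#' @param dH_act Activation enthalpy, cal/mol.
#' @param dS_act Activation entropy, cal/(mol K).
#' @param kappa Transmission coefficient, default 1.
#' @return Rate constants (1/s scale for kappa = 1).
#' @export
eyring_rate <- function(temps, dH_act, dS_act, kappa = 1) {
  R <- .const$R_cal
  kappa * (.const$kB * temps / .const$h) *
    exp(-dH_act / (R * temps) + dS_act / R)
}

# ---- ionic strength ---------------------------------------------------------

# stoichiometry of supported formal salts: list of (ion charge, count).
# Phosphate salts contribute to a common phosphate pool that is re-speciated
# at the stated pH; their counterions stay at formal concentration.
.salt_table <- list(
  NaCl    = list(cations = c(`1` = 1), anions = c(`-1` = 1), phosphate = 0),
  KCl     = list(cations = c(`1` = 1), anions = c(`-1` = 1), phosphate = 0),
  MgCl2   = list(cations = c(`2` = 1), anions = c(`-1` = 2), phosphate = 0),
  CaCl2   = list(cations = c(`2` = 1), anions = c(`-1` = 2), phosphate = 0),
  Na2SO4  = list(cations = c(`1` = 2), anions = c(`-2` = 1), phosphate = 0),
  Na2HPO4 = list(cations = c(`1` = 2), anions = NULL, phosphate = 1),
  K2HPO4  = list(cations = c(`1` = 2), anions = NULL, phosphate = 1),
  NaH2PO4 = list(cations = c(`1` = 1), anions = NULL, phosphate = 1),
  KH2PO4  = list(cations = c(`1` = 1), anions = NULL, phosphate = 1)
)

#' Buffer composition
#'
#' A list of formal salts with concentrations in mM plus the pH at which
#' phosphate is speciated. Only the second phosphate ionization
#' (H2PO4- / HPO4^2-, pKa2 default 7.2) is considered, the other protonation
#' states being negligible near neutral pH. Each supported salt dissolves
#' into a charge-neutral set of formal ions.
#'
#' @param salts Named numeric vector of formal concentrations in mM, names
#'   from the supported set (see Details in [ionic_strength()]).
#' @param pH Solution pH.
#' @param phosphate_pKa2 Second phosphate pKa (default 7.2).
#' @return Object of class `"buffer_composition"`.
#' @export
buffer_composition <- function(salts, pH = 7.0, phosphate_pKa2 = 7.2) {
  stopifnot(all(salts >= 0), length(names(salts)) == length(salts))
  unknown <- setdiff(names(salts), names(.salt_table))
  if (length(unknown)) stop("unknown salt identity: ",
                            paste(unknown, collapse = ", "))
  structure(list(salts = salts, pH = pH, phosphate_pKa2 = phosphate_pKa2),
            class = "buffer_composition")
}

#' Phosphate-buffered saline with 0.1 mM MgCl2 (buffer A)
#'
#' The working buffer of the study: 2.7 mM KCl, 8 mM Na2HPO4, 2 mM KH2PO4,
#' 137 mM NaCl, 0.1 mM MgCl2, pH 7.0.
#'
#' @param pH Solution pH (default 7.0).
#' @return A [buffer_composition()].
#' @export
buffer_a <- function(pH = 7.0) {
  buffer_composition(c(KCl = 2.7, Na2HPO4 = 8, KH2PO4 = 2, NaCl = 137,
                       MgCl2 = 0.1), pH = pH)
}

#' Ionic strength of a buffer with phosphate speciation
#'
#' I = 1/2 * sum(c_i * z_i^2) over all ionic species. Total phosphate is
#' split between H2PO4- and HPO4^2- by Henderson-Hasselbalch at the buffer
#' pH; counterions of the formal salts are counted at their formal
#' concentrations. Supported salts: NaCl, KCl, MgCl2, CaCl2, Na2SO4,
#' Na2HPO4, K2HPO4, NaH2PO4, KH2PO4.
#'
#' @param buffer A [buffer_composition()].
#' @return Ionic strength in mM.
#' @export
#' @examples
#' ionic_strength(buffer_a())  # 159.8 mM, i.e. 160 mM at 2 s.f.
ionic_strength <- function(buffer) {
  stopifnot(inherits(buffer, "buffer_composition"))
  tot <- 0
  phosphate <- 0
  for (nm in names(buffer$salts)) {
    conc <- buffer$salts[[nm]]
    s <- .salt_table[[nm]]
    for (z in names(s$cations))
      tot <- tot + conc * s$cations[[z]] * as.numeric(z)^2
    for (z in names(s$anions))
      tot <- tot + conc * s$anions[[z]] * as.numeric(z)^2
    phosphate <- phosphate + conc * s$phosphate
  }
  if (phosphate > 0) {
    f2 <- 1 / (1 + 10^(buffer$phosphate_pKa2 - buffer$pH))  # HPO4^2- frac
    tot <- tot + phosphate * ((1 - f2) * 1 + f2 * 4)
  }
  tot / 2
}
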