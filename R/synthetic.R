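# Seeded generators producing inputs with the statistical structure every
# fitter assumes. Default parameter values are the study conditions the
# corresponding experiments report; noise defaults are 2-3% of the dynamic
# range. Zero-noise generation is exactly on-model, so every
# generator/fitter pair closes (the closure suite in the tests).

.gen_meta <- function(generator, params, seed) {
  c(list(generator = generator, seed = seed),
    lapply(params, function(p) paste(signif(unlist(p), 8), collapse = " ")))
}

#' Synthetic monomer-dimer association titration
#'
#' Hydrodynamic-radius (or apparent-tm) observable on a log-spaced total
#' concentration grid under the monomer-dimer model, plus Gaussian noise.
#' The default design mirrors the wild-type FIDA titration: KD = 0.23 uM,
#' monomer/dimer endpoints 4.3 and 5.8 nm, 12 concentrations from 0.032 to
#' 33.5 uM. The preset `"ailac-dsf"` instead emulates the apparent-tm
#' titration (KD = 0.15 uM, endpoints 35.2 and 40.9 degrees C).
#'
#' @param KD Dissociation constant, mol/L.
#' @param obs_mono,obs_dimer Endpoint observables.
#' @param conc_range Range of total monomer concentration, mol/L.
#' @param n Number of log-spaced concentrations.
#' @param noise_sd Gaussian noise SD in observable units (default 0).
#' @param seed RNG seed.
#' @param preset `"ailac-wt-fida"`, `"ailac-dsf"` or `NULL` (use the
#'   explicit arguments).
#' @return A [titration_series()] of observable vs M0.
#' @export
gen_association_titration <- function(KD = 0.23e-6, obs_mono = 4.3,
                                      obs_dimer = 5.8,
                                      conc_range = c(0.032e-6, 33.5e-6),
                                      n = 12, noise_sd = 0, seed = 1,
                                      preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "ailac-wt-fida") {
      # defaults already are this preset
    } else if (preset == "ailac-dsf") {
      KD <- 0.15e-6; obs_mono <- 35.2; obs_dimer <- 40.9
    } else stop("unknown preset: ", preset)
  }
  M0 <- 10^seq(log10(conc_range[1]), log10(conc_range[2]), length.out = n)
  y <- association_observable(M0, list(KD = KD, obs_mono = obs_mono,
                                       obs_dimer = obs_dimer))
  set.seed(seed)
  y <- y + stats::rnorm(n, 0, noise_sd)
  titration_series(M0, y, sigma = if (noise_sd > 0) noise_sd else NA,
                   x_axis = "concentration_M",
                   meta = .gen_meta("association",
                                    list(KD = KD, obs_mono = obs_mono,
                                         obs_dimer = obs_dimer,
                                         noise_sd = noise_sd), seed))
}

#' Synthetic chemical denaturation curve
#'
#' Two- or three-state isothermal denaturation signal plus noise. The
#' two-state default has a midpoint of 0.66 M urea (activity-loss
#' transition); the three-state default has midpoints 0.6 and 4.0 M with an
#' intermediate plateau, mirroring a double-sigmoid unfolding.
#'
#' @param states 2 or 3.
#' @param params Named list of model parameters
#'   (see [two_state_signal()]/[three_state_signal()]); defaults supplied.
#' @param urea Denaturant grid, M (default 25 points over 0-3 M for two
#'   states, 0-6 M for three states).
#' @param noise_sd Gaussian noise SD in signal units (default 0).
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
gen_denaturation <- function(states = 2, params = NULL, urea = NULL,
                             noise_sd = 0, seed = 1) {
  RT <- .const$R_cal * 298.15
  if (states == 2) {
    p <- utils::modifyList(list(alpha_N = 1, beta_N = 0, alpha_D = 0,
                                beta_D = 0, m_DN = 3 * RT, u50 = 0.66,
                                RT = RT), params %||% list())
    if (is.null(urea)) urea <- seq(0, 3, length.out = 25)
    y <- two_state_signal(urea, p)
  } else if (states == 3) {
    p <- utils::modifyList(list(alpha_N = 1, beta_N = 0, alpha_I = 0.5,
                                beta_I = 0, alpha_D = 0, beta_D = 0,
                                m_IN = 3 * RT, m_DI = 3 * RT,
                                u50_I = 0.6, u50_D = 4.0, RT = RT),
                           params %||% list())
    if (is.null(urea)) urea <- seq(0, 6, length.out = 31)
    y <- three_state_signal(urea, p)
  } else stop("states must be 2 or 3")
  set.seed(seed)
  y <- y + stats::rnorm(length(urea), 0, noise_sd)
  titration_series(urea, y, sigma = if (noise_sd > 0) noise_sd else NA,
                   x_axis = "urea_M",
                   meta = .gen_meta("denaturation",
                                    c(list(states = states),
                                      p[intersect(c("u50", "u50_I", "u50_D"),
                                                  names(p))],
                                      list(noise_sd = noise_sd)), seed))
}

#' Synthetic thermal transition curve
#'
#' Van 't Hoff one- or two-step melting signal plus noise. Presets:
#' `"eclac-thermal"` (single transition at 53.6 C),
#' `"ailac-far-uv"` (double transition at 23.3 and 34.0 C),
#' `"ailac-dsf-ip"` (single transition at 40.9 C, DSF-ratio-like signal).
#'
#' @param transitions 1 or 2.
#' @param params Named list of parameters for [thermal_signal()]; defaults
#'   supplied (van 't Hoff enthalpies 100 kcal/mol, flat unit baselines).
#' @param temps Temperature grid, K (default 10-70 C in 0.5 C steps).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @param preset Optional preset name.
#' @return A [titration_series()] of signal vs temperature (K).
#' @export
gen_thermal <- function(transitions = 1, params = NULL, temps = NULL,
                        noise_sd = 0, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "eclac-thermal") {
      transitions <- 1
      params <- utils::modifyList(list(tm = celsius_to_kelvin(53.6)),
                                  params %||% list())
    } else if (preset == "ailac-far-uv") {
      transitions <- 2
      params <- utils::modifyList(
        list(tm1 = celsius_to_kelvin(23.3), tm2 = celsius_to_kelvin(34.0)),
        params %||% list())
    } else if (preset == "ailac-dsf-ip") {
      transitions <- 1
      params <- utils::modifyList(list(tm = celsius_to_kelvin(40.9)),
                                  params %||% list())
    } else stop("unknown preset: ", preset)
  }
  if (transitions == 1) {
    p <- utils::modifyList(list(tm = celsius_to_kelvin(53.6),
                                dH_vH = 1e5, aN = 1, bN = 0, aD = 0,
                                bD = 0), params %||% list())
  } else {
    p <- utils::modifyList(list(tm1 = celsius_to_kelvin(23.3), dH1 = 8e4,
                                tm2 = celsius_to_kelvin(34.0), dH2 = 1.2e5,
                                aN = 1, bN = 0, aI = 0.6, bI = 0, aD = 0,
                                bD = 0), params %||% list())
  }
  if (is.null(temps))
    temps <- celsius_to_kelvin(seq(10, 70, by = 0.5))
  y <- thermal_signal(temps, p, transitions)
  set.seed(seed)
  y <- y + stats::rnorm(length(temps), 0, noise_sd)
  titration_series(temps, y, sigma = if (noise_sd > 0) noise_sd else NA,
                   x_axis = "temperature_K",
                   meta = .gen_meta("thermal",
                                    c(list(transitions = transitions),
                                      p[grep("tm", names(p))],
                                      list(noise_sd = noise_sd)), seed))
}

#' Synthetic kinetics series
#'
#' Forward evaluation of a rate law plus relative Gaussian noise.
#' Models: `"biphasic"` (rate vs substrate), `"mg"` (rate vs Mg2+),
#' `"eyring"` (rate vs absolute temperature; default parameters are the
#' cold-enzyme activation preset dH_act = 8030 cal/mol, dS_act = 25.0
#' cal/(mol K) over 10-25 C).
#'
#' @param model `"biphasic"`, `"mg"` or `"eyring"`.
#' @param params Named list of rate-law parameters; defaults supplied.
#' @param x Independent-variable grid; defaults per model.
#' @param rel_noise Relative Gaussian noise (fraction of each value,
#'   default 0).
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
gen_kinetics <- function(model = c("biphasic", "mg", "eyring"),
                         params = NULL, x = NULL, rel_noise = 0, seed = 1) {
  model <- match.arg(model)
  if (model == "biphasic") {
    p <- utils::modifyList(list(kcat1 = 10, kcat2 = 100, K1 = 1e-3,
                                K2 = 1e-2), params %||% list())
    if (is.null(x)) x <- 10^seq(-5, -1, length.out = 12)
    y <- biphasic_rate(x, p)
  } else if (model == "mg") {
    p <- utils::modifyList(list(kcat_a = 4.6, kcat_b = 85.5, kcat_c = 20,
                                KA = 1e-5, KB = 1e-1), params %||% list())
    if (is.null(x)) x <- 10^seq(-7, 0, length.out = 15)
    y <- mg_activation_rate(x, p)
  } else {
    p <- utils::modifyList(list(dH_act = 8030, dS_act = 25.0, kappa = 1),
                           params %||% list())
    if (is.null(x)) x <- seq(283.15, 298.15, by = 5)
    y <- eyring_rate(x, p$dH_act, p$dS_act, p$kappa)
  }
  set.seed(seed)
  y <- y * (1 + stats::rnorm(length(x), 0, rel_noise))
  titration_series(x, y,
                   sigma = if (rel_noise > 0) abs(y) * rel_noise else NA,
                   x_axis = if (model == "eyring") "temperature_K"
                            else "concentration_M",
                   meta = .gen_meta(paste0("kinetics_", model),
                                    c(p, list(rel_noise = rel_noise)),
                                    seed))
}

#' Synthetic two-lobe bead dimer and its scattering curve
#'
#' Builds a parametric elongated dimer: two spherical lobes of beads on a
#' cubic lattice (one per "monomer") joined by a thin bridge, labeled as
#' three rigid parts (lobe / bridge / lobe). The default geometry (lobe
#' radius 25 Angstrom, center separation 83 Angstrom) has a Guinier radius
#' of gyration of ~43-44 Angstrom, the size of the dimeric enzyme. The
#' Debye curve on the requested q grid gets q-dependent Gaussian noise
#' sigma(q) = a + b*I(q).
#'
#' @param lobe_radius Lobe radius, Angstrom.
#' @param separation Lobe center separation, Angstrom.
#' @param spacing Bead lattice spacing, Angstrom (default 7; smaller =
#'   more beads).
#' @param q_grid Scattering grid (default 60 points, 0.008-0.35 1/A).
#' @param noise_a,noise_b Noise model sigma(q) = a + b*I(q)
#'   (defaults 0, i.e. noiseless).
#' @param scale,background Curve scale and constant background.
#' @param seed RNG seed.
#' @return List with `structure` (a [bead_structure()] with 3 parts and
#'   `anchors` attribute) and `curve` (a [saxs_curve()]).
#' @export
gen_bead_dimer <- function(lobe_radius = 25, separation = 83, spacing = 7,
                           q_grid = seq(0.008, 0.35, length.out = 60),
                           noise_a = 0, noise_b = 0, scale = 1,
                           background = 0, seed = 1) {
  g <- seq(-lobe_radius, lobe_radius, by = spacing)
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))
  lobe <- lat[rowSums(lat^2) <= lobe_radius^2, , drop = FALSE]
  half <- separation / 2
  lobe1 <- sweep(lobe, 2, c(-half, 0, 0), "+")
  lobe2 <- sweep(lobe, 2, c(half, 0, 0), "+")
  nb <- max(3, floor((separation - 2 * lobe_radius) / spacing) + 1)
  bx <- seq(-half + lobe_radius, half - lobe_radius, length.out = nb)
  bridge <- cbind(bx, 0, 0)
  xyz <- rbind(lobe1, bridge, lobe2)
  part <- c(rep(1L, nrow(lobe1)), rep(2L, nrow(bridge)),
            rep(3L, nrow(lobe2)))
  st <- bead_structure(xyz, part = part)
  # anchors: nearest lobe bead to each bridge end
  end1 <- bridge[1, ]; end2 <- bridge[nrow(bridge), ]
  i1 <- which.min(rowSums(sweep(lobe1, 2, end1)^2))
  i2 <- which.min(rowSums(sweep(lobe2, 2, end2)^2))
  b1 <- nrow(lobe1) + 1
  b2 <- nrow(lobe1) + nrow(bridge)
  anchors <- list(
    list(i = i1, j = b1,
         rest = sqrt(sum((lobe1[i1, ] - end1)^2)) + 1),
    list(i = nrow(lobe1) + nrow(bridge) + i2, j = b2,
         rest = sqrt(sum((lobe2[i2, ] - end2)^2)) + 1)
  )
  attr(st, "anchors") <- anchors
  cur <- debye_intensity(st, q_grid, scale = scale, background = background)
  I <- cur$I
  sig <- noise_a + noise_b * I
  if (any(sig > 0)) {
    set.seed(seed)
    I <- I + stats::rnorm(length(I), 0, sig)
  }
  list(structure = st,
       curve = saxs_curve(q_grid, I,
                          sigma = if (any(sig > 0)) sig else NA))
}

#' Synthetic protein family MSA
#'
#' Draws sequences from a column-profile model with three column classes:
#' invariant columns (a single residue), conserved "interface-coupled"
#' columns (a dominant residue with probability `conservation`, coupled to
#' a hidden two-state sequence label), and free columns (near-uniform
#' draws). Gaps are injected per position with probability `gap_prob`, and
#' `n_dup` exact duplicate sequences are appended to exercise the
#' redundancy filter.
#'
#' @param n Number of (unique) sequences.
#' @param n_invariant,n_coupled,n_free Column counts per class.
#' @param conservation Dominant-residue probability in coupled columns
#'   (default 0.9).
#' @param gap_prob Per-position gap probability (default 0.05).
#' @param n_dup Number of duplicated sequences appended (default 0).
#' @param seed RNG seed.
#' @return A [msa()] with attributes `column_class` (character vector
#'   "invariant"/"coupled"/"free") and `consensus` (character vector).
#' @export
gen_msa <- function(n = 200, n_invariant = 5, n_coupled = 10, n_free = 15,
                    conservation = 0.9, gap_prob = 0.05, n_dup = 0,
                    seed = 1) {
  set.seed(seed)
  aa <- setdiff(aa_alphabet(), "-")
  L <- n_invariant + n_coupled + n_free
  class <- c(rep("invariant", n_invariant), rep("coupled", n_coupled),
             rep("free", n_free))
  cons <- sample(aa, L, replace = TRUE)
  alt <- vapply(cons, function(a) sample(setdiff(aa, a), 1), character(1))
  state <- sample(0:1, n, replace = TRUE)  # hidden label coupling columns
  m <- matrix("", n, L)
  for (j in seq_len(L)) {
    if (class[j] == "invariant") {
      m[, j] <- cons[j]
    } else if (class[j] == "coupled") {
      dom <- ifelse(state == 1, cons[j], alt[j])
      hit <- stats::runif(n) < conservation
      m[, j] <- ifelse(hit, dom, sample(aa, n, replace = TRUE))
    } else {
      m[, j] <- sample(aa, n, replace = TRUE)
    }
  }
  if (gap_prob > 0) {
    gaps <- matrix(stats::runif(n * L) < gap_prob, n, L)
    gaps[, class == "invariant"] <- FALSE
    m[gaps] <- "-"
  }
  if (n_dup > 0) {
    dup <- m[sample(n, n_dup, replace = TRUE), , drop = FALSE]
    m <- rbind(m, dup)
  }
  out <- msa(m)
  attr(out, "column_class") <- class
  attr(out, "consensus") <- cons
  out
}

#' Synthetic taylorgram
#'
#' [taylorgram_simulate()] wrapper with the declared synthetic instrument
#' fixture. The default mixture is the wild-type endpoint: free label at
#' 0.6 nm plus protein at 4.3 nm.
#'
#' @param mix Species data frame (`Rh` nm, `amplitude`); default label +
#'   protein mixture.
#' @param instrument A [fida_instrument()].
#' @param noise_sd Detector noise SD (default 0).
#' @param seed RNG seed.
#' @return A `"taylorgram"`.
#' @export
gen_taylorgram <- function(mix = data.frame(Rh = c(0.6, 4.3),
                                            amplitude = c(0.3, 1.0)),
                           instrument = fida_instrument(),
                           noise_sd = 0, seed = 1) {
  taylorgram_simulate(mix, instrument, noise_sd = noise_sd, seed = seed)
}
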