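# Seeded synthetic-data generators mirroring the three experiment
# families, for download-free tests and parameter-recovery studies.
# Defaults reproduce the study's own conditions: the stepwise-dilution
# concentration grid (0.013-0.789 mM), coefficient scales around
# 2.1e-10 m^2/s (ligand) and 0.75e-10 m^2/s (duplex), and localized
# ppm-scale perturbations at the nick-flanking units.

# H1' shifts (ppm) of the free nicked decamer, used as the CSP baseline
default_csp_baseline <- c(
  G1 = 6.022, C2 = 5.663, G3 = 6.110, T4 = 6.095, T5 = 6.215,
  G6 = 5.830, T7 = 6.093, C8 = 5.766, G9 = 5.904, C10 = 6.238,
  G11 = 6.022, C12 = 5.633, G13 = 5.690, A14 = 6.261, C15 = 5.560,
  A16 = 5.826, A17 = 6.156, C18 = 5.604, G19 = 5.904, C20 = 6.226)

#' Ground-truth specification for the synthetic generators
#'
#' Collects the parameters, grids, noise levels and seed from which the
#' three generators ([simulate_dilution_series()],
#' [simulate_dosy_experiment()], [simulate_csp_tables()]) produce data.
#' The noise model is additive homoscedastic Gaussian on each observable
#' (Hz for dilution shifts, coefficient units for diffusion, ppm for
#' CSP), matching the single symmetric uncertainties with which such
#' measurements are reported.
#'
#' Defaults are the study's own scale: the compound-1 dilution grid, a
#' self-association constant of 6.4 mM^-1 with a 112 Hz limiting shift,
#' 3 Hz shift noise, a binding constant of 76 mM^-1 with free
#' coefficients 2.12 / 0.75 (1e-10 m^2/s) and 0.05 coefficient noise,
#' and the compound-1 H1' perturbation pattern at the nick (T5, G6,
#' C15, A16) over the measured free-duplex baseline with 0.005 ppm
#' noise.
#'
#' @param seed Integer RNG seed; every generator call is reproducible
#'   given the spec.
#' @param conc_grid Dilution concentrations, mM, strictly increasing.
#' @param truth_ka True self-association constant, mM^-1.
#' @param truth_delta_max Named numeric: per-proton limiting shift, Hz.
#' @param shift_noise_sd Gaussian noise on dilution shifts, Hz.
#' @param binding_truth_ka True 1:1 binding constant, mM^-1.
#' @param d_free_ligand,d_free_dna,d_complex Diffusion coefficients,
#'   1e-10 m^2/s; `d_complex <= d_free_dna` (set it lower to study the
#'   bias of approximating the complex coefficient by the duplex one).
#' @param d_noise_sd Gaussian noise on observed coefficients.
#' @param csp_baseline Named numeric: free-state shift per unit, ppm.
#' @param csp_perturbation_sites Named numeric: injected shift change
#'   (ppm, free minus complexed) per perturbed unit.
#' @param csp_noise_sd Gaussian noise on complexed-state shifts, ppm.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(seed = 1, truth_ka = 5)
#' @export
synthetic_spec <- function(seed = 1L,
                           conc_grid = c(0.013, 0.027, 0.053, 0.099,
                                         0.199, 0.349, 0.543, 0.789),
                           truth_ka = 6.4,
                           truth_delta_max = c(H9 = 111.9),
                           shift_noise_sd = 3,
                           binding_truth_ka = 76,
                           d_free_ligand = 2.12,
                           d_free_dna = 0.75,
                           d_complex = 0.75,
                           d_noise_sd = 0.05,
                           csp_baseline = default_csp_baseline,
                           csp_perturbation_sites = c(T5 = 0.064, G6 = 0.035,
                                                      C15 = -0.050, A16 = 0.019),
                           csp_noise_sd = 0.005) {
  if (any(diff(conc_grid) <= 0)) abort("`conc_grid` must be strictly increasing")
  if (any(c(shift_noise_sd, d_noise_sd, csp_noise_sd) < 0)) {
    abort("noise standard deviations must be non-negative")
  }
  if (truth_ka <= 0 || binding_truth_ka < 0) abort("association constants must be positive")
  if (is.null(names(truth_delta_max)) || any(!nzchar(names(truth_delta_max)))) {
    abort("`truth_delta_max` must be a named vector (proton labels)")
  }
  if (!(d_free_ligand > d_free_dna)) abort("d_free_ligand must exceed d_free_dna")
  if (d_complex > d_free_dna) abort("d_complex must not exceed d_free_dna")
  if (is.null(names(csp_baseline))) abort("`csp_baseline` must be named (unit labels)")
  structure(list(seed = as.integer(seed), conc_grid = conc_grid,
                 truth_ka = truth_ka, truth_delta_max = truth_delta_max,
                 shift_noise_sd = shift_noise_sd,
                 binding_truth_ka = binding_truth_ka,
                 d_free_ligand = d_free_ligand, d_free_dna = d_free_dna,
                 d_complex = d_complex, d_noise_sd = d_noise_sd,
                 csp_baseline = csp_baseline,
                 csp_perturbation_sites = csp_perturbation_sites,
                 csp_noise_sd = csp_noise_sd),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic ground-truth spec (seed ", x$seed, ")\n",
      "  dilution: ka = ", x$truth_ka, " mM^-1, ",
      length(x$truth_delta_max), " proton(s), noise ", x$shift_noise_sd, " Hz\n",
      "  binding:  ka = ", x$binding_truth_ka, " mM^-1, D = ",
      x$d_free_ligand, "/", x$d_free_dna, "/", x$d_complex,
      " (1e-10 m^2/s), noise ", x$d_noise_sd, "\n",
      "  csp:      ", length(x$csp_perturbation_sites), " perturbed unit(s), noise ",
      x$csp_noise_sd, " ppm\n", sep = "")
  invisible(x)
}

#' Simulate dilution chemical-shift series
#'
#' Forward-simulates the isodesmic stacking model on the spec's
#' concentration grid for every proton in `truth_delta_max`, adds
#' Gaussian noise, and re-references each series so the lowest-
#' concentration point is exactly 0 (the convention of measured
#' dilution tables).
#'
#' @param spec A [synthetic_spec()].
#' @param compound_id Identifier recorded in the output.
#' @return A long tibble in the shape of [read_dilution_table()] output.
#' @examples
#' simulate_dilution_series(synthetic_spec(seed = 7, shift_noise_sd = 0))
#' @export
simulate_dilution_series <- function(spec, compound_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  out <- purrr::imap(spec$truth_delta_max, function(dmax, proton) {
    y <- isodesmic_shift(spec$truth_ka, spec$conc_grid, dmax) +
      rnorm(length(spec$conc_grid), 0, spec$shift_noise_sd)
    y <- y - y[1]   # re-reference to the lowest-concentration sample
    tibble(compound_id = compound_id, proton = proton,
           conc = spec$conc_grid, delta_shift = y)
  })
  dplyr::bind_rows(out)
}

#' Simulate a DOSY binding experiment
#'
#' Solves the 1:1 mass-action equilibrium at the true binding constant,
#' forms the fast-exchange population-weighted diffusion coefficients of
#' ligand and duplex using the spec's complex coefficient, and adds
#' Gaussian noise to both observed coefficients.  With zero noise and
#' `d_complex = d_free_dna`, [analyze_binding()] inverts the experiment
#' exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param c_dna,c_ligand Total concentrations, mM.
#' @return A one-row tibble ready for [analyze_binding()], with the
#'   noise level in the sigma columns.
#' @examples
#' simulate_dosy_experiment(synthetic_spec(seed = 3), 0.6, 0.6)
#' @export
simulate_dosy_experiment <- function(spec, c_dna = 0.6, c_ligand = 0.6) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  x <- solve_equilibrium(spec$binding_truth_ka, c_dna, c_ligand)
  mf_l <- 1 - x / c_ligand
  mf_dna <- 1 - x / c_dna
  d_obs_l <- mf_l * spec$d_free_ligand + (1 - mf_l) * spec$d_complex +
    rnorm(1, 0, spec$d_noise_sd)
  d_obs_dna <- mf_dna * spec$d_free_dna + (1 - mf_dna) * spec$d_complex +
    rnorm(1, 0, spec$d_noise_sd)
  tibble(c_ligand = c_ligand, c_dna = c_dna,
         d_obs_ligand = d_obs_l, d_obs_dna = d_obs_dna,
         d_free_ligand = spec$d_free_ligand, d_free_dna = spec$d_free_dna,
         sigma_d_obs_ligand = spec$d_noise_sd,
         sigma_d_obs_dna = spec$d_noise_sd,
         sigma_d_free_ligand = 0, sigma_d_free_dna = 0)
}

#' Simulate free/complexed chemical-shift tables
#'
#' The free table is the spec's baseline; the complexed table is the
#' baseline minus the injected perturbations (at the named sites) plus
#' Gaussian noise everywhere, so `compute_csp()` recovers the injected
#' pattern up to noise.  Perturbation sites must be units of the nick
#' map.
#'
#' @param spec A [synthetic_spec()].
#' @param nick A [nick_map()]; sites are validated against its units.
#' @param proton_class Class recorded in the output records.
#' @return A tibble in the shape of [read_shift_table()] output, holding
#'   the free (`delta_free`) and complexed (`delta_complex`) tables.
#' @examples
#' simulate_csp_tables(synthetic_spec(seed = 5))
#' @export
simulate_csp_tables <- function(spec, nick = nick_map(), proton_class = "H1'") {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(nick, "nick_map"))
  set.seed(spec$seed)
  units <- names(spec$csp_baseline)
  sites <- names(spec$csp_perturbation_sites)
  unknown <- setdiff(sites, c(nick$strand1, nick$strand2))
  if (length(unknown)) {
    abort(sprintf("perturbation site(s) not in the nick map: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (length(setdiff(sites, units))) {
    abort("perturbation sites must appear in the baseline")
  }
  inject <- setNames(rep(0, length(units)), units)
  inject[sites] <- spec$csp_perturbation_sites
  free <- spec$csp_baseline
  complexed <- free - inject + rnorm(length(units), 0, spec$csp_noise_sd)
  tibble(unit_label = units, proton_class = proton_class,
         delta_free = unname(free), delta_complex = unname(complexed))
}
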