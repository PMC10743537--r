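# DOSY fast-exchange binding analysis: mole fractions from diffusion
# coefficients, 1:1 mass-action binding constant, delta-method and
# Monte-Carlo uncertainty, and the dilution-trend check.
#
# Hard model assumptions (echoed in every report): 1:1 stoichiometry,
# fast exchange on the NMR timescale (observed coefficients are
# population-weighted averages), ligand self-association neglected, and
# by default the complex diffuses like the duplex (its observed
# coefficient in the mixture stands in for the complex coefficient).

#' Free-ligand mole fraction from diffusion coefficients
#'
#' Under fast exchange the observed ligand coefficient is the population-
#' weighted average `d_obs = MF * d_free + (1 - MF) * d_complex`, so the
#' free mole fraction is `MF = (d_obs - d_complex) / (d_free - d_complex)`.
#' Values outside `[0, 1]` by at most `noise` are clipped with a warning
#' (measurement noise); larger excursions abort, since they mean the
#' two-state fast-exchange model is violated.  The fraction is invariant
#' under a common rescaling of all three coefficients.
#'
#' @param d_obs Observed (averaged) coefficient of the ligand in the
#'   mixture, 1e-10 m^2/s.
#' @param d_free Coefficient of the uncomplexed ligand.
#' @param d_complex Coefficient of the complex.
#' @param noise Tolerance (same units) within which out-of-range values
#'   are clipped rather than rejected.  Default 0.
#' @return Free mole fraction in `[0, 1]`.
#' @examples
#' free_fraction(0.93, 2.12, 0.74)  # ligand mostly bound
#' @export
free_fraction <- function(d_obs, d_free, d_complex, noise = 0) {
  if (any(c(d_obs, d_free, d_complex) <= 0)) {
    abort("diffusion coefficients must be positive")
  }
  span <- d_free - d_complex
  if (span == 0) {
    abort(paste("d_free equals d_complex: no diffusion contrast,",
                "binding is unobservable by DOSY"))
  }
  mf <- (d_obs - d_complex) / span
  excess <- pmax(mf - 1, -mf, 0)
  if (excess > noise + 1e-12) {
    abort(sprintf(
      "mole fraction %.3f outside [0, 1] by more than the noise tolerance %.3g; the two-state fast-exchange model does not hold for these inputs",
      mf, noise))
  }
  if (excess > 0) {
    warn(sprintf("mole fraction %.3f clipped to [0, 1] (within noise)", mf))
    mf <- min(max(mf, 0), 1)
  }
  mf
}

#' Complex concentration from the bound mole fraction
#'
#' `[DNA.L] = mf_bound * c_total`, the ligand-side mass balance.
#'
#' @param mf_bound Bound mole fraction of the ligand, in `[0, 1]`.
#' @param c_total Total ligand concentration, mM.
#' @return Complex concentration, mM.
#' @export
complex_concentration <- function(mf_bound, c_total) {
  if (any(mf_bound < 0 | mf_bound > 1)) abort("`mf_bound` must lie in [0, 1]")
  if (any(c_total < 0)) abort("`c_total` must be non-negative")
  mf_bound * c_total
}

#' 1:1 binding constant from the complex concentration
#'
#' Mass action for `DNA + L <-> DNA.L`:
#' `Ka = [DNA.L] / ((C_DNA - [DNA.L]) * (C_L - [DNA.L]))` with total
#' (initial) concentrations `C_DNA`, `C_L`.
#'
#' @param complex_conc Complex concentration, mM; must be below both
#'   totals (saturation leaves Ka undefined).
#' @param c_dna Total duplex concentration, mM.
#' @param c_ligand Total ligand concentration, mM.
#' @return Binding constant, mM^-1.
#' @examples
#' binding_constant(0.54, 0.60, 0.60)  # 150 mM^-1
#' @export
binding_constant <- function(complex_conc, c_dna, c_ligand) {
  if (any(complex_conc < 0)) abort("`complex_conc` must be non-negative")
  if (any(complex_conc >= pmin(c_dna, c_ligand))) {
    abort("complex concentration reaches a total concentration: saturated, Ka undefined")
  }
  complex_conc / ((c_dna - complex_conc) * (c_ligand - complex_conc))
}

#' Equilibrium complex concentration for a known binding constant
#'
#' Inverts the mass-action relation: solves
#' `ka * x^2 - (ka * (c_dna + c_ligand) + 1) * x + ka * c_dna * c_ligand = 0`
#' for the physical root `x` in `[0, min(c_dna, c_ligand))`, evaluated in
#' the cancellation-free form `x = 2 ka P / (B + sqrt(B^2 - 4 ka^2 P))`
#' with `B = ka (c_dna + c_ligand) + 1` and `P = c_dna * c_ligand`.
#' `ka = 0` gives 0; as `ka` grows `x` approaches the stoichiometric
#' limit `min(c_dna, c_ligand)`.
#'
#' @param ka Binding constant, mM^-1 (>= 0).
#' @param c_dna,c_ligand Total concentrations, mM.
#' @return Complex concentration, mM.
#' @examples
#' solve_equilibrium(150, 0.60, 0.60)  # 0.54
#' @export
solve_equilibrium <- function(ka, c_dna, c_ligand) {
  if (any(ka < 0)) abort("`ka` must be non-negative")
  if (any(c(c_dna, c_ligand) < 0)) abort("concentrations must be non-negative")
  B <- ka * (c_dna + c_ligand) + 1
  P <- c_dna * c_ligand
  2 * ka * P / (B + sqrt(B^2 - 4 * ka^2 * P))
}

# central-difference gradient of f at x (named numeric vector)
num_grad <- function(f, x, rel_h = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- rel_h * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Ka as a closed-form chain of the three measured coefficients
ka_chain <- function(d_obs_l, d_free_l, d_complex, c_ligand, c_dna) {
  mf_free <- (d_obs_l - d_complex) / (d_free_l - d_complex)
  x <- (1 - mf_free) * c_ligand
  x / ((c_dna - x) * (c_ligand - x))
}

#' DOSY binding analysis of ligand-DNA experiments
#'
#' Chains the fast-exchange mole fraction, the ligand-side complex
#' concentration and the 1:1 mass-action binding constant for each
#' experiment (row).  Unless an independent `d_complex` is supplied, the
#' complex coefficient is approximated by the observed duplex coefficient
#' in the mixture (`d_obs_dna`), justified when the duplex is much larger
#' than the ligand.  The free-ligand coefficient must be measured at the
#' most dilute available concentration (see [as_binding_experiment()]),
#' since self-association biases it at working concentrations.
#'
#' `ka_sigma` is a first-order (delta-method) propagation of the stated
#' coefficient uncertainties (`sigma_d_obs_ligand`, `sigma_d_obs_dna`,
#' `sigma_d_free_ligand`; absent columns count as 0) through the
#' closed-form chain, using a central-difference gradient.  Because Ka
#' depends hyperbolically on the complex concentration near saturation,
#' its sampling distribution is heavy-tailed; [ka_uncertainty_mc()]
#' provides the Monte-Carlo cross-check.
#'
#' If the ligand diffuses as when free (`d_obs_ligand == d_free_ligand`)
#' the experiment shows no binding: `ka = 0` is reported with
#' `no_binding = TRUE`.
#'
#' @param data Tibble with one experiment per row; required columns
#'   `c_ligand`, `c_dna` (mM), `d_obs_ligand`, `d_obs_dna`,
#'   `d_free_ligand`, `d_free_dna` (1e-10 m^2/s); optional per-coefficient
#'   uncertainty columns `sigma_d_obs_ligand`, `sigma_d_obs_dna`,
#'   `sigma_d_free_ligand`, `sigma_d_free_dna`.
#' @param d_complex Optional independent complex coefficient(s); default
#'   `NULL` uses `d_obs_dna`.
#' @param noise Clipping tolerance for mole fractions passed to
#'   [free_fraction()]; default: propagated first-order uncertainty of
#'   the mole fraction itself.
#' @return The input with columns `mf_free_ligand`, `mf_bound`,
#'   `complex_conc` (mM), `ka`, `ka_sigma` (mM^-1) and `no_binding`
#'   appended.  The model-assumption list is attached as the
#'   `"assumptions"` attribute and shown by the report functions.
#' @examples
#' dosy <- read_diffusion_table(nmrbind_example("dosy_binding_compound1.csv"))
#' as_binding_experiment(dosy, c_ligand = 0.6, c_dna = 0.6) |>
#'   analyze_binding()
#' @export
analyze_binding <- function(data, d_complex = NULL, noise = NULL) {
  need <- c("c_ligand", "c_dna", "d_obs_ligand", "d_obs_dna",
            "d_free_ligand", "d_free_dna")
  stopifnot(all(need %in% names(data)))
  for (s in paste0("sigma_", c("d_obs_ligand", "d_obs_dna",
                               "d_free_ligand", "d_free_dna"))) {
    if (!s %in% names(data)) data[[s]] <- 0
  }
  if (any(data$d_free_ligand <= data$d_free_dna)) {
    abort("d_free_ligand must exceed d_free_dna (the ligand is the smaller species)")
  }
  n <- nrow(data)
  d_complex <- if (is.null(d_complex)) data$d_obs_dna else rep_len(d_complex, n)
  res <- purrr::map(seq_len(n), function(i) {
    r <- data[i, ]
    dc <- d_complex[i]
    # first-order uncertainty of the free mole fraction, for the clipping
    # tolerance and for diagnostics
    g_mf <- num_grad(function(p) (p[1] - p[3]) / (p[2] - p[3]),
                     c(r$d_obs_ligand, r$d_free_ligand, dc))
    sig <- c(r$sigma_d_obs_ligand, r$sigma_d_free_ligand, r$sigma_d_obs_dna)
    mf_sigma <- sqrt(sum((g_mf * sig)^2))
    tol <- noise %||% mf_sigma
    mf_free <- free_fraction(r$d_obs_ligand, r$d_free_ligand, dc, noise = tol)
    no_binding <- mf_free >= 1
    x <- complex_concentration(1 - mf_free, r$c_ligand)
    ka <- if (no_binding) 0 else binding_constant(x, r$c_dna, r$c_ligand)
    g <- num_grad(function(p) ka_chain(p[1], p[2], p[3], r$c_ligand, r$c_dna),
                  c(r$d_obs_ligand, r$d_free_ligand, dc))
    ka_sigma <- sqrt(sum((g * sig)^2))
    tibble(mf_free_ligand = mf_free, mf_bound = 1 - mf_free,
           complex_conc = x, ka = ka, ka_sigma = ka_sigma,
           no_binding = no_binding)
  })
  out <- dplyr::bind_cols(data, dplyr::bind_rows(res))
  attr(out, "assumptions") <- binding_assumptions(independent_d_complex =
                                                    !is.null(d_complex) && !identical(d_complex, data$d_obs_dna))
  out
}

binding_assumptions <- function(independent_d_complex = FALSE) {
  c("1:1 DNA.L stoichiometry",
    "fast exchange: observed diffusion coefficients are population-weighted averages",
    "ligand self-association neglected in the mixture",
    if (independent_d_complex)
      "complex coefficient supplied independently"
    else
      "complex coefficient approximated by the observed duplex coefficient in the mixture",
    "free-ligand coefficient taken at the most dilute available concentration")
}

#' Assemble a binding experiment from diffusion records
#'
#' Builds the one-row experiment table [analyze_binding()] consumes from
#' a long diffusion table whose `species_id` values follow the
#' convention `"ligand_free"`, `"dna_free"`, `"ligand_obs"`,
#' `"dna_obs"` (the latter two measured in the mixture).  When several
#' `ligand_free` records exist (a dilution series), the most dilute one
#' is selected: the free coefficient must come from the lowest available
#' concentration, where self-association bias is smallest.
#'
#' @param records Tibble from [read_diffusion_table()].
#' @param c_ligand,c_dna Total concentrations in the mixture, mM.
#' @return A one-row tibble ready for [analyze_binding()].
#' @export
as_binding_experiment <- function(records, c_ligand, c_dna) {
  pick <- function(id, dilutest = FALSE) {
    r <- dplyr::filter(records, .data$species_id == id)
    if (nrow(r) == 0) abort(sprintf("no record with species '%s'", id))
    if (dilutest) r <- r[which.min(r$conc), ] else r <- r[1, ]
    r
  }
  lf <- pick("ligand_free", dilutest = TRUE)
  df <- pick("dna_free")
  lo <- pick("ligand_obs")
  do <- pick("dna_obs")
  tibble(c_ligand = c_ligand, c_dna = c_dna,
         d_obs_ligand = lo$d_coef, d_obs_dna = do$d_coef,
         d_free_ligand = lf$d_coef, d_free_dna = df$d_coef,
         sigma_d_obs_ligand = lo$d_sigma, sigma_d_obs_dna = do$d_sigma,
         sigma_d_free_ligand = lf$d_sigma, sigma_d_free_dna = df$d_sigma)
}

#' DNA-side consistency check of the complex concentration
#'
#' The duplex-side counterpart of the ligand-side mass balance: with an
#' independent complex coefficient, the free-DNA mole fraction follows
#' from the observed duplex coefficient and gives
#' `[DNA.L] = (1 - MF_DNA) * c_dna`.  With the default approximation
#' (complex coefficient = observed duplex coefficient) the contrast
#' degenerates, so an explicit `d_complex` is required here.
#'
#' @param d_obs_dna Observed duplex coefficient in the mixture.
#' @param d_free_dna Free-duplex coefficient.
#' @param d_complex Independent complex coefficient.
#' @param c_dna Total duplex concentration, mM.
#' @param noise Clipping tolerance for the mole fraction.
#' @return Complex concentration (mM) estimated from the DNA side.
#' @export
complex_conc_dna_side <- function(d_obs_dna, d_free_dna, d_complex, c_dna,
                                  noise = 0) {
  mf_dna <- free_fraction(d_obs_dna, d_free_dna, d_complex, noise = noise)
  complex_concentration(1 - mf_dna, c_dna)
}

#' Monte-Carlo uncertainty of the DOSY binding constant
#'
#' Draws the three measured coefficients from independent Gaussians at
#' their stated uncertainties, recomputes Ka for each draw, and
#' summarises the spread.  Draws that land outside the physical domain
#' (mole fraction outside `[0, 1]` or saturation) are dropped and
#' counted.  Because the Ka distribution is strongly right-skewed near
#' saturation, the summary reports both the raw standard deviation and a
#' robust sigma: half the central 68.27% interquantile width, the
#' Gaussian-equivalent spread customarily quoted for heavy-tailed
#' derived quantities.
#'
#' @param experiment One-row tibble as consumed by [analyze_binding()].
#' @param n Number of draws.
#' @param seed Optional RNG seed for reproducibility.
#' @return A one-row tibble: `ka_sd`, `ka_sigma_robust`, `ka_median`,
#'   `n_valid`, `n_dropped`.
#' @export
ka_uncertainty_mc <- function(experiment, n = 10000, seed = NULL) {
  stopifnot(nrow(experiment) == 1)
  if (!is.null(seed)) set.seed(seed)
  e <- experiment
  d_obs <- rnorm(n, e$d_obs_ligand, e$sigma_d_obs_ligand %||% 0)
  d_free <- rnorm(n, e$d_free_ligand, e$sigma_d_free_ligand %||% 0)
  d_comp <- rnorm(n, e$d_obs_dna, e$sigma_d_obs_dna %||% 0)
  mf <- (d_obs - d_comp) / (d_free - d_comp)
  x <- (1 - mf) * e$c_ligand
  ok <- is.finite(mf) & mf >= 0 & mf <= 1 & x < pmin(e$c_dna, e$c_ligand)
  ka <- binding_constant(x[ok], e$c_dna, e$c_ligand)
  q <- stats::quantile(ka, c(0.5 - 0.6827 / 2, 0.5, 0.5 + 0.6827 / 2),
                       names = FALSE)
  tibble(ka_sd = sd(ka), ka_sigma_robust = (q[3] - q[1]) / 2,
         ka_median = q[2], n_valid = sum(ok), n_dropped = n - sum(ok))
}

#' Concentration trend of diffusion coefficients
#'
#' Self-associating solutes diffuse more slowly at higher concentration,
#' so their apparent coefficient should be non-increasing with
#' concentration.  For each species the records are ordered by ascending
#' concentration and each consecutive increase is compared against the
#' combined stated uncertainty `sqrt(s_i^2 + s_{i+1}^2)`; increases
#' beyond it are violations.  A species whose total decrease also
#' exceeds the combined end-point uncertainty is reported as
#' aggregation-consistent; one whose coefficients are flat within noise
#' shows no trend.
#'
#' @param records Tibble from [read_diffusion_table()]; at least 2
#'   records per species.
#' @return A tibble with one row per species: `n_points`,
#'   `monotone_decreasing`, `n_violations`, `total_decrease`, and a
#'   `conclusion` string (`"aggregation-consistent"`, `"no significant
#'   trend"`, or `"trend violated"`).
#' @examples
#' read_diffusion_table(nmrbind_example("diffusion_free_ligand.csv")) |>
#'   check_concentration_trend()
#' @export
check_concentration_trend <- function(records) {
  stopifnot(all(c("species_id", "conc", "d_coef", "d_sigma") %in% names(records)))
  dplyr::summarise(
    dplyr::group_by(records, species_id = .data$species_id),
    {
      d <- dplyr::arrange(dplyr::pick(dplyr::everything()), .data$conc)
      if (nrow(d) < 2) {
        abort(sprintf("species '%s' has fewer than 2 records", species_id[1]))
      }
      inc <- diff(d$d_coef)
      tol <- sqrt(d$d_sigma[-nrow(d)]^2 + d$d_sigma[-1]^2)
      viol <- sum(inc > tol)
      drop_total <- d$d_coef[1] - d$d_coef[nrow(d)]
      drop_tol <- sqrt(d$d_sigma[1]^2 + d$d_sigma[nrow(d)]^2)
      tibble(n_points = nrow(d),
             monotone_decreasing = viol == 0 && all(inc <= 0),
             n_violations = viol,
             total_decrease = drop_total,
             conclusion = if (viol > 0) "trend violated"
                          else if (drop_total > drop_tol) "aggregation-consistent"
                          else "no significant trend")
    },
    .groups = "drop")
}
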