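# Isodesmic (indefinite, equal-K) self-association: forward model,
# per-proton nonlinear fitting, and compound-level aggregation.

#' Isodesmic stacking shift change
#'
#' Forward model for the fast-exchange-averaged chemical-shift change of a
#' self-associating solute under the isodesmic model, in which every
#' stacking step has the same association constant `ka`.  With
#' `C = ka * conc_total`, the observed change relative to the monomer
#' shift is
#'
#'   delta_obs = delta_max * (2C + 1 - sqrt(4C + 1)) / (2C)
#'
#' The bracket is the stacked fraction `x = ka * m`, where `m` is the
#' monomer concentration solving the isodesmic mass balance
#' `conc_total = m / (1 - ka * m)^2`; it lies in `[0, 1)` and tends to 1
#' at saturation.  Internally the algebraically equivalent cancellation-
#' free form `x = 2C / (1 + 2C + sqrt(1 + 4C))` is evaluated.
#'
#' @param ka Self-association constant, mM^-1 (> 0).
#' @param conc_total Total solute concentration, mM (>= 0, vectorised).
#' @param delta_max Maximal shift change between monomer and oligomer,
#'   Hz; sign free (positive = low-frequency shift).
#' @return Shift change(s) in Hz, same length as `conc_total`.
#' @examples
#' isodesmic_shift(4.536, c(0.013, 0.789), 111.9)
#' @export
isodesmic_shift <- function(ka, conc_total, delta_max) {
  if (!is.numeric(ka) || length(ka) != 1 || is.na(ka) || ka <= 0) {
    abort("`ka` must be a single positive number (mM^-1)")
  }
  if (any(conc_total < 0)) abort("`conc_total` must be non-negative")
  C <- ka * conc_total
  x <- 2 * C / (1 + 2 * C + sqrt(1 + 4 * C))
  delta_max * x
}

# residuals of the isodesmic model on the log-ka scale
iso_resid <- function(par, conc, shift, offset_free) {
  mu <- isodesmic_shift(exp(par[["log_ka"]]), conc, par[["delta_max"]])
  if (offset_free) mu <- mu + par[["offset"]]
  shift - mu
}

#' Fit the isodesmic model to one dilution series
#'
#' Least-squares estimation of the self-association constant `ka` and the
#' limiting shift change `delta_max` from one proton's concentration vs.
#' shift-change series.  The optimiser is Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) on the log-`ka` scale (which enforces
#' `ka > 0`), restarted from `ka` = 0.5, 2 and 8 mM^-1 with
#' `delta_max` started at twice the most extreme observed change; the
#' best of the restarts is kept.  `delta_max` is unconstrained in sign:
#' protons that shift to high frequency on stacking fit with negative
#' `delta_max`.
#'
#' Tabulated series are referenced to the lowest-concentration sample,
#' whose shift change is 0 by construction and carries no information;
#' by default that reference point is excluded from the residuals and the
#' remaining changes are fitted directly, treating the lowest-
#' concentration shift as the monomer shift.  Set
#' `include_reference = TRUE` to keep the zero point in the fit, or
#' `offset_free = TRUE` to additionally estimate a reference offset
#' (a sensitivity check on the monomer-shift approximation; with it the
#' model is `delta_max * x(ka * conc) + offset`).
#'
#' @param data Tibble with columns `conc` (mM) and `delta_shift` (Hz) for
#'   a single series (as one group of [read_dilution_table()] output).
#' @param include_reference Keep the construction-zero reference point in
#'   the fit? Default `FALSE`.
#' @param offset_free Also fit a reference offset? Default `FALSE`.
#' @param ka_starts Multistart values for `ka` (mM^-1).
#' @return An object of class `isodesmic_fit` with elements `proton`,
#'   `compound_id`, `ka`, `delta_max`, `offset`, `ka_se`, `delta_max_se`,
#'   `rss` (Hz^2), `n_points`, `converged`, and the fitted data.  Never
#'   errors on non-convergence: the flag records it.
#' @examples
#' dil <- read_dilution_table(nmrbind_example("dilution_compound1.csv"), "1")
#' fit_isodesmic(dplyr::filter(dil, proton == "H9"))
#' @export
fit_isodesmic <- function(data, include_reference = FALSE, offset_free = FALSE,
                          ka_starts = c(0.5, 2, 8)) {
  stopifnot(all(c("conc", "delta_shift") %in% names(data)))
  if (nrow(data) < 4) abort("at least 4 points are required")
  if ("proton" %in% names(data) && dplyr::n_distinct(data$proton) > 1) {
    abort("`data` holds several protons; fit one series at a time (or use fit_isodesmic_each())")
  }
  data <- dplyr::arrange(data, .data$conc)
  fitted_rows <- if (include_reference) seq_len(nrow(data)) else -1L
  conc <- data$conc[fitted_rows]
  shift <- data$delta_shift[fitted_rows]
  extreme <- shift[which.max(abs(shift))]
  if (length(extreme) == 0 || extreme == 0) extreme <- 1
  best <- NULL
  for (k0 in ka_starts) {
    par0 <- c(log_ka = log(k0), delta_max = 2 * extreme)
    if (offset_free) par0 <- c(par0, offset = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = iso_resid, conc = conc, shift = shift,
                         offset_free = offset_free,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort("all optimiser starts failed (degenerate series?)")
  }
  est <- best$par
  cf <- tryCatch(summary(best)$coefficients, error = function(e) NULL)
  se <- if (is.null(cf)) rep(NA_real_, length(est)) else cf[, "Std. Error"]
  ka <- exp(est[["log_ka"]])
  structure(list(
    compound_id = if ("compound_id" %in% names(data)) data$compound_id[1] else NA_character_,
    proton = if ("proton" %in% names(data)) data$proton[1] else NA_character_,
    ka = ka,
    delta_max = est[["delta_max"]],
    offset = if (offset_free) est[["offset"]] else 0,
    ka_se = ka * se[[1]],          # delta method from the log scale
    delta_max_se = se[[2]],
    rss = best$deviance,
    n_points = length(conc),
    converged = best$info %in% 1:3,
    include_reference = include_reference,
    offset_free = offset_free,
    data = as_tibble(data)), class = "isodesmic_fit")
}

#' @export
print.isodesmic_fit <- function(x, ...) {
  cat(sprintf("Isodesmic fit%s%s\n",
              if (is.na(x$compound_id)) "" else paste0(", compound ", x$compound_id),
              if (is.na(x$proton)) "" else paste0(", proton ", x$proton)))
  cat(sprintf("  ka        = %.4g mM^-1 (se %.3g)\n", x$ka, x$ka_se))
  cat(sprintf("  delta_max = %.4g Hz    (se %.3g)\n", x$delta_max, x$delta_max_se))
  if (x$offset_free) cat(sprintf("  offset    = %.4g Hz\n", x$offset))
  cat(sprintf("  rss = %.4g Hz^2 over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' @rdname fit_isodesmic
#' @param object,x An `isodesmic_fit`.
#' @param newdata Optional tibble with a `conc` column for prediction.
#' @param ... Unused.
#' @export
predict.isodesmic_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  isodesmic_shift(object$ka, conc, object$delta_max) + object$offset
}

#' Tidy an isodesmic fit
#'
#' @param x An `isodesmic_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @method tidy isodesmic_fit
#' @export
tidy.isodesmic_fit <- function(x, ...) {
  out <- tibble(term = c("ka", "delta_max"),
                estimate = c(x$ka, x$delta_max),
                std.error = c(x$ka_se, x$delta_max_se))
  if (x$offset_free) {
    out <- dplyr::bind_rows(out, tibble(term = "offset", estimate = x$offset,
                                        std.error = NA_real_))
  }
  out
}

#' Glance at an isodesmic fit
#'
#' @param x An `isodesmic_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @method glance isodesmic_fit
#' @export
glance.isodesmic_fit <- function(x, ...) {
  tibble(rss = x$rss,
         sigma = sqrt(x$rss / max(1, x$n_points - 2 - x$offset_free)),
         n_points = x$n_points, converged = x$converged,
         include_reference = x$include_reference, offset_free = x$offset_free)
}

#' Fit the isodesmic model to every proton series of a dilution table
#'
#' Maps [fit_isodesmic()] over the compound/proton groups of a long
#' dilution table and returns one row per series.
#'
#' @inheritParams fit_isodesmic
#' @param data Long tibble as returned by [read_dilution_table()].
#' @return A tibble with columns `compound_id`, `proton`, `ka`,
#'   `delta_max`, `ka_se`, `delta_max_se`, `rss`, `n_points`,
#'   `converged` and a `fit` list-column of `isodesmic_fit` objects.
#' @examples
#' read_dilution_table(nmrbind_example("dilution_compound1.csv"), "1") |>
#'   fit_isodesmic_each()
#' @export
fit_isodesmic_each <- function(data, include_reference = FALSE,
                               offset_free = FALSE, ka_starts = c(0.5, 2, 8)) {
  protons <- unique(data$proton)
  grouped <- dplyr::group_split(dplyr::group_by(data, .data$compound_id, .data$proton))
  rows <- purrr::map(grouped, function(d) {
    f <- fit_isodesmic(d, include_reference = include_reference,
                       offset_free = offset_free, ka_starts = ka_starts)
    tibble(compound_id = f$compound_id, proton = f$proton, ka = f$ka,
           delta_max = f$delta_max, ka_se = f$ka_se,
           delta_max_se = f$delta_max_se, rss = f$rss,
           n_points = f$n_points, converged = f$converged, fit = list(f))
  })
  dplyr::arrange(dplyr::bind_rows(rows),
                 .data$compound_id, factor(.data$proton, levels = protons))
}

#' Compound-level mean self-association constant
#'
#' Aggregates per-proton isodesmic fits into the compound-level mean
#' association constant: the unweighted arithmetic mean and sample
#' (n-1) standard deviation of the included per-proton `ka` values.
#' Exclusions are explicit user input (protons whose fitted constants
#' deviate for reasons outside the model are named by the analyst, never
#' auto-detected).
#'
#' @param fits Tibble from [fit_isodesmic_each()] (columns `compound_id`,
#'   `proton`, `ka` required).
#' @param exclude Character vector of proton labels excluded from the
#'   mean (matched exactly).
#' @return A tibble with one row per compound: `n_fits`, `n_used`,
#'   `mean_ka`, `sd_ka` (mM^-1; 0 when a single fit is used) and the
#'   excluded labels collapsed into `excluded`.
#' @examples
#' read_dilution_table(nmrbind_example("dilution_compound1.csv"), "1") |>
#'   fit_isodesmic_each() |>
#'   summarize_ka(exclude = "H12")
#' @export
summarize_ka <- function(fits, exclude = character()) {
  stopifnot(all(c("compound_id", "proton", "ka") %in% names(fits)))
  if (nrow(fits) == 0) abort("`fits` is empty")
  missing <- setdiff(exclude, fits$proton)
  if (length(missing)) {
    abort(sprintf("excluded proton(s) not present in fits: %s",
                  paste(missing, collapse = ", ")))
  }
  kept <- dplyr::filter(fits, !.data$proton %in% exclude)
  if (nrow(kept) == 0) abort("exclusion removed every fit")
  dplyr::summarise(
    dplyr::group_by(kept, .data$compound_id),
    n_fits = sum(fits$compound_id == .data$compound_id[1]),
    n_used = dplyr::n(),
    mean_ka = mean(.data$ka),
    sd_ka = if (dplyr::n() > 1) sd(.data$ka) else 0,
    excluded = paste(exclude, collapse = ","),
    .groups = "drop")
}

#' Plot an isodesmic fit
#'
#' Observed shift changes against concentration with the fitted
#' isodesmic curve.
#'
#' @param object An `isodesmic_fit`.
#' @param n_curve Number of points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isodesmic_fit
#' @export
autoplot.isodesmic_fit <- function(object, n_curve = 200, ...) {
  grid <- tibble(conc = seq(0, max(object$data$conc), length.out = n_curve))
  grid$delta_shift <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$delta_shift)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "total concentration (mM)",
      y = expression(Delta * delta ~ "(Hz)"),
      title = sprintf("Isodesmic fit%s: ka = %.3g mM^-1, delta_max = %.3g Hz",
                      if (is.na(object$proton)) "" else paste0(" ", object$proton),
                      object$ka, object$delta_max))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
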