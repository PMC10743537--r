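# Chemical-shift perturbation: per-proton shift changes on complex
# formation, significance flagging, and localisation relative to the nick.

#' Chemical-shift perturbations
#'
#' Computes the shift change on complexation for every record:
#' `delta_delta = delta_free - delta_complex` (ppm), so positive values
#' denote a low-frequency (upfield) shift, the signature of ring-current
#' shielding by aromatic stacking.  The raw difference is kept in
#' `delta_delta_raw`; `delta_delta` is rounded to 3 decimals (the
#' precision at which ppm tables are customarily reported).
#'
#' @param records Tibble from [read_shift_table()].
#' @return The input with `delta_delta_raw` and `delta_delta` (ppm)
#'   appended.
#' @examples
#' read_shift_table(nmrbind_example("dna_shifts_compound1.csv")) |>
#'   compute_csp()
#' @export
compute_csp <- function(records) {
  stopifnot(all(c("unit_label", "proton_class", "delta_free", "delta_complex")
                %in% names(records)))
  dplyr::mutate(records,
                delta_delta_raw = .data$delta_free - .data$delta_complex,
                delta_delta = round(.data$delta_delta_raw, 3))
}

#' Flag significant shift perturbations
#'
#' Marks records whose rounded `|delta_delta|` reaches the significance
#' threshold, by default 0.02 ppm.  With `rounding_slack = TRUE` (the
#' default) the comparison allows 0.001 ppm of slack, so a value printed
#' as 0.019 ppm -- at the resolution limit of a rounded table -- is
#' admitted; with `rounding_slack = FALSE` the strict `>= threshold`
#' rule applies.  Raising the threshold never adds flags.
#'
#' @param records Tibble from [compute_csp()].
#' @param threshold Significance threshold in ppm (> 0).
#' @param rounding_slack Allow 0.001 ppm of rounding slack? Default
#'   `TRUE`.
#' @return The input with a logical `flagged` column appended.
#' @export
flag_significant <- function(records, threshold = 0.02, rounding_slack = TRUE) {
  stopifnot("delta_delta" %in% names(records))
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0")
  eff <- threshold - if (isTRUE(rounding_slack)) 0.001 else 0
  dplyr::mutate(records, flagged = abs(.data$delta_delta) >= eff - 1e-12)
}

#' Localise flagged DNA perturbations relative to the nick
#'
#' Counts how many flagged DNA records (classes `"H6/H8"` and `"H1'"`)
#' fall on nick-adjacent units of the duplex, the data-level statement
#' of where the ligand binds.  Ligand-class records are ignored.  A
#' flagged DNA unit absent from the nick map is an error.
#'
#' @param records Tibble from [flag_significant()].
#' @param nick A [nick_map()].
#' @return A one-row tibble: `n_flagged`, `n_flagged_near_nick`,
#'   `all_near_nick`, `flagged_units` (comma-collapsed, with class) and
#'   a `conclusion` string.
#' @examples
#' read_shift_table(nmrbind_example("dna_shifts_compound1.csv")) |>
#'   compute_csp() |>
#'   flag_significant() |>
#'   localize_to_nick()
#' @export
localize_to_nick <- function(records, nick = nick_map()) {
  stopifnot(inherits(nick, "nick_map"), "flagged" %in% names(records))
  dna <- dplyr::filter(records, .data$proton_class != "ligand")
  fl <- dplyr::filter(dna, .data$flagged)
  units <- c(nick$strand1, nick$strand2)
  unknown <- setdiff(unique(fl$unit_label), units)
  if (length(unknown)) {
    abort(sprintf("flagged unit(s) not in the nick map: %s",
                  paste(unknown, collapse = ", ")))
  }
  near <- fl$unit_label %in% nick$nick_adjacent
  n_fl <- nrow(fl)
  tibble(
    n_flagged = n_fl,
    n_flagged_near_nick = sum(near),
    all_near_nick = n_fl > 0 && all(near),
    flagged_units = paste(sprintf("%s(%s)", fl$unit_label, fl$proton_class),
                          collapse = ","),
    conclusion = if (n_fl == 0) {
      "no significant perturbation"
    } else if (all(near)) {
      "all flagged DNA protons are nick-adjacent: binding localised inside the nick"
    } else {
      sprintf("%d of %d flagged DNA protons are nick-adjacent", sum(near), n_fl)
    })
}

#' Plot chemical-shift perturbations along the duplex
#'
#' Bar chart of `delta_delta` per unit, faceted by proton class, with
#' the significance threshold drawn and nick-adjacent units shaded.
#'
#' @param records Tibble from [flag_significant()] (DNA classes only are
#'   shown).
#' @param nick A [nick_map()] used for unit ordering and shading.
#' @param threshold Threshold drawn as horizontal guides, ppm.
#' @return A ggplot object.
#' @export
plot_csp <- function(records, nick = nick_map(), threshold = 0.02) {
  dna <- dplyr::filter(records, .data$proton_class != "ligand")
  units <- c(nick$strand1, nick$strand2)
  dna <- dplyr::mutate(dna, unit_label = factor(.data$unit_label, levels = units))
  shade <- tibble(unit_label = factor(nick$nick_adjacent, levels = units))
  ggplot2::ggplot(dna, ggplot2::aes(.data$unit_label, .data$delta_delta)) +
    ggplot2::geom_vline(data = shade,
                        ggplot2::aes(xintercept = .data$unit_label),
                        colour = "grey85", linewidth = 4) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$flagged), width = 0.6) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~proton_class, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey50",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(Delta * delta ~ "(ppm)"),
                  fill = sprintf("|CSP| >= %.3g ppm", threshold)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
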