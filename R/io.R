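# Readers and writers for the three table families the pipeline consumes.
# Unit conventions are fixed, never autodetected: concentrations are mM
# throughout; dilution-series shift changes are Hz; CSP shift tables are ppm.
# Positive shift changes denote a low-frequency (upfield) shift.

# Parse a character vector of numbers tolerating the Unicode minus (U+2212)
# and stray whitespace; returns NA where not numeric.
parse_signed_numeric <- function(x) {
  x <- gsub("−", "-", trimws(as.character(x)))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

read_raw_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

fail_cells <- function(values, raw, column) {
  bad <- which(is.na(values) & !is.na(raw))
  if (length(bad)) {
    abort(sprintf("non-numeric value '%s' in column '%s', data row %d",
                  raw[bad[1]], column, bad[1]))
  }
}

#' Read a dilution chemical-shift table
#'
#' Reads a wide CSV in which the first column (named `conc_mM`) holds the
#' total ligand concentration in mM and every further column holds the
#' chemical-shift change of one proton in Hz, relative to the
#' lowest-concentration sample (positive = low-frequency shift).  This is
#' the layout in which stepwise-dilution series are customarily tabulated.
#'
#' Rows are returned sorted by ascending concentration within each proton.
#' Each proton series must have at least 4 points, strictly increasing
#' concentrations, and a shift change of exactly 0 at the lowest
#' concentration (it is the reference point).  Both the ASCII hyphen and
#' the Unicode minus are accepted as negative signs.
#'
#' @param path Path to the CSV file.
#' @param compound_id Identifier recorded in the `compound_id` column;
#'   defaults to the file name without extension.
#' @return A tibble with columns `compound_id`, `proton`, `conc`
#'   (mM) and `delta_shift` (Hz), one row per measured point, protons in
#'   file column order.
#' @examples
#' read_dilution_table(nmrbind_example("dilution_compound1.csv"), "1")
#' @export
read_dilution_table <- function(path, compound_id = NULL) {
  raw <- read_raw_csv(path)
  if (ncol(raw) < 1 || names(raw)[1] != "conc_mM") {
    abort("dilution table must have 'conc_mM' as its first column")
  }
  compound_id <- compound_id %||% sub("\\.[^.]*$", "", basename(path))
  protons <- names(raw)[-1]
  if (nrow(raw) == 0 || length(protons) == 0) {
    return(tibble(compound_id = character(), proton = character(),
                  conc = double(), delta_shift = double()))
  }
  conc <- parse_signed_numeric(raw$conc_mM)
  fail_cells(conc, raw$conc_mM, "conc_mM")
  if (anyNA(conc)) abort("missing value in column 'conc_mM'")
  if (any(conc <= 0)) abort("concentrations must be positive")
  if (anyDuplicated(conc)) abort("duplicated concentration value")
  out <- purrr::map(protons, function(p) {
    val <- parse_signed_numeric(raw[[p]])
    fail_cells(val, raw[[p]], p)
    tibble(compound_id = compound_id, proton = p, conc = conc,
           delta_shift = val)
  })
  out <- dplyr::arrange(dplyr::bind_rows(out),
                        factor(.data$proton, levels = protons), .data$conc)
  validate_dilution(out)
  out
}

validate_dilution <- function(data) {
  dplyr::group_walk(dplyr::group_by(data, .data$compound_id, .data$proton),
    function(d, key) {
      lab <- paste0(key$compound_id, "/", key$proton)
      if (nrow(d) < 4) {
        abort(sprintf("series %s has %d points; at least 4 required", lab, nrow(d)))
      }
      if (anyNA(d$delta_shift)) abort(sprintf("missing shift value in series %s", lab))
      if (abs(d$delta_shift[which.min(d$conc)]) > 1e-9) {
        abort(sprintf(
          "series %s: shift at the lowest concentration must be 0 (it is the reference)", lab))
      }
    })
  invisible(data)
}

#' Write a dilution chemical-shift table
#'
#' Inverse of [read_dilution_table()]: writes the wide CSV dialect (one
#' `conc_mM` column, one column per proton).  Values round-trip to at
#' least 12 significant digits.
#'
#' @param data Tibble as returned by [read_dilution_table()] (a single
#'   compound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dilution_table <- function(data, path) {
  stopifnot(all(c("proton", "conc", "delta_shift") %in% names(data)))
  if ("compound_id" %in% names(data) && dplyr::n_distinct(data$compound_id) > 1) {
    abort("write_dilution_table() writes one compound per file")
  }
  protons <- unique(data$proton)
  wide <- tidyr::pivot_wider(
    dplyr::select(dplyr::mutate(data, proton = factor(.data$proton, levels = protons)),
                  "proton", "conc", "delta_shift"),
    names_from = "proton", values_from = "delta_shift")
  wide <- dplyr::arrange(dplyr::rename(wide, conc_mM = "conc"), .data$conc_mM)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a diffusion-coefficient table
#'
#' Reads a long CSV with columns `species`, `conc` (mM), `D` and `sigma`,
#' where `D` and `sigma` are a diffusion coefficient and its stated
#' uncertainty in units of 1e-10 m^2/s.  Records are kept in file order.
#' A missing `sigma` column is tolerated: uncertainties are set to 0 and
#' a warning is emitted.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `species_id`, `conc`, `d_coef`,
#'   `d_sigma` (coefficients in 1e-10 m^2/s).
#' @examples
#' read_diffusion_table(nmrbind_example("diffusion_free_ligand.csv"))
#' @export
read_diffusion_table <- function(path) {
  raw <- read_raw_csv(path)
  need <- c("species", "conc", "D")
  if (!all(need %in% names(raw))) {
    abort(sprintf("diffusion table must have columns %s (and optionally 'sigma')",
                  paste(sQuote(need), collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(species_id = character(), conc = double(),
                  d_coef = double(), d_sigma = double()))
  }
  conc <- parse_signed_numeric(raw$conc); fail_cells(conc, raw$conc, "conc")
  d <- parse_signed_numeric(raw$D); fail_cells(d, raw$D, "D")
  if (any(d <= 0, na.rm = TRUE)) abort("diffusion coefficients must be positive")
  if ("sigma" %in% names(raw)) {
    s <- parse_signed_numeric(raw$sigma); fail_cells(s, raw$sigma, "sigma")
    s[is.na(s)] <- 0
    if (any(s < 0)) abort("sigma must be non-negative")
  } else {
    warn("no 'sigma' column; uncertainties set to 0")
    s <- rep(0, nrow(raw))
  }
  tibble(species_id = as.character(raw$species), conc = conc,
         d_coef = d, d_sigma = s)
}

#' Write a diffusion-coefficient table
#'
#' @param data Tibble as returned by [read_diffusion_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diffusion_table <- function(data, path) {
  stopifnot(all(c("species_id", "conc", "d_coef", "d_sigma") %in% names(data)))
  out <- tibble(species = data$species_id, conc = data$conc,
                D = data$d_coef, sigma = data$d_sigma)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

proton_classes <- c("H6/H8", "H1'", "ligand")

#' Read a chemical-shift table
#'
#' Reads a long CSV with columns `unit`, `class`, `free` and `complex`:
#' one row per proton (group), giving its chemical shift in ppm free in
#' solution and in the equimolar ligand-DNA mixture.  `class` must be one
#' of `"H6/H8"`, `"H1'"` (the two reporter proton classes of the DNA
#' units) or `"ligand"`.  Unit/class pairs must be unique and shifts must
#' lie in 0-20 ppm.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `unit_label`, `proton_class`,
#'   `delta_free`, `delta_complex` (ppm), one row per input row.
#' @examples
#' read_shift_table(nmrbind_example("dna_shifts_compound1.csv"))
#' @export
read_shift_table <- function(path) {
  raw <- read_raw_csv(path)
  need <- c("unit", "class", "free", "complex")
  if (!all(need %in% names(raw))) {
    abort(sprintf("shift table must have columns %s",
                  paste(sQuote(need), collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(unit_label = character(), proton_class = character(),
                  delta_free = double(), delta_complex = double()))
  }
  cls <- as.character(raw$class)
  bad <- setdiff(unique(cls), proton_classes)
  if (length(bad)) {
    abort(sprintf("unknown proton class '%s' (expected %s)", bad[1],
                  paste(sQuote(proton_classes), collapse = ", ")))
  }
  free <- parse_signed_numeric(raw$free); fail_cells(free, raw$free, "free")
  cmpl <- parse_signed_numeric(raw$complex); fail_cells(cmpl, raw$complex, "complex")
  if (any(c(free, cmpl) < 0 | c(free, cmpl) > 20, na.rm = TRUE)) {
    abort("chemical shifts must lie within 0-20 ppm")
  }
  key <- paste(raw$unit, cls, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicated unit/class pair: %s",
                  gsub("\r", " / ", dup, fixed = TRUE)))
  }
  tibble(unit_label = as.character(raw$unit), proton_class = cls,
         delta_free = free, delta_complex = cmpl)
}

#' Write a chemical-shift table
#'
#' @param data Tibble as returned by [read_shift_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(data, path) {
  stopifnot(all(c("unit_label", "proton_class", "delta_free", "delta_complex")
                %in% names(data)))
  out <- tibble(unit = data$unit_label, class = data$proton_class,
                free = data$delta_free, complex = data$delta_complex)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
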