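# Band tables for the bundled synthetic reference library. Centres follow
# standard cellular Raman assignments (phenylalanine 1004, amide III
# 1230-1300, CH2 deformation ~1450, amide I ~1657 for proteins; DNA/RNA
# ring and backbone modes 729/785/813/1094/1484/1575; lipid C-C/CH2/C=C
# 1065-1300/1440/1665 and ester C=O 1745; glycogen 478/850/940/1085).
# Heights set the cps scale of a unit-weight (= calibration concentration)
# profile. shape = Lorentzian fraction of the pseudo-Voigt.
band <- function(center, height, width, shape = 0.2) {
  tibble::tibble(center = center, height = height, width = width, shape = shape)
}

# lipid band model parameterized by the 1665/1440 height ratio; the two
# diagnostic bands share one width so the local-chord baseline correction
# of the peak reader cancels exactly in the ratio
lipid_bands <- function(ratio) {
  dplyr::bind_rows(
    band(1065, 6, 12), band(1080, 6, 14), band(1130, 6, 12),
    band(1266, 5, 16), band(1300, 9, 14), band(1440, 18, 14, 0.25),
    band(1665, ratio * 18, 14, 0.25), band(1745, 4, 16)
  )
}

protein_common_bands <- function() {
  dplyr::bind_rows(
    band(621, 6, 12), band(643, 8, 12), band(757, 10, 12),
    band(830, 10, 14), band(852, 14, 14), band(1004, 60, 9, 0.3),
    band(1032, 14, 10), band(1127, 16, 16), band(1340, 28, 18),
    band(1557, 7, 14)
  )
}

default_band_tables <- function() {
  list(
    protein.generic = dplyr::bind_rows(
      protein_common_bands(),
      band(1250, 45, 24, 0.3), band(1450, 48, 18, 0.3),
      band(1657, 78, 22, 0.3)
    ),
    # cytoplasmic proteins carry the 717 peak; nuclear do not, and the two
    # differ in the amide III / CH deformation / amide I windows
    protein.cytoplasmic = dplyr::bind_rows(
      protein_common_bands(), band(717, 12, 12),
      band(1250, 42, 24, 0.3), band(1450, 51, 18, 0.3),
      band(1659, 80, 22, 0.3)
    ),
    protein.nuclear = dplyr::bind_rows(
      protein_common_bands(),
      band(1253, 47, 24, 0.3), band(1447, 46, 18, 0.3),
      band(1655, 76, 22, 0.3)
    ),
    # ethanol fixation visibly reshapes the protein spectrum
    protein.ethanol_fixed = dplyr::bind_rows(
      protein_common_bands(),
      band(1248, 38, 28, 0.3), band(1452, 44, 20, 0.3),
      band(1664, 70, 26, 0.3)
    ),
    dna.generic = dplyr::bind_rows(
      band(729, 18, 12), band(785, 42, 12), band(1094, 30, 16),
      band(1255, 20, 20), band(1375, 22, 14), band(1490, 26, 14),
      band(1578, 30, 14)
    ),
    # nuclear vs cytoplasmic RNA differ chiefly at the 813 cm-1 O-P-O
    # symmetric stretch (more intense for cytoplasmic RNA)
    rna.nuclear = dplyr::bind_rows(
      band(785, 12, 12), band(813, 30, 13), band(867, 10, 14),
      band(1100, 22, 18), band(1240, 26, 20), band(1320, 18, 16),
      band(1484, 28, 14), band(1575, 26, 14)
    ),
    rna.cytoplasmic = dplyr::bind_rows(
      band(785, 12, 12), band(813, 40, 13), band(867, 10, 14),
      band(1100, 22, 18), band(1240, 26, 20), band(1320, 18, 16),
      band(1484, 28, 14), band(1575, 26, 14)
    ),
    # generic lipid has 1665/1440 height ratio 0.57 (between saturated and
    # polyunsaturated acyl chains); context variants are added by
    # default_library() with the per-organelle mean ratio
    lipid.generic = lipid_bands(0.57),
    glycogen.generic = dplyr::bind_rows(
      band(478, 25, 14), band(850, 12, 14), band(940, 14, 16),
      band(1045, 12, 16), band(1085, 14, 16), band(1123, 12, 14),
      band(1340, 10, 16), band(1460, 14, 16)
    )
  )
}

background_band_tables <- function() {
  list(
    # glass: broad fused-silica bands riding on a wide fluorescence pedestal
    glass = dplyr::bind_rows(
      band(560, 0.75, 220, 0.4), band(1100, 0.65, 280, 0.4),
      band(1200, 0.85, 1700, 0.7)
    ),
    # aqueous medium: water bending band plus broad librational wings
    medium = dplyr::bind_rows(
      band(1640, 0.8, 90, 0.3), band(900, 0.35, 350, 0.5),
      band(1350, 0.25, 250, 0.4)
    ),
    # residual fluorophore (stain) signal: a few weak narrow bands
    stain = dplyr::bind_rows(
      band(610, 0.3, 20), band(1180, 0.5, 25), band(1520, 0.8, 30)
    )
  )
}

#' Bundled synthetic reference library
#'
#' Builds the five calibrated component profiles (with protein
#' compartment/fixation variants and nuclear/cytoplasmic RNA variants)
#' from analytic pseudo-Voigt band models. Band positions follow standard
#' cellular Raman assignments; the profiles are synthetic stand-ins, not
#' measured standards. Calibration follows the instrument convention:
#' unit weight is 100 mg/mL for protein and 20 mg/mL for the other
#' classes.
#'
#' @param grid Library [spectral_grid()]; default 50-1900 cm^-1 at 1 cm^-1.
#' @return A [reference_library()].
#' @export
default_library <- function(grid = spectral_grid()) {
  tabs <- default_band_tables()
  # context lipid variants: one per organelle/state with a measured mean
  # saturation ratio, emulating a library refined from accumulated fits
  presets <- organelle_presets()
  with_ratio <- presets[!is.na(presets$ratio_mean), ]
  for (i in seq_len(nrow(with_ratio))) {
    key <- sprintf("lipid.%s_%s", with_ratio$organelle[i], with_ratio$state[i])
    tabs[[key]] <- lipid_bands(with_ratio$ratio_mean[i])
  }
  profiles <- purrr::imap(tabs, function(bands, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    build_synthetic_profile(bands, grid, name = parts[1], variant = parts[2])
  })
  reference_library(unname(profiles), grid)
}

#' Write / read a reference library
#'
#' On disk a library is a directory of per-profile CSV spectra plus a
#' `manifest.csv` (name, variant, role, calibration, file, provenance).
#' Background basis spectra may be stored alongside with
#' `role = "background"`.
#'
#' @param lib A [reference_library()].
#' @param dir Directory (created if needed).
#' @param background Optional [background_model()] stored with the library.
#' @return `dir` invisibly (`write_library`); a list with elements
#'   `library` and `background` (`read_library`).
#' @export
write_library <- function(lib, dir, background = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(lib$profiles, function(p) {
    fname <- sprintf("%s.%s.csv", p$name, p$variant)
    write_spectrum(p$spectrum, file.path(dir, fname), format = "csv")
    tibble::tibble(name = p$name, variant = p$variant, role = "component",
                   calibration = p$calibration, file = fname,
                   provenance = p$provenance)
  })
  if (!is.null(background)) {
    rows <- c(rows, purrr::imap(background$components, function(s, nm) {
      fname <- sprintf("background.%s.csv", nm)
      write_spectrum(s, file.path(dir, fname), format = "csv")
      tibble::tibble(name = nm, variant = "generic", role = "background",
                     calibration = NA_real_, file = fname,
                     provenance = "background basis")
    }))
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @param dir Library directory containing `manifest.csv`.
#' @param grid Grid the profiles are validated against; inferred from the
#'   first profile when `NULL`.
#' @export
#' @rdname write_library
read_library <- function(dir, grid = NULL) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    rlang::abort(sprintf("No manifest.csv in %s.", dir),
                 class = "ramanbca_io_error")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  comp <- dplyr::filter(manifest, .data$role == "component")
  profiles <- purrr::pmap(comp, function(name, variant, role, calibration,
                                         file, provenance, ...) {
    component_profile(name, read_spectrum(file.path(dir, file), "csv"),
                      calibration = calibration, variant = variant,
                      provenance = provenance)
  })
  if (is.null(grid)) {
    wn <- profiles[[1]]$spectrum$wavenumber
    grid <- spectral_grid(min(wn), max(wn), wn[2] - wn[1])
  }
  bg_rows <- dplyr::filter(manifest, .data$role == "background")
  background <- NULL
  if (nrow(bg_rows) > 0) {
    comps <- purrr::pmap(bg_rows, function(name, file, ...) {
      read_spectrum(file.path(dir, file), "csv")
    })
    names(comps) <- bg_rows$name
    background <- background_model(comps)
  }
  list(library = reference_library(profiles, grid), background = background)
}
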