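COMPONENT_CLASSES <- c("protein", "dna", "rna", "lipid", "glycogen")
ORGANELLES <- c("nucleus", "nucleolus", "mitochondrion", "er", "golgi",
                "mitotic_cytoplasm", "mitotic_chromosome")
FIXATION_STATES <- c("live", "formaldehyde_fixed", "ethanol_fixed")
NUCLEAR_ORGANELLES <- c("nucleus", "nucleolus", "mitotic_chromosome")
CYTOPLASMIC_ORGANELLES <- c("mitochondrion", "er", "golgi", "mitotic_cytoplasm")

#' Pseudo-Voigt band profile
#'
#' Linear Gaussian/Lorentzian mix, the standard Raman line-shape
#' compromise. `shape = 0` is pure Gaussian, `shape = 1` pure Lorentzian;
#' `width` is the full width at half maximum and the peak value at
#' `center` is exactly `height`.
#'
#' @param x Wavenumber axis (cm^-1).
#' @param center Band centre (cm^-1).
#' @param height Peak height (cps).
#' @param width FWHM (cm^-1, > 0).
#' @param shape Lorentzian fraction in `[0, 1]`.
#' @return Numeric vector of band intensities on `x`.
#' @export
pseudo_voigt <- function(x, center, height, width, shape = 0.2) {
  stopifnot(width > 0, shape >= 0, shape <= 1)
  u <- (x - center) / (width / 2)
  g <- exp(-log(2) * u^2)
  l <- 1 / (1 + u^2)
  height * ((1 - shape) * g + shape * l)
}

#' Calibrated biomolecular component profile
#'
#' A reference spectrum for one biomolecular class on the library grid.
#' The normalization convention ties weight to concentration: a fit weight
#' of exactly 1 corresponds to `calibration` mg/mL (100 for proteins, 20
#' for DNA, RNA, lipids, and glycogen), so fitted weights convert to
#' absolute concentrations by a single multiplication.
#'
#' @param name Component class, one of `r paste(COMPONENT_CLASSES, collapse=", ")`.
#' @param spectrum A nonnegative `raman_spectrum` on the library grid.
#' @param calibration mg/mL represented by unit weight (> 0).
#' @param variant Context tag (`"generic"`, `"cytoplasmic"`, `"nuclear"`,
#'   `"ethanol_fixed"`, ...).
#' @param bands Optional band table (center, height, width, shape) when the
#'   profile is an analytic band model.
#' @param provenance Free-text origin note.
#' @return A `component_profile`.
#' @export
component_profile <- function(name, spectrum, calibration = default_calibration(name),
                              variant = "generic", bands = NULL,
                              provenance = "") {
  name <- rlang::arg_match(name, COMPONENT_CLASSES)
  stopifnot(is_raman_spectrum(spectrum))
  if (any(spectrum$intensity < 0)) {
    rlang::abort("Component profiles must be nonnegative everywhere.",
                 class = "ramanbca_param_error")
  }
  if (!is.numeric(calibration) || calibration <= 0) {
    rlang::abort("`calibration` must be > 0 mg/mL.",
                 class = "ramanbca_param_error")
  }
  structure(
    list(name = name, variant = variant, spectrum = spectrum,
         calibration = calibration, bands = bands, provenance = provenance),
    class = "component_profile"
  )
}

#' @export
#' @rdname component_profile
default_calibration <- function(name) {
  ifelse(name == "protein", 100, 20)
}

#' @export
format.component_profile <- function(x, ...) {
  sprintf("<component_profile %s.%s, %d points, %g mg/mL per unit weight>",
          x$name, x$variant, nrow(x$spectrum), x$calibration)
}

#' @export
print.component_profile <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build a component profile from an analytic band model
#'
#' Sums pseudo-Voigt bands on the grid; nonnegative by construction. Band
#' centres outside the grid raise a warning but are still evaluated (their
#' tails may contribute).
#'
#' @param bands Data frame with columns `center`, `height`, `width`, and
#'   optionally `shape` (default 0.2).
#' @param grid A [spectral_grid()].
#' @param calibration mg/mL per unit weight.
#' @inheritParams component_profile
#' @return A `component_profile`.
#' @export
build_synthetic_profile <- function(bands, grid, name,
                                    calibration = default_calibration(name),
                                    variant = "generic") {
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) == 0) {
    rlang::abort("`bands` must be nonempty.", class = "ramanbca_param_error")
  }
  if (!"shape" %in% names(bands)) bands$shape <- 0.2
  ax <- grid_axis(grid)
  outside <- bands$center < min(ax) | bands$center > max(ax)
  if (any(outside)) {
    rlang::warn(sprintf("%d band centre(s) outside the grid; tails may still contribute.",
                        sum(outside)))
  }
  y <- eval_bands(ax, bands)
  component_profile(
    name,
    raman_spectrum(ax, y, meta = list(label = paste0(name, ".", variant))),
    calibration = calibration, variant = variant, bands = bands,
    provenance = "synthetic pseudo-Voigt band model"
  )
}

eval_bands <- function(x, bands) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(bands))) {
    y <- y + pseudo_voigt(x, bands$center[i], bands$height[i],
                          bands$width[i], bands$shape[i])
  }
  y
}

#' Calibrate a profile from a pure-standard solution spectrum
#'
#' Given a background-subtracted spectrum of an aqueous standard of known
#' concentration (e.g. bovine serum albumin for protein), rescale it so
#' that unit fit weight corresponds to `target_calibration` mg/mL. Fitting
#' the resulting profile back to the raw standard spectrum returns weight
#' `known_concentration / target_calibration` exactly.
#'
#' @param raw Background-subtracted `raman_spectrum` of the pure standard.
#' @param known_concentration Standard concentration in mg/mL (> 0).
#' @param target_calibration Calibration convention for the class (mg/mL).
#' @inheritParams component_profile
#' @return A `component_profile`.
#' @export
calibrate_profile <- function(raw, known_concentration, target_calibration,
                              name, variant = "generic") {
  if (!is.numeric(known_concentration) || known_concentration <= 0 ||
      !is.numeric(target_calibration) || target_calibration <= 0) {
    rlang::abort("Concentrations must be > 0 mg/mL.",
                 class = "ramanbca_param_error")
  }
  scaled <- spec_update(raw,
                        intensity = raw$intensity * target_calibration / known_concentration)
  component_profile(name, scaled, calibration = target_calibration,
                    variant = variant,
                    provenance = sprintf("calibrated from %g mg/mL standard",
                                         known_concentration))
}

#' Reference library of component and background profiles
#'
#' @param profiles List of [component_profile()] objects sharing one grid.
#' @param grid The library [spectral_grid()].
#' @return A `reference_library` keyed by `name.variant`.
#' @export
reference_library <- function(profiles, grid) {
  stopifnot(all(purrr::map_lgl(profiles, inherits, "component_profile")))
  n_axis <- length(grid_axis(grid))
  ok <- purrr::map_lgl(profiles, function(p) {
    nrow(p$spectrum) == n_axis &&
      max(abs(p$spectrum$wavenumber - grid_axis(grid))) < 1e-9
  })
  if (!all(ok)) {
    rlang::abort("All profiles must live on the library grid.",
                 class = "ramanbca_config_error")
  }
  names(profiles) <- purrr::map_chr(profiles, ~ paste0(.x$name, ".", .x$variant))
  structure(list(profiles = profiles, grid = grid),
            class = "reference_library")
}

#' @export
format.reference_library <- function(x, ...) {
  sprintf("<reference_library: %s>",
          paste(names(x$profiles), collapse = ", "))
}

#' @export
print.reference_library <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Measurement context
#'
#' The organelle and fixation state of a measurement; selects which
#' profile variants the fit uses. Ethanol fixation of endoplasmic
#' reticulum or Golgi is flagged unsupported (no such measurements exist).
#'
#' @param organelle One of `r paste(ORGANELLES, collapse=", ")`.
#' @param state One of `r paste(FIXATION_STATES, collapse=", ")`.
#' @return A `measurement_context`.
#' @export
measurement_context <- function(organelle, state = "live") {
  organelle <- rlang::arg_match(organelle, ORGANELLES)
  state <- rlang::arg_match(state, FIXATION_STATES)
  supported <- !(organelle %in% c("er", "golgi") && state == "ethanol_fixed")
  structure(list(organelle = organelle, state = state, supported = supported),
            class = "measurement_context")
}

#' @export
format.measurement_context <- function(x, ...) {
  sprintf("<context %s/%s%s>", x$organelle, x$state,
          if (x$supported) "" else " [unsupported]")
}

#' @export
print.measurement_context <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

lib_get <- function(lib, name, variant) {
  lib$profiles[[paste0(name, ".", variant)]]
}

#' Resolve the five component profiles for a measurement context
#'
#' RNA uses the cytoplasmic variant for cytoplasmic organelles
#' (mitochondrion, ER, Golgi, mitotic cytoplasm) and the nuclear variant
#' for nuclear compartments (nucleus, nucleolus, mitotic chromosome) —
#' the two differ most at the 815 cm^-1 O-P-O stretching band. Protein
#' picks a fixation- or compartment-specific variant when the library has
#' one, falling back to the generic profile with a warning.
#'
#' @param lib A [reference_library()].
#' @param ctx A [measurement_context()].
#' @return Named list of five `component_profile`s
#'   (protein, dna, rna, lipid, glycogen).
#' @export
resolve_profiles <- function(lib, ctx) {
  stopifnot(inherits(lib, "reference_library"),
            inherits(ctx, "measurement_context"))
  compartment <- if (ctx$organelle %in% NUCLEAR_ORGANELLES) "nuclear" else "cytoplasmic"

  rna <- lib_get(lib, "rna", compartment)
  if (is.null(rna)) {
    rlang::abort(sprintf("Library is missing the rna.%s profile required for %s.",
                         compartment, ctx$organelle),
                 class = "ramanbca_config_error")
  }

  protein_prefs <- c(
    if (ctx$state == "ethanol_fixed") "ethanol_fixed",
    compartment, "generic"
  )
  protein <- NULL
  for (v in protein_prefs) {
    protein <- lib_get(lib, "protein", v)
    if (!is.null(protein)) {
      if (v == "generic" && length(protein_prefs) > 1) {
        rlang::warn(sprintf("No protein variant for %s/%s; using the generic profile.",
                            ctx$organelle, ctx$state))
      }
      break
    }
  }

  # lipid: a context-specific variant (library refined per organelle/state)
  # when one exists, silently falling back to the generic profile
  lipid <- lib_get(lib, "lipid", paste(ctx$organelle, ctx$state, sep = "_")) %||%
    lib_get(lib, "lipid", "generic")

  out <- list(
    protein = protein,
    dna = lib_get(lib, "dna", "generic"),
    rna = rna,
    lipid = lipid,
    glycogen = lib_get(lib, "glycogen", "generic")
  )
  missing <- names(out)[purrr::map_lgl(out, is.null)]
  if (length(missing)) {
    rlang::abort(sprintf("Library is missing profiles for: %s.",
                         paste(missing, collapse = ", ")),
                 class = "ramanbca_config_error")
  }
  out
}

#' Refine a component profile from accumulated fits
#'
#' The feedback procedure: for each accepted fit, subtract the other four
#' weighted components from the background-free spectrum and divide by the
#' class weight, giving one per-spectrum estimate of the profile; average
#' the estimates pointwise, clip negatives to zero, and rescale so the
#' refined profile best reproduces the averaged estimate at unit weight.
#' Noise-free fits generated from the library profile are a fixed point:
#' refinement returns that profile unchanged.
#'
#' @param lib A [reference_library()].
#' @param fits List of `bca_fit` objects (see [fit_bca()]).
#' @param class_to_refine Component class name.
#' @param weight_floor Fits with class weight below this are excluded with
#'   a warning (division blow-up guard); default 0.05.
#' @return The refined `component_profile` (the library is not mutated).
#' @export
refine_profile_feedback <- function(lib, fits, class_to_refine,
                                    weight_floor = 0.05) {
  class_to_refine <- rlang::arg_match(class_to_refine, COMPONENT_CLASSES)
  stopifnot(length(fits) >= 1)
  estimates <- list()
  for (fit in fits) {
    w <- fit$weights[[class_to_refine]]
    if (is.null(w) || w < weight_floor) {
      rlang::warn(sprintf("Excluding a fit with %s weight %.3g below floor %.3g.",
                          class_to_refine, w %||% NA_real_, weight_floor))
      next
    }
    others <- setdiff(COMPONENT_CLASSES, class_to_refine)
    rest <- rowSums(vapply(others, function(cl) {
      fit$weights[[cl]] * fit$profiles[[cl]]$spectrum$intensity
    }, numeric(nrow(fit$background_free))))
    estimates[[length(estimates) + 1]] <-
      (fit$background_free$intensity - rest) / w
  }
  if (length(estimates) == 0) {
    rlang::abort("All fits fell below the weight floor; nothing to refine.",
                 class = "ramanbca_refinement_error")
  }
  avg <- Reduce(`+`, estimates) / length(estimates)
  clipped <- pmax(avg, 0)
  scale <- sum(avg * clipped) / sum(clipped^2)
  refined <- clipped * scale
  template <- fits[[1]]$profiles[[class_to_refine]]
  component_profile(
    class_to_refine,
    raman_spectrum(fits[[1]]$background_free$wavenumber, refined),
    calibration = template$calibration,
    variant = paste0(template$variant, ".refined"),
    provenance = sprintf("feedback refinement from %d fits", length(estimates))
  )
}
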