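#' Background model
#'
#' The non-cellular signal of a glass-bottom-dish measurement: normalized
#' basis spectra for the glass substrate, the aqueous medium, and (when a
#' fluorescent label is present) the stain, plus a smooth Chebyshev
#' baseline of order `baseline_order` that absorbs broad fluorescence.
#' Each basis spectrum is smoothed and max-normalized to 1, so fitted
#' background coefficients are in cps.
#'
#' @param components Named list of nonnegative `raman_spectrum` basis
#'   spectra on the library grid (each max-normalized to 1; normalization
#'   is applied here if needed).
#' @param baseline_order Chebyshev polynomial order, 0-7 (default 5).
#' @param region_mask Optional list of `c(lo, hi)` wavenumber windows used
#'   by diagnostics (e.g. the near-zero-median check after subtraction);
#'   defaults to the full axis.
#' @return A `background_model`.
#' @export
background_model <- function(components, baseline_order = 5,
                             region_mask = NULL) {
  stopifnot(length(components) >= 1,
            all(purrr::map_lgl(components, is_raman_spectrum)))
  if (baseline_order < 0 || baseline_order > 7) {
    rlang::abort("`baseline_order` must be in [0, 7].",
                 class = "ramanbca_param_error")
  }
  if (is.null(names(components))) {
    names(components) <- paste0("component", seq_along(components))
  }
  components <- purrr::map(components, function(s) {
    if (any(s$intensity < 0)) {
      rlang::abort("Background components must be nonnegative.",
                   class = "ramanbca_param_error")
    }
    m <- max(s$intensity)
    if (m <= 0) {
      rlang::abort("Background component is identically zero.",
                   class = "ramanbca_param_error")
    }
    spec_update(s, intensity = s$intensity / m)
  })
  structure(list(components = components, baseline_order = baseline_order,
                 region_mask = region_mask),
            class = "background_model")
}

#' Bundled synthetic background model
#'
#' Glass, medium, and stain basis spectra built from broad pseudo-Voigt
#' band models on the library grid.
#'
#' @param grid A [spectral_grid()].
#' @param baseline_order Chebyshev baseline order.
#' @return A `background_model`.
#' @export
default_background <- function(grid = spectral_grid(), baseline_order = 5) {
  ax <- grid_axis(grid)
  comps <- purrr::map(background_band_tables(), function(bands) {
    raman_spectrum(ax, eval_bands(ax, bands))
  })
  background_model(comps, baseline_order = baseline_order)
}

chebyshev_basis <- function(x, order) {
  u <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  vapply(0:order, function(k) cos(k * acos(u)), numeric(length(x)))
}

#' Fit the background of a raw spectrum
#'
#' Solves one joint constrained least-squares problem whose design matrix
#' stacks the background basis spectra, the Chebyshev baseline basis, and
#' the five biomolecular component profiles. Fitting everything jointly
#' prevents the baseline from absorbing real biomolecular bands
#' ("band-stealing"). Background component coefficients are constrained
#' nonnegative; baseline coefficients are free in sign (fluorescence decay
#' can require signed polynomial terms). The returned background is the
#' background-component sum plus the baseline — the biomolecular columns
#' are only there to protect the cellular signal.
#'
#' @param raw Raw `raman_spectrum` on the library grid (resample first).
#' @param model A [background_model()].
#' @param library_profiles Named list of five profiles from
#'   [resolve_profiles()].
#' @return List with `background` (`raman_spectrum`), `coefficients`
#'   (named, background components), `baseline_coefficients`, and
#'   `component_weights` (the jointly fitted biomolecular weights).
#' @export
fit_background <- function(raw, model, library_profiles) {
  stopifnot(is_raman_spectrum(raw), inherits(model, "background_model"))
  ax <- raw$wavenumber
  bg_mat <- vapply(model$components, function(s) {
    if (nrow(s) != length(ax) || max(abs(s$wavenumber - ax)) > 1e-9) {
      rlang::abort("Background components must share the spectrum's grid.",
                   class = "ramanbca_contract_error")
    }
    s$intensity
  }, numeric(length(ax)))
  cheb <- chebyshev_basis(ax, model$baseline_order)
  prof_mat <- vapply(library_profiles, function(p) p$spectrum$intensity,
                     numeric(length(ax)))
  A <- cbind(bg_mat, cheb, prof_mat)
  nb <- ncol(bg_mat)
  nc <- ncol(cheb)

  # collinearity guard on the normalized design
  norms <- sqrt(colSums(A^2))
  if (any(norms == 0) || kappa(A / rep(norms, each = nrow(A)), exact = FALSE) > 1e10) {
    rlang::abort("Degenerate background design (collinear or zero columns).",
                 class = "ramanbca_numeric_error")
  }

  free <- c(rep(FALSE, nb), rep(TRUE, nc), rep(FALSE, ncol(prof_mat)))
  sol <- nnls_solve(A, raw$intensity, free = free)
  bg_coef <- sol$x[seq_len(nb)]
  names(bg_coef) <- colnames(bg_mat) %||% names(model$components)
  base_coef <- sol$x[nb + seq_len(nc)]
  comp_w <- sol$x[nb + nc + seq_along(library_profiles)]
  names(comp_w) <- names(library_profiles)
  bg_curve <- drop(bg_mat %*% bg_coef) + drop(cheb %*% base_coef)
  list(
    background = spec_update(raw, intensity = bg_curve,
                             meta = list(label = "fitted background")),
    coefficients = bg_coef,
    baseline_coefficients = base_coef,
    component_weights = comp_w
  )
}

#' Subtract the fitted background
#'
#' Returns `raw - background` with the result flagged background-free in
#' its metadata. Small negative excursions from noise are expected and
#' permitted on the output.
#'
#' @inheritParams fit_background
#' @return A background-free `raman_spectrum`.
#' @export
subtract_background <- function(raw, model, library_profiles) {
  fb <- fit_background(raw, model, library_profiles)
  spec_update(raw, intensity = raw$intensity - fb$background$intensity,
              meta = list(background_free = TRUE))
}
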