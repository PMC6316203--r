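# relative amounts of the background basis spectra per unit
# background_scale (glass dominates, medium next, stain weak)
BG_MIX <- c(glass = 1.0, medium = 0.45, stain = 0.08)

#' Per-organelle concentration presets
#'
#' The synthetic generator's study conditions: per organelle and fixation
#' state, the mean and SD of the protein, DNA, RNA, and lipid
#' concentrations (mg/mL) and of the 1665/1440 lipid saturation ratio,
#' mirroring the measured per-organelle tables, plus a trace glycogen
#' level (2.0 +/- 1.5 mg/mL, not tabulated in the source data), the
#' background amplitude, and the instrument noise SD (1 cps by default,
#' so the +/- 3 cps QC gate sits at 3 sigma). Ratio cells that were
#' unmeasurable ("-") are `NA`; the ethanol-fixed ER/Golgi combinations
#' do not exist and are marked unsupported.
#'
#' @return A tibble, one row per organelle x state.
#' @export
organelle_presets <- function() {
  path <- system.file("extdata", "organelle_presets.csv", package = "ramanbca")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @param name Preset name, `"<organelle>_<state>"` with state one of
#'   `live`, `ff` (formaldehyde-fixed), `ef` (ethanol-fixed); e.g.
#'   `"nucleolus_live"`, `"er_ff"`.
#' @export
#' @rdname organelle_presets
get_preset <- function(name) {
  presets <- organelle_presets()
  state_abbr <- c(live = "live", formaldehyde_fixed = "ff", ethanol_fixed = "ef")
  keys <- paste0(presets$organelle, "_", state_abbr[presets$state])
  i <- match(name, keys)
  if (is.na(i)) {
    rlang::abort(sprintf("Unknown preset '%s'. Available: %s.", name,
                         paste(keys, collapse = ", ")),
                 class = "ramanbca_config_error")
  }
  presets[i, ]
}

# per-draw lipid profile with the requested 1665/1440 band-height ratio.
# The variant is scaled so its projection onto the library lipid component
# is exactly unit weight per calibration concentration: the ground-truth
# concentration is thereby defined operationally (what the calibrated fit
# reports), and shape variation flows to the extracted lipid spectrum and
# the measured ratio rather than into a concentration bias.
ratio_adjusted_lipid <- function(ref, lib, ratio) {
  if (is.na(ratio)) return(ref)
  bands <- ref$bands
  if (is.null(bands)) {
    rlang::abort("The library lipid profile has no band model to adjust.",
                 class = "ramanbca_config_error")
  }
  h1440 <- bands$height[bands$center == 1440]
  bands$height[bands$center == 1665] <- ratio * h1440
  ax <- grid_axis(lib$grid)
  y <- eval_bands(ax, bands)
  cref <- ref$spectrum$intensity
  y <- y * sum(cref^2) / sum(y * cref)
  component_profile("lipid", raman_spectrum(ax, y),
                    calibration = ref$calibration,
                    variant = sprintf("ratio_%.3f", ratio), bands = bands)
}

#' Simulate a raw single-organelle spectrum with known ground truth
#'
#' Draws per-component concentrations from zero-truncated normal
#' distributions (`max(N(mean, sd), 0)`), draws the lipid saturation
#' ratio and reshapes the lipid component's 1665 cm^-1 band to match,
#' composes the raw spectrum as weighted component profiles plus the
#' scaled background basis plus additive Gaussian instrument noise, and
#' returns both the spectrum and the generating truth. Identical
#' `(preset, seed)` pairs reproduce the spectrum bit for bit.
#'
#' @param preset A one-row preset (see [organelle_presets()], [get_preset()]).
#' @param lib A [reference_library()] (defaults to the bundled one).
#' @param bg A [background_model()] (defaults to the bundled one).
#' @param seed Integer seed.
#' @return List with `spectrum` (raw `raman_spectrum`) and `truth` (list:
#'   `concentrations`, `weights`, `lipid_ratio`, `background_coefficients`,
#'   `context`, `seed`).
#' @export
simulate_spectrum <- function(preset, lib = default_library(),
                              bg = default_background(lib$grid), seed = 1) {
  preset <- as.list(tibble::as_tibble(preset)[1, ])
  ctx <- measurement_context(preset$organelle, preset$state)
  if (!isTRUE(preset$supported)) {
    rlang::abort(sprintf("Preset %s/%s is an unsupported context.",
                         preset$organelle, preset$state),
                 class = "ramanbca_config_error")
  }
  profiles <- resolve_profiles(lib, ctx)
  withr::with_seed(seed, {
    conc <- vapply(COMPONENT_CLASSES, function(cl) {
      max(stats::rnorm(1, preset[[paste0(cl, "_mean")]],
                       preset[[paste0(cl, "_sd")]]), 0)
    }, numeric(1))
    ratio <- if (is.na(preset$ratio_mean)) NA_real_ else {
      max(stats::rnorm(1, preset$ratio_mean, preset$ratio_sd), 0.05)
    }
    lipid_prof <- ratio_adjusted_lipid(profiles$lipid, lib, ratio)
    gen <- profiles
    gen$lipid <- lipid_prof
    calib <- purrr::map_dbl(gen, "calibration")[COMPONENT_CLASSES]
    weights <- conc / calib
    ax <- grid_axis(lib$grid)
    cell <- rowSums(vapply(COMPONENT_CLASSES, function(cl) {
      weights[[cl]] * gen[[cl]]$spectrum$intensity
    }, numeric(length(ax))))
    bg_coef <- BG_MIX[names(bg$components)]
    bg_coef[is.na(bg_coef)] <- 0.2
    bg_coef <- bg_coef * preset$background_scale
    bg_curve <- rowSums(vapply(seq_along(bg$components), function(i) {
      bg_coef[[i]] * bg$components[[i]]$intensity
    }, numeric(length(ax))))
    noise <- stats::rnorm(length(ax), 0, preset$noise_sd)
    raw <- raman_spectrum(ax, cell + bg_curve + noise,
                          meta = list(label = sprintf("simulated %s/%s",
                                                      ctx$organelle, ctx$state),
                                      simulated = TRUE),
                          allow_negative = TRUE)
    list(
      spectrum = raw,
      truth = list(concentrations = conc, weights = weights,
                   lipid_ratio = ratio,
                   background_coefficients = stats::setNames(bg_coef,
                                                             names(bg$components)),
                   context = ctx, seed = seed)
    )
  })
}

#' Simulate a repeat-measurement reproducibility series
#'
#' Emulates repeated acquisition of the same homogeneous specimen (e.g. a
#' concentrated protein medium): `n` copies of `base` with independent
#' additive Gaussian noise. The per-wavenumber relative SD of the series
#' is the reproducibility figure of merit.
#'
#' @param n Number of replicates (>= 2).
#' @param base The noiseless `raman_spectrum`.
#' @param noise_sd Instrument noise SD in cps.
#' @param seed Integer seed.
#' @return List of `n` `raman_spectrum` replicates.
#' @export
simulate_reproducibility_series <- function(n, base, noise_sd, seed = 1) {
  stopifnot(is_raman_spectrum(base))
  if (n < 2) {
    rlang::abort("Need n >= 2 replicates.", class = "ramanbca_param_error")
  }
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      spec_update(base,
                  intensity = base$intensity +
                    stats::rnorm(nrow(base), 0, noise_sd),
                  meta = list(replicate = i))
    })
  })
}

#' Per-wavenumber relative standard deviation of a replicate series
#'
#' @param replicates List of `raman_spectrum` objects on one grid.
#' @return A tibble: `wavenumber`, `mean`, `sd`, `relative_sd`
#'   (`sd / mean`, `NA` where the mean is <= 0).
#' @export
relative_sd_spectrum <- function(replicates) {
  stopifnot(length(replicates) >= 2)
  Y <- vapply(replicates, function(s) s$intensity,
              numeric(nrow(replicates[[1]])))
  m <- rowMeans(Y)
  s <- apply(Y, 1, stats::sd)
  tibble::tibble(
    wavenumber = replicates[[1]]$wavenumber,
    mean = m, sd = s,
    relative_sd = ifelse(m > 0, s / m, NA_real_)
  )
}

#' Noiseless homogeneous protein-medium spectrum
#'
#' The reproducibility-series base: a concentrated (100 mg/mL) protein
#' solution measured on glass, i.e. the unit-weight generic protein
#' profile plus the scaled background — an egg-white-like homogeneous
#' specimen.
#'
#' @param lib A [reference_library()].
#' @param bg A [background_model()].
#' @param background_scale Background amplitude in cps.
#' @return A `raman_spectrum`.
#' @export
protein_medium_spectrum <- function(lib = default_library(),
                                    bg = default_background(lib$grid),
                                    background_scale = 120) {
  prof <- lib_get(lib, "protein", "generic")
  ax <- grid_axis(lib$grid)
  bg_coef <- BG_MIX[names(bg$components)] * background_scale
  bg_curve <- rowSums(vapply(seq_along(bg$components), function(i) {
    bg_coef[[i]] * bg$components[[i]]$intensity
  }, numeric(length(ax))))
  raman_spectrum(ax, prof$spectrum$intensity + bg_curve,
                 meta = list(label = "homogeneous protein medium"))
}
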