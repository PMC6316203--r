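test_that("pseudo-Voigt band models evaluate with unit peak height", {
  g <- spectral_grid(900, 1100, 1)
  p <- build_synthetic_profile(
    data.frame(center = 1000, height = 1, width = 10, shape = 0),
    g, name = "protein"
  )
  expect_equal(max(p$spectrum$intensity), 1, tolerance = 1e-12)
  expect_equal(p$spectrum$wavenumber[which.max(p$spectrum$intensity)], 1000)
  expect_true(all(p$spectrum$intensity >= 0))

  expect_error(build_synthetic_profile(data.frame(), g, name = "protein"),
               class = "ramanbca_param_error")
  expect_warning(
    build_synthetic_profile(
      data.frame(center = 2000, height = 1, width = 10), g, name = "protein"
    ),
    "outside"
  )
})

test_that("cytoplasmic RNA carries the stronger 815 cm-1 O-P-O band", {
  cyto <- test_lib$profiles[["rna.cytoplasmic"]]$spectrum
  nuc <- test_lib$profiles[["rna.nuclear"]]$spectrum
  at_815 <- which.min(abs(cyto$wavenumber - 815))
  expect_gt(cyto$intensity[at_815], nuc$intensity[at_815])
})

test_that("profile calibration ties unit weight to the standard concentration", {
  prof <- test_profiles()
  # albumin-style identity: a 100 mg/mL standard calibrated to 100 keeps
  # its spectrum, and refitting recovers weight 1 = 100 mg/mL
  raw <- prof$protein$spectrum
  cal <- calibrate_profile(raw, known_concentration = 100,
                           target_calibration = 100, name = "protein")
  expect_equal(cal$spectrum$intensity, raw$intensity)
  set_cal <- prof
  set_cal$protein <- cal
  fit <- fit_bca(raw, set_cal)
  expect_equal(unname(fit$concentrations["protein"]), 100, tolerance = 1e-9)

  # a 40 mg/mL glycogen standard calibrated to 20 halves the spectrum
  gly <- calibrate_profile(prof$glycogen$spectrum, 40, 20, name = "glycogen")
  expect_equal(gly$spectrum$intensity, prof$glycogen$spectrum$intensity / 2)

  expect_error(calibrate_profile(raw, 0, 100, name = "protein"),
               class = "ramanbca_param_error")
})

test_that("calibration is linear in the fitted amount", {
  prof <- test_profiles()
  for (k in c(0.1, 0.5, 1, 2)) {
    for (cl in c("protein", "rna", "lipid")) {
      s <- make_mixture(prof, stats::setNames(k, cl))
      fit <- fit_bca(s, prof)
      expect_equal(unname(fit$concentrations[cl]),
                   k * prof[[cl]]$calibration, tolerance = 1e-8)
    }
  }
})

test_that("variant resolution follows compartment and fixation rules", {
  # RNA: cytoplasmic for cytoplasmic organelles, nuclear for nuclear ones
  for (org in c("mitochondrion", "er", "golgi", "mitotic_cytoplasm")) {
    prof <- resolve_profiles(test_lib, measurement_context(org, "live"))
    expect_equal(prof$rna$variant, "cytoplasmic")
    expect_equal(prof$protein$variant, "cytoplasmic")
  }
  for (org in c("nucleus", "nucleolus", "mitotic_chromosome")) {
    prof <- resolve_profiles(test_lib, measurement_context(org, "live"))
    expect_equal(prof$rna$variant, "nuclear")
    expect_equal(prof$protein$variant, "nuclear")
  }
  # ethanol fixation picks the reshaped protein profile
  prof_ef <- resolve_profiles(
    test_lib, measurement_context("nucleus", "ethanol_fixed")
  )
  expect_equal(prof_ef$protein$variant, "ethanol_fixed")

  # resolution is total over the supported context matrix
  for (org in ramanbca:::ORGANELLES) {
    for (st in ramanbca:::FIXATION_STATES) {
      ctx <- measurement_context(org, st)
      if (!ctx$supported) next
      expect_named(resolve_profiles(test_lib, ctx),
                   c("protein", "dna", "rna", "lipid", "glycogen"))
    }
  }
})

test_that("missing classes and variants are reported correctly", {
  keep <- test_lib$profiles[!grepl("^glycogen", names(test_lib$profiles))]
  crippled <- reference_library(unname(keep), test_grid)
  expect_error(
    resolve_profiles(crippled, measurement_context("nucleus", "live")),
    "glycogen", class = "ramanbca_config_error"
  )

  # generic-protein fallback warns but succeeds
  no_variants <- test_lib$profiles[
    !names(test_lib$profiles) %in%
      c("protein.nuclear", "protein.cytoplasmic", "protein.ethanol_fixed")
  ]
  generic_only <- reference_library(unname(no_variants), test_grid)
  expect_warning(
    prof <- resolve_profiles(generic_only,
                             measurement_context("nucleus", "live")),
    "generic"
  )
  expect_equal(prof$protein$variant, "generic")
})

test_that("ethanol-fixed ER and Golgi contexts are flagged unsupported", {
  expect_false(measurement_context("er", "ethanol_fixed")$supported)
  expect_false(measurement_context("golgi", "ethanol_fixed")$supported)
  expect_true(measurement_context("er", "formaldehyde_fixed")$supported)
  expect_error(measurement_context("ribosome", "live"))
})

test_that("feedback refinement is a fixed point on noise-free fits", {
  prof <- test_profiles()
  w <- c(protein = 1.1, dna = 0.4, rna = 1.5, lipid = 0.7, glycogen = 0.2)
  fit <- fit_bca(make_mixture(prof, w), prof)
  for (cl in c("protein", "rna")) {
    refined <- refine_profile_feedback(test_lib, list(fit), cl)
    expect_lt(
      max(abs(refined$spectrum$intensity - prof[[cl]]$spectrum$intensity)),
      1e-8
    )
    expect_equal(refined$calibration, prof[[cl]]$calibration)
  }
})

test_that("averaging noisy fits beats any single-profile estimate", {
  prof <- test_profiles()
  truth <- prof$protein$spectrum$intensity
  w <- c(protein = 1, dna = 0.3, rna = 1.2, lipid = 0.6, glycogen = 0.15)
  fits <- withr::with_seed(21, {
    lapply(1:20, function(i) {
      s <- make_mixture(prof, w)
      noisy <- raman_spectrum(s$wavenumber, s$intensity + rnorm(nrow(s)),
                              allow_negative = TRUE)
      fit_bca(noisy, prof)
    })
  })
  refined <- refine_profile_feedback(test_lib, fits, "protein")
  l2 <- function(y) sqrt(sum((y - truth)^2))
  singles <- vapply(fits, function(f) {
    one <- refine_profile_feedback(test_lib, list(f), "protein")
    l2(one$spectrum$intensity)
  }, numeric(1))
  expect_lt(l2(refined$spectrum$intensity), min(singles))
})

test_that("refinement refuses fits below the weight floor", {
  prof <- test_profiles()
  fit <- fit_bca(make_mixture(prof, c(protein = 1, dna = 0, rna = 0,
                                      lipid = 0, glycogen = 0)), prof)
  expect_warning(
    expect_error(refine_profile_feedback(test_lib, list(fit), "dna"),
                 class = "ramanbca_refinement_error"),
    "floor"
  )
})

test_that("libraries round-trip through the on-disk manifest format", {
  dir <- withr::local_tempdir()
  write_library(test_lib, dir, background = test_bg)
  loaded <- read_library(dir)
  expect_setequal(names(loaded$library$profiles), names(test_lib$profiles))
  p0 <- test_lib$profiles[["lipid.generic"]]
  p1 <- loaded$library$profiles[["lipid.generic"]]
  expect_equal(p1$spectrum$intensity, p0$spectrum$intensity, tolerance = 1e-6)
  expect_equal(p1$calibration, p0$calibration)
  expect_named(loaded$background$components, names(test_bg$components))
})
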