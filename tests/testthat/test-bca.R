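test_that("fitting a pure unit-weight profile returns its calibration concentration", {
  prof <- test_profiles()
  expected <- c(protein = 100, dna = 20, rna = 20, lipid = 20, glycogen = 20)
  for (cl in names(expected)) {
    fit <- fit_bca(prof[[cl]]$spectrum, prof)
    expect_equal(unname(fit$concentrations[cl]), expected[[cl]],
                 tolerance = 1e-9)
    expect_lt(sum(fit$concentrations[setdiff(names(expected), cl)]), 1e-6)
    expect_lt(fit$qc_metric, 1e-8)
    expect_true(fit$qc_pass)
  }
})

test_that("an all-zero spectrum yields a valid all-zero fit", {
  prof <- test_profiles()
  zero <- raman_spectrum(grid_axis(test_grid),
                         numeric(length(grid_axis(test_grid))),
                         allow_negative = TRUE)
  fit <- fit_bca(zero, prof)
  expect_equal(unname(fit$weights), rep(0, 5))
  expect_true(fit$qc_pass)
})

test_that("linear mixtures are recovered by linearity", {
  prof <- test_profiles()
  s <- make_mixture(prof, c(protein = 0, dna = 0.5, rna = 2,
                            lipid = 0, glycogen = 0))
  fit <- fit_bca(s, prof)
  expect_equal(unname(fit$concentrations["dna"]), 10, tolerance = 1e-8)
  expect_equal(unname(fit$concentrations["rna"]), 40, tolerance = 1e-8)
})

test_that("fit_bca is scale-equivariant and permutation-invariant", {
  prof <- test_profiles()
  w <- c(protein = 0.9, dna = 0.3, rna = 1.4, lipid = 0.6, glycogen = 0.2)
  s <- make_mixture(prof, w)
  base <- fit_bca(s, prof)
  for (k in c(0.25, 3, 7.5)) {
    scaled <- fit_bca(spec_update(s, intensity = k * s$intensity), prof)
    expect_equal(scaled$weights, k * base$weights, tolerance = 1e-10)
  }
  shuffled <- prof[c("lipid", "rna", "protein", "glycogen", "dna")]
  fit2 <- fit_bca(s, shuffled)
  expect_equal(fit2$weights, base$weights, tolerance = 1e-10)
})

test_that("the residual identity and KKT orthogonality hold", {
  prof <- test_profiles()
  s <- withr::with_seed(13, {
    m <- make_mixture(prof, c(protein = 1, dna = 0.4, rna = 1.2,
                              lipid = 0.7, glycogen = 0.1))
    spec_update(m, intensity = m$intensity + rnorm(nrow(m)))
  })
  fit <- fit_bca(s, prof)
  expect_equal(fit$residual$intensity,
               fit$background_free$intensity - fit$model$intensity)
  C <- vapply(fit$profiles, function(p) p$spectrum$intensity,
              numeric(nrow(s)))
  g <- drop(crossprod(C, fit$residual$intensity))
  scale <- max(abs(crossprod(C, s$intensity)))
  active <- fit$weights > 0
  expect_lt(max(abs(g[active])) / scale, 1e-8)
})

test_that("concentration RMSE scales linearly with the noise level", {
  prof <- test_profiles()
  w <- c(protein = 1, dna = 0.4, rna = 1.2, lipid = 0.7, glycogen = 0.15)
  mix <- make_mixture(prof, w)
  truth <- w * vapply(prof[names(w)], `[[`, numeric(1), "calibration")
  rmse <- withr::with_seed(31, {
    vapply(c(0.5, 1, 2), function(sigma) {
      errs <- vapply(1:40, function(i) {
        s <- spec_update(mix, intensity = mix$intensity +
                           rnorm(nrow(mix), 0, sigma))
        fit <- fit_bca(s, prof)
        sqrt(mean((fit$concentrations - truth)^2))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  })
  expect_true(all(diff(rmse) > 0))
  # quadrupling sigma should about quadruple the RMSE
  expect_gt(rmse[3] / rmse[1], 2.5)
  expect_lt(rmse[3] / rmse[1], 6)
})

test_that("QC rejects a fit made with the wrong protein variant", {
  p <- get_preset("nucleolus_live")
  sim <- simulate_spectrum(p, test_lib, test_bg, seed = 7)
  right <- test_profiles("nucleolus", "live")
  wrong <- right
  wrong$protein <- test_lib$profiles[["protein.cytoplasmic"]]

  bad <- fit_bca(subtract_background(sim$spectrum, test_bg, wrong), wrong)
  expect_false(bad$qc_pass)
  expect_gt(bad$qc_metric, 3)

  good <- fit_bca(subtract_background(sim$spectrum, test_bg, right), right)
  expect_true(good$qc_pass)
})

test_that("a zero threshold rejects any noisy fit", {
  prof <- test_profiles()
  s <- withr::with_seed(2, {
    m <- make_mixture(prof, c(protein = 1, dna = 0.2, rna = 1,
                              lipid = 0.5, glycogen = 0.1))
    spec_update(m, intensity = m$intensity + rnorm(nrow(m)))
  })
  fit <- fit_bca(s, prof, qc = qc_policy(threshold = 0))
  expect_false(fit$qc_pass)
  # rejected fits keep their numbers
  expect_true(all(is.finite(fit$concentrations)))
})

test_that("the extracted lipid spectrum keeps the sample's own band shape", {
  prof <- test_profiles()
  w <- c(protein = 1, dna = 0.3, rna = 1.2, lipid = 1, glycogen = 0.2)

  s <- make_mixture(prof, w)
  fit <- fit_bca(s, prof)
  lip <- extract_lipid_spectrum(fit)
  expect_equal(lip$intensity, prof$lipid$spectrum$intensity,
               tolerance = 1e-6)

  # no lipid: extraction leaves only the (near-zero) residual
  s0 <- make_mixture(prof, replace(w, "lipid", 0))
  lip0 <- extract_lipid_spectrum(fit_bca(s0, prof))
  expect_lt(mean(abs(lip0$intensity)), 1e-6)

  # a shifted-ratio lipid variant is recovered as itself, not as the library
  variant <- test_lib$profiles[["lipid.golgi_live"]]  # ratio 0.43
  mix <- make_mixture(prof, replace(w, "lipid", 0))
  s_var <- spec_update(mix, intensity = mix$intensity +
                         variant$spectrum$intensity)
  lip_var <- extract_lipid_spectrum(fit_bca(s_var, prof))
  r <- saturation_ratio(lip_var)
  expect_equal(r, 0.43, tolerance = 0.02)
})

test_that("every fit honours the output contract", {
  prof <- test_profiles()
  fit <- fit_bca(make_mixture(prof, c(protein = 1, dna = 0.3, rna = 1,
                                      lipid = 0.8, glycogen = 0.1)), prof)
  expect_named(fit$weights, c("protein", "dna", "rna", "lipid", "glycogen"))
  expect_named(fit$concentrations, names(fit$weights))
  expect_s3_class(fit$residual, "raman_spectrum")
  expect_s3_class(fit$background_free, "raman_spectrum")
  expect_true(is.numeric(fit$lipid_ratio))

  td <- tidy(fit)
  expect_equal(td$component, names(fit$weights))
  expect_equal(td$concentration, unname(fit$concentrations))
  gl <- glance(fit)
  expect_named(gl, c("organelle", "state", "rss", "qc_metric",
                     "qc_threshold", "qc_pass", "ratio_1665_1440"))
  row <- fit_report_row(fit, "x.csv")
  expect_true(all(c("w_protein", "c_glycogen", "qc_metric",
                    "ratio_1665_1440") %in% names(row)))
})

test_that("aggregation reports mean, SD, and rejection counts per group", {
  prof <- test_profiles("nucleus", "live")
  ctx <- measurement_context("nucleus", "live")
  mk <- function(protein_conc, pass = TRUE) {
    fit <- fit_bca(make_mixture(prof, c(protein = protein_conc / 100,
                                        dna = 0.5, rna = 0.5, lipid = 0.5,
                                        glycogen = 0.1)),
                   prof, context = ctx)
    fit$qc_pass <- pass
    fit
  }
  agg <- aggregate_fits(list(mk(90), mk(110), mk(150, pass = FALSE)))
  prot <- agg[agg$component == "protein", ]
  expect_equal(prot$n, 2)
  expect_equal(prot$n_rejected, 1)
  expect_equal(prot$mean, 100, tolerance = 1e-6)
  expect_equal(prot$sd, sd(c(90, 110)), tolerance = 1e-6)
  lip <- agg[agg$component == "lipid", ]
  expect_true(is.finite(lip$ratio_mean))

  # single accepted fit: mean reported, SD unavailable
  agg1 <- aggregate_fits(list(mk(95), mk(130, pass = FALSE)))
  expect_true(all(is.na(agg1$sd)))
  expect_equal(agg1$mean[agg1$component == "protein"], 95, tolerance = 1e-6)
})

test_that("autoplot methods return ggplot objects", {
  prof <- test_profiles()
  fit <- fit_bca(make_mixture(prof, c(protein = 1, dna = 0.3, rna = 1,
                                      lipid = 0.8, glycogen = 0.1)), prof)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$residual), "ggplot")
})
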