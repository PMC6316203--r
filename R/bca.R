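#' Residual-based quality-control policy
#'
#' A fit is accepted when the residual intensity over the significant
#' wavelength range stays within the instrument's reproducibility band of
#' +/- 3 cps. The metric is the maximum absolute residual (strictest
#' reading; `"mean_abs"` available) evaluated after light Savitzky-Golay
#' smoothing of the residual, so the gate responds to systematic model
#' error rather than to single-pixel noise extremes (set
#' `smooth_window = 1` to disable smoothing).
#'
#' @param threshold Acceptance threshold in cps (> 0; default 3).
#' @param significant_range `c(lo, hi)` window in cm^-1 over which
#'   residuals are judged; default 600-1800 covers every diagnostic band
#'   while avoiding the noisy grid edges.
#' @param metric `"max"` or `"mean_abs"`.
#' @param smooth_window,smooth_order Savitzky-Golay parameters applied to
#'   the residual before the metric.
#' @return A `qc_policy`.
#' @export
qc_policy <- function(threshold = 3, significant_range = c(600, 1800),
                      metric = c("max", "mean_abs"),
                      smooth_window = 11, smooth_order = 3) {
  metric <- rlang::arg_match(metric)
  if (threshold < 0) {
    rlang::abort("`threshold` must be >= 0.", class = "ramanbca_param_error")
  }
  stopifnot(length(significant_range) == 2,
            significant_range[1] < significant_range[2])
  structure(list(threshold = threshold, significant_range = significant_range,
                 metric = metric, smooth_window = smooth_window,
                 smooth_order = smooth_order),
            class = "qc_policy")
}

#' Decompose a background-free spectrum into biomolecular components
#'
#' Models the background-free organellar spectrum as a linear sum of the
#' five weighted component profiles, `S(v) = sum_i w_i C_i(v)`, and
#' estimates the weights by nonnegative least squares. Because each
#' profile is calibrated so unit weight equals its calibration
#' concentration, the weights map to absolute concentrations by
#' `c_i = w_i * calibration_i`. The residual spectrum
#' (`background_free - model`) feeds the accept/reject rule of
#' [apply_qc()], and the extracted lipid spectrum yields the 1665/1440
#' saturation ratio when the lipid signal is measurable.
#'
#' @param background_free A background-free `raman_spectrum`.
#' @param profiles Named list of five profiles from [resolve_profiles()].
#' @param qc A [qc_policy()].
#' @param context Optional [measurement_context()] recorded in the result.
#' @return A `bca_fit` with elements `weights`, `concentrations` (mg/mL),
#'   `background_free`, `model`, `residual`, `qc_metric`, `qc_pass`,
#'   `lipid_ratio`, `profiles`, `context`.
#' @examples
#' lib <- default_library(spectral_grid(400, 1900, 2))
#' ctx <- measurement_context("nucleolus", "live")
#' prof <- resolve_profiles(lib, ctx)
#' s <- prof$protein$spectrum  # a pure 100 mg/mL protein spectrum
#' fit <- fit_bca(s, prof, context = ctx)
#' round(fit$concentrations, 6)
#' @export
fit_bca <- function(background_free, profiles, qc = qc_policy(),
                    context = NULL) {
  stopifnot(is_raman_spectrum(background_free))
  if (!identical(sort(names(profiles)), sort(COMPONENT_CLASSES))) {
    rlang::abort("`profiles` must be a named list of the five component classes.",
                 class = "ramanbca_contract_error")
  }
  profiles <- profiles[COMPONENT_CLASSES]
  ax <- background_free$wavenumber
  C <- vapply(profiles, function(p) {
    if (nrow(p$spectrum) != length(ax) ||
        max(abs(p$spectrum$wavenumber - ax)) > 1e-9) {
      rlang::abort("Spectrum and profiles must share one grid.",
                   class = "ramanbca_contract_error")
    }
    p$spectrum$intensity
  }, numeric(length(ax)))

  norms <- sqrt(colSums(C^2))
  if (any(norms == 0)) {
    rlang::abort("A component profile is identically zero.",
                 class = "ramanbca_numeric_error")
  }
  if (kappa(C / rep(norms, each = nrow(C)), exact = TRUE) > 1e8) {
    rlang::abort("Component profiles are too collinear to fit (condition number > 1e8).",
                 class = "ramanbca_numeric_error")
  }

  sol <- nnls_solve(C, background_free$intensity)
  weights <- stats::setNames(sol$x, COMPONENT_CLASSES)
  calib <- purrr::map_dbl(profiles, "calibration")
  fit <- structure(
    list(
      weights = weights,
      concentrations = weights * calib,
      background_free = background_free,
      model = spec_update(background_free, intensity = sol$fitted,
                          meta = list(label = "component model")),
      residual = spec_update(background_free, intensity = sol$residual,
                             meta = list(label = "residual", residual = TRUE)),
      qc_metric = NA_real_, qc_pass = NA, qc = qc,
      lipid_ratio = NA_real_,
      profiles = profiles, context = context
    ),
    class = "bca_fit"
  )
  fit <- apply_qc(fit, qc)
  lip <- extract_lipid_spectrum(fit)
  noise <- stats::sd(fit$residual$intensity)
  fit$lipid_ratio <- tryCatch(
    saturation_ratio(lip, noise_floor = 3 * noise),
    ramanbca_domain_error = function(e) NA_real_
  )
  fit
}

#' Apply the residual quality-control rule
#'
#' Recomputes `qc_metric` over the policy's significant range and sets
#' `qc_pass = (qc_metric <= threshold)`. Rejected fits keep all their
#' numbers; they are only flagged (and later excluded from aggregation).
#'
#' @param fit A `bca_fit`.
#' @param qc A [qc_policy()].
#' @return The updated `bca_fit`.
#' @export
apply_qc <- function(fit, qc = fit$qc) {
  stopifnot(inherits(fit, "bca_fit"), inherits(qc, "qc_policy"))
  r <- fit$residual
  y <- r$intensity
  if (qc$smooth_window > 1) {
    y <- signal::sgolayfilt(y, p = qc$smooth_order, n = qc$smooth_window)
  }
  sel <- r$wavenumber >= qc$significant_range[1] &
    r$wavenumber <= qc$significant_range[2]
  if (!any(sel)) {
    rlang::abort("Significant range is outside the spectrum grid.",
                 class = "ramanbca_param_error")
  }
  fit$qc_metric <- switch(qc$metric,
    max = max(abs(y[sel])),
    mean_abs = mean(abs(y[sel]))
  )
  fit$qc_pass <- fit$qc_metric <= qc$threshold
  fit$qc <- qc
  fit
}

#' Extract the organellar lipid spectrum
#'
#' Subtracts the weighted protein, DNA, RNA, and glycogen profiles from the
#' background-free spectrum. The result equals the weighted lipid profile
#' plus the fit residual, so it retains the sample's actual lipid band
#' shape (e.g. its true 1665/1440 ratio) rather than the library's.
#'
#' @param fit A `bca_fit`.
#' @param profiles Profiles used in the fit; defaults to those stored in it.
#' @return A `raman_spectrum`.
#' @export
extract_lipid_spectrum <- function(fit, profiles = fit$profiles) {
  stopifnot(inherits(fit, "bca_fit"))
  others <- setdiff(COMPONENT_CLASSES, "lipid")
  rest <- rowSums(vapply(others, function(cl) {
    fit$weights[[cl]] * profiles[[cl]]$spectrum$intensity
  }, numeric(nrow(fit$background_free))))
  spec_update(fit$background_free,
              intensity = fit$background_free$intensity - rest,
              meta = list(label = "organellar lipid spectrum", lipid = TRUE))
}

#' @export
format.bca_fit <- function(x, ...) {
  conc <- paste(sprintf("%s %.1f", names(x$concentrations), x$concentrations),
                collapse = ", ")
  sprintf("<bca_fit: %s mg/mL; qc %s (%.3g cps); 1665/1440 %s>",
          conc, if (isTRUE(x$qc_pass)) "pass" else "REJECT", x$qc_metric,
          ifelse(is.na(x$lipid_ratio), "-", sprintf("%.2f", x$lipid_ratio)))
}

#' @export
print.bca_fit <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a BCA fit
#'
#' One row per biomolecular component with the fitted weight, the
#' calibration constant, and the absolute concentration.
#'
#' @param x A `bca_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `variant`, `weight`,
#'   `calibration`, `concentration`.
#' @export
tidy.bca_fit <- function(x, ...) {
  tibble::tibble(
    component = COMPONENT_CLASSES,
    variant = purrr::map_chr(x$profiles[COMPONENT_CLASSES], "variant"),
    weight = unname(x$weights[COMPONENT_CLASSES]),
    calibration = purrr::map_dbl(x$profiles[COMPONENT_CLASSES], "calibration"),
    concentration = unname(x$concentrations[COMPONENT_CLASSES])
  )
}

#' Glance at a BCA fit
#'
#' @param x A `bca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: context, residual summary, QC verdict, and
#'   the lipid saturation ratio.
#' @export
glance.bca_fit <- function(x, ...) {
  tibble::tibble(
    organelle = x$context$organelle %||% NA_character_,
    state = x$context$state %||% NA_character_,
    rss = sum(x$residual$intensity^2),
    qc_metric = x$qc_metric,
    qc_threshold = x$qc$threshold,
    qc_pass = x$qc_pass,
    ratio_1665_1440 = x$lipid_ratio
  )
}

#' One-row fit report
#'
#' The serialized form of a fit: context, weights, concentrations, QC, and
#' saturation ratio; the row format written by the command-line `fit`.
#'
#' @param fit A `bca_fit`.
#' @param file Optional source-file label.
#' @return A one-row tibble.
#' @export
fit_report_row <- function(fit, file = NA_character_) {
  w <- as.list(stats::setNames(fit$weights, paste0("w_", COMPONENT_CLASSES)))
  cc <- as.list(stats::setNames(fit$concentrations,
                                paste0("c_", COMPONENT_CLASSES)))
  tibble::tibble(
    file = file,
    organelle = fit$context$organelle %||% NA_character_,
    state = fit$context$state %||% NA_character_,
    !!!w, !!!cc,
    qc_metric = fit$qc_metric, qc_pass = fit$qc_pass,
    ratio_1665_1440 = fit$lipid_ratio
  )
}

#' Aggregate fits into a per-group concentration table
#'
#' Groups accepted fits by organelle and fixation state and reports, per
#' component, the number of accepted fits, the mean and sample SD of the
#' concentrations (mg/mL), and — on the lipid rows — the mean and SD of
#' the 1665/1440 saturation ratio. Rejected fits are excluded and counted.
#' Groups with fewer than two accepted fits keep their mean but have SD
#' marked unavailable.
#'
#' @param fits List of `bca_fit` objects, or a report tibble of
#'   [fit_report_row()] rows.
#' @return A tibble with columns `organelle`, `state`, `component`,
#'   `n`, `n_rejected`, `mean`, `sd`, `ratio_mean`, `ratio_sd`.
#' @export
aggregate_fits <- function(fits) {
  report <- if (is.data.frame(fits)) {
    tibble::as_tibble(fits)
  } else {
    purrr::map_dfr(fits, fit_report_row)
  }
  long <- report |>
    tidyr::pivot_longer(dplyr::all_of(paste0("c_", COMPONENT_CLASSES)),
                        names_to = "component", names_prefix = "c_",
                        values_to = "concentration")
  long |>
    dplyr::group_by(.data$organelle, .data$state, .data$component) |>
    dplyr::summarise(
      n = sum(.data$qc_pass),
      n_rejected = sum(!.data$qc_pass),
      mean = mean(.data$concentration[.data$qc_pass]),
      sd = ifelse(sum(.data$qc_pass) >= 2,
                  stats::sd(.data$concentration[.data$qc_pass]), NA_real_),
      ratio_mean = ifelse(.data$component[1] == "lipid",
                          mean(.data$ratio_1665_1440[.data$qc_pass], na.rm = TRUE),
                          NA_real_),
      ratio_sd = ifelse(.data$component[1] == "lipid" & sum(.data$qc_pass) >= 2,
                        stats::sd(.data$ratio_1665_1440[.data$qc_pass], na.rm = TRUE),
                        NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(component = factor(.data$component, COMPONENT_CLASSES)) |>
    dplyr::arrange(.data$organelle, .data$state, .data$component) |>
    dplyr::mutate(component = as.character(.data$component))
}

#' Plot a BCA fit
#'
#' Background-free spectrum with the fitted component model overlaid, and
#' the residual in a lower panel with the +/- QC threshold band.
#'
#' @param object A `bca_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bca_fit <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(panel = "spectrum", series = "background-free",
                   wavenumber = object$background_free$wavenumber,
                   intensity = object$background_free$intensity),
    tibble::tibble(panel = "spectrum", series = "model",
                   wavenumber = object$model$wavenumber,
                   intensity = object$model$intensity),
    tibble::tibble(panel = "residual", series = "residual",
                   wavenumber = object$residual$wavenumber,
                   intensity = object$residual$intensity)
  )
  thr <- object$qc$threshold
  ggplot2::ggplot(dat, ggplot2::aes(.data$wavenumber, .data$intensity,
                                    colour = .data$series)) +
    ggplot2::geom_hline(
      data = tibble::tibble(panel = "residual", y = c(-thr, thr)),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey50"
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (cps)", colour = NULL)
}

#' Plot an aggregated concentration table
#'
#' Mean +/- SD concentration per component and group, the synthetic
#' analogue of a per-organelle concentration bar chart.
#'
#' @param agg Output of [aggregate_fits()].
#' @return A ggplot.
#' @export
plot_concentrations <- function(agg) {
  ggplot2::ggplot(agg, ggplot2::aes(.data$component, .data$mean,
                                    fill = .data$state)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$organelle)) +
    ggplot2::labs(x = NULL, y = "Concentration (mg/mL)")
}
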