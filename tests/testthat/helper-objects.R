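# Shared fixtures, built once per test run. The test grid trims the axis
# to 400-1900 cm^-1 at 2 cm^-1 to keep the suite fast; the acceptance
# tests use the full default grid.
test_grid <- spectral_grid(400, 1900, 2)
test_lib <- default_library(test_grid)
test_bg <- default_background(test_grid)

test_profiles <- function(organelle = "nucleolus", state = "live") {
  resolve_profiles(test_lib, measurement_context(organelle, state))
}

# background-free mixture spectrum with known weights
make_mixture <- function(profiles, weights) {
  ax <- profiles[[1]]$spectrum$wavenumber
  y <- rowSums(vapply(names(weights), function(cl) {
    weights[[cl]] * profiles[[cl]]$spectrum$intensity
  }, numeric(length(ax))))
  raman_spectrum(ax, y, meta = list(background_free = TRUE),
                 allow_negative = TRUE)
}

# independent projected-gradient NNLS, used only as a test oracle
nnls_projected_gradient <- function(A, b, max_iter = 200000, tol = 1e-12) {
  L <- norm(A, "2")^2
  x <- numeric(ncol(A))
  for (i in seq_len(max_iter)) {
    g <- drop(crossprod(A, A %*% x - b))
    x_new <- pmax(x - g / L, 0)
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  x
}
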