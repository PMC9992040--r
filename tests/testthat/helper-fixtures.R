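# Shared fixture builders. Everything is generated in code at test time.

# A plain synthetic series from explicit magnitude/phase stacks.
make_series <- function(mag, phi, spacing = 0.2, venc = 20,
                        grid_kind = "reconstructed") {
  cine_pc_series(mag, phi, pixel_spacing_mm = spacing, venc_cm_s = venc,
                 grid_kind = grid_kind)
}

# Noise-only series: constant tissue magnitude plus i.i.d. complex Gaussian
# noise, no zero-filling (pixels independent). Valid-linearization regime
# when tissue >> sigma.
noise_only_series <- function(nr = 64, nc = 64, n_phases = 12, tissue = 50,
                              sigma = 2, seed = 1) {
  set.seed(seed)
  cplx <- complex(
    real = tissue + rnorm(nr * nc * n_phases, 0, sigma),
    imaginary = rnorm(nr * nc * n_phases, 0, sigma)
  )
  cplx <- array(cplx, c(nr, nc, n_phases))
  make_series(Mod(cplx), Arg(cplx))
}

full_roi <- function(series) {
  d <- dim(series$magnitude)
  roi_mask(matrix(TRUE, d[1], d[2]))
}

# Small high-SNR scene with a handful of circular vessels; cheap enough for
# unit tests.
small_scene <- function(n_vessels = 5, seed = 3, ...) {
  standard_scene(n_vessels = n_vessels, n_oblique = 0, n_ghost = 0,
                 fov_mm = 20, seed = seed, ...)
}

# Brute-force O(N^2) 1D DFT matrices for the zero-filling oracle.
dft_matrix <- function(n, inverse = FALSE) {
  s <- if (inverse) 1i else -1i
  outer(0:(n - 1), 0:(n - 1), function(j, k) exp(s * 2 * pi * j * k / n))
}
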