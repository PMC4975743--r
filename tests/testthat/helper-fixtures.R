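# Shared deterministic fixtures, built in code.

rand_img <- function(seed, h = 8, w = h) {
  withr::with_seed(seed, matrix(stats::rnorm(h * w), h, w))
}

rand_vf <- function(seed, h = 8, w = h) {
  vector_field(rand_img(seed, h, w), rand_img(seed + 1000, h, w))
}

rand_stf <- function(seed, h = 8, w = h) {
  sym_tensor_field(rand_img(seed, h, w), rand_img(seed + 1000, h, w),
                   rand_img(seed + 2000, h, w))
}

# assemble the dense matrix of a linear image operator on h x w grids
dense_op <- function(op, h, w) {
  n <- h * w
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- matrix(0, h, w); e[i] <- 1
    M[, i] <- as.vector(op(e))
  }
  M
}

# the three study degradation problems: one 64x64 phantom per PSF family,
# with the published parameter preset for that family's experiment; memoized
fixture_env <- new.env(parent = emptyenv())

fixture_problems <- function() {
  if (!is.null(fixture_env$problems)) return(fixture_env$problems)
  spec <- list(
    gaussian = list(psf = gaussian_psf(5, 2), kind = "ramp_disks", preset = "test1"),
    box      = list(psf = box_psf(5),        kind = "shapes",     preset = "test2"),
    motion   = list(psf = motion_psf(2, 45), kind = "piecewise_affine", preset = "test3"))
  problems <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    u <- make_phantom(64, 64, s$kind, seed = i)
    K <- blur_operator(s$psf, dim(u))
    list(family = names(spec)[i], u = u, K = K,
         f = degrade(u, K, seed = 50 + i), preset = s$preset)
  })
  names(problems) <- names(spec)
  fixture_env$problems <- problems
  problems
}

# staircase energy: L1 norm of periodic second differences along both axes
staircase_energy <- function(u) {
  d2x <- tgvpois:::shift_cols(u, 1, "periodic") - 2 * u +
    tgvpois:::shift_cols(u, -1, "periodic")
  d2y <- tgvpois:::shift_rows(u, 1, "periodic") - 2 * u +
    tgvpois:::shift_rows(u, -1, "periodic")
  sum(abs(d2x)) + sum(abs(d2y))
}
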