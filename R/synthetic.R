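# Synthetic phantoms and the blur + Poisson degradation protocol, so the
# whole pipeline is testable without external images.

#' Generate a clean test phantom
#'
#' Deterministic (given `seed`) nonnegative images in `[0, peak]` combining
#' sharp edges with smooth intensity ramps - exactly the two regimes where
#' second-order TGV improves on plain TV (edge preservation vs. staircasing
#' on ramps).
#'
#' * `"piecewise_affine"`: tilted affine planes split by a vertical and a
#'   diagonal jump; second finite differences vanish inside each region.
#' * `"shapes"`: constant disks and rectangles of random intensity over a
#'   gentle background ramp.
#' * `"ramp_disks"`: a global diagonal ramp with three constant disks.
#'
#' @param height,width Image dimensions, >= 32.
#' @param kind Phantom family.
#' @param seed RNG seed controlling the random geometry.
#' @param peak Maximum intensity (default 255, the 8-bit scale).
#' @return Numeric matrix in `[0, peak]`.
#' @export
make_phantom <- function(height, width,
                         kind = c("piecewise_affine", "shapes", "ramp_disks"),
                         seed = 1, peak = 255) {
  kind <- match.arg(kind)
  if (height < 32 || width < 32) stop("make_phantom: dims must be >= 32")
  yy <- matrix(seq_len(height), height, width)         # row = vertical
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  u <- withr::with_seed(seed, {
    switch(kind,
      piecewise_affine = {
        sp <- stats::runif(1, 0.35, 0.65) * width
        slope <- stats::runif(4, -0.8, 0.8)
        base <- stats::runif(3, 0.2, 0.8) * peak
        left <- base[1] + slope[1] * xx + slope[2] * yy
        right <- base[2] + slope[3] * (width - xx) + slope[4] * yy
        u0 <- ifelse(xx < sp, left, right)
        diag_reg <- (xx - yy) > stats::runif(1, -0.2, 0.2) * width
        u0[diag_reg] <- base[3] + 0.5 * slope[1] * (xx + yy)[diag_reg] / 2
        u0
      },
      shapes = {
        u0 <- 30 + 40 * xx / width + 20 * yy / height
        for (i in 1:4) {
          cx <- stats::runif(1, 0.2, 0.8) * width
          cy <- stats::runif(1, 0.2, 0.8) * height
          r <- stats::runif(1, 0.08, 0.2) * min(height, width)
          val <- stats::runif(1, 0.3, 1) * peak
          if (i %% 2 == 0) {
            u0[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- val
          } else {
            u0[abs(xx - cx) <= r & abs(yy - cy) <= 0.7 * r] <- val
          }
        }
        u0
      },
      ramp_disks = {
        u0 <- 20 + (peak - 40) * (xx + yy) / (width + height)
        for (i in 1:3) {
          cx <- stats::runif(1, 0.2, 0.8) * width
          cy <- stats::runif(1, 0.2, 0.8) * height
          r <- stats::runif(1, 0.08, 0.16) * min(height, width)
          u0[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- stats::runif(1, 0.4, 1) * peak
        }
        u0
      })
  })
  u <- pmin(pmax(u, 0), peak)
  # span the full scale (emulates 8-bit test images whose brightest content
  # reaches the peak), so the Poisson draw in degrade() acts at scale 1
  u * (peak / max(u))
}

#' Degradation protocol descriptor
#'
#' Bundles the PSF, Poisson intensity scale and seed of the blur + Poisson
#' degradation so that `(spec, clean image)` reproduces the degraded image
#' exactly.
#'
#' @param psf A [psf()] or a character descriptor for [parse_psf_spec()].
#' @param peak Poisson intensity scale: the blurred image is rescaled so its
#'   reference maximum is `peak` before drawing counts (default 255; when
#'   the clean image already peaks at 255 this leaves intensities
#'   untouched).
#' @param seed RNG seed for the Poisson draw.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(psf = gaussian_psf(5, 2), peak = 255, seed = 1) {
  if (is.character(psf)) psf <- parse_psf_spec(psf)
  stopifnot(inherits(psf, "psf"), peak > 0)
  structure(list(psf = psf, peak = peak, seed = seed), class = "degradation_spec")
}

#' Blur an image and corrupt it with Poisson noise
#'
#' Implements the observation model `f = Poisson(K u)`: the clean image is
#' convolved with the PSF, scaled so the clean maximum maps to `peak`, and
#' every pixel is replaced by an independent Poisson draw with that blurred
#' intensity as its mean.  The result is left on that scale (integer
#' counts).  With the default `peak = 255` and an 8-bit-scale input the
#' counts are drawn directly from the blurred intensities.
#'
#' @param u Clean nonnegative image.
#' @param K A [blur_operator()], [psf()], kernel matrix, or a
#'   [degradation_spec()] (whose `peak`/`seed` then apply).
#' @param peak Poisson intensity scale (see [degradation_spec()]).
#' @param seed Optional RNG seed; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @param bc Boundary convention for the blur.
#' @return Integer-valued matrix of Poisson counts.
#' @export
degrade <- function(u, K, peak = 255, seed = NULL, bc = "periodic") {
  if (!is.matrix(u) || any(u < 0)) stop("degrade: clean image must be a nonnegative matrix")
  if (inherits(K, "degradation_spec")) {
    peak <- K$peak; if (is.null(seed)) seed <- K$seed; K <- K$psf
  }
  if (inherits(K, "psf") || is.matrix(K)) K <- blur_operator(K, dim(u), bc)
  blurred <- pmax(apply_blur(K, u), 0)
  scale <- if (max(u) > 0) peak / max(u) else 1
  lam <- blurred * scale
  draw <- function() matrix(as.numeric(stats::rpois(length(lam), lam)),
                            nrow(lam), ncol(lam))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate the synthetic fixture suite
#'
#' Builds (clean, psf, degraded) triples covering the three PSF families
#' (Gaussian 5/2, box 5x5, linear motion r = 2 at 45 degrees) at the given
#' sizes, writes them as 16-bit TIFFs with a JSON manifest, and returns the
#' suite.  Clean phantoms are quantized to integer intensities (the 8-bit-
#' style grid, stored on the 16-bit scale) so that reloading reproduces
#' bit-identical arrays and [read_image()] returns both members of a pair
#' on one common intensity scale.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed; phantom geometry and Poisson draws derive from
#'   it deterministically.
#' @param sizes Square image sizes to generate (each size x each PSF).
#' @param peak Intensity scale passed to [make_phantom()] and [degrade()].
#' @return Invisibly, a list of fixtures, each with `clean`, `degraded`,
#'   `psf`, `psf_spec`, `name`.
#' @seealso [load_fixture_suite()]
#' @export
make_fixture_suite <- function(dir, seed = 1, sizes = c(64, 128), peak = 255) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  psf_specs <- c(gaussian = "gaussian:5,2", box = "box:5", motion = "motion:2,45")
  kinds <- c(gaussian = "ramp_disks", box = "shapes", motion = "piecewise_affine")
  fixtures <- list()
  manifest <- list(seed = seed, peak = peak, fixtures = list())
  idx <- 0L
  for (n in sizes) {
    for (fam in names(psf_specs)) {
      idx <- idx + 1L
      sub_seed <- (seed * 1000L + idx) %% .Machine$integer.max
      p <- parse_psf_spec(psf_specs[[fam]])
      clean <- round(make_phantom(n, n, kinds[[fam]], seed = sub_seed, peak = peak))
      degraded <- degrade(clean, p, peak = peak, seed = sub_seed + 1L)
      name <- sprintf("%s_%d", fam, n)
      cf <- sprintf("%s_clean.tif", name); df <- sprintf("%s_degraded.tif", name)
      tiff::writeTIFF(clean / 65535, file.path(dir, cf), bits.per.sample = 16)
      tiff::writeTIFF(degraded / 65535, file.path(dir, df), bits.per.sample = 16)
      fixtures[[name]] <- list(clean = clean, degraded = degraded, psf = p,
                               psf_spec = psf_specs[[fam]], name = name)
      manifest$fixtures[[name]] <- list(
        name = name, size = n, psf = psf_specs[[fam]], kind = kinds[[fam]],
        seed = sub_seed, clean_file = cf, degraded_file = df)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fixtures)
}

#' Reload a fixture suite written by [make_fixture_suite()]
#'
#' @param dir Directory holding the TIFFs and `manifest.json`.
#' @return A list of fixtures in the same layout as [make_fixture_suite()]
#'   returns.
#' @export
load_fixture_suite <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (fx in manifest$fixtures) {
    clean <- round(tiff::readTIFF(file.path(dir, fx$clean_file)) * 65535)
    degraded <- round(tiff::readTIFF(file.path(dir, fx$degraded_file)) * 65535)
    out[[fx$name]] <- list(clean = clean, degraded = degraded,
                           psf = parse_psf_spec(fx$psf), psf_spec = fx$psf,
                           name = fx$name)
  }
  out
}
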