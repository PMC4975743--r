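# Restoration quality metrics: RelErr, SNR, MSE, PSNR, SSIM.

check_pair <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !identical(dim(u), dim(v)))
    stop("images must be numeric matrices of one shape")
}

#' Relative L2 error
#'
#' `||u_true - u_hat||_2 / ||u_true||_2` (scale-free, the default).  With
#' `squared_denominator = TRUE` the denominator is `||u_true||_2^2` instead,
#' a non-scale-free variant kept for completeness.
#'
#' @param u_true Reference (clean) image.
#' @param u_hat Image under test.
#' @param squared_denominator Use `||u||^2` in the denominator.
#' @return A nonnegative scalar.
#' @export
relerr <- function(u_true, u_hat, squared_denominator = FALSE) {
  check_pair(u_true, u_hat)
  den <- sqrt(sum(u_true^2))
  if (den == 0) stop("relerr: reference image is identically zero")
  if (squared_denominator) den <- den^2
  sqrt(sum((u_true - u_hat)^2)) / den
}

#' Mean squared error
#'
#' @inheritParams relerr
#' @return Mean of squared pixel differences.
#' @export
mse <- function(u_true, u_hat) {
  check_pair(u_true, u_hat)
  mean((u_true - u_hat)^2)
}

#' Signal-to-noise ratio in dB
#'
#' `20 log10(||u||_2 / ||u_hat - u||_2)`; `+Inf` when the images are
#' identical.
#'
#' @inheritParams relerr
#' @return SNR in decibels.
#' @export
snr <- function(u_true, u_hat) {
  check_pair(u_true, u_hat)
  err <- sqrt(sum((u_hat - u_true)^2))
  if (err == 0) return(Inf)
  20 * log10(sqrt(sum(u_true^2)) / err)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(peak^2 / MSE)` with `peak = 255` for 8-bit-scale intensities;
#' `+Inf` when the images are identical.
#'
#' @inheritParams relerr
#' @param peak Peak intensity of the scale (default 255).
#' @return PSNR in decibels.
#' @export
psnr <- function(u_true, u_hat, peak = 255) {
  m <- mse(u_true, u_hat)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

# separable correlation with zero padding, renormalized by the local window
# mass so boundary windows keep unit weight
filter_norm <- function(u, g) {
  pad <- (length(g) - 1) / 2
  conv1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (t in seq_along(g)) {
      s <- t - 1 - pad
      src <- seq_len(w) + s
      ok <- src >= 1 & src <= w
      out[, ok] <- out[, ok] + g[t] * m[, src[ok], drop = FALSE]
    }
    out
  }
  num <- t(conv1(t(conv1(u))))
  one <- matrix(1, nrow(u), ncol(u))
  den <- t(conv1(t(conv1(one))))
  num / den
}

#' Structural similarity index
#'
#' Mean over local windows of
#' \deqn{\frac{(2\mu_u\mu_{\hat u} + C_1)(2\sigma_{u\hat u} + C_2)}
#'            {(\mu_u^2 + \mu_{\hat u}^2 + C_1)
#'             (\sigma_u^2 + \sigma_{\hat u}^2 + C_2)}.}
#' The default computes local statistics under an 11x11 Gaussian window
#' (standard deviation 1.5) with the customary stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L`.
#' `method = "global"` instead evaluates the formula once with whole-image
#' means, variances and covariance.
#'
#' @inheritParams relerr
#' @param method `"window"` (default) or `"global"`.
#' @param window_size Odd Gaussian window support (windowed method).
#' @param window_sigma Gaussian window standard deviation.
#' @param L Dynamic range of the intensities (default 255).
#' @param C1,C2 Stabilizing constants; default from `L`.
#' @return SSIM in `[-1, 1]`; 1 iff (windows of) the images agree exactly.
#' @export
ssim <- function(u_true, u_hat, method = c("window", "global"),
                 window_size = 11, window_sigma = 1.5, L = 255,
                 C1 = (0.01 * L)^2, C2 = (0.03 * L)^2) {
  check_pair(u_true, u_hat)
  method <- match.arg(method)
  if (method == "global") {
    n <- length(u_true)
    mu1 <- mean(u_true); mu2 <- mean(u_hat)
    v1 <- mean((u_true - mu1)^2); v2 <- mean((u_hat - mu2)^2)
    cv <- mean((u_true - mu1) * (u_hat - mu2))
    return(((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
             ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
  }
  if (window_size %% 2 == 0) stop("ssim: window_size must be odd")
  if (any(dim(u_true) < window_size)) stop("ssim: window larger than image")
  off <- seq(-(window_size - 1) / 2, (window_size - 1) / 2)
  g <- exp(-off^2 / (2 * window_sigma^2)); g <- g / sum(g)
  mu1 <- filter_norm(u_true, g); mu2 <- filter_norm(u_hat, g)
  v1 <- filter_norm(u_true^2, g) - mu1^2
  v2 <- filter_norm(u_hat^2, g) - mu2^2
  cv <- filter_norm(u_true * u_hat, g) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
    ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
  mean(ssim_map)
}

#' Full quality report for a restoration
#'
#' Computes SNR, PSNR, RelErr, MSE and SSIM of `u_hat` against the clean
#' reference.
#'
#' @inheritParams psnr
#' @param ... Passed to [ssim()].
#' @return A `metrics_report`: list with fields `snr`, `psnr`, `relerr`,
#'   `mse`, `ssim`.
#' @export
metrics_report <- function(u_true, u_hat, peak = 255, ...) {
  structure(list(snr = snr(u_true, u_hat),
                 psnr = psnr(u_true, u_hat, peak = peak),
                 relerr = relerr(u_true, u_hat),
                 mse = mse(u_true, u_hat),
                 ssim = ssim(u_true, u_hat, ...)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%-8s %10s\n", "metric", "value"))
  for (nm in c("snr", "psnr", "relerr", "mse", "ssim"))
    cat(sprintf("%-8s %10.4f\n", toupper(nm), x[[nm]]))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param x A [metrics_report()].
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
metrics_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metrics_report"))
  out <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
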