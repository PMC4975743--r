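# Point-spread functions and the blur operator K / K^T.

#' Point-spread function
#'
#' A small nonnegative 2-D kernel with a designated anchor (center) cell.
#' Named builders ([gaussian_psf()], [box_psf()], [motion_psf()]) normalize
#' the kernel to sum one, so convolution conserves total intensity (flux).
#'
#' @param kernel Small numeric matrix with nonnegative entries.
#' @param anchor Integer pair `(row, col)` of the kernel cell that sits on the
#'   pixel being blurred; defaults to the central cell.
#' @param normalize Divide the kernel by its sum (default `TRUE`).
#' @return An object of class `psf`.
#' @export
psf <- function(kernel, anchor = NULL, normalize = TRUE) {
  stopifnot(is.matrix(kernel), all(is.finite(kernel)), all(kernel >= 0))
  if (sum(kernel) <= 0) stop("psf: kernel must have positive sum")
  if (normalize) kernel <- kernel / sum(kernel)
  if (is.null(anchor)) anchor <- c((nrow(kernel) + 1L) %/% 2L, (ncol(kernel) + 1L) %/% 2L)
  anchor <- as.integer(anchor)
  structure(list(kernel = kernel, anchor = anchor), class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("<psf %dx%d, anchor (%d,%d), sum %.6f>\n",
              nrow(x$kernel), ncol(x$kernel), x$anchor[1], x$anchor[2], sum(x$kernel)))
  print(signif(x$kernel, 4))
  invisible(x)
}

#' Sampled Gaussian point-spread function
#'
#' A truncated 2-D Gaussian sampled at integer offsets on a `size` x `size`
#' grid and normalized to sum one.  `gaussian_psf(5, 2)` is the common
#' "Gaussian blur of support 5, standard deviation 2" recipe.
#'
#' @param size Odd kernel support (an even size has no center cell).
#' @param sigma Standard deviation in pixels, > 0.
#' @return A [psf()].
#' @examples
#' gaussian_psf(5, 2)
#' @export
gaussian_psf <- function(size, sigma) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("gaussian_psf: size must be odd and >= 1")
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_psf: sigma must be > 0")
  m <- (size - 1L) / 2L
  off <- seq(-m, m)
  g <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  psf(g)
}

#' Uniform (box) point-spread function
#'
#' Every entry equals `1 / size^2`; e.g. `box_psf(5)` is the 5x5 moving
#' average.
#'
#' @param size Kernel side length, >= 1.
#' @return A [psf()].
#' @export
box_psf <- function(size) {
  size <- as.integer(size)
  if (size < 1L) stop("box_psf: size must be >= 1")
  psf(matrix(1, size, size))
}

#' Linear-motion point-spread function
#'
#' Approximates the blur from a camera translating by `length` pixels at
#' `angle_degrees` counter-clockwise from the horizontal axis.  The segment
#' of that length through the kernel center is rasterized with anti-aliased
#' (linear sub-pixel coverage) weights and normalized to sum one.
#'
#' @param length Motion extent in pixels, >= 1.
#' @param angle_degrees Motion direction, counter-clockwise, in degrees.
#' @return A [psf()].
#' @examples
#' motion_psf(2, 45)
#' @export
motion_psf <- function(length, angle_degrees) {
  if (!is.finite(length) || length < 1) stop("motion_psf: length must be >= 1")
  half <- (length - 1) / 2
  theta <- angle_degrees * pi / 180
  # image rows increase downward, so a counter-clockwise angle has dy = -sin
  ex <- half * cos(theta)
  ey <- -half * sin(theta)
  m <- max(1L, ceiling(abs(c(ex, ey)) + 0.5))
  off <- seq(-m, m)
  k <- matrix(0, length(off), length(off))
  for (i in seq_along(off)) {
    for (j in seq_along(off)) {
      # distance from pixel center to the closed segment [-e, e]
      px <- off[j]; py <- off[i]
      if (half > 0) {
        t <- max(-1, min(1, (px * ex + py * ey) / (ex^2 + ey^2)))
      } else t <- 0
      d <- sqrt((px - t * ex)^2 + (py - t * ey)^2)
      k[i, j] <- max(0, 1 - d)
    }
  }
  # trim all-zero border rows/cols while keeping the center cell
  nz_r <- range(which(rowSums(k) > 0)); nz_c <- range(which(colSums(k) > 0))
  c0 <- m + 1L
  nz_r <- c(min(nz_r[1], c0), max(nz_r[2], c0))
  nz_c <- c(min(nz_c[1], c0), max(nz_c[2], c0))
  k <- k[nz_r[1]:nz_r[2], nz_c[1]:nz_c[2], drop = FALSE]
  psf(k, anchor = c(c0 - nz_r[1] + 1L, c0 - nz_c[1] + 1L))
}

#' Blur operator K for a fixed image shape
#'
#' Realizes convolution with a [psf()] and its exact adjoint on `shape`-sized
#' images.  Under `"periodic"` boundaries the operator is circular
#' convolution, applied in the frequency domain through the precomputed
#' transfer function (the DFT of the zero-padded, anchor-shifted kernel);
#' the adjoint uses the conjugate transfer.  Under `"symmetric"` boundaries
#' the convolution replicates edge values and the adjoint is the exact
#' matrix transpose of that operation.
#'
#' @param psf A [psf()] (or matrix, passed to [psf()]).
#' @param shape Integer pair `(height, width)` of the target images.
#' @param bc Boundary convention.
#' @return An object of class `blur_operator` with fields `psf`, `shape`,
#'   `bc`, and (periodic only) `transfer`.
#' @examples
#' K <- blur_operator(gaussian_psf(5, 2), c(32, 32))
#' u <- matrix(runif(32 * 32), 32, 32)
#' all.equal(sum(apply_blur(K, u)), sum(u))
#' @export
blur_operator <- function(psf, shape, bc = c("periodic", "symmetric")) {
  bc <- match_bc(bc)
  if (is.matrix(psf)) psf <- psf(psf)
  stopifnot(inherits(psf, "psf"), length(shape) == 2)
  shape <- as.integer(shape)
  k <- psf$kernel
  if (any(dim(k) > shape)) stop("blur_operator: kernel larger than image")
  transfer <- NULL
  if (bc == "periodic") {
    big <- matrix(0, shape[1], shape[2])
    ri <- ((seq_len(nrow(k)) - psf$anchor[1]) %% shape[1]) + 1L
    ci <- ((seq_len(ncol(k)) - psf$anchor[2]) %% shape[2]) + 1L
    big[ri, ci] <- k
    transfer <- stats::fft(big)
  }
  structure(list(psf = psf, shape = shape, bc = bc, transfer = transfer),
            class = "blur_operator")
}

blur_spatial <- function(Kop, u, adjoint = FALSE) {
  k <- Kop$psf$kernel
  a <- Kop$psf$anchor
  out <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      sr <- i - a[1]; sc <- j - a[2]
      # K u = sum_o k_o u(. - o); its transpose accumulates the shifts back
      term <- if (!adjoint) {
        shift_rows(shift_cols(u, -sc, Kop$bc), -sr, Kop$bc)
      } else {
        shift_rows_t(shift_cols_t(u, -sc, Kop$bc), -sr, Kop$bc)
      }
      out <- out + k[i, j] * term
    }
  }
  out
}

#' Apply a blur operator or its adjoint
#'
#' `apply_blur()` computes `K u`; `apply_blur_adjoint()` computes `K^T u`.
#' The pair satisfies the adjoint identity
#' \eqn{\langle Ku, v\rangle = \langle u, K^T v\rangle} to round-off.
#'
#' @param Kop A [blur_operator()].
#' @param u Numeric matrix matching the operator's shape.
#' @return Numeric matrix.
#' @export
apply_blur <- function(Kop, u) {
  stopifnot(inherits(Kop, "blur_operator"))
  if (!identical(dim(u), as.integer(Kop$shape))) stop("apply_blur: shape mismatch")
  if (Kop$bc == "periodic") return(ifft2_re(stats::fft(u) * Kop$transfer))
  blur_spatial(Kop, u)
}

#' @rdname apply_blur
#' @export
apply_blur_adjoint <- function(Kop, u) {
  stopifnot(inherits(Kop, "blur_operator"))
  if (!identical(dim(u), as.integer(Kop$shape))) stop("apply_blur_adjoint: shape mismatch")
  if (Kop$bc == "periodic") return(ifft2_re(stats::fft(u) * Conj(Kop$transfer)))
  blur_spatial(Kop, u, adjoint = TRUE)
}

#' Read or write a PSF kernel as a plain-text matrix
#'
#' Whitespace-separated full-precision values, one kernel row per line.  The
#' anchor is taken to be the central cell on read.
#'
#' @param p A [psf()].
#' @param path File path.
#' @return `read_psf_txt()` returns a [psf()]; `write_psf_txt()` returns the
#'   path invisibly.
#' @export
write_psf_txt <- function(p, path) {
  stopifnot(inherits(p, "psf"))
  lines <- apply(p$kernel, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_psf_txt
#' @export
read_psf_txt <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  k <- do.call(rbind, lapply(rows, as.numeric))
  psf(k, normalize = FALSE)
}

#' Parse a PSF command-line descriptor
#'
#' Accepts `"gaussian:SIZE,SIGMA"`, `"box:SIZE"`, `"motion:LENGTH,ANGLE"` or
#' `"file:PATH"` (plain-text kernel).
#'
#' @param spec Character descriptor.
#' @return A [psf()].
#' @examples
#' parse_psf_spec("gaussian:5,2")
#' @export
parse_psf_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("psf spec must look like 'gaussian:5,2', 'box:5', 'motion:2,45' or 'file:<path>'")
  kind <- parts[1]
  if (kind == "file") return(read_psf_txt(parts[2]))
  args <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  switch(kind,
    gaussian = gaussian_psf(args[1], args[2]),
    box      = box_psf(args[1]),
    motion   = motion_psf(args[1], args[2]),
    stop("unknown psf kind: ", kind)
  )
}
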