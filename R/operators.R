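# Discrete first-order differential operators and exact adjoints.
#
# D1 = forward difference along columns (horizontal / x),
# D2 = forward difference along rows (vertical / y).
# div, sym_div are *defined* as the negative adjoints of grad, sym_grad under
# the Euclidean pairing (off-diagonal tensor plane counted twice), so the
# adjoint identities hold to round-off for both boundary conventions.

match_bc <- function(bc) match.arg(bc, c("periodic", "symmetric"))

# shift a matrix so that out[i, j] = u[i, j + s] (columns) under the bc
shift_cols <- function(u, s, bc) {
  w <- ncol(u)
  idx <- seq_len(w) + s
  if (bc == "periodic") idx <- ((idx - 1) %% w) + 1 else idx <- pmin(pmax(idx, 1L), w)
  u[, idx, drop = FALSE]
}

shift_rows <- function(u, s, bc) {
  h <- nrow(u)
  idx <- seq_len(h) + s
  if (bc == "periodic") idx <- ((idx - 1) %% h) + 1 else idx <- pmin(pmax(idx, 1L), h)
  u[idx, , drop = FALSE]
}

# transpose of shift_cols(., s, bc): accumulation onto clamped targets
shift_cols_t <- function(u, s, bc) {
  w <- ncol(u)
  if (bc == "periodic") return(shift_cols(u, -s, bc))
  idx <- pmin(pmax(seq_len(w) + s, 1L), w)
  out <- matrix(0, nrow(u), w)
  for (j in seq_len(w)) out[, idx[j]] <- out[, idx[j]] + u[, j]
  out
}

shift_rows_t <- function(u, s, bc) {
  h <- nrow(u)
  if (bc == "periodic") return(shift_rows(u, -s, bc))
  idx <- pmin(pmax(seq_len(h) + s, 1L), h)
  out <- matrix(0, h, ncol(u))
  for (i in seq_len(h)) out[idx[i], ] <- out[idx[i], ] + u[i, ]
  out
}

d1_fwd <- function(u, bc) shift_cols(u, 1L, bc) - u
d2_fwd <- function(u, bc) shift_rows(u, 1L, bc) - u
d1_adj <- function(u, bc) shift_cols_t(u, 1L, bc) - u  # D1^T
d2_adj <- function(u, bc) shift_rows_t(u, 1L, bc) - u  # D2^T

check_image <- function(u, arg = "u") {
  if (!is.matrix(u) || !is.numeric(u)) stop(arg, " must be a numeric matrix")
  if (!all(is.finite(u))) stop(arg, " must be finite")
  if (nrow(u) < 2 && ncol(u) < 2)
    stop("degenerate input: image must have at least 2 pixels along one dimension")
  invisible(u)
}

#' Discrete gradient of an image
#'
#' Forward finite differences: `comp1` differences along columns (horizontal),
#' `comp2` along rows (vertical).  Under `"periodic"` boundaries the last
#' difference wraps around; under `"symmetric"` the edge value is replicated,
#' so the last difference is zero.
#'
#' @param u Numeric matrix (the image).
#' @param bc Boundary convention, `"periodic"` (default) or `"symmetric"`.
#' @return A [vector_field()].
#' @examples
#' u <- matrix(c(0, 1, 3, 0), 1, 4)
#' grad(u)$comp1   # 1, 2, -3, 0 (wraps)
#' @export
grad <- function(u, bc = c("periodic", "symmetric")) {
  bc <- match_bc(bc)
  check_image(u)
  vector_field(d1_fwd(u, bc), d2_fwd(u, bc))
}

#' Discrete divergence of a vector field
#'
#' Defined as the exact negative adjoint of [grad()]:
#' \eqn{\langle \nabla u, v\rangle = -\langle u, \mathrm{div}\, v\rangle}
#' holds to round-off.  Under periodic boundaries this is the backward
#' difference stencil, and `divergence(grad(u))` is the 5-point Laplacian.
#'
#' @param v A [vector_field()].
#' @inheritParams grad
#' @return Numeric matrix.
#' @export
divergence <- function(v, bc = c("periodic", "symmetric")) {
  bc <- match_bc(bc)
  stopifnot(inherits(v, "vector_field"))
  -(d1_adj(v$comp1, bc) + d2_adj(v$comp2, bc))
}

#' Symmetrized gradient of a vector field
#'
#' The symmetric part of the Jacobian of `p`, stored as three planes:
#' `t11 = D1 p1`, `t22 = D2 p2`, `t12 = (D2 p1 + D1 p2) / 2`, with the same
#' difference stencils as [grad()].
#'
#' @param p A [vector_field()].
#' @inheritParams grad
#' @return A [sym_tensor_field()].
#' @export
sym_grad <- function(p, bc = c("periodic", "symmetric")) {
  bc <- match_bc(bc)
  stopifnot(inherits(p, "vector_field"))
  sym_tensor_field(d1_fwd(p$comp1, bc),
                   d2_fwd(p$comp2, bc),
                   0.5 * (d2_fwd(p$comp1, bc) + d1_fwd(p$comp2, bc)))
}

#' Divergence of a symmetric tensor field
#'
#' The exact negative adjoint of [sym_grad()] under the pairing in which the
#' off-diagonal plane is counted twice (it represents two equal entries of
#' the 2x2 tensor):
#' \eqn{\langle \varepsilon(p), y\rangle = -\langle p, \mathrm{sym\_div}\, y\rangle}.
#'
#' @param y A [sym_tensor_field()].
#' @inheritParams grad
#' @return A [vector_field()].
#' @export
sym_div <- function(y, bc = c("periodic", "symmetric")) {
  bc <- match_bc(bc)
  stopifnot(inherits(y, "sym_tensor_field"))
  vector_field(-(d1_adj(y$t11, bc) + d2_adj(y$t12, bc)),
               -(d2_adj(y$t22, bc) + d1_adj(y$t12, bc)))
}

# Frequency-domain symbols of D1, D2 under periodic boundaries, computed from
# impulse responses so the spatial and spectral paths agree exactly.
diff_symbols <- function(h, w) {
  delta <- matrix(0, h, w)
  delta[1, 1] <- 1
  list(d1 = stats::fft(d1_fwd(delta, "periodic")),
       d2 = stats::fft(d2_fwd(delta, "periodic")))
}

fft2 <- function(u) stats::fft(u)

ifft2_re <- function(U) Re(stats::fft(U, inverse = TRUE)) / length(U)
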