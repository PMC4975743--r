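#' Per-pixel 2-vector field
#'
#' A pair of H x W matrices holding the x- and y-components of a vector
#' attached to every pixel.  Used for the auxiliary field `p` of the TGV2
#' regularizer, the split variable `x` and the multiplier `b2`.
#'
#' @param comp1 Numeric matrix; horizontal (x) component.
#' @param comp2 Numeric matrix of the same shape; vertical (y) component.
#' @return An object of class `vector_field`.
#' @examples
#' v <- vector_field(matrix(1, 4, 4), matrix(0, 4, 4))
#' vf_magnitude(v)[1, 1]
#' @export
vector_field <- function(comp1, comp2) {
  stopifnot(is.matrix(comp1), is.matrix(comp2))
  if (!identical(dim(comp1), dim(comp2)))
    stop("vector_field: components must share one shape")
  structure(list(comp1 = comp1, comp2 = comp2), class = "vector_field")
}

#' Per-pixel symmetric 2x2 tensor field
#'
#' Stores the symmetric matrix \eqn{[[t11, t12], [t12, t22]]} at every pixel
#' as three planes.  Because the off-diagonal entry appears twice in the full
#' tensor, inner products and norms over this type count the `t12` plane
#' twice; see [stf_inner()] and [stf_magnitude()].
#'
#' @param t11,t22,t12 Numeric matrices of one common shape: the two diagonal
#'   planes and the single off-diagonal plane.
#' @return An object of class `sym_tensor_field`.
#' @export
sym_tensor_field <- function(t11, t22, t12) {
  stopifnot(is.matrix(t11), is.matrix(t22), is.matrix(t12))
  if (!identical(dim(t11), dim(t22)) || !identical(dim(t11), dim(t12)))
    stop("sym_tensor_field: planes must share one shape")
  structure(list(t11 = t11, t22 = t22, t12 = t12), class = "sym_tensor_field")
}

zero_vf <- function(h, w) vector_field(matrix(0, h, w), matrix(0, h, w))

zero_stf <- function(h, w) sym_tensor_field(matrix(0, h, w), matrix(0, h, w), matrix(0, h, w))

#' @export
Ops.vector_field <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*")) stop("unsupported operation for vector_field")
  if (missing(e2)) return(vector_field(get(.Generic)(e1$comp1), get(.Generic)(e1$comp2)))
  g <- function(a, b) get(.Generic)(a, b)
  pick <- function(e, comp) if (inherits(e, "vector_field")) e[[comp]] else e
  vector_field(g(pick(e1, "comp1"), pick(e2, "comp1")),
               g(pick(e1, "comp2"), pick(e2, "comp2")))
}

#' @export
Ops.sym_tensor_field <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*")) stop("unsupported operation for sym_tensor_field")
  if (missing(e2)) return(sym_tensor_field(get(.Generic)(e1$t11), get(.Generic)(e1$t22),
                                           get(.Generic)(e1$t12)))
  g <- function(a, b) get(.Generic)(a, b)
  pick <- function(e, comp) if (inherits(e, "sym_tensor_field")) e[[comp]] else e
  sym_tensor_field(g(pick(e1, "t11"), pick(e2, "t11")),
                   g(pick(e1, "t22"), pick(e2, "t22")),
                   g(pick(e1, "t12"), pick(e2, "t12")))
}

#' Pointwise Euclidean magnitude of a vector field
#'
#' @param v A [vector_field()].
#' @return Matrix of \eqn{\sqrt{v_1^2 + v_2^2}}.
#' @export
vf_magnitude <- function(v) sqrt(v$comp1^2 + v$comp2^2)

#' Pointwise Frobenius magnitude of a symmetric tensor field
#'
#' The off-diagonal plane is counted twice because it stands for the two
#' equal off-diagonal entries of the full 2x2 tensor:
#' \eqn{\sqrt{t_{11}^2 + t_{22}^2 + 2 t_{12}^2}}.
#'
#' @param s A [sym_tensor_field()].
#' @return Matrix of pointwise magnitudes.
#' @export
stf_magnitude <- function(s) sqrt(s$t11^2 + s$t22^2 + 2 * s$t12^2)

#' Inner products for images, vector fields and tensor fields
#'
#' `stf_inner()` weights the off-diagonal plane by two, so that the pairing
#' agrees with the Euclidean pairing of the full 2x2 tensors.
#'
#' @param a,b Two objects of matching type and shape.
#' @return A scalar.
#' @export
img_inner <- function(a, b) sum(a * b)

#' @rdname img_inner
#' @export
vf_inner <- function(a, b) sum(a$comp1 * b$comp1 + a$comp2 * b$comp2)

#' @rdname img_inner
#' @export
stf_inner <- function(a, b) sum(a$t11 * b$t11 + a$t22 * b$t22 + 2 * a$t12 * b$t12)

#' L1 norms of the pointwise magnitude
#'
#' `vf_l1()` sums the per-pixel Euclidean magnitude of a vector field;
#' `stf_l1()` sums the per-pixel Frobenius magnitude (off-diagonal counted
#' twice) of a tensor field.  These are the isotropic L1 norms appearing in
#' the TGV2 regularizer.
#'
#' @param v A [vector_field()].
#' @param s A [sym_tensor_field()].
#' @return A scalar.
#' @export
vf_l1 <- function(v) sum(vf_magnitude(v))

#' @rdname vf_l1
#' @export
stf_l1 <- function(s) sum(stf_magnitude(s))
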