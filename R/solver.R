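# Split Bregman solver for the TGV2 + L2 + Kullback-Leibler model.
#
# Multiplier convention used throughout: every augmented term is
# (rho/2) * || residual + b ||^2 with the dual update b <- b + residual.
# Under this convention the Poisson proximal step and the nonnegative
# projection take their textbook forms w = (a + sqrt(a^2 + 4 beta f / mu1))/2
# with a = K u + b1 - beta/mu1, and z = max(u + b4, 0); the multipliers enter
# the shrinkage arguments with a plus sign and the linear-solve right-hand
# sides with a minus sign.  The mirrored convention (b <- b - residual, minus
# signs swapped) generates the identical iterate sequence.

#' Solver parameters for [restore()]
#'
#' @param beta Weight of the Kullback-Leibler (Poisson) fidelity term, > 0.
#'   Scale-dependent: intensities are assumed on their native (e.g. 0-255)
#'   scale.
#' @param lam Weight of the quadratic \eqn{\|u\|_2^2/2} regularizer, >= 0.
#'   `lam = 0` gives the plain-TGV2 reduction of the model.
#' @param alpha0 TGV2 weight on the second-order term
#'   \eqn{\|\varepsilon(p)\|_1}, > 0.
#' @param alpha1 TGV2 weight on the first-order term
#'   \eqn{\|\nabla u - p\|_1}, > 0.
#' @param mu Positive penalty weights `(mu1, mu2, mu3, mu4)` of the four
#'   splitting constraints `Ku = w`, `grad u - p = x`, `sym_grad p = y`,
#'   `u = z`.
#' @param tol Stopping tolerance on the relative change
#'   \eqn{\|u^{k+1}-u^k\|_2 / \|u^k\|_2}.
#' @param max_iter Iteration cap.
#' @param bc Boundary convention; `"periodic"` enables the exact FFT solves.
#' @param inner_iters Sweeps of the coupled (u, p) Gauss-Seidel block per
#'   outer iteration (1 = single pass, matching the solver's cost profile).
#' @return An object of class `solver_params`.
#' @seealso [solver_preset()] for the published experiment settings.
#' @export
solver_params <- function(beta = 54, lam = 0.001, alpha0 = 16, alpha1 = 9,
                          mu = c(0.1, 0.6, 0.1, 0.02), tol = 1e-3,
                          max_iter = 300, bc = c("periodic", "symmetric"),
                          inner_iters = 1) {
  bc <- match_bc(bc)
  mu <- as.numeric(mu)
  if (length(mu) != 4 || any(!is.finite(mu)) || any(mu <= 0))
    stop("invalid parameter 'mu': need 4 positive penalty weights")
  chk <- function(x, nm, lo = 0, strict = TRUE) {
    if (length(x) != 1 || !is.finite(x) || (strict && x <= lo) || (!strict && x < lo))
      stop("invalid parameter '", nm, "': must be ", if (strict) "> " else ">= ", lo)
  }
  chk(beta, "beta"); chk(alpha0, "alpha0"); chk(alpha1, "alpha1")
  chk(lam, "lam", strict = FALSE); chk(tol, "tol")
  if (max_iter < 1) stop("invalid parameter 'max_iter': must be >= 1")
  structure(list(beta = beta, lam = lam, alpha0 = alpha0, alpha1 = alpha1,
                 mu1 = mu[1], mu2 = mu[2], mu3 = mu[3], mu4 = mu[4],
                 tol = tol, max_iter = as.integer(max_iter), bc = bc,
                 inner_iters = as.integer(inner_iters)),
            class = "solver_params")
}

#' @export
print.solver_params <- function(x, ...) {
  cat(sprintf(paste0("solver_params: beta=%g lam=%g alpha0=%g alpha1=%g ",
                     "mu=(%g, %g, %g, %g) tol=%g max_iter=%d bc=%s\n"),
              x$beta, x$lam, x$alpha0, x$alpha1, x$mu1, x$mu2, x$mu3, x$mu4,
              x$tol, x$max_iter, x$bc))
  invisible(x)
}

#' Published parameter presets
#'
#' `"test1"` (Gaussian blur experiment): beta = 54, lambda = 0.001,
#' alpha = (alpha0 16, alpha1 9).  `"test2"` and `"test3"` (box and motion
#' blur experiments): beta = 75, lambda = 1e-5, alpha = (17, 13).  All share
#' the penalty vector mu = (0.1, 0.6, 0.1, 0.02).  The bracketed alpha pairs
#' are read in the order (alpha0, alpha1), matching the weight-vector
#' ordering of the TGV definition; pass `alpha0`/`alpha1` explicitly to
#' override.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [solver_params()].
#' @return A [solver_params()].
#' @export
solver_preset <- function(name = c("test1", "test2", "test3"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    test1 = list(beta = 54, lam = 0.001, alpha0 = 16, alpha1 = 9),
    test2 = ,
    test3 = list(beta = 75, lam = 1e-5, alpha0 = 17, alpha1 = 13))
  do.call(solver_params, utils::modifyList(base, list(...)))
}

#' Model objective
#'
#' Evaluates
#' \deqn{\beta \sum_i [(Ku)_i - f_i \log(Ku)_i] + \frac{\lambda}{2}\|u\|_2^2
#'   + \alpha_1\|\nabla u - p\|_1 + \alpha_0\|\varepsilon(p)\|_1}
#' with the photon-counting conventions `0 log 0 = 0` and `log` of a
#' nonpositive value where `f > 0` giving `+Inf`.  Returns `+Inf` if `u` has
#' a negative entry (the nonnegativity indicator).
#'
#' @param u Candidate image (numeric matrix).
#' @param p Auxiliary [vector_field()] of the TGV2 regularizer.
#' @param f Observed degraded image.
#' @param K A [blur_operator()].
#' @param params A [solver_params()].
#' @return A scalar (possibly `Inf`).
#' @export
objective <- function(u, p, f, K, params) {
  stopifnot(identical(dim(u), dim(f)))
  if (any(u < 0)) return(Inf)
  Ku <- apply_blur(K, u)
  pos <- f > 0
  if (any(Ku[pos] <= 0)) return(Inf)
  kl <- sum(Ku) - sum(f[pos] * log(Ku[pos]))
  params$beta * kl + params$lam / 2 * sum(u^2) +
    params$alpha1 * vf_l1(grad(u, params$bc) - p) +
    params$alpha0 * stf_l1(sym_grad(p, params$bc))
}

#' Poisson proximal update for the fidelity split variable w
#'
#' Pointwise exact minimizer of
#' \eqn{\beta (w - f \log w) + \frac{\mu_1}{2} (w - (Ku + b_1))^2}:
#' the positive root
#' \eqn{w = \frac{1}{2}\left(a + \sqrt{a^2 + 4\beta f/\mu_1}\right)} with
#' \eqn{a = Ku + b_1 - \beta/\mu_1}.  Always nonnegative; strictly positive
#' wherever `f > 0`.
#'
#' @param Ku Blurred current image `K u`.
#' @param b1 Multiplier image.
#' @param f Observed image (nonnegative).
#' @param beta,mu1 Fidelity and penalty weights, > 0.
#' @return Numeric matrix `w`.
#' @export
update_w <- function(Ku, b1, f, beta, mu1) {
  a <- Ku + b1 - beta / mu1
  0.5 * (a + sqrt(a^2 + 4 * beta * f / mu1))
}

#' Isotropic soft-thresholding (shrinkage) of a vector field
#'
#' The proximal operator of `threshold * ||.||_1` (sum of pointwise Euclidean
#' magnitudes): each per-pixel 2-vector keeps its direction and has its
#' magnitude reduced by `threshold`, clamping at zero.
#'
#' @param v A [vector_field()].
#' @param threshold Positive scalar.
#' @return A [vector_field()].
#' @export
shrink_vec <- function(v, threshold) {
  stopifnot(threshold > 0)
  m <- vf_magnitude(v)
  fac <- ifelse(m > 0, pmax(m - threshold, 0) / m, 0)
  vector_field(fac * v$comp1, fac * v$comp2)
}

#' Isotropic soft-thresholding of a symmetric tensor field
#'
#' Proximal operator of `threshold * ||.||_1` with the pointwise magnitude
#' \eqn{\sqrt{t_{11}^2 + t_{22}^2 + 2 t_{12}^2}} (off-diagonal counted twice)
#' and the matching weighted quadratic term.
#'
#' @param s A [sym_tensor_field()].
#' @param threshold Positive scalar.
#' @return A [sym_tensor_field()].
#' @export
shrink_tensor <- function(s, threshold) {
  stopifnot(threshold > 0)
  m <- stf_magnitude(s)
  fac <- ifelse(m > 0, pmax(m - threshold, 0) / m, 0)
  sym_tensor_field(fac * s$t11, fac * s$t22, fac * s$t12)
}

#' Nonnegative projection update for the split variable z
#'
#' @param u Current image iterate.
#' @param b4 Multiplier image.
#' @return `pmax(u + b4, 0)`.
#' @export
update_z <- function(u, b4) pmax(u + b4, 0)

# --- linear solves -----------------------------------------------------------

# Frequency-domain machinery shared by solve_u / solve_p; built once per
# (shape, K, params) and reused across iterations.
solver_cache <- function(K, params) {
  h <- K$shape[1]; w <- K$shape[2]
  if (params$bc != "periodic" || K$bc != "periodic") return(list(bc = "symmetric"))
  sy <- diff_symbols(h, w)
  a1m2 <- params$alpha1 * params$mu2
  a0m3 <- params$alpha0 * params$mu3
  list(bc = "periodic", d1 = sy$d1, d2 = sy$d2,
       denom_u = params$lam + params$beta * params$mu1 * Mod(K$transfer)^2 +
         a1m2 * (Mod(sy$d1)^2 + Mod(sy$d2)^2) + params$mu4,
       denom_p1 = a1m2 + a0m3 * Mod(sy$d1)^2 + a0m3 / 2 * Mod(sy$d2)^2,
       denom_p2 = a1m2 + a0m3 * Mod(sy$d2)^2 + a0m3 / 2 * Mod(sy$d1)^2)
}

# conjugate gradient on an SPD operator given as a closure (symmetric-bc path)
cg_solve <- function(Aop, b, x0 = NULL, tol = 1e-10, maxit = 500) {
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - Aop(x)
  p <- r
  rs <- sum(r^2)
  b2 <- sum(b^2)
  if (b2 == 0) return(b * 0)
  for (i in seq_len(maxit)) {
    Ap <- Aop(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (rs_new <= tol^2 * b2) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Image subproblem solve
#'
#' Solves the normal equation of the u-subproblem,
#' \deqn{(\lambda I + \beta\mu_1 K^T K + \alpha_1\mu_2 \sum_j D_j^T D_j
#'   + \mu_4 I)\, u = \beta\mu_1 K^T(w - b_1)
#'   + \alpha_1\mu_2 \sum_j D_j^T(p_j + x_j - b_{2j}) + \mu_4 (z - b_4),}
#' exactly by frequency-domain division under periodic boundaries (the
#' system is diagonalized by the DFT and strictly positive definite because
#' \eqn{\lambda + \mu_4 > 0}), or by conjugate gradients under symmetric
#' boundaries.
#'
#' @param w,b1,z,b4 Images (numeric matrices): fidelity split variable and
#'   multiplier, nonnegativity split variable and multiplier.
#' @param p,x,b2 [vector_field()]s: TGV2 auxiliary field, gradient split
#'   variable and multiplier.
#' @param K A [blur_operator()].
#' @param params A [solver_params()].
#' @param cache Optional precomputed spectral cache (internal).
#' @return The updated image `u`.
#' @export
solve_u <- function(w, b1, p, x, b2, z, b4, K, params, cache = NULL) {
  if (is.null(cache)) cache <- solver_cache(K, params)
  bc <- params$bc
  a1m2 <- params$alpha1 * params$mu2
  bm1 <- params$beta * params$mu1
  q1 <- p$comp1 + x$comp1 - b2$comp1
  q2 <- p$comp2 + x$comp2 - b2$comp2
  rhs <- bm1 * apply_blur_adjoint(K, w - b1) +
    a1m2 * (d1_adj(q1, bc) + d2_adj(q2, bc)) +
    params$mu4 * (z - b4)
  if (!all(is.finite(rhs))) stop("solve_u: non-finite inputs")
  if (cache$bc == "periodic")
    return(ifft2_re(stats::fft(rhs) / cache$denom_u))
  Aop <- function(v) {
    params$lam * v + bm1 * apply_blur_adjoint(K, apply_blur(K, v)) +
      a1m2 * (d1_adj(d1_fwd(v, bc), bc) + d2_adj(d2_fwd(v, bc), bc)) +
      params$mu4 * v
  }
  cg_solve(Aop, rhs)
}

#' Auxiliary vector field subproblem solve
#'
#' One Gauss-Seidel pass over the two components of `p`: `p1` is solved from
#' its normal equation using the previous `p2`, then `p2` using the new
#' `p1`.  Each component system
#' \deqn{(\alpha_1\mu_2 I + \alpha_0\mu_3 D_i^T D_i
#'   + \tfrac{\alpha_0\mu_3}{2} D_j^T D_j)\, p_i = \mathrm{rhs}_i}
#' is solved exactly by FFT under periodic boundaries (conjugate gradients
#' otherwise).  The right-hand sides carry the doubled off-diagonal terms
#' `2 y3 - 2 b33` coming from the weighted tensor pairing.
#'
#' @param u Current image iterate.
#' @param x,b2 Gradient split variable and multiplier ([vector_field()]s).
#' @param y,b3 Tensor split variable and multiplier ([sym_tensor_field()]s).
#' @param p_prev Previous vector field iterate (supplies the lagged
#'   component).
#' @param params A [solver_params()].
#' @param cache Optional precomputed spectral cache (internal).
#' @return The updated [vector_field()] `p`.
#' @export
solve_p <- function(u, x, b2, y, b3, p_prev, params, cache = NULL) {
  bc <- params$bc
  if (is.null(cache)) {
    K0 <- structure(list(shape = dim(u), bc = bc,
                         transfer = matrix(1, nrow(u), ncol(u))),
                    class = "blur_operator")
    cache <- solver_cache(K0, params)
  }
  a1m2 <- params$alpha1 * params$mu2
  a0m3 <- params$alpha0 * params$mu3
  y3t <- 2 * (y$t12 - b3$t12)
  rhs1 <- a1m2 * (d1_fwd(u, bc) - x$comp1 + b2$comp1) +
    a0m3 * d1_adj(y$t11 - b3$t11, bc) +
    a0m3 / 2 * d2_adj(y3t - d1_fwd(p_prev$comp2, bc), bc)
  if (!all(is.finite(rhs1))) stop("solve_p: non-finite inputs")
  p1 <- if (cache$bc == "periodic") {
    ifft2_re(stats::fft(rhs1) / cache$denom_p1)
  } else {
    cg_solve(function(v) a1m2 * v + a0m3 * d1_adj(d1_fwd(v, bc), bc) +
               a0m3 / 2 * d2_adj(d2_fwd(v, bc), bc), rhs1)
  }
  rhs2 <- a1m2 * (d2_fwd(u, bc) - x$comp2 + b2$comp2) +
    a0m3 * d2_adj(y$t22 - b3$t22, bc) +
    a0m3 / 2 * d1_adj(y3t - d2_fwd(p1, bc), bc)
  p2 <- if (cache$bc == "periodic") {
    ifft2_re(stats::fft(rhs2) / cache$denom_p2)
  } else {
    cg_solve(function(v) a1m2 * v + a0m3 * d2_adj(d2_fwd(v, bc), bc) +
               a0m3 / 2 * d1_adj(d1_fwd(v, bc), bc), rhs2)
  }
  vector_field(p1, p2)
}

#' Bregman multiplier update
#'
#' Adds the current constraint residuals to the four multipliers:
#' `b1 += Ku - w`, `b2 += grad(u) - p - x`, `b3 += sym_grad(p) - y`,
#' `b4 += u - z`.  Starting from zero multipliers, one update equals the raw
#' residuals; at a fixed point (all residuals zero) the multipliers are
#' unchanged.
#'
#' @param state Solver state: a list with elements `u`, `p`, `w`, `x`, `y`,
#'   `z`, `b1`, `b2`, `b3`, `b4`.
#' @param Ku Precomputed `K u` for the current `u` (recomputed if `NULL`).
#' @param eps_p Precomputed `sym_grad(p)` (recomputed if `NULL`).
#' @param K A [blur_operator()] (needed when `Ku` is `NULL`).
#' @param params A [solver_params()].
#' @return The state with updated multipliers.
#' @export
update_multipliers <- function(state, Ku = NULL, eps_p = NULL, K = NULL,
                               params = solver_params()) {
  if (is.null(Ku)) Ku <- apply_blur(K, state$u)
  if (is.null(eps_p)) eps_p <- sym_grad(state$p, params$bc)
  state$b1 <- state$b1 + (Ku - state$w)
  state$b2 <- state$b2 + (grad(state$u, params$bc) - state$p - state$x)
  state$b3 <- state$b3 + (eps_p - state$y)
  state$b4 <- state$b4 + (state$u - state$z)
  state
}

#' Augmented Lagrangian value at a solver state
#'
#' Evaluates the augmented objective with frozen multipliers,
#' \deqn{\beta\sum(w - f\log w) + \frac{\lambda}{2}\|u\|^2 + \alpha_1\|x\|_1
#'  + \alpha_0\|y\|_1 + \iota_{\ge0}(z) + \sum_i \frac{\rho_i}{2}
#'  \|r_i + b_i\|^2,}
#' where the \eqn{r_i} are the four splitting residuals.  `weights = "prox"`
#' uses the penalties \eqn{(\mu_1, \mu_2, \mu_3, \mu_4)} under which the
#' proximal steps (w, x, y, z) are exact block minimizers; `"solve"` uses
#' \eqn{(\beta\mu_1, \alpha_1\mu_2, \alpha_0\mu_3, \mu_4)}, the weights of
#' the (u, p) normal equations.
#'
#' @param state Solver state list (see [update_multipliers()]).
#' @param f Observed image.
#' @param K A [blur_operator()].
#' @param params A [solver_params()].
#' @param weights `"prox"` or `"solve"`.
#' @return A scalar (possibly `Inf`).
#' @export
augmented_objective <- function(state, f, K, params,
                                weights = c("prox", "solve")) {
  weights <- match.arg(weights)
  rho <- with(params, switch(weights,
    prox = c(mu1, mu2, mu3, mu4),
    solve = c(beta * mu1, alpha1 * mu2, alpha0 * mu3, mu4)))
  s <- state
  if (any(s$z < 0)) return(Inf)
  pos <- f > 0
  if (any(s$w[pos] <= 0)) return(Inf)
  kl <- sum(s$w) - sum(f[pos] * log(s$w[pos]))
  r1 <- apply_blur(K, s$u) - s$w
  r2 <- grad(s$u, params$bc) - s$p - s$x
  r3 <- sym_grad(s$p, params$bc) - s$y
  r4 <- s$u - s$z
  params$beta * kl + params$lam / 2 * sum(s$u^2) +
    params$alpha1 * vf_l1(s$x) + params$alpha0 * stf_l1(s$y) +
    rho[1] / 2 * sum((r1 + s$b1)^2) +
    rho[2] / 2 * vf_inner(r2 + s$b2, r2 + s$b2) +
    rho[3] / 2 * stf_inner(r3 + s$b3, r3 + s$b3) +
    rho[4] / 2 * sum((r4 + s$b4)^2)
}

init_state <- function(f, params) {
  h <- nrow(f); w <- ncol(f)
  list(u = f, p = zero_vf(h, w), w = matrix(0, h, w), x = zero_vf(h, w),
       y = zero_stf(h, w), z = matrix(0, h, w), b1 = matrix(0, h, w),
       b2 = zero_vf(h, w), b3 = zero_stf(h, w), b4 = matrix(0, h, w))
}

# one full sweep in the order w -> x -> y -> (u, p) -> z; multipliers are NOT
# updated here so block-descent diagnostics can interleave
sweep_state <- function(state, f, K, params, cache) {
  s <- state
  Ku <- apply_blur(K, s$u)
  s$w <- update_w(Ku, s$b1, f, params$beta, params$mu1)
  gu <- grad(s$u, params$bc)
  s$x <- shrink_vec(gu - s$p + s$b2, params$alpha1 / params$mu2)
  s$y <- shrink_tensor(sym_grad(s$p, params$bc) + s$b3, params$alpha0 / params$mu3)
  for (it in seq_len(params$inner_iters)) {
    s$u <- solve_u(s$w, s$b1, s$p, s$x, s$b2, s$z, s$b4, K, params, cache)
    s$p <- solve_p(s$u, s$x, s$b2, s$y, s$b3, s$p, params, cache)
  }
  s$z <- update_z(s$u, s$b4)
  s
}

residual_norms <- function(state, f, K, params) {
  c(r1 = sqrt(sum((apply_blur(K, state$u) - state$w)^2)),
    r2 = {
      r <- grad(state$u, params$bc) - state$p - state$x
      sqrt(vf_inner(r, r))
    },
    r3 = {
      r <- sym_grad(state$p, params$bc) - state$y
      sqrt(stf_inner(r, r))
    },
    r4 = sqrt(sum((state$u - state$z)^2)))
}

#' Restore a Poisson-degraded image
#'
#' Runs the split Bregman iteration for the TGV2 + L2 + Kullback-Leibler
#' model: per outer iteration the sub-steps are taken in the order
#' `w` (Poisson proximal root), `x` (vector shrinkage), `y` (tensor
#' shrinkage), `(u, p)` (FFT-diagonalized linear solves), `z` (nonnegative
#' projection), then the four multiplier updates.  Iterates start from
#' `u = f` (warm start; the observed image) with all auxiliary variables and
#' multipliers at zero.  Iteration stops when the relative change
#' \eqn{\|u^{k+1}-u^k\|_2 / \|u^k\|_2} falls below `tol` (the test is
#' skipped for the first two iterations) or at `max_iter`.  The returned
#' image is projected onto the nonnegative orthant.
#'
#' @param f Observed degraded image: a nonnegative numeric matrix.
#' @param K A [blur_operator()] matching `dim(f)` (a [psf()] is promoted
#'   using the parameter boundary convention).
#' @param params A [solver_params()].
#' @param verbose Print per-iteration diagnostics every `verbose` iterations
#'   (0 = silent).
#' @return An object of class `restoration_result`: a list with the restored
#'   image `u` (nonnegative), `iterations`, `converged`, the final `params`,
#'   and `history`, a data frame with per-iteration relative change,
#'   objective value and the four constraint residual norms.
#' @examples
#' u <- make_phantom(48, 48, "ramp_disks", seed = 1)
#' K <- blur_operator(gaussian_psf(5, 2), dim(u))
#' f <- degrade(u, K, seed = 1)
#' res <- restore(f, K, solver_preset("test1", max_iter = 40))
#' psnr(u, res$u) > psnr(u, f)
#' @export
restore <- function(f, K, params = solver_params(), verbose = 0) {
  if (!is.matrix(f) || !all(is.finite(f))) stop("f must be a finite numeric matrix")
  if (any(f < 0)) stop("f must be nonnegative (photon counts)")
  if (inherits(K, "psf") || is.matrix(K)) K <- blur_operator(K, dim(f), params$bc)
  if (!identical(as.integer(K$shape), dim(f))) stop("operator/image shape mismatch")
  cache <- solver_cache(K, params)
  s <- init_state(f, params)
  hist <- vector("list", params$max_iter)
  converged <- FALSE
  iter <- 0L
  for (k in seq_len(params$max_iter)) {
    u_prev <- s$u
    s <- sweep_state(s, f, K, params, cache)
    s <- update_multipliers(s, Ku = apply_blur(K, s$u),
                            eps_p = sym_grad(s$p, params$bc), params = params)
    rel <- sqrt(sum((s$u - u_prev)^2)) / max(sqrt(sum(u_prev^2)), .Machine$double.eps)
    rn <- residual_norms(s, f, K, params)
    obj <- objective(pmax(s$u, 0), s$p, f, K, params)
    hist[[k]] <- c(iteration = k, rel_change = rel, objective = obj, rn)
    iter <- k
    if (verbose > 0 && k %% verbose == 0)
      message(sprintf("iter %4d  rel %.3e  obj %.6e  max-res %.3e",
                      k, rel, obj, max(rn)))
    if (k > 2 && rel <= params$tol) { converged <- TRUE; break }
  }
  history <- as.data.frame(do.call(rbind, hist[seq_len(iter)]))
  structure(list(u = pmax(s$u, 0), iterations = iter, converged = converged,
                 params = params, history = history, state = s),
            class = "restoration_result")
}

#' @export
print.restoration_result <- function(x, ...) {
  cat(sprintf("restoration_result: %dx%d image, %d iteration%s, %s\n",
              nrow(x$u), ncol(x$u), x$iterations,
              if (x$iterations == 1) "" else "s",
              if (x$converged) sprintf("converged (rel change %.2e <= tol %.2e)",
                                       utils::tail(x$history$rel_change, 1),
                                       x$params$tol)
              else "max_iter reached"))
  invisible(x)
}

#' Plain-TGV2 restoration (no quadratic term)
#'
#' The model reduction with `lam = 0`: the quadratic regularizer is absent
#' from the objective and from the u-solve.  Identical to calling
#' [restore()] with `lam = 0`.
#'
#' @inheritParams restore
#' @param ... Overrides forwarded to the parameter constructor.
#' @return A `restoration_result`.
#' @export
restore_tgv <- function(f, K, params = solver_params(), ...) {
  params$lam <- 0
  restore(f, K, params, ...)
}

#' Approximate TGV2 value of an image
#'
#' Evaluates \eqn{\min_p \alpha_1 \|\nabla u - p\|_1 +
#' \alpha_0\|\varepsilon(p)\|_1} by running the solver's own splitting
#' (shrinkage steps plus FFT p-solves) with the image held fixed.
#'
#' @param u Image (numeric matrix).
#' @param alpha0,alpha1 TGV2 weights.
#' @param iters Number of alternating iterations.
#' @param params Optional [solver_params()] supplying `mu2`, `mu3` and the
#'   boundary convention.
#' @return List with the TGV2 `value` and the minimizing field `p`.
#' @export
tgv2_value <- function(u, alpha0 = 2, alpha1 = 1, iters = 60,
                       params = solver_params(alpha0 = alpha0, alpha1 = alpha1)) {
  params$alpha0 <- alpha0; params$alpha1 <- alpha1
  h <- nrow(u); w <- ncol(u)
  K0 <- structure(list(shape = dim(u), bc = params$bc,
                       transfer = matrix(1, h, w)), class = "blur_operator")
  cache <- solver_cache(K0, params)
  p <- zero_vf(h, w); x <- zero_vf(h, w); y <- zero_stf(h, w)
  b2 <- zero_vf(h, w); b3 <- zero_stf(h, w)
  gu <- grad(u, params$bc)
  for (k in seq_len(iters)) {
    x <- shrink_vec(gu - p + b2, params$alpha1 / params$mu2)
    y <- shrink_tensor(sym_grad(p, params$bc) + b3, params$alpha0 / params$mu3)
    p <- solve_p(u, x, b2, y, b3, p, params, cache)
    b2 <- b2 + (gu - p - x)
    b3 <- b3 + (sym_grad(p, params$bc) - y)
  }
  list(value = alpha1 * vf_l1(gu - p) + alpha0 * stf_l1(sym_grad(p, params$bc)),
       p = p)
}
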