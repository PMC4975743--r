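test_that("solver_params validates and presets carry the published settings", {
  p <- solver_preset("test1")
  expect_equal(c(p$beta, p$lam, p$alpha0, p$alpha1), c(54, 0.001, 16, 9))
  p2 <- solver_preset("test2")
  expect_equal(c(p2$beta, p2$lam, p2$alpha0, p2$alpha1), c(75, 1e-5, 17, 13))
  expect_equal(solver_preset("test3")$beta, 75)
  expect_equal(c(p$mu1, p$mu2, p$mu3, p$mu4), c(0.1, 0.6, 0.1, 0.02))
  expect_equal(p$tol, 1e-3)
  expect_error(solver_params(beta = -1), "beta")
  expect_error(solver_params(mu = c(1, 2, 3)), "mu")
  expect_error(solver_params(tol = 0), "tol")
  expect_silent(solver_params(lam = 0))
})

test_that("update_w solves the pointwise Poisson proximal problem", {
  # golden closed-form value: a = 1, beta/mu1 = 1, f = 1 gives (1+sqrt(5))/2
  w <- update_w(Ku = matrix(2), b1 = matrix(0), f = matrix(1), beta = 1, mu1 = 1)
  expect_equal(w[1, 1], (1 + sqrt(5)) / 2, tolerance = 1e-12)
  # ... which zeroes the 1-D optimality condition beta(1 - f/w) + mu1(w - c)
  expect_equal(1 * (1 - 1 / w[1, 1]) + 1 * (w[1, 1] - 2), 0, tolerance = 1e-12)

  # f = 0 and a <= 0 collapse to zero
  w0 <- update_w(matrix(0.5, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                 beta = 10, mu1 = 1)
  expect_equal(w0, matrix(0, 2, 2))

  # against an independent root-finding oracle on random pixels
  withr::with_seed(42, {
    for (i in 1:25) {
      cc <- stats::rnorm(1, 0, 30)
      f1 <- stats::rpois(1, 40)
      beta <- stats::runif(1, 1, 100)
      mu1 <- stats::runif(1, 0.01, 1)
      w <- update_w(matrix(cc), matrix(0), matrix(f1), beta, mu1)[1, 1]
      if (f1 > 0) {
        oracle <- stats::uniroot(function(x) beta * (1 - f1 / x) + mu1 * (x - cc),
                                 c(1e-12, abs(cc) + beta / mu1 + f1 + 10),
                                 tol = 1e-12)$root
      } else {
        oracle <- max(cc - beta / mu1, 0)
      }
      expect_equal(w, oracle, tolerance = 1e-8)
      expect_gte(w, 0)
    }
  })
})

test_that("shrink_vec is the proximal map of the isotropic vector L1 norm", {
  # magnitude-5 vectors shrink to magnitude 2 keeping direction
  v <- vector_field(matrix(3, 4, 4), matrix(4, 4, 4))
  s <- shrink_vec(v, 3)
  expect_equal(vf_magnitude(s), matrix(2, 4, 4))
  expect_equal(s$comp1 / s$comp2, v$comp1 / v$comp2)

  # zero input and sub-threshold input give zero
  z <- vector_field(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(shrink_vec(z, 1), z)
  small <- vector_field(matrix(0.1, 3, 3), matrix(0.1, 3, 3))
  expect_equal(vf_magnitude(shrink_vec(small, 5)), matrix(0, 3, 3))

  # numerical prox oracle per pixel
  withr::with_seed(7, {
    for (i in 1:15) {
      s0 <- stats::rnorm(2, 0, 2)
      t <- stats::runif(1, 0.2, 2)
      obj <- function(x) t * sqrt(sum(x^2)) + 0.5 * sum((x - s0)^2)
      cand <- rbind(c(0, 0), stats::optim(s0, obj, method = "Nelder-Mead",
                                          control = list(reltol = 1e-14))$par)
      num <- cand[which.min(apply(cand, 1, obj)), ]
      ours <- shrink_vec(vector_field(matrix(s0[1]), matrix(s0[2])), t)
      ours <- c(ours$comp1[1, 1], ours$comp2[1, 1])
      expect_lte(obj(ours), obj(num) + 1e-8)
      if (sqrt(sum(num^2)) > 1e-5) expect_equal(ours, num, tolerance = 1e-5)
    }
  })
})

test_that("shrink_tensor is the prox under the doubled off-diagonal magnitude", {
  z <- sym_tensor_field(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(shrink_tensor(z, 1), z)

  # diagonal-only tensor reduces to scalar shrinkage
  s <- shrink_tensor(sym_tensor_field(matrix(3), matrix(0), matrix(0)), 1)
  expect_equal(s$t11[1, 1], 2)
  expect_equal(s$t22[1, 1], 0)
  expect_equal(s$t12[1, 1], 0)

  # numerical prox oracle with the weighted inner product
  withr::with_seed(8, {
    for (i in 1:15) {
      s0 <- stats::rnorm(3, 0, 2)
      t <- stats::runif(1, 0.2, 2)
      obj <- function(x) t * sqrt(x[1]^2 + x[2]^2 + 2 * x[3]^2) +
        0.5 * ((x[1] - s0[1])^2 + (x[2] - s0[2])^2 + 2 * (x[3] - s0[3])^2)
      cand <- rbind(c(0, 0, 0), stats::optim(s0, obj, method = "Nelder-Mead",
                                             control = list(reltol = 1e-14))$par)
      num <- cand[which.min(apply(cand, 1, obj)), ]
      ours <- shrink_tensor(sym_tensor_field(matrix(s0[1]), matrix(s0[2]),
                                             matrix(s0[3])), t)
      ours <- c(ours$t11[1, 1], ours$t22[1, 1], ours$t12[1, 1])
      expect_lte(obj(ours), obj(num) + 1e-8)
      if (sqrt(sum(num^2)) > 1e-5) expect_equal(ours, num, tolerance = 1e-4)
    }
  })
})

test_that("update_z is the pointwise nonnegative projection", {
  expect_equal(update_z(matrix(-3, 2, 2), matrix(1, 2, 2)), matrix(0, 2, 2))
  expect_equal(update_z(matrix(3, 2, 2), matrix(1, 2, 2)), matrix(4, 2, 2))
  m <- matrix(c(-1, 2, -3, 4), 2, 2)
  expect_equal(update_z(m, matrix(0, 2, 2)), pmax(m, 0))
})

test_that("solve_u matches the dense normal-equation solve", {
  params <- solver_preset("test1")
  h <- 8; w <- 8; n <- h * w
  K <- blur_operator(gaussian_psf(3, 1), c(h, w))

  # constant problem with identity blur: closed scalar form
  Ki <- blur_operator(box_psf(1), c(h, w))
  wv <- matrix(2, h, w); z <- matrix(1.5, h, w)
  zvf <- vector_field(matrix(0, h, w), matrix(0, h, w))
  u <- solve_u(wv, matrix(0, h, w), zvf, zvf, zvf, z, matrix(0, h, w), Ki, params)
  scal <- with(params, (beta * mu1 * 2 + mu4 * 1.5) / (lam + beta * mu1 + mu4))
  expect_equal(u, matrix(scal, h, w), tolerance = 1e-10)

  # dense oracle on a random 8x8 problem
  D1 <- dense_op(function(m) tgvpois:::d1_fwd(m, "periodic"), h, w)
  D2 <- dense_op(function(m) tgvpois:::d2_fwd(m, "periodic"), h, w)
  KM <- dense_op(function(m) apply_blur(K, m), h, w)
  wv <- abs(rand_img(1)); b1 <- rand_img(2) * 0.1
  p <- rand_vf(3); x <- rand_vf(5); b2 <- rand_vf(7) * 0.1
  z <- abs(rand_img(8)); b4 <- rand_img(9) * 0.1
  A <- with(params, lam * diag(n) + beta * mu1 * t(KM) %*% KM +
              alpha1 * mu2 * (t(D1) %*% D1 + t(D2) %*% D2) + mu4 * diag(n))
  rhs <- with(params, beta * mu1 * t(KM) %*% as.vector(wv - b1) +
                alpha1 * mu2 * (t(D1) %*% as.vector(p$comp1 + x$comp1 - b2$comp1) +
                                  t(D2) %*% as.vector(p$comp2 + x$comp2 - b2$comp2)) +
                mu4 * as.vector(z - b4))
  ud <- solve(A, rhs)
  uf <- solve_u(wv, b1, p, x, b2, z, b4, K, params)
  expect_lt(max(abs(as.vector(uf) - ud)) / max(abs(ud)), 1e-8)
  # normal-equation residual at the returned iterate
  expect_lt(max(abs(A %*% as.vector(uf) - rhs)) / max(abs(rhs)), 1e-8)

  # conjugate-gradient path (symmetric bc) against its own dense system
  ps <- solver_preset("test1", bc = "symmetric")
  Ks <- blur_operator(gaussian_psf(3, 1), c(h, w), bc = "symmetric")
  D1s <- dense_op(function(m) tgvpois:::d1_fwd(m, "symmetric"), h, w)
  D2s <- dense_op(function(m) tgvpois:::d2_fwd(m, "symmetric"), h, w)
  KMs <- dense_op(function(m) apply_blur(Ks, m), h, w)
  As <- with(ps, lam * diag(n) + beta * mu1 * t(KMs) %*% KMs +
               alpha1 * mu2 * (t(D1s) %*% D1s + t(D2s) %*% D2s) + mu4 * diag(n))
  rhss <- with(ps, beta * mu1 * t(KMs) %*% as.vector(wv - b1) +
                 alpha1 * mu2 * (t(D1s) %*% as.vector(p$comp1 + x$comp1 - b2$comp1) +
                                   t(D2s) %*% as.vector(p$comp2 + x$comp2 - b2$comp2)) +
                 mu4 * as.vector(z - b4))
  us <- solve_u(wv, b1, p, x, b2, z, b4, Ks, ps)
  expect_lt(max(abs(as.vector(us) - solve(As, rhss))) / max(abs(rhss)), 1e-6)
})

test_that("solve_p matches the dense Gauss-Seidel component solves", {
  params <- solver_preset("test1")
  h <- 8; w <- 8; n <- h * w

  # zero right-hand side gives the zero field
  zv <- vector_field(matrix(0, h, w), matrix(0, h, w))
  zt <- sym_tensor_field(matrix(0, h, w), matrix(0, h, w), matrix(0, h, w))
  p0 <- solve_p(matrix(1, h, w), zv, zv, zt, zt, zv, params)
  expect_equal(vf_magnitude(p0), matrix(0, h, w), tolerance = 1e-12)

  D1 <- dense_op(function(m) tgvpois:::d1_fwd(m, "periodic"), h, w)
  D2 <- dense_op(function(m) tgvpois:::d2_fwd(m, "periodic"), h, w)
  u <- rand_img(11); x <- rand_vf(12); b2 <- rand_vf(13) * 0.1
  y <- rand_stf(14); b3 <- rand_stf(15) * 0.1; pprev <- rand_vf(16)
  a1m2 <- params$alpha1 * params$mu2; a0m3 <- params$alpha0 * params$mu3
  y3t <- 2 * as.vector(y$t12 - b3$t12)
  A1 <- a1m2 * diag(n) + a0m3 * t(D1) %*% D1 + a0m3 / 2 * t(D2) %*% D2
  r1 <- a1m2 * as.vector(tgvpois:::d1_fwd(u, "periodic") - x$comp1 + b2$comp1) +
    a0m3 * t(D1) %*% as.vector(y$t11 - b3$t11) +
    a0m3 / 2 * t(D2) %*% (y3t - as.vector(tgvpois:::d1_fwd(pprev$comp2, "periodic")))
  p1d <- solve(A1, r1)
  A2 <- a1m2 * diag(n) + a0m3 * t(D2) %*% D2 + a0m3 / 2 * t(D1) %*% D1
  r2 <- a1m2 * as.vector(tgvpois:::d2_fwd(u, "periodic") - x$comp2 + b2$comp2) +
    a0m3 * t(D2) %*% as.vector(y$t22 - b3$t22) +
    a0m3 / 2 * t(D1) %*% (y3t - as.vector(tgvpois:::d2_fwd(matrix(p1d, h, w), "periodic")))
  p2d <- solve(A2, r2)
  pf <- solve_p(u, x, b2, y, b3, pprev, params)
  expect_lt(max(abs(as.vector(pf$comp1) - p1d)) / max(abs(p1d)), 1e-8)
  expect_lt(max(abs(as.vector(pf$comp2) - p2d)) / max(abs(p2d)), 1e-8)
  # per-component normal-equation residuals
  expect_lt(max(abs(A1 %*% as.vector(pf$comp1) - r1)) / max(abs(r1)), 1e-8)
})

test_that("multiplier updates accumulate the constraint residuals", {
  params <- solver_params()
  h <- 6; w <- 6
  K <- blur_operator(gaussian_psf(3, 1), c(h, w))
  u <- abs(rand_img(20, h, w))
  # consistent state: all residuals zero -> multipliers unchanged
  p <- rand_vf(21, h, w)
  s <- list(u = u, p = p, w = apply_blur(K, u),
            x = grad(u) - p, y = sym_grad(p), z = u,
            b1 = rand_img(22, h, w), b2 = rand_vf(23, h, w),
            b3 = rand_stf(24, h, w), b4 = rand_img(25, h, w))
  s2 <- update_multipliers(s, K = K, params = params)
  expect_equal(s2$b1, s$b1, tolerance = 1e-12)
  expect_equal(s2$b2$comp1, s$b2$comp1, tolerance = 1e-12)
  expect_equal(s2$b3$t12, s$b3$t12, tolerance = 1e-12)
  expect_equal(s2$b4, s$b4, tolerance = 1e-12)

  # from zero multipliers one update equals the raw residuals
  z6 <- matrix(0, h, w)
  s$w <- s$w + 1; s$z <- s$z - 0.5
  s$b1 <- z6; s$b2 <- vector_field(z6, z6); s$b3 <- sym_tensor_field(z6, z6, z6)
  s$b4 <- z6
  s3 <- update_multipliers(s, K = K, params = params)
  expect_equal(s3$b1, apply_blur(K, s$u) - s$w)
  expect_equal(s3$b4, s$u - s$z)
})

test_that("objective evaluates the KL + L2 + TGV2 model with its conventions", {
  h <- 8; w <- 8
  Ki <- blur_operator(box_psf(1), c(h, w))
  params <- solver_params(beta = 3, lam = 0)
  u <- matrix(1, h, w)
  p0 <- vector_field(matrix(0, h, w), matrix(0, h, w))
  # f = Ku = 1, p = grad u = 0: objective reduces to beta * N
  expect_equal(objective(u, p0, matrix(1, h, w), Ki, params), 3 * h * w)

  # negative pixel trips the nonnegativity indicator
  un <- u; un[2, 2] <- -0.1
  expect_equal(objective(un, p0, matrix(1, h, w), Ki, params), Inf)
  # 0 log 0 = 0: zero image against zero observation is finite
  expect_equal(objective(matrix(0, h, w), p0, matrix(0, h, w), Ki, params), 0)
  # log(0) with positive counts is +Inf
  expect_equal(objective(matrix(0, h, w), p0, matrix(1, h, w), Ki, params), Inf)
})

test_that("restore handles the fidelity-dominated identity problem", {
  u_true <- make_phantom(32, 32, "shapes", seed = 5)
  Ki <- blur_operator(box_psf(1), dim(u_true))
  res <- restore(u_true, Ki, solver_params(beta = 5000, lam = 0, max_iter = 100))
  expect_lt(relerr(u_true, res$u), 0.02)
  expect_gte(min(res$u), 0)
})

test_that("restore enforces its input and stopping contracts", {
  u <- make_phantom(32, 32, "ramp_disks", seed = 2)
  K <- blur_operator(gaussian_psf(5, 2), dim(u))
  f <- degrade(u, K, seed = 4)
  res <- restore(f, K, solver_preset("test1"))
  expect_true(res$converged)
  expect_lte(utils::tail(res$history$rel_change, 1), 1e-3)
  expect_lte(res$iterations, res$params$max_iter)
  expect_gte(min(res$u), 0)
  expect_named(res$history,
               c("iteration", "rel_change", "objective", "r1", "r2", "r3", "r4"))
  expect_equal(res$history$iteration, seq_len(res$iterations))

  expect_error(restore(f - 100, K), "nonnegative")
  # all-zero observation converges to the zero image
  rz <- restore(matrix(0, 32, 32), K, solver_preset("test1"))
  expect_true(rz$converged)
  expect_equal(max(abs(rz$u)), 0)
})

test_that("the final iterate improves the model objective over the input", {
  u <- make_phantom(32, 32, "ramp_disks", seed = 9)
  K <- blur_operator(gaussian_psf(5, 2), dim(u))
  f <- degrade(u, K, seed = 10)
  params <- solver_preset("test1")
  res <- restore(f, K, params)
  # each image is scored with (an approximation of) its own best p
  obj_at <- function(img) {
    pbest <- tgv2_value(img, params$alpha0, params$alpha1, iters = 80,
                        params = params)$p
    objective(img, pbest, f, K, params)
  }
  expect_lt(obj_at(res$u), obj_at(pmax(f, 1e-8)))
})

test_that("lam = 0 reproduces the plain-TGV2 path bit for bit", {
  u <- make_phantom(32, 32, "shapes", seed = 12)
  K <- blur_operator(box_psf(5), dim(u))
  f <- degrade(u, K, seed = 13)
  r1 <- restore(f, K, solver_preset("test2", lam = 0, max_iter = 40))
  r2 <- restore_tgv(f, K, solver_preset("test2", max_iter = 40))
  expect_identical(r1$u, r2$u)
  expect_identical(r1$history, r2$history)
})
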