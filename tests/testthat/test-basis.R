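# Basis construction, evaluation, curve projection, cross-products,
# penalties and whitening, checked against dense-quadrature and
# loop-based oracles.

dom <- c(392, 851)

test_that("basis construction enforces its contracts", {
  b <- build_basis("fourier", dom, 21)
  expect_equal(b$size, 21L)
  expect_equal(b$period, diff(dom))

  # degenerate Fourier basis of size 1 is the constant function
  b1 <- build_basis("fourier", dom, 1)
  v <- evaluate_basis(b1, c(400, 600, 800))
  expect_equal(v[, 1], rep(1 / sqrt(diff(dom)), 3))

  expect_error(build_basis("fourier", dom, 20), "odd")
  expect_error(build_basis("bspline", dom, 3, order = 4), "size >= order")
  expect_error(evaluate_basis(b, 900), "outside")
})

test_that("B-splines form a partition of unity for any order and size", {
  pts <- seq(0, 1, length.out = 57)
  for (ord in c(2L, 3L, 4L)) {
    for (size in c(ord, ord + 1L, 12L)) {
      b <- build_basis("bspline", c(0, 1), size, order = ord)
      Phi <- evaluate_basis(b, pts)
      expect_equal(rowSums(Phi), rep(1, length(pts)), tolerance = 1e-10)
    }
  }
})

test_that("basis evaluation matches per-function scalar evaluation", {
  b <- build_basis("fourier", dom, 7)
  grid <- seq(dom[1], dom[2], length.out = 250)
  Phi <- evaluate_basis(b, grid)
  # scalar oracle: evaluate each function at each point separately
  oracle <- matrix(NA_real_, length(grid), b$size)
  for (r in seq_along(grid)) {
    for (l in seq_len(b$size)) {
      oracle[r, l] <- evaluate_basis(b, grid[r])[1, l]
    }
  }
  expect_equal(Phi, oracle)
})

test_that("Fourier basis is orthonormal under dense quadrature", {
  b <- build_basis("fourier", dom, 9)
  J <- cross_product_matrix(b, b)
  expect_equal(J, diag(9), tolerance = 1e-8)
})

test_that("curve projection solves the least-squares normal equations", {
  set.seed(11)
  b <- build_basis("bspline", dom, 21)
  grid <- seq(dom[1], dom[2], length.out = 250)
  Phi <- evaluate_basis(b, grid)

  # a curve in the span is reproduced exactly
  curve_in_span <- Phi[, 3]
  cf <- fit_curve_coefficients(rbind(curve_in_span), grid, b)
  e3 <- numeric(21); e3[3] <- 1
  expect_equal(drop(cf$coef), e3, tolerance = 1e-8)
  expect_equal(drop(Phi %*% drop(cf$coef)), curve_in_span, tolerance = 1e-8)

  # all-zero curve gives zero coefficients
  cf0 <- fit_curve_coefficients(rbind(rep(0, 250)), grid, b)
  expect_equal(drop(cf0$coef), numeric(21))

  # random curve matches an independent lm() solve
  y <- rnorm(250)
  cf2 <- fit_curve_coefficients(rbind(y), grid, b)
  oracle <- unname(coef(lm(y ~ 0 + Phi)))
  expect_equal(drop(cf2$coef), oracle, tolerance = 1e-8)

  # unresolvable basis rejected with a condition diagnostic
  few <- grid[1:5]
  expect_error(fit_curve_coefficients(rbind(y[1:5]), few, b), "at least")
})

test_that("cross-product matrix agrees with a dense trapezoid oracle", {
  phi <- build_basis("bspline", dom, 21)
  psi <- build_basis("fourier", dom, 21)
  J <- cross_product_matrix(phi, psi)
  xs <- seq(dom[1], dom[2], length.out = 100001)
  A <- evaluate_basis(phi, xs); B <- evaluate_basis(psi, xs)
  h <- diff(dom) / (length(xs) - 1)
  w <- rep(h, length(xs)); w[c(1, length(xs))] <- h / 2
  J_oracle <- crossprod(A, w * B)
  expect_lt(max(abs(J - J_oracle)), 1e-6)

  # column for a single constant coefficient function
  psi1 <- build_basis("fourier", dom, 1)
  J1 <- cross_product_matrix(phi, psi1)
  ints <- crossprod(A, w)  # plain integrals of each phi_l
  expect_equal(drop(J1), drop(ints) / sqrt(diff(dom)), tolerance = 1e-6)

  expect_error(cross_product_matrix(phi, build_basis("fourier", c(0, 1), 3)),
               "domain")
})

test_that("penalty matrix matches quadrature oracle; Fourier fix applied", {
  # order-2 splines are piecewise linear: zero curvature penalty
  b2 <- build_basis("bspline", c(0, 1), 6, order = 2)
  P2 <- penalty_matrix(b2)
  expect_equal(max(abs(P2$values)), 0, tolerance = 1e-10)

  # Fourier: diagonal after the (1,1) overwrite, (1,1) exactly 1
  bf <- build_basis("fourier", dom, 7)
  Pf <- penalty_matrix(bf)
  expect_identical(Pf$values[1, 1], 1)
  offdiag <- Pf$values - diag(diag(Pf$values))
  expect_lt(max(abs(offdiag)), 1e-6)
  # pair h has curvature eigenvalue (2*pi*h/T)^4 under orthonormality
  Tt <- diff(dom)
  expect_equal(Pf$values[2, 2], (2 * pi / Tt)^4, tolerance = 1e-6)

  # cubic B-spline penalty vs dense Simpson oracle at higher resolution
  bb <- build_basis("bspline", dom, 21)
  P <- penalty_matrix(bb)
  qn <- 100000L
  xs <- seq(dom[1], dom[2], length.out = qn + 1)
  D2 <- evaluate_basis(bb, xs, deriv = 2)
  h <- diff(dom) / qn
  w <- rep(c(2, 4), length.out = qn + 1); w[c(1, qn + 1)] <- 1
  P_oracle <- crossprod(D2, (w * h / 3) * D2)
  expect_lt(max(abs(P$values - P_oracle)) / max(abs(P_oracle)), 1e-6)
  expect_lt(max(abs(P$values - t(P$values))), 1e-12)
  expect_gt(min(eigen(P$values, symmetric = TRUE)$values), -1e-6)
})

test_that("functional design reduces dimension and is linear in the curve", {
  set.seed(21)
  phi <- build_basis("bspline", dom, 21)
  psi <- build_basis("bspline", dom, 21)
  grid <- seq(dom[1], dom[2], length.out = 250)
  J <- cross_product_matrix(phi, psi)
  X <- matrix(rnorm(3 * 250), 3, 250)
  cf <- fit_curve_coefficients(X, grid, phi)
  des <- functional_design(cf, J)
  expect_equal(dim(des$scores), c(3L, 21L))

  # score s equals quadrature of (fitted curve) * psi_s
  q <- funbandr:::simpson_grid(dom, 4096)
  fitted_curve <- evaluate_basis(phi, q$x) %*% cf$coef[1, ]
  Psi_q <- evaluate_basis(psi, q$x)
  oracle <- drop(crossprod(Psi_q, q$w * fitted_curve))
  expect_equal(drop(des$scores[1, ]), oracle, tolerance = 1e-6)

  # linearity: scores(a*x + b*y) = a*scores(x) + b*scores(y)
  z <- 2.5 * X[1, ] - 1.2 * X[2, ]
  cz <- fit_curve_coefficients(rbind(z), grid, phi)
  dz <- functional_design(cz, J)
  expect_equal(drop(dz$scores),
               drop(2.5 * des$scores[1, ] - 1.2 * des$scores[2, ]),
               tolerance = 1e-8)

  # orthonormal shared basis: J = I, scores equal the coefficients
  pf <- build_basis("fourier", dom, 9)
  cfF <- fit_curve_coefficients(X, grid, pf)
  desF <- functional_design(cfF, cross_product_matrix(pf, pf))
  expect_equal(desF$scores, cfF$coef, tolerance = 1e-7)

  expect_error(functional_design(cf, J[1:10, ]), "match")
})

test_that("whitening realizes the penalty-inverse prior covariance", {
  set.seed(31)
  phi <- build_basis("fourier", dom, 9)
  grid <- seq(dom[1], dom[2], length.out = 120)
  cf <- fit_curve_coefficients(matrix(rnorm(5 * 120), 5, 120), grid, phi)
  des <- functional_design(cf, cross_product_matrix(phi, phi))

  # identity penalty leaves the design unchanged
  d_id <- whiten_design(des, diag(9))
  expect_equal(d_id$scores, des$scores, tolerance = 1e-10)

  # full-rank penalty: (X P^-1/2)(X P^-1/2)' = X P^-1 X'
  P <- penalty_matrix(phi)$values
  dw <- whiten_design(des, P)
  expect_true(dw$whitened)
  lhs <- tcrossprod(dw$scores)
  rhs <- des$scores %*% solve(P, t(des$scores))
  expect_equal(lhs, rhs, tolerance = 1e-8)

  # degenerate zero penalty falls back to identity with a warning
  expect_warning(dz <- whiten_design(des, matrix(0, 9, 9)), "degenerate")
  expect_equal(dz$scores, des$scores, tolerance = 1e-10)

  expect_error(whiten_design(des, matrix(rnorm(81), 9, 9)), "symmetric")
})
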