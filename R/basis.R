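# Truncated bases for scalar-on-function regression of yield on
# reflectance curves: B-spline and Fourier systems, least-squares curve
# projection, cross-product and roughness-penalty matrices, and the
# low-dimensional functional design used by the model catalogue.

#' Construct a truncated basis system
#'
#' Builds a B-spline or Fourier basis on a closed wavelength interval.
#' B-spline bases use equally spaced knots; Fourier bases are orthonormal
#' (constant function plus sine/cosine pairs of harmonics of the
#' fundamental period), so their size must be odd.
#'
#' @param kind `"bspline"` or `"fourier"`.
#' @param domain Numeric length-2 interval `c(a, b)` in nm, `a < b`.
#' @param size Number of basis functions (default 21). Must be odd for
#'   Fourier and at least `order` for B-splines.
#' @param order Spline order for B-splines (4 = cubic, the default).
#' @param period Fourier period; defaults to `b - a`.
#' @return An object of class `fb_basis`.
#' @export
build_basis <- function(kind = c("bspline", "fourier"), domain, size = 21L,
                        order = 4L, period = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  size <- as.integer(size)
  if (size < 1L) stop("basis size must be >= 1")
  obj <- list(kind = kind, domain = as.numeric(domain), size = size)
  if (kind == "bspline") {
    order <- as.integer(order)
    if (order < 1L) stop("spline order must be >= 1")
    if (size < order) {
      stop("B-spline basis needs size >= order (got size ", size,
           ", order ", order, ")")
    }
    n_interior <- size - order
    interior <- if (n_interior > 0) {
      seq(domain[1], domain[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
    } else numeric(0)
    obj$order <- order
    obj$knots <- c(rep(domain[1], order), interior, rep(domain[2], order))
  } else {
    if (size > 1L && size %% 2L == 0L) {
      stop("Fourier basis size must be odd (constant + sine/cosine pairs); got ",
           size)
    }
    obj$period <- if (is.null(period)) diff(domain) else as.numeric(period)
    if (obj$period <= 0) stop("Fourier period must be positive")
  }
  class(obj) <- "fb_basis"
  obj
}

#' @export
print.fb_basis <- function(x, ...) {
  cat(sprintf("<fb_basis> %s basis, %d functions on [%g, %g]\n",
              x$kind, x$size, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a basis system on a grid
#'
#' @param basis An `fb_basis`.
#' @param points Numeric vector of evaluation points inside the domain
#'   (an absolute tolerance of 1e-8 times the domain width is allowed at
#'   the endpoints).
#' @param deriv Derivative order (0, 1 or 2).
#' @return Matrix `Phi` with `length(points)` rows and `basis$size`
#'   columns, `Phi[r, l] = phi_l(points[r])`.
#' @export
evaluate_basis <- function(basis, points, deriv = 0L) {
  stopifnot(inherits(basis, "fb_basis"))
  a <- basis$domain[1]; b <- basis$domain[2]
  tol <- 1e-8 * (b - a)
  bad <- points < a - tol | points > b + tol
  if (any(bad)) {
    stop("evaluation point outside basis domain: ",
         paste(utils::head(points[bad], 3L), collapse = ", "))
  }
  x <- pmin(pmax(points, a), b)
  if (basis$kind == "bspline") {
    if (deriv >= basis$order) {
      # derivative order at or above the spline order vanishes a.e.
      return(matrix(0, length(x), basis$size))
    }
    Phi <- splines::splineDesign(basis$knots, x, ord = basis$order,
                                 derivs = rep(as.integer(deriv), length(x)))
  } else {
    Phi <- fourier_eval(x, basis$size, basis$period, deriv)
  }
  dimnames(Phi) <- NULL
  Phi
}

# Orthonormal Fourier system on an interval of length `period`:
# constant 1/sqrt(T), then sqrt(2/T) sin(2*pi*h*t/T), sqrt(2/T) cos(...)
# for harmonics h = 1, 2, ...
fourier_eval <- function(x, size, period, deriv = 0L) {
  out <- matrix(0, length(x), size)
  out[, 1] <- if (deriv == 0L) 1 / sqrt(period) else 0
  n_pairs <- (size - 1L) %/% 2L
  if (n_pairs > 0) {
    amp <- sqrt(2 / period)
    for (h in seq_len(n_pairs)) {
      om <- 2 * pi * h / period
      s <- amp * sin(om * x); cc <- amp * cos(om * x)
      if (deriv == 0L) {
        out[, 2 * h]     <- s
        out[, 2 * h + 1] <- cc
      } else if (deriv == 1L) {
        out[, 2 * h]     <- om * cc
        out[, 2 * h + 1] <- -om * s
      } else if (deriv == 2L) {
        out[, 2 * h]     <- -om^2 * s
        out[, 2 * h + 1] <- -om^2 * cc
      } else stop("deriv must be 0, 1 or 2")
    }
  }
  out
}

# Composite-Simpson quadrature nodes/weights on [a, b]; `n_intervals`
# must be even (default 4096 subintervals, i.e. 4097 nodes).
simpson_grid <- function(domain, n_intervals = 4096L) {
  n <- as.integer(n_intervals)
  if (n %% 2L != 0L) n <- n + 1L
  x <- seq(domain[1], domain[2], length.out = n + 1L)
  h <- (domain[2] - domain[1]) / n
  w <- rep(c(2, 4), length.out = n + 1L)
  w[c(1L, n + 1L)] <- 1
  list(x = x, w = w * h / 3)
}

#' Project observed curves onto a basis by least squares
#'
#' Fits each curve's basis coefficients by ordinary least squares on the
#' observation grid: `c_hat = (Phi' Phi)^{-1} Phi' x`.
#'
#' @param values Numeric matrix, one curve per row, sampled on `wavelengths`.
#' @param wavelengths Strictly increasing grid the curves are observed on.
#' @param basis An `fb_basis` whose domain covers the grid.
#' @return An object of class `fb_curvecoef` with elements `coef`
#'   (`nrow(values)` x `basis$size`) and `basis`.
#' @export
fit_curve_coefficients <- function(values, wavelengths, basis) {
  values <- as.matrix(values)
  stopifnot(length(wavelengths) == ncol(values),
            all(diff(wavelengths) > 0))
  if (ncol(values) < basis$size) {
    stop("need at least as many grid points (", ncol(values),
         ") as basis functions (", basis$size, ")")
  }
  Phi <- evaluate_basis(basis, wavelengths)
  G <- crossprod(Phi)
  kappa <- tryCatch(rcond(G), error = function(e) 0)
  if (!is.finite(kappa) || kappa < 1e-12) {
    stop("Phi'Phi is numerically singular on this grid ",
         sprintf("(reciprocal condition %.3g); ", kappa),
         "the grid does not resolve the basis")
  }
  coef <- t(solve(G, crossprod(Phi, t(values))))
  structure(list(coef = coef, basis = basis, wavelengths = wavelengths),
            class = "fb_curvecoef")
}

#' Cross-product matrix between two bases
#'
#' Computes `J[l, s] = \int phi_l(k) psi_s(k) dk` over the shared domain
#' by composite-Simpson quadrature on a fixed fine grid.
#'
#' @param phi,psi `fb_basis` objects sharing the same domain.
#' @param n_quad Number of quadrature subintervals (default 4096).
#' @return `phi$size` x `psi$size` matrix.
#' @export
cross_product_matrix <- function(phi, psi, n_quad = 4096L) {
  stopifnot(inherits(phi, "fb_basis"), inherits(psi, "fb_basis"))
  if (!isTRUE(all.equal(phi$domain, psi$domain))) {
    stop("bases must share the same integration domain")
  }
  q <- simpson_grid(phi$domain, n_quad)
  A <- evaluate_basis(phi, q$x)
  B <- evaluate_basis(psi, q$x)
  crossprod(A, q$w * B)
}

#' Second-derivative roughness penalty of a basis
#'
#' `P[i, j] = \int psi_i''(k) psi_j''(k) dk`, computed by Simpson
#' quadrature. For Fourier bases the constant function has a vanishing
#' second derivative, which would give the corresponding coefficient an
#' improper degenerate prior, so entry `(1, 1)` is overwritten with 1.
#'
#' @param basis An `fb_basis`.
#' @param n_quad Number of quadrature subintervals (default 4096).
#' @return An object of class `fb_penalty` with elements `values`
#'   (symmetric `size` x `size` matrix) and `basis`.
#' @export
penalty_matrix <- function(basis, n_quad = 4096L) {
  if (basis$kind == "bspline") {
    # knot-aligned composite Simpson: the squared second derivative is
    # polynomial within each knot span, so span-wise Simpson at modest
    # resolution integrates it essentially exactly
    spans <- unique(basis$knots)
    qx <- numeric(0); qw <- numeric(0)
    for (i in seq_len(length(spans) - 1L)) {
      qi <- simpson_grid(spans[i:(i + 1L)], 16L)
      qx <- c(qx, qi$x); qw <- c(qw, qi$w)
    }
    q <- list(x = qx, w = qw)
  } else {
    q <- simpson_grid(basis$domain, n_quad)
  }
  D2 <- evaluate_basis(basis, q$x, deriv = 2L)
  P <- crossprod(D2, q$w * D2)
  P <- (P + t(P)) / 2
  if (basis$kind == "fourier") P[1, 1] <- 1
  structure(list(values = P, basis = basis), class = "fb_penalty")
}

#' Functional design matrix from curve coefficients
#'
#' Scores `x_ij[s] = sum_l c_hat[ij, l] * J[l, s]`, one row per curve:
#' the low-dimensional representation of `\int x_ij(k) psi_s(k) dk`.
#'
#' @param curve_coefs An `fb_curvecoef`.
#' @param J Cross-product matrix from [cross_product_matrix()], with row
#'   dimension equal to the coefficient-basis size.
#' @return An object of class `fb_design` with elements `scores`
#'   (n_curves x S), `J`, and `whitened = FALSE`.
#' @export
functional_design <- function(curve_coefs, J) {
  stopifnot(inherits(curve_coefs, "fb_curvecoef"))
  J <- as.matrix(J)
  if (ncol(curve_coefs$coef) != nrow(J)) {
    stop("coefficient count (", ncol(curve_coefs$coef),
         ") does not match J row dimension (", nrow(J), ")")
  }
  structure(list(scores = curve_coefs$coef %*% J, J = J,
                 whitened = FALSE, unwhiten = NULL),
            class = "fb_design")
}

# Symmetric pseudo-inverse square root of a PSD matrix. Eigenvalues
# below rel_tol * max(eigenvalue) are treated as exact zeros.
pseudo_inv_sqrt <- function(P, rel_tol = 1e-8) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  pos <- e$values > rel_tol * max(e$values, 0)
  if (!any(pos)) return(NULL)
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / sqrt(e$values[pos]))
}

# Symmetric pseudo square root (used to map coefficient functions back
# to the whitened scale).
pseudo_sqrt <- function(P, rel_tol = 1e-8) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  pos <- e$values > rel_tol * max(e$values, 0)
  if (!any(pos)) return(NULL)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) * sqrt(e$values[pos]))
}

#' Whiten a functional design by the penalty square root
#'
#' Post-multiplies the score matrix by the symmetric (pseudo-inverse)
#' square root of the penalty, so that independent standard-normal
#' coefficients on the whitened scale imply the smoothness prior
#' `N(0, sigma^2 P^{-1})` on the original coefficient scale.  A penalty
#' with no positive eigenvalues (e.g. from a piecewise-linear spline
#' basis) degenerates; the identity is substituted with a warning.
#'
#' @param design An `fb_design`.
#' @param penalty An `fb_penalty` (or symmetric matrix) of matching size.
#' @return The design with `scores` transformed, `whitened = TRUE`, and
#'   an `unwhiten` matrix mapping whitened coefficients back to the
#'   original basis-coefficient scale. If the penalty is rank deficient
#'   (e.g. the curvature penalty of a cubic spline basis, whose null
#'   space holds the constant and linear functions), the null-space
#'   directions are returned separately as `null_basis` (eigenvectors)
#'   and `null_scores` (the scores projected on them): those directions
#'   carry no roughness information and must stay in the model as
#'   unpenalized columns rather than being annihilated.
#' @export
whiten_design <- function(design, penalty) {
  stopifnot(inherits(design, "fb_design"))
  P <- if (inherits(penalty, "fb_penalty")) penalty$values else as.matrix(penalty)
  if (max(abs(P - t(P))) > 1e-8 * max(1, max(abs(P)))) {
    stop("penalty matrix must be symmetric")
  }
  if (ncol(design$scores) != nrow(P)) stop("penalty size does not match design")
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values, 0)
  if (!any(pos)) {
    warning("penalty has no positive eigenvalues; whitening degenerates, ",
            "substituting the identity")
    design$whitened <- TRUE
    design$unwhiten <- diag(nrow(P))
    return(design)
  }
  V <- e$vectors[, pos, drop = FALSE]
  Pm12 <- V %*% (t(V) / sqrt(e$values[pos]))
  if (any(!pos)) {
    V0 <- e$vectors[, !pos, drop = FALSE]
    design$null_basis <- V0
    design$null_scores <- design$scores %*% V0
  }
  design$scores <- design$scores %*% Pm12
  design$whitened <- TRUE
  design$unwhiten <- Pm12
  design
}

#' Evaluate a basis expansion on a grid
#'
#' Convenience helper: `f(k) = sum_s d_s psi_s(k)`.
#'
#' @param basis An `fb_basis`.
#' @param coef Coefficient vector (or matrix, one expansion per column).
#' @param points Evaluation grid.
#' @return Numeric vector (or matrix) of function values.
#' @export
basis_expand <- function(basis, coef, points) {
  Phi <- evaluate_basis(basis, points)
  out <- Phi %*% as.matrix(coef)
  if (is.vector(coef)) drop(out) else out
}
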