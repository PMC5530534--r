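# Gibbs sampler interface: prior and run configuration, fitting a
# compiled design bundle, prediction for unobserved cells, and
# reconstruction of the functional coefficient curves.

#' Prior configuration for the Gibbs sampler
#'
#' Fixed effects get a flat normal prior with large variance. Each
#' block variance gets a scaled inverse chi-square prior, parameterized
#' so the prior mode is `scale / (df + 2)`. The residual variance prior
#' is near-degenerate at 1 (`scale = df = 2e10`): the second-stage
#' response is pre-scaled by the square root of the stage-one weights,
#' under which the residual variance is 1 by construction.  For the
#' remaining variances the scale is resolved per bundle: `df = 5` and
#' prior mode equal to a fraction `r2` of the response variance split
#' equally across the ridge blocks (divided by each block's mean row
#' sum of squares so the mode refers to the block's contribution to the
#' response variance).
#'
#' @param fixed_var Prior variance of fixed effects (default 10000).
#' @param residual_scale,residual_df Residual prior (defaults 2e10 each,
#'   pinning the residual variance near 1).
#' @param ridge_df Prior degrees of freedom for block variances
#'   (default 5).
#' @param r2 Fraction of the response variance assigned, a priori,
#'   to the random blocks jointly (default 0.5).
#' @return Object of class `fb_priors`.
#' @export
prior_config <- function(fixed_var = 1e4, residual_scale = 2e10,
                         residual_df = 2e10, ridge_df = 5, r2 = 0.5) {
  structure(list(fixed_var = fixed_var, residual_scale = residual_scale,
                 residual_df = residual_df, ridge_df = ridge_df, r2 = r2),
            class = "fb_priors")
}

#' Sampler run configuration
#'
#' @param iterations Total Gibbs iterations (default 30000).
#' @param burn_in Burn-in iterations discarded (default 20000).
#' @param thin Thinning interval (default 1).
#' @param seed Optional integer seed applied via [set.seed()].
#' @return Object of class `fb_sampler_control`.
#' @export
sampler_control <- function(iterations = 30000L, burn_in = 20000L,
                            thin = 1L, seed = NULL) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  structure(list(iterations = iterations, burn_in = burn_in,
                 thin = as.integer(thin), seed = seed),
            class = "fb_sampler_control")
}

# Resolve per-block scaled-inv-chi-square hyperparameters for a bundle.
resolve_priors <- function(priors, blocks, y) {
  ridge <- names(blocks)[vapply(blocks, function(b) b$type == "ridge",
                                logical(1))]
  vy <- stats::var(y)
  out <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (b$type != "ridge") return(list(scale = 0, df = 0))
    msx <- mean(rowSums(b$X^2))
    if (!is.finite(msx) || msx <= 0) msx <- 1
    mode <- priors$r2 * vy / length(ridge) / msx
    if (!is.finite(mode) || mode <= 0) mode <- 1e-4
    list(scale = mode * (priors$ridge_df + 2), df = priors$ridge_df)
  })
  names(out) <- names(blocks)
  out
}

#' Fit a compiled model by Gibbs sampling
#'
#' Runs the Gibbs sampler on a design bundle: normal full-conditional
#' updates for every coefficient (fixed-effect columns with constant
#' prior variance; ridge columns sharing a block variance) and scaled
#' inverse chi-square full conditionals for each block variance and the
#' residual variance. Kernel random effects and penalized functional
#' coefficients enter through the pre-transformed columns created by
#' [compile_design()], so their updates here are plain ridge updates.
#'
#' @param bundle An `fb_design_bundle`.
#' @param priors An `fb_priors` (default [prior_config()]).
#' @param control An `fb_sampler_control` (default [sampler_control()]).
#' @param rows Optional integer vector of rows to train on (e.g. a CV
#'   training set); all columns are kept so unobserved cells can still
#'   be predicted.
#' @param fix_variances Optional named list pinning block variances (and
#'   optionally `residual`) at fixed values; those variances are then
#'   not updated. Used mainly for validation against closed-form
#'   mixed-model solutions.
#' @return Object of class `fb_posterior_fit`.
#' @export
gibbs_fit <- function(bundle, priors = prior_config(),
                      control = sampler_control(), rows = NULL,
                      fix_variances = NULL) {
  stopifnot(inherits(bundle, "fb_design_bundle"))
  if (!is.null(control$seed)) set.seed(control$seed)
  idx <- if (is.null(rows)) seq_along(bundle$y) else as.integer(rows)
  y <- bundle$y[idx]
  if (any(!is.finite(y))) stop("non-finite response values")
  sw <- if (!is.null(bundle$weights)) sqrt(bundle$weights[idx]) else NULL

  Xs <- lapply(bundle$blocks, function(b) b$X[idx, , drop = FALSE])
  sizes <- vapply(Xs, ncol, integer(1))
  X <- do.call(cbind, Xs)
  if (!is.null(sw)) {
    y <- y * sw
    X <- X * sw
  }
  block_id <- rep(seq_along(Xs) - 1L, times = sizes)
  types <- vapply(bundle$blocks, function(b)
    if (b$type == "fixed") 0L else 1L, integer(1))

  hp <- resolve_priors(priors, bundle$blocks, y)
  S0 <- vapply(hp, function(h) h$scale, numeric(1))
  df0 <- vapply(hp, function(h) h$df, numeric(1))
  init_var <- ifelse(types == 1L, pmax(S0 / (df0 + 2), 1e-8), priors$fixed_var)
  init_resid <- 1
  update_var <- rep(TRUE, length(types))
  update_resid <- TRUE
  if (!is.null(fix_variances)) {
    for (nm in names(fix_variances)) {
      if (nm == "residual") {
        init_resid <- fix_variances[[nm]]
        update_resid <- FALSE
      } else {
        k <- match(nm, names(bundle$blocks))
        if (is.na(k)) stop("fix_variances names unknown block: ", nm)
        init_var[k] <- fix_variances[[nm]]
        update_var[k] <- FALSE
      }
    }
  }
  # pinned ridge blocks are passed as type 0 (never updated) but keep
  # their own initial variance; fixed blocks use priors$fixed_var
  pinned <- !update_var & types == 1L
  res <- .gibbs_core(y, X, block_id,
                     ifelse(pinned, 0L, types),
                     S0, df0,
                     priors$residual_scale, priors$residual_df,
                     init_var, init_resid,
                     TRUE, update_resid,
                     control$iterations, control$burn_in, control$thin)
  coef <- drop(res$coef_mean)
  coef_split <- split(coef, rep(names(Xs), times = sizes))[names(Xs)]
  sd_split <- split(drop(res$coef_sd),
                    rep(names(Xs), times = sizes))[names(Xs)]
  var_chain <- res$var_chain
  colnames(var_chain) <- names(Xs)
  fitted_all <- drop(do.call(cbind, lapply(bundle$blocks, function(b) b$X)) %*%
                       coef)
  structure(list(coef = coef_split, coef_sd = sd_split,
                 var_chain = var_chain[, types == 1L, drop = FALSE],
                 resid_chain = drop(res$resid_chain),
                 fitted = fitted_all, train_rows = idx,
                 bundle = bundle, priors = priors, control = control),
            class = "fb_posterior_fit")
}

#' @export
print.fb_posterior_fit <- function(x, ...) {
  cat(sprintf("<fb_posterior_fit> %s/%s, %d kept draws\n",
              x$bundle$spec$model_id, x$bundle$spec$mode,
              length(x$resid_chain)))
  vm <- colMeans(x$var_chain)
  cat("posterior mean variances:",
      paste(sprintf("%s=%.4g", names(vm), vm), collapse = ", "),
      sprintf("residual=%.4g\n", mean(x$resid_chain)))
  invisible(x)
}

#' Predict yield for cells of the design or new rows
#'
#' Predictions are the sum of block contributions at the posterior
#' means: environment effect, kernel prediction of the line effect (and
#' its environment interaction, borrowing across lines through the
#' kinship), and band or functional-score contributions.
#'
#' @param object An `fb_posterior_fit`.
#' @param newdata Optional table of new rows (same format as the
#'   second-stage table used at compile time); its genotypes must exist
#'   in the kinship and its environments among the training
#'   environments.
#' @param rows Optional row indices into the compiled bundle (e.g. a CV
#'   test set); used when `newdata` is not given.
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.fb_posterior_fit <- function(object, newdata = NULL, rows = NULL,
                                     ...) {
  coef <- unlist(object$coef, use.names = FALSE)
  if (!is.null(newdata)) {
    blocks <- build_blocks(object$bundle$artifacts, as.data.frame(newdata))
    X <- do.call(cbind, lapply(blocks, function(b) b$X))
  } else {
    idx <- if (is.null(rows)) seq_along(object$bundle$y) else rows
    return(object$fitted[idx])
  }
  drop(X %*% coef)
}

#' Posterior-mean line effects
#'
#' Maps the eigen-scale coefficients of the line kernel block back to
#' per-line genetic effects (`u = T b` with `K = T T'`).
#'
#' @param fit An `fb_posterior_fit`.
#' @return Named numeric vector over the kinship's lines.
#' @export
line_effects <- function(fit) {
  b <- fit$coef$g
  u <- drop(fit$bundle$artifacts$Tg %*% b)
  stats::setNames(u, fit$bundle$artifacts$line_ids)
}

#' Reconstruct the functional coefficient curves
#'
#' Un-whitens the posterior-mean basis coefficients and expands them in
#' the coefficient basis: the common curve `beta1(k)` and, for models
#' with functional band-by-environment interaction, one curve
#' `beta2_i(k)` per environment.
#'
#' @param fit An `fb_posterior_fit` from a functional model.
#' @param grid Wavelength grid to evaluate on (default: the band grid
#'   the model was compiled with).
#' @return List with `grid`, `beta1` (numeric vector) and `beta2`
#'   (matrix grid x environments, or `NULL`). When per-environment
#'   curves are present they are reported centered across environments
#'   with their mean folded into `beta1`, the canonical identified
#'   decomposition.
#' @export
reconstruct_beta_function <- function(fit, grid = NULL) {
  art <- fit$bundle$artifacts
  if (!fit$bundle$spec$functional) {
    stop("model ", fit$bundle$spec$model_id,
         " is not a functional model; no coefficient curve to reconstruct")
  }
  if (is.null(grid)) grid <- art$wavelengths
  unw <- fit$bundle$blocks$basis_common$unwhiten
  V0 <- fit$bundle$blocks$basis_common$null_basis
  d1 <- drop(unw %*% fit$coef$basis_common)
  if (!is.null(V0)) d1 <- d1 + drop(V0 %*% fit$coef$basis_null)
  beta1 <- basis_expand(art$psi, d1, grid)
  beta2 <- NULL
  if (!is.null(fit$coef$basis_by_env)) {
    S <- art$spec$S
    k <- if (is.null(V0)) 0L else ncol(V0)
    beta2 <- sapply(seq_along(art$envs), function(i) {
      bw <- fit$coef$basis_by_env[(i - 1L) * S + seq_len(S)]
      d <- drop(unw %*% bw)
      if (k > 0) {
        bn <- fit$coef$basis_null_by_env[(i - 1L) * k + seq_len(k)]
        d <- d + drop(V0 %*% bn)
      }
      basis_expand(art$psi, d, grid)
    })
    # only beta1 + mean(beta2) and the environment contrasts of beta2
    # are identified when every environment has its own curve; report
    # the canonical decomposition with the interaction curves centered
    # across environments
    m <- rowMeans(beta2)
    beta1 <- beta1 + m
    beta2 <- beta2 - m
    colnames(beta2) <- art$envs
  }
  list(grid = grid, beta1 = beta1, beta2 = beta2)
}
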