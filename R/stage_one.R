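# First stage of the two-stage trial analysis: per-environment REML for
# the alpha-lattice plot model (random replicate-in-trial, trial and
# incomplete-block effects), generalized-least-squares BLUEs of the
# genotype-in-environment means, and inverse-variance weights carried
# into the second stage.

plot_table_cols <- c("env", "trial", "rep", "block", "genotype", "yield")

# Adds the nested design factors used by the plot model.
add_design_factors <- function(tab) {
  tab$trial_id <- factor(tab$trial)
  tab$rep_id <- interaction(tab$trial, tab$rep, drop = TRUE)
  tab$block_id <- interaction(tab$trial, tab$rep, tab$block, drop = TRUE)
  tab$genotype <- factor(as.character(tab$genotype))
  tab
}

#' REML variance components for one environment
#'
#' Fits the plot-level model of a single environment — fixed
#' genotype-in-environment means plus random replicate-within-trial,
#' trial and incomplete-block effects — by REML and returns the four
#' environment-specific variance components.
#'
#' @param env_table Plot rows of one environment with columns `trial`,
#'   `rep`, `block`, `genotype` and the trait column.
#' @param trait Name of the trait column (default `"yield"`).
#' @return List with `sigma_r2` (replicate), `sigma_t2` (trial),
#'   `sigma_b2` (block) and `sigma_e2` (residual), all `>= 0`.
#' @export
reml_varcomps <- function(env_table, trait = "yield") {
  tab <- add_design_factors(as.data.frame(env_table))
  if (length(unique(tab$rep)) < 2L) stop("need at least 2 replicates")
  tab$.y <- tab[[trait]]
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ 0 + genotype + (1 | rep_id) + (1 | trial_id) +
                 (1 | block_id),
               data = tab, REML = TRUE,
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) max(v, 0) else 0
  }
  list(sigma_r2 = get("rep_id"), sigma_t2 = get("trial_id"),
       sigma_b2 = get("block_id"), sigma_e2 = get("Residual"))
}

# Sparse marginal covariance of the plot data given the variance
# components, and the genotype incidence matrix.
plot_cov_design <- function(tab, vc) {
  n <- nrow(tab)
  Zr <- Matrix::sparse.model.matrix(~ 0 + rep_id, tab)
  Zt <- Matrix::sparse.model.matrix(~ 0 + trial_id, tab)
  Zb <- Matrix::sparse.model.matrix(~ 0 + block_id, tab)
  Sigma <- vc$sigma_e2 * Matrix::Diagonal(n) +
    vc$sigma_r2 * Matrix::tcrossprod(Zr) +
    vc$sigma_t2 * Matrix::tcrossprod(Zt) +
    vc$sigma_b2 * Matrix::tcrossprod(Zb)
  X <- Matrix::sparse.model.matrix(~ 0 + genotype, tab)
  colnames(X) <- levels(tab$genotype)
  list(Sigma = Sigma, X = X)
}

#' Generalized-least-squares BLUEs for one environment
#'
#' Computes `mu_hat = (X' Sigma^-1 X)^-1 X' Sigma^-1 y` for one or more
#' traits sharing the same design and variance components, together with
#' the inverse-variance weights `omega_j = [X' Sigma^-1 X]_jj` (the
#' diagonal of the inverse of `Psi = var(mu_hat)`).
#'
#' @param env_table Plot rows of one environment.
#' @param traits Character vector of trait columns to adjust.
#' @param varcomps Variance components from [reml_varcomps()].
#' @return Object of class `fb_stage1_env`: list with `blues` (genotype
#'   x trait matrix), `weights` (named vector, one per genotype, from
#'   the first trait), and `varcomps`.
#' @export
blues <- function(env_table, traits = "yield", varcomps) {
  if (varcomps$sigma_e2 <= 0) stop("sigma_e2 must be positive")
  tab <- add_design_factors(as.data.frame(env_table))
  cd <- plot_cov_design(tab, varcomps)
  Y <- as.matrix(tab[, traits, drop = FALSE])
  if (anyNA(Y)) stop("missing trait values in stage one input")
  SiX <- Matrix::solve(cd$Sigma, cd$X)
  C <- as.matrix(Matrix::crossprod(cd$X, SiX))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    aliased <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("genotype design is not full rank; aliased: ",
         paste(aliased, collapse = ", "))
  }
  B <- solve(C, as.matrix(Matrix::crossprod(SiX, Y)))
  rownames(B) <- colnames(cd$X)
  colnames(B) <- traits
  structure(list(blues = B,
                 weights = stats::setNames(diag(C), colnames(cd$X)),
                 varcomps = varcomps),
            class = "fb_stage1_env")
}

#' Detect band columns of a plot or second-stage table
#'
#' Band columns follow the `band_<wavelength>_t<timepoint>` pattern.
#'
#' @param tab Data frame.
#' @return Character vector of band column names, ordered
#'   wavelength-major within time-point.
#' @export
band_columns <- function(tab) {
  nm <- grep("^band_[0-9.]+_t[0-9]+$", names(tab), value = TRUE)
  if (!length(nm)) return(character(0))
  wl <- as.numeric(sub("^band_([0-9.]+)_t[0-9]+$", "\\1", nm))
  tp <- as.integer(sub("^band_[0-9.]+_t([0-9]+)$", "\\1", nm))
  nm[order(tp, wl)]
}

#' Full first-stage adjustment of a multi-environment trial
#'
#' Runs [reml_varcomps()] and [blues()] per environment for yield and
#' every band column. Band traits can either get their own REML fit
#' (`band_varcomps = "per_band"`, the default) or reuse the yield
#' variance components (`"share_yield"`), which shares one covariance
#' factorization across all band columns.
#'
#' @param plot_table Plot-level table with columns `env`, `trial`,
#'   `rep`, `block`, `genotype`, `yield` and `band_<wl>_t<tp>` columns.
#' @param band_varcomps `"per_band"` or `"share_yield"`.
#' @return Object of class `fb_stage1`: named list of `fb_stage1_env`
#'   per environment, with attribute `traits`.
#' @export
stage_one <- function(plot_table, band_varcomps = c("per_band", "share_yield")) {
  band_varcomps <- match.arg(band_varcomps)
  miss <- setdiff(plot_table_cols, names(plot_table))
  if (length(miss)) stop("plot table missing column(s): ",
                         paste(miss, collapse = ", "))
  bands <- band_columns(plot_table)
  envs <- unique(as.character(plot_table$env))
  out <- lapply(envs, function(e) {
    tab <- plot_table[plot_table$env == e, , drop = FALSE]
    vc_y <- reml_varcomps(tab, "yield")
    res_y <- blues(tab, "yield", vc_y)
    if (length(bands)) {
      if (band_varcomps == "share_yield") {
        res_b <- blues(tab, bands, vc_y)
        res_y$blues <- cbind(res_y$blues, res_b$blues)
      } else {
        for (b in bands) {
          vc_b <- reml_varcomps(tab, b)
          res_b <- blues(tab, b, vc_b)
          res_y$blues <- cbind(res_y$blues, res_b$blues)
        }
      }
    }
    res_y
  })
  names(out) <- envs
  structure(out, class = "fb_stage1", traits = c("yield", bands))
}

#' Assemble the second-stage table
#'
#' One row per (environment, genotype): environment, genotype, yield
#' BLUE, its inverse-variance weight, then every band BLUE
#' (wavelength-major within time-point). Check entries are dropped.
#'
#' @param stage1 An `fb_stage1` from [stage_one()], or a compatible
#'   named list of per-environment results.
#' @param checks Character vector of check genotype ids to exclude
#'   (default: genotypes whose id starts with `"CHK"`).
#' @return Data frame of class `fb_second_stage`.
#' @export
assemble_second_stage <- function(stage1, checks = NULL) {
  traits <- attr(stage1, "traits")
  rows <- lapply(names(stage1), function(e) {
    r <- stage1[[e]]
    g <- rownames(r$blues)
    drop_g <- if (is.null(checks)) grepl("^CHK", g) else g %in% checks
    keep <- !drop_g
    if (any(is.na(r$blues[keep, ]))) {
      bad <- which(is.na(r$blues[keep, ]), arr.ind = TRUE)[1, ]
      stop("missing BLUE for genotype ", g[keep][bad[1]],
           " trait ", colnames(r$blues)[bad[2]], " in environment ", e)
    }
    data.frame(env = e, genotype = g[keep],
               yield = r$blues[keep, "yield"],
               weight_yield = unname(r$weights[g[keep]]),
               r$blues[keep, setdiff(colnames(r$blues), "yield"),
                       drop = FALSE],
               check.names = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fb_second_stage", "data.frame")
  out
}
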