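# The catalogue of fourteen second-stage prediction models (M1-M14) in
# WG / WA / WO relationship mode, compiled from a second-stage table
# into fixed, kernel-random and coefficient design blocks with their
# prior tags.

model_table <- data.frame(
  model_id = paste0("M", 1:14),
  has_gE = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE,
             FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
  has_bands = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  functional = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
  has_bandxenv = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  default_basis = c(NA, NA, NA, NA, "bspline", "fourier", "bspline",
                    "fourier", NA, NA, "bspline", "fourier", "bspline",
                    "fourier"),
  stringsAsFactors = FALSE)

#' Specify one of the fourteen prediction models
#'
#' Models M1-M4, M9 and M10 are conventional (per-band regression
#' coefficients); M5-M8 and M11-M14 represent the reflectance curve
#' through a truncated basis (B-spline or Fourier). M9-M14 add
#' band-by-environment interaction; M2, M4, M7, M8, M10, M13 and M14
#' add the genotype-by-environment kernel term.
#'
#' @param model_id `"M1"` ... `"M14"`.
#' @param mode `"WG"` (genomic kinship), `"WA"` (pedigree kinship) or
#'   `"WO"` (identity).
#' @param basis_kind Basis family for functional models; defaults to
#'   the catalogue assignment (B-spline for M5/M7/M11/M13, Fourier for
#'   M6/M8/M12/M14).
#' @param L,S Sizes of the curve basis and the coefficient basis
#'   (default 21 each).
#' @param penalty_mode `"penalty"` uses the second-derivative roughness
#'   penalty prior for functional coefficients; `"identity"` assumes an
#'   identity prior covariance instead.
#' @param standardize_bands Column-standardize conventional band
#'   covariates (default `TRUE`).
#' @param use_weights Scale rows by the square root of the stage-one
#'   weights (default `TRUE`).
#' @return Object of class `fb_model_spec`.
#' @export
model_spec <- function(model_id, mode = c("WG", "WA", "WO"),
                       basis_kind = NULL, L = 21L, S = 21L,
                       penalty_mode = c("penalty", "identity"),
                       standardize_bands = TRUE, use_weights = TRUE) {
  mode <- match.arg(mode)
  penalty_mode <- match.arg(penalty_mode)
  row <- model_table[model_table$model_id == model_id, ]
  if (nrow(row) != 1L) stop("unknown model id: ", model_id)
  if (is.null(basis_kind)) {
    basis_kind <- if (row$functional) row$default_basis else NA_character_
  }
  structure(list(model_id = model_id, mode = mode,
                 has_gE = row$has_gE, has_bands = row$has_bands,
                 functional = row$functional,
                 has_bandxenv = row$has_bandxenv,
                 basis_kind = basis_kind, L = as.integer(L),
                 S = as.integer(S), penalty_mode = penalty_mode,
                 standardize_bands = standardize_bands,
                 use_weights = use_weights),
            class = "fb_model_spec")
}

#' Conventional / functional counterpart map
#'
#' Returns the structure map used in reporting: each conventional model
#' with band information paired with its B-spline and Fourier
#' functional counterparts, plus the band-free pair (M1, M2).
#'
#' @return A list with elements `pairs` (data frame with columns
#'   `conventional`, `bspline`, `fourier`) and `no_bands`
#'   (`c("M1", "M2")`).
#' @export
spec_pairs <- function() {
  list(pairs = data.frame(conventional = c("M3", "M4", "M9", "M10"),
                          bspline = c("M5", "M7", "M11", "M13"),
                          fourier = c("M6", "M8", "M12", "M14"),
                          stringsAsFactors = FALSE),
       no_bands = c("M1", "M2"))
}

# Band columns of one time-point, ordered by wavelength.
timepoint_bands <- function(tab, time_point) {
  nm <- band_columns(tab)
  tp <- as.integer(sub("^band_[0-9.]+_t([0-9]+)$", "\\1", nm))
  if (is.null(time_point)) {
    tps <- unique(tp)
    if (length(tps) > 1L) {
      stop("table has time-points ", paste(sort(tps), collapse = ", "),
           "; give `time_point`")
    }
    time_point <- tps
  }
  nm[tp == time_point]
}

# Eigen square root of a PSD kernel; tiny negative eigenvalues clipped.
kernel_sqrt <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), nrow(K))
}

#' Compile a model into design blocks
#'
#' Turns a model specification, second-stage table and kinship into the
#' design bundle consumed by [gibbs_fit()]: a fixed environment block,
#' kernel random blocks for the line effect (and its interaction with
#' environments, expressed in the eigenbasis of the kinship so that the
#' implied covariance is `K sigma^2` and `(K %x% I) sigma^2`), and
#' coefficient blocks for band or functional-score covariates, common
#' and environment-specific.
#'
#' @param spec An `fb_model_spec`.
#' @param table Second-stage table (one row per env x genotype) with
#'   columns `env`, `genotype`, `yield`, `weight_yield` and band
#'   columns.
#' @param kinship `fb_kinship` covering every genotype in `table`
#'   (required for WG/WA; built as the identity for WO if omitted).
#' @param time_point Which time-point's bands to use (required when the
#'   table carries several).
#' @return Object of class `fb_design_bundle`.
#' @export
compile_design <- function(spec, table, kinship = NULL, time_point = NULL) {
  stopifnot(inherits(spec, "fb_model_spec"))
  table <- as.data.frame(table)
  lines_all <- unique(as.character(table$genotype))
  if (spec$mode == "WO") {
    kinship <- identity_kinship(if (is.null(kinship)) lines_all
                                else kinship$line_ids)
  }
  if (is.null(kinship)) {
    stop("mode ", spec$mode, " requires a kinship matrix")
  }
  missing_lines <- setdiff(lines_all, kinship$line_ids)
  if (length(missing_lines)) {
    stop("genotypes absent from the kinship: ",
         paste(utils::head(missing_lines, 5L), collapse = ", "))
  }
  envs <- unique(as.character(table$env))

  artifacts <- list(spec = spec, envs = envs,
                    line_ids = kinship$line_ids,
                    Tg = kernel_sqrt(kinship$values))

  if (spec$has_bands || spec$functional) {
    bcols <- timepoint_bands(table, time_point)
    if (!length(bcols)) stop("model ", spec$model_id,
                             " needs band columns in the table")
    wl <- as.numeric(sub("^band_([0-9.]+)_t[0-9]+$", "\\1", bcols))
    o <- order(wl)
    artifacts$band_cols <- bcols[o]
    artifacts$wavelengths <- wl[o]
    if (spec$has_bands) {
      B <- as.matrix(table[, artifacts$band_cols, drop = FALSE])
      if (spec$standardize_bands) {
        artifacts$band_center <- colMeans(B)
        sdv <- apply(B, 2, stats::sd)
        artifacts$band_scale <- ifelse(sdv > 0, sdv, 1)
      }
    }
    if (spec$functional) {
      dom <- range(artifacts$wavelengths)
      artifacts$phi <- build_basis(spec$basis_kind, dom, spec$L)
      artifacts$psi <- build_basis(spec$basis_kind, dom, spec$S)
      artifacts$J <- cross_product_matrix(artifacts$phi, artifacts$psi)
      if (spec$penalty_mode == "penalty") {
        artifacts$penalty <- penalty_matrix(artifacts$psi)
      } else {
        artifacts$penalty <- structure(
          list(values = diag(spec$S), basis = artifacts$psi),
          class = "fb_penalty")
      }
    }
  }

  blocks <- build_blocks(artifacts, table)
  if (spec$functional) {
    # centre the score columns and rebuild: reflectance curves share a
    # large mean component which otherwise leaves the coefficient
    # blocks collinear with the intercepts and miscalibrates the
    # variance prior; a column shift only moves the environment
    # intercepts. Prediction rows are shifted by the same centres.
    artifacts$score_center <- colMeans(blocks$basis_common$X)
    if (!is.null(blocks$basis_null)) {
      artifacts$null_center <- colMeans(blocks$basis_null$X)
    }
    blocks <- build_blocks(artifacts, table)
  }
  structure(list(y = table$yield,
                 weights = if (spec$use_weights &&
                               "weight_yield" %in% names(table))
                   table$weight_yield else NULL,
                 env = as.character(table$env),
                 genotype = as.character(table$genotype),
                 blocks = blocks, artifacts = artifacts,
                 spec = spec),
            class = "fb_design_bundle")
}

# Builds the per-row design blocks from compiled artifacts. Reused for
# prediction rows, so everything data-dependent lives in `artifacts`.
build_blocks <- function(artifacts, table) {
  spec <- artifacts$spec
  env <- factor(as.character(table$env), levels = artifacts$envs)
  if (anyNA(env)) stop("unknown environment: ",
                       paste(unique(table$env[is.na(env)]), collapse = ", "))
  gid <- match(as.character(table$genotype), artifacts$line_ids)
  n <- nrow(table)
  J_lines <- length(artifacts$line_ids)
  blocks <- list()

  Xe <- stats::model.matrix(~ 0 + env)
  colnames(Xe) <- artifacts$envs
  blocks$env <- list(name = "env", type = "fixed", X = Xe)

  Z <- matrix(0, n, J_lines)
  Z[cbind(seq_len(n), gid)] <- 1
  blocks$g <- list(name = "g", type = "ridge", X = Z %*% artifacts$Tg,
                   transform = artifacts$Tg)

  if (spec$has_gE) {
    XgE <- matrix(0, n, J_lines * length(artifacts$envs))
    for (i in seq_along(artifacts$envs)) {
      r <- which(env == artifacts$envs[i])
      cols <- (i - 1L) * J_lines + seq_len(J_lines)
      XgE[r, cols] <- blocks$g$X[r, ]
    }
    blocks$gE <- list(name = "gE", type = "ridge", X = XgE,
                      transform = artifacts$Tg)
  }

  if (spec$has_bands) {
    B <- as.matrix(table[, artifacts$band_cols, drop = FALSE])
    if (!is.null(artifacts$band_center)) {
      B <- sweep(sweep(B, 2, artifacts$band_center), 2,
                 artifacts$band_scale, "/")
    }
    blocks$band_common <- list(name = "band_common", type = "ridge", X = B)
    if (spec$has_bandxenv) {
      p <- ncol(B)
      Xi <- matrix(0, n, p * length(artifacts$envs))
      for (i in seq_along(artifacts$envs)) {
        r <- which(env == artifacts$envs[i])
        Xi[r, (i - 1L) * p + seq_len(p)] <- B[r, ]
      }
      blocks$band_by_env <- list(name = "band_by_env", type = "ridge",
                                 X = Xi)
    }
  }

  if (spec$functional) {
    curves <- fit_curve_coefficients(
      as.matrix(table[, artifacts$band_cols, drop = FALSE]),
      artifacts$wavelengths, artifacts$phi)
    des <- functional_design(curves, artifacts$J)
    des <- whiten_design(des, artifacts$penalty)
    if (!is.null(artifacts$score_center)) {
      des$scores <- sweep(des$scores, 2, artifacts$score_center)
    }
    null_sc <- des$null_scores
    if (!is.null(null_sc) && !is.null(artifacts$null_center)) {
      null_sc <- sweep(null_sc, 2, artifacts$null_center)
    }
    S <- ncol(des$scores)
    blocks$basis_common <- list(name = "basis_common", type = "ridge",
                                X = des$scores, unwhiten = des$unwhiten,
                                null_basis = des$null_basis)
    if (!is.null(null_sc)) {
      # penalty null-space directions (constant/linear coefficient
      # functions) carry no roughness information: unpenalized columns
      blocks$basis_null <- list(name = "basis_null", type = "fixed",
                                X = null_sc)
    }
    if (spec$has_bandxenv) {
      Xi <- matrix(0, n, S * length(artifacts$envs))
      for (i in seq_along(artifacts$envs)) {
        r <- which(env == artifacts$envs[i])
        Xi[r, (i - 1L) * S + seq_len(S)] <- des$scores[r, ]
      }
      blocks$basis_by_env <- list(name = "basis_by_env", type = "ridge",
                                  X = Xi, unwhiten = des$unwhiten,
                                  null_basis = des$null_basis)
      if (!is.null(null_sc)) {
        k <- ncol(null_sc)
        Xn <- matrix(0, n, k * length(artifacts$envs))
        for (i in seq_along(artifacts$envs)) {
          r <- which(env == artifacts$envs[i])
          Xn[r, (i - 1L) * k + seq_len(k)] <- null_sc[r, ]
        }
        blocks$basis_null_by_env <- list(name = "basis_null_by_env",
                                         type = "fixed", X = Xn)
      }
    }
  }
  blocks
}

#' @export
print.fb_design_bundle <- function(x, ...) {
  cat(sprintf("<fb_design_bundle> %s/%s: %d rows, blocks: %s\n",
              x$spec$model_id, x$spec$mode, length(x$y),
              paste(sprintf("%s[%d]", names(x$blocks),
                            vapply(x$blocks, function(b) ncol(b$X),
                                   integer(1))),
                    collapse = " ")))
  invisible(x)
}
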