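# Relationship matrices for the line effect and its interaction with
# environments: marker QC, the genomic matrix G = WW'/m, the pedigree
# additive matrix A (tabular method), and the (K x I) interaction
# covariance used by the G x E / A x E terms.

#' Marker quality control
#'
#' Applies, in order: (1) drop markers with more than 30% missing calls,
#' (2) impute remaining missing calls with the marker (column) mean,
#' (3) drop markers with minor allele frequency strictly below the
#' threshold (computed from the imputed dosages, boundary retained).
#'
#' @param dosages Numeric matrix of allele dosages in `{0, 1, 2}` with
#'   `NA` for missing, lines in rows; row names are line ids.
#' @param max_missing Maximum tolerated missing fraction (default 0.30).
#' @param min_maf Minor-allele-frequency threshold (default 0.05);
#'   markers with MAF `< min_maf` are removed.
#' @return Object of class `fb_markers`: the filtered, imputed dosage
#'   matrix plus per-filter counts in attribute `qc_counts`.
#' @export
qc_markers <- function(dosages, max_missing = 0.30, min_maf = 0.05) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("L", seq_len(nrow(dosages)))
  }
  ok_range <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok_range)) stop("dosages must be 0, 1, 2 or NA")
  miss_frac <- colMeans(is.na(dosages))
  keep1 <- miss_frac <= max_missing
  W <- dosages[, keep1, drop = FALSE]
  # mean imputation per marker
  for (k in which(colSums(is.na(W)) > 0)) {
    mu <- mean(W[, k], na.rm = TRUE)
    W[is.na(W[, k]), k] <- mu
  }
  p <- colMeans(W) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- maf >= min_maf
  W <- W[, keep2, drop = FALSE]
  if (ncol(W) == 0L) {
    stop("all markers removed by QC (missing filter removed ",
         sum(!keep1), ", MAF filter removed ", sum(!keep2), ")")
  }
  structure(W, class = c("fb_markers", "matrix", "array"),
            qc_counts = c(dropped_missing = sum(!keep1),
                          dropped_maf = sum(!keep2),
                          retained = ncol(W)))
}

#' Genomic relationship matrix
#'
#' `G = WW'/m`. By default dosage columns are centered by twice the
#' observed allele frequency (VanRaden-style) before the cross product;
#' set `center = FALSE` for the raw-dosage product.
#'
#' @param markers QC'd dosage matrix (lines x markers).
#' @param center Center columns by `2 * p_hat` first (default `TRUE`).
#' @return Object of class `fb_kinship` (list with `values`, `line_ids`,
#'   `source = "genomic"`).
#' @export
genomic_relationship <- function(markers, center = TRUE) {
  W <- unclass(as.matrix(markers))
  m <- ncol(W)
  if (m < 1L) stop("no markers available")
  if (center) W <- sweep(W, 2, colMeans(W))
  G <- tcrossprod(W) / m
  new_kinship((G + t(G)) / 2, rownames(W), "genomic")
}

new_kinship <- function(values, line_ids, source) {
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  dimnames(values) <- list(line_ids, line_ids)
  structure(list(values = values, line_ids = line_ids, source = source),
            class = "fb_kinship")
}

#' Identity kinship (no marker or pedigree information)
#'
#' @param line_ids Character vector of line identifiers.
#' @return `fb_kinship` with an identity relationship matrix.
#' @export
identity_kinship <- function(line_ids) {
  new_kinship(diag(length(line_ids)), line_ids, "identity")
}

#' @export
print.fb_kinship <- function(x, ...) {
  cat(sprintf("<fb_kinship> %s relationship matrix, %d lines\n",
              x$source, length(x$line_ids)))
  invisible(x)
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix A (twice the coefficient
#' of parentage) by the tabular method, handling inbreeding, with
#' unknown parents coded as `NA`, `""` or `"0"`.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`.
#' @return `fb_kinship` with `source = "pedigree"`, rows ordered as the
#'   topologically sorted pedigree but reported in input id order.
#' @export
pedigree_A <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  names(ped)[1:3] <- c("id", "sire", "dam")
  ped$id <- as.character(ped$id)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA") | is.na(x)] <- NA_character_
    x
  }
  ped$sire <- clean(ped$sire); ped$dam <- clean(ped$dam)
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  unknown_parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(unknown_parents)) {
    ped <- rbind(data.frame(id = unknown_parents, sire = NA_character_,
                            dam = NA_character_), ped)
  }
  # topological sort (parents before offspring); detects cycles
  n <- nrow(ped)
  order_idx <- integer(0)
  placed <- logical(n); names(placed) <- ped$id
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      s <- ped$sire[i]; d <- ped$dam[i]
      (is.na(s) || placed[s]) && (is.na(d) || placed[d])
    }, logical(1))
    if (!any(ready)) {
      stop("pedigree contains a cycle involving: ",
           paste(ped$id[remaining], collapse = ", "))
    }
    order_idx <- c(order_idx, remaining[ready])
    placed[ped$id[remaining[ready]]] <- TRUE
    remaining <- remaining[!ready]
  }
  ped <- ped[order_idx, ]
  idx <- stats::setNames(seq_len(n), ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    si <- if (is.na(s)) 0L else idx[[s]]
    di <- if (is.na(d)) 0L else idx[[d]]
    for (j in seq_len(i - 1L)) {
      a <- 0
      if (si > 0L) a <- a + 0.5 * A[j, si]
      if (di > 0L) a <- a + 0.5 * A[j, di]
      A[i, j] <- A[j, i] <- a
    }
    f <- if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
    A[i, i] <- 1 + f
  }
  keep <- idx[as.character(pedigree[[1]])]
  new_kinship(A[keep, keep, drop = FALSE], as.character(pedigree[[1]]),
              "pedigree")
}

#' Interaction covariance structure for K x E terms
#'
#' Describes the covariance of the stacked genotype-by-environment
#' interaction effects: effects of cells `(line j, env i)` and
#' `(line j', env i')` have covariance `K[j, j'] * 1[i == i'] * sigma2`,
#' i.e. the Kronecker structure `(K %x% I)` under line-major ordering
#' with environment varying fastest.
#'
#' @param kinship An `fb_kinship`.
#' @param envs Character vector of environment labels.
#' @return Object of class `fb_interaction` with the base kinship, the
#'   environments, and the cell ordering.
#' @export
interaction_cov <- function(kinship, envs) {
  stopifnot(inherits(kinship, "fb_kinship"))
  envs <- unique(as.character(envs))
  cells <- data.frame(
    line = rep(kinship$line_ids, each = length(envs)),
    env = rep(envs, times = length(kinship$line_ids)),
    stringsAsFactors = FALSE)
  structure(list(kinship = kinship, envs = envs, cells = cells),
            class = "fb_interaction")
}

#' Dense covariance matrix of an interaction structure
#'
#' Materializes the full cell-level covariance `(K %x% I_I) * sigma2`.
#' Intended for small problems and testing; model fitting works from the
#' factorized form instead.
#'
#' @param x An `fb_interaction`.
#' @param sigma2 Interaction variance component (default 1).
#' @return Symmetric matrix over the cells in `x$cells` order.
#' @export
interaction_matrix <- function(x, sigma2 = 1) {
  stopifnot(inherits(x, "fb_interaction"))
  kronecker(x$kinship$values, diag(length(x$envs))) * sigma2
}

#' Ensure a kinship matrix is positive definite
#'
#' Adds an increasing diagonal jitter (starting at
#' `1e-8 * trace / n`, multiplied by 10 on each failure) until a
#' Cholesky factorization succeeds.
#'
#' @param kinship An `fb_kinship`.
#' @param max_rel Maximum tolerated jitter relative to the mean diagonal
#'   (default 1e-2); exceeding it is an error.
#' @return The kinship with jitter applied; attribute `jitter` records
#'   the amount added (0 if already PD).
#' @export
ensure_pd <- function(kinship, max_rel = 1e-2) {
  stopifnot(inherits(kinship, "fb_kinship"))
  K <- kinship$values
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("kinship matrix must be symmetric")
  }
  mean_diag <- mean(diag(K))
  jitter <- 0
  step <- 1e-8 * mean_diag
  repeat {
    ok <- tryCatch({ chol(K + jitter * diag(nrow(K))); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    jitter <- if (jitter == 0) step else jitter * 10
    if (jitter > max_rel * mean_diag) {
      stop("jitter needed to reach positive definiteness exceeds ",
           max_rel, " of the mean diagonal")
    }
  }
  if (jitter > 0) kinship$values <- K + jitter * diag(nrow(K))
  attr(kinship, "jitter") <- jitter
  kinship
}
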