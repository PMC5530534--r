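# Synthetic multi-environment trial generator: pedigree and markers by
# gene dropping, heritable reflectance curves, and alpha-lattice plot
# data in which yield responds to genetic, genotype-by-environment and
# functional band effects. Every simulated effect is exported as ground
# truth so recovery can be checked.

#' Simulation configuration
#'
#' Defaults describe a desk-scale trial that preserves the structure of
#' a large multi-environment wheat experiment: 3 environments, trials
#' laid out as alpha-lattices with 3 replicates of 6 incomplete blocks
#' of 5 plots (30 entries per trial: 28 unique lines plus 2 shared
#' checks), reflectance in 100 bands on the 392 to 851 nm interval at one
#' time-point. Variance components are in (t/ha)^2. The functional
#' signal is specified by target contribution variances: the fixed
#' smooth coefficient curves are rescaled so the common functional term
#' and the environment-specific functional term have (approximately)
#' variance `sigma_f2` and `sigma_fE2` across cells.
#'
#' @param n_envs Number of environments.
#' @param n_trials Trials per environment.
#' @param n_reps,blocks_per_rep,block_size Alpha-lattice layout.
#' @param n_checks Check entries repeated in every trial.
#' @param n_lines Number of experimental lines; defaults to
#'   `n_trials * (blocks_per_rep * block_size - n_checks)`.
#' @param n_bands,band_domain,n_timepoints Reflectance grid.
#' @param env_means Fixed environment means (t/ha).
#' @param sigma_L2,sigma_gE2 Line and line-by-environment variances.
#' @param sigma_r2,sigma_t2,sigma_b2,sigma_e2 Replicate, trial, block
#'   and plot-residual variances (used in every environment).
#' @param sigma_f2,sigma_fE2 Target variances of the common and
#'   environment-specific functional band contributions.
#' @param curve_sd Scale of the heritable smooth curve deviations
#'   (reflectance units).
#' @param curve_noise Plot-level reflectance noise sd.
#' @param n_founders,n_markers Pedigree/marker simulation.
#' @param seed Integer master seed; genetics, curves and design noise
#'   use independent sub-streams derived from it.
#' @return Object of class `fb_sim_config`.
#' @export
sim_config <- function(n_envs = 3L, n_trials = 10L, n_reps = 3L,
                       blocks_per_rep = 6L, block_size = 5L,
                       n_checks = 2L, n_lines = NULL,
                       n_bands = 100L, band_domain = c(392, 851),
                       n_timepoints = 1L,
                       env_means = NULL,
                       sigma_L2 = 0.25, sigma_gE2 = 0.15,
                       sigma_r2 = 0.05, sigma_t2 = 0.10,
                       sigma_b2 = 0.05, sigma_e2 = 0.25,
                       sigma_f2 = 0.20, sigma_fE2 = 0.15,
                       curve_sd = 0.02, curve_noise = 0.01,
                       n_founders = 40L, n_markers = 600L,
                       seed = 1L) {
  entries <- blocks_per_rep * block_size
  lines_per_trial <- entries - n_checks
  if (lines_per_trial < 1L) stop("layout leaves no room for lines")
  if (is.null(n_lines)) n_lines <- n_trials * lines_per_trial
  if (n_lines > n_trials * lines_per_trial) {
    stop("layout infeasible: ", n_lines, " lines exceed ",
         n_trials, " trials x ", lines_per_trial, " lines")
  }
  if (is.null(env_means)) env_means <- seq(4, 6, length.out = n_envs)
  cfg <- as.list(environment())
  cfg$entries <- entries
  cfg$lines_per_trial <- lines_per_trial
  structure(cfg, class = "fb_sim_config")
}

# Full-scale configuration of the emulated experiment: 976 genotyped
# lines drawn from 39 trials of 28 lines, 250 bands, 9 time-points.
#' @rdname sim_config
#' @export
full_scale_config <- function(seed = 1L) {
  sim_config(n_trials = 39L, n_lines = 976L, n_bands = 250L,
             n_timepoints = 9L, seed = seed)
}

sub_seed <- function(seed, k) (as.integer(seed) * 7L + k * 1013L) %% 2000000011L

#' Simulate a pedigree and marker matrix by gene dropping
#'
#' Founders get allele frequencies uniform on (0.05, 0.5); later
#' individuals are produced by mating two random distinct earlier
#' individuals and dropping one allele per parent per marker. Missing
#' calls and markers destined to fail QC (high missingness, very low
#' MAF) are injected so the QC filters are exercised.
#'
#' @param config An `fb_sim_config`.
#' @return List with `pedigree` (data frame id/sire/dam), `dosages`
#'   (raw marker matrix with `NA`s), and `haplotypes` (internal).
#' @export
simulate_pedigree_markers <- function(config) {
  set.seed(sub_seed(config$seed, 1L))
  n <- config$n_lines; m <- config$n_markers
  nf <- min(config$n_founders, n)
  p <- stats::runif(m, 0.05, 0.5)
  ids <- sprintf("L%04d", seq_len(n))
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  sire <- rep(NA_character_, n); dam <- rep(NA_character_, n)
  H1[1:nf, ] <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  H2[1:nf, ] <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  if (n > nf) {
    for (i in (nf + 1L):n) {
      par <- sample.int(i - 1L, 2L)
      sire[i] <- ids[par[1]]; dam[i] <- ids[par[2]]
      pick1 <- stats::runif(m) < 0.5
      pick2 <- stats::runif(m) < 0.5
      H1[i, ] <- ifelse(pick1, H1[par[1], ], H2[par[1], ])
      H2[i, ] <- ifelse(pick2, H1[par[2], ], H2[par[2], ])
    }
  }
  dos <- H1 + H2
  rownames(dos) <- ids
  colnames(dos) <- sprintf("M%04d", seq_len(m))
  # inject missingness and QC-failing markers
  miss <- matrix(stats::runif(n * m) < 0.02, n, m)
  dos[miss] <- NA_integer_
  bad <- sample.int(m, min(3L, m))
  for (k in bad) dos[stats::runif(n) < 0.4, k] <- NA_integer_
  mono <- sample.int(m, min(3L, m))
  dos[, mono] <- 0L
  dos[sample.int(n, 1L), mono] <- 1L   # MAF well below threshold
  list(pedigree = data.frame(id = ids, sire = sire, dam = dam,
                             stringsAsFactors = FALSE),
       dosages = dos)
}

# Smooth mean reflectance: green peak plus red-edge sigmoid, with a
# mild time-point trend.
mean_reflectance <- function(k, tp = 1L, n_tp = 1L) {
  trend <- 1 + 0.05 * (tp - (n_tp + 1) / 2)
  0.05 + 0.25 * exp(-((k - 550) / 60)^2) +
    0.35 * trend / (1 + exp(-(k - 710) / 15))
}

#' Simulate heritable reflectance curves
#'
#' Each line-by-environment cell curve is the smooth mean reflectance
#' plus a small environment offset plus a line-specific smooth
#' deviation whose basis coefficients are drawn with covariance
#' proportional to the kinship (so curve differences are heritable).
#' Values are clipped to the unit interval.
#'
#' @param config An `fb_sim_config`.
#' @param kinship `fb_kinship` over the simulated lines.
#' @return List with `wavelengths` and `curves`, a list (by time-point)
#'   of `n_lines * n_envs` x `n_bands` matrices of noise-free cell
#'   curves, rows ordered env-within-line.
#' @export
simulate_curves <- function(config, kinship) {
  set.seed(sub_seed(config$seed, 2L))
  wl <- seq(config$band_domain[1], config$band_domain[2],
            length.out = config$n_bands)
  n <- config$n_lines; I <- config$n_envs
  dev_basis <- build_basis("bspline", config$band_domain, 7L)
  Phi <- evaluate_basis(dev_basis, wl)
  Kc <- kernel_sqrt(kinship$values)
  cell_line <- rep(seq_len(n), each = I)
  cell_env <- rep(seq_len(I), times = n)
  env_offset <- seq(-0.01, 0.01, length.out = I)
  curves <- lapply(seq_len(config$n_timepoints), function(tp) {
    C_line <- Kc %*% matrix(stats::rnorm(n * dev_basis$size, 0,
                                         config$curve_sd),
                            n, dev_basis$size)
    # small non-heritable env-specific wiggle per line
    C_cell <- matrix(stats::rnorm(n * I * dev_basis$size, 0,
                                  config$curve_sd / 4),
                     n * I, dev_basis$size)
    base <- matrix(mean_reflectance(wl, tp, config$n_timepoints),
                   n * I, config$n_bands, byrow = TRUE)
    dev <- (C_line[cell_line, , drop = FALSE] + C_cell) %*% t(Phi) * 10
    out <- base + dev + env_offset[cell_env]
    pmin(pmax(out, 0), 1)
  })
  list(wavelengths = wl, curves = curves,
       cell_line = cell_line, cell_env = cell_env)
}

# True smooth coefficient curves: a fixed shape for the common effect
# and environment-contrasting shapes for the interaction, rescaled so
# the realized cell-level contributions hit the configured variances.
true_beta_curves <- function(config, wl, curves) {
  a <- config$band_domain[1]; b <- config$band_domain[2]
  u <- (wl - a) / (b - a)
  beta1_raw <- sin(2 * pi * u) + 0.5 * u
  I <- config$n_envs
  beta2_raw <- sapply(seq_len(I), function(i) {
    cos(2 * pi * u + 2 * pi * (i - 1) / I) * (1 + 0.3 * u)
  })
  beta2_raw <- beta2_raw - rowMeans(beta2_raw)  # centered across envs
  q <- simpson_weights_grid(wl)
  f1_raw <- drop(curves %*% (q * beta1_raw))
  s1 <- stats::sd(f1_raw)
  scale1 <- if (s1 > 0 && config$sigma_f2 > 0)
    sqrt(config$sigma_f2) / s1 else 0
  list(beta1 = beta1_raw * scale1, beta2_raw = beta2_raw, quad = q)
}

# Composite-Simpson weights on an (odd-length preferred) grid; falls
# back to trapezoid weights for even-length grids.
simpson_weights_grid <- function(x) {
  m <- length(x)
  h <- (x[m] - x[1]) / (m - 1)
  if (m %% 2L == 1L) {
    w <- rep(c(2, 4), length.out = m); w[c(1L, m)] <- 1
    w * h / 3
  } else {
    w <- rep(h, m); w[c(1L, m)] <- h / 2
    w
  }
}

#' Simulate an alpha-lattice multi-environment trial
#'
#' Plot yield is built from Eq.-style components: environment mean,
#' line effect `g ~ N(0, K sigma_L2)`, interaction
#' `gE ~ N(0, (K x I) sigma_gE2)`, the functional contributions
#' `int x_ij(k) beta1(k) dk` and `int x_ij(k) beta2_i(k) dk` of the
#' cell's reflectance curve, plus replicate, trial, block and plot
#' errors with environment-specific draws. Band columns carry the cell
#' curve plus plot-level noise.
#'
#' @param config An `fb_sim_config`.
#' @param kinship `fb_kinship` over the lines.
#' @param curves Result of [simulate_curves()].
#' @return List with `plot_table` (a `FieldTrialTable` data frame) and
#'   `truth` (all simulated effects and coefficient curves).
#' @export
simulate_trial <- function(config, kinship, curves) {
  set.seed(sub_seed(config$seed, 3L))
  n <- config$n_lines; I <- config$n_envs
  wl <- curves$wavelengths
  ids <- kinship$line_ids
  Kc <- kernel_sqrt(kinship$values)
  g <- drop(Kc %*% stats::rnorm(n)) * sqrt(config$sigma_L2)
  gE <- Kc %*% matrix(stats::rnorm(n * I), n, I) * sqrt(config$sigma_gE2)

  tb <- true_beta_curves(config, wl, curves$curves[[1]])
  q <- tb$quad
  # common functional contribution per cell/timepoint (cells: env within line)
  f1 <- lapply(curves$curves, function(M) drop(M %*% (q * tb$beta1)))
  # env-specific: scale raw shapes to the target variance
  f2_raw <- lapply(curves$curves, function(M) {
    vapply(seq_len(nrow(M)), function(r) {
      sum(M[r, ] * q * tb$beta2_raw[, curves$cell_env[r]])
    }, numeric(1))
  })
  s2 <- stats::sd(f2_raw[[1]])
  scale2 <- if (s2 > 0 && config$sigma_fE2 > 0)
    sqrt(config$sigma_fE2) / s2 else 0
  beta2 <- tb$beta2_raw * scale2
  f2 <- lapply(f2_raw, function(v) v * scale2)

  # layout: lines assigned to trials in order; checks shared
  checks <- if (config$n_checks > 0) sprintf("CHK%d", seq_len(config$n_checks))
            else character(0)
  trial_of_line <- rep(seq_len(config$n_trials),
                       each = config$lines_per_trial)[seq_len(n)]
  env_labels <- sprintf("Env%d", seq_len(I))
  rows <- vector("list", I)
  for (i in seq_len(I)) {
    r_eff <- stats::rnorm(config$n_trials * config$n_reps, 0,
                          sqrt(config$sigma_r2))
    t_eff <- stats::rnorm(config$n_trials, 0, sqrt(config$sigma_t2))
    b_eff <- stats::rnorm(config$n_trials * config$n_reps *
                            config$blocks_per_rep, 0,
                          sqrt(config$sigma_b2))
    trial_rows <- list()
    for (tr in seq_len(config$n_trials)) {
      entries <- c(ids[trial_of_line == tr], checks)
      for (rp in seq_len(config$n_reps)) {
        perm <- sample(entries)
        blk <- rep(seq_len(config$blocks_per_rep),
                   each = config$block_size)[seq_along(perm)]
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          env = env_labels[i], trial = tr, rep = rp, block = blk,
          genotype = perm, stringsAsFactors = FALSE)
      }
    }
    tabi <- do.call(rbind, trial_rows)
    gi <- match(tabi$genotype, ids)            # NA for checks
    cell <- (gi - 1L) * I + i                  # env-within-line index
    is_chk <- is.na(gi)
    chk_eff <- stats::setNames(stats::rnorm(length(checks), 0,
                                            sqrt(config$sigma_L2)), checks)
    gen_eff <- ifelse(is_chk, chk_eff[tabi$genotype], g[gi])
    ge_eff <- ifelse(is_chk, 0, gE[cbind(gi, i)])
    func1 <- func2 <- numeric(nrow(tabi))
    func1[!is_chk] <- f1[[1]][cell[!is_chk]]
    func2[!is_chk] <- f2[[1]][cell[!is_chk]]
    # checks get the environment mean curve's contribution
    mean_curve <- mean_reflectance(wl, 1L, config$n_timepoints)
    func1[is_chk] <- sum(mean_curve * q * tb$beta1)
    func2[is_chk] <- sum(mean_curve * q * beta2[, i])
    rep_idx <- (tabi$trial - 1L) * config$n_reps + tabi$rep
    blk_idx <- (rep_idx - 1L) * config$blocks_per_rep + tabi$block
    eps <- stats::rnorm(nrow(tabi), 0, sqrt(config$sigma_e2))
    tabi$yield <- config$env_means[i] + gen_eff + ge_eff + func1 + func2 +
      r_eff[rep_idx] + t_eff[tabi$trial] + b_eff[blk_idx] + eps
    # band columns (all time-points), cell curve + plot noise
    for (tp in seq_len(config$n_timepoints)) {
      M <- matrix(mean_reflectance(wl, tp, config$n_timepoints),
                  nrow(tabi), length(wl), byrow = TRUE)
      M[!is_chk, ] <- curves$curves[[tp]][cell[!is_chk], , drop = FALSE]
      M <- M + matrix(stats::rnorm(length(M), 0, config$curve_noise),
                      nrow(M), ncol(M))
      colnames(M) <- sprintf("band_%s_t%d", format(round(wl, 1),
                                                   trim = TRUE), tp)
      tabi <- cbind(tabi, M)
    }
    rows[[i]] <- tabi
  }
  plot_table <- do.call(rbind, rows)
  rownames(plot_table) <- NULL
  truth <- list(g = stats::setNames(g, ids),
                gE = structure(gE, dimnames = list(ids, env_labels)),
                env_means = stats::setNames(config$env_means, env_labels),
                beta1 = tb$beta1, beta2 = beta2, wavelengths = wl,
                f_common = f1, f_env = f2,
                cell_line = curves$cell_line, cell_env = curves$cell_env,
                varcomps = config[c("sigma_L2", "sigma_gE2", "sigma_r2",
                                    "sigma_t2", "sigma_b2", "sigma_e2")])
  list(plot_table = plot_table, truth = truth)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: pedigree and markers, marker QC, genomic and
#' pedigree kinships, heritable curves, and the plot-level trial table.
#'
#' @param config An `fb_sim_config`.
#' @return List with `plot_table`, `truth`, `pedigree`, `dosages`
#'   (raw), `markers` (QC'd), `G`, `A`, and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  pm <- simulate_pedigree_markers(config)
  markers <- qc_markers(pm$dosages)
  G <- ensure_pd(genomic_relationship(markers))
  A <- pedigree_A(pm$pedigree)
  curves <- simulate_curves(config, G)
  tr <- simulate_trial(config, G, curves)
  c(tr, list(pedigree = pm$pedigree, dosages = pm$dosages,
             markers = markers, G = G, A = A, config = config))
}

#' Simulate second-stage (cell-level) data directly
#'
#' Generates the adjusted line-mean table that the second-stage models
#' consume, bypassing the plot level: one row per environment x line
#' with `yield = E_i + g_j + gE_ij + f1_ij + f2_ij + gamma_ij`,
#' `gamma ~ N(0, sigma_gamma2)`, unit-information weights
#' `1/sigma_gamma2`, and band columns equal to the cell curves plus
#' small measurement noise. Used for fast model-level studies where
#' the first-stage adjustment is not itself under test.
#'
#' @param config An `fb_sim_config`.
#' @param kinship Optional `fb_kinship`; simulated genomically if
#'   omitted.
#' @param sigma_gamma2 Residual variance of the cell means
#'   (default 0.1).
#' @return List with `table` (second-stage data frame), `truth`,
#'   `kinship` and `config`.
#' @export
simulate_second_stage <- function(config = sim_config(),
                                  kinship = NULL, sigma_gamma2 = 0.1) {
  if (is.null(kinship)) {
    pm <- simulate_pedigree_markers(config)
    kinship <- ensure_pd(genomic_relationship(qc_markers(pm$dosages)))
  }
  curves <- simulate_curves(config, kinship)
  set.seed(sub_seed(config$seed, 4L))
  n <- config$n_lines; I <- config$n_envs
  ids <- kinship$line_ids
  Kc <- kernel_sqrt(kinship$values)
  g <- drop(Kc %*% stats::rnorm(n)) * sqrt(config$sigma_L2)
  gE <- Kc %*% matrix(stats::rnorm(n * I), n, I) * sqrt(config$sigma_gE2)
  wl <- curves$wavelengths
  tb <- true_beta_curves(config, wl, curves$curves[[1]])
  q <- tb$quad
  f1 <- drop(curves$curves[[1]] %*% (q * tb$beta1))
  f2_raw <- vapply(seq_len(n * I), function(r) {
    sum(curves$curves[[1]][r, ] * q * tb$beta2_raw[, curves$cell_env[r]])
  }, numeric(1))
  s2 <- stats::sd(f2_raw)
  scale2 <- if (s2 > 0 && config$sigma_fE2 > 0)
    sqrt(config$sigma_fE2) / s2 else 0
  beta2 <- tb$beta2_raw * scale2
  gamma <- stats::rnorm(n * I, 0, sqrt(sigma_gamma2))
  env_labels <- sprintf("Env%d", seq_len(I))
  yield <- config$env_means[curves$cell_env] + g[curves$cell_line] +
    gE[cbind(curves$cell_line, curves$cell_env)] + f1 +
    f2_raw * scale2 + gamma
  tab <- data.frame(env = env_labels[curves$cell_env],
                    genotype = ids[curves$cell_line],
                    yield = yield,
                    weight_yield = rep(1 / sigma_gamma2, n * I),
                    stringsAsFactors = FALSE)
  for (tp in seq_len(config$n_timepoints)) {
    M <- curves$curves[[tp]] +
      matrix(stats::rnorm(n * I * length(wl), 0, 0.002), n * I, length(wl))
    colnames(M) <- sprintf("band_%s_t%d", format(round(wl, 1), trim = TRUE),
                           tp)
    tab <- cbind(tab, M)
  }
  truth <- list(g = stats::setNames(g, ids),
                gE = structure(gE, dimnames = list(ids, env_labels)),
                beta1 = tb$beta1, beta2 = beta2, wavelengths = wl,
                f_common = f1, f_env = f2_raw * scale2, gamma = gamma)
  list(table = tab, truth = truth, kinship = kinship, config = config)
}
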