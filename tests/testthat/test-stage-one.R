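# First-stage REML + GLS adjustment, checked against closed-form
# balanced-design results, a dense GLS oracle, the REML criterion
# itself, and lme4's own fixed-effect estimates.

make_env_table <- function(seed = 3, n_geno = 8, n_trials = 2, n_reps = 2,
                           blocks = 2, effects = TRUE) {
  set.seed(seed)
  g_eff <- rnorm(n_geno, 5, 0.5)
  rows <- expand.grid(genotype = paste0("L", seq_len(n_geno)),
                      rep = seq_len(n_reps), trial = seq_len(n_trials),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$block <- 1 + (match(rows$genotype, unique(rows$genotype)) - 1) %/%
    ceiling(n_geno / blocks)
  rows$env <- "E1"
  mu <- g_eff[match(rows$genotype, paste0("L", seq_len(n_geno)))]
  if (effects) {
    t_eff <- rnorm(n_trials, 0, 0.3)
    r_eff <- rnorm(n_trials * n_reps, 0, 0.2)
    b_eff <- rnorm(n_trials * n_reps * blocks, 0, 0.2)
    mu <- mu + t_eff[rows$trial] +
      r_eff[(rows$trial - 1) * n_reps + rows$rep] +
      b_eff[((rows$trial - 1) * n_reps + rows$rep - 1) * blocks + rows$block]
  }
  rows$yield <- mu + rnorm(nrow(rows), 0, 0.3)
  rows
}

test_that("balanced design with iid errors gives means and n/sigma2 weights", {
  tab <- make_env_table(effects = FALSE)
  vc <- list(sigma_r2 = 0, sigma_t2 = 0, sigma_b2 = 0, sigma_e2 = 0.09)
  res <- blues(tab, "yield", vc)
  means <- tapply(tab$yield, tab$genotype, mean)
  expect_equal(drop(res$blues[, "yield"]), means[rownames(res$blues)],
               ignore_attr = TRUE, tolerance = 1e-10)
  n_per <- table(tab$genotype)
  expect_equal(res$weights,
               stats::setNames(as.numeric(n_per[names(res$weights)]) / 0.09,
                               names(res$weights)),
               tolerance = 1e-10)
})

test_that("GLS solution matches a dense-matrix oracle", {
  tab <- make_env_table(seed = 17)
  vc <- list(sigma_r2 = 0.04, sigma_t2 = 0.09, sigma_b2 = 0.02,
             sigma_e2 = 0.1)
  res <- blues(tab, "yield", vc)

  td <- funbandr:::add_design_factors(tab)
  Zr <- model.matrix(~ 0 + rep_id, td)
  Zt <- model.matrix(~ 0 + trial_id, td)
  Zb <- model.matrix(~ 0 + block_id, td)
  Sigma <- 0.1 * diag(nrow(td)) + 0.04 * tcrossprod(Zr) +
    0.09 * tcrossprod(Zt) + 0.02 * tcrossprod(Zb)
  X <- model.matrix(~ 0 + genotype, td)
  Si <- solve(Sigma)
  C <- t(X) %*% Si %*% X
  mu <- solve(C, t(X) %*% Si %*% td$yield)
  expect_lt(max(abs(res$blues[, "yield"] - drop(mu))) / max(abs(mu)), 1e-8)
  expect_equal(unname(res$weights), unname(diag(C)), tolerance = 1e-8)
})

test_that("BLUEs are shift-equivariant and weights are shift-invariant", {
  tab <- make_env_table(seed = 23)
  vc <- list(sigma_r2 = 0.04, sigma_t2 = 0.09, sigma_b2 = 0.02,
             sigma_e2 = 0.1)
  res <- blues(tab, "yield", vc)
  tab2 <- tab; tab2$yield <- tab$yield + 3.7
  res2 <- blues(tab2, "yield", vc)
  expect_equal(res2$blues[, "yield"], res$blues[, "yield"] + 3.7,
               tolerance = 1e-9)
  expect_equal(res2$weights, res$weights, tolerance = 1e-10)
})

test_that("REML estimates maximize the restricted likelihood", {
  tab <- make_env_table(seed = 31, n_geno = 10, n_trials = 3, n_reps = 3)
  vc <- reml_varcomps(tab)
  expect_true(all(unlist(vc) >= 0))
  expect_gt(vc$sigma_e2, 0)

  # dense restricted log-likelihood at a variance-component vector
  td <- funbandr:::add_design_factors(tab)
  X <- model.matrix(~ 0 + genotype, td)
  Zr <- model.matrix(~ 0 + rep_id, td)
  Zt <- model.matrix(~ 0 + trial_id, td)
  Zb <- model.matrix(~ 0 + block_id, td)
  reml_ll <- function(v) {
    Sigma <- v[4] * diag(nrow(td)) + v[1] * tcrossprod(Zr) +
      v[2] * tcrossprod(Zt) + v[3] * tcrossprod(Zb)
    Si <- solve(Sigma)
    C <- t(X) %*% Si %*% X
    mu <- solve(C, t(X) %*% Si %*% td$yield)
    r <- td$yield - drop(X %*% mu)
    -0.5 * (determinant(Sigma)$modulus + determinant(C)$modulus +
              drop(t(r) %*% Si %*% r))
  }
  v_hat <- unlist(vc)
  ll_hat <- reml_ll(v_hat)
  # perturbing any nonzero component in either direction cannot improve
  for (k in 1:4) {
    for (f in c(0.7, 1.4)) {
      v <- v_hat
      v[k] <- v[k] * f + (v[k] == 0) * 0.01
      expect_lt(reml_ll(v), ll_hat + 1e-6)
    }
  }
})

test_that("variance components are near zero when effects are absent", {
  set.seed(47)
  reps <- replicate(5, {
    tab <- make_env_table(seed = sample.int(1e6, 1), n_geno = 12,
                          n_trials = 3, n_reps = 3, effects = FALSE)
    unlist(reml_varcomps(tab))
  })
  # mean across replicates: design variances small, residual near 0.09
  m <- rowMeans(reps)
  expect_lt(m["sigma_r2"], 0.03)
  expect_lt(m["sigma_t2"], 0.03)
  expect_lt(m["sigma_b2"], 0.03)
  expect_equal(unname(m["sigma_e2"]), 0.09, tolerance = 0.15)
})

test_that("GLS BLUEs at REML components equal lme4 fixed effects", {
  tab <- make_env_table(seed = 53)
  vc <- reml_varcomps(tab)
  res <- blues(tab, "yield", vc)
  td <- funbandr:::add_design_factors(tab)
  td$.y <- td$yield
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(.y ~ 0 + genotype + (1 | rep_id) + (1 | trial_id) +
                 (1 | block_id), data = td, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  fe <- lme4::fixef(fit)
  names(fe) <- sub("^genotype", "", names(fe))
  expect_equal(res$blues[names(fe), "yield"], fe, tolerance = 1e-4)
})

test_that("band columns are detected and ordered within time points", {
  tab <- data.frame(band_700.5_t2 = 1, yield = 1, band_450_t1 = 1,
                    band_392_t2 = 1, band_851_t1 = 1, bandx_1_t1 = 1)
  expect_equal(band_columns(tab),
               c("band_450_t1", "band_851_t1", "band_392_t2",
                 "band_700.5_t2"))
  expect_equal(band_columns(data.frame(yield = 1)), character(0))
})

test_that("stage one assembles one row per environment-genotype cell", {
  exp <- small_experiment()
  ss <- small_second_stage()
  n_lines <- length(exp$truth$g)
  n_envs <- length(unique(exp$plot_table$env))
  expect_s3_class(ss, "fb_second_stage")
  expect_equal(nrow(ss), n_lines * n_envs)
  bands <- band_columns(exp$plot_table)
  expect_equal(names(ss), c("env", "genotype", "yield", "weight_yield",
                            bands))
  expect_false(any(grepl("^CHK", ss$genotype)))
  expect_true(all(ss$weight_yield > 0))
  expect_false(anyNA(ss))
  # every line appears exactly once per environment
  expect_true(all(table(ss$genotype, ss$env) == 1))
})

test_that("stage one validates its inputs", {
  tab <- make_env_table()
  expect_error(stage_one(tab[, setdiff(names(tab), "block")]), "block")
  vc <- list(sigma_r2 = 0, sigma_t2 = 0, sigma_b2 = 0, sigma_e2 = 1)
  tab_na <- tab; tab_na$yield[1] <- NA
  expect_error(blues(tab_na, "yield", vc), "missing")
  vc0 <- vc; vc0$sigma_e2 <- 0
  expect_error(blues(tab, "yield", vc0), "positive")
})
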