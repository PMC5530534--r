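# Catalogue of second-stage models: flag table, counterpart pairs, and
# compiled block structure for every model and relationship mode.

# small purpose-built table: 6 genotypes x 3 envs, p bands at one time
toy_table <- function(p = 12, seed = 99) {
  set.seed(seed)
  g <- paste0("L", 1:6)
  envs <- paste0("Env", 1:3)
  tab <- expand.grid(genotype = g, env = envs, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tab$yield <- rnorm(nrow(tab), 5)
  tab$weight_yield <- runif(nrow(tab), 5, 15)
  wl <- seq(392, 851, length.out = p)
  B <- matrix(runif(nrow(tab) * p), nrow(tab), p)
  colnames(B) <- sprintf("band_%s_t1", wl)
  cbind(tab, as.data.frame(B))
}

toy_kinship <- function(seed = 4) {
  set.seed(seed)
  W <- matrix(sample(0:2, 6 * 80, TRUE), 6, 80)
  rownames(W) <- paste0("L", 1:6)
  ensure_pd(genomic_relationship(W))
}

test_that("the catalogue pairs cover all fourteen models consistently", {
  sp <- spec_pairs()
  all_ids <- c(sp$no_bands, sp$pairs$conventional, sp$pairs$bspline,
               sp$pairs$fourier)
  expect_setequal(all_ids, paste0("M", 1:14))
  expect_equal(anyDuplicated(all_ids), 0L)
  for (r in seq_len(nrow(sp$pairs))) {
    mc <- model_spec(sp$pairs$conventional[r])
    mb <- model_spec(sp$pairs$bspline[r])
    mf <- model_spec(sp$pairs$fourier[r])
    expect_true(mc$has_bands && !mc$functional)
    expect_true(mb$functional && mb$basis_kind == "bspline")
    expect_true(mf$functional && mf$basis_kind == "fourier")
    # counterparts share the gE and band-by-env flags
    expect_equal(mb$has_gE, mc$has_gE)
    expect_equal(mf$has_gE, mc$has_gE)
    expect_equal(mb$has_bandxenv, mc$has_bandxenv)
    expect_equal(mf$has_bandxenv, mc$has_bandxenv)
  }
  for (id in sp$no_bands) {
    m <- model_spec(id)
    expect_false(m$has_bands || m$functional)
  }
  expect_error(model_spec("M15"), "unknown model")
})

test_that("compiled blocks have the documented structure for all models", {
  tab <- toy_table()
  kin <- toy_kinship()
  I <- 3L; J <- 6L; p <- 12L; S <- 7L
  for (id in paste0("M", 1:14)) {
    spec <- model_spec(id, "WG", L = 7, S = 7)
    d <- compile_design(spec, tab, kin)
    b <- d$blocks
    expect_equal(ncol(b$env$X), I)
    expect_equal(b$env$type, "fixed")
    expect_equal(ncol(b$g$X), J)
    expect_equal("gE" %in% names(b), spec$has_gE, info = id)
    if (spec$has_gE) expect_equal(ncol(b$gE$X), J * I)
    expect_equal("band_common" %in% names(b), spec$has_bands, info = id)
    if (spec$has_bands) expect_equal(ncol(b$band_common$X), p)
    expect_equal("band_by_env" %in% names(b),
                 spec$has_bands && spec$has_bandxenv, info = id)
    if (spec$has_bands && spec$has_bandxenv) {
      expect_equal(ncol(b$band_by_env$X), p * I)
    }
    expect_equal("basis_common" %in% names(b), spec$functional, info = id)
    if (spec$functional) expect_equal(ncol(b$basis_common$X), S)
    expect_equal("basis_by_env" %in% names(b),
                 spec$functional && spec$has_bandxenv, info = id)
    if (spec$functional && spec$has_bandxenv) {
      expect_equal(ncol(b$basis_by_env$X), S * I)
    }
    # cubic B-spline curvature penalties have a 2-dimensional null
    # space (constant and linear coefficient functions) carried as
    # unpenalized columns; the Fourier penalty is full rank
    expect_equal("basis_null" %in% names(b),
                 isTRUE(spec$basis_kind == "bspline"), info = id)
    if (isTRUE(spec$basis_kind == "bspline")) {
      expect_equal(ncol(b$basis_null$X), 2L)
      if (spec$has_bandxenv) {
        expect_equal(ncol(b$basis_null_by_env$X), 2L * I)
      }
    }
    # no other blocks exist
    expect_true(all(names(b) %in% c("env", "g", "gE", "band_common",
                                    "band_by_env", "basis_common",
                                    "basis_null", "basis_by_env",
                                    "basis_null_by_env")))
  }
})

test_that("conventional band-by-env model scales as p + I*p columns", {
  tab <- toy_table(p = 250)
  d <- compile_design(model_spec("M9", "WO"), tab)
  expect_equal(ncol(d$blocks$band_common$X), 250L)
  expect_equal(ncol(d$blocks$band_by_env$X), 750L)
})

test_that("kernel blocks realize the kinship covariance", {
  tab <- toy_table()
  kin <- toy_kinship()
  d <- compile_design(model_spec("M2", "WG"), tab, kin)
  Tg <- d$artifacts$Tg
  expect_equal(tcrossprod(Tg), kin$values, ignore_attr = TRUE,
               tolerance = 1e-10)
  # row covariance of the g design equals K between matching genotypes
  XXt <- tcrossprod(d$blocks$g$X)
  gid <- match(tab$genotype, kin$line_ids)
  expect_equal(XXt, kin$values[gid, gid], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("environment-specific blocks are zero outside their own env", {
  tab <- toy_table()
  kin <- toy_kinship()
  d <- compile_design(model_spec("M13", "WG", L = 7, S = 7), tab, kin)
  envs <- d$artifacts$envs
  for (i in seq_along(envs)) {
    other <- which(tab$env != envs[i])
    cols_gE <- (i - 1) * 6 + 1:6
    expect_true(all(d$blocks$gE$X[other, cols_gE] == 0))
    cols_f <- (i - 1) * 7 + 1:7
    expect_true(all(d$blocks$basis_by_env$X[other, cols_f] == 0))
    # inside the env, the slice equals the common block
    own <- which(tab$env == envs[i])
    expect_equal(d$blocks$gE$X[own, cols_gE], d$blocks$g$X[own, ])
    expect_equal(d$blocks$basis_by_env$X[own, cols_f],
                 d$blocks$basis_common$X[own, ])
  }
})

test_that("WO mode equals WG with an identity kinship, bit for bit", {
  tab <- toy_table()
  idk <- identity_kinship(paste0("L", 1:6))
  d_wo <- compile_design(model_spec("M4", "WO", L = 7, S = 7), tab)
  d_wg <- compile_design(model_spec("M4", "WG", L = 7, S = 7), tab, idk)
  for (nm in names(d_wo$blocks)) {
    expect_identical(d_wo$blocks[[nm]]$X, d_wg$blocks[[nm]]$X)
  }
})

test_that("compile validates kinship coverage and time points", {
  tab <- toy_table()
  expect_error(compile_design(model_spec("M1", "WG"), tab), "kinship")
  short <- toy_kinship()
  short$values <- short$values[1:4, 1:4]
  short$line_ids <- short$line_ids[1:4]
  expect_error(compile_design(model_spec("M1", "WG"), tab, short),
               "absent")
  # two time points require an explicit choice
  tab2 <- tab
  names(tab2) <- sub("_t1$", "_t2", names(tab2))
  both <- cbind(tab, tab2[, grep("_t2$", names(tab2))])
  expect_error(compile_design(model_spec("M3", "WO"), both), "time")
  d1 <- compile_design(model_spec("M3", "WO"), both, time_point = 2)
  expect_equal(length(d1$artifacts$band_cols), 12L)
  expect_true(all(grepl("_t2$", d1$artifacts$band_cols)))
})

test_that("identity penalty mode leaves functional scores unwhitened", {
  tab <- toy_table()
  sp <- model_spec("M5", "WO", L = 7, S = 7, penalty_mode = "identity")
  d <- compile_design(sp, tab)
  sw <- model_spec("M5", "WO", L = 7, S = 7)
  dw <- compile_design(sw, tab)
  expect_equal(d$artifacts$penalty$values, diag(7))
  # identity-penalty scores are the raw cross-product scores up to
  # column centering
  curves <- fit_curve_coefficients(
    as.matrix(tab[, d$artifacts$band_cols]),
    d$artifacts$wavelengths, d$artifacts$phi)
  raw <- functional_design(curves, d$artifacts$J)$scores
  raw_c <- sweep(raw, 2, colMeans(raw))
  expect_equal(d$blocks$basis_common$X, raw_c, tolerance = 1e-10)
  expect_equal(max(abs(colMeans(d$blocks$basis_common$X))), 0,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(dw$blocks$basis_common$X, raw_c)))
})
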