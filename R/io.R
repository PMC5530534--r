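# Readers/writers for the package's interchange files (all comma
# delimited text), run-configuration handling, and the pipeline driver
# behind the command-line interface.

#' Read a plot-level trial table
#'
#' @param path CSV file with mandatory columns `env`, `trial`, `rep`,
#'   `block`, `genotype`, `yield` and any number of
#'   `band_<wavelength>_t<timepoint>` columns.
#' @return Data frame; band columns are validated as numeric.
#' @export
read_plot_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(plot_table_cols, names(tab))
  if (length(miss)) {
    stop("plot table ", path, " missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  for (b in c("yield", band_columns(tab))) {
    if (!is.numeric(tab[[b]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[b]]))))[1]
      stop("non-numeric value in column ", b, ", row ", bad)
    }
  }
  tab
}

#' Read a marker dosage matrix
#'
#' @param path CSV with a header row of marker ids and first column of
#'   line ids; entries 0/1/2 with `NA` for missing.
#' @return Numeric matrix, lines in rows.
#' @export
read_markers <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a 3-column pedigree file
#'
#' @param path CSV with columns id, sire, dam; `0` or empty marks an
#'   unknown parent.
#' @return Data frame with columns `id`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(tab)[1:3] <- c("id", "sire", "dam")
  tab
}

#' Write / read a kinship matrix as delimited text
#'
#' @param kinship An `fb_kinship`.
#' @param path Output CSV path (square matrix with id header).
#' @export
write_kinship <- function(kinship, path) {
  utils::write.csv(data.frame(id = kinship$line_ids, kinship$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
}

#' @rdname write_kinship
#' @param source Kinship source tag for the read object.
#' @export
read_kinship <- function(path, source = "genomic") {
  tab <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  new_kinship(M, as.character(tab[[1]]), source)
}

#' Read and validate a run configuration
#'
#' @param path YAML file. Recognized top-level keys: `seed`, `out_dir`,
#'   `task` (`fit` or `cv`), `simulate` (sim_config overrides or
#'   `false`), `paths` (`plots`, `markers`, `pedigree`), `model`
#'   (`id`, `mode`, `basis`, `L`, `S`, or `id: all` for the whole
#'   catalogue under `cv`), `sampler` (`iterations`, `burn_in`, `thin`),
#'   `cv` (`scheme`, `partitions`, `focal_env`), `stage1`
#'   (`band_varcomps`), `time_point`. Unknown keys are rejected.
#' @return Validated config list of class `fb_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg Configuration list (as parsed from YAML).
#' @param dir Base directory for relative paths.
#' @export
validate_run_config <- function(cfg, dir = ".") {
  known <- c("seed", "out_dir", "task", "simulate", "paths", "model",
             "sampler", "cv", "stage1", "time_point")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$task <- if (is.null(cfg$task)) "cv" else match.arg(cfg$task,
                                                         c("fit", "cv"))
  if (is.null(cfg$model)) cfg$model <- list()
  if (is.null(cfg$model$id)) cfg$model$id <- "M13"
  if (is.null(cfg$model$mode)) cfg$model$mode <- "WG"
  if (!identical(cfg$model$id, "all") &&
      !all(cfg$model$id %in% model_table$model_id)) {
    stop("unknown model id: ",
         paste(setdiff(cfg$model$id, model_table$model_id),
               collapse = ", "))
  }
  if (cfg$task == "fit" && length(cfg$model$id) != 1L) {
    stop("task 'fit' takes exactly one model id")
  }
  simulate_run <- is.null(cfg$paths$plots)
  if (!simulate_run) {
    for (p in unlist(cfg$paths)) {
      fp <- if (file.exists(p)) p else file.path(dir, p)
      if (!file.exists(fp)) stop("configured path does not exist: ", p)
    }
    if (cfg$model$mode == "WG" && is.null(cfg$paths$markers)) {
      stop("mode WG requires a marker file")
    }
    if (cfg$model$mode == "WA" && is.null(cfg$paths$pedigree)) {
      stop("mode WA requires a pedigree file")
    }
  }
  cfg$dir <- dir
  class(cfg) <- "fb_run_config"
  cfg
}

resolve_path <- function(p, dir) if (file.exists(p)) p else file.path(dir, p)

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, the first-stage adjustment, model
#' compilation and either a single Gibbs fit or a cross-validation over
#' the configured models, writing all artifacts to the output
#' directory: `second_stage.csv`, `fit_summary.csv` or
#' `cv_result.csv`, and `provenance.txt` (seed, configuration hash,
#' package version).
#'
#' @param cfg An `fb_run_config` (or path to a YAML file).
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return Invisibly, a list with the main in-memory artifacts.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "fb_run_config"))
  out_dir <- if (!is.null(out_dir)) out_dir else
    if (!is.null(cfg$out_dir)) cfg$out_dir else "funbandr_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  kinships <- list()
  if (is.null(cfg$paths$plots)) {
    sim <- step("simulate", {
      args <- cfg$simulate
      if (is.logical(args) || is.null(args)) args <- list()
      args$seed <- cfg$seed
      do.call(sim_config, args)
    })
    exp <- step("simulate", simulate_experiment(sim))
    plots <- exp$plot_table
    kinships <- list(WG = exp$G, WA = exp$A)
    utils::write.csv(plots, file.path(out_dir, "plots.csv"),
                     row.names = FALSE)
  } else {
    plots <- step("read", read_plot_table(resolve_path(cfg$paths$plots,
                                                       cfg$dir)))
    if (!is.null(cfg$paths$markers)) {
      kinships$WG <- step("kinship", ensure_pd(genomic_relationship(
        qc_markers(read_markers(resolve_path(cfg$paths$markers,
                                             cfg$dir))))))
    }
    if (!is.null(cfg$paths$pedigree)) {
      kinships$WA <- step("kinship", pedigree_A(
        read_pedigree(resolve_path(cfg$paths$pedigree, cfg$dir))))
    }
  }

  bv <- if (!is.null(cfg$stage1$band_varcomps)) cfg$stage1$band_varcomps
        else "per_band"
  s1 <- step("stage1", stage_one(plots, band_varcomps = bv))
  tab <- step("stage1", assemble_second_stage(s1))
  utils::write.csv(tab, file.path(out_dir, "second_stage.csv"),
                   row.names = FALSE)

  sc <- cfg$sampler
  control <- sampler_control(
    iterations = if (!is.null(sc$iterations)) sc$iterations else 30000L,
    burn_in = if (!is.null(sc$burn_in)) sc$burn_in else 20000L,
    thin = if (!is.null(sc$thin)) sc$thin else 1L,
    seed = cfg$seed)
  spec_args <- function(id) {
    model_spec(id, mode = cfg$model$mode,
               basis_kind = cfg$model$basis,
               L = if (!is.null(cfg$model$L)) cfg$model$L else 21L,
               S = if (!is.null(cfg$model$S)) cfg$model$S else 21L)
  }
  result <- NULL
  if (cfg$task == "fit") {
    spec <- step("compile", spec_args(cfg$model$id))
    bundle <- step("compile", compile_design(spec, tab,
                                             kinships[[spec$mode]],
                                             cfg$time_point))
    fit <- step("fit", gibbs_fit(bundle, control = control))
    vm <- colMeans(fit$var_chain)
    summary <- data.frame(component = c(colnames(fit$var_chain),
                                        "residual"),
                          posterior_mean = c(vm, mean(fit$resid_chain)))
    utils::write.csv(summary, file.path(out_dir, "fit_summary.csv"),
                     row.names = FALSE)
    result <- fit
  } else {
    ids <- if (identical(cfg$model$id, "all")) model_table$model_id
           else cfg$model$id
    specs <- lapply(ids, spec_args)
    lines <- unique(tab$genotype); envs <- unique(tab$env)
    npart <- if (!is.null(cfg$cv$partitions)) cfg$cv$partitions else 10L
    parts <- step("cv", {
      if (identical(cfg$cv$scheme, "90")) {
        make_90cv(lines, envs, cfg$cv$focal_env, npart, cfg$seed)
      } else {
        make_50cv(lines, envs, npart, cfg$seed)
      }
    })
    cvres <- step("cv", evaluate_cv(parts, specs, tab, kinships,
                                    cfg$time_point, control = control))
    utils::write.csv(cvres$summary, file.path(out_dir, "cv_result.csv"),
                     row.names = FALSE)
    utils::write.csv(cvres$correlations,
                     file.path(out_dir, "cv_correlations.csv"),
                     row.names = FALSE)
    result <- cvres
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  cfg_out <- unclass(cfg); cfg_out$dir <- NULL
  yaml::write_yaml(cfg_out, cfg_file)
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("config_md5: %s",
                       unname(tools::md5sum(cfg_file))),
               sprintf("funbandr_version: %s",
                       as.character(utils::packageVersion("funbandr"))),
               sprintf("r_version: %s", R.version.string)),
             file.path(out_dir, "provenance.txt"))
  invisible(list(second_stage = tab, result = result,
                 kinships = kinships, out_dir = out_dir))
}
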