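# Cross-validation schemes for multi-environment trials: random 50%
# line partitions per environment (with the constraint that every
# tested line is observed in at least one environment) and the
# one-environment-depleted scheme where 90% of a focal environment's
# lines are predicted from the other environments.

#' Random 50% line partitions per environment
#'
#' For each partition and each environment, half of the lines' cells go
#' to training and half to testing, under the constraint that no line
#' is in the test set in every environment it appears in (each tested
#' line must be observed somewhere). Violations are repaired by
#' swapping the line into training in one uniformly chosen environment
#' against a line that remains safely observed elsewhere.
#'
#' @param lines Character vector of line ids.
#' @param envs Character vector of environment labels (at least 2).
#' @param n_partitions Number of partitions (default 10).
#' @param seed Integer seed; partitions are deterministic given it.
#' @return List of `n_partitions` objects of class `fb_cv_partition`,
#'   each a data frame of cells (`env`, `genotype`, `role`).
#' @export
make_50cv <- function(lines, envs, n_partitions = 10L, seed = 1L) {
  lines <- as.character(lines); envs <- as.character(envs)
  if (length(envs) < 2L) {
    stop("the observed-somewhere constraint needs at least 2 environments")
  }
  set.seed(seed)
  lapply(seq_len(n_partitions), function(p) {
    n_train <- floor(length(lines) / 2)
    in_train <- sapply(envs, function(e) {
      tr <- logical(length(lines))
      tr[sample.int(length(lines), n_train)] <- TRUE
      tr
    })
    rownames(in_train) <- lines
    # repair: each line must be in training in >= 1 environment
    for (j in which(rowSums(in_train) == 0L)) {
      e <- sample.int(length(envs), 1L)
      # swap with a training line of that env that stays observed elsewhere
      safe <- which(in_train[, e] & rowSums(in_train) >= 2L)
      if (length(safe)) {
        in_train[safe[sample.int(length(safe), 1L)], e] <- FALSE
      }
      in_train[j, e] <- TRUE
    }
    cells <- expand.grid(genotype = lines, env = envs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$role <- ifelse(in_train[cbind(cells$genotype, cells$env)],
                         "train", "test")
    structure(cells[, c("env", "genotype", "role")],
              class = c("fb_cv_partition", "data.frame"),
              scheme = "50CV", partition = p)
  })
}

#' Focal-environment depletion partitions (90CV)
#'
#' All lines of the non-focal environments are in training; in the
#' focal environment only `floor(0.10 * n_lines)` lines are kept in
#' training and the remaining 90% are predicted.
#'
#' @param lines Character vector of line ids.
#' @param envs Character vector of environment labels (at least 2).
#' @param focal_env Environment whose lines are depleted.
#' @param n_partitions Number of partitions (default 10).
#' @param seed Integer seed.
#' @return List of `fb_cv_partition` objects.
#' @export
make_90cv <- function(lines, envs, focal_env, n_partitions = 10L,
                      seed = 1L) {
  lines <- as.character(lines); envs <- as.character(envs)
  if (length(envs) < 2L) stop("need at least 2 environments")
  if (!focal_env %in% envs) stop("unknown focal environment: ", focal_env)
  set.seed(seed)
  n_keep <- floor(0.10 * length(lines))
  lapply(seq_len(n_partitions), function(p) {
    keep <- lines[sample.int(length(lines), n_keep)]
    cells <- expand.grid(genotype = lines, env = envs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$role <- ifelse(cells$env != focal_env | cells$genotype %in% keep,
                         "train", "test")
    structure(cells[, c("env", "genotype", "role")],
              class = c("fb_cv_partition", "data.frame"),
              scheme = "90CV", partition = p, focal_env = focal_env)
  })
}

# Match partition cells to rows of a second-stage table.
partition_rows <- function(partition, table) {
  key_t <- paste(table$env, table$genotype, sep = "\r")
  key_p <- paste(partition$env, partition$genotype, sep = "\r")
  role <- partition$role[match(key_t, key_p)]
  list(train = which(role == "train"), test = which(role == "test"))
}

#' Cross-validated prediction accuracy of a set of models
#'
#' Compiles each model once on the full table (so the identical
#' partitions are reused across models, giving paired comparisons),
#' fits it on the training cells of each partition and computes, per
#' environment, the Pearson correlation between predicted and observed
#' second-stage yield over that environment's test cells. Environments
#' with fewer than 3 test cells get `NA`.
#'
#' @param partitions List of `fb_cv_partition` (from [make_50cv()] or
#'   [make_90cv()]).
#' @param specs List of `fb_model_spec` (one per model to compare).
#' @param table Second-stage table.
#' @param kinships Named list of `fb_kinship` by mode (`WG`, `WA`);
#'   `WO` needs none.
#' @param time_point Band time-point passed to [compile_design()].
#' @param priors,control Passed to [gibbs_fit()].
#' @return Object of class `fb_cv_result`: list with `correlations`
#'   (data frame: model, mode, env, partition, cor) and `summary`
#'   (model, mode, env, apc, se) where `apc` is the mean and `se` the
#'   standard deviation over partitions divided by the square root of
#'   the number of partitions.
#' @export
evaluate_cv <- function(partitions, specs, table, kinships = list(),
                        time_point = NULL, priors = prior_config(),
                        control = sampler_control()) {
  if (inherits(specs, "fb_model_spec")) specs <- list(specs)
  rows_list <- lapply(partitions, partition_rows, table = table)
  res <- list()
  for (spec in specs) {
    kin <- if (spec$mode == "WO") NULL else kinships[[spec$mode]]
    bundle <- compile_design(spec, table, kin, time_point)
    for (p in seq_along(partitions)) {
      rl <- rows_list[[p]]
      fit <- gibbs_fit(bundle, priors, control, rows = rl$train)
      pred <- predict(fit, rows = rl$test)
      obs <- bundle$y[rl$test]
      env_t <- bundle$env[rl$test]
      for (e in unique(env_t)) {
        sel <- env_t == e
        r <- if (sum(sel) < 3L) NA_real_ else
          stats::cor(pred[sel], obs[sel])
        res[[length(res) + 1L]] <- data.frame(
          model = spec$model_id, mode = spec$mode, env = e,
          partition = p, cor = r, stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, res)
  summary <- stats::aggregate(cor ~ model + mode + env, correlations,
                              function(x) c(apc = mean(x),
                                            se = stats::sd(x) / sqrt(length(x))),
                              na.action = stats::na.omit)
  summary <- cbind(summary[, c("model", "mode", "env")],
                   as.data.frame(summary$cor))
  structure(list(correlations = correlations, summary = summary),
            class = "fb_cv_result")
}

#' @export
print.fb_cv_result <- function(x, ...) {
  cat("<fb_cv_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
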