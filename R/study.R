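#' Simulation-study configuration
#'
#' Defines a scenario grid (the cross of relationships, omics
#' configurations, phenotype dimensions and noise variances), the replicate
#' protocol (160/40 train/test split by default), the competing methods and
#' the shared penalty grid. Replicate r of any scenario is seeded with
#' `base_seed + r`, so studies are reproducible and resumable per replicate.
#'
#' @param relationships,omics,phenotype_dims,noise_vars vectors crossed into
#'   the scenario grid.
#' @param n_replicates replicates per scenario (20 at desk scale; the full
#'   protocol uses 200).
#' @param n_train,n_test split sizes; their sum is the sample size.
#' @param methods subset of "MFDL", "FLM", "NN", "FNN-3HL".
#' @param lambda_grid candidate L2 penalties shared by all methods.
#' @param max_epochs epoch cap for gradient-trained methods.
#' @param base_seed integer base seed.
#' @param p1,p2,interaction_c,ld_rho forwarded to [scenario_spec()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(relationships = "interaction", omics = "G-G",
                         phenotype_dims = 1L, noise_vars = 0.3,
                         n_replicates = 20L, n_train = 160L, n_test = 40L,
                         methods = c("MFDL", "FLM", "NN", "FNN-3HL"),
                         lambda_grid = c(0.1, 0.3, 1, 3, 10),
                         max_epochs = 1000L, base_seed = 1L, p1 = 100L,
                         p2 = 1L, interaction_c = 1, ld_rho = 0.9) {
  methods <- match.arg(methods, c("MFDL", "FLM", "NN", "FNN-3HL"),
                       several.ok = TRUE)
  if (length(methods) < 1L) stop("'methods' must be nonempty")
  grid <- expand.grid(relationship = relationships, omics = omics,
                      phenotype_dim = phenotype_dims,
                      noise_var = noise_vars, stringsAsFactors = FALSE)
  structure(list(grid = grid, n_replicates = as.integer(n_replicates),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 methods = methods, lambda_grid = lambda_grid,
                 max_epochs = as.integer(max_epochs),
                 base_seed = as.integer(base_seed), p1 = as.integer(p1),
                 p2 = as.integer(p2), interaction_c = interaction_c,
                 ld_rho = ld_rho),
            class = "study_config")
}

scenario_from_row <- function(study, row) {
  scenario_spec(relationship = row$relationship, omics = row$omics,
                phenotype_dim = row$phenotype_dim, noise_var = row$noise_var,
                n = study$n_train + study$n_test, p1 = study$p1,
                p2 = study$p2, interaction_c = study$interaction_c,
                ld_rho = study$ld_rho)
}

#' @export
predict.mfdl_fit <- function(object, modalities, covariates = NULL, ...) {
  mfdl_forward(object$model, modalities, covariates)
}

# Default multimodal architecture for a simulated scenario: a functional
# subnet per genotype modality, a dense subnet per expression matrix, and a
# single-hidden-layer head.
mfdl_configs_for <- function(modalities, output_dim) {
  configs <- lapply(modalities, function(m) {
    if (inherits(m, "variant_function"))
      subnet_config("functional", n_hidden = 0L, embedding_width = 8L)
    else
      subnet_config("dense", p = ncol(as.matrix(m)), embedding_width = 8L)
  })
  list(subnets = configs,
       head = head_config(hidden_widths = 16L, output_dim = output_dim))
}

# Per-method fit functions with the (modalities, y, covariates, lambda)
# signature expected by select_lambda(). Each returns an object with a
# predict() method. The gradient-trained methods standardize their inputs
# and response from the training batch (stored on the model, so predictions
# return to the phenotype scale). Penalty selection only needs to rank
# candidates, so it runs on a shortened schedule; the final fit uses the
# full epoch budget.
method_fitters <- function(study, output_dim, seed, selection = FALSE) {
  epochs <- if (selection) max(100L, study$max_epochs %/% 2L) else
    study$max_epochs
  schedule <- fit_schedule(max_epochs = epochs)
  list(
    "FLM" = function(mods, y, cov, lambda) {
      fit_flm(mods, y, cov, basis = bspline_system(5L, 7L), lambda = lambda)
    },
    "MFDL" = function(mods, y, cov, lambda) {
      arch <- mfdl_configs_for(mods, output_dim)
      model <- build_mfdl(arch$subnets, arch$head, seed = seed)
      fit <- fit_mfdl(model, mods, y, covariates = cov, lambda = lambda,
                      schedule = schedule, normalize_inputs = TRUE,
                      standardize_response = TRUE)
      structure(list(model = fit$model, history = fit$history),
                class = "mfdl_fit")
    },
    "NN" = function(mods, y, cov, lambda) {
      X <- do.call(cbind, lapply(mods, function(m)
        if (inherits(m, "variant_function")) m$values else as.matrix(m)))
      fit_nn(X, y, widths = c(16L, 8L), lambda = lambda,
             schedule = schedule, seed = seed, normalize_inputs = TRUE,
             standardize_response = TRUE)
    },
    "FNN-3HL" = function(mods, y, cov, lambda) {
      fit_fnn3hl(mods, y, lambda = lambda, schedule = schedule, seed = seed,
                 normalize_inputs = TRUE, standardize_response = TRUE)
    }
  )
}

#' Run one simulation replicate
#'
#' Generates the replicate's dataset (seed `base_seed + replicate_id`),
#' splits it into training and test sets, and for every method selects the
#' penalty on the training portion, refits on the full training set and
#' evaluates MSE, MAE and RV on both splits. A method failure is recorded
#' and does not stop the other methods.
#'
#' @param spec a [scenario_spec()] (its `n` must equal
#'   `n_train + n_test`).
#' @param study a [study_config()].
#' @param replicate_id integer replicate index.
#' @return List with `results` (one row per method and split) and
#'   `failures` (zero or more rows describing failed methods).
#' @export
run_replicate <- function(spec, study, replicate_id) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(study, "study_config"))
  n <- study$n_train + study$n_test
  if (spec$n != n) stop("scenario n must equal n_train + n_test")
  seed <- study$base_seed + replicate_id
  ds <- make_dataset(spec, seed)
  idx_train <- with_seed(seed + 100000L, sort(sample.int(n, study$n_train)))
  idx_test <- setdiff(seq_len(n), idx_train)
  mods_tr <- subset_modalities(ds$modalities, idx_train)
  mods_te <- subset_modalities(ds$modalities, idx_test)
  y_tr <- ds$y[idx_train, , drop = FALSE]
  y_te <- ds$y[idx_test, , drop = FALSE]
  fitters <- method_fitters(study, ncol(ds$y), seed)
  sel_fitters <- method_fitters(study, ncol(ds$y), seed, selection = TRUE)
  results <- list(); failures <- list()
  for (method in study$methods) {
    out <- tryCatch({
      sel <- select_lambda(sel_fitters[[method]], mods_tr, y_tr,
                           covariates = NULL, grid = study$lambda_grid,
                           seed = seed)
      fit <- fitters[[method]](mods_tr, y_tr, NULL, sel$lambda)
      rbind(
        eval_result(method, "train", y_tr,
                    stats::predict(fit, mods_tr, NULL),
                    replicate_id, seed, sel$lambda),
        eval_result(method, "test", y_te,
                    stats::predict(fit, mods_te, NULL),
                    replicate_id, seed, sel$lambda))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(method = method, replicate_id = replicate_id,
                   seed = seed, message = conditionMessage(out))
    } else {
      results[[length(results) + 1L]] <- out
    }
  }
  list(results = if (length(results)) do.call(rbind, results) else NULL,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}

#' Run a full simulation study
#'
#' Loops the scenario grid and replicates, aggregates per-scenario,
#' per-method medians and interquartile ranges of the test and training
#' metrics, and optionally writes tidy CSV/JSON outputs. Outputs contain no
#' wall-clock information, so a rerun with the same configuration
#' reproduces every file byte for byte; progress messages (with timing) go
#' to the console only.
#'
#' @param study a [study_config()].
#' @param outdir optional output directory for `results.csv`,
#'   `summary.csv` and `summary.json`.
#' @param verbose emit per-replicate progress messages.
#' @return List with `results` (raw per-replicate rows), `summary`
#'   (aggregated rows) and `failures`.
#' @export
run_study <- function(study, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(study, "study_config"))
  all_res <- list(); all_fail <- list()
  for (si in seq_len(nrow(study$grid))) {
    row <- study$grid[si, , drop = FALSE]
    spec <- scenario_from_row(study, row)
    scen_id <- sprintf("%s_%s_d%d_v%g", row$relationship, row$omics,
                       row$phenotype_dim, row$noise_var)
    for (r in seq_len(study$n_replicates)) {
      t0 <- Sys.time()
      rep_out <- run_replicate(spec, study, r)
      if (!is.null(rep_out$results)) {
        rep_out$results <- cbind(scenario = scen_id, row,
                                 rep_out$results, row.names = NULL)
        all_res[[length(all_res) + 1L]] <- rep_out$results
      }
      if (!is.null(rep_out$failures)) {
        rep_out$failures <- cbind(scenario = scen_id, rep_out$failures,
                                  row.names = NULL)
        all_fail[[length(all_fail) + 1L]] <- rep_out$failures
      }
      if (verbose)
        message(sprintf("[%s] %s replicate %d/%d (%.1fs)",
                        format(Sys.time(), "%H:%M:%S"), scen_id, r,
                        study$n_replicates,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  results <- if (length(all_res)) do.call(rbind, all_res) else
    stop("every replicate failed; see failures")
  failures <- if (length(all_fail)) do.call(rbind, all_fail) else NULL
  summary <- summarize_study(results)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(results, file.path(outdir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(summary, digits = NA, dataframe = "rows"),
               file.path(outdir, "summary.json"))
    if (!is.null(failures))
      utils::write.csv(failures, file.path(outdir, "failures.csv"),
                       row.names = FALSE)
  }
  list(results = results, summary = summary, failures = failures)
}

#' Aggregate raw replicate results into medians and IQRs
#'
#' @param results the raw results table from [run_study()].
#' @return Data frame with one row per scenario, method and split.
#' @export
summarize_study <- function(results) {
  key <- interaction(results$scenario, results$method, results$split,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(scenario = g$scenario[1L], method = g$method[1L],
               split = g$split[1L], n_replicates = nrow(g),
               mse_median = stats::median(g$mse),
               mse_iqr = stats::IQR(g$mse),
               mae_median = stats::median(g$mae),
               mae_iqr = stats::IQR(g$mae),
               rv_median = stats::median(g$rv),
               rv_iqr = stats::IQR(g$rv))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, out$method, out$split), , drop = FALSE]
  rownames(out) <- NULL
  out
}
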