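# CSV I/O, run configuration, and the simulate / embed / evaluate drivers
# behind the command-line script.

#' Read a subjects x features matrix from CSV/TSV
#'
#' The first column holds subject IDs; remaining columns are numeric
#' features. The delimiter is inferred from the file extension (`.tsv` ->
#' tab) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; NULL infers from the extension.
#' @return numeric matrix with subject-ID row names.
#' @export
read_view_csv <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("ill-formed matrix file (need ID column + features): ", path,
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a subjects x features matrix as CSV
#'
#' @param x matrix with subject-ID row names.
#' @param path output file.
#' @param id_col name of the subject-ID column.
#' @param digits significant digits written (6 by default; computation stays
#'   in double precision).
#' @export
write_view_csv <- function(x, path, id_col = "subject_id", digits = 6L) {
  df <- data.frame(id = rownames(x),
                   signif(as.matrix(x), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an embedding with a JSON provenance sidecar
#'
#' The coordinates go to `<path>` as CSV (subject-ID column plus D coordinate
#' columns); method, parameters, diffusion time, seed, and stress go to
#' `<path>.json`.
#'
#' @param fit an `"ephate"` object.
#' @param path CSV output path.
#' @export
write_embedding <- function(fit, path) {
  stopifnot(inherits(fit, "ephate"))
  write_view_csv(fit$embedding, path)
  prov <- list(method = fit$method, t = fit$t, stress = fit$stress,
               seed = fit$seed, D = ncol(fit$embedding),
               params = fit$params[!vapply(fit$params, is.list, logical(1))])
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Assemble a run configuration
#'
#' Plain-list configuration consumed by [run_simulate()], [run_embed()],
#' [run_evaluate()] and [run_all()]. Values supplied in `...` override the
#' (YAML) file values, which override the defaults.
#'
#' @param file optional YAML configuration file.
#' @param ... named overrides (e.g. `n = 100`, `representations = c("phate",
#'   "ephate")`).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    out_dir = "ephate_run",
    brain_file = NULL, env_file = NULL, outcome_file = NULL,
    representations = c("voxel", "pca", "phate", "phate_plus_env",
                        "ephate", "ephate_control"),
    outcome_name = "outcome",
    covariate_names = NULL,
    D = 20L, F = 20L, n_perm = 10000L, seed = 0L,
    k_brain = 5L, alpha_brain = 40, k_env = 5L, alpha_env = 2,
    standardize_env = TRUE, combine_order = "brain_env",
    # synthetic-generator block
    n = 300L, p = 200L, q = 5L
  )
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    from_file <- yaml::read_yaml(file)
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

as_view_config <- function(cfg) {
  view_config(k_brain = cfg$k_brain, alpha_brain = cfg$alpha_brain,
              k_env = cfg$k_env, alpha_env = cfg$alpha_env,
              standardize_env = cfg$standardize_env,
              combine_order = cfg$combine_order)
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  manifest <- c(unclass(cfg), extra,
                list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     package_version = as.character(utils::packageVersion("ephate"))))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Simulate a dataset and write it to disk
#'
#' Writes `brain.csv`, `environment.csv`, `outcomes.csv`, `latents.csv`, and
#' a `manifest.yaml` echoing the configuration and seed.
#'
#' @param cfg a [run_config()].
#' @return the `"synthetic_dataset"`, invisibly.
#' @export
run_simulate <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(synthetic_config(n = cfg$n, p = cfg$p, q = cfg$q,
                                          seed = cfg$seed))
  write_view_csv(ds$brain, file.path(cfg$out_dir, "brain.csv"))
  write_view_csv(ds$env, file.path(cfg$out_dir, "environment.csv"))
  utils::write.csv(ds$outcomes, file.path(cfg$out_dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_view_csv(ds$latents, file.path(cfg$out_dir, "latents.csv"))
  write_manifest(cfg, cfg$out_dir, list(stage = "simulate"))
  invisible(ds)
}

load_run_inputs <- function(cfg) {
  if (is.null(cfg$brain_file))
    stop("config must name a brain_file (run_simulate writes one)",
         call. = FALSE)
  brain <- read_view_csv(cfg$brain_file)
  env <- if (!is.null(cfg$env_file)) read_view_csv(cfg$env_file) else NULL
  outcomes <- NULL
  if (!is.null(cfg$outcome_file)) {
    if (!file.exists(cfg$outcome_file))
      stop("input file not found: ", cfg$outcome_file, call. = FALSE)
    outcomes <- utils::read.csv(cfg$outcome_file, stringsAsFactors = FALSE)
  }
  if (!is.null(env)) {
    if (!identical(rownames(brain), rownames(env))) {
      bad <- union(setdiff(rownames(brain), rownames(env)),
                   setdiff(rownames(env), rownames(brain)))
      stop("subject IDs differ between brain and environment files: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(outcomes)) {
    if (!identical(as.character(outcomes[[1L]]), rownames(brain))) {
      bad <- union(setdiff(rownames(brain), as.character(outcomes[[1L]])),
                   setdiff(as.character(outcomes[[1L]]), rownames(brain)))
      stop("subject IDs differ between brain and outcome files: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  list(brain = brain, env = env, outcomes = outcomes)
}

#' Compute and write the requested embeddings
#'
#' One embedding CSV (plus JSON provenance) per requested representation.
#' Logs the selected diffusion time and elapsed seconds per representation.
#'
#' @param cfg a [run_config()] with `brain_file` (and `env_file` for the
#'   E-PHATE variants) set.
#' @return named list of feature matrices, invisibly.
#' @export
run_embed <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(cfg)
  vcfg <- as_view_config(cfg)
  ds <- list(brain = inputs$brain, env = inputs$env)
  reps <- list()
  for (r in cfg$representations) {
    t0 <- proc.time()[["elapsed"]]
    coords <- build_representation(ds, r, D = cfg$D, cfg = vcfg,
                                   seed = cfg$seed)
    reps[[r]] <- coords
    out <- file.path(cfg$out_dir, paste0("embedding_", r, ".csv"))
    fit_like <- structure(list(embedding = coords, method = r,
                               t = attr(coords, "t") %||% NA_integer_,
                               stress = NA_real_, seed = cfg$seed,
                               params = list(D = ncol(coords))),
                          class = "ephate")
    write_embedding(fit_like, out)
    message(sprintf("[embed] %s: %d x %d in %.1fs", r, nrow(coords),
                    ncol(coords), proc.time()[["elapsed"]] - t0))
  }
  write_manifest(cfg, cfg$out_dir, list(stage = "embed"))
  invisible(reps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate representations and write results tables
#'
#' Runs [benchmark_representations()] on the configured inputs and writes
#' `scores_per_fold.csv` (one row per representation/fold),
#' `scores_summary.csv`, `comparisons.csv` (raw and Bonferroni-adjusted
#' p-values), and a manifest.
#'
#' @param cfg a [run_config()] with input files set, or with `dataset`
#'   passed directly.
#' @param dataset optional in-memory dataset (bypasses file reading).
#' @return the `"ephate_benchmark"`, invisibly.
#' @export
run_evaluate <- function(cfg = run_config(), dataset = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dataset)) {
    inputs <- load_run_inputs(cfg)
    if (is.null(inputs$outcomes))
      stop("config must name an outcome_file", call. = FALSE)
    dataset <- list(brain = inputs$brain, env = inputs$env,
                    outcomes = inputs$outcomes)
  }
  bench <- benchmark_representations(
    dataset, representations = cfg$representations,
    outcome_name = cfg$outcome_name, covariate_names = cfg$covariate_names,
    D = cfg$D, F = cfg$F, n_perm = cfg$n_perm, cfg = as_view_config(cfg),
    seed = cfg$seed)
  per_fold <- do.call(rbind, lapply(bench$scores, function(s) {
    data.frame(representation = s$representation,
               fold = seq_along(s$per_fold_rho), rho = s$per_fold_rho,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(per_fold, file.path(cfg$out_dir, "scores_per_fold.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bench$summary,
                   file.path(cfg$out_dir, "scores_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bench$comparisons))
    utils::write.csv(bench$comparisons,
                     file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  write_manifest(cfg, cfg$out_dir, list(stage = "evaluate"))
  invisible(bench)
}

#' Simulate, embed, and evaluate in one call
#'
#' @param cfg a [run_config()].
#' @return the `"ephate_benchmark"`, invisibly.
#' @export
run_all <- function(cfg = run_config()) {
  ds <- run_simulate(cfg)
  cfg$brain_file <- file.path(cfg$out_dir, "brain.csv")
  cfg$env_file <- file.path(cfg$out_dir, "environment.csv")
  cfg$outcome_file <- file.path(cfg$out_dir, "outcomes.csv")
  run_embed(cfg)
  run_evaluate(cfg, dataset = ds)
}
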