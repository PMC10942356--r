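# Benchmarking representations against each other on one dataset, mirroring
# the comparisons a brain-behavior prediction study runs: raw features, PCA,
# PHATE, PHATE with environment scores concatenated, E-PHATE, and an E-PHATE
# control with a random-noise environment view.

#' Build one representation of a dataset
#'
#' @param dataset a `"synthetic_dataset"` or a list with `brain` and `env`
#'   matrices.
#' @param representation one of `"voxel"`, `"pca"`, `"phate"`,
#'   `"phate_plus_env"`, `"ephate"`, `"ephate_control"`.
#' @param D embedding dimension for the manifold/PCA representations.
#' @param cfg a [view_config()].
#' @param seed integer; seeds the noise environment of the control variant
#'   and is recorded in embedding provenance.
#' @param phate_fit optional precomputed [phate()] fit reused by `"phate"`
#'   and `"phate_plus_env"` to avoid recomputation.
#' @return n x d numeric matrix of features for downstream regression.
#' @export
build_representation <- function(dataset, representation, D = 20L,
                                 cfg = view_config(), seed = 0L,
                                 phate_fit = NULL) {
  representation <- match.arg(representation,
                              c("voxel", "pca", "phate", "phate_plus_env",
                                "ephate", "ephate_control"))
  brain <- dataset$brain
  env <- dataset$env
  switch(representation,
    voxel = as_data_matrix(brain),
    pca = as.matrix(pca_embed(brain, D = D)),
    phate = {
      fit <- if (is.null(phate_fit)) phate(brain, k = cfg$k_brain,
                                           alpha = cfg$alpha_brain, D = D,
                                           seed = seed) else phate_fit
      as.matrix(fit)
    },
    phate_plus_env = {
      fit <- if (is.null(phate_fit)) phate(brain, k = cfg$k_brain,
                                           alpha = cfg$alpha_brain, D = D,
                                           seed = seed) else phate_fit
      cbind(as.matrix(fit), standardize_exogenous(env))
    },
    ephate = as.matrix(ephate(brain, env, cfg = cfg, D = D, seed = seed)),
    ephate_control = {
      # environment replaced by seeded standard-normal noise, same shape:
      # tests whether gains come from environmental information rather than
      # from feeding the algorithm more columns
      noise_env <- with_seed(derive_seed(seed, 9L), {
        m <- matrix(stats::rnorm(nrow(env) * ncol(env)), nrow(env), ncol(env))
        dimnames(m) <- dimnames(env)
        m
      })
      as.matrix(ephate(brain, noise_env, cfg = cfg, D = D, seed = seed))
    }
  )
}

#' Score several representations of one dataset and compare them
#'
#' Evaluates each requested representation with F-fold cross-validated linear
#' regression scored by partial Spearman correlation (scanner as covariate
#' when present in the outcomes), then compares a reference representation
#' against every other with paired sign-flip permutation tests and Bonferroni
#' adjustment over the comparison family.
#'
#' @param dataset a `"synthetic_dataset"` (or compatible list with `brain`,
#'   `env`, `outcomes`).
#' @param representations subset of `c("voxel", "pca", "phate",
#'   "phate_plus_env", "ephate", "ephate_control")`.
#' @param outcome_name column of `dataset$outcomes` to predict.
#' @param covariate_names columns of `dataset$outcomes` used as covariates in
#'   the partial correlation (default: `"scanner"` when present).
#' @param D embedding dimension; `F` folds; `n_perm` permutation iterations.
#' @param cfg a [view_config()].
#' @param seed master seed (folds, permutations, control noise).
#' @param reference representation compared against all others.
#' @return list of class `"ephate_benchmark"` with `scores` (named list of
#'   `"fold_scores"`), `summary` (data frame), and `comparisons` (data frame
#'   with raw and Bonferroni-adjusted p-values).
#' @export
benchmark_representations <- function(dataset,
                                      representations = c("voxel", "pca",
                                                          "phate",
                                                          "phate_plus_env",
                                                          "ephate",
                                                          "ephate_control"),
                                      outcome_name = "outcome",
                                      covariate_names = NULL,
                                      D = 20L, F = 20L, n_perm = 10000L,
                                      cfg = view_config(), seed = 0L,
                                      reference = "ephate") {
  representations <- match.arg(representations,
                               c("voxel", "pca", "phate", "phate_plus_env",
                                 "ephate", "ephate_control"),
                               several.ok = TRUE)
  outcomes <- dataset$outcomes
  if (!outcome_name %in% names(outcomes))
    stop("outcome column not found: ", outcome_name, call. = FALSE)
  y <- outcomes[[outcome_name]]
  if (is.null(covariate_names) && "scanner" %in% names(outcomes))
    covariate_names <- "scanner"
  covs <- if (length(covariate_names))
    outcomes[, covariate_names, drop = FALSE] else NULL

  phate_fit <- NULL
  if (any(c("phate", "phate_plus_env") %in% representations))
    phate_fit <- phate(dataset$brain, k = cfg$k_brain, alpha = cfg$alpha_brain,
                       D = D, seed = seed)

  scores <- lapply(representations, function(r) {
    coords <- build_representation(dataset, r, D = D, cfg = cfg, seed = seed,
                                   phate_fit = phate_fit)
    evaluate_representation(coords, y, covariates = covs, F = F,
                            seed = seed, name = r)
  })
  names(scores) <- representations

  summary_df <- do.call(rbind, lapply(scores, function(s) {
    data.frame(representation = s$representation, mean_rho = s$mean_rho,
               ci_lo = s$ci95[1], ci_hi = s$ci95[2], folds = s$F,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL

  comparisons <- NULL
  if (reference %in% representations && length(representations) > 1L) {
    others <- setdiff(representations, reference)
    comp <- lapply(others, function(r) {
      pt <- pairwise_permutation_test(scores[[reference]], scores[[r]],
                                      n_perm = n_perm,
                                      seed = derive_seed(seed, 7L))
      data.frame(a = reference, b = r, mean_diff = pt$observed,
                 p_raw = pt$p_raw, stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, comp)
    comparisons$p_adjusted <- bonferroni_adjust(comparisons$p_raw,
                                                m = nrow(comparisons))
    comparisons$n_permutations <- as.integer(n_perm)
  }

  structure(list(scores = scores, summary = summary_df,
                 comparisons = comparisons, outcome = outcome_name,
                 seed = seed, D = D, F = F),
            class = "ephate_benchmark")
}

#' @export
print.ephate_benchmark <- function(x, ...) {
  cat(sprintf("Representation benchmark on outcome '%s' (%d folds, D = %d)\n",
              x$outcome, x$F, x$D))
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$comparisons)) {
    cat("\nPairwise sign-flip permutation tests (Bonferroni-adjusted):\n")
    print(x$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
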