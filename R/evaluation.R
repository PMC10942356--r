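# Cross-validated linear prediction scored with partial Spearman correlation,
# paired sign-flip permutation tests, and the log-linear corrected d-prime.

#' Deterministic k-fold split keyed to subject identifiers
#'
#' Subjects are shuffled by a seeded permutation of their *sorted* IDs, so
#' the assignment of subject to fold depends only on (IDs, F, seed), not on
#' row order. Test sets are disjoint, cover all subjects, and differ in size
#' by at most one; the default F = 20 gives 95/5 train/test splits.
#'
#' @param subject_ids character or numeric vector of unique IDs.
#' @param F number of folds (>= 2, <= n).
#' @param seed integer seed.
#' @return list of F lists, each with integer index vectors `train` and
#'   `test` (positions in `subject_ids`).
#' @export
kfold_split <- function(subject_ids, F = 20L, seed = 0L) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("subject IDs must be unique", call. = FALSE)
  F <- as.integer(F)
  if (F < 2L || F > n) stop("F must satisfy 2 <= F <= n", call. = FALSE)
  ord <- order(as.character(subject_ids))        # canonical ordering by ID
  shuffled <- with_seed(seed, sample(ord))
  fold_of <- rep(seq_len(F), length.out = n)     # sizes differ by <= 1
  lapply(seq_len(F), function(f) {
    test <- sort(shuffled[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Out-of-fold predictions from per-fold ordinary least squares
#'
#' For each fold, fits an intercept-plus-features linear regression on the
#' training subjects and predicts the held-out subjects, returning one
#' out-of-fold prediction per subject. A rank-deficient design is solved by
#' the minimum-norm least-squares solution (Moore-Penrose pseudoinverse) with
#' a warning.
#'
#' @param rep_coords n x d numeric feature matrix (an embedding or raw view).
#' @param outcome numeric vector of length n.
#' @param folds output of [kfold_split()].
#' @return numeric vector of n out-of-fold predictions.
#' @export
fit_predict_linear <- function(rep_coords, outcome, folds) {
  rep_coords <- as.matrix(rep_coords)
  n <- nrow(rep_coords)
  if (length(outcome) != n)
    stop("outcome length does not match the representation", call. = FALSE)
  if (anyNA(rep_coords) || anyNA(outcome))
    stop("missing values are not allowed", call. = FALSE)
  pred <- rep(NA_real_, n)
  warned <- FALSE
  for (fold in folds) {
    Xtr <- cbind(1, rep_coords[fold$train, , drop = FALSE])
    Xte <- cbind(1, rep_coords[fold$test, , drop = FALSE])
    ytr <- outcome[fold$train]
    qr_x <- qr(Xtr)
    if (qr_x$rank < ncol(Xtr)) {
      if (!warned) {
        warning("rank-deficient design; using minimum-norm least-squares solution",
                call. = FALSE)
        warned <- TRUE
      }
      beta <- MASS::ginv(Xtr) %*% ytr
    } else {
      beta <- qr.coef(qr_x, ytr)
    }
    pred[fold$test] <- drop(Xte %*% beta)
  }
  pred
}

#' Partial Spearman correlation
#'
#' Rank-transforms both vectors (average ranks for ties), regresses each rank
#' vector on the covariate design (intercept plus one-hot categorical
#' covariates with a dropped reference level and numeric covariates as-is),
#' and returns the Pearson correlation of the two residual vectors. With no
#' covariates this is exactly the ordinary Spearman correlation.
#'
#' @param pred,truth numeric vectors of equal length (>= 3).
#' @param covariates optional data frame (or matrix) of covariates; NULL or
#'   zero columns means plain Spearman.
#' @return correlation in `[-1, 1]`.
#' @export
partial_spearman <- function(pred, truth, covariates = NULL) {
  n <- length(pred)
  if (length(truth) != n || n < 3L)
    stop("pred and truth must have equal length >= 3", call. = FALSE)
  rp <- rank(pred); rt <- rank(truth)
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    if (stats::sd(rp) == 0 || stats::sd(rt) == 0)
      stop("undefined correlation: zero-variance ranks", call. = FALSE)
    return(stats::cor(rp, rt))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    stop("covariates must have one row per observation", call. = FALSE)
  X <- stats::model.matrix(~ ., data = covariates)
  res_p <- stats::lm.fit(X, rp)$residuals
  res_t <- stats::lm.fit(X, rt)$residuals
  if (stats::sd(res_p) == 0 || stats::sd(res_t) == 0)
    stop("undefined correlation: zero-variance residuals", call. = FALSE)
  stats::cor(res_p, res_t)
}

#' Cross-validated prediction score for one representation/outcome pair
#'
#' Runs [kfold_split()], [fit_predict_linear()] within each fold, and scores
#' each fold's held-out subjects with [partial_spearman()]. Reports the
#' per-fold correlations, their mean, and a 95% t-interval across folds.
#'
#' @param rep an `"ephate"` object or an n x d numeric matrix.
#' @param outcome numeric vector of length n (aligned with the
#'   representation's subjects).
#' @param covariates optional covariate data frame (see [partial_spearman()]).
#' @param F number of folds.
#' @param seed seed for the fold split.
#' @param name label for the representation.
#' @return object of class `"fold_scores"`: list with `representation`,
#'   `per_fold_rho`, `mean_rho`, `ci95`, `F`, `seed`.
#' @export
evaluate_representation <- function(rep, outcome, covariates = NULL,
                                    F = 20L, seed = 0L,
                                    name = NULL) {
  if (inherits(rep, "ephate")) {
    if (is.null(name)) name <- rep$method
    coords <- rep$embedding
  } else {
    coords <- as.matrix(rep)
    if (is.null(name)) name <- "matrix"
  }
  n <- nrow(coords)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (length(outcome) != n)
    stop("outcome is not aligned with the representation", call. = FALSE)
  folds <- kfold_split(ids, F = F, seed = seed)
  pred <- fit_predict_linear(coords, outcome, folds)
  rho <- vapply(folds, function(fold) {
    idx <- fold$test
    cov_f <- if (is.null(covariates)) NULL
             else droplevels(as.data.frame(covariates)[idx, , drop = FALSE])
    partial_spearman(pred[idx], outcome[idx], cov_f)
  }, numeric(1))
  m <- mean(rho)
  se <- stats::sd(rho) / sqrt(length(rho))
  ci <- m + c(-1, 1) * stats::qt(0.975, df = length(rho) - 1L) * se
  structure(list(representation = name, per_fold_rho = rho, mean_rho = m,
                 ci95 = ci, F = length(rho), seed = seed),
            class = "fold_scores")
}

#' @export
print.fold_scores <- function(x, ...) {
  cat(sprintf("%s: mean partial Spearman rho = %.3f (95%% CI %.3f to %.3f, %d folds)\n",
              x$representation, x$mean_rho, x$ci95[1], x$ci95[2], x$F))
  invisible(x)
}

#' Paired sign-flip permutation test on per-fold score differences
#'
#' Two-sided test of the mean paired difference between two representations'
#' fold scores. Under the null the fold differences are sign-symmetric, so
#' signs are flipped at random; the p-value uses the add-one estimator
#' `(1 + #{|permuted mean| >= |observed mean|}) / (n_perm + 1)`, which is
#' never zero.
#'
#' @param fold_rhos_a,fold_rhos_b equal-length vectors of per-fold scores
#'   (paired by fold), or `"fold_scores"` objects.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return list with `p_raw`, `observed` (mean difference), `n_perm`.
#' @export
pairwise_permutation_test <- function(fold_rhos_a, fold_rhos_b,
                                      n_perm = 10000L, seed = 0L) {
  if (inherits(fold_rhos_a, "fold_scores")) fold_rhos_a <- fold_rhos_a$per_fold_rho
  if (inherits(fold_rhos_b, "fold_scores")) fold_rhos_b <- fold_rhos_b$per_fold_rho
  if (length(fold_rhos_a) != length(fold_rhos_b))
    stop("fold score vectors must have equal length (paired by fold)",
         call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  d <- fold_rhos_a - fold_rhos_b
  F <- length(d)
  obs <- mean(d)
  perm_means <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * F, replace = TRUE), n_perm, F)
    drop(signs %*% d) / F
  })
  p <- (1 + sum(abs(perm_means) >= abs(obs))) / (n_perm + 1)
  list(p_raw = p, observed = obs, n_perm = as.integer(n_perm))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`. `m` may exceed the number of p-values supplied
#' (for a comparison family spread over several calls).
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size, `m >= length(p_values)`.
#' @return adjusted p-values in the original order.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values", call. = FALSE)
  pmin(1, m * p_values)
}

#' Sensitivity (d-prime) with the log-linear (Hautus) correction
#'
#' Adds 0.5 to the hit and false-alarm counts and 1 to the trial counts
#' before computing rates, so perfect or zero rates stay inside (0, 1):
#' `d' = qnorm((hits + 0.5) / (hits + misses + 1)) -
#'       qnorm((false_alarms + 0.5) / (false_alarms + correct_rejections + 1))`.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative trial
#'   counts; at least one signal trial and one noise trial are required.
#' @return d-prime (numeric scalar).
#' @export
dprime_hautus <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (hits + misses == 0 || false_alarms + correct_rejections == 0)
    stop("need at least one signal trial and one noise trial", call. = FALSE)
  hr <- (hits + 0.5) / (hits + misses + 1)
  far <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  stats::qnorm(hr) - stats::qnorm(far)
}
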