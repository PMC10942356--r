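# Potential distances, metric MDS, and the PHATE / E-PHATE / PCA fitting
# functions.

#' Potential distances between the rows of a powered diffusion operator
#'
#' `U(i, j) = || log P^t(i, .) - log P^t(j, .) ||_2`, with transition
#' probabilities clamped below `log_floor` before taking logs so that
#' unreachable states do not produce infinities. Log-scaling makes small
#' transition probabilities (long-range, global structure) count on the same
#' footing as large ones (local structure); the result is a metric.
#'
#' @param op a `"diffusion_operator"`.
#' @param t positive integer diffusion time (the operator is powered by t).
#' @param log_floor smallest probability retained before the log, in (0, 1).
#' @return symmetric, zero-diagonal n x n distance matrix with attribute
#'   `"t"`.
#' @export
potential_distance <- function(op, t = 1L, log_floor = 1e-7) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  if (!(log_floor > 0 && log_floor < 1))
    stop("log_floor must lie in (0, 1)", call. = FALSE)
  Pt <- if (t > 1L) power_operator(op, t)$P else op$P
  L <- log(pmax(Pt, log_floor))
  U <- as.matrix(stats::dist(L, method = "euclidean"))
  dimnames(U) <- dimnames(op$P)
  attr(U, "t") <- as.integer(t)
  U
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and takes the top-D
#' eigenvectors scaled by root eigenvalues. Negative eigenvalues (distances
#' not Euclidean-embeddable in D dimensions) are truncated at zero, so the
#' output is always finite. Used as the deterministic initialization for
#' [smacof_refine()].
#'
#' @param distances symmetric zero-diagonal distance matrix.
#' @param D embedding dimension, `1 <= D < n`.
#' @return n x D coordinate matrix.
#' @export
classical_mds <- function(distances, D) {
  distances <- check_distance_matrix(distances)
  n <- nrow(distances)
  D <- as.integer(D)
  if (D < 1L || D >= n) stop("D must satisfy 1 <= D < n", call. = FALSE)
  D2 <- distances^2
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(D)], 0)
  X <- eig$vectors[, seq_len(D), drop = FALSE] %*% diag(sqrt(lam), D, D)
  rownames(X) <- rownames(distances)
  colnames(X) <- paste0("D", seq_len(D))
  X
}

# Raw metric stress: sum over unordered pairs of squared discrepancy.
stress_raw <- function(distances, X) {
  dX <- as.matrix(stats::dist(X))
  sum((distances - dX)^2) / 2
}

#' Refine an MDS configuration by SMACOF stress majorization
#'
#' Iterates the Guttman transform from the supplied initialization. Metric
#' stress is non-increasing across iterations (majorization guarantee);
#' iteration stops when the relative stress decrease falls below `tol` or
#' after `max_iter` iterations. The reported stress is the normalized
#' stress-1, `sqrt(sum((d - delta)^2) / sum(delta^2))`.
#'
#' @param distances target distance matrix.
#' @param init_coords n x D initial configuration (finite), typically from
#'   [classical_mds()].
#' @param max_iter maximum Guttman iterations.
#' @param tol relative stress-change tolerance.
#' @return list with `coords`, `stress` (normalized stress-1), `stress_trace`
#'   (raw stress per iteration, including the initial value), `iterations`,
#'   and `converged`.
#' @export
smacof_refine <- function(distances, init_coords, max_iter = 300L, tol = 1e-6) {
  distances <- check_distance_matrix(distances)
  if (!is.matrix(init_coords) || any(!is.finite(init_coords)))
    stop("init_coords must be a finite numeric matrix", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  n <- nrow(distances)
  X <- init_coords
  sig <- stress_raw(distances, X)
  trace <- sig
  converged <- FALSE
  denom <- sum(distances^2) / 2
  for (it in seq_len(max_iter)) {
    dX <- as.matrix(stats::dist(X))
    ratio <- matrix(0, n, n)
    pos <- dX > 0
    ratio[pos] <- distances[pos] / dX[pos]
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- (B %*% X) / n
    sig_new <- stress_raw(distances, X_new)
    trace <- c(trace, sig_new)
    improved <- sig - sig_new
    X <- X_new
    if (sig > 0 && improved / sig < tol) {
      sig <- sig_new
      converged <- TRUE
      break
    }
    sig <- sig_new
    if (sig == 0) { converged <- TRUE; break }
  }
  stress1 <- if (denom > 0) sqrt(sum((as.matrix(stats::dist(X)) - distances)^2) / 2 / denom) else 0
  dimnames(X) <- dimnames(init_coords)
  list(coords = X, stress = stress1, stress_trace = trace,
       iterations = length(trace) - 1L, converged = converged)
}

# Shared tail of the PHATE/E-PHATE pipeline: operator -> spectrum -> t ->
# potential distances -> classical MDS init -> SMACOF. One spectrum routine
# (dense eigenvalues of P) serves both single-view and fused operators, so an
# identity environment view reduces E-PHATE to PHATE bitwise.
embed_operator <- function(op, D, t = NULL, t_max = 150L, log_floor = 1e-7,
                           mds_max_iter = 300L, mds_tol = 1e-6) {
  spectrum <- operator_spectrum_general(op)
  if (is.null(t)) t <- select_diffusion_time(spectrum, t_max = t_max)
  t <- as.integer(t)
  U <- potential_distance(op, t = t, log_floor = log_floor)
  init <- classical_mds(U, D)
  fit <- smacof_refine(U, init, max_iter = mds_max_iter, tol = mds_tol)
  list(coords = fit$coords, stress = fit$stress, t = t,
       spectrum = as.numeric(spectrum), potential = U,
       smacof_iterations = fit$iterations)
}

new_ephate <- function(coords, method, params, seed, stress = NA_real_,
                       t = NA_integer_, operator = NULL, extra = list()) {
  colnames(coords) <- paste0(toupper(method), seq_len(ncol(coords)))
  structure(
    c(list(embedding = coords, method = method, params = params, seed = seed,
           stress = stress, t = t, operator = operator,
           subject_ids = rownames(coords)),
      extra),
    class = "ephate"
  )
}

#' PHATE embedding of a high-dimensional view
#'
#' Runs the full single-view pipeline: Euclidean distances, adaptive
#' alpha-decay kernel, row normalization, von Neumann entropy time-scale
#' selection, potential distances, classical-MDS-initialized SMACOF. The
#' result is deterministic given the inputs and settings; `seed` is recorded
#' for provenance and only consulted by optional stochastic extensions.
#'
#' @param x subjects x features numeric matrix.
#' @param k adaptive bandwidth neighbor count.
#' @param alpha kernel decay exponent.
#' @param D embedding dimension (20 for analysis by convention; 2-3 for
#'   plotting).
#' @param t diffusion time; NULL (default) selects it at the knee of the von
#'   Neumann entropy curve.
#' @param t_max largest candidate diffusion time.
#' @param log_floor probability clamp in the potential distance.
#' @param mds_max_iter,mds_tol SMACOF settings.
#' @param seed integer recorded in the provenance.
#' @return an object of class `"ephate"` with elements `embedding` (n x D),
#'   `method`, `t`, `stress`, `params`, `seed`, `operator`.
#' @seealso [ephate()], [pca_embed()]
#' @export
phate <- function(x, k = 5L, alpha = 40, D = 20L, t = NULL, t_max = 150L,
                  log_floor = 1e-7, mds_max_iter = 300L, mds_tol = 1e-6,
                  seed = 0L) {
  x <- as_data_matrix(x, view_name = "brain")
  d <- pairwise_distances(x)
  eps <- adaptive_bandwidths(d, k)
  K <- alpha_decay_kernel(d, eps, alpha)
  op <- row_normalize(K, source = "brain")
  res <- embed_operator(op, D = D, t = t, t_max = t_max, log_floor = log_floor,
                        mds_max_iter = mds_max_iter, mds_tol = mds_tol)
  new_ephate(res$coords, method = "phate",
             params = list(k = k, alpha = alpha, D = D, t = res$t,
                           t_max = t_max, log_floor = log_floor,
                           mds_max_iter = mds_max_iter, mds_tol = mds_tol),
             seed = seed, stress = res$stress, t = res$t, operator = op,
             extra = list(potential = res$potential,
                          spectrum = res$spectrum,
                          smacof_iterations = res$smacof_iterations))
}

#' E-PHATE: multi-view embedding of a data view and an exogenous view
#'
#' Builds a diffusion operator over the high-dimensional view and an affinity
#' operator over the exogenous covariates, fuses them by dual-diffusion
#' (matrix product), selects the diffusion time on the fused operator's
#' spectrum, and embeds the potential distances with metric MDS. With
#' `env = NULL` this is exactly [phate()].
#'
#' @param x subjects x features matrix (the high-dimensional view).
#' @param env subjects x scores matrix of exogenous covariates, aligned with
#'   `x` by row order and (when present) row names; NULL for plain PHATE. A
#'   prebuilt `"diffusion_operator"` is also accepted and used as the
#'   environment operator directly (an identity operator makes E-PHATE reduce
#'   exactly to PHATE).
#' @param cfg a [view_config()] with per-view kernel parameters and the
#'   fusion order.
#' @param D,t,t_max,log_floor,mds_max_iter,mds_tol,seed as in [phate()].
#' @return an object of class `"ephate"` (method `"ephate"`).
#' @export
ephate <- function(x, env = NULL, cfg = view_config(), D = 20L, t = NULL,
                   t_max = 150L, log_floor = 1e-7, mds_max_iter = 300L,
                   mds_tol = 1e-6, seed = 0L) {
  if (is.null(env)) {
    return(phate(x, k = cfg$k_brain, alpha = cfg$alpha_brain, D = D, t = t,
                 t_max = t_max, log_floor = log_floor,
                 mds_max_iter = mds_max_iter, mds_tol = mds_tol, seed = seed))
  }
  x <- as_data_matrix(x, view_name = "brain")
  env_is_op <- inherits(env, "diffusion_operator")
  if (!env_is_op) {
    env <- as_data_matrix(env, view_name = "environment")
    if (nrow(env) != nrow(x))
      stop("brain and environment views have different numbers of subjects",
           call. = FALSE)
    had_ids <- function(m) !identical(rownames(m), paste0("S", seq_len(nrow(m))))
    if (had_ids(x) && had_ids(env) && !identical(rownames(x), rownames(env)))
      stop("subject IDs of brain and environment views are misaligned",
           call. = FALSE)
  }
  d <- pairwise_distances(x)
  eps <- adaptive_bandwidths(d, cfg$k_brain)
  K <- alpha_decay_kernel(d, eps, cfg$alpha_brain)
  p_brain <- row_normalize(K, source = "brain")
  if (env_is_op) {
    p_env <- env
  } else {
    rownames(env) <- rownames(x)
    p_env <- exogenous_affinity(env, cfg)
  }
  op <- dual_diffusion_combine(p_brain, p_env, cfg)
  res <- embed_operator(op, D = D, t = t, t_max = t_max, log_floor = log_floor,
                        mds_max_iter = mds_max_iter, mds_tol = mds_tol)
  new_ephate(res$coords, method = "ephate",
             params = list(cfg = cfg, D = D, t = res$t, t_max = t_max,
                           log_floor = log_floor, mds_max_iter = mds_max_iter,
                           mds_tol = mds_tol),
             seed = seed, stress = res$stress, t = res$t, operator = op,
             extra = list(potential = res$potential,
                          spectrum = res$spectrum,
                          operator_brain = p_brain, operator_env = p_env,
                          smacof_iterations = res$smacof_iterations))
}

#' PCA scores as a linear comparator embedding
#'
#' Scores on the top-D principal components of the column-centered matrix.
#'
#' @param x subjects x features matrix.
#' @param D number of components, `D <= min(n, p)`.
#' @return an object of class `"ephate"` (method `"pca"`, no stress).
#' @export
pca_embed <- function(x, D = 20L) {
  x <- as_data_matrix(x)
  D <- as.integer(D)
  if (D < 1L || D > min(dim(x)))
    stop("D must satisfy 1 <= D <= min(n, p)", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = D)
  coords <- pc$x[, seq_len(D), drop = FALSE]
  rownames(coords) <- rownames(x)
  new_ephate(coords, method = "pca", params = list(D = D), seed = NA_integer_,
             extra = list(sdev = pc$sdev[seq_len(D)], rotation = pc$rotation,
                          center = pc$center))
}

# ---- methods -------------------------------------------------------------

#' @export
as.matrix.ephate <- function(x, ...) x$embedding

#' @export
print.ephate <- function(x, ...) {
  cat(sprintf("%s embedding: %d subjects in %d dimensions\n",
              toupper(x$method), nrow(x$embedding), ncol(x$embedding)))
  if (!is.na(x$t)) cat(sprintf("  diffusion time t = %d\n", x$t))
  if (!is.na(x$stress)) cat(sprintf("  metric-MDS stress-1 = %.4g\n", x$stress))
  invisible(x)
}

#' @export
summary.ephate <- function(object, ...) {
  out <- list(method = object$method, n = nrow(object$embedding),
              D = ncol(object$embedding), t = object$t,
              stress = object$stress, params = object$params,
              seed = object$seed)
  class(out) <- "summary.ephate"
  out
}

#' @export
print.summary.ephate <- function(x, ...) {
  cat(sprintf("%s embedding of %d subjects into %d dimensions\n",
              toupper(x$method), x$n, x$D))
  if (!is.na(x$t)) cat(sprintf("  diffusion time (VNE knee): %d\n", x$t))
  if (!is.na(x$stress)) cat(sprintf("  final stress-1: %.6g\n", x$stress))
  cat("  parameters:\n")
  p <- x$params
  p$cfg <- NULL
  for (nm in names(p)) cat(sprintf("    %s = %s\n", nm, format(p[[nm]])))
  if (!is.null(x$params$cfg)) {
    cfg <- x$params$cfg
    cat(sprintf("    kernel (brain): k = %d, alpha = %g\n",
                cfg$k_brain, cfg$alpha_brain))
    cat(sprintf("    kernel (environment): k = %d, alpha = %g, standardize = %s\n",
                cfg$k_env, cfg$alpha_env, cfg$standardize_env))
    cat(sprintf("    fusion order: %s\n", cfg$combine_order))
  }
  invisible(x)
}

#' Scatter plot of the first two embedding dimensions
#'
#' @param x an `"ephate"` object.
#' @param color optional numeric or factor vector (length n) used to color
#'   points, e.g. an outcome score.
#' @param dims which two dimensions to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ephate <- function(x, color = NULL, dims = c(1L, 2L), ...) {
  co <- x$embedding
  if (ncol(co) < 2L) stop("need at least 2 embedding dimensions to plot",
                          call. = FALSE)
  col <- "grey30"
  if (!is.null(color)) {
    if (is.numeric(color)) {
      pal <- grDevices::hcl.colors(64, "Viridis")
      idx <- cut(color, breaks = 64, labels = FALSE, include.lowest = TRUE)
      col <- pal[idx]
    } else {
      col <- as.integer(as.factor(color))
    }
  }
  graphics::plot(co[, dims[1L]], co[, dims[2L]], col = col, pch = 16,
                 xlab = colnames(co)[dims[1L]], ylab = colnames(co)[dims[2L]],
                 main = sprintf("%s embedding", toupper(x$method)), ...)
  invisible(x)
}
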