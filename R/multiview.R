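# Multi-view fusion: exogenous-view affinity and dual-diffusion combination.

#' Kernel and fusion settings for a two-view embedding
#'
#' @param k_brain,alpha_brain adaptive-kernel parameters for the
#'   high-dimensional (brain) view. The sharp default `alpha_brain = 40`
#'   approximates a k-nearest-neighbor graph, appropriate where distances
#'   concentrate in high dimension.
#' @param k_env,alpha_env adaptive-kernel parameters for the exogenous
#'   (environment) view. The default `alpha_env = 2` is a Gaussian kernel
#'   with adaptive bandwidth: the exogenous view is low-dimensional and
#'   dense, where graded affinities carry far more of its structure into the
#'   fused operator than a near-binary neighborhood kernel does.
#' @param standardize_env z-score each environment column before building its
#'   kernel. The exogenous scores usually mix scales (composite indices next
#'   to survey scores), so this defaults to TRUE.
#' @param combine_order `"brain_env"` applies the brain operator first
#'   (`P_brain %*% P_env`, the default), `"env_brain"` the reverse; the
#'   product does not commute.
#' @return a list of class `"view_config"`.
#' @export
view_config <- function(k_brain = 5L, alpha_brain = 40,
                        k_env = 5L, alpha_env = 2,
                        standardize_env = TRUE,
                        combine_order = c("brain_env", "env_brain")) {
  combine_order <- match.arg(combine_order)
  stopifnot(k_brain >= 1, alpha_brain > 0, k_env >= 1, alpha_env > 0)
  structure(list(k_brain = as.integer(k_brain), alpha_brain = alpha_brain,
                 k_env = as.integer(k_env), alpha_env = alpha_env,
                 standardize_env = isTRUE(standardize_env),
                 combine_order = combine_order),
            class = "view_config")
}

#' Z-score the columns of an exogenous score matrix
#'
#' Centers each column and divides by its population standard deviation
#' (`sqrt(mean((x - mean(x))^2))`), so each score contributes on the same
#' scale regardless of its native units. Idempotent. A constant column has no
#' ordering information and raises an error naming the column.
#'
#' @param env subjects x scores numeric matrix or data frame.
#' @return matrix of the same shape with column means 0 and unit population
#'   variance.
#' @export
standardize_exogenous <- function(env) {
  env <- as_data_matrix(env, view_name = "environment")
  mu <- colMeans(env)
  sd_pop <- sqrt(colMeans(sweep(env, 2L, mu, "-")^2))
  if (any(sd_pop == 0)) {
    bad <- colnames(env)[sd_pop == 0]
    if (is.null(bad)) bad <- which(sd_pop == 0)
    stop("constant exogenous column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- sweep(sweep(env, 2L, mu, "-"), 2L, sd_pop, "/")
  attr(out, "view") <- "environment"
  out
}

#' Diffusion operator over the exogenous (environment) view
#'
#' Builds the same alpha-decay adaptive kernel used for the high-dimensional
#' view, but over the subjects' exogenous scores, and row-normalizes it. When
#' all subjects share identical scores the kernel is all ones and the
#' operator is uniform (every entry 1/n).
#'
#' @param env subjects x scores matrix (row names are subject IDs).
#' @param cfg a [view_config()]; `k_env`, `alpha_env` and `standardize_env`
#'   are used.
#' @return a `"diffusion_operator"` with source `"environment"`.
#' @export
exogenous_affinity <- function(env, cfg = view_config()) {
  env <- as_data_matrix(env, view_name = "environment")
  if (cfg$standardize_env) {
    # an all-constant environment is degenerate but legal: skip the z-score
    if (any(apply(env, 2L, function(col) diff(range(col)) > 0)))
      env <- standardize_exogenous(env)
  }
  d <- pairwise_distances(env)
  if (max(d) == 0) {
    n <- nrow(env)
    K <- matrix(1, n, n, dimnames = dimnames(d))
  } else {
    eps <- suppressWarnings(adaptive_bandwidths(d, cfg$k_env))
    K <- alpha_decay_kernel(d, eps, cfg$alpha_env)
  }
  row_normalize(K, source = "environment")
}

#' Fuse two diffusion operators by dual-diffusion
#'
#' The fused operator is the matrix product of the two row-stochastic
#' operators (default order: endogenous/brain first, then environment). A
#' random-walk step under the product moves along the data manifold and is
#' then re-routed among environmentally similar subjects, so the fused
#' operator encodes relations in both views. The product of row-stochastic
#' matrices is row-stochastic; it has no symmetric source affinity, so its
#' spectrum is computed directly (see [select_diffusion_time()]).
#'
#' @param p_brain,p_env `"diffusion_operator"`s over the same subjects in the
#'   same order.
#' @param cfg a [view_config()]; `combine_order` is used.
#' @return a `"diffusion_operator"` with source `"dual"`.
#' @export
dual_diffusion_combine <- function(p_brain, p_env, cfg = view_config()) {
  stopifnot(inherits(p_brain, "diffusion_operator"),
            inherits(p_env, "diffusion_operator"))
  if (!identical(dim(p_brain$P), dim(p_env$P)))
    stop("operators have mismatched dimensions", call. = FALSE)
  ids_b <- rownames(p_brain$P); ids_e <- rownames(p_env$P)
  if (!is.null(ids_b) && !is.null(ids_e) && !identical(ids_b, ids_e))
    stop("subject IDs of the two views are misaligned", call. = FALSE)
  P <- if (cfg$combine_order == "brain_env") p_brain$P %*% p_env$P
       else p_env$P %*% p_brain$P
  new_diffusion_operator(P, t = 1L, degrees = NULL, source = "dual")
}
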