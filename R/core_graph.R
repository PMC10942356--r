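# ---- data-matrix validation ---------------------------------------------

#' Validate and coerce a subjects x features data matrix
#'
#' A view is an n x p numeric matrix with one row per subject. Row names carry
#' the subject identifiers; when absent, `S1..Sn` are assigned. At least three
#' subjects are required (a one- or two-point graph has no meaningful
#' neighborhood structure) and missing values are not allowed.
#'
#' @param x matrix or data frame coercible to a numeric matrix.
#' @param view_name label stored as the `"view"` attribute.
#' @return numeric matrix with unique row names.
#' @export
as_data_matrix <- function(x, view_name = "view") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("data must be a numeric matrix or data frame", call. = FALSE)
  if (nrow(x) < 3L)
    stop("at least 3 subjects (rows) are required", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("data contains missing or non-finite values", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("subject identifiers (row names) must be unique", call. = FALSE)
  attr(x, "view") <- view_name
  x
}

# ---- distances and kernel ------------------------------------------------

#' Pairwise Euclidean distances between subjects
#'
#' @param x subjects x features matrix (see [as_data_matrix()]).
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(x) {
  x <- as_data_matrix(x)
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Adaptive per-point kernel bandwidths
#'
#' The bandwidth of point i is its distance to its k-th nearest neighbor,
#' excluding itself. Duplicate points make this distance zero; such bandwidths
#' are replaced by the smallest positive distance from that point (or 1 when
#' the point coincides with every other point) with a warning, so that
#' survey-derived views with exact ties still yield a usable kernel.
#'
#' @param distances symmetric distance matrix.
#' @param k neighbor count, `1 <= k <= n - 1`.
#' @return numeric vector of n positive bandwidths.
#' @export
adaptive_bandwidths <- function(distances, k) {
  distances <- check_distance_matrix(distances)
  n <- nrow(distances)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k <= n - 1", call. = FALSE)
  eps <- vapply(seq_len(n), function(i) {
    sort(distances[i, -i], method = "quick")[k]
  }, numeric(1))
  if (any(eps == 0)) {
    fixed <- vapply(which(eps == 0), function(i) {
      pos <- distances[i, -i]
      pos <- pos[pos > 0]
      if (length(pos)) min(pos) else 1
    }, numeric(1))
    eps[eps == 0] <- fixed
    warning("zero bandwidth from duplicate points; substituted smallest positive distance",
            call. = FALSE)
  }
  names(eps) <- rownames(distances)
  eps
}

#' Alpha-decay affinity kernel with adaptive bandwidths
#'
#' Computes the symmetric affinity
#' `K(i, j) = 0.5 * exp(-(d(i,j)/eps_i)^alpha) + 0.5 * exp(-(d(i,j)/eps_j)^alpha)`,
#' where `eps_i` is the adaptive bandwidth of point i. Large `alpha` gives the
#' kernel sharp, nearly binary neighborhoods; `alpha = 2` recovers a Gaussian
#' kernel. The diagonal is exactly 1 and the kernel is invariant to a common
#' rescaling of distances and bandwidths.
#'
#' @param distances symmetric distance matrix.
#' @param bandwidths positive per-point bandwidths (see [adaptive_bandwidths()]).
#' @param alpha positive decay exponent.
#' @return symmetric affinity matrix with unit diagonal and attributes
#'   `"alpha"` and (when available from the caller) `"k"`.
#' @export
alpha_decay_kernel <- function(distances, bandwidths, alpha) {
  distances <- check_distance_matrix(distances)
  n <- nrow(distances)
  if (length(bandwidths) != n || any(bandwidths <= 0))
    stop("bandwidths must be positive and one per point", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  E <- exp(-(sweep(distances, 1L, bandwidths, "/")^alpha))
  K <- 0.5 * (E + t(E))
  diag(K) <- 1
  dimnames(K) <- dimnames(distances)
  attr(K, "alpha") <- alpha
  K
}

# ---- diffusion operators -------------------------------------------------

#' Construct a diffusion operator by row-normalizing an affinity matrix
#'
#' Each row of the affinity is divided by its sum, turning affinities into a
#' row-stochastic transition matrix (a lazy random walk over subjects). The
#' row sums of the affinity (degrees) are retained: they define the symmetric
#' conjugate used for spectral computations.
#'
#' @param affinity non-negative matrix with strictly positive row sums.
#' @param source label recording which view(s) produced the operator.
#' @return object of class `"diffusion_operator"`: a list with elements
#'   `P` (row-stochastic matrix), `t` (diffusion time, 1), `degrees`
#'   (affinity row sums, NULL for fused operators), and `source`.
#' @export
row_normalize <- function(affinity, source = "view") {
  if (!is.matrix(affinity) || !is.numeric(affinity))
    stop("affinity must be a numeric matrix", call. = FALSE)
  if (nrow(affinity) != ncol(affinity))
    stop("affinity must be square", call. = FALSE)
  if (any(affinity < 0))
    stop("affinity entries must be non-negative", call. = FALSE)
  rs <- rowSums(affinity)
  if (any(rs <= 0))
    stop("affinity has a zero row; cannot normalize", call. = FALSE)
  P <- matrix(affinity / rs, nrow(affinity), ncol(affinity),
              dimnames = dimnames(affinity))
  new_diffusion_operator(P, t = 1L, degrees = rs, source = source)
}

new_diffusion_operator <- function(P, t, degrees = NULL, source = "view") {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(P < -1e-12))
    stop("diffusion operator has negative entries", call. = FALSE)
  if (max(abs(rowSums(P) - 1)) > 1e-8)
    stop("diffusion operator rows must sum to 1", call. = FALSE)
  structure(
    list(P = P, t = as.integer(t), degrees = degrees, source = source),
    class = "diffusion_operator"
  )
}

#' @export
as.matrix.diffusion_operator <- function(x, ...) x$P

#' @export
print.diffusion_operator <- function(x, ...) {
  cat(sprintf("Diffusion operator over %d subjects (source: %s, t = %d)\n",
              nrow(x$P), x$source, x$t))
  invisible(x)
}

#' Eigenvalues of the symmetric conjugate of a diffusion operator
#'
#' For an operator `P = D^-1 K` built from a symmetric affinity `K` with
#' degrees `D`, the conjugate `D^{1/2} P D^{-1/2} = D^{-1/2} K D^{-1/2}` is
#' symmetric and shares P's eigenvalues, so they can be computed with a
#' stable symmetric eigendecomposition. Errors when the operator does not
#' carry a symmetric source affinity (for example a fused dual-diffusion
#' operator); see `select_diffusion_time` for the general path.
#'
#' @param op a `"diffusion_operator"`.
#' @return numeric vector of eigenvalues sorted non-increasing, the largest
#'   equal to 1 (class `"operator_spectrum"`).
#' @export
symmetric_conjugate_eigenvalues <- function(op) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (is.null(op$degrees))
    stop("operator has no symmetric source affinity", call. = FALSE)
  K <- op$P * op$degrees            # implied affinity, rows scaled by degree
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K)))
    stop("source affinity is not symmetric", call. = FALSE)
  s <- sqrt(op$degrees)
  S <- K / outer(s, s)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(sort(ev, decreasing = TRUE), class = "operator_spectrum")
}

# General spectrum: modulus of dense eigenvalues of P itself. Works for any
# row-stochastic operator, including fused ones with no symmetric source.
operator_spectrum_general <- function(op) {
  P <- if (inherits(op, "diffusion_operator")) op$P else op
  ev <- eigen(P, only.values = TRUE)$values
  structure(sort(Mod(ev), decreasing = TRUE), class = "operator_spectrum")
}

#' Von Neumann entropy of a powered operator spectrum
#'
#' The eigenvalue moduli raised to the power t are normalized to a probability
#' vector eta; the entropy is `-sum(eta * log(eta))` in nats (zero terms
#' contribute nothing). As t grows, mass concentrates on the leading
#' eigenvalues and the entropy decreases; the knee of this curve marks the
#' diffusion time at which noise has been washed out but structure remains.
#'
#' @param spectrum eigenvalues (see [symmetric_conjugate_eigenvalues()]).
#' @param t positive integer diffusion time.
#' @return entropy in nats, between 0 and log(n).
#' @export
von_neumann_entropy <- function(spectrum, t) {
  if (length(spectrum) == 0L)
    stop("empty spectrum", call. = FALSE)
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  lam <- abs(as.numeric(spectrum))^t
  eta <- lam / sum(lam)
  eta <- eta[eta > 0]
  -sum(eta * log(eta))
}

#' Select the diffusion time at the knee of the entropy curve
#'
#' Computes `H(t)` for `t = 1..t_max` and returns the t maximizing the
#' perpendicular distance to the chord joining `(1, H(1))` and
#' `(t_max, H(t_max))` — the knee of the curve. Ties break to the smallest t,
#' so a flat curve returns 1. The selection is invariant to affine rescaling
#' of H.
#'
#' @param spectrum operator spectrum.
#' @param t_max largest candidate diffusion time (>= 2).
#' @return integer t in `[1, t_max]`, with the entropy curve attached as
#'   attribute `"entropy"`.
#' @export
select_diffusion_time <- function(spectrum, t_max = 150L) {
  if (t_max < 2) stop("t_max must be >= 2", call. = FALSE)
  ts <- seq_len(t_max)
  H <- vapply(ts, function(t) von_neumann_entropy(spectrum, t), numeric(1))
  # perpendicular distance to chord (up to the constant chord length)
  dH <- H[t_max] - H[1L]
  dt <- t_max - 1
  num <- abs(dH * (ts - 1) - dt * (H - H[1L]))
  t_star <- which.max(num)            # which.max breaks ties to smallest t
  structure(as.integer(t_star), entropy = H)
}

#' Power a diffusion operator
#'
#' Computes `P^t` by repeated squaring. Powers of a row-stochastic matrix are
#' row-stochastic; the degrees of a reversible operator are unchanged.
#'
#' @param op a `"diffusion_operator"`.
#' @param t positive integer power.
#' @return a `"diffusion_operator"` with diffusion time `op$t * t`.
#' @export
power_operator <- function(op, t) {
  stopifnot(inherits(op, "diffusion_operator"))
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be a positive integer", call. = FALSE)
  Pt <- matrix_power(op$P, t)
  # renormalize away accumulated floating-point drift (order ~1e-15 per step)
  Pt <- pmax(Pt, 0) / rowSums(pmax(Pt, 0))
  new_diffusion_operator(Pt, t = op$t * t, degrees = op$degrees, source = op$source)
}

matrix_power <- function(P, t) {
  if (t == 1L) return(P)
  out <- NULL
  base <- P
  while (t > 0L) {
    if (t %% 2L == 1L) out <- if (is.null(out)) base else out %*% base
    base <- base %*% base
    t <- t %/% 2L
  }
  out
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distances must be a square numeric matrix", call. = FALSE)
  if (any(d < 0) || max(abs(diag(d))) > 0)
    stop("distances must be non-negative with zero diagonal", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-10 * max(1, max(d)))
    stop("distance matrix must be symmetric", call. = FALSE)
  d
}

# ---- seeded evaluation ---------------------------------------------------

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a user seed, kept within 32-bit
# integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1000003) %% 2147483647)
}
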