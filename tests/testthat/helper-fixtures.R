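# Small deterministic fixtures shared across test files.

# points on a line at 0, 1, 3 (one feature)
line_points <- function() {
  m <- matrix(c(0, 1, 3), ncol = 1)
  rownames(m) <- c("a", "b", "c")
  m
}

random_data <- function(n, p, seed = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  rownames(m) <- sprintf("S%03d", seq_len(n))
  m
}

# operator from a random symmetric positive affinity
random_operator <- function(n, seed = 0) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.05, 1), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  row_normalize(A)
}

# a noiseless 1-D curve lifted into `p` ambient dimensions
noiseless_arc <- function(n, p, seed = 0) {
  ds <- generate_dataset(synthetic_config(n = n, p = p, noise_sd_brain = 0,
                                          seed = seed))
  list(x = ds$brain, latent = ds$latents[, "brain"])
}
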