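# Potential distances, classical MDS, SMACOF, and the fitting functions.

test_that("potential distances match direct log-norm evaluation", {
  # duplicate rows of P^t are at distance zero
  op <- row_normalize(rbind(c(1, 1, 0.5), c(1, 1, 0.5), c(0.5, 0.5, 1)))
  U <- potential_distance(op, t = 1, log_floor = 1e-12)
  expect_equal(U[1, 2], 0)

  # rows (0.9, 0.1) and (0.5, 0.5): direct evaluation
  P <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  op2 <- structure(list(P = P, t = 1L, degrees = NULL, source = "test"),
                   class = "diffusion_operator")
  U2 <- potential_distance(op2, t = 1, log_floor = 1e-12)
  expect_equal(U2[1, 2],
               sqrt((log(0.9) - log(0.5))^2 + (log(0.1) - log(0.5))^2),
               tolerance = 1e-12)
  expect_equal(U2[1, 2], 1.7134, tolerance = 1e-4)

  # brute-force double-loop oracle on an 8x8 operator
  op3 <- random_operator(8, seed = 1)
  U3 <- potential_distance(op3, t = 3, log_floor = 1e-7)
  P3 <- power_operator(op3, 3)$P
  L <- log(pmax(P3, 1e-7))
  for (i in 1:8) for (j in 1:8)
    expect_equal(U3[i, j], sqrt(sum((L[i, ] - L[j, ])^2)), tolerance = 1e-10)

  # metric properties
  expect_lt(max(abs(U3 - t(U3))), 1e-8)
  expect_equal(unname(diag(U3)), rep(0, 8))
})

test_that("classical MDS reproduces Euclidean-embeddable distances", {
  # all-zero distances -> all-zero coordinates
  Z <- classical_mds(matrix(0, 4, 4), 2)
  expect_equal(unname(Z), matrix(0, 4, 2))

  # 3-4-5 triangle reconstructed exactly in 2-D
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 3
  d[1, 3] <- d[3, 1] <- 4
  d[2, 3] <- d[3, 2] <- 5
  X <- classical_mds(d, 2)
  expect_equal(unname(as.matrix(dist(X))), unname(d), tolerance = 1e-8)
  expect_true(all(is.finite(X)))

  # cross-check against the stats::cmdscale implementation
  x <- random_data(12, 5, seed = 2)
  dd <- pairwise_distances(x)
  ours <- classical_mds(dd, 3)
  ref <- cmdscale(dd, k = 3)
  # column signs are arbitrary; compare reconstructed distances
  expect_equal(as.matrix(dist(ours)), as.matrix(dist(ref)), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(classical_mds(dd, 12), "D must")
})

test_that("SMACOF decreases stress monotonically from the classical init", {
  x <- random_data(30, 4, seed = 3)
  target <- pairwise_distances(x)

  # exact (centered) configuration is a fixed point; the Guttman transform
  # returns centered coordinates, so compare up to translation
  init <- scale(x, scale = FALSE)
  fit <- smacof_refine(target, unname(init), max_iter = 50)
  expect_lt(fit$stress, 1e-10)
  expect_equal(unname(fit$coords), unname(init), tolerance = 1e-6,
               ignore_attr = TRUE)

  # random 30-point instance, D = 2: monotone trace, final <= initial stress
  init2 <- classical_mds(target, 2)
  fit2 <- smacof_refine(target, init2, max_iter = 100)
  expect_true(all(diff(fit2$stress_trace) <= 1e-10 * fit2$stress_trace[1]))
  expect_lte(fit2$stress_trace[length(fit2$stress_trace)], fit2$stress_trace[1])

  expect_error(smacof_refine(target, init2 * NA), "finite")
})

test_that("PHATE recovers a noiseless 1-D latent and is deterministic", {
  arc <- noiseless_arc(60, 50, seed = 0)
  fit <- phate(arc$x, D = 2)
  rho <- cor(arc$latent, fit$embedding[, 1], method = "spearman")
  expect_gt(abs(rho), 0.95)

  # same inputs -> bitwise identical coordinates
  fit2 <- phate(arc$x, D = 2)
  expect_identical(fit$embedding, fit2$embedding)

  # duplicate subjects map to identical coordinates
  x <- random_data(20, 10, seed = 4)
  x[2, ] <- x[1, ]
  fitd <- suppressWarnings(phate(x, D = 3))
  expect_lt(max(abs(fitd$embedding[1, ] - fitd$embedding[2, ])), 1e-6)
})

test_that("E-PHATE with an identity environment operator equals PHATE", {
  x <- random_data(30, 12, seed = 5)
  p_id <- row_normalize(diag(30))
  fit_e <- ephate(x, p_id, D = 4)
  fit_p <- phate(x, D = 4)
  expect_identical(unname(fit_e$embedding), unname(fit_p$embedding))
  expect_identical(unname(fit_e$potential), unname(fit_p$potential))
})

test_that("uniform environment smooths the brain operator uniformly", {
  x <- random_data(15, 8, seed = 6)
  env <- matrix(2, 15, 3, dimnames = list(rownames(x), NULL))
  fit <- ephate(x, env, D = 3, t = 2)
  # the fused operator is P_brain %*% (uniform): compute that path explicitly
  d <- pairwise_distances(x)
  K <- alpha_decay_kernel(d, adaptive_bandwidths(d, 5), 40)
  p_b <- row_normalize(K)
  fused <- p_b$P %*% matrix(1 / 15, 15, 15)
  op <- structure(list(P = fused, t = 1L, degrees = NULL, source = "x"),
                  class = "diffusion_operator")
  expect_equal(unname(fit$potential),
               unname(potential_distance(op, t = 2)), tolerance = 1e-12)
})

test_that("misaligned subject IDs are rejected", {
  x <- random_data(10, 5, seed = 7)
  env <- random_data(10, 3, seed = 8)
  rownames(env) <- rev(rownames(x))
  expect_error(ephate(x, env, D = 2), "misaligned")
})

test_that("PCA embedding matches singular-value structure", {
  # exact rank-2 data is reconstructed from 2 components
  set.seed(9)
  A <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(12), 2, 6)
  rownames(A) <- sprintf("S%02d", 1:20)
  fit <- pca_embed(A, D = 2)
  recon <- as.matrix(fit) %*% t(fit$rotation[, 1:2])
  centered <- sweep(A, 2, colMeans(A))
  expect_equal(unname(recon), unname(centered), tolerance = 1e-8)

  # component variances non-increasing; agreement with svd oracle
  x <- random_data(20, 10, seed = 10)
  fit2 <- pca_embed(x, D = 5)
  vars <- apply(as.matrix(fit2), 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  sv <- svd(sweep(x, 2, colMeans(x)))
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  expect_equal(abs(unname(as.matrix(fit2))), abs(oracle), tolerance = 1e-8)

  expect_error(pca_embed(x, D = 11), "D must")
})

test_that("embedding objects print, summarize, and convert", {
  arc <- noiseless_arc(30, 20, seed = 11)
  fit <- phate(arc$x, D = 2)
  expect_output(print(fit), "PHATE embedding")
  expect_output(print(summary(fit)), "diffusion time")
  expect_identical(as.matrix(fit), fit$embedding)
  pdf(NULL)
  expect_silent(plot(fit, color = arc$latent))
  dev.off()
})
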