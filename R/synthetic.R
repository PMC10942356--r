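# Synthetic datasets with the statistical structure the method assumes: a
# low-dimensional latent manifold lifted nonlinearly into a high-dimensional
# "brain" view, a correlated low-dimensional "environment" view, and outcomes
# driven by a brain-latent x environment-latent interaction.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale planted-interaction study: 300 subjects, a
#' 200-feature brain view lifted from a 1-D latent arc by a sinusoidal
#' random-feature map, a 5-score environment view mixing a 1-D environment
#' latent (correlated 0.5 with the brain latent at the construct level), and
#' an outcome dominated by the brain x environment latent interaction
#' (interaction variance roughly 40 times either main effect).
#'
#' @param n subjects (>= 50 recommended for evaluation tests).
#' @param p brain features.
#' @param q environment scores; the default 5 mirrors family conflict,
#'   caregiver acceptance, youth- and caregiver-perceived neighborhood
#'   safety/crime, and neighborhood disadvantage (FES, CRPBI, NCY, NSC, ADI).
#' @param latent_dims integer pair: dimensions of the brain and environment
#'   latents (currently 1 each is the supported, tested configuration).
#' @param latent_correlation correlation between brain and environment
#'   latents, in `[-1, 1]`.
#' @param interaction_weight coefficient of the brain x environment latent
#'   product in the outcome.
#' @param main_effect_weights length-2 numeric: coefficients of the brain and
#'   environment latents in the outcome.
#' @param noise_sd_brain,noise_sd_env,noise_sd_outcome non-negative Gaussian
#'   noise SDs for the three generated blocks.
#' @param n_scanners levels of the categorical pseudo-scanner covariate.
#' @param scanner_effect_sd SD of the small additive per-scanner shift.
#' @param baseline_weight weight of the outcome signal in the optional
#'   correlated "baseline" score (for longitudinal-style analyses).
#' @param nonlinearity latent-to-brain map family; `"sine"` (random-feature
#'   sinusoidal expansion) is the supported default.
#' @param seed integer master seed; every block derives its own stream.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n = 300L, p = 200L, q = 5L,
                             latent_dims = c(1L, 1L),
                             latent_correlation = 0.5,
                             interaction_weight = 2,
                             main_effect_weights = c(0.25, 0.25),
                             noise_sd_brain = 0.5,
                             noise_sd_env = 0.3,
                             noise_sd_outcome = 0.5,
                             n_scanners = 4L,
                             scanner_effect_sd = 0.1,
                             baseline_weight = 0.5,
                             nonlinearity = "sine",
                             seed = 0L) {
  stopifnot(n >= 3, p >= 1, q >= 1,
            noise_sd_brain >= 0, noise_sd_env >= 0, noise_sd_outcome >= 0,
            abs(latent_correlation) <= 1, n_scanners >= 1,
            length(main_effect_weights) == 2L)
  nonlinearity <- match.arg(nonlinearity, "sine")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 latent_dims = as.integer(latent_dims),
                 latent_correlation = latent_correlation,
                 interaction_weight = interaction_weight,
                 main_effect_weights = main_effect_weights,
                 noise_sd_brain = noise_sd_brain,
                 noise_sd_env = noise_sd_env,
                 noise_sd_outcome = noise_sd_outcome,
                 n_scanners = as.integer(n_scanners),
                 scanner_effect_sd = scanner_effect_sd,
                 baseline_weight = baseline_weight,
                 nonlinearity = nonlinearity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw ground-truth latents
#'
#' The brain latent is the (standardized) parameter of points spread along an
#' arc; the environment latent is correlated with it at
#' `cfg$latent_correlation` and standard-normal otherwise.
#'
#' @param cfg a [synthetic_config()].
#' @return n x 2 matrix with columns `brain` and `env` and subject row names.
#' @export
generate_latents <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    # jittered regular spacing along the arc: raw uniform draws leave gaps
    # whose sparse tips dominate the adaptive-bandwidth graph at small n
    theta <- sort((seq_len(cfg$n) - 0.5) / cfg$n +
                    stats::runif(cfg$n, -0.3, 0.3) / cfg$n)
    u <- (theta - mean(theta)) / stats::sd(theta)    # standardized brain latent
    rho <- cfg$latent_correlation
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(cfg$n)
    L <- cbind(brain = u, env = v)
    rownames(L) <- sprintf("SUB%04d", seq_len(cfg$n))
    L
  })
}

#' Lift latents into the high-dimensional brain view
#'
#' Each feature j is `a_j * sin(w_j * u + phi_j)` evaluated on the brain
#' latent u — a smooth random-feature expansion, fixed by the seed, that is
#' nonlinear (so a linear method cannot trivially flatten it) while remaining
#' invertible along the arc. Gaussian noise with SD `noise_sd_brain` is
#' added.
#'
#' @param latents matrix from [generate_latents()].
#' @param cfg a [synthetic_config()].
#' @return n x p matrix (a valid brain-view data matrix).
#' @export
generate_brain_view <- function(latents, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  u <- latents[, "brain"]
  with_seed(derive_seed(cfg$seed, 2L), {
    # frequencies capped so w * range(u) < pi: expected chordal distance stays
    # monotone in |u - u'| and the curve cannot fold back on itself
    w <- stats::runif(cfg$p, 0.1, 0.8)
    phi <- stats::runif(cfg$p, 0, 2 * pi)
    a <- stats::runif(cfg$p, 0.5, 1.5)
    X <- outer(u, w) + matrix(phi, cfg$n, cfg$p, byrow = TRUE)
    X <- sin(X) * matrix(a, cfg$n, cfg$p, byrow = TRUE)
    X <- X + cfg$noise_sd_brain * matrix(stats::rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
    rownames(X) <- rownames(latents)
    colnames(X) <- paste0("V", seq_len(cfg$p))
    X
  })
}

#' Mix the environment latent into q observed scores
#'
#' Each of the q columns is a fixed random linear mix of the environment
#' latent plus Gaussian noise. Default column names follow the five
#' family/neighborhood scores (FES, CRPBI, NCY, NSC, ADI).
#'
#' @param latents matrix from [generate_latents()].
#' @param cfg a [synthetic_config()].
#' @return n x q matrix of environment scores.
#' @export
generate_environment_view <- function(latents, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  v <- latents[, "env"]
  with_seed(derive_seed(cfg$seed, 3L), {
    mix <- stats::rnorm(cfg$q, mean = 1, sd = 0.4) * sample(c(-1, 1), cfg$q, TRUE)
    E <- outer(v, mix)
    E <- E + cfg$noise_sd_env * matrix(stats::rnorm(cfg$n * cfg$q), cfg$n, cfg$q)
    rownames(E) <- rownames(latents)
    default_names <- c("FES", "CRPBI", "NCY", "NSC", "ADI")
    colnames(E) <- if (cfg$q <= 5L) default_names[seq_len(cfg$q)]
                   else c(default_names, paste0("ENV", seq_len(cfg$q - 5L)))
    E
  })
}

#' Generate outcomes from latent main effects plus interaction
#'
#' `outcome = w_b * u + w_e * v + w_i * u * v + scanner shift + noise`, with
#' a categorical pseudo-scanner covariate (small additive shift) and a
#' correlated "baseline" score for longitudinal-style covariate tests.
#'
#' @param latents matrix from [generate_latents()].
#' @param cfg a [synthetic_config()].
#' @return data frame with columns `subject_id`, `outcome`, `baseline`,
#'   `scanner`.
#' @export
generate_outcomes <- function(latents, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  u <- latents[, "brain"]; v <- latents[, "env"]
  with_seed(derive_seed(cfg$seed, 4L), {
    signal <- cfg$main_effect_weights[1] * u +
      cfg$main_effect_weights[2] * v +
      cfg$interaction_weight * u * v
    scanner <- factor(sample(sprintf("SCANNER_%02d", seq_len(cfg$n_scanners)),
                             cfg$n, replace = TRUE))
    shift <- stats::rnorm(cfg$n_scanners, 0, cfg$scanner_effect_sd)
    y <- signal + shift[as.integer(scanner)] +
      cfg$noise_sd_outcome * stats::rnorm(cfg$n)
    baseline <- cfg$baseline_weight * signal +
      sqrt(max(0, 1 - cfg$baseline_weight^2)) * stats::rnorm(cfg$n)
    data.frame(subject_id = rownames(latents), outcome = y,
               baseline = baseline, scanner = scanner,
               stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic dataset
#'
#' Composes [generate_latents()], [generate_brain_view()],
#' [generate_environment_view()], and [generate_outcomes()]. Bitwise
#' reproducible from `(cfg, cfg$seed)`.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `"synthetic_dataset"` with elements `brain`, `env`,
#'   `outcomes`, `latents`, `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  latents <- generate_latents(cfg)
  structure(list(brain = generate_brain_view(latents, cfg),
                 env = generate_environment_view(latents, cfg),
                 outcomes = generate_outcomes(latents, cfg),
                 latents = latents,
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d subjects, %d brain features, %d environment scores (seed %d)\n",
              x$config$n, x$config$p, x$config$q, x$config$seed))
  invisible(x)
}
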