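# Empirical item parameter estimates for the 40 spatial-rotation items
# (slipping, guessing, time discrimination, time intensity), used as the
# default simulation truth. Items 1-10 belong to module 1, 11-20 to
# module 2, and so on.
item_param_table <- function() {
  tibble::tibble(
    item_id = 1:40,
    s = c(0.045, 0.086, 0.082, 0.224, 0.140, 0.223, 0.195, 0.195, 0.299,
          0.279, 0.019, 0.011, 0.037, 0.088, 0.106, 0.064, 0.095, 0.060,
          0.089, 0.119, 0.032, 0.220, 0.329, 0.135, 0.257, 0.146, 0.215,
          0.361, 0.483, 0.532, 0.063, 0.035, 0.033, 0.227, 0.141, 0.205,
          0.232, 0.274, 0.494, 0.254),
    g = c(0.811, 0.737, 0.699, 0.635, 0.484, 0.570, 0.355, 0.530, 0.379,
          0.378, 0.876, 0.943, 0.842, 0.843, 0.855, 0.585, 0.498, 0.783,
          0.658, 0.613, 0.798, 0.317, 0.405, 0.429, 0.421, 0.261, 0.392,
          0.370, 0.327, 0.273, 0.756, 0.825, 0.892, 0.458, 0.537, 0.520,
          0.345, 0.366, 0.171, 0.285),
    a = c(1.410, 1.776, 1.865, 1.679, 1.781, 1.702, 1.869, 1.737, 1.735,
          1.533, 2.103, 2.271, 2.113, 2.150, 2.155, 1.820, 2.011, 1.975,
          1.723, 1.655, 1.848, 1.769, 1.947, 1.500, 2.099, 1.817, 1.732,
          1.810, 1.749, 1.743, 2.108, 2.106, 1.867, 1.701, 1.727, 1.780,
          1.546, 1.662, 1.373, 1.368),
    gamma = c(2.312, 2.940, 3.371, 3.762, 3.452, 3.476, 3.510, 3.658, 3.687,
              3.612, 2.671, 2.594, 2.601, 2.464, 2.187, 3.040, 3.019, 2.854,
              3.135, 3.179, 2.630, 3.292, 2.979, 3.173, 2.904, 3.333, 3.509,
              3.395, 3.289, 3.271, 2.622, 2.264, 2.736, 3.241, 3.075, 3.498,
              3.492, 3.299, 3.439, 3.206)
  )
}

#' Default true parameters for the simulation design
#'
#' Assembles the reference parameter set used as simulation truth: the
#' empirical item estimates for the 40 items (10 per module over `T = 4`
#' modules, `K = 4` skills), the higher-order transition coefficients
#' `lambda = (-2.214, 2.757, 0.286)`, speed-change coefficient
#' `phi = -0.332`, disengaged accuracy `gstar = 0.503`, disengaged
#' log-latency law `(mu1, sigma1_sq) = (2.528, 1.158)`, and a synthetic
#' Q-matrix (the operational one is not public) generated per module with a
#' fixed seed so every skill is identified at every time point.
#'
#' The initial-class simplex places 0.527 mass on full mastery — the only
#' published feature of the empirical class distribution — and spreads the
#' remaining 0.473 uniformly over the other 15 classes. The latent-speed
#' variance, also unpublished, defaults to 2/3 (the mean of its
#' Inv-Gamma(2.5, 1) prior).
#'
#' @param omega Disengagement probability (default 0.03).
#' @param sigma_tau_sq Variance of initial latent speed (default 2/3).
#' @param pi Optional initial-class simplex of length `2^K` overriding the
#'   default completion.
#' @param q_seed Seed for the synthetic Q-matrix (default 20181205).
#' @return A list of class `mlm_params` with elements `items` (tibble),
#'   `q` (40 x 4 binary matrix), `item_time`, `lambda0`, `lambda1`,
#'   `lambda2`, `pi`, `omega`, `gstar`, `mu1`, `sigma1_sq`, `phi`,
#'   `sigma_tau_sq`, `n_skills`, `n_times`.
#' @export
#' @examples
#' p <- default_true_params()
#' exp(p$mu1)              # typical disengaged latency, ~12.5 s
#' mean(p$items$gamma)     # mean time intensity, ~3.10
default_true_params <- function(omega = 0.03, sigma_tau_sq = 2 / 3,
                                pi = NULL, q_seed = 20181205) {
  K <- 4L; T_ <- 4L
  items <- item_param_table()
  q <- do.call(rbind, lapply(seq_len(T_), function(m) {
    generate_q_matrix(10L, K, seed = q_seed + m)
  }))
  rownames(q) <- NULL
  if (is.null(pi)) {
    pi <- rep(0.473 / 15, 2^K)
    pi[profile_index(rep(1, K))] <- 0.527
  }
  stopifnot(length(pi) == 2^K, abs(sum(pi) - 1) < 1e-8)
  structure(list(
    items = items, q = q, item_time = rep(seq_len(T_), each = 10L),
    lambda0 = -2.214, lambda1 = 2.757, lambda2 = 0.286,
    pi = pi, omega = omega, gstar = 0.503,
    mu1 = 2.528, sigma1_sq = 1.158, phi = -0.332,
    sigma_tau_sq = sigma_tau_sq, n_skills = K, n_times = T_
  ), class = "mlm_params")
}

#' Prior hyperparameters for the Bayesian mixture learning model
#'
#' Collects the (fixed) hyperparameters of the prior: Beta(1,1) on `omega`
#' and `gstar`; Dirichlet(1) on the initial class simplex; N(0,1) on
#' `lambda0`, log-normal on `lambda1` (meanlog 0.5, sdlog 1) and `lambda2`
#' (meanlog -0.5, sdlog `lambda2_sd`); Beta priors on (s, g) restricted to
#' the order region `0 <= g < 1 - s <= 1`; N(0,1) on `gamma` and `phi`;
#' Gamma(1,1) on the squared time discrimination `a^2`; N(0,1) on `mu1` and
#' Inv-Gamma(1,1) on `sigma1_sq`; Inv-Gamma(2.5,1) on `sigma_tau_sq`;
#' standard normal on `theta`; N(0, sigma_tau_sq) on `tau`.
#'
#' @param a_s,b_s,a_g,b_g Beta hyperparameters for slipping and guessing
#'   (default 1, i.e. uniform on the constrained region).
#' @param lambda2_sd Sdlog of the log-normal prior on `lambda2`. The source
#'   literature's "0.6^2" notation is ambiguous between sd 0.6 and variance
#'   0.62; default reads it as sd 0.6.
#' @return List of class `mlm_priors`.
#' @export
prior_spec <- function(a_s = 1, b_s = 1, a_g = 1, b_g = 1, lambda2_sd = 0.6) {
  stopifnot(a_s > 0, b_s > 0, a_g > 0, b_g > 0, lambda2_sd > 0)
  structure(list(a_s = a_s, b_s = b_s, a_g = a_g, b_g = b_g,
                 lambda0_mean = 0, lambda0_sd = 1,
                 lambda1_meanlog = 0.5, lambda1_sdlog = 1,
                 lambda2_meanlog = -0.5, lambda2_sdlog = lambda2_sd,
                 gamma_mean = 0, gamma_sd = 1,
                 phi_mean = 0, phi_sd = 1,
                 a_sq_shape = 1, a_sq_rate = 1,
                 mu1_mean = 0, mu1_sd = 1,
                 sigma1_sq_shape = 1, sigma1_sq_rate = 1,
                 sigma_tau_sq_shape = 2.5, sigma_tau_sq_rate = 1),
            class = "mlm_priors")
}

# One draw of every fixed parameter from the prior (used by the
# simulate/update joint-correctness check).
draw_prior_params <- function(n_items, n_skills, n_times, item_time,
                              priors = prior_spec()) {
  C <- 2L^n_skills
  s <- stats::rbeta(n_items, priors$a_s, priors$b_s)
  g <- stats::rbeta(n_items, priors$a_g, priors$b_g)
  bad <- which(g >= 1 - s)
  while (length(bad) > 0) { # per-item rejection onto the order region
    s[bad] <- stats::rbeta(length(bad), priors$a_s, priors$b_s)
    g[bad] <- stats::rbeta(length(bad), priors$a_g, priors$b_g)
    bad <- which(g >= 1 - s)
  }
  list(
    items = tibble::tibble(
      item_id = seq_len(n_items), s = s, g = g,
      a = sqrt(stats::rgamma(n_items, priors$a_sq_shape,
                             rate = priors$a_sq_rate)),
      gamma = stats::rnorm(n_items, priors$gamma_mean, priors$gamma_sd)
    ),
    item_time = item_time,
    lambda0 = stats::rnorm(1, priors$lambda0_mean, priors$lambda0_sd),
    lambda1 = stats::rlnorm(1, priors$lambda1_meanlog, priors$lambda1_sdlog),
    lambda2 = stats::rlnorm(1, priors$lambda2_meanlog, priors$lambda2_sdlog),
    pi = as.numeric(rdirichlet1(rep(1, C))),
    omega = stats::rbeta(1, 1, 1),
    gstar = stats::rbeta(1, 1, 1),
    mu1 = stats::rnorm(1, priors$mu1_mean, priors$mu1_sd),
    sigma1_sq = 1 / stats::rgamma(1, priors$sigma1_sq_shape,
                                  rate = priors$sigma1_sq_rate),
    phi = stats::rnorm(1, priors$phi_mean, priors$phi_sd),
    sigma_tau_sq = 1 / stats::rgamma(1, priors$sigma_tau_sq_shape,
                                     rate = priors$sigma_tau_sq_rate),
    n_skills = n_skills, n_times = n_times
  )
}

rdirichlet1 <- function(shape) {
  x <- stats::rgamma(length(shape), shape, rate = 1)
  x / sum(x)
}
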