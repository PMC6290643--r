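# Shared fixtures: small parameter sets and datasets built in code.

# A small truth object in the same layout as default_true_params(), for
# arbitrary K / T / items-per-time.
make_params <- function(K = 2, T_ = 2, J_per = 2, omega = 0.2,
                        lambda = c(-0.5, 1, 0.5), gstar = 0.5,
                        mu1 = 2.5, sigma1_sq = 1, phi = -0.3,
                        sigma_tau_sq = 0.5, pi = NULL, q_seed = 42) {
  J <- J_per * T_
  q <- do.call(rbind, lapply(seq_len(T_), function(m) {
    if (J_per >= K) {
      generate_q_matrix(J_per, K, seed = q_seed + m)
    } else {
      # fewer items than skills in a module: single-skill rows, cycling
      m0 <- matrix(0L, J_per, K)
      for (r in seq_len(J_per)) m0[r, ((r - 1) %% K) + 1] <- 1L
      colnames(m0) <- paste0("skill_", seq_len(K))
      m0
    }
  }))
  if (is.null(pi)) pi <- rep(1 / 2^K, 2^K)
  withr::with_seed(q_seed, {
    items <- tibble::tibble(
      item_id = seq_len(J),
      s = stats::runif(J, 0.05, 0.2),
      g = stats::runif(J, 0.1, 0.3),
      a = stats::runif(J, 1.5, 2.5),
      gamma = stats::runif(J, 2.5, 3.5)
    )
  })
  list(items = items, q = q, item_time = rep(seq_len(T_), each = J_per),
       lambda0 = lambda[1], lambda1 = lambda[2], lambda2 = lambda[3],
       pi = pi, omega = omega, gstar = gstar, mu1 = mu1,
       sigma1_sq = sigma1_sq, phi = phi, sigma_tau_sq = sigma_tau_sq,
       n_skills = K, n_times = T_)
}

# Convert a class-index matrix (N x T, 0-based) to an N x T x K bit array.
classes_to_alpha <- function(cls, K) {
  N <- nrow(cls); T_ <- ncol(cls)
  tab <- profile_classes(K)
  out <- array(0L, c(N, T_, K))
  for (t in seq_len(T_)) out[, t, ] <- tab[cls[, t] + 1L, ]
  out
}

# Convert an N x T x K bit array to 0-based class indices.
alpha_to_classes <- function(alpha) {
  N <- dim(alpha)[1]; T_ <- dim(alpha)[2]; K <- dim(alpha)[3]
  cls <- matrix(0L, N, T_)
  for (t in seq_len(T_)) {
    A <- matrix(alpha[, t, ], ncol = K)
    cls[, t] <- as.integer(A %*% 2L^(seq_len(K) - 1L))
  }
  cls
}

# A sampler starting state with the latent states pinned to given values.
pinned_init <- function(sim, params = sim$params, latent = sim$truth) {
  J <- nrow(params$q)
  list(
    alpha = alpha_to_classes(latent$alpha),
    D = latent$D,
    theta = latent$theta, tau = latent$tau,
    s = params$items$s, g = params$items$g,
    gamma = params$items$gamma, a = params$items$a,
    lambda = c(params$lambda0, params$lambda1, params$lambda2),
    pi = params$pi, omega = params$omega, gstar = params$gstar,
    mu1 = params$mu1, sigma1_sq = params$sigma1_sq, phi = params$phi,
    sigma_tau_sq = params$sigma_tau_sq
  )
}

# An mlm_data shell with zero learners (prior-recovery runs).
empty_mlm_data <- function(J = 2, K = 1, T_ = 1) {
  q <- matrix(1L, J, K, dimnames = list(NULL, paste0("skill_", seq_len(K))))
  structure(list(
    responses = matrix(integer(), 0, J),
    latencies = matrix(numeric(), 0, J),
    q = q,
    item_time = rep(seq_len(T_), length.out = J),
    learner_ids = integer(), item_ids = seq_len(J),
    n_learners = 0L, n_times = T_, n_skills = K, n_items = J
  ), class = "mlm_data")
}

update_only <- function(...) {
  u <- list(latents = FALSE, person = FALSE, item = FALSE,
            structural = FALSE)
  for (nm in c(...)) u[[nm]] <- TRUE
  u
}
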