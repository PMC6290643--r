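#' Sample initial attribute profiles from a class simplex
#'
#' Draws i.i.d. initial profiles from the multinomial distribution over all
#' `2^K` latent classes.
#'
#' @param pi Probability simplex over the `2^K` classes (class order as in
#'   [profile_classes()]).
#' @param n Number of learners.
#' @param seed Optional seed.
#' @return An `n x K` binary matrix of profiles.
#' @export
sample_initial_profiles <- function(pi, n, seed = NULL) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must be a probability simplex.", call. = FALSE)
  }
  K <- log2(length(pi))
  if (K != round(K)) {
    stop("`pi` must have length 2^K.", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  classes <- sample.int(length(pi), n, replace = TRUE, prob = pi)
  profile_classes(as.integer(K))[classes, , drop = FALSE]
}

# Latent trajectories (alpha, D, theta, tau) for N learners under the
# mixture learning model. Engaged transitions follow the higher-order
# logistic acquisition model with no forgetting; disengaged time points
# freeze the profile.
simulate_latent_trajectories <- function(params, n_learners) {
  K <- params$n_skills; T_ <- params$n_times; N <- n_learners
  theta <- stats::rnorm(N)
  tau <- stats::rnorm(N, 0, sqrt(params$sigma_tau_sq))
  D <- matrix(stats::rbinom(N * T_, 1, params$omega), N, T_)
  alpha <- array(0L, c(N, T_, K))
  alpha[, 1, ] <- sample_initial_profiles(params$pi, N)
  for (t in seq_len(T_ - 1)) {
    for (i in seq_len(N)) {
      cur <- alpha[i, t, ]
      if (D[i, t] == 1) {
        alpha[i, t + 1, ] <- cur
      } else {
        p <- skill_transition_prob(theta[i], sum(cur), params$lambda0,
                                   params$lambda1, params$lambda2)
        nxt <- cur
        idx <- which(cur == 0)
        nxt[idx] <- stats::rbinom(length(idx), 1, p)
        alpha[i, t + 1, ] <- nxt
      }
    }
  }
  list(alpha = alpha, D = D, theta = theta, tau = tau)
}

# Measurement step: responses and latencies given latent states and
# parameters. Shared by the simulator and the posterior predictive checks.
simulate_observations <- function(params, latent) {
  N <- dim(latent$alpha)[1]; T_ <- dim(latent$alpha)[2]
  q <- params$q; item_time <- params$item_time
  J <- nrow(q)
  X <- matrix(0L, N, J)
  L <- matrix(0, N, J)
  s <- params$items$s; g <- params$items$g
  a <- params$items$a; gamma <- params$items$gamma
  for (t in seq_len(T_)) {
    A_t <- matrix(latent$alpha[, t, ], nrow = N)
    d <- latent$D[, t]
    for (j in which(item_time == t)) {
      # eta doubles as the speed covariate G (same component-wise rule)
      eta <- as.integer(A_t %*% q[j, ] == sum(q[j, ]))
      p_correct <- ifelse(d == 1, params$gstar,
                          ifelse(eta == 1, 1 - s[j], g[j]))
      X[, j] <- stats::rbinom(N, 1, p_correct)
      mean_log <- ifelse(d == 1, params$mu1,
                         gamma[j] - (latent$tau + params$phi * eta))
      sd_log <- ifelse(d == 1, sqrt(params$sigma1_sq), 1 / a[j])
      L[, j] <- exp(stats::rnorm(N, mean_log, sd_log))
    }
  }
  list(responses = X, latencies = L)
}

#' Simulate a full learner-log dataset from the mixture learning model
#'
#' Generates latent trajectories and observations for `n_learners` under
#' the study design: `K = 4` skills, `T = 4` modules of 10 items each (for
#' the default parameters), engagement mode drawn per (learner, time) with
#' probability `omega` of disengagement. Engaged cells answer under DINA
#' with the dynamic log-normal latency model; disengaged cells rapid-guess
#' at `gstar` with the flat log-normal latency law and frozen profiles.
#' The latent truth is returned alongside the data for recovery scoring.
#'
#' @param n_learners Number of learners (default 585).
#' @param params True parameters, an `mlm_params` list as returned by
#'   [default_true_params()].
#' @param seed Optional seed, recorded in the result.
#' @return An object of class `mlm_sim`: list with `data` (long tibble),
#'   `q_matrix` (tibble), `mlm` (validated `mlm_data`), `truth` (list with
#'   `alpha`, `D`, `theta`, `tau`), `params`, and `seed`.
#' @export
#' @examples
#' sim <- simulate_learning_data(20, seed = 1)
#' sim$data
simulate_learning_data <- function(n_learners = 585,
                                   params = default_true_params(),
                                   seed = NULL) {
  stopifnot(n_learners >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  latent <- simulate_latent_trajectories(params, n_learners)
  obs <- simulate_observations(params, latent)
  J <- nrow(params$q)
  data <- tibble::tibble(
    learner_id = rep(seq_len(n_learners), each = J),
    time = rep(params$item_time, n_learners),
    item_id = rep(seq_len(J), n_learners),
    response = as.integer(t(obs$responses)),
    rt_seconds = as.numeric(t(obs$latencies))
  )
  q_matrix <- tibble::as_tibble(cbind(item_id = seq_len(J), params$q))
  structure(list(
    data = data, q_matrix = q_matrix,
    mlm = as_mlm_data(data, q_matrix),
    truth = latent, params = params, seed = seed
  ), class = "mlm_sim")
}

#' @export
print.mlm_sim <- function(x, ...) {
  cat("<mlm_sim> ", x$mlm$n_learners, " learners, ", x$mlm$n_times,
      " time points, ", x$mlm$n_items, " items; omega = ",
      x$params$omega, if (!is.null(x$seed)) paste0("; seed = ", x$seed),
      "\n", sep = "")
  invisible(x)
}
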