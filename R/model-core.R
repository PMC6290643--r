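#' Enumerate all attribute profiles for K skills
#'
#' Returns the full set of binary mastery profiles, one per latent class.
#' Class `c` corresponds to the binary expansion of `c - 1` with skill 1 as
#' the least significant bit, so `profile_index()` and `profile_classes()`
#' are inverses.
#'
#' @param n_skills Number of skills `K` (>= 1).
#' @return A `2^K x K` binary matrix; row `c` is the profile of class `c`.
#' @export
#' @examples
#' profile_classes(2)
profile_classes <- function(n_skills) {
  stopifnot(is.numeric(n_skills), length(n_skills) == 1L, n_skills >= 1)
  K <- as.integer(n_skills)
  C <- 2L^K
  m <- matrix(0L, C, K)
  for (k in seq_len(K)) {
    m[, k] <- bitwAnd(seq_len(C) - 1L, bitwShiftL(1L, k - 1L)) > 0L
  }
  storage.mode(m) <- "integer"
  colnames(m) <- paste0("skill_", seq_len(K))
  m
}

#' Class index of an attribute profile
#'
#' @param alpha Binary mastery profile (vector of 0/1).
#' @return Integer class index in `1..2^K`.
#' @export
profile_index <- function(alpha) {
  check_binary(alpha, "alpha")
  1L + as.integer(sum(alpha * 2L^(seq_along(alpha) - 1L)))
}

check_binary <- function(x, name) {
  if (!is.numeric(x) && !is.logical(x)) {
    stop(sprintf("`%s` must be a binary (0/1) vector.", name), call. = FALSE)
  }
  if (any(is.na(x)) || any(!x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0 and 1.", name), call. = FALSE)
  }
  invisible(x)
}

check_prob <- function(x, name, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad) {
    stop(sprintf("`%s` must lie in the unit interval.", name), call. = FALSE)
  }
  invisible(x)
}

#' Ideal response under the DINA rule
#'
#' The ideal response is 1 exactly when every skill required by the item is
#' mastered: `eta = prod_k alpha_k ^ q_k`.
#'
#' @param alpha Binary mastery profile, length `K`.
#' @param q_row Binary skill-requirement vector of the item, length `K`.
#' @return 0 or 1.
#' @export
#' @examples
#' ideal_response(c(1, 0, 1, 0), c(1, 0, 1, 0)) # 1
#' ideal_response(c(0, 1, 1, 1), c(1, 0, 0, 0)) # 0
ideal_response <- function(alpha, q_row) {
  check_binary(alpha, "alpha")
  check_binary(q_row, "q_row")
  if (length(alpha) != length(q_row)) {
    stop("`alpha` and `q_row` must have the same length.", call. = FALSE)
  }
  as.integer(all(alpha >= q_row))
}

#' Speed covariate for the engaged response-time model
#'
#' Indicator that the profile dominates the item's requirements
#' component-wise (`alpha >= q` in every skill). Numerically identical to
#' [ideal_response()]; kept as its own verb because it plays a different
#' role, shifting the engaged latency mean by the speed-change coefficient.
#'
#' @inheritParams ideal_response
#' @return 0 or 1.
#' @export
speed_covariate <- function(alpha, q_row) {
  ideal_response(alpha, q_row)
}

#' Probability of a correct response under either engagement mode
#'
#' Engaged (`mode = 0`): DINA, `(1 - s)^eta * g^(1 - eta)`. Disengaged
#' (`mode = 1`): rapid guessing at the flat accuracy `gstar`, regardless of
#' the profile.
#'
#' @param mode Engagement mode: 0 = engaged, 1 = disengaged.
#' @param eta Ideal response (0/1); ignored when `mode = 1`.
#' @param s,g Slipping and guessing probabilities of the item.
#' @param gstar Disengaged correct-response probability.
#' @return Probability of a correct response.
#' @export
#' @examples
#' response_prob(0, 1, s = 0.045, g = 0.811)          # 0.955
#' response_prob(1, 0, s = 0.5, g = 0.5, gstar = 0.503) # 0.503
response_prob <- function(mode, eta, s, g, gstar = 0.5) {
  stopifnot(mode %in% c(0, 1))
  if (mode == 1) {
    check_prob(gstar, "gstar")
    return(gstar)
  }
  check_binary(eta, "eta")
  check_prob(s, "s")
  check_prob(g, "g")
  if (eta == 1) 1 - s else g
}

#' Log-density of an observed latency under either engagement mode
#'
#' Latencies are log-normal in both modes. Engaged: `log L ~ N(gamma -
#' (tau + phi * G), 1/a^2)`. Disengaged: `log L ~ N(mu1, sigma1_sq)`. The
#' returned value is the log-density of `L` itself (normal kernel on
#' `log(l)` plus the `-log(l)` Jacobian).
#'
#' @param mode Engagement mode: 0 = engaged, 1 = disengaged.
#' @param l Observed latency in seconds (> 0).
#' @param gamma Item time intensity (log-seconds).
#' @param a Item time discrimination (> 0); latency precision is `a^2`.
#' @param tau Learner's initial latent speed.
#' @param phi Speed-change coefficient applied when `G = 1`.
#' @param G Speed covariate (0/1) from [speed_covariate()].
#' @param mu1,sigma1_sq Disengaged log-latency mean and variance.
#' @return Log-density value.
#' @export
rt_logdensity <- function(mode, l, gamma = NULL, a = NULL, tau = NULL,
                          phi = NULL, G = NULL, mu1 = NULL, sigma1_sq = NULL) {
  stopifnot(mode %in% c(0, 1))
  if (any(l <= 0)) stop("Latencies must be strictly positive.", call. = FALSE)
  if (mode == 1) {
    stopifnot(sigma1_sq > 0)
    stats::dnorm(log(l), mu1, sqrt(sigma1_sq), log = TRUE) - log(l)
  } else {
    stopifnot(a > 0)
    stats::dnorm(log(l), gamma - (tau + phi * G), 1 / a, log = TRUE) - log(l)
  }
}

#' Per-skill acquisition probability for an engaged learner
#'
#' Logistic probability of transitioning from non-mastery to mastery of one
#' skill between adjacent time points:
#' `logit(p) = lambda0 + lambda1 * theta + lambda2 * n_other_mastered`.
#'
#' @param theta Learner's general learning ability.
#' @param n_other_mastered Number of *other* skills currently mastered.
#' @param lambda0 Intercept.
#' @param lambda1 Slope on learning ability (> 0).
#' @param lambda2 Slope on the count of other mastered skills (> 0).
#' @return Acquisition probability.
#' @export
#' @examples
#' skill_transition_prob(0, 0, -2.214, 2.757, 0.286) # 0.0985
skill_transition_prob <- function(theta, n_other_mastered,
                                  lambda0, lambda1, lambda2) {
  stopifnot(n_other_mastered >= 0)
  stats::plogis(lambda0 + lambda1 * theta + lambda2 * n_other_mastered)
}

#' Transition probability between whole attribute profiles
#'
#' Disengaged (`D_t = 1`): the profile is frozen, so the probability is the
#' indicator that the next profile equals the current one. Engaged
#' (`D_t = 0`): mastered skills are retained with probability 1 (no
#' forgetting); each unmastered skill is acquired independently with the
#' probability from [skill_transition_prob()].
#'
#' @param alpha_t,alpha_next Binary profiles at times `t` and `t + 1`.
#' @param theta Learner's learning ability.
#' @param D_t Engagement mode at time `t`.
#' @param lambdas Numeric vector `c(lambda0, lambda1, lambda2)`.
#' @return Transition probability.
#' @export
profile_transition_prob <- function(alpha_t, alpha_next, theta, D_t, lambdas) {
  check_binary(alpha_t, "alpha_t")
  check_binary(alpha_next, "alpha_next")
  stopifnot(length(alpha_t) == length(alpha_next), length(lambdas) == 3,
            D_t %in% c(0, 1))
  if (D_t == 1) {
    return(as.numeric(all(alpha_next == alpha_t)))
  }
  if (any(alpha_t == 1 & alpha_next == 0)) {
    return(0) # forgetting a mastered skill has probability 0
  }
  n_mastered <- sum(alpha_t)
  p <- 1
  for (k in seq_along(alpha_t)) {
    if (alpha_t[k] == 0) {
      pk <- skill_transition_prob(theta, n_mastered,
                                  lambdas[1], lambdas[2], lambdas[3])
      p <- p * if (alpha_next[k] == 1) pk else 1 - pk
    }
  }
  p
}

#' Complete-data log-likelihood of the mixture learning model
#'
#' Sums, over learners, time points and items, the log-probability of the
#' full latent-and-observed configuration: initial class membership, the
#' Bernoulli engagement indicators, the mode-conditional profile
#' transitions, and the mode-conditional response and latency terms. The
#' latent priors on `theta` and `tau` are not included: this is the density
#' of `(X, L, alpha, D)` given all parameters.
#'
#' A latent configuration that violates the model's support (an engaged
#' transition that loses a mastered skill, or a profile change under a
#' frozen disengaged link) yields `-Inf` with attribute
#' `invariant_violation = TRUE`.
#'
#' @param data An [mlm_data] object (see [as_mlm_data()]).
#' @param latent List with `alpha` (`N x T x K` binary array) and `D`
#'   (`N x T` binary matrix).
#' @param item_params List or data frame with vectors `s`, `g`, `gamma`,
#'   `a`, one entry per item (in `data` item order).
#' @param person_params List with vectors `theta` and `tau`, one per learner.
#' @param structural List with `lambda0`, `lambda1`, `lambda2`, `pi`
#'   (length `2^K`), `omega`, `gstar`, `mu1`, `sigma1_sq`, `phi`.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(data, latent, item_params, person_params,
                                 structural) {
  stopifnot(inherits(data, "mlm_data"))
  N <- data$n_learners; T_ <- data$n_times; K <- data$n_skills
  alpha <- latent$alpha; D <- latent$D
  stopifnot(all(dim(alpha) == c(N, T_, K)), all(dim(D) == c(N, T_)))
  lambdas <- c(structural$lambda0, structural$lambda1, structural$lambda2)

  ll <- 0
  violated <- FALSE
  for (i in seq_len(N)) {
    ll <- ll + log(structural$pi[profile_index(alpha[i, 1, ])])
    for (t in seq_len(T_)) {
      d <- D[i, t]
      ll <- ll + if (d == 1) log(structural$omega) else log1p(-structural$omega)
      if (t < T_) {
        ptr <- profile_transition_prob(alpha[i, t, ], alpha[i, t + 1, ],
                                       person_params$theta[i], d, lambdas)
        if (ptr == 0) violated <- TRUE
        ll <- ll + log(ptr)
      }
      for (j in which(data$item_time == t)) {
        eta <- ideal_response(alpha[i, t, ], data$q[j, ])
        pr <- response_prob(d, eta, item_params$s[j], item_params$g[j],
                            structural$gstar)
        x <- data$responses[i, j]
        ll <- ll + log(if (x == 1) pr else 1 - pr)
        ll <- ll + rt_logdensity(d, data$latencies[i, j],
                                 gamma = item_params$gamma[j],
                                 a = item_params$a[j],
                                 tau = person_params$tau[i],
                                 phi = structural$phi, G = eta,
                                 mu1 = structural$mu1,
                                 sigma1_sq = structural$sigma1_sq)
      }
    }
  }
  if (violated) ll <- -Inf
  attr(ll, "invariant_violation") <- violated
  ll
}

# Measurement-only log-likelihood (responses + latencies given latents and
# parameters); the quantity whose -2x is the joint deviance.
measurement_loglik <- function(data, latent, item_params, person_params,
                               structural) {
  N <- data$n_learners; T_ <- data$n_times
  alpha <- latent$alpha; D <- latent$D
  ll <- 0
  for (i in seq_len(N)) {
    for (t in seq_len(T_)) {
      d <- D[i, t]
      for (j in which(data$item_time == t)) {
        eta <- ideal_response(alpha[i, t, ], data$q[j, ])
        pr <- response_prob(d, eta, item_params$s[j], item_params$g[j],
                            structural$gstar)
        x <- data$responses[i, j]
        ll <- ll + log(if (x == 1) pr else 1 - pr)
        ll <- ll + rt_logdensity(d, data$latencies[i, j],
                                 gamma = item_params$gamma[j],
                                 a = item_params$a[j],
                                 tau = person_params$tau[i],
                                 phi = structural$phi, G = eta,
                                 mu1 = structural$mu1,
                                 sigma1_sq = structural$sigma1_sq)
      }
    }
  }
  ll
}
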