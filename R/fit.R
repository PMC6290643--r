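#' Sampler control settings
#'
#' Tuning knobs for the MH-within-Gibbs sampler. Random-walk proposal
#' scales default to 0.5 (learning ability) and 0.2 (acquisition
#' coefficients, on the `(lambda0, log lambda1, log lambda2)` scale) and
#' are adapted during burn-in toward a 20-50% acceptance rate.
#'
#' @param prop_theta Initial proposal sd for each learner's ability.
#' @param prop_lambda Initial proposal sd for the acquisition-coefficient
#'   block.
#' @param adapt Adapt proposal scales during burn-in (default TRUE).
#' @param n_snapshots Target number of stored latent-state snapshots used
#'   by the DIC and posterior predictive machinery (default 100).
#' @param save_person Store full per-draw ability/speed chains (needed when
#'   person parameters should enter convergence diagnostics; default FALSE
#'   because running means suffice for point estimates).
#' @param priors Prior hyperparameters, see [prior_spec()].
#' @param update Named logical list selecting which blocks are updated
#'   (`latents`, `person`, `item`, `structural`); partial updates are used
#'   by the package's own validation machinery.
#' @return List of class `mlm_control`.
#' @export
mlm_control <- function(prop_theta = 0.5, prop_lambda = 0.2, adapt = TRUE,
                        n_snapshots = 100, save_person = FALSE,
                        priors = prior_spec(),
                        update = list(latents = TRUE, person = TRUE,
                                      item = TRUE, structural = TRUE)) {
  stopifnot(prop_theta > 0, prop_lambda > 0, n_snapshots >= 0)
  structure(list(prop_theta = prop_theta, prop_lambda = prop_lambda,
                 adapt = adapt, n_snapshots = n_snapshots,
                 save_person = save_person, priors = priors,
                 update = update),
            class = "mlm_control")
}

#' Draw a dispersed starting state for the sampler
#'
#' Generates initial values from the dispersed recipe used for the
#' estimation experiments: `lambda0 ~ N(0,1)`, `lambda1, lambda2 ~ U(0,1)`,
#' `pi ~ Dirichlet(1)`, `phi ~ U(0,1)`, `omega ~ U(0, 0.2)`,
#' `gstar ~ U(0, 0.5)`, `s_j, g_j ~ U(0, 0.3)` (automatically inside the
#' order region), `mu1 ~ N(2, 1)`, `sigma1 ~ U(0,1)`,
#' `gamma_j ~ N(3.45, 0.5^2)`, `a_j ~ U(2, 4)`,
#' `sigma_tau_sq ~ Inv-Gamma(1,1)`; the latent states are then drawn
#' forward from the model given these values.
#'
#' @param data An `mlm_data` object.
#' @param mixture If FALSE, initialize the engaged-only restriction
#'   (`omega = 0`, all modes engaged).
#' @param seed Optional seed.
#' @return A named list of starting values (profiles as class indices).
#' @export
init_chain <- function(data, mixture = TRUE, seed = NULL) {
  stopifnot(inherits(data, "mlm_data"))
  if (!is.null(seed)) withr::local_seed(seed)
  N <- data$n_learners; T_ <- data$n_times; K <- data$n_skills
  J <- data$n_items; C <- 2L^K
  st <- list(
    lambda = c(stats::rnorm(1), stats::runif(1), stats::runif(1)),
    pi = as.numeric(rdirichlet1(rep(1, C))),
    phi = stats::runif(1),
    omega = if (mixture) stats::runif(1, 0, 0.2) else 0,
    gstar = stats::runif(1, 0, 0.5),
    s = stats::runif(J, 0, 0.3),
    g = stats::runif(J, 0, 0.3),
    mu1 = stats::rnorm(1, 2, 1),
    sigma1_sq = stats::runif(1)^2,
    gamma = stats::rnorm(J, 3.45, 0.5),
    a = stats::runif(J, 2, 4),
    sigma_tau_sq = 1 / stats::rgamma(1, 1, rate = 1)
  )
  st$theta <- stats::rnorm(N)
  st$tau <- stats::rnorm(N, 0, sqrt(st$sigma_tau_sq))
  D <- matrix(if (mixture) stats::rbinom(N * T_, 1, st$omega) else 0L,
              N, T_)
  alpha <- matrix(0L, N, T_)
  classes <- profile_classes(K)
  alpha[, 1] <- sample.int(C, N, replace = TRUE, prob = st$pi) - 1L
  for (t in seq_len(T_ - 1)) {
    for (i in seq_len(N)) {
      if (D[i, t] == 1) {
        alpha[i, t + 1] <- alpha[i, t]
      } else {
        cur <- classes[alpha[i, t] + 1L, ]
        p <- skill_transition_prob(st$theta[i], sum(cur), st$lambda[1],
                                   st$lambda[2], st$lambda[3])
        nxt <- cur
        idx <- which(cur == 0)
        if (length(idx) > 0) nxt[idx] <- stats::rbinom(length(idx), 1, p)
        alpha[i, t + 1] <- profile_index(nxt) - 1L
      }
    }
  }
  st$alpha <- alpha
  st$D <- D
  st
}

#' Fit the mixture learning model by MH-within-Gibbs sampling
#'
#' Runs the posterior sampler: block updates of attribute-profile segments
#' frozen together by disengaged links, two-point Gibbs draws of the
#' engagement modes, random-walk Metropolis for abilities and acquisition
#' coefficients, and conjugate draws for everything else. Point estimates
#' are posterior means (EAP); discrete latents are dichotomized at 0.5 by
#' [latent_estimates()].
#'
#' @param data Long-format tibble of learner logs (see [as_mlm_data()]) or
#'   an `mlm_data` object.
#' @param q_matrix Q-matrix tibble; ignored when `data` is already
#'   `mlm_data`.
#' @param n_iter Total chain length (default 30000).
#' @param burnin Burn-in iterations excluded from estimates (default 5000).
#' @param mixture If FALSE, fit the engaged-only restriction (`omega = 0`,
#'   every mode engaged) — the non-mixture joint model nested in this one.
#' @param init Starting state as from [init_chain()]; drawn automatically
#'   if NULL.
#' @param seed Optional seed; a seeded run is bit-reproducible.
#' @param control Sampler settings from [mlm_control()].
#' @return An object of class `mlm_fit`; see [tidy.mlm_fit()],
#'   [glance.mlm_fit()], [latent_estimates()], [joint_dic()],
#'   [ppc_pvalues()].
#' @export
#' @examples
#' sim <- simulate_learning_data(25, seed = 1)
#' fit <- fit_mlm(sim$data, sim$q_matrix, n_iter = 200, burnin = 50, seed = 2)
#' tidy(fit)
fit_mlm <- function(data, q_matrix = NULL, n_iter = 30000, burnin = 5000,
                    mixture = TRUE, init = NULL, seed = NULL,
                    control = mlm_control()) {
  mlm <- if (inherits(data, "mlm_data")) data else as_mlm_data(data, q_matrix)
  stopifnot(n_iter >= 1, burnin >= 0, burnin < n_iter)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(init)) init <- init_chain(mlm, mixture = mixture)
  n_keep <- n_iter - burnin
  snap_stride <- if (control$n_snapshots > 0 && n_keep > 0) {
    max(1L, n_keep %/% as.integer(control$n_snapshots))
  } else 0L

  # proposals adapt over the burn-in; when everything is stored
  # (burnin = 0, for convergence diagnostics that discard the first half
  # themselves) adaptation runs over the first half instead
  adapt_iter <- if (burnin > 0) burnin else floor(n_iter / 2)
  cfg <- list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
              adapt_iter = as.integer(adapt_iter),
              snap_stride = as.integer(snap_stride), mixture = mixture,
              update_latents = isTRUE(control$update$latents),
              update_person = isTRUE(control$update$person),
              update_item = isTRUE(control$update$item),
              update_structural = isTRUE(control$update$structural),
              adapt = isTRUE(control$adapt),
              save_person = isTRUE(control$save_person),
              prop_theta = control$prop_theta,
              prop_lambda = control$prop_lambda)
  res <- .mlm_mcmc_cpp(mlm$responses, log(mlm$latencies),
                       as.integer(mlm$item_time), mlm$q,
                       as.integer(mlm$n_times), init, cfg, control$priors)
  structure(list(
    draws = res$draws,
    person_draws = if (control$save_person) res$person_draws else NULL,
    theta_mean = as.numeric(res$theta_mean),
    tau_mean = as.numeric(res$tau_mean),
    alpha_prob = res$alpha_prob,
    D_prob = res$D_prob,
    snapshots = list(alpha = res$snap_alpha, D = res$snap_D,
                     tau = res$snap_tau, iter = as.integer(res$snap_iter)),
    accept = c(theta = res$accept_theta, lambda = res$accept_lambda),
    final_state = res$final_state,
    data = mlm, mixture = mixture,
    n_iter = n_iter, burnin = burnin, seed = seed
  ), class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("<mlm_fit> ", if (x$mixture) "mixture" else "engaged-only (omega = 0)",
      " model; ", x$n_iter, " iterations (", x$burnin, " burn-in), ",
      x$data$n_learners, " learners\n", sep = "")
  est <- tidy(x)
  core <- est[est$term %in% c("lambda0", "lambda1", "lambda2", "omega",
                              "gstar", "mu1", "sigma1_sq", "phi",
                              "sigma_tau_sq"), ]
  print(core, n = nrow(core))
  invisible(x)
}

#' Posterior summaries of the fixed parameters
#'
#' One row per stored scalar parameter with its posterior mean (EAP) and
#' posterior standard deviation.
#'
#' @param x An `mlm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy mlm_fit
#' @export
tidy.mlm_fit <- function(x, ...) {
  d <- x$draws
  keep <- colnames(d) != "deviance"
  tibble::tibble(
    term = colnames(d)[keep],
    estimate = unname(colMeans(d[, keep, drop = FALSE])),
    std.error = unname(apply(d[, keep, drop = FALSE], 2, stats::sd))
  )
}

#' One-row model summary
#'
#' @param x An `mlm_fit` object.
#' @param ... Unused.
#' @return A tibble with the chain setup, MH acceptance rates, estimated
#'   disengagement probability, and the joint DIC.
#' @method glance mlm_fit
#' @export
glance.mlm_fit <- function(x, ...) {
  tibble::tibble(
    n_learners = x$data$n_learners,
    n_items = x$data$n_items,
    n_iter = x$n_iter,
    burnin = x$burnin,
    mixture = x$mixture,
    accept_theta = unname(x$accept["theta"]),
    accept_lambda = unname(x$accept["lambda"]),
    omega = mean(x$draws[, "omega"]),
    dic = joint_dic(x)$dic
  )
}

#' Point estimates of the discrete latent states
#'
#' Dichotomizes the post-burn-in inclusion frequencies at 0.5: a skill is
#' called mastered, or a cell disengaged, when its posterior frequency
#' exceeds 0.5. Exact ties resolve to 0 (non-mastery / engaged).
#'
#' @param fit An `mlm_fit` object.
#' @return List with `alpha` (`N x T x K` binary array), `D` (`N x T`
#'   binary matrix), `theta` and `tau` (posterior-mean vectors).
#' @export
latent_estimates <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  list(alpha = (fit$alpha_prob > 0.5) * 1L,
       D = (fit$D_prob > 0.5) * 1L,
       theta = fit$theta_mean, tau = fit$tau_mean)
}

#' Posterior summaries of a fitted model
#'
#' Convenience wrapper returning EAP/SD summaries of the fixed parameters
#' together with the dichotomized latent-state estimates.
#'
#' @param fit An `mlm_fit` object.
#' @return List with `parameters` (tibble, as [tidy.mlm_fit()]) and
#'   `latents` (as [latent_estimates()]).
#' @export
posterior_summaries <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (nrow(fit$draws) == 0) {
    stop("No post-burn-in draws stored.", call. = FALSE)
  }
  list(parameters = tidy(fit), latents = latent_estimates(fit))
}

# Extract the EAP parameter set of a fit in the same layout as the
# simulator truth (used by DIC, PPC and the evaluation harness).
eap_params <- function(fit) {
  est <- colMeans(fit$draws)
  J <- fit$data$n_items
  grab <- function(prefix) unname(est[paste0(prefix, "_", seq_len(J))])
  list(
    items = tibble::tibble(item_id = seq_len(J), s = grab("s"),
                           g = grab("g"), a = grab("a"),
                           gamma = grab("gamma")),
    q = fit$data$q, item_time = fit$data$item_time,
    lambda0 = unname(est["lambda0"]), lambda1 = unname(est["lambda1"]),
    lambda2 = unname(est["lambda2"]),
    pi = unname(est[paste0("pi_", seq_len(2^fit$data$n_skills))]),
    omega = unname(est["omega"]), gstar = unname(est["gstar"]),
    mu1 = unname(est["mu1"]), sigma1_sq = unname(est["sigma1_sq"]),
    phi = unname(est["phi"]), sigma_tau_sq = unname(est["sigma_tau_sq"]),
    n_skills = fit$data$n_skills, n_times = fit$data$n_times
  )
}

# Parameter set at one stored draw (by kept-draw row index).
draw_params <- function(fit, row) {
  est <- fit$draws[row, ]
  J <- fit$data$n_items
  grab <- function(prefix) unname(est[paste0(prefix, "_", seq_len(J))])
  list(
    items = tibble::tibble(item_id = seq_len(J), s = grab("s"),
                           g = grab("g"), a = grab("a"),
                           gamma = grab("gamma")),
    q = fit$data$q, item_time = fit$data$item_time,
    lambda0 = unname(est["lambda0"]), lambda1 = unname(est["lambda1"]),
    lambda2 = unname(est["lambda2"]),
    pi = unname(est[paste0("pi_", seq_len(2^fit$data$n_skills))]),
    omega = unname(est["omega"]), gstar = unname(est["gstar"]),
    mu1 = unname(est["mu1"]), sigma1_sq = unname(est["sigma1_sq"]),
    phi = unname(est["phi"]), sigma_tau_sq = unname(est["sigma_tau_sq"]),
    n_skills = fit$data$n_skills, n_times = fit$data$n_times
  )
}

#' Trace and posterior-summary plot for a fitted model
#'
#' Trace plots of selected parameters over the stored draws.
#'
#' @param object An `mlm_fit` object.
#' @param pars Character vector of parameter names (columns of the draw
#'   matrix); defaults to the structural block.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlm_fit
#' @export
autoplot.mlm_fit <- function(object, pars = c("lambda0", "lambda1",
                                              "lambda2", "omega", "gstar",
                                              "mu1", "phi"), ...) {
  pars <- intersect(pars, colnames(object$draws))
  df <- tibble::as_tibble(object$draws[, pars, drop = FALSE])
  df$.iteration <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -".iteration", names_to = "term",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "stored iteration", y = NULL)
}
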