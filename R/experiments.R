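#' Replicated parameter-recovery experiment
#'
#' Runs the full simulate-then-refit recovery study: each replicate
#' simulates a dataset under the reference truth ([default_true_params()])
#' and refits the mixture model with the MH-within-Gibbs sampler, and the
#' replicates are scored against truth with [recovery_report()].
#'
#' @param n_replicates Number of simulate/fit replicates (default 3).
#' @param n_learners Learners per replicate (default 585).
#' @param omega True disengagement probability (default 0.03).
#' @param n_iter,burnin Chain length and burn-in per fit (defaults 5000 /
#'   1000; the full-scale analysis recipe is 30000 / 5000).
#' @param seed Base seed; replicate r uses `seed + r` for the data and
#'   `seed + 1000 + r` for the chain.
#' @param params True parameter set (default [default_true_params()] with
#'   the given `omega`).
#' @return List with `sims`, `fits`, and `report` (an `mlm_recovery`).
#' @export
recovery_experiment <- function(n_replicates = 3, n_learners = 585,
                                omega = 0.03, n_iter = 5000, burnin = 1000,
                                seed = 1,
                                params = default_true_params(omega = omega)) {
  sims <- lapply(seq_len(n_replicates), function(r) {
    simulate_learning_data(n_learners, params = params, seed = seed + r)
  })
  fits <- lapply(seq_len(n_replicates), function(r) {
    fit_mlm(sims[[r]]$mlm, n_iter = n_iter, burnin = burnin,
            seed = seed + 1000 + r)
  })
  list(sims = sims, fits = fits, report = recovery_report(sims, fits))
}

#' Multi-chain convergence experiment
#'
#' Simulates one dataset and runs several chains from independent
#' dispersed starting states ([init_chain()]), storing every iteration so
#' the Gelman-Rubin diagnostic can be evaluated with the first half of the
#' chain as burn-in. Person parameters are stored per draw and included.
#'
#' @param n_learners Learners in the simulated dataset (default 200, a
#'   reduced size at which the diagnostic already reproduces the
#'   full-design behavior).
#' @param omega True disengagement probability (default 0.10).
#' @param n_chains Number of chains (default 5).
#' @param n_iter Iterations per chain (default 5000).
#' @param seed Base seed.
#' @param params True parameter set.
#' @return List with `sim`, `fits`, `psrf` (tibble from [psrf_summary()])
#'   and `max_psrf`.
#' @export
convergence_experiment <- function(n_learners = 200, omega = 0.10,
                                   n_chains = 5, n_iter = 5000, seed = 1,
                                   params = default_true_params(
                                     omega = omega)) {
  sim <- simulate_learning_data(n_learners, params = params, seed = seed)
  fits <- lapply(seq_len(n_chains), function(k) {
    fit_mlm(sim$mlm, n_iter = n_iter, burnin = 0,
            init = init_chain(sim$mlm, seed = seed + 100 + k),
            seed = seed + 200 + k,
            control = mlm_control(save_person = TRUE))
  })
  ps <- psrf_summary(fits)
  list(sim = sim, fits = fits, psrf = ps, max_psrf = max(ps$rhat))
}

#' Misspecification comparison: mixture fit vs engaged-only fit
#'
#' Fits both the mixture model and its engaged-only restriction
#' (`omega = 0`, all modes engaged) to the same mixture-generated dataset
#' and compares joint DIC, attribute agreement, and the latent-speed
#' correlation.
#'
#' @param sim An `mlm_sim` simulated under the mixture model.
#' @param fit_mixture Optional pre-computed mixture fit of `sim`.
#' @param n_iter,burnin Chain settings for (re)fitting.
#' @param seed Seed for the fits.
#' @return List with `fit_mixture`, `fit_joint`, and a `comparison` tibble
#'   (model, dic, mean_aar, rho_tau).
#' @export
misspecification_experiment <- function(sim, fit_mixture = NULL,
                                        n_iter = 5000, burnin = 1000,
                                        seed = 1) {
  stopifnot(inherits(sim, "mlm_sim"))
  if (is.null(fit_mixture)) {
    fit_mixture <- fit_mlm(sim$mlm, n_iter = n_iter, burnin = burnin,
                           seed = seed)
  }
  fit_joint <- fit_mlm(sim$mlm, n_iter = n_iter, burnin = burnin,
                       mixture = FALSE, seed = seed + 1)
  score <- function(fit) {
    lat <- latent_estimates(fit)
    ag <- attribute_agreement(sim$truth$alpha, lat$alpha,
                              if (fit$mixture) lat$D else NULL)
    tibble::tibble(
      dic = joint_dic(fit)$dic,
      mean_aar = mean(ag$aar),
      rho_tau = correlation_recovery(sim, fit)$correlation[
        correlation_recovery(sim, fit)$parameter == "tau"]
    )
  }
  comparison <- dplyr::bind_rows(
    dplyr::mutate(score(fit_mixture), model = "mixture", .before = 1),
    dplyr::mutate(score(fit_joint), model = "engaged-only", .before = 1)
  )
  list(fit_mixture = fit_mixture, fit_joint = fit_joint,
       comparison = comparison)
}
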