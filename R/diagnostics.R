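#' Gelman-Rubin potential scale reduction factor
#'
#' Classic univariate PSRF for one scalar parameter traced by several
#' chains: with `W` the mean within-chain variance and `B/n` the
#' between-chain variance of the chain means,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param chains A numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors, at least two chains of length >= 2.
#' @return The PSRF (>= 1, up to floating point). Defined as 1 when all
#'   chains are identical and constant.
#' @export
#' @examples
#' psrf(cbind(c(1, 2, 3), c(2, 3, 4))) # 1.0801
psrf <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2 || n < 2) {
    stop("PSRF needs at least two chains of length >= 2.", call. = FALSE)
  }
  # identical chains are defined to have converged exactly
  if (all(chains == chains[, 1])) return(1)
  W <- mean(apply(chains, 2, stats::var))
  Bn <- stats::var(colMeans(chains)) # = B / n
  if (W == 0) {
    stop("Zero within-chain variance with distinct chains.", call. = FALSE)
  }
  sqrt(((n - 1) / n * W + Bn) / W)
}

# Stack the stored draws of several chains into a per-parameter list of
# iteration x chain matrices, using the first `frac_burn` of each chain as
# burn-in. Chains must be stored from iteration 1 (fit with burnin = 0).
chain_matrix <- function(fits, term, n_use = NULL, frac_burn = 0.5) {
  cols <- lapply(fits, function(f) {
    d <- if (term %in% colnames(f$draws)) f$draws[, term] else
      f$person_draws[, term]
    if (!is.null(n_use)) d <- d[seq_len(n_use)]
    d[-seq_len(floor(length(d) * frac_burn))]
  })
  do.call(cbind, cols)
}

#' Maximum PSRF across all stored parameters
#'
#' Computes the univariate PSRF of every stored parameter across several
#' chains — run with `burnin = 0` so the full trace is available — using
#' the first half of each chain as burn-in, and reports the per-parameter
#' values and their maximum. When the chains carry per-draw person
#' parameters (`save_person = TRUE`), those are included.
#'
#' @param fits List of `mlm_fit` objects for the same data with different
#'   starting states.
#' @param chain_length Use only the first `chain_length` stored iterations
#'   of each chain (default: all), so convergence can be traced as a
#'   function of chain length.
#' @return A tibble with columns `term` and `rhat`, ordered by decreasing
#'   `rhat`; the maximum is `max(result$rhat)`.
#' @export
psrf_summary <- function(fits, chain_length = NULL) {
  stopifnot(length(fits) >= 2)
  terms <- setdiff(colnames(fits[[1]]$draws), "deviance")
  if (!is.null(fits[[1]]$person_draws) &&
      ncol(fits[[1]]$person_draws) > 0) {
    N <- fits[[1]]$data$n_learners
    pn <- c(paste0("theta_", seq_len(N)), paste0("tau_", seq_len(N)))
    fits <- lapply(fits, function(f) {
      colnames(f$person_draws) <- pn
      f
    })
    terms <- c(terms, pn)
  }
  rhat <- vapply(terms, function(tm) {
    psrf(chain_matrix(fits, tm, n_use = chain_length))
  }, numeric(1))
  tibble::tibble(term = terms, rhat = unname(rhat)) |>
    dplyr::arrange(dplyr::desc(.data$rhat))
}

#' @rdname psrf_summary
#' @export
max_psrf <- function(fits, chain_length = NULL) {
  max(psrf_summary(fits, chain_length)$rhat)
}

#' PSRF trajectory over increasing chain lengths
#'
#' The maximum PSRF over all parameters as a function of chain length,
#' the standard convergence progression plot.
#'
#' @param fits List of `mlm_fit` objects (stored from iteration 1).
#' @param lengths Chain lengths at which to evaluate (default: 10 points
#'   up to the full stored length).
#' @return A tibble with columns `chain_length` and `max_rhat`; has class
#'   `mlm_psrf_trajectory` for [autoplot.mlm_psrf_trajectory()].
#' @export
psrf_trajectory <- function(fits, lengths = NULL) {
  n <- nrow(fits[[1]]$draws)
  if (is.null(lengths)) {
    lengths <- unique(round(seq(max(20, n / 10), n, length.out = 10)))
  }
  out <- tibble::tibble(
    chain_length = as.integer(lengths),
    max_rhat = vapply(lengths, function(l) max_psrf(fits, l), numeric(1))
  )
  class(out) <- c("mlm_psrf_trajectory", class(out))
  out
}

#' @method autoplot mlm_psrf_trajectory
#' @export
autoplot.mlm_psrf_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$chain_length,
                                       y = .data$max_rhat)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1.2, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1) +
    ggplot2::labs(x = "chain length", y = "maximum PSRF")
}

# Vectorized measurement log-likelihood (responses + latencies given
# latent states and parameters); R-side counterpart of the deviance the
# sampler stores, used for the DIC plug-in term and as an independent
# cross-check of the C++ likelihood.
measurement_loglik_vec <- function(data, latent, params) {
  N <- data$n_learners
  q <- data$q
  s <- params$items$s; g <- params$items$g
  a <- params$items$a; gamma <- params$items$gamma
  ll <- 0
  for (t in seq_len(data$n_times)) {
    A_t <- matrix(latent$alpha[, t, ], nrow = N)
    d <- latent$D[, t]
    for (j in which(data$item_time == t)) {
      eta <- as.integer(A_t %*% q[j, ] == sum(q[j, ]))
      p <- ifelse(d == 1, params$gstar, ifelse(eta == 1, 1 - s[j], g[j]))
      x <- data$responses[, j]
      ll <- ll + sum(log(ifelse(x == 1, p, 1 - p)))
      r <- log(data$latencies[, j])
      meanlog <- ifelse(d == 1, params$mu1,
                        gamma[j] - (latent$tau + params$phi * eta))
      sdlog <- ifelse(d == 1, sqrt(params$sigma1_sq), 1 / a[j])
      ll <- ll + sum(stats::dnorm(r, meanlog, sdlog, log = TRUE) - r)
    }
  }
  ll
}

#' Joint deviance information criterion
#'
#' DIC for the joint response-and-latency measurement model, conditional
#' on the sampled latent states: the deviance of one draw is `-2` times
#' the complete-data response + latency log-likelihood given that draw's
#' latents; `Dbar` is its posterior mean, the plug-in deviance `Dhat` is
#' evaluated at the EAP parameters with the discrete latents at their
#' dichotomized modes, `p_D = Dbar - Dhat`, and `DIC = Dbar + p_D`. This
#' conditional-on-latents formulation is one of several possible "joint
#' DIC" definitions and is labeled as such in the report.
#'
#' @param fit An `mlm_fit` object (latent snapshots must be stored, the
#'   default).
#' @return List with `dic`, `dbar`, `dhat`, `p_d`.
#' @export
joint_dic <- function(fit) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (nrow(fit$draws) == 0) stop("No stored draws.", call. = FALSE)
  dbar <- mean(fit$draws[, "deviance"])
  lat <- latent_estimates(fit)
  dhat <- -2 * measurement_loglik_vec(fit$data, lat, eap_params(fit))
  p_d <- dbar - dhat
  list(dic = dbar + p_d, dbar = dbar, dhat = dhat, p_d = p_d)
}

# Default posterior predictive test quantities: per-learner change score
# (last-module total minus first-module total) and change time (same for
# summed latencies).
ppc_stat_fns <- function() {
  list(
    change_score = function(X, L, item_time) {
      T_ <- max(item_time)
      rowSums(X[, item_time == T_, drop = FALSE]) -
        rowSums(X[, item_time == 1, drop = FALSE])
    },
    change_time = function(X, L, item_time) {
      T_ <- max(item_time)
      rowSums(L[, item_time == T_, drop = FALSE]) -
        rowSums(L[, item_time == 1, drop = FALSE])
    }
  )
}

#' Posterior predictive p-values for change-score and change-time checks
#'
#' For each stored latent snapshot, simulates a replicate dataset from the
#' fitted measurement model given that draw's parameters and latent
#' states, computes the minimum, mean and maximum over learners of the
#' per-learner change score (last-module total score minus first-module
#' total) and change time (same for total latency), and reports the
#' upper-tail posterior predictive p-value `P(T_rep >= T_obs)` for each of
#' the six quantities. Values near 0 or 1 are both flagged as extreme:
#' either tail means the model fails to capture that aspect of the data.
#'
#' @param fit An `mlm_fit` object with stored snapshots.
#' @param aggregators Aggregators applied over learners (default
#'   `c("min", "mean", "max")`).
#' @param extreme Two-sided flag threshold (default 0.05).
#' @return A tibble with columns `quantity`, `aggregator`, `observed`,
#'   `p_value`, `extreme`.
#' @export
ppc_pvalues <- function(fit, aggregators = c("min", "mean", "max"),
                        extreme = 0.05) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (fit$data$n_times < 2) {
    stop("Posterior predictive change quantities need T >= 2.",
         call. = FALSE)
  }
  snaps <- fit$snapshots
  n_rep <- nrow(snaps$alpha)
  if (n_rep < 50) {
    warning("Only ", n_rep, " stored draws available for the posterior ",
            "predictive check; p-values will be coarse.", call. = FALSE)
  }
  stats_fns <- ppc_stat_fns()
  N <- fit$data$n_learners; T_ <- fit$data$n_times
  K <- fit$data$n_skills
  classes <- profile_classes(K)
  item_time <- fit$data$item_time

  observed <- lapply(stats_fns, function(f) {
    per <- f(fit$data$responses, fit$data$latencies, item_time)
    vapply(aggregators, function(ag) match.fun(ag)(per), numeric(1))
  })

  reps <- array(NA_real_, c(n_rep, length(stats_fns), length(aggregators)))
  for (k in seq_len(n_rep)) {
    params <- draw_params(fit, snaps$iter[k])
    alpha_cls <- matrix(snaps$alpha[k, ], N, T_)
    alpha <- array(0L, c(N, T_, K))
    for (t in seq_len(T_)) alpha[, t, ] <- classes[alpha_cls[, t] + 1L, ]
    latent <- list(alpha = alpha, D = matrix(snaps$D[k, ], N, T_),
                   tau = as.numeric(snaps$tau[k, ]))
    obs <- simulate_observations(params, latent)
    for (si in seq_along(stats_fns)) {
      per <- stats_fns[[si]](obs$responses, obs$latencies, item_time)
      for (ai in seq_along(aggregators)) {
        reps[k, si, ai] <- match.fun(aggregators[ai])(per)
      }
    }
  }

  out <- tidyr::expand_grid(quantity = names(stats_fns),
                            aggregator = aggregators)
  out$observed <- purrr::map2_dbl(out$quantity, out$aggregator, function(qn, ag) {
    observed[[qn]][[ag]]
  })
  out$p_value <- purrr::map2_dbl(out$quantity, out$aggregator, function(qn, ag) {
    si <- match(qn, names(stats_fns)); ai <- match(ag, aggregators)
    mean(reps[, si, ai] >= observed[[qn]][[ag]])
  })
  out$extreme <- out$p_value < extreme | out$p_value > 1 - extreme
  out
}

#' Plain-text model-fit report
#'
#' Writes a short report combining the PSRF summary (when several chains
#' are supplied), the joint DIC, and the posterior predictive table.
#'
#' @param fit An `mlm_fit` object.
#' @param fits Optional list of replicate chains for the PSRF block.
#' @param file Optional path; when NULL the report is returned invisibly
#'   as a character vector and printed.
#' @return Invisibly, the report lines.
#' @export
fit_report <- function(fit, fits = NULL, file = NULL) {
  dic <- joint_dic(fit)
  ppc <- ppc_pvalues(fit)
  lines <- c(
    "Mixture learning model fit report",
    "=================================",
    sprintf("Joint DIC (conditional on latents): %.1f", dic$dic),
    sprintf("  Dbar = %.1f, Dhat = %.1f, p_D = %.1f",
            dic$dbar, dic$dhat, dic$p_d),
    "",
    "Posterior predictive p-values (upper tail, extremes flagged):",
    utils::capture.output(as.data.frame(ppc))
  )
  if (!is.null(fits)) {
    ps <- psrf_summary(fits)
    lines <- c(lines, "",
               sprintf("Maximum PSRF over %d parameters: %.3f",
                       nrow(ps), max(ps$rhat)))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
  } else {
    cat(lines, sep = "\n")
  }
  invisible(lines)
}
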