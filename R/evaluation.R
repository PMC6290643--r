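#' Attribute- and pattern-wise agreement rates per time point
#'
#' Compares true and estimated attribute profiles at every time point.
#' `AAR` is the share of (learner, skill) cells that agree; `PAR` is the
#' share of learners whose whole profile agrees. Learners estimated as
#' disengaged at every time point are excluded — their profiles are never
#' measured under the engaged model, so no information is available.
#'
#' @param true_alpha True `N x T x K` binary array.
#' @param est_alpha Estimated `N x T x K` binary array (dichotomized).
#' @param est_D Estimated `N x T` engagement-mode matrix; NULL (e.g. for
#'   an engaged-only fit) excludes no one.
#' @return Tibble with columns `time`, `aar`, `par`, `n_included`.
#' @export
attribute_agreement <- function(true_alpha, est_alpha, est_D = NULL) {
  stopifnot(all(dim(true_alpha) == dim(est_alpha)))
  N <- dim(true_alpha)[1]; T_ <- dim(true_alpha)[2]; K <- dim(true_alpha)[3]
  keep <- rep(TRUE, N)
  if (!is.null(est_D)) keep <- rowSums(est_D == 1) < T_
  if (!any(keep)) {
    stop("Every learner was estimated as never engaged; agreement rates ",
         "are undefined.", call. = FALSE)
  }
  purrr::map_dfr(seq_len(T_), function(t) {
    tr <- matrix(true_alpha[keep, t, ], ncol = K)
    es <- matrix(est_alpha[keep, t, ], ncol = K)
    agree <- tr == es
    tibble::tibble(time = t,
                   aar = mean(agree),
                   par = mean(rowSums(agree) == K),
                   n_included = sum(keep))
  })
}

#' Sensitivity and specificity of disengagement detection
#'
#' Over all (learner, time) cells: sensitivity is the share of truly
#' disengaged cells estimated as disengaged, specificity the share of
#' truly engaged cells estimated as engaged.
#'
#' @param true_D,est_D `N x T` binary mode matrices (1 = disengaged).
#' @return Tibble with `sensitivity`, `specificity` and the 2x2 counts.
#'   Sensitivity is `NA` when no cell is truly disengaged (and likewise
#'   for specificity).
#' @export
mode_detection_metrics <- function(true_D, est_D) {
  stopifnot(all(dim(true_D) == dim(est_D)))
  tp <- sum(true_D == 1 & est_D == 1)
  fn <- sum(true_D == 1 & est_D == 0)
  tn <- sum(true_D == 0 & est_D == 0)
  fp <- sum(true_D == 0 & est_D == 1)
  tibble::tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

# Scalar structural parameters compared truth-vs-EAP across replicates.
structural_terms <- c("lambda0", "lambda1", "lambda2", "omega", "gstar",
                      "mu1", "sigma1_sq", "phi", "sigma_tau_sq")

#' Bias and RMSE of the structural parameters across replicates
#'
#' For each structural parameter, `bias = mean(EAP - truth)` and
#' `RMSE = sqrt(mean((EAP - truth)^2))` over the supplied replicate fits.
#'
#' @param truth An `mlm_params` truth object (as used to simulate).
#' @param fits List of `mlm_fit` objects, one per replicate.
#' @return Tibble with columns `parameter`, `true`, `bias`, `rmse`.
#' @export
structural_recovery <- function(truth, fits) {
  if (inherits(fits, "mlm_fit")) fits <- list(fits)
  est <- vapply(fits, function(f) colMeans(f$draws)[structural_terms],
                numeric(length(structural_terms)))
  est <- matrix(est, nrow = length(structural_terms))
  true_vals <- vapply(structural_terms, function(p) truth[[p]], numeric(1))
  err <- est - true_vals
  tibble::tibble(
    parameter = structural_terms,
    true = unname(true_vals),
    bias = rowMeans(err),
    rmse = sqrt(rowMeans(err^2))
  )
}

#' Correlations between true and estimated person and item parameters
#'
#' Pearson correlations between truth and EAP estimates for the learning
#' abilities, initial speeds, and the four item-parameter vectors.
#' Learners whose *estimated* initial profile is full mastery are excluded
#' from the ability correlation: they contribute no acquisition
#' transitions, so the data carry no information about their ability.
#'
#' @param sim An `mlm_sim` simulation (truth source).
#' @param fit The corresponding `mlm_fit`.
#' @return Tibble with columns `parameter` (`theta`, `tau`, `a`, `gamma`,
#'   `s`, `g`), `correlation`, `n`. A correlation over a degenerate
#'   (zero-variance) vector is reported as `NA`.
#' @export
correlation_recovery <- function(sim, fit) {
  stopifnot(inherits(sim, "mlm_sim"), inherits(fit, "mlm_fit"))
  lat <- latent_estimates(fit)
  K <- sim$mlm$n_skills
  full <- rowSums(matrix(lat$alpha[, 1, ], ncol = K)) == K
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  est <- colMeans(fit$draws)
  J <- sim$mlm$n_items
  grab <- function(prefix) unname(est[paste0(prefix, "_", seq_len(J))])
  tibble::tibble(
    parameter = c("theta", "tau", "a", "gamma", "s", "g"),
    correlation = c(
      safe_cor(sim$truth$theta[!full], lat$theta[!full]),
      safe_cor(sim$truth$tau, lat$tau),
      safe_cor(sim$params$items$a, grab("a")),
      safe_cor(sim$params$items$gamma, grab("gamma")),
      safe_cor(sim$params$items$s, grab("s")),
      safe_cor(sim$params$items$g, grab("g"))
    ),
    n = c(sum(!full), length(sim$truth$tau), J, J, J, J)
  )
}

#' Parameter-recovery report across simulation replicates
#'
#' Scores a set of fitted replicates against their simulation truths:
#' agreement rates per time point (averaged over replicates), pooled
#' disengagement detection, structural bias/RMSE, and truth-estimate
#' correlations (averaged over replicates, computed per replicate first).
#'
#' @param sims List of `mlm_sim` objects (or one).
#' @param fits Matching list of `mlm_fit` objects.
#' @return List of class `mlm_recovery` with tibbles `agreement`,
#'   `mode_detection`, `structural`, `correlations`, and `exclusions`.
#' @export
recovery_report <- function(sims, fits) {
  if (inherits(sims, "mlm_sim")) sims <- list(sims)
  if (inherits(fits, "mlm_fit")) fits <- list(fits)
  stopifnot(length(sims) == length(fits))
  per_rep <- purrr::map2(sims, fits, function(sm, ft) {
    lat <- latent_estimates(ft)
    list(
      agreement = attribute_agreement(sm$truth$alpha, lat$alpha, lat$D),
      modes = list(true_D = sm$truth$D, est_D = lat$D),
      correlations = correlation_recovery(sm, ft)
    )
  })
  agreement <- purrr::map_dfr(per_rep, "agreement") |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(aar = mean(.data$aar), par = mean(.data$par),
                     n_included = mean(.data$n_included), .groups = "drop")
  modes <- mode_detection_metrics(
    do.call(rbind, purrr::map(per_rep, ~ .x$modes$true_D)),
    do.call(rbind, purrr::map(per_rep, ~ .x$modes$est_D))
  )
  correlations <- purrr::map_dfr(per_rep, "correlations") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(correlation = mean(.data$correlation),
                     .groups = "drop")
  structure(list(
    agreement = agreement,
    mode_detection = modes,
    structural = structural_recovery(sims[[1]]$params, fits),
    correlations = correlations,
    exclusions = tibble::tibble(
      replicate = seq_along(per_rep),
      n_excluded = purrr::map_int(per_rep, function(x) {
        nrow(x$modes$est_D) - x$agreement$n_included[1]
      })
    ),
    n_replicates = length(sims)
  ), class = "mlm_recovery")
}

#' @export
print.mlm_recovery <- function(x, ...) {
  cat("<mlm_recovery> ", x$n_replicates, " replicate(s)\n\n", sep = "")
  cat("Attribute agreement (averaged over replicates):\n")
  print(as.data.frame(x$agreement), row.names = FALSE)
  cat("\nDisengagement detection (pooled):\n")
  print(as.data.frame(x$mode_detection[c("sensitivity", "specificity")]),
        row.names = FALSE)
  cat("\nStructural parameters:\n")
  print(as.data.frame(x$structural), row.names = FALSE, digits = 3)
  cat("\nTruth-estimate correlations:\n")
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  invisible(x)
}
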