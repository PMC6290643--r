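test_that("chain initialization is seeded and respects the recipe", {
  sim <- simulate_learning_data(10, params = make_params(), seed = 1)
  i1 <- init_chain(sim$mlm, seed = 4)
  i2 <- init_chain(sim$mlm, seed = 4)
  expect_identical(i1, i2)
  expect_true(all(i1$s > 0 & i1$s < 0.3))
  expect_true(all(i1$g < 1 - i1$s)) # order region holds by construction
  expect_true(all(i1$a >= 2 & i1$a <= 4))
  expect_true(i1$omega >= 0 && i1$omega <= 0.2)
  expect_true(i1$gstar <= 0.5)

  # initial latents satisfy the frozen-link invariant
  for (t in seq_len(sim$mlm$n_times - 1)) {
    frozen <- i1$D[, t] == 1
    expect_true(all(i1$alpha[frozen, t + 1] == i1$alpha[frozen, t]))
  }

  # omega inits are uniform on (0, 0.2)
  oms <- vapply(1:2000, function(k) {
    init_chain(sim$mlm, seed = 10000 + k)$omega
  }, numeric(1))
  expect_gt(ks.test(oms, "punif", 0, 0.2)$p.value, 0.001)
})

test_that("segment sampler matches exhaustive enumeration at K=1, T=2", {
  params <- make_params(K = 1, T_ = 2, J_per = 1, omega = 0.25)
  sim <- simulate_learning_data(1, params = params, seed = 21)
  pp <- list(theta = sim$truth$theta, tau = sim$truth$tau)

  # exact posterior over the 16 latent paths, by enumeration; the latent
  # sampler integrates the learner's speed out of its conditionals, so the
  # oracle marginalizes tau by quadrature over the brute-force likelihood
  paths <- expand.grid(a1 = 0:1, a2 = 0:1, d1 = 0:1, d2 = 0:1)
  wts <- apply(paths, 1, function(p) {
    latent <- list(alpha = array(c(p["a1"], p["a2"]), c(1, 2, 1)),
                   D = matrix(c(p["d1"], p["d2"]), 1, 2))
    f <- Vectorize(function(tau) {
      pp_tau <- list(theta = sim$truth$theta, tau = tau)
      exp(as.numeric(complete_data_loglik(sim$mlm, latent, params$items,
                                          pp_tau, params))) *
        dnorm(tau, 0, sqrt(params$sigma_tau_sq))
    })
    integrate(f, -8, 8, rel.tol = 1e-10)$value
  })
  exact <- wts / sum(wts)

  n_sweeps <- 20000
  fit <- fit_mlm(sim$mlm, n_iter = n_sweeps, burnin = 0, seed = 22,
                 init = pinned_init(sim),
                 control = mlm_control(
                   n_snapshots = n_sweeps, adapt = FALSE,
                   update = update_only("latents")))
  snap <- fit$snapshots
  emp_key <- paste(snap$alpha[, 1], snap$alpha[, 2],
                   snap$D[, 1], snap$D[, 2])
  key <- paste(paths$a1, paths$a2, paths$d1, paths$d2)
  emp <- vapply(key, function(k) mean(emp_key == k), numeric(1))
  expect_equal(unname(emp), unname(exact), tolerance = 0.025)

  # impossible paths (changed profile under a frozen link) never occur
  impossible <- paths$d1 == 1 & paths$a1 != paths$a2
  expect_true(all(emp[impossible] == 0))
})

test_that("a changed profile forces the engaged mode at the earlier link", {
  params <- make_params(K = 2, T_ = 3, J_per = 2, omega = 0.3)
  sim <- simulate_learning_data(25, params = params, seed = 23)
  fit <- fit_mlm(sim$mlm, n_iter = 400, burnin = 0, seed = 24,
                 control = mlm_control(n_snapshots = 400))
  snap <- fit$snapshots
  N <- 25; T_ <- 3
  for (k in seq_len(nrow(snap$alpha))) {
    al <- matrix(snap$alpha[k, ], N, T_)
    D <- matrix(snap$D[k, ], N, T_)
    for (t in 1:(T_ - 1)) {
      expect_true(all(D[al[, t] != al[, t + 1], t] == 0))
    }
  }
})

test_that("without data terms the profile conditional reduces to the prior", {
  # under a disengaged mode the measurement is profile-free, so for an
  # always-disengaged learner the profile conditional is exactly pi
  params <- make_params(K = 1, T_ = 1, J_per = 1, omega = 1 - 1e-9,
                        pi = c(0.3, 0.7))
  sim <- simulate_learning_data(1, params = params, seed = 25)
  stopifnot(all(sim$truth$D == 1))
  fit <- fit_mlm(sim$mlm, n_iter = 20000, burnin = 0, seed = 26,
                 init = pinned_init(sim),
                 control = mlm_control(n_snapshots = 20000, adapt = FALSE,
                                       update = update_only("latents")))
  kept <- fit$snapshots$D[, 1] == 1
  expect_gt(mean(kept), 0.99)
  expect_equal(mean(fit$snapshots$alpha[kept, 1]), 0.7, tolerance = 0.02)
})

test_that("tau update matches the normal-normal closed form on two items", {
  params <- make_params(K = 1, T_ = 1, J_per = 2, omega = 1e-9,
                        sigma_tau_sq = 0.8)
  sim <- simulate_learning_data(1, params = params, seed = 27)
  stopifnot(all(sim$truth$D == 0))
  fit <- fit_mlm(sim$mlm, n_iter = 6000, burnin = 0, seed = 28,
                 init = pinned_init(sim),
                 control = mlm_control(n_snapshots = 6000, adapt = FALSE,
                                       update = update_only("person")))
  a2 <- params$items$a^2
  eta <- vapply(1:2, function(j) {
    ideal_response(sim$truth$alpha[1, 1, ], params$q[j, ])
  }, integer(1))
  y <- params$items$gamma - params$phi * eta - log(sim$mlm$latencies[1, ])
  prec <- 1 / params$sigma_tau_sq + sum(a2)
  post_mean <- sum(a2 * y) / prec
  taus <- fit$snapshots$tau[, 1]
  expect_equal(mean(taus), post_mean, tolerance = 4 / sqrt(prec * 6000) + 0.01)
  expect_equal(var(taus), 1 / prec, tolerance = 0.1 * (1 / prec) + 0.005)
})

test_that("theta with no informative transitions samples its prior", {
  # single time point: no transitions at all, so theta | . = N(0, 1)
  params <- make_params(K = 1, T_ = 1, J_per = 2)
  sim <- simulate_learning_data(2, params = params, seed = 29)
  fit <- fit_mlm(sim$mlm, n_iter = 30000, burnin = 0, seed = 30,
                 init = pinned_init(sim),
                 control = mlm_control(save_person = TRUE, adapt = FALSE,
                                       update = update_only("person")))
  th <- fit$person_draws[, 1]
  expect_lt(abs(mean(th)), 0.1)
  expect_lt(abs(sd(th) - 1), 0.08)
})

test_that("conjugate structural updates match their closed forms", {
  params <- make_params(K = 1, T_ = 2, J_per = 2, omega = 0.3)
  sim <- simulate_learning_data(6, params = params, seed = 31)
  # pin latents; structural-only updates leave their conditionals fixed
  fit <- fit_mlm(sim$mlm, n_iter = 8000, burnin = 0, seed = 32,
                 init = pinned_init(sim),
                 control = mlm_control(adapt = FALSE,
                                       update = update_only("structural")))
  N <- 6; T_ <- 2
  # omega | D ~ Beta(1 + sum D, 1 + NT - sum D)
  sd_ <- sum(sim$truth$D)
  ab <- c(1 + sd_, 1 + N * T_ - sd_)
  om <- fit$draws[, "omega"]
  expect_lt(abs(mean(om) - ab[1] / sum(ab)), 0.01)
  expect_lt(abs(var(om) - prod(ab) / (sum(ab)^2 * (sum(ab) + 1))), 0.001)
  # pi | alpha_1 ~ Dirichlet(1 + counts)
  cnt <- tabulate(sim$truth$alpha[, 1, 1] + 1, 2)
  expect_lt(abs(mean(fit$draws[, "pi_2"]) - (1 + cnt[2]) / (2 + N)), 0.01)
  # gstar | disengaged responses ~ Beta(1 + correct, 1 + incorrect)
  dis <- sim$truth$D[, sim$mlm$item_time] == 1
  corr <- sum(sim$mlm$responses[dis]); inc <- sum(dis) - corr
  gs <- fit$draws[, "gstar"]
  expect_lt(abs(mean(gs) - (1 + corr) / (2 + corr + inc)), 0.015)
  # sigma_tau_sq | tau ~ Inv-Gamma(2.5 + N/2, 1 + sum(tau^2)/2)
  sh <- 2.5 + N / 2; ra <- 1 + sum(sim$truth$tau^2) / 2
  expect_lt(abs(mean(fit$draws[, "sigma_tau_sq"]) - ra / (sh - 1)),
            0.05 * ra / (sh - 1))
})

test_that("item updates match closed forms and never break the order region", {
  params <- make_params(K = 1, T_ = 1, J_per = 2, omega = 1e-9)
  sim <- simulate_learning_data(40, params = params, seed = 33)
  # pin a_j^2 via an overwhelming prior so the gamma_j conditional is exact
  pr <- prior_spec()
  a0 <- params$items$a
  pr$a_sq_shape <- 1e8
  pr$a_sq_rate <- 1e8 / mean(a0^2)
  fit <- fit_mlm(sim$mlm, n_iter = 6000, burnin = 0, seed = 34,
                 init = pinned_init(sim),
                 control = mlm_control(priors = pr, adapt = FALSE,
                                       update = update_only("item")))
  a2_pinned <- mean(a0^2)
  for (j in 1:2) {
    eta <- vapply(seq_len(40), function(i) {
      ideal_response(sim$truth$alpha[i, 1, ], params$q[j, ])
    }, integer(1))
    y <- log(sim$mlm$latencies[, j]) + sim$truth$tau + params$phi * eta
    prec <- 1 + 40 * a2_pinned
    post_mean <- a2_pinned * sum(y) / prec
    gj <- fit$draws[, paste0("gamma_", j)]
    expect_lt(abs(mean(gj) - post_mean), 0.02)
    expect_lt(abs(var(gj) - 1 / prec), 0.2 / prec)
    expect_lt(abs(mean(fit$draws[, paste0("a_", j)]^2) - a2_pinned), 0.03)
  }
  # the order constraint g < 1 - s holds for every stored draw
  s_draws <- fit$draws[, paste0("s_", 1:2)]
  g_draws <- fit$draws[, paste0("g_", 1:2)]
  expect_true(all(g_draws < 1 - s_draws))
})

test_that("slipping and guessing conditionals match the Beta closed form", {
  # one item, eta known for every learner, truncation barely active
  params <- make_params(K = 1, T_ = 1, J_per = 1, omega = 1e-9)
  sim <- simulate_learning_data(60, params = params, seed = 35)
  fit <- fit_mlm(sim$mlm, n_iter = 8000, burnin = 0, seed = 36,
                 init = pinned_init(sim),
                 control = mlm_control(adapt = FALSE,
                                       update = update_only("item")))
  eta <- vapply(seq_len(60), function(i) {
    ideal_response(sim$truth$alpha[i, 1, ], params$q[1, ])
  }, integer(1))
  x <- sim$mlm$responses[, 1]
  n1 <- sum(eta == 1); c1 <- sum(x[eta == 1])
  sh <- c(1 + n1 - c1, 1 + c1)
  s_draws <- fit$draws[, "s_1"]
  # truncation to (0, 1 - g) matters little when g draws stay small
  expect_equal(mean(s_draws), sh[1] / sum(sh), tolerance = 0.02)
  expect_true(all(fit$draws[, "g_1"] < 1 - s_draws))
})

test_that("a zero-data run reproduces the prior marginals", {
  fit <- fit_mlm(empty_mlm_data(J = 2, K = 1, T_ = 1),
                 n_iter = 6000, burnin = 0, seed = 37,
                 control = mlm_control(adapt = FALSE))
  d <- fit$draws
  expect_lt(abs(mean(d[, "omega"]) - 0.5), 0.03)
  expect_lt(abs(var(d[, "omega"]) - 1 / 12), 0.005)
  expect_equal(mean(d[, "gstar"]), 0.5, tolerance = 0.03)
  expect_equal(mean(d[, "mu1"]), 0, tolerance = 0.05)
  expect_equal(sd(d[, "mu1"]), 1, tolerance = 0.05)
  expect_equal(mean(d[, "pi_1"]), 0.5, tolerance = 0.03)
  expect_equal(mean(d[, "gamma_1"]), 0, tolerance = 0.05)
  # uniform-on-region (s, g): P(g < 1 - s) = 1/2 region, E[s] = 1/3
  expect_equal(mean(d[, "s_1"]), 1 / 3, tolerance = 0.03)
  expect_true(all(d[, "g_1"] < 1 - d[, "s_1"]))
  # lambda1 ~ Log-normal(0.5, 1): median exp(0.5)
  expect_equal(median(d[, "lambda1"]), exp(0.5), tolerance = 0.25)
})

test_that("simulate/update cycles preserve the prior (joint correctness)", {
  # successive-conditional simulator: params ~ prior, latents | params,
  # data | latents, then one full Gibbs sweep; the marginal law of the
  # parameters must stay at the prior.
  K <- 1; T_ <- 2; N <- 5; J_per <- 1
  q <- matrix(1L, J_per * T_, K)
  item_time <- rep(seq_len(T_), each = J_per)
  withr::local_seed(38)
  params <- draw_prior_params(J_per * T_, K, T_, item_time)
  params$q <- q
  latent <- mixlearn:::simulate_latent_trajectories(params, N)
  state <- NULL
  n_cycles <- 6000
  rec <- matrix(NA_real_, n_cycles, 3,
                dimnames = list(NULL, c("omega", "gstar", "mu1")))
  for (it in seq_len(n_cycles)) {
    obs <- mixlearn:::simulate_observations(params, latent)
    mlm <- structure(list(
      responses = obs$responses, latencies = obs$latencies, q = q,
      item_time = item_time, learner_ids = seq_len(N),
      item_ids = seq_len(J_per * T_), n_learners = N, n_times = T_,
      n_skills = K, n_items = J_per * T_), class = "mlm_data")
    init <- if (is.null(state)) {
      list(alpha = alpha_to_classes(latent$alpha), D = latent$D,
           theta = latent$theta, tau = latent$tau,
           s = params$items$s, g = params$items$g,
           gamma = params$items$gamma, a = params$items$a,
           lambda = c(params$lambda0, params$lambda1, params$lambda2),
           pi = params$pi, omega = params$omega, gstar = params$gstar,
           mu1 = params$mu1, sigma1_sq = params$sigma1_sq,
           phi = params$phi, sigma_tau_sq = params$sigma_tau_sq)
    } else {
      state
    }
    fit <- fit_mlm(mlm, n_iter = 1, burnin = 0, init = init,
                   control = mlm_control(adapt = FALSE, n_snapshots = 0))
    state <- fit$final_state
    rec[it, ] <- c(state$omega, state$gstar, state$mu1)
    params <- list(items = tibble::tibble(
      item_id = seq_len(J_per * T_), s = state$s, g = state$g,
      a = state$a, gamma = state$gamma),
      q = q, item_time = item_time,
      lambda0 = state$lambda[1], lambda1 = state$lambda[2],
      lambda2 = state$lambda[3], pi = state$pi, omega = state$omega,
      gstar = state$gstar, mu1 = state$mu1, sigma1_sq = state$sigma1_sq,
      phi = state$phi, sigma_tau_sq = state$sigma_tau_sq,
      n_skills = K, n_times = T_)
    latent <- list(alpha = classes_to_alpha(state$alpha, K), D = state$D,
                   theta = state$theta, tau = state$tau)
  }
  # Beta(1,1) priors: mean 1/2, sd 1/sqrt(12); mu1 prior N(0,1)
  expect_lt(abs(mean(rec[, "omega"]) - 0.5), 0.06)
  expect_lt(abs(sd(rec[, "omega"]) - sqrt(1 / 12)), 0.03)
  expect_lt(abs(mean(rec[, "gstar"]) - 0.5), 0.06)
  expect_lt(abs(sd(rec[, "gstar"]) - sqrt(1 / 12)), 0.03)
  expect_lt(abs(mean(rec[, "mu1"])), 0.12)
  expect_lt(abs(sd(rec[, "mu1"]) - 1), 0.1)
})

test_that("seeded fits are bit-reproducible", {
  sim <- simulate_learning_data(15, params = make_params(), seed = 39)
  f1 <- fit_mlm(sim$mlm, n_iter = 300, burnin = 100, seed = 40)
  f2 <- fit_mlm(sim$mlm, n_iter = 300, burnin = 100, seed = 40)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$alpha_prob, f2$alpha_prob)
  f3 <- fit_mlm(sim$mlm, n_iter = 300, burnin = 100, seed = 41)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every stored draw respects the parameter-space constraints", {
  sim <- simulate_learning_data(20, params = make_params(omega = 0.2),
                                seed = 42)
  fit <- fit_mlm(sim$mlm, n_iter = 500, burnin = 100, seed = 43)
  d <- fit$draws
  J <- 4
  s_draws <- d[, paste0("s_", 1:J)]
  g_draws <- d[, paste0("g_", 1:J)]
  expect_true(all(g_draws >= 0 & g_draws < 1 - s_draws))
  expect_true(all(d[, paste0("a_", 1:J)] > 0))
  expect_true(all(d[, c("sigma1_sq", "sigma_tau_sq")] > 0))
  expect_true(all(d[, "omega"] > 0 & d[, "omega"] < 1))
  expect_true(all(d[, c("lambda1", "lambda2")] > 0))
  pis <- d[, paste0("pi_", 1:4)]
  expect_equal(unname(rowSums(pis)), rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("posterior summaries dichotomize at 0.5 with ties to zero", {
  sim <- simulate_learning_data(10, params = make_params(), seed = 44)
  fit <- fit_mlm(sim$mlm, n_iter = 200, burnin = 100, seed = 45)
  fit$alpha_prob[] <- 0.7
  fit$alpha_prob[1, 1, 1] <- 0.3
  fit$alpha_prob[2, 1, 1] <- 0.5 # exact tie
  lat <- latent_estimates(fit)
  expect_equal(lat$alpha[1, 1, 1], 0L)
  expect_equal(lat$alpha[2, 1, 1], 0L)
  expect_equal(lat$alpha[3, 1, 1], 1L)

  # constant chain: EAP equals the constant, SD 0
  fit$draws[, "omega"] <- 0.125
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "omega"], 0.125)
  expect_equal(td$std.error[td$term == "omega"], 0)
})

test_that("the engaged-only restriction keeps every mode engaged", {
  sim <- simulate_learning_data(15, params = make_params(omega = 0.2),
                                seed = 46)
  fit <- fit_mlm(sim$mlm, n_iter = 300, burnin = 100, seed = 47,
                 mixture = FALSE)
  expect_true(all(fit$D_prob == 0))
  expect_true(all(fit$draws[, "omega"] == 0))
})
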