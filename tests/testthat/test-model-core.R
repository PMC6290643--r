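test_that("ideal response requires every listed skill", {
  expect_equal(ideal_response(c(1, 1, 1, 1), c(1, 0, 1, 0)), 1L)
  expect_equal(ideal_response(c(0, 1, 1, 1), c(1, 0, 0, 0)), 0L)
  expect_equal(ideal_response(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1L)
  expect_error(ideal_response(c(1, 0), c(1, 0, 1)), "same length")
  expect_error(ideal_response(c(1, 2), c(1, 0)), "only 0 and 1")
})

test_that("speed covariate equals the ideal-response indicator", {
  expect_equal(speed_covariate(c(0, 0, 0, 0), c(0, 1, 0, 0)), 0L)
  expect_equal(speed_covariate(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1L)
  withr::with_seed(7, {
    for (rep in 1:50) {
      K <- sample(1:5, 1)
      alpha <- rbinom(K, 1, 0.5)
      q <- rbinom(K, 1, 0.5)
      q[sample(K, 1)] <- 1
      expect_identical(speed_covariate(alpha, q), ideal_response(alpha, q))
    }
  })
})

test_that("response probability follows DINA when engaged, gstar when not", {
  expect_equal(response_prob(0, 1, s = 0.045, g = 0.811), 0.955)
  expect_equal(response_prob(0, 0, s = 0.045, g = 0.811), 0.811)
  expect_equal(response_prob(1, 0, s = 0.1, g = 0.2, gstar = 0.503), 0.503)
  expect_equal(response_prob(1, 1, s = 0.1, g = 0.2, gstar = 0.503), 0.503)
  expect_error(response_prob(0, 1, s = 1.2, g = 0.5), "unit interval")
  expect_error(response_prob(1, 1, s = 0.1, g = 0.1, gstar = -0.1),
               "unit interval")
})

test_that("engaged responses are monotone in the ideal response", {
  withr::with_seed(1, {
    for (rep in 1:25) {
      s <- runif(1, 0.01, 0.4)
      g <- runif(1, 0.01, 1 - s - 0.01) # order constraint g < 1 - s
      expect_gt(response_prob(0, 1, s, g), response_prob(0, 0, s, g))
    }
  })
})

test_that("latency log-density matches an independent log-normal oracle", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      l <- runif(1, 0.3, 60)
      gamma <- runif(1, 2, 4); a <- runif(1, 1, 3)
      tau <- rnorm(1); phi <- rnorm(1, 0, 0.5); G <- rbinom(1, 1, 0.5)
      expect_equal(
        rt_logdensity(0, l, gamma = gamma, a = a, tau = tau, phi = phi,
                      G = G),
        dlnorm(l, meanlog = gamma - (tau + phi * G), sdlog = 1 / a,
               log = TRUE),
        tolerance = 1e-12
      )
      mu1 <- rnorm(1, 2.5); s1 <- runif(1, 0.5, 2)
      expect_equal(
        rt_logdensity(1, l, mu1 = mu1, sigma1_sq = s1),
        dlnorm(l, mu1, sqrt(s1), log = TRUE),
        tolerance = 1e-12
      )
    }
  })
})

test_that("latency density normalizes and has the documented median", {
  # disengaged law: median latency exp(mu1) ~ 12.5 s
  med <- integrate(function(l) {
    exp(vapply(l, function(x) {
      rt_logdensity(1, x, mu1 = 2.528, sigma1_sq = 1.158)
    }, numeric(1)))
  }, 0, exp(2.528))$value
  expect_equal(med, 0.5, tolerance = 1e-6)
  expect_equal(exp(2.528), 12.5, tolerance = 0.05)

  for (case in list(list(mode = 0, gamma = 3, a = 1.8, tau = 0.4,
                         phi = -0.3, G = 1),
                    list(mode = 1, mu1 = 2.5, sigma1_sq = 1.2))) {
    total <- integrate(function(l) {
      exp(vapply(l, function(x) {
        do.call(rt_logdensity, c(list(l = x), case))
      }, numeric(1)))
    }, 0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }

  # at the engaged mean, the kernel collapses to log(a) - log(l) - log(2*pi)/2
  expect_equal(rt_logdensity(0, exp(3), gamma = 3, a = 2, tau = 0, phi = 0,
                             G = 0),
               log(2) - 3 - 0.5 * log(2 * pi))
  expect_error(rt_logdensity(0, -1, gamma = 3, a = 2, tau = 0, phi = 0,
                             G = 0), "positive")
})

test_that("skill acquisition probability follows the higher-order logistic", {
  expect_equal(skill_transition_prob(0, 0, -2.214, 2.757, 0.286),
               0.0985, tolerance = 1e-4)
  expect_equal(skill_transition_prob(0, 3, -2.214, 2.757, 0.286),
               0.2049, tolerance = 1e-4)
  expect_equal(skill_transition_prob(0, 0, -1e6, 1, 1), 0)
})

test_that("profile transitions freeze when disengaged and never forget", {
  lam <- c(-0.5, 1, 0.5)
  expect_equal(profile_transition_prob(c(1, 0), c(1, 0), 0.3, 1, lam), 1)
  expect_equal(profile_transition_prob(c(1, 0), c(1, 1), 0.3, 1, lam), 0)
  expect_equal(profile_transition_prob(c(1, 1), c(1, 0), 0.3, 0, lam), 0)
  # K = 2 from (0,0): two independent logistic(0) draws under lambda=(0,1,1)
  expect_equal(
    profile_transition_prob(c(0, 0), c(1, 1), 0, 0, c(0, 1, 1)), 0.25)
})

test_that("engaged transition distribution normalizes over reachable profiles", {
  withr::with_seed(3, {
    for (K in 1:4) {
      classes <- profile_classes(K)
      for (rep in 1:5) {
        theta <- rnorm(1)
        lam <- c(rnorm(1), runif(1, 0.2, 2), runif(1, 0.1, 1))
        from <- classes[sample(nrow(classes), 1), ]
        total <- sum(apply(classes, 1, function(to) {
          profile_transition_prob(from, to, theta, 0, lam)
        }))
        expect_equal(total, 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("a negative speed-change coefficient slows mastered items", {
  # with phi < 0 the engaged mean log-latency is larger when G = 1
  phi <- -0.332
  m1 <- 3.1 - (0.2 + phi * 1)
  m0 <- 3.1 - (0.2 + phi * 0)
  expect_gt(m1, m0)
  expect_equal(m1 - m0, 0.332)
})

test_that("complete-data log-likelihood composes its parts", {
  params <- make_params(K = 1, T_ = 1, J_per = 1, omega = 0.2)
  sim <- simulate_learning_data(1, params = params, seed = 5)
  item <- params$items
  latent <- list(alpha = sim$truth$alpha, D = sim$truth$D)
  pp <- list(theta = sim$truth$theta, tau = sim$truth$tau)
  ll <- complete_data_loglik(sim$mlm, latent, item, pp, params)
  d <- sim$truth$D[1, 1]
  eta <- ideal_response(sim$truth$alpha[1, 1, ], params$q[1, ])
  x <- sim$mlm$responses[1, 1]
  pr <- response_prob(d, eta, item$s[1], item$g[1], params$gstar)
  manual <- log(params$pi[profile_index(sim$truth$alpha[1, 1, ])]) +
    (if (d == 1) log(params$omega) else log(1 - params$omega)) +
    log(if (x == 1) pr else 1 - pr) +
    rt_logdensity(d, sim$mlm$latencies[1, 1], gamma = item$gamma[1],
                  a = item$a[1], tau = pp$tau[1], phi = params$phi,
                  G = eta, mu1 = params$mu1, sigma1_sq = params$sigma1_sq)
  expect_equal(as.numeric(ll), manual, tolerance = 1e-12)
})

test_that("log-likelihood is additive over learners", {
  params <- make_params(K = 2, T_ = 2, J_per = 2)
  sim <- simulate_learning_data(1, params = params, seed = 9)
  # duplicate the single learner
  d2 <- dplyr::bind_rows(sim$data,
                         dplyr::mutate(sim$data, learner_id = 2))
  mlm2 <- as_mlm_data(d2, sim$q_matrix)
  dup <- function(x) {
    a <- array(0L, c(2, dim(x)[2], dim(x)[3]))
    a[1, , ] <- x[1, , ]; a[2, , ] <- x[1, , ]
    a
  }
  latent1 <- list(alpha = sim$truth$alpha, D = sim$truth$D)
  latent2 <- list(alpha = dup(sim$truth$alpha),
                  D = rbind(sim$truth$D, sim$truth$D))
  pp1 <- list(theta = sim$truth$theta, tau = sim$truth$tau)
  pp2 <- list(theta = rep(sim$truth$theta, 2), tau = rep(sim$truth$tau, 2))
  ll1 <- complete_data_loglik(sim$mlm, latent1, sim$params$items, pp1, params)
  ll2 <- complete_data_loglik(mlm2, latent2, sim$params$items, pp2, params)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll1), tolerance = 1e-10)
})

test_that("invariant violations flag the likelihood as impossible", {
  params <- make_params(K = 1, T_ = 2, J_per = 1, omega = 0.2)
  sim <- simulate_learning_data(1, params = params, seed = 2)
  latent <- list(alpha = sim$truth$alpha, D = sim$truth$D)
  latent$alpha[1, 1, ] <- 1L
  latent$alpha[1, 2, ] <- 0L # forgetting
  latent$D[1, 1] <- 0L
  pp <- list(theta = sim$truth$theta, tau = sim$truth$tau)
  ll <- complete_data_loglik(sim$mlm, latent, params$items, pp, params)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "invariant_violation"))
})

test_that("path enumeration reproduces the marginal likelihood at K=1, T=2", {
  params <- make_params(K = 1, T_ = 2, J_per = 1, omega = 0.2)
  sim <- simulate_learning_data(1, params = params, seed = 31)
  pp <- list(theta = sim$truth$theta, tau = sim$truth$tau)

  # route 1: sum of exp(complete_data_loglik) over all latent paths
  paths <- expand.grid(a1 = 0:1, a2 = 0:1, d1 = 0:1, d2 = 0:1)
  via_loglik <- sum(apply(paths, 1, function(p) {
    latent <- list(alpha = array(c(p["a1"], p["a2"]), c(1, 2, 1)),
                   D = matrix(c(p["d1"], p["d2"]), 1, 2))
    exp(as.numeric(
      complete_data_loglik(sim$mlm, latent, params$items, pp, params)))
  }))

  # route 2: independent brute-force density written from scratch
  x <- sim$mlm$responses[1, ]; l <- sim$mlm$latencies[1, ]
  w <- params$omega; gs <- params$gstar
  s <- params$items$s; g <- params$items$g
  a <- params$items$a; gam <- params$items$gamma
  tau <- pp$tau[1]
  pacq <- plogis(params$lambda0 + params$lambda1 * pp$theta[1])
  meas <- function(t, alpha, d) {
    if (d == 1) {
      (gs^x[t] * (1 - gs)^(1 - x[t])) *
        dlnorm(l[t], params$mu1, sqrt(params$sigma1_sq))
    } else {
      pr <- if (alpha == 1) 1 - s[t] else g[t]
      (pr^x[t] * (1 - pr)^(1 - x[t])) *
        dlnorm(l[t], gam[t] - (tau + params$phi * alpha), 1 / a[t])
    }
  }
  brute <- 0
  for (a1 in 0:1) for (a2 in 0:1) for (d1 in 0:1) for (d2 in 0:1) {
    trans <- if (d1 == 1) {
      as.numeric(a2 == a1)
    } else if (a1 == 1) {
      as.numeric(a2 == 1)
    } else {
      if (a2 == 1) pacq else 1 - pacq
    }
    brute <- brute + params$pi[a1 + 1] *
      w^d1 * (1 - w)^(1 - d1) * w^d2 * (1 - w)^(1 - d2) *
      trans * meas(1, a1, d1) * meas(2, a2, d2)
  }
  expect_equal(via_loglik, brute, tolerance = 1e-12)
})
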