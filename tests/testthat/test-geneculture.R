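test_that("exponential survival is a CDF in the endowment", {
  expect_equal(survival(0, 1), 0)
  expect_equal(survival(1, 1), 1 - exp(-1))
  r <- seq(0, 5, by = 0.1)
  expect_true(all(diff(survival(r, 2)) > 0))
  expect_true(all(survival(r, 2) >= 0 & survival(r, 2) < 1))
  expect_error(survival(-0.1, 1), "non-negative")
  expect_error(survival(1, -2), "positive rate")
})

test_that("twinning is never maladaptive under the concave exponential", {
  for (M in c(0.1, 0.5, 1, 2, 10)) {
    for (lam in c(0.2, 1, 5)) {
      expect_false(twinning_maladaptive(M, lambda_surv = lam))
    }
  }
  # Michaelis-Menten saturation is also concave through the origin
  expect_false(twinning_maladaptive(1, surv_fn = function(r) r / (r + 1)))
  # a survival threshold above the half-share makes twinning maladaptive
  expect_true(twinning_maladaptive(1, surv_fn = step_survival(0.75)))
  expect_true(twinning_maladaptive(1, surv_fn = convex_survival))
})

test_that("non-geminophilous fitness interpolates its pure strategies", {
  M <- 1.4; lam <- 1.7
  expect_equal(fitness_A(0, M, lam), survival(M, lam))
  expect_equal(fitness_A(1, M, lam), 2 * survival(M / 2, lam))
  # strictly decreasing in the twinning probability when twinning is
  # maladaptive for the configured survival function
  stopifnot(twinning_maladaptive(1, surv_fn = convex_survival))
  betas <- seq(0, 1, by = 0.05)
  w <- fitness_A(betas, 1, surv_fn = convex_survival)
  expect_true(all(diff(w) < 0))
})

test_that("pool accounting conserves contributions", {
  scn <- gemino_scenario(M = 1, gamma_cost = 0.1, alpha_share = 0.01,
                         lambda_surv = 2, beta = 0, delta = 1, N_GQ = 100)
  out <- pool(scn, n_G_singleton_producers = 99)
  expect_equal(out$kappa, 0.01 * 0.9 * 99)
  expect_equal(out$T_G, 1L)
  expect_equal(out$per_twinner_payout, 0.891)
  # total distributed equals total contributed whenever anyone twins
  out2 <- pool(scn, 60)
  expect_equal(out2$per_twinner_payout * out2$T_G, out2$kappa)
  # no contributions without a norm share
  scn0 <- gemino_scenario(1, 0.1, 0, 2, beta = 0.5, delta = 0, N_GQ = 100)
  expect_equal(pool(scn0, 40)$kappa, 0)
  # no twinners: pool collected but idle
  expect_true(is.na(pool(scn, 100)$per_twinner_payout))
  expect_error(pool(scn, 101), "N_GQ")
})

test_that("geminophilous fitness reduces to the norm-free case", {
  # alpha = gamma = 0: the pool never holds anything, shares are M and M/2
  for (genotype in c("Q", "Qt")) {
    scn <- gemino_scenario(M = 1.2, gamma_cost = 0, alpha_share = 0,
                           lambda_surv = 1.3, beta = 0.3, delta = 0.4,
                           N_GQ = 6, N_GQt = 4)
    b <- scn$beta + if (genotype == "Qt") scn$delta else 0
    expect_equal(expected_fitness_G(scn, genotype, method = "exact"),
                 fitness_A(b, scn$M, scn$lambda_surv))
  }
  # nobody ever twins: deterministic contributing-singleton fitness
  scn0 <- gemino_scenario(M = 2, gamma_cost = 0.5, alpha_share = 0.2,
                          lambda_surv = 0.8, beta = 0, delta = 0,
                          N_GQ = 5, N_GQt = 3)
  expect_equal(expected_fitness_G(scn0, "Q", method = "exact"),
               survival((1 - 0.2) * (2 - 0.5), 0.8))
})

test_that("exact enumeration and Monte Carlo agree within sampling error", {
  set.seed(33)
  for (i in 1:8) {
    scn <- random_small_G_scenario()
    genotype <- sample(c("Q", "Qt"), 1)
    exact <- expected_fitness_G(scn, genotype, method = "exact")
    expect_mc_agreement(function(stage) {
      expected_fitness_G(scn, genotype, method = "monte-carlo",
                         n_draws = stage * 4e4, seed = 100 + 50 * stage + i)
    }, exact)
  }
})

test_that("exact enumeration above its cap directs to Monte Carlo", {
  scn <- gemino_scenario(1, 0.1, 0.05, 2, beta = 0.2, delta = 0.1,
                         N_GQ = 30, N_GQt = 5)
  expect_error(expected_fitness_G(scn, "Q", method = "exact"), "monte-carlo")
})

test_that("twinning-path fitness rises with the pool share, falls with the
           membership cost", {
  base <- function(alpha, gamma) {
    scn <- gemino_scenario(M = 1, gamma_cost = gamma, alpha_share = alpha,
                           lambda_surv = 2, beta = 0.2, delta = 0.8,
                           N_GQ = 8, N_GQt = 1)
    # the Qt type here always twins, isolating the twinning path
    expected_fitness_G(scn, "Qt", method = "exact")
  }
  w_alpha <- vapply(seq(0, 0.3, by = 0.05), base, numeric(1), gamma = 0.1)
  expect_true(all(diff(w_alpha) >= 0))
  w_gamma <- vapply(seq(0, 0.5, by = 0.1), base, numeric(1), alpha = 0.1)
  expect_true(all(diff(w_gamma) <= 0))
})

test_that("invasion condition matches direct evaluation of the two sides", {
  N <- 100; M <- 1; gamma <- 0.1; alpha <- 0.01; lam <- 2
  lhs <- 2 * survival((M - gamma) * (1 + alpha * (N - 1)) / 2, lam)
  rhs <- survival((1 - alpha) * (M - gamma), lam)
  expect_identical(invasion_condition(N, M, gamma, alpha, lam), lhs > rhs)
  # without a pool, a threshold survival that penalises half-shares blocks
  # the mutant
  S_step <- step_survival(0.75 * (M - gamma))
  stopifnot(twinning_maladaptive(M - gamma, surv_fn = S_step))
  expect_false(invasion_condition(N, M, gamma, 0, surv_fn = S_step))
})

test_that("a norm share of about 1/N guarantees invasion", {
  # alpha >= 1/(N+1) makes the twin half-share at least the contributing
  # singleton share, so monotonicity plus the factor of two decide
  for (N in c(10, 100, 1000)) {
    alpha <- 1 / (N + 1)
    for (S in strictly_increasing_survivals()) {
      expect_true(invasion_condition(N, 1, 0.1, alpha, surv_fn = S))
    }
  }
})

test_that("the conservative share is tight at 1/(N + 1)", {
  expect_equal(conservative_alpha(99), 0.01)
  expect_lt(conservative_alpha(1e6), 1e-6 + 1e-12)
  N <- 100
  net <- 0.9
  a_star <- conservative_alpha(N)
  # just below the bound the twin half-share drops under the singleton
  # share, and a survival rising steeply between the two fails the invasion
  a_eps <- a_star - 1e-9
  lhs_arg <- net * (1 + a_eps * (N - 1)) / 2
  rhs_arg <- (1 - a_eps) * net
  expect_lt(lhs_arg, rhs_arg)
  S_knife <- function(r) stats::plogis((r - (lhs_arg + rhs_arg) / 2) / 1e-12)
  expect_false(invasion_condition(N, 1, 0.1, a_eps, surv_fn = S_knife))
  expect_true(invasion_condition(N, 1, 0.1, a_star, surv_fn = S_knife))
})

test_that("scenario validation enforces the documented invariants", {
  expect_error(gemino_scenario(1, 1.2, 0.1, 2, 0.1, 0, N_GQ = 10),
               "gamma_cost < M")
  expect_error(gemino_scenario(1, 0.1, 1.4, 2, 0.1, 0, N_GQ = 10),
               "alpha_share")
  expect_error(gemino_scenario(1, 0.1, 0.1, -1, 0.1, 0, N_GQ = 10),
               "lambda_surv")
  expect_error(gemino_scenario(1, 0.1, 0.1, 2, 0.7, 0.5, N_GQ = 10),
               "beta \\+ delta")
  expect_error(gemino_scenario(1, 0.1, 0.1, 2, 0.1, 0, N_GQ = 2.5),
               "integer")
  expect_error(gemino_scenario(1, 0.1, 0.1, 2, 0.1, 0), "at least 1")
})
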