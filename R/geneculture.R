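#' Offspring survival under the exponential parameterisation
#'
#' The default survival function of the gene-culture model: the exponential
#' cumulative distribution function
#' \deqn{S(r) = 1 - e^{-\lambda r},}
#' mapping the resources `r` invested in an offspring to its survival
#' probability. `S` is smooth, strictly increasing and concave; note that
#' concavity through the origin implies `2 S(M/2) > S(M)` for every `M > 0`,
#' so under this parameterisation alone a twin birth always yields more
#' expected survivors than a singleton — twinning costliness, where assumed,
#' must come from a differently shaped survival function (see
#' [twinning_maladaptive()]).
#'
#' @param resources Non-negative resource amount(s) invested per offspring.
#' @param lambda_surv Positive rate parameter (per resource unit).
#' @return Survival probability/probabilities in `[0, 1)`.
#' @examples
#' survival(1, lambda_surv = 1)  # 1 - exp(-1) ~ 0.632
#' @export
survival <- function(resources, lambda_surv) {
  if (!is.numeric(resources) || any(!is.finite(resources)) ||
      any(resources < 0)) {
    stop("`resources` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(lambda_surv) || length(lambda_surv) != 1L ||
      lambda_surv <= 0) {
    stop("`lambda_surv` must be a single positive rate", call. = FALSE)
  }
  1 - exp(-lambda_surv * resources)
}

# Resolve the pluggable survival function: a user-supplied monotone map from
# resources to [0,1], or the exponential default at rate lambda_surv.
.resolve_surv <- function(surv_fn = NULL, lambda_surv = NULL) {
  if (!is.null(surv_fn)) {
    if (!is.function(surv_fn)) stop("`surv_fn` must be a function",
                                    call. = FALSE)
    return(surv_fn)
  }
  if (is.null(lambda_surv)) {
    stop("supply either `surv_fn` or `lambda_surv`", call. = FALSE)
  }
  function(r) survival(r, lambda_surv)
}

#' Is twinning maladaptive without institutions?
#'
#' Singleton births are favoured by selection when a single offspring with
#' the full endowment beats two offspring on half-shares:
#' \deqn{S(M) > 2\, S(M/2).}
#' This is a functional inequality on the shape of `S`: it fails for every
#' concave survival function through the origin (including the exponential
#' default) and holds for sufficiently convex or threshold-like ones, so the
#' survival function is pluggable and the check is reported for the
#' configured `S` rather than assumed.
#'
#' @param M Per-individual resource endowment (positive).
#' @param lambda_surv Rate of the exponential default survival; ignored when
#'   `surv_fn` is given.
#' @param surv_fn Optional survival function: a monotone increasing map from
#'   resources to `[0, 1]`.
#' @return Logical flag: `TRUE` when singleton births are favoured.
#' @examples
#' twinning_maladaptive(1, lambda_surv = 2)                 # FALSE (concave S)
#' twinning_maladaptive(1, surv_fn = function(r) pmin(r, 1)^2)  # TRUE (convex)
#' @export
twinning_maladaptive <- function(M, lambda_surv = NULL, surv_fn = NULL) {
  if (!is.numeric(M) || length(M) != 1L || M <= 0) {
    stop("`M` must be a single positive endowment", call. = FALSE)
  }
  S <- .resolve_surv(surv_fn, lambda_surv)
  S(M) > 2 * S(M / 2)
}

#' Expected fitness of non-geminophilous individuals
#'
#' An `A`-type (no support network) individual with genotype twinning
#' probability `beta` produces a twin birth with probability `beta` (each
#' twin on a half-share `M/2`) and a singleton otherwise (full endowment):
#' \deqn{W_A = (1 - \beta) S(M) + \beta \, 2 S(M/2).}
#' When twinning is maladaptive for the configured `S`
#' ([twinning_maladaptive()]), `W_A` is strictly decreasing in `beta`, so the
#' twinning rate can never increase in a population purely of type `A`.
#'
#' @param genotype_beta Twin-birth probability of the genotype, in `[0, 1]`
#'   (use `beta + delta` for the high-twinning mutant).
#' @inheritParams twinning_maladaptive
#' @return Expected number of surviving offspring.
#' @export
fitness_A <- function(genotype_beta, M, lambda_surv = NULL, surv_fn = NULL) {
  if (!is.numeric(genotype_beta) || any(genotype_beta < 0) ||
      any(genotype_beta > 1)) {
    stop("`genotype_beta` must be a probability in [0, 1]", call. = FALSE)
  }
  S <- .resolve_surv(surv_fn, lambda_surv)
  (1 - genotype_beta) * S(M) + genotype_beta * 2 * S(M / 2)
}

#' Define a gene-culture scenario
#'
#' Parameters of the geminophilous-redistribution model. Two genotypes — a
#' low-twinning resident `Q` (twin-birth probability `beta`) and a
#' high-twinning mutant `Qt` (probability `beta + delta`) — cross two
#' cultural types: `G` (member of the geminophilous support network) and `A`
#' (not a member), giving four types `AQ`, `AQt`, `GQ`, `GQt`. All
#' individuals hold `M` resource units and produce one birth per generation.
#' `G`-types pay a fixed membership cost `gamma_cost`; `G`-types who produce
#' a singleton additionally contribute the variable share
#' `alpha_share * (M - gamma_cost)` to the redistribution pool, which is
#' split equally among the `G`-types who produced twins that generation.
#'
#' @param M Per-individual resource endowment (resource units, positive).
#' @param gamma_cost Fixed membership cost of the support network; must
#'   satisfy `0 <= gamma_cost < M`.
#' @param alpha_share Fraction of `(M - gamma_cost)` contributed by
#'   non-twinning `G`-types, in `[0, 1]`.
#' @param lambda_surv Rate of the exponential default survival function
#'   (positive).
#' @param beta Twin-birth probability of genotype `Q`, in `[0, 1]`.
#' @param delta Twinning increment of the mutant `Qt` (additive:
#'   `beta + delta` must stay in `[0, 1]`).
#' @param N_AQ,N_AQt,N_GQ,N_GQt Counts of the four types (non-negative
#'   integers, total at least 1).
#' @return An object of class `"gemino_scenario"` (a validated list of the
#'   above fields plus the total `N`).
#' @examples
#' scn <- gemino_scenario(M = 1, gamma_cost = 0.1, alpha_share = 0.01,
#'                        lambda_surv = 2, beta = 0, delta = 1,
#'                        N_GQ = 99, N_GQt = 1)
#' @export
gemino_scenario <- function(M, gamma_cost, alpha_share, lambda_surv,
                            beta, delta,
                            N_AQ = 0, N_AQt = 0, N_GQ = 0, N_GQt = 0) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    v
  }
  M <- num1(M, "M"); gamma_cost <- num1(gamma_cost, "gamma_cost")
  alpha_share <- num1(alpha_share, "alpha_share")
  lambda_surv <- num1(lambda_surv, "lambda_surv")
  beta <- num1(beta, "beta"); delta <- num1(delta, "delta")
  if (M <= 0) stop("`M` must be positive", call. = FALSE)
  if (gamma_cost < 0 || gamma_cost >= M) {
    stop("`gamma_cost` must satisfy 0 <= gamma_cost < M", call. = FALSE)
  }
  if (alpha_share < 0 || alpha_share > 1) {
    stop("`alpha_share` must lie in [0, 1]", call. = FALSE)
  }
  if (lambda_surv <= 0) stop("`lambda_surv` must be positive", call. = FALSE)
  if (beta < 0 || delta < 0 || beta + delta > 1) {
    stop("need 0 <= beta <= beta + delta <= 1", call. = FALSE)
  }
  counts <- c(N_AQ = N_AQ, N_AQt = N_AQt, N_GQ = N_GQ, N_GQt = N_GQt)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("type counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (sum(counts) < 1L) stop("total population must be at least 1",
                             call. = FALSE)
  structure(
    list(M = M, gamma_cost = gamma_cost, alpha_share = alpha_share,
         lambda_surv = lambda_surv, beta = beta, delta = delta,
         N_AQ = counts[[1]], N_AQt = counts[[2]],
         N_GQ = counts[[3]], N_GQt = counts[[4]],
         N = sum(counts)),
    class = "gemino_scenario"
  )
}

#' @export
print.gemino_scenario <- function(x, ...) {
  cat("Gene-culture scenario\n")
  cat(sprintf("  endowment M = %.4g, membership cost gamma = %.4g,",
              x$M, x$gamma_cost),
      sprintf(" pool share alpha = %.4g\n", x$alpha_share))
  cat(sprintf("  survival rate lambda = %.4g\n", x$lambda_surv))
  cat(sprintf("  twinning: beta = %.4g (Q), beta + delta = %.4g (Qt)\n",
              x$beta, x$beta + x$delta))
  cat(sprintf("  counts: AQ = %d, AQt = %d, GQ = %d, GQt = %d (N = %d)\n",
              x$N_AQ, x$N_AQt, x$N_GQ, x$N_GQt, x$N))
  invisible(x)
}

.check_scenario <- function(scenario) {
  if (!inherits(scenario, "gemino_scenario")) {
    stop("`scenario` must be a `gemino_scenario` object", call. = FALSE)
  }
  scenario
}

#' Redistribution-pool accounting for one generation
#'
#' Given the realised number of `G`-type singleton producers, the pool holds
#' `alpha_share * (M - gamma_cost)` resource units per contributor,
#' \deqn{\kappa = \alpha (M - \gamma)\, n_{\mathrm{singleton}},}
#' and is split equally among the `T_G` `G`-types who produced twins. When no
#' `G`-type twins, contributions are still collected (non-twinner fitness
#' uses `(1 - alpha)(M - gamma)` unconditionally) and the pool is discarded.
#'
#' @param scenario A [gemino_scenario()].
#' @param n_G_singleton_producers Realised count of `G`-type individuals who
#'   produced singletons this generation (at most the total `G` count).
#' @return An object of class `"pool_outcome"`: list with `kappa`, `T_G`
#'   (the complementary count of `G`-type twinners) and
#'   `per_twinner_payout` (`kappa / T_G`, or `NA` when `T_G = 0`).
#' @examples
#' scn <- gemino_scenario(1, 0.1, 0.01, 2, beta = 0, delta = 1, N_GQ = 100)
#' pool(scn, n_G_singleton_producers = 99)  # kappa = 0.891 to one twinner
#' @export
pool <- function(scenario, n_G_singleton_producers) {
  .check_scenario(scenario)
  n_G <- scenario$N_GQ + scenario$N_GQt
  n_s <- n_G_singleton_producers
  if (!is.numeric(n_s) || length(n_s) != 1L || n_s < 0 || n_s > n_G ||
      n_s != round(n_s)) {
    stop("`n_G_singleton_producers` must be an integer in [0, N_GQ + N_GQt]",
         call. = FALSE)
  }
  kappa <- scenario$alpha_share * (scenario$M - scenario$gamma_cost) * n_s
  T_G <- n_G - n_s
  structure(
    list(kappa = kappa, T_G = as.integer(T_G),
         per_twinner_payout = if (T_G > 0) kappa / T_G else NA_real_),
    class = "pool_outcome"
  )
}

#' @export
print.pool_outcome <- function(x, ...) {
  cat(sprintf("Pool outcome: kappa = %.6g across %d twinner(s)", x$kappa,
              x$T_G))
  if (x$T_G > 0) cat(sprintf(" (%.6g each)", x$per_twinner_payout))
  cat("\n")
  invisible(x)
}

#' Expected fitness of geminophilous individuals
#'
#' The expected surviving-offspring count of a focal `G`-type individual of
#' the given genotype, taking the expectation over the twin/singleton
#' Bernoulli draws of **all** `G`-type individuals (the focal draw and the
#' binomial twin counts of the others, which jointly determine the pool
#' `kappa` and the twinner count `T_G`; the focal individual's own outcome
#' counts towards both):
#' \deqn{W_G = E\big[(1 - B)\, S\big((1-\alpha)(M-\gamma)\big) +
#'   B \, 2 S\big((M - \gamma + \kappa/T_G)/2\big)\big].}
#' The exact method enumerates the joint binomial outcomes and is limited to
#' small networks (`exact_cap`); the Monte Carlo method averages seeded
#' independent replicates and attaches its standard error.
#'
#' @param scenario A [gemino_scenario()] with at least one `G`-type of the
#'   requested genotype.
#' @param genotype `"Q"` (twin probability `beta`) or `"Qt"`
#'   (`beta + delta`).
#' @param method `"exact"` enumeration (requires
#'   `N_GQ + N_GQt <= exact_cap`) or `"monte-carlo"`.
#' @param n_draws Number of Monte Carlo replicates (default `1e5`).
#' @param seed RNG seed for the Monte Carlo method.
#' @param exact_cap Largest `G`-population size accepted by the exact method
#'   (default 20).
#' @param surv_fn Optional survival function overriding the exponential
#'   default.
#' @return Expected surviving offspring (scalar). For the Monte Carlo method
#'   the estimate carries an attribute `"mc_se"` with its standard error.
#' @examples
#' scn <- gemino_scenario(1, 0.1, 0.05, 2, beta = 0.2, delta = 0.3,
#'                        N_GQ = 5, N_GQt = 5)
#' expected_fitness_G(scn, "Q", method = "exact")
#' @export
expected_fitness_G <- function(scenario, genotype = c("Q", "Qt"),
                               method = c("exact", "monte-carlo"),
                               n_draws = 1e5, seed = NULL, exact_cap = 20,
                               surv_fn = NULL) {
  .check_scenario(scenario)
  genotype <- match.arg(genotype)
  method <- match.arg(method)
  S <- .resolve_surv(surv_fn, scenario$lambda_surv)
  n_G <- scenario$N_GQ + scenario$N_GQt
  n_focal_class <- if (genotype == "Q") scenario$N_GQ else scenario$N_GQt
  if (n_focal_class < 1L) {
    stop("scenario has no G-type individual of genotype ", genotype,
         call. = FALSE)
  }
  p_f <- scenario$beta + if (genotype == "Qt") scenario$delta else 0
  n1 <- scenario$N_GQ - (genotype == "Q")    # other G residents
  n2 <- scenario$N_GQt - (genotype == "Qt")  # other G mutants
  net <- scenario$M - scenario$gamma_cost
  s_singleton <- S((1 - scenario$alpha_share) * net)
  twin_share <- function(T_G) {
    # kappa/T_G payout with kappa from the complementary singleton count
    kappa <- scenario$alpha_share * net * (n_G - T_G)
    (net + kappa / T_G) / 2
  }

  if (method == "exact") {
    if (n_G > exact_cap) {
      stop("exact enumeration is limited to N_GQ + N_GQt <= ", exact_cap,
           " (got ", n_G, "); use method = \"monte-carlo\"", call. = FALSE)
    }
    k1 <- 0:n1
    k2 <- 0:n2
    w12 <- outer(stats::dbinom(k1, n1, scenario$beta),
                 stats::dbinom(k2, n2, scenario$beta + scenario$delta))
    k_oth <- outer(k1, k2, `+`)
    # focal singleton branch: fitness independent of others' outcomes
    f0 <- s_singleton
    # focal twin branch: T_G = k_oth + 1 >= 1
    f1 <- sum(w12 * 2 * S(twin_share(k_oth + 1)))
    return((1 - p_f) * f0 + p_f * f1)
  }

  if (!is.null(seed)) set.seed(seed)
  B <- stats::rbinom(n_draws, 1L, p_f)
  k_oth <- stats::rbinom(n_draws, n1, scenario$beta) +
    stats::rbinom(n_draws, n2, scenario$beta + scenario$delta)
  f <- ifelse(B == 1L, 2 * S(twin_share(k_oth + 1)), s_singleton)
  est <- mean(f)
  attr(est, "mc_se") <- stats::sd(f) / sqrt(n_draws)
  est
}

#' Invasion condition for a lone high-twinning mutant
#'
#' In an all-geminophilous population of size `N` with non-twinning
#' residents (`beta = 0`), a single mutant who twins receives the whole pool
#' `kappa = alpha_share * (M - gamma_cost) * (N - 1)` as the lone twinner.
#' The mutant's twin birth beats a resident singleton birth when
#' \deqn{2\, S\!\big((M-\gamma)(1 + \alpha(N-1))/2\big) >
#'   S\big((1-\alpha)(M-\gamma)\big).}
#' Since `S` is monotone increasing, the condition is guaranteed whenever the
#' left argument is at least the right one, i.e. whenever
#' `alpha_share >= 1/(N + 1)` (see [conservative_alpha()]); so a cultural
#' norm as mild as contributing about `1/N` of net wealth suffices.
#'
#' @param N Total population size (all `G`-type, `N >= 2`).
#' @param M Per-individual endowment.
#' @param gamma_cost Fixed membership cost, `0 <= gamma_cost < M`.
#' @param alpha_share Pool contribution fraction in `[0, 1]`.
#' @param lambda_surv Rate of the exponential default survival.
#' @param surv_fn Optional survival function overriding the default.
#' @return Logical flag: `TRUE` when the lone twinning mutant out-reproduces
#'   residents.
#' @examples
#' invasion_condition(N = 100, M = 1, gamma_cost = 0.1, alpha_share = 0.01,
#'                    lambda_surv = 2)
#' @export
invasion_condition <- function(N, M, gamma_cost, alpha_share,
                               lambda_surv = NULL, surv_fn = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  if (gamma_cost < 0 || gamma_cost >= M) {
    stop("`gamma_cost` must satisfy 0 <= gamma_cost < M", call. = FALSE)
  }
  if (alpha_share < 0 || alpha_share > 1) {
    stop("`alpha_share` must lie in [0, 1]", call. = FALSE)
  }
  S <- .resolve_surv(surv_fn, lambda_surv)
  net <- M - gamma_cost
  2 * S(net * (1 + alpha_share * (N - 1)) / 2) > S((1 - alpha_share) * net)
}

#' Conservative pool share sufficient for invasion
#'
#' The smallest contribution fraction for which the *argument* comparison
#' behind the invasion condition holds — the lone mutant twin's half-share
#' `(M - gamma)(1 + alpha(N - 1))/2` at least matching a contributing
#' singleton's `(1 - alpha)(M - gamma)` — which reduces to
#' \deqn{\alpha \ge \frac{1}{N + 1}.}
#' At this value the invasion condition holds for *every* strictly
#' increasing survival function (equal arguments, and the factor of two
#' breaks the tie); any smaller value fails for some survival function (one
#' rising steeply between the two arguments). It vanishes as `N` grows: in a
#' large community the per-capita cost of insuring twinners is small.
#'
#' @param N Total `G`-population size (`N >= 2`).
#' @return The fraction `1/(N + 1)`.
#' @examples
#' conservative_alpha(99)  # 0.01; the norm alpha ~ 1/99 exceeds it
#' @export
conservative_alpha <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  1 / (N + 1)
}
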