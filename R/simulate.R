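# One generation of the stochastic model, operating on type counts.
# Individuals within a type x birth-outcome class are exchangeable, so
# binomial draws per class are distribution-identical to individual-level
# Bernoulli draws. Returns realised twin counts, pool accounting and
# survivor totals per type.
.gc_generation <- function(counts, scenario, S) {
  p_twin <- scenario$beta + c(0, scenario$delta, 0, scenario$delta)
  twins <- stats::rbinom(4L, counts, p_twin)
  singles <- counts - twins
  T_G <- twins[3L] + twins[4L]
  n_Gs <- singles[3L] + singles[4L]
  net <- scenario$M - scenario$gamma_cost
  kappa <- scenario$alpha_share * net * n_Gs
  s_A1 <- S(scenario$M)
  s_A2 <- S(scenario$M / 2)
  s_G1 <- S((1 - scenario$alpha_share) * net)
  s_G2 <- if (T_G > 0L) S((net + kappa / T_G) / 2) else 0
  survivors <- c(
    stats::rbinom(1L, singles[1L], s_A1) +
      stats::rbinom(1L, 2L * twins[1L], s_A2),
    stats::rbinom(1L, singles[2L], s_A1) +
      stats::rbinom(1L, 2L * twins[2L], s_A2),
    stats::rbinom(1L, singles[3L], s_G1) +
      stats::rbinom(1L, 2L * twins[3L], s_G2),
    stats::rbinom(1L, singles[4L], s_G1) +
      stats::rbinom(1L, 2L * twins[4L], s_G2)
  )
  list(twins = twins, kappa = kappa, T_G = T_G, survivors = survivors)
}

#' Simulate the gene-culture model generation by generation
#'
#' Full stochastic dynamics of the four types under Wright-Fisher (fixed-N)
#' regulation. Each generation: (1) every individual independently draws a
#' twin or singleton birth (Bernoulli with its genotype's twin probability);
#' (2) the redistribution pool is filled by the realised `G`-type singleton
#' producers and split equally among the realised `G`-type twinners; (3)
#' every offspring survives independently with probability `S` of its
#' resource share — `M` for an `A` singleton, `M/2` per `A` twin,
#' `(1 - alpha)(M - gamma)` for a `G` singleton, `(M - gamma + kappa/T_G)/2`
#' per `G` twin; (4) the next generation of constant size `N` is formed by
#' multinomial resampling of parents in proportion to their realised
#' surviving-offspring counts, offspring inheriting genotype and cultural
#' type clonally. A neutral mutant (`delta = 0`) therefore drifts with
#' fixation probability equal to its initial frequency (1/N when starting
#' from a single copy).
#'
#' If a generation produces no surviving offspring at all, the trajectory is
#' truncated there and flagged extinct.
#'
#' @param scenario A [gemino_scenario()].
#' @param generations Number of generations to simulate (integer >= 1).
#' @param seed Integer RNG seed; the trajectory is fully reproducible from
#'   `scenario` + `seed`.
#' @param surv_fn Optional survival function (monotone map from resources to
#'   `[0, 1]`) overriding the exponential default at `lambda_surv`.
#' @return A data frame of class `"population_trajectory"`, one row per
#'   generation (row 0 records the initial state), with columns `generation`,
#'   type counts `N_AQ`, `N_AQt`, `N_GQ`, `N_GQt`, realised twin counts
#'   `twins_AQ` ... `twins_GQt`, `kappa`, survivor totals `surv_AQ` ...
#'   `surv_GQt`, and `extinct`. The seed and scenario are attached as
#'   attributes.
#' @examples
#' scn <- gemino_scenario(1, 0.1, 0.05, 2, beta = 0, delta = 1,
#'                        N_GQ = 99, N_GQt = 1)
#' traj <- simulate_geneculture(scn, generations = 20, seed = 42)
#' tail(traj, 3)
#' @export
simulate_geneculture <- function(scenario, generations, seed = NULL,
                                 surv_fn = NULL) {
  .check_scenario(scenario)
  if (!is.numeric(generations) || length(generations) != 1L ||
      generations < 1 || generations != round(generations)) {
    stop("`generations` must be a single integer >= 1", call. = FALSE)
  }
  generations <- as.integer(generations)
  if (!is.null(seed)) set.seed(seed)
  S <- .resolve_surv(surv_fn, scenario$lambda_surv)
  N <- scenario$N
  counts <- c(scenario$N_AQ, scenario$N_AQt, scenario$N_GQ, scenario$N_GQt)

  rec <- matrix(NA_real_, nrow = generations + 1L, ncol = 14L)
  colnames(rec) <- c("generation", "N_AQ", "N_AQt", "N_GQ", "N_GQt",
                     "twins_AQ", "twins_AQt", "twins_GQ", "twins_GQt",
                     "kappa", "surv_AQ", "surv_AQt", "surv_GQ", "surv_GQt")
  rec[1L, ] <- c(0, counts, rep(NA_real_, 9L))
  extinct <- FALSE
  last <- 1L
  for (g in seq_len(generations)) {
    step <- .gc_generation(counts, scenario, S)
    tot <- sum(step$survivors)
    if (tot == 0L) {
      rec[g + 1L, ] <- c(g, rep(0, 4L), step$twins, step$kappa,
                         step$survivors)
      extinct <- TRUE
      last <- g + 1L
      break
    }
    counts <- as.integer(stats::rmultinom(1L, N, step$survivors))
    rec[g + 1L, ] <- c(g, counts, step$twins, step$kappa, step$survivors)
    last <- g + 1L
  }
  traj <- as.data.frame(rec[seq_len(last), , drop = FALSE])
  traj$extinct <- c(rep(FALSE, last - 1L), extinct)
  class(traj) <- c("population_trajectory", "data.frame")
  attr(traj, "scenario") <- scenario
  attr(traj, "seed") <- seed
  traj
}

#' @export
print.population_trajectory <- function(x, ...) {
  n_gen <- max(x$generation)
  cat("Population trajectory:", n_gen, "generation(s), N =",
      sum(x[1, c("N_AQ", "N_AQt", "N_GQ", "N_GQt")]),
      if (any(x$extinct)) "(extinct)" else "", "\n")
  print(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Run seeded replicate simulations
#'
#' Repeats [simulate_geneculture()] with per-replicate child seeds derived
#' deterministically from one root seed, and stacks the trajectories.
#'
#' @inheritParams simulate_geneculture
#' @param replicates Number of independent replicates (integer >= 1).
#' @param seed Root seed; child seeds are drawn from it reproducibly.
#' @return A data frame: all trajectories row-bound with a leading
#'   `replicate` column.
#' @export
simulate_replicates <- function(scenario, generations, replicates, seed,
                                surv_fn = NULL) {
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates < 1 || replicates != round(replicates)) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, replicates)
  out <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    traj <- simulate_geneculture(scenario, generations,
                                 seed = child_seeds[i], surv_fn = surv_fn)
    out[[i]] <- cbind(replicate = i, as.data.frame(traj))
  }
  do.call(rbind, out)
}
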