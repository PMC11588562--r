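#' Define an ovulation-strategy ecology
#'
#' Bundles the coefficients of the resource-dependent fitness landscape that
#' compares a double-ovulation genotype \eqn{P} against a mono-ovulation
#' genotype \eqn{S}. Embryo/foetal mortality declines linearly with the
#' maternal resource endowment \eqn{E \in (0, 1)},
#' \deqn{m(E) = d - cE,}
#' the reproductive value of a twin birth rises linearly,
#' \deqn{R_t(E) = aE + b,}
#' and a singleton birth has constant reproductive value \eqn{R_s}. Above the
#' resource threshold \eqn{E^* = (R_s - b)/a} a twin birth outvalues a
#' singleton and twinning is adaptive outright; below it, twinning is costly
#' but double ovulation may still be favoured as insurance against embryo
#' mortality.
#'
#' Validation is strict and fails fast: parameter sets under which \eqn{m(E)}
#' could leave \eqn{[0, 1]} on the open unit interval are rejected here rather
#' than clamped later, because clamping would silently change the model.
#'
#' @param a Slope of twin reproductive value in resources (fitness units per
#'   resource unit); must be positive.
#' @param b Intercept of twin reproductive value (fitness units).
#' @param c Slope magnitude of embryo mortality in resources (probability per
#'   resource unit); must be positive.
#' @param d Intercept of embryo mortality (probability); requires
#'   `c < d <= 1` so that `d - c*E` stays inside the unit interval for all
#'   `E` in (0, 1).
#' @param Rs Reproductive value of a singleton birth (fitness units); must
#'   exceed `b` so that the threshold `E*` is positive.
#'
#' @return An object of class `"ovulation_ecology"`: a list with fields
#'   `a`, `b`, `c`, `d`, `Rs` and the derived threshold `E_star`.
#' @examples
#' eco <- ovulation_ecology(a = 2, b = 0.2, c = 0.5, d = 0.9, Rs = 1)
#' eco$E_star  # 0.4
#' @seealso [selection_quadratic()], [partition_resource_space()]
#' @export
ovulation_ecology <- function(a, b, c, d, Rs) {
  for (nm in c("a", "b", "c", "d", "Rs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (c <= 0) stop("`c` must be positive (mortality declines with resources)",
                   call. = FALSE)
  if (d <= c) stop("`d` must exceed `c` so that m(1) = d - c stays positive",
                   call. = FALSE)
  if (d > 1) stop("`d` must not exceed 1: m(E) = d - c*E is a probability",
                  call. = FALSE)
  if (a <= 0) stop("`a` must be positive (twin value increases with resources)",
                   call. = FALSE)
  if (Rs <= b) stop("`Rs` must exceed `b` so that the threshold E* = (Rs - b)/a ",
                    "is positive (twinning costly at the bottom of the range)",
                    call. = FALSE)
  structure(
    list(a = a, b = b, c = c, d = d, Rs = Rs, E_star = (Rs - b) / a),
    class = "ovulation_ecology"
  )
}

#' @export
print.ovulation_ecology <- function(x, ...) {
  cat("Ovulation ecology\n")
  cat(sprintf("  mortality      m(E)  = %.4g - %.4g E\n", x$d, x$c))
  cat(sprintf("  twin value     R_t(E) = %.4g E + %.4g\n", x$a, x$b))
  cat(sprintf("  singleton value R_s  = %.4g\n", x$Rs))
  cat(sprintf("  threshold      E*    = %.4g\n", x$E_star))
  invisible(x)
}

.check_E <- function(E) {
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("resource endowment `E` must lie in the open interval (0, 1)",
         call. = FALSE)
  }
  E
}

.check_eco <- function(eco) {
  if (!inherits(eco, "ovulation_ecology")) {
    stop("`eco` must be an `ovulation_ecology` object", call. = FALSE)
  }
  eco
}

#' Embryo/foetal mortality as a function of resources
#'
#' The linearly decreasing mortality `m(E) = d - c*E`. Vectorised over `E`.
#'
#' @param E Resource endowment(s) in the open interval (0, 1).
#' @param eco An [ovulation_ecology()].
#' @return Mortality probability/probabilities in `[0, 1]`.
#' @examples
#' eco <- ovulation_ecology(2, 0.2, 0.5, 0.9, 1)
#' embryo_mortality(0.4, eco)  # 0.7
#' @export
embryo_mortality <- function(E, eco) {
  .check_eco(eco)
  eco$d - eco$c * .check_E(E)
}

#' Reproductive value of a twin birth
#'
#' The linearly increasing twin value `R_t(E) = a*E + b`. At the threshold
#' `E* = (Rs - b)/a` it equals the singleton value `Rs`.
#'
#' @inheritParams embryo_mortality
#' @return Twin reproductive value(s) in fitness units.
#' @examples
#' eco <- ovulation_ecology(2, 0.2, 0.5, 0.9, 1)
#' twin_reproductive_value(0.3, eco)        # 0.8
#' twin_reproductive_value(eco$E_star, eco) # equals Rs
#' @export
twin_reproductive_value <- function(E, eco) {
  .check_eco(eco)
  eco$a * .check_E(E) + eco$b
}

#' Fitness of the double-ovulation genotype
#'
#' Both ova are fertilised and each embryo independently survives gestation
#' with probability `1 - m(E)`:
#' \deqn{W_P(E) = R_t(E)\,(1 - m)^2 + R_s \, 2 m (1 - m).}
#' Two survivors give a twin birth worth `R_t(E)`; exactly one survivor gives
#' a singleton worth `Rs`; no survivor contributes nothing.
#'
#' @inheritParams embryo_mortality
#' @return Expected fitness value(s), non-negative.
#' @examples
#' eco <- ovulation_ecology(2, 0.2, 0.5, 0.9, 1)
#' fitness_double_ovulation(0.4, eco)  # 0.51
#' @export
fitness_double_ovulation <- function(E, eco) {
  .check_eco(eco)
  m <- embryo_mortality(E, eco)
  twin_reproductive_value(E, eco) * (1 - m)^2 + eco$Rs * 2 * m * (1 - m)
}

#' Fitness of the mono-ovulation genotype
#'
#' A single ovum survives with probability `1 - m(E)` and yields a singleton:
#' \deqn{W_S(E) = R_s (1 - m(E)).}
#'
#' @inheritParams embryo_mortality
#' @return Expected fitness value(s), non-negative.
#' @examples
#' eco <- ovulation_ecology(2, 0.2, 0.5, 0.9, 1)
#' fitness_mono_ovulation(0.4, eco)  # 0.3
#' @export
fitness_mono_ovulation <- function(E, eco) {
  .check_eco(eco)
  eco$Rs * (1 - embryo_mortality(E, eco))
}

#' The quadratic selection condition
#'
#' Collecting the terms of the inequality \eqn{W_P(E) > W_S(E)} (below the
#' threshold `E*`) yields a concave parabola
#' \deqn{q(E) = \alpha E^2 + \beta E + \gamma,\quad
#'   \alpha = -ac,\;\; \beta = a(d - 1) + c(2R_s - b),\;\;
#'   \gamma = R_s(1 - 2d) + b(d - 1),}
#' and the exact identity \eqn{W_P - W_S = -(1 - m(E))\, q(E)} holds, so
#' wherever embryo mortality is below one, double ovulation is favoured if
#' and only if \eqn{q(E) < 0} — i.e. outside the root interval
#' \eqn{[E_1, E_2]} of the parabola.
#'
#' A discriminant within `1e-12` of zero is treated as a double root (a
#' single tangency point with no sign change, reported as two equal roots).
#'
#' @param eco An [ovulation_ecology()].
#' @return An object of class `"selection_quadratic"`: list with
#'   `alpha_q` (< 0 always), `beta_q`, `gamma_q`, `discriminant`, and `roots`
#'   (numeric vector of length 0, 1 or 2, sorted ascending).
#' @examples
#' sq <- selection_quadratic(ovulation_ecology(2, 0.2, 0.5, 0.9, 1))
#' c(sq$alpha_q, sq$beta_q, sq$gamma_q)  # -1.0, 0.7, -0.82
#' @export
selection_quadratic <- function(eco) {
  .check_eco(eco)
  alpha_q <- -eco$a * eco$c
  beta_q <- eco$a * (eco$d - 1) + eco$c * (2 * eco$Rs - eco$b)
  gamma_q <- eco$Rs * (1 - 2 * eco$d) + eco$b * (eco$d - 1)
  disc <- beta_q^2 - 4 * alpha_q * gamma_q
  tol <- 1e-12
  roots <- if (disc < -tol) {
    numeric(0)
  } else if (abs(disc) <= tol) {
    -beta_q / (2 * alpha_q)
  } else {
    sort((-beta_q + c(-1, 1) * sqrt(disc)) / (2 * alpha_q))
  }
  structure(
    list(alpha_q = alpha_q, beta_q = beta_q, gamma_q = gamma_q,
         discriminant = disc, roots = roots),
    class = "selection_quadratic"
  )
}

#' @export
print.selection_quadratic <- function(x, ...) {
  cat(sprintf("Selection quadratic q(E) = %.4g E^2 + %.4g E + %.4g\n",
              x$alpha_q, x$beta_q, x$gamma_q))
  if (length(x$roots) == 0) {
    cat("  no real roots (q(E) < 0 everywhere: double ovulation favoured",
        "wherever m(E) < 1)\n")
  } else {
    cat("  roots:", paste(signif(x$roots, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate the selection quadratic
#'
#' @param E Resource endowment(s) in (0, 1).
#' @param sq A [selection_quadratic()] (or an [ovulation_ecology()], from
#'   which the quadratic is derived).
#' @return `q(E)`; negative values mean double ovulation is favoured
#'   (wherever `m(E) < 1`).
#' @export
selection_quadratic_value <- function(E, sq) {
  if (inherits(sq, "ovulation_ecology")) sq <- selection_quadratic(sq)
  if (!inherits(sq, "selection_quadratic")) {
    stop("`sq` must be a `selection_quadratic` or `ovulation_ecology`",
         call. = FALSE)
  }
  .check_E(E)
  sq$alpha_q * E^2 + sq$beta_q * E + sq$gamma_q
}

#' Partition resource space into adaptive regions
#'
#' Splits the open unit interval of resource endowments at the roots of the
#' selection quadratic and at the twinning threshold `E*` (those falling
#' inside (0, 1)), and labels each maximal interval by whether twinning is
#' adaptive (`R_t(E) >= Rs`, i.e. `E >= E*`) and whether double ovulation is
#' favoured (`q(E) < 0`, equivalently `W_P > W_S` wherever `m(E) < 1`). With
#' both roots inside `(0, E*)` and `E* < 1` this reproduces the canonical
#' four-region layout in which double ovulation pays at both low and high
#' resource levels; fewer regions arise when roots are complex, coincident or
#' fall outside the interval.
#'
#' @param eco An [ovulation_ecology()].
#' @param tol Regions narrower than `tol` are dropped (guards against
#'   boundaries coinciding to rounding error). Default `1e-8`.
#' @return A data frame of class `"resource_regions"` with columns
#'   `lower`, `upper`, `twinning_adaptive`, `double_ov_favoured`; rows are
#'   ordered, disjoint and tile (0, 1).
#' @examples
#' eco <- ovulation_ecology(a = 1.1, b = 0.02, c = 0.5, d = 0.55, Rs = 1)
#' partition_resource_space(eco)  # four regions
#' @export
partition_resource_space <- function(eco, tol = 1e-8) {
  .check_eco(eco)
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("`tol` must be a small positive number", call. = FALSE)
  }
  sq <- selection_quadratic(eco)
  cuts <- c(sq$roots, eco$E_star)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < 1]))
  bounds <- c(0, cuts, 1)
  keep <- diff(bounds) >= tol
  lower <- bounds[-length(bounds)][keep]
  upper <- bounds[-1][keep]
  mid <- (lower + upper) / 2
  regions <- data.frame(
    lower = lower,
    upper = upper,
    twinning_adaptive = mid >= eco$E_star,
    double_ov_favoured = selection_quadratic_value(mid, sq) < 0
  )
  class(regions) <- c("resource_regions", "data.frame")
  attr(regions, "ecology") <- eco
  regions
}

#' @export
print.resource_regions <- function(x, ...) {
  cat("Resource-space partition (", nrow(x), " region",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  df <- as.data.frame(x)
  df$lower <- signif(df$lower, 6)
  df$upper <- signif(df$upper, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate the fitness landscape on a resource grid
#'
#' Evaluates mortality, twin value, both genotype fitnesses and the
#' favoured-genotype flag on a uniform grid over (0, 1), endpoints excluded
#' by a `1e-6` margin (the model is defined on the open interval).
#'
#' @param eco An [ovulation_ecology()].
#' @param n_grid Number of grid points (default 201).
#' @return A data frame with columns `E`, `m`, `R_t`, `W_P`, `W_S`,
#'   `favoured` (logical: double ovulation favoured).
#' @export
ovulation_curve <- function(eco, n_grid = 201) {
  .check_eco(eco)
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 2) {
    stop("`n_grid` must be an integer >= 2", call. = FALSE)
  }
  E <- seq(1e-6, 1 - 1e-6, length.out = as.integer(n_grid))
  data.frame(
    E = E,
    m = embryo_mortality(E, eco),
    R_t = twin_reproductive_value(E, eco),
    W_P = fitness_double_ovulation(E, eco),
    W_S = fitness_mono_ovulation(E, eco),
    favoured = selection_quadratic_value(E, eco) < 0
  )
}
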