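#' Probability of ever becoming a mother of twins
#'
#' Under a constant per-pregnancy twinning probability `x` and `P` successful
#' pregnancies (twinning neither reduces future pregnancies nor varies with
#' age or parity), the cumulative probability of at least one twin birth is
#' \deqn{T = 1 - (1 - x)^P.}
#' With a modern low-fertility regime (`P = 2`) and the global average
#' twinning rate (`x = 0.013`) about 2.6\% of women ever mother twins; in a
#' high-fertility regime (`P = 10`) at a Yoruba-like rate (`x = 0.045`) the
#' figure reaches roughly 37\%.
#'
#' @param x Per-pregnancy twinning probability (or vector), in `[0, 1]`.
#' @param P Number of successful pregnancies (or vector), non-negative
#'   integer(s). `x` and `P` are recycled to a common length.
#' @return Probability vector `T` in `[0, 1]`, non-decreasing in both
#'   arguments.
#' @examples
#' mother_of_twins_probability(0.013, 2)   # ~0.026
#' mother_of_twins_probability(0.045, 10)  # ~0.37
#' mother_of_twins_probability(0.028, 5)   # ~0.132
#' @export
mother_of_twins_probability <- function(x, P) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(P) || any(!is.finite(P)) || any(P < 0) ||
      any(P != round(P))) {
    stop("`P` must be non-negative integer pregnancy counts", call. = FALSE)
  }
  1 - (1 - x)^P
}

#' Prevalence of twin-maternity across fertility regimes
#'
#' Long-format table of the cumulative twin-maternity probability for each
#' supplied twinning rate over pregnancy counts `0..P_max`, suitable for
#' plotting prevalence curves.
#'
#' @param x_values Vector of per-pregnancy twinning probabilities in `[0, 1]`.
#' @param P_max Maximum number of pregnancies (integer >= 1).
#' @return A data frame with columns `x`, `P`, `T`, one row per `(x, P)`
#'   combination with `P = 0, ..., P_max`; within each `x`, `T` is
#'   non-decreasing in `P`.
#' @examples
#' curves <- prevalence_curves(c(0.013, 0.045), P_max = 10)
#' subset(curves, P == 10)
#' @export
prevalence_curves <- function(x_values, P_max) {
  if (!is.numeric(P_max) || length(P_max) != 1L || P_max < 1 ||
      P_max != round(P_max)) {
    stop("`P_max` must be a single integer >= 1", call. = FALSE)
  }
  grid <- expand.grid(P = 0:P_max, x = x_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("x", "P")]
  grid$T <- mother_of_twins_probability(grid$x, grid$P)
  rownames(grid) <- NULL
  grid
}

#' Plot twin-maternity prevalence curves
#'
#' Base-graphics rendering of [prevalence_curves()] output: one curve per
#' twinning rate, cumulative probability against number of pregnancies.
#'
#' @param curves A data frame from [prevalence_curves()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `curves`.
#' @export
plot_prevalence_curves <- function(curves, ...) {
  stopifnot(all(c("x", "P", "T") %in% names(curves)))
  wide <- stats::reshape(curves, direction = "wide", idvar = "P",
                         timevar = "x")
  Tm <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$P, Tm, type = "b", pch = 16, lty = 1,
                    xlab = "Number of pregnancies, P",
                    ylab = "P(at least one twin birth)", ...)
  graphics::legend("topleft", bty = "n", lty = 1, pch = 16,
                   col = seq_len(ncol(Tm)),
                   legend = paste0("x = ", unique(curves$x)))
  invisible(curves)
}
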