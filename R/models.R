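#' Protein burst model
#'
#' Transcription events arrive at exponentially distributed intervals with
#' rate \code{kx}; in the short-lived mRNA limit each event produces a burst
#' of \eqn{B} proteins drawn from the burst-size distribution.  Only the
#' first two moments of \eqn{B} enter the mean and noise formulas; the family
#' matters for stochastic simulation.
#'
#' Families:
#' \describe{
#'   \item{geometric0}{geometric on \{0, 1, 2, ...\} with mean \code{burst_mean};
#'     then \eqn{\langle B^2\rangle/\langle B\rangle = 1 + 2\langle B\rangle}.
#'     This is the default convention, matching the inference formulas.}
#'   \item{geometric1}{shifted geometric on \{1, 2, ...\};
#'     \eqn{\langle B^2\rangle/\langle B\rangle = 2\langle B\rangle - 1}.}
#'   \item{point_mass}{\eqn{B \equiv} \code{burst_mean} with probability 1.}
#'   \item{custom}{moments supplied explicitly via \code{burst_second_moment};
#'     not sampleable.}
#' }
#'
#' @param kx positive burst-arrival (transcription) rate, time^-1.
#' @param burst_mean positive mean burst size, molecules.
#' @param burst_family one of \code{"geometric0"}, \code{"geometric1"},
#'   \code{"point_mass"}, \code{"custom"}.
#' @param burst_second_moment \eqn{\langle B^2\rangle}; required for
#'   \code{"custom"}, derived otherwise.
#' @return object of class \code{burst_model}.
#' @export
burst_model <- function(kx, burst_mean,
                        burst_family = c("geometric0", "geometric1",
                                         "point_mass", "custom"),
                        burst_second_moment = NULL) {
  burst_family <- match.arg(burst_family)
  stopifnot(kx >= 0, burst_mean > 0)  # kx = 0 allowed for degenerate cases
  b <- burst_mean
  b2 <- switch(burst_family,
    geometric0 = b * (1 + 2 * b),
    geometric1 = b * (2 * b - 1),
    point_mass = b^2,
    custom = burst_second_moment
  )
  if (is.null(b2)) stop("`burst_second_moment` required for custom family")
  if (b2 < b^2 - 1e-12) stop("<B^2> must be at least <B>^2")
  structure(
    list(kx = kx, burst_mean = b, burst_second_moment = b2,
         burst_family = burst_family),
    class = "burst_model"
  )
}

#' @export
print.burst_model <- function(x, ...) {
  cat("Burst model: kx =", x$kx, " <B> =", x$burst_mean,
      " <B^2> =", x$burst_second_moment,
      " family =", x$burst_family, "\n")
  invisible(x)
}

#' Molecule-partitioning model at cell division
#'
#' At division each daughter inherits on average half of the mother's
#' molecules.  The conditional variance of the daughter's allotment is set by
#' the non-negative error parameter \code{alpha}:
#' \describe{
#'   \item{proportional}{\eqn{Var(x_+ | x) = \alpha x / 4}.  \code{alpha = 1}
#'     is binomial partitioning, \code{alpha = 0} deterministic halving,
#'     \code{alpha > 1} over-dispersed (aggregates/multimers).}
#'   \item{constant}{\eqn{Var(x_+ | x) = \alpha}, independent of the mother
#'     level; supported in the continuous hybrid models only.}
#' }
#'
#' @param alpha non-negative partitioning-error parameter.
#' @param variance_law \code{"proportional"} or \code{"constant"}.
#' @return object of class \code{partition_model}.
#' @export
partition_model <- function(alpha = 1,
                            variance_law = c("proportional", "constant")) {
  variance_law <- match.arg(variance_law)
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be non-negative")
  structure(list(alpha = alpha, variance_law = variance_law),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat("Partition model: alpha =", x$alpha, " law =", x$variance_law, "\n")
  invisible(x)
}

#' Gene-duplication schedule
#'
#' Splits the cell cycle into a pre-duplication phase of duration
#' \eqn{T_1} and a post-duplication phase \eqn{T_2}, each with its own
#' phase-type clock; after duplication the burst arrival rate is multiplied
#' by the dosage factor \code{f}.  The derived quantities are
#' \eqn{\beta = \langle T_1\rangle / (\langle T_1\rangle + \langle T_2\rangle)}
#' and the composite cycle noise
#' \eqn{CV_T^2 = \beta^2 CV_{T1}^2 + (1-\beta)^2 CV_{T2}^2}.
#'
#' @param f dosage factor >= 1 (fold increase of the burst arrival rate
#'   after duplication).
#' @param t1_clock,t2_clock \code{\link{erlang_mixture}} clocks for the two
#'   phases.
#' @return object of class \code{duplication_schedule} with the clocks plus
#'   derived fields \code{beta}, \code{mean_T}, \code{cv2_T1}, \code{cv2_T2},
#'   \code{cv2_T}.
#' @export
duplication_schedule <- function(f, t1_clock, t2_clock) {
  stopifnot(f >= 1, inherits(t1_clock, "erlang_mixture"),
            inherits(t2_clock, "erlang_mixture"))
  m1 <- timing_moments(t1_clock)
  m2 <- timing_moments(t2_clock)
  beta <- m1$mean / (m1$mean + m2$mean)
  structure(
    list(f = f, t1_clock = t1_clock, t2_clock = t2_clock,
         beta = beta, mean_T = m1$mean + m2$mean,
         cv2_T1 = m1$cv2, cv2_T2 = m2$cv2,
         cv2_T = beta^2 * m1$cv2 + (1 - beta)^2 * m2$cv2),
    class = "duplication_schedule"
  )
}

#' @export
print.duplication_schedule <- function(x, ...) {
  cat("Duplication schedule: f =", x$f, " beta =", signif(x$beta, 6),
      " <T> =", x$mean_T, "\n")
  cat("  CV_T1^2 =", signif(x$cv2_T1, 6),
      " CV_T2^2 =", signif(x$cv2_T2, 6),
      " composite CV_T^2 =", signif(x$cv2_T, 6), "\n")
  invisible(x)
}

#' Three-way protein noise decomposition
#'
#' Container for the steady-state mean protein level and the additive noise
#' components: extrinsic (random division/duplication timing,
#' \eqn{CV_E^2}), partitioning (\eqn{CV_R^2}) and production
#' (\eqn{CV_P^2}); the intrinsic noise is the sum of the last two.
#'
#' @param mean_x steady-state mean protein count.
#' @param cv2_ext,cv2_part,cv2_prod the three components (>= 0).
#' @return object of class \code{noise_decomposition}; the \code{cv2_total}
#'   field is the exact sum of the three components.
#' @export
noise_decomposition <- function(mean_x, cv2_ext, cv2_part, cv2_prod) {
  stopifnot(mean_x > 0, cv2_ext >= 0, cv2_part >= 0, cv2_prod >= 0)
  structure(
    list(mean_x = mean_x, cv2_ext = cv2_ext, cv2_part = cv2_part,
         cv2_prod = cv2_prod,
         cv2_total = cv2_ext + cv2_part + cv2_prod),
    class = "noise_decomposition"
  )
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("Protein noise decomposition\n")
  cat(sprintf("  mean            %12.6g molecules\n", x$mean_x))
  cat(sprintf("  CV^2 extrinsic  %12.6g\n", x$cv2_ext))
  cat(sprintf("  CV^2 partition  %12.6g\n", x$cv2_part))
  cat(sprintf("  CV^2 production %12.6g\n", x$cv2_prod))
  cat(sprintf("  CV^2 total      %12.6g\n", x$cv2_total))
  invisible(x)
}

#' @export
as.data.frame.noise_decomposition <- function(x, ...) {
  data.frame(mean_x = x$mean_x, cv2_ext = x$cv2_ext,
             cv2_part = x$cv2_part, cv2_prod = x$cv2_prod,
             cv2_total = x$cv2_total)
}
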