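#' Steady-state mean protein level
#'
#' For a stable protein expressed in bursts and diluted only by division,
#' the lineage steady-state mean is
#' \deqn{\bar{\langle x\rangle} = k_x \langle B\rangle \langle T\rangle
#'   (3 + CV_T^2)/2.}
#' The mean depends on the cycle-time noise: more variable cycles are more
#' positively skewed, so long cycles (and hence high accumulation) are more
#' likely.  Moving from an exponential cycle (\eqn{CV_T^2 = 1}) to a periodic
#' one (\eqn{CV_T^2 = 0}) at fixed \eqn{\langle T\rangle} lowers the mean by
#' 25\%.
#'
#' @param b a \code{\link{burst_model}}.
#' @param t a \code{\link{timing_moments}} object or an
#'   \code{\link{erlang_mixture}}.
#' @return mean protein copy number (molecules).
#' @export
mean_protein <- function(b, t) {
  t <- as_timing_moments(t)
  b$kx * b$burst_mean * t$mean * (3 + t$cv2) / 2
}

as_timing_moments <- function(t) {
  if (inherits(t, "erlang_mixture")) timing_moments(t)
  else if (inherits(t, "timing_moments")) t
  else stop("expected an `erlang_mixture` or `timing_moments` object")
}

#' Extrinsic noise from random cell-division timing
#'
#' Noise contribution of random division events alone (the continuous hybrid
#' model with deterministic production and error-free partitioning):
#' \deqn{CV_E^2 = \frac{1}{27} + \frac{4}{27}\,
#'  \frac{9\,\langle T^3\rangle/\langle T\rangle^3 - 9 - 6 CV_T^2 - 7 CV_T^4}
#'       {(3 + CV_T^2)^2}.}
#' It depends on the cycle-time distribution only through its first three
#' moments and tends to the floor 1/27 as the cycle time approaches a delta
#' distribution.  Division is a global event shared by all genes, hence
#' "extrinsic".
#'
#' @param cv2_T squared coefficient of variation of the cycle time (>= 0).
#' @param third_moment_ratio \eqn{\langle T^3\rangle/\langle T\rangle^3}
#'   (>= 1).
#' @param taylor if \code{TRUE}, return the small-noise expansion
#'   \eqn{1/27 + 28 CV_T^2/81} instead (ignores \eqn{CV_T^4} and higher).
#' @return extrinsic noise \eqn{CV_E^2} (dimensionless).
#' @seealso \code{\link{extrinsic_noise_clock}},
#'   \code{\link{extrinsic_noise_lognormal}}
#' @export
extrinsic_noise <- function(cv2_T, third_moment_ratio, taylor = FALSE) {
  stopifnot(cv2_T >= 0)
  if (taylor) return(1 / 27 + 28 * cv2_T / 81)
  if (third_moment_ratio < 1) {
    stop("`third_moment_ratio` must be >= 1 (Jensen)")
  }
  1 / 27 + (4 / 27) *
    (9 * third_moment_ratio - 9 - 6 * cv2_T - 7 * cv2_T^2) /
    (3 + cv2_T)^2
}

#' @param m an \code{\link{erlang_mixture}}; its exact third moment is used.
#' @rdname extrinsic_noise
#' @export
extrinsic_noise_clock <- function(m) {
  tm <- as_timing_moments(m)
  extrinsic_noise(tm$cv2, tm$third_moment_ratio)
}

#' @rdname extrinsic_noise
#' @export
extrinsic_noise_lognormal <- function(cv2_T) {
  # lognormal cycle time: <T^3>/<T>^3 = (1 + CV_T^2)^3
  extrinsic_noise(cv2_T, (1 + cv2_T)^3)
}

#' Partitioning noise
#'
#' Contribution of molecule-partitioning errors at division to the protein
#' noise level.  Under the proportional variance law
#' \eqn{Var(x_+|x) = \alpha x/4},
#' \deqn{CV_R^2 = \frac{4\alpha}{3(3 + CV_T^2)}\,
#'   \frac{1}{\bar{\langle x\rangle}},}
#' which (at fixed mean) \emph{decreases} as division timing gets noisier:
#' maintaining the mean with noisier timing requires fewer molecules at
#' division, hence smaller partitioning errors.  Under the constant law
#' \eqn{Var(x_+|x) = \alpha} the contribution is
#' \eqn{4\alpha/(3 \bar{\langle x\rangle}^2)} and the timing dependence
#' disappears.
#'
#' @param p a \code{\link{partition_model}}.
#' @param cv2_T cycle-time CV^2 (>= 0).
#' @param mean_x steady-state mean protein level.
#' @return \eqn{CV_R^2}.
#' @export
partitioning_noise <- function(p, cv2_T, mean_x) {
  stopifnot(inherits(p, "partition_model"), mean_x > 0, cv2_T >= 0)
  switch(p$variance_law,
    proportional = 4 * p$alpha / (3 * (3 + cv2_T)) / mean_x,
    constant = 4 * p$alpha / 3 / mean_x^2
  )
}

#' Production noise
#'
#' Contribution of stochastic bursty synthesis:
#' \deqn{CV_P^2 = \frac{3 CV_T^2 + 5}{3(3 + CV_T^2)}\,
#'   \frac{\langle B^2\rangle}{\langle B\rangle}\,
#'   \frac{1}{\bar{\langle x\rangle}}.}
#' At fixed mean it \emph{increases} with timing noise, opposite to the
#' partitioning component.  For \eqn{B \equiv 1} and binomial partitioning
#' the two intrinsic terms always sum to \eqn{1/\bar{\langle x\rangle}}
#' whatever the cycle-time distribution.
#'
#' @param b a \code{\link{burst_model}}.
#' @inheritParams partitioning_noise
#' @return \eqn{CV_P^2}.
#' @export
production_noise <- function(b, cv2_T, mean_x) {
  stopifnot(inherits(b, "burst_model"), mean_x > 0, cv2_T >= 0)
  (3 * cv2_T + 5) / (3 * (3 + cv2_T)) *
    (b$burst_second_moment / b$burst_mean) / mean_x
}

#' Closed-form three-way noise decomposition (no duplication)
#'
#' Combines the mean formula with the extrinsic, partitioning and production
#' components; the total is their exact sum,
#' \eqn{CV^2 = CV_E^2 + CV_R^2 + CV_P^2}.
#'
#' @param b a \code{\link{burst_model}}.
#' @param clock an \code{\link{erlang_mixture}} cell-cycle clock (or a
#'   \code{timing_moments} object carrying the first three moments).
#' @param p a \code{\link{partition_model}} (proportional or constant law).
#' @return a \code{\link{noise_decomposition}}.
#' @examples
#' b <- burst_model(kx = 10, burst_mean = 1.5)        # geometric bursts
#' clk <- erlang_mixture_from_target(1, 0.05)          # Erlang-20 clock
#' decompose_noise(b, clk, partition_model(alpha = 1))
#' @export
decompose_noise <- function(b, clock, p) {
  tm <- as_timing_moments(clock)
  mx <- mean_protein(b, tm)
  noise_decomposition(
    mean_x = mx,
    cv2_ext = extrinsic_noise(tm$cv2, tm$third_moment_ratio),
    cv2_part = partitioning_noise(p, tm$cv2, mx),
    cv2_prod = production_noise(b, tm$cv2, mx)
  )
}

#' Mean protein level with gene duplication
#'
#' With a duplication schedule (phase \eqn{T_1} at rate \eqn{k_x}, then
#' phase \eqn{T_2} at rate \eqn{f k_x}) the steady-state mean is
#' \deqn{\bar{\langle x\rangle} =
#'  k_x\langle B\rangle\langle T_1\rangle
#'    \frac{2f(1-\beta) + 3\beta + \beta CV_{T1}^2}{2} +
#'  k_x\langle B\rangle\langle T_2\rangle
#'    \frac{3f(1-\beta) + 4\beta + f(1-\beta) CV_{T2}^2}{2}.}
#' At \eqn{\beta = 1} this reduces to the no-duplication mean; at
#' \eqn{\beta = 0} it equals \eqn{f} times that mean.  Early-duplicating
#' genes therefore carry more protein on average.
#'
#' @param b a \code{\link{burst_model}}.
#' @param d a \code{\link{duplication_schedule}}.
#' @return mean protein copy number.
#' @export
duplication_mean <- function(b, d) {
  stopifnot(inherits(d, "duplication_schedule"))
  duplication_mean_params(b, d$f, d$beta, d$mean_T, d$cv2_T1, d$cv2_T2)
}

#' @param f dosage factor >= 1.
#' @param beta mean duplication-time fraction in [0, 1].
#' @param mean_T mean cell-cycle duration.
#' @param cv2_T1,cv2_T2 phase-timing CVs (may be exactly 0, unlike a
#'   phase-type clock).
#' @rdname duplication_mean
#' @export
duplication_mean_params <- function(b, f, beta, mean_T = 1,
                                    cv2_T1 = 0, cv2_T2 = 0) {
  stopifnot(f >= 1, beta >= 0, beta <= 1, mean_T > 0)
  kb <- b$kx * b$burst_mean
  t1 <- beta * mean_T
  t2 <- (1 - beta) * mean_T
  kb * t1 * (2 * f * (1 - beta) + 3 * beta + beta * cv2_T1) / 2 +
    kb * t2 * (3 * f * (1 - beta) + 4 * beta +
                 f * (1 - beta) * cv2_T2) / 2
}

# shared denominator of the f = 2 intrinsic-noise closed form
dup_f2_denom <- function(beta, cv2_T1, cv2_T2) {
  3 * ((beta^2 - 4 * beta + 6) + beta^2 * cv2_T1 +
         2 * (1 - beta)^2 * cv2_T2)
}

#' Intrinsic noise components under f = 2 duplication
#'
#' Closed form for the partitioning and production components when the
#' burst arrival rate exactly doubles at duplication:
#' \deqn{CV_R^2 = \frac{4\alpha(2-\beta)}{D}\frac{1}{\bar{\langle x\rangle}},
#' \qquad
#' CV_P^2 = \frac{(10-8\beta+3\beta^2) + 6(1-\beta)^2 CV_{T2}^2
#'   + 3\beta^2 CV_{T1}^2}{D}
#'   \frac{\langle B^2\rangle}{\langle B\rangle}
#'   \frac{1}{\bar{\langle x\rangle}},}
#' with \eqn{D = 3[(\beta^2-4\beta+6) + \beta^2 CV_{T1}^2
#'   + 2(1-\beta)^2 CV_{T2}^2]}.  At \eqn{\beta \in \{0, 1\}} these reduce to
#' the no-duplication components.  For \eqn{B \equiv 1} and \eqn{\alpha = 1}
#' their sum is \eqn{1/\bar{\langle x\rangle}} for every \eqn{\beta} and any
#' phase CVs.  Dosage factors other than 2 have no closed form here; use
#' \code{\link{decompose_numeric}}.
#'
#' @param b a \code{\link{burst_model}}.
#' @param p a \code{\link{partition_model}} (proportional law).
#' @param beta mean duplication time as a fraction of the mean cycle, in
#'   [0, 1].
#' @param cv2_T1,cv2_T2 squared CVs of the two phase durations.
#' @param mean_x steady-state mean protein level.
#' @param f dosage factor; must equal 2 (other values go through the
#'   numeric moment-ODE path).
#' @return named vector \code{c(cv2_part, cv2_prod)}.
#' @export
duplication_intrinsic_f2 <- function(b, p, beta, cv2_T1, cv2_T2, mean_x,
                                     f = 2) {
  if (f != 2) {
    stop("closed form available for f = 2 only; use decompose_numeric() ",
         "for general dosage factors")
  }
  stopifnot(beta >= 0, beta <= 1, mean_x > 0)
  D <- dup_f2_denom(beta, cv2_T1, cv2_T2)
  cv2_part <- 4 * p$alpha * (2 - beta) / D / mean_x
  cv2_prod <- ((10 - 8 * beta + 3 * beta^2) +
                 6 * (1 - beta)^2 * cv2_T2 + 3 * beta^2 * cv2_T1) / D *
    (b$burst_second_moment / b$burst_mean) / mean_x
  c(cv2_part = cv2_part, cv2_prod = cv2_prod)
}

#' Deterministic-timing noise factors under f = 2 duplication
#'
#' In the high-precision timing limit (\eqn{CV_{T1}, CV_{T2} \to 0}) the
#' three components reduce to simple rational functions of \eqn{\beta}:
#' \deqn{CV_E^2 = \frac{4 - 3\beta^2(\beta-2)^2}{3(\beta^2-4\beta+6)^2},
#' \quad
#' CV_R^2 = \frac{4\alpha(2-\beta)}{3(\beta^2-4\beta+6)}
#'   \frac{1}{\bar{\langle x\rangle}},
#' \quad
#' CV_P^2 = \frac{10-8\beta+3\beta^2}{3(\beta^2-4\beta+6)}
#'   \frac{\langle B^2\rangle}{\langle B\rangle}
#'   \frac{1}{\bar{\langle x\rangle}}.}
#' \code{duplication_extrinsic_limit} returns the extrinsic term (it equals
#' 1/27 at \eqn{\beta \in \{0,1\}});
#' \code{duplication_prod_factor} and \code{duplication_part_factor} return
#' the dimensionless \eqn{\beta}-dependent factors of the intrinsic terms,
#' the quantities compared across \eqn{\beta} at fixed mean.
#'
#' @param beta duplication-time fraction in [0, 1]; vectorized.
#' @param cv2_T1,cv2_T2 optional phase-timing CVs (default 0, the
#'   deterministic-timing limit) for the intrinsic factors.
#' @return numeric vector of the same length as \code{beta}.
#' @export
duplication_extrinsic_limit <- function(beta) {
  stopifnot(all(beta >= 0 & beta <= 1))
  (4 - 3 * beta^2 * (beta - 2)^2) / (3 * (beta^2 - 4 * beta + 6)^2)
}

#' @rdname duplication_extrinsic_limit
#' @export
duplication_prod_factor <- function(beta, cv2_T1 = 0, cv2_T2 = 0) {
  ((10 - 8 * beta + 3 * beta^2) + 6 * (1 - beta)^2 * cv2_T2 +
     3 * beta^2 * cv2_T1) / dup_f2_denom(beta, cv2_T1, cv2_T2)
}

#' @rdname duplication_extrinsic_limit
#' @export
duplication_part_factor <- function(beta, cv2_T1 = 0, cv2_T2 = 0) {
  4 * (2 - beta) / dup_f2_denom(beta, cv2_T1, cv2_T2)
}

#' Locate the extremum of an intrinsic noise factor over beta
#'
#' At fixed mean (the transcription rate is rescaled as \eqn{\beta} moves),
#' the f = 2 production factor has a minimum and the partitioning factor a
#' maximum in \eqn{\beta}; when the two phase CVs are equal both extrema sit
#' at \eqn{\beta = 2 - \sqrt 2 \approx 0.59}.  The extremum is bracketed on
#' a dense grid (step \code{grid_step}) and refined by golden-section search
#' to tolerance \code{tol}.
#'
#' @param component \code{"production"} (minimum) or \code{"partitioning"}
#'   (maximum).
#' @param cv2_T1,cv2_T2 phase-timing CVs (default 0).
#' @param grid_step grid resolution for bracketing (default 1e-4).
#' @param tol refinement tolerance (default 1e-8).
#' @return list with \code{beta_opt}, \code{value_opt}, \code{value_at_0},
#'   and \code{rel_change} = value_opt/value_at_0 - 1.
#' @export
beta_optimum <- function(component = c("production", "partitioning"),
                         cv2_T1 = 0, cv2_T2 = 0,
                         grid_step = 1e-4, tol = 1e-8) {
  component <- match.arg(component)
  fn <- switch(component,
    production = function(beta) duplication_prod_factor(beta, cv2_T1, cv2_T2),
    partitioning = function(beta) duplication_part_factor(beta, cv2_T1, cv2_T2)
  )
  maximum <- component == "partitioning"
  grid <- seq(0, 1, by = grid_step)
  vals <- fn(grid)
  i <- if (maximum) which.max(vals) else which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- if (i == 1L || i == length(grid)) {
    list(par = grid[i], obj = vals[i])
  } else {
    o <- stats::optimize(fn, c(lo, hi), maximum = maximum, tol = tol)
    list(par = if (maximum) o$maximum else o$minimum, obj = o$objective)
  }
  v0 <- fn(0)
  list(beta_opt = opt$par, value_opt = opt$obj, value_at_0 = v0,
       rel_change = opt$obj / v0 - 1)
}

#' Noise decomposition for an unstable protein
#'
#' For a protein with turnover much faster than the cell cycle
#' (decay rate \eqn{\gamma_x}, \eqn{\gamma_x \langle T\rangle \gg 1}) the
#' level re-equilibrates essentially instantly after division and
#' duplication, so partitioning errors contribute nothing, while the
#' two-level dosage cycle contributes
#' \deqn{CV_E^2 = \frac{(1-\beta)\beta}{(2-\beta)^2},}
#' maximized at \eqn{\beta = 2/3} with value 1/8 (f = 2).  Production/decay
#' noise is \eqn{CV_P^2 = \frac{(\langle B^2\rangle/\langle B\rangle + 1)/2}
#' {\bar{\langle x\rangle}}} with
#' \eqn{\bar{\langle x\rangle} = k_x\langle B\rangle(2-\beta)/\gamma_x}; its
#' Fano factor is independent of \eqn{\beta}.
#'
#' @param b a \code{\link{burst_model}}.
#' @param beta duplication-time fraction in [0, 1].
#' @param gamma_x positive protein decay rate (time^-1); the fast-turnover
#'   regime \eqn{\gamma_x \langle T\rangle \gg 1} is assumed.
#' @return a \code{\link{noise_decomposition}} (with \code{cv2_part = 0}).
#' @export
unstable_noise <- function(b, beta, gamma_x) {
  stopifnot(beta >= 0, beta <= 1, gamma_x > 0)
  mx <- b$kx * b$burst_mean * (2 - beta) / gamma_x
  noise_decomposition(
    mean_x = mx,
    cv2_ext = (1 - beta) * beta / (2 - beta)^2,
    cv2_part = 0,
    cv2_prod = ((b$burst_second_moment / b$burst_mean + 1) / 2) / mx
  )
}

#' Stage-conditioned moments for synchronized cells
#'
#' For a pure Erlang clock of order \eqn{n} (cells progressing through
#' \eqn{n} cycle stages), the moments conditioned on residing in stage
#' \eqn{j} are available in closed form:
#' \deqn{\bar{\langle x | g_{nj}=1\rangle} =
#'   k_x\langle B\rangle\langle T\rangle (1 + j/n),}
#' \deqn{CV^2 | g_{nj}=1 = \frac{n+3j}{3(n+j)^2}
#'  + \frac{2n\alpha}{3(n+j)}\frac{1}{\bar{\langle x|g_{nj}\rangle}}
#'  + \frac{n+3j}{3(n+j)}\frac{\langle B^2\rangle}{\langle B\rangle}
#'    \frac{1}{\bar{\langle x|g_{nj}\rangle}}.}
#' For large \eqn{n} the intrinsic prefactors at birth (\eqn{j=1}) are
#' \eqn{(2\alpha/3,\; \langle B^2\rangle/3\langle B\rangle)} and at division
#' (\eqn{j=n}) \eqn{(\alpha/3,\; 2\langle B^2\rangle/3\langle B\rangle)}:
#' comparing synchronized measurements at birth and division separates
#' \eqn{\alpha} from the burst moment ratio.
#'
#' @param n_stages Erlang order \eqn{n} of the cycle clock.
#' @param j cycle stage index, 1..n.
#' @param b a \code{\link{burst_model}}.
#' @param p a \code{\link{partition_model}} (proportional law).
#' @param mean_T mean cycle duration (default 1).
#' @return list with \code{cond_mean}, \code{cv2_ext}, \code{cv2_part},
#'   \code{cv2_prod}, \code{cv2_total}.
#' @export
synchronized_moments <- function(n_stages, j, b, p, mean_T = 1) {
  n <- n_stages
  if (any(j < 1) || any(j > n)) stop("stage index j must lie in 1..n")
  cm <- b$kx * b$burst_mean * mean_T * (1 + j / n)
  cv2_ext <- (n + 3 * j) / (3 * (n + j)^2)
  cv2_part <- 2 * n * p$alpha / (3 * (n + j)) / cm
  cv2_prod <- (n + 3 * j) / (3 * (n + j)) *
    (b$burst_second_moment / b$burst_mean) / cm
  list(cond_mean = cm, cv2_ext = cv2_ext, cv2_part = cv2_part,
       cv2_prod = cv2_prod, cv2_total = cv2_ext + cv2_part + cv2_prod)
}
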