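#' Phase-type cell-cycle clock: mixture of Erlang distributions
#'
#' The cell-cycle (or duplication-phase) time is modeled as a mixture of
#' Erlang distributions: with probability \code{probs[i]} the time is the sum
#' of \code{orders[i]} i.i.d. exponential stages, each with rate
#' \code{orders[i] * rate_scale}.  This phase-type class is dense in the set
#' of positively-valued distributions with coefficient of variation at most
#' one, and admits an exact continuous-time Markov-chain representation with
#' stages \eqn{G_{ij}}.
#'
#' With this stage-rate convention the mean is \code{1/rate_scale} regardless
#' of the mixing probabilities, the squared coefficient of variation is
#' \eqn{CV_T^2 = \sum_i p_i / i}, and the skewness is \eqn{2 \sum_i p_i/i^2}.
#'
#' @param orders integer vector of Erlang shape parameters (strictly
#'   increasing, all >= 1).
#' @param probs probability vector aligned with \code{orders}; must sum to 1.
#' @param rate_scale positive rate \eqn{k} (time^-1); stage \eqn{G_{ij}} has
#'   exit rate \eqn{i k} so that the mixture mean is \eqn{1/k}.
#' @return an object of class \code{erlang_mixture} with fields
#'   \code{orders}, \code{probs}, \code{rate_scale}.
#' @examples
#' clk <- erlang_mixture(orders = c(3, 4), probs = c(0.6, 0.4), rate_scale = 1)
#' timing_moments(clk)
#' @export
erlang_mixture <- function(orders, probs, rate_scale = 1) {
  if (length(orders) == 0L) stop("empty Erlang mixture")
  if (length(orders) != length(probs)) {
    stop("`orders` and `probs` must have the same length")
  }
  orders <- as.integer(orders)
  if (any(orders < 1L)) stop("Erlang orders must be >= 1")
  if (is.unsorted(orders, strictly = TRUE)) {
    stop("Erlang orders must be strictly increasing")
  }
  if (any(probs < 0)) stop("mixing probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("mixing probabilities must sum to 1 (within 1e-12)")
  }
  if (!is.finite(rate_scale) || rate_scale <= 0) {
    stop("`rate_scale` must be a positive rate")
  }
  structure(
    list(orders = orders, probs = as.numeric(probs),
         rate_scale = as.numeric(rate_scale)),
    class = "erlang_mixture"
  )
}

#' @export
print.erlang_mixture <- function(x, ...) {
  cat("Erlang mixture clock (phase-type)\n")
  cat("  orders:", paste(x$orders, collapse = ", "), "\n")
  cat("  probs: ", paste(signif(x$probs, 6), collapse = ", "), "\n")
  cat("  rate scale k:", x$rate_scale,
      " (mean =", format(1 / x$rate_scale), ")\n")
  m <- timing_moments(x)
  cat("  CV^2 =", format(m$cv2), "  skewness coef =", format(m$skewness), "\n")
  invisible(x)
}

#' Construct an Erlang-mixture clock matching a target mean and CV^2
#'
#' Builds the minimal-state phase-type clock with the requested first two
#' moments.  If \code{1/cv2_T} is an integer \eqn{m} the pure Erlang of order
#' \eqn{m} is returned; otherwise the two-component mixture of the adjacent
#' orders \eqn{m = \lfloor 1/cv2_T \rfloor} and \eqn{m+1} is used, with the
#' mixing probability solving \eqn{p/m + (1-p)/(m+1) = cv2_T}.  Phase-type
#' clocks cannot represent CV^2 = 0 (a delta distribution) exactly; a request
#' with \code{cv2_T = 0} is mapped to a pure Erlang of order \code{n_det}
#' with a warning.
#'
#' @param mean_T positive target mean cycle time.
#' @param cv2_T target squared coefficient of variation, in (0, 1].
#' @param n_det Erlang order standing in for deterministic timing when
#'   \code{cv2_T = 0} (default 200, i.e. CV^2 = 0.005).
#' @return an \code{\link{erlang_mixture}} whose mean is \code{mean_T}
#'   exactly and whose CV^2 is \code{cv2_T} exactly (when \code{cv2_T > 0}).
#' @examples
#' erlang_mixture_from_target(1, 0.3)   # orders {3, 4}, p = c(0.6, 0.4)
#' @export
erlang_mixture_from_target <- function(mean_T, cv2_T, n_det = 200L) {
  if (!is.finite(mean_T) || mean_T <= 0) stop("`mean_T` must be positive")
  if (!is.finite(cv2_T) || cv2_T < 0 || cv2_T > 1) {
    stop("`cv2_T` must lie in (0, 1]: a phase-type (Erlang-mixture) clock ",
         "cannot have CV^2 above 1")
  }
  k <- 1 / mean_T
  if (cv2_T == 0) {
    warning("cv2_T = 0 (delta-distributed timing) is not representable ",
            "exactly by a phase-type clock; using a pure Erlang of order ",
            n_det)
    return(erlang_mixture(n_det, 1, rate_scale = k))
  }
  m_exact <- 1 / cv2_T
  m <- floor(m_exact + 1e-9)
  if (abs(m_exact - m) < 1e-9) {
    return(erlang_mixture(as.integer(m), 1, rate_scale = k))
  }
  # p/m + (1 - p)/(m + 1) = cv2_T
  p <- (cv2_T - 1 / (m + 1)) / (1 / m - 1 / (m + 1))
  erlang_mixture(c(m, m + 1L), c(p, 1 - p), rate_scale = k)
}

#' Exact moments of an Erlang-mixture clock
#'
#' Closed-form mean, squared coefficient of variation, skewness, and
#' normalized third moment of the phase-type cell-cycle time.  The third
#' moment obeys
#' \deqn{\langle T^3 \rangle / \langle T \rangle^3 =
#'   1 + 3 CV_T^2 + 2 \sum_i p_i / i^2,}
#' so increasing CV_T^2 necessarily makes the distribution more positively
#' skewed: long cell cycles become more probable.
#'
#' @param m an \code{\link{erlang_mixture}}.
#' @return a list of class \code{timing_moments} with fields \code{mean},
#'   \code{cv2}, \code{skewness} (the coefficient \eqn{2\sum p_i/i^2}) and
#'   \code{third_moment_ratio} (\eqn{\langle T^3\rangle/\langle T\rangle^3}).
#' @export
timing_moments <- function(m) {
  stopifnot(inherits(m, "erlang_mixture"))
  cv2 <- sum(m$probs / m$orders)
  skew <- 2 * sum(m$probs / m$orders^2)
  structure(
    list(mean = 1 / m$rate_scale,
         cv2 = cv2,
         skewness = skew,
         third_moment_ratio = 1 + 3 * cv2 + skew),
    class = "timing_moments"
  )
}

#' Bundle externally-supplied timing moments
#'
#' For analytics that only need the first three moments of the cycle time
#' (e.g. a lognormally-distributed cycle, which is not phase-type), moments
#' can be supplied directly rather than through an Erlang mixture.
#'
#' @param mean positive mean cycle time.
#' @param cv2 squared coefficient of variation (>= 0).
#' @param third_moment_ratio \eqn{\langle T^3\rangle/\langle T\rangle^3};
#'   defaults to the small-fluctuation Taylor value \code{1 + 3 * cv2}.
#' @return a \code{timing_moments} object.
#' @export
timing_moments_manual <- function(mean, cv2,
                                  third_moment_ratio = 1 + 3 * cv2) {
  stopifnot(mean > 0, cv2 >= 0, third_moment_ratio >= 1)
  structure(
    list(mean = mean, cv2 = cv2,
         skewness = third_moment_ratio - 1 - 3 * cv2,
         third_moment_ratio = third_moment_ratio),
    class = "timing_moments"
  )
}

#' Sample cell-cycle times from an Erlang-mixture clock
#'
#' Realizes the stage chain: each draw picks an Erlang order \eqn{i} with
#' probability \eqn{p_i} and sums \eqn{i} exponentials of rate
#' \eqn{i k}.
#'
#' @param m an \code{\link{erlang_mixture}}.
#' @param n_draws number of i.i.d. cycle times to draw.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of positive times.
#' @export
sample_times <- function(m, n_draws, seed = NULL) {
  stopifnot(inherits(m, "erlang_mixture"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(m$orders), n_draws, replace = TRUE,
                    prob = m$probs)
  ord <- m$orders[idx]
  # sum of i exponentials of rate i*k == Gamma(shape = i, rate = i*k)
  stats::rgamma(n_draws, shape = ord, rate = ord * m$rate_scale)
}

#' Serialize / deserialize an Erlang mixture as JSON
#'
#' The JSON form \code{{"orders": [...], "probs": [...], "rate_scale": k}} is
#' accepted anywhere a timing distribution is required in run configurations.
#'
#' @param m an \code{\link{erlang_mixture}}.
#' @return \code{erlang_mixture_to_json}: a JSON string;
#'   \code{erlang_mixture_from_list}: an \code{erlang_mixture}.
#' @export
erlang_mixture_to_json <- function(m) {
  stopifnot(inherits(m, "erlang_mixture"))
  jsonlite::toJSON(list(orders = m$orders, probs = m$probs,
                        rate_scale = m$rate_scale),
                   auto_unbox = TRUE, digits = NA)
}

#' @param x a list (parsed JSON/YAML) with fields \code{orders},
#'   \code{probs}, \code{rate_scale}, or the target form
#'   \code{mean}/\code{cv2}.
#' @rdname erlang_mixture_to_json
#' @export
erlang_mixture_from_list <- function(x) {
  if (inherits(x, "erlang_mixture")) return(x)
  if (is.character(x) && length(x) == 1L) x <- jsonlite::fromJSON(x)
  if (!is.null(x$orders)) {
    erlang_mixture(unlist(x$orders), unlist(x$probs),
                   rate_scale = x$rate_scale %||% 1)
  } else if (!is.null(x$mean) && !is.null(x$cv2)) {
    erlang_mixture_from_target(x$mean, x$cv2)
  } else {
    stop("timing spec needs either orders/probs/rate_scale or mean/cv2")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
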