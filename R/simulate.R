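#' Draw a daughter-cell allotment at division
#'
#' Samples the number of molecules inherited by the followed daughter,
#' matching the partitioning law's first two conditional moments: mean
#' \eqn{x/2}, variance \eqn{\alpha x / 4} (proportional law).  The sampling
#' scheme depends on the regime:
#' \itemize{
#'   \item \eqn{\alpha = 0}: deterministic halving (a fair coin decides the
#'     odd molecule, adding variance 1/4 which vanishes in relative terms);
#'   \item \eqn{0 < \alpha \le 1}: with probability \eqn{\alpha} a
#'     Binomial(x, 1/2) draw, otherwise the deterministic split;
#'   \item \eqn{\alpha > 1}: beta-binomial with intra-class correlation
#'     \eqn{\rho = (\alpha-1)/(x-1)}, which matches the variance exactly for
#'     \eqn{2 \le \alpha < x} (binomial fallback below that).
#' }
#' Only the first two conditional moments are specified by the partitioning
#' framework, so any distribution matching them is admissible.
#'
#' @param x non-negative integer mother-cell copy number (vectorized over
#'   \code{n} draws from the same \code{x}).
#' @param p a \code{\link{partition_model}} with the proportional law.
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @return integer vector of length \code{n}, each in \code{0..x}.
#' @export
sample_partition <- function(x, p, n = 1, seed = NULL) {
  stopifnot(inherits(p, "partition_model"), x >= 0, x == round(x))
  if (p$variance_law != "proportional") {
    stop("discrete partition sampling is defined for the proportional ",
         "variance law only; the constant law applies to the continuous ",
         "hybrid models")
  }
  if (!is.null(seed)) set.seed(seed)
  alpha <- p$alpha
  if (x == 0) return(integer(n))
  half <- function(m) {
    h <- rep(x %/% 2, m)
    if (x %% 2 == 1) h <- h + (stats::runif(m) < 0.5)
    as.integer(h)
  }
  if (alpha == 0) return(half(n))
  if (alpha <= 1) {
    use_bin <- stats::runif(n) < alpha
    out <- integer(n)
    out[use_bin] <- stats::rbinom(sum(use_bin), x, 0.5)
    out[!use_bin] <- half(sum(!use_bin))
    return(out)
  }
  if (x < 2 || alpha >= x) return(stats::rbinom(n, x, 0.5))
  a <- (x - alpha) / (2 * (alpha - 1))
  as.integer(stats::rbinom(n, x, stats::rbeta(n, a, a)))
}

sim_mode <- function(flags) {
  if (flags$include_burst_noise) 0L
  else if (flags$include_partition_noise) 2L
  else 1L
}

#' Simulate a single-cell lineage exactly
#'
#' Event-driven simulation of the full or hybrid models along one line of
#' descent: competing exponential clocks for bursts (rate \eqn{k_x}, or
#' \eqn{f k_x} after duplication), cell-cycle stage transitions (rate
#' \eqn{i k} in a branch of order \eqn{i}) and decay events (rate
#' \eqn{\gamma_x x}, full model only).  Bursts add a draw from the burst
#' distribution; division applies \code{\link{sample_partition}} (or its
#' continuous counterpart in hybrid C, or exact halving in hybrid B) and
#' restarts the stage chain.  One daughter is followed; under symmetric
#' partitioning the choice is statistically irrelevant and is made
#' uniformly.  In the hybrid modes protein accumulates deterministically at
#' rate \eqn{k_x\langle B\rangle} (times \eqn{f} after duplication) between
#' events.
#'
#' @param clock an \code{\link{erlang_mixture}} cell-cycle clock (ignored
#'   when \code{flags$duplication} is present).
#' @param b a \code{\link{burst_model}}.
#' @param p a \code{\link{partition_model}}.
#' @param flags a \code{\link{model_flags}} selecting the variant.
#' @param n_cycles number of cell cycles (division events) to simulate.
#' @param seed optional integer seed; identical seeds give identical traces.
#' @param x0 initial protein level (default 0).
#' @return object of class \code{lineage_trace}: list with the event
#'   \code{trace} (data.frame: \code{t}, \code{x}, \code{phase},
#'   \code{branch}, \code{step}, \code{event}), the accumulation
#'   \code{slope} per phase (0 for the full model), and the call
#'   parameters.  Event codes: 0 init, 1 burst, 2 stage, 3 duplication,
#'   4 division, 5 decay.
#' @export
simulate_lineage <- function(clock = NULL, b, p, flags = model_flags(),
                             n_cycles, seed = NULL, x0 = 0) {
  stopifnot(inherits(b, "burst_model"), inherits(p, "partition_model"),
            inherits(flags, "model_flags"), n_cycles >= 1)
  mode <- sim_mode(flags)
  if (mode == 0L && b$burst_family == "custom") {
    stop("the full model needs a sampleable burst family ",
         "(geometric0, geometric1 or point_mass)")
  }
  if (mode == 0L && p$variance_law == "constant") {
    stop("the constant partition-variance law has no discrete counterpart; ",
         "it is supported in the hybrid (continuous) modes only")
  }
  gam <- flags$degradation %||% 0
  if (mode != 0L && gam > 0) {
    stop("degradation in the hybrid modes is handled by the moment-ODE ",
         "engine; the event-driven simulator supports decay in the full ",
         "model only")
  }
  if (is.null(flags$duplication)) {
    stopifnot(inherits(clock, "erlang_mixture"))
    o1 <- clock$orders; p1 <- clock$probs; k1 <- clock$rate_scale
    o2 <- integer(0); p2 <- numeric(0); k2 <- 0; f <- 1
  } else {
    d <- flags$duplication
    o1 <- d$t1_clock$orders; p1 <- d$t1_clock$probs
    k1 <- d$t1_clock$rate_scale
    o2 <- d$t2_clock$orders; p2 <- d$t2_clock$probs
    k2 <- d$t2_clock$rate_scale
    f <- d$f
  }
  if (!is.null(seed)) set.seed(seed)
  fam <- match(b$burst_family, c("geometric0", "geometric1", "point_mass")) - 1L
  raw <- sim_lineage_cpp(o1, p1, k1, o2, p2, k2, f,
                         b$kx, b$burst_mean, fam, b$burst_mean,
                         p$alpha, as.integer(p$variance_law == "constant"),
                         mode, gam, as.integer(n_cycles), x0)
  trace <- data.frame(t = raw$t, x = raw$x, phase = as.integer(raw$phase),
                      branch = as.integer(raw$branch),
                      step = as.integer(raw$step),
                      event = as.integer(raw$event))
  structure(
    list(trace = trace, mode = mode,
         slope = if (mode == 0L) c(0, 0) else b$kx * b$burst_mean * c(1, f),
         n_cycles = n_cycles, burst = b, partition = p, flags = flags,
         seed = seed),
    class = "lineage_trace"
  )
}

#' @export
print.lineage_trace <- function(x, ...) {
  tr <- x$trace
  cat("Lineage trace:", nrow(tr), "events,",
      sum(tr$event == 4L), "divisions,",
      sum(tr$event == 3L), "duplications; mode",
      c("full", "hybrid B", "hybrid C")[x$mode + 1], "\n")
  invisible(x)
}

#' Division and duplication event times of a trace
#' @param trace a \code{\link{simulate_lineage}} result.
#' @return numeric vector of event times.
#' @export
division_times <- function(trace) {
  trace$trace$t[trace$trace$event == 4L]
}

#' @rdname division_times
#' @export
duplication_times <- function(trace) {
  trace$trace$t[trace$trace$event == 3L]
}

# per-epoch time integrals of x and x^2 (piecewise constant in the full
# model, piecewise linear in the hybrids)
epoch_integrals <- function(trace) {
  tr <- trace$trace
  n <- nrow(tr)
  dt <- diff(tr$t)
  xs <- tr$x[-n]
  s <- trace$slope[tr$phase[-n]]
  list(
    dt = dt,
    i1 = dt * (xs + s * dt / 2),
    i2 = dt * (xs^2 + xs * s * dt + s^2 * dt^2 / 3),
    cycle = cumsum(tr$event == 4L)[-n]  # 0-based cycle index per epoch
  )
}

#' Steady-state moment estimates from a lineage trace
#'
#' Time-weighted mean and CV^2 of the protein level over the post-burn-in
#' portion of a lineage, realizing the stationary lineage expectations by
#' long-run time averaging.  Standard errors come from non-overlapping
#' batch means over whole cell cycles.
#'
#' @param trace a \code{\link{simulate_lineage}} result.
#' @param burn_in_cycles cycles discarded before averaging (default 50).
#' @param n_batches number of batches for the standard errors (default 20;
#'   at least 3 are required).
#' @return object of class \code{moment_estimate}: list with \code{mean},
#'   \code{cv2}, \code{se_mean}, \code{se_cv2}, \code{n_effective}.
#' @export
lineage_moments <- function(trace, burn_in_cycles = 50, n_batches = 20) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (n_batches < 3) stop("need at least 3 batches for standard errors")
  ei <- epoch_integrals(trace)
  keep <- ei$cycle >= burn_in_cycles
  if (!any(keep)) {
    stop("trace shorter than burn-in: simulate more cycles or lower ",
         "`burn_in_cycles`")
  }
  cyc <- ei$cycle[keep]
  ncyc <- max(cyc) - burn_in_cycles + 1L
  if (ncyc < n_batches) {
    stop("fewer post-burn-in cycles (", ncyc, ") than batches (",
         n_batches, "); simulate more cycles")
  }
  batch <- pmin(((cyc - burn_in_cycles) * n_batches) %/% ncyc, n_batches - 1L)
  tb <- rowsum(ei$dt[keep], batch)
  m1b <- rowsum(ei$i1[keep], batch) / tb
  m2b <- rowsum(ei$i2[keep], batch) / tb
  cv2b <- m2b / m1b^2 - 1
  mean_hat <- sum(ei$i1[keep]) / sum(ei$dt[keep])
  m2_hat <- sum(ei$i2[keep]) / sum(ei$dt[keep])
  nb <- length(tb)
  structure(
    list(mean = mean_hat,
         cv2 = m2_hat / mean_hat^2 - 1,
         se_mean = stats::sd(m1b) / sqrt(nb),
         se_cv2 = stats::sd(cv2b) / sqrt(nb),
         n_effective = nb),
    class = "moment_estimate"
  )
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat(sprintf("mean = %.6g (se %.3g); CV^2 = %.6g (se %.3g); %d batches\n",
              x$mean, x$se_mean, x$cv2, x$se_cv2, x$n_effective))
  invisible(x)
}

#' Sample protein levels conditioned on a cell-cycle stage
#'
#' For a pure Erlang clock of order \eqn{n} (so the chain's stage index is a
#' meaningful cell-cycle coordinate), samples the protein level at times
#' drawn uniformly over the total post-burn-in time the chain spends in
#' stage \eqn{j}, emulating a synchronized-cell snapshot.  Uniformity over
#' occupancy time (rather than one draw per cycle) is what realizes the
#' stationary stage-conditioned distribution: per-cycle draws would
#' over-weight short stage sojourns.  With one draw per cycle on average the
#' samples are effectively independent.
#'
#' @param clock a pure Erlang \code{\link{erlang_mixture}} (single order).
#' @param j stage index in 1..n.
#' @param b,p,flags model components as in \code{\link{simulate_lineage}}
#'   (no duplication).
#' @param n_cells number of post-burn-in draws.
#' @param seed optional integer seed.
#' @param burn_in_cycles cycles discarded before sampling (default 50).
#' @return numeric vector of \code{n_cells} protein levels.
#' @export
synchronized_sample <- function(clock, j, b, p, flags = model_flags(),
                                n_cells, seed = NULL,
                                burn_in_cycles = 50) {
  stopifnot(inherits(clock, "erlang_mixture"))
  if (length(clock$orders) != 1L) {
    stop("synchronized sampling needs a pure Erlang clock")
  }
  if (!is.null(flags$duplication)) {
    stop("synchronized sampling is defined for the no-duplication model")
  }
  n <- clock$orders[1]
  if (j < 1 || j > n) stop("stage index j must lie in 1..", n)
  tr <- simulate_lineage(clock, b, p, flags,
                         n_cycles = burn_in_cycles + n_cells, seed = seed)
  d <- tr$trace
  ndat <- nrow(d)
  dt <- diff(d$t)
  cyc <- cumsum(d$event == 4L)[-ndat]
  sel <- which(d$step[-ndat] == j & cyc >= burn_in_cycles & dt > 0)
  cs <- cumsum(dt[sel])
  u <- stats::runif(n_cells, 0, cs[length(cs)])
  e <- findInterval(u, c(0, cs), rightmost.closed = TRUE)
  off <- u - c(0, cs)[e]
  d$x[sel[e]] + tr$slope[d$phase[sel[e]]] * off
}
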