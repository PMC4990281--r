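#' Model variant flags for the moment system and simulator
#'
#' Selects which noise mechanisms are active.  The full model has bursty
#' (discrete) production and noisy partitioning; the hybrid models replace
#' production by deterministic accumulation and optionally remove
#' partitioning errors, which is what makes the three-way noise
#' decomposition possible:
#' \itemize{
#'   \item hybrid B: \code{include_burst_noise = FALSE},
#'     \code{include_partition_noise = FALSE} — division timing is the only
#'     noise source (extrinsic).
#'   \item hybrid C: partitioning noise only
#'     (\code{include_burst_noise = FALSE}).
#'   \item full: both \code{TRUE}.
#' }
#'
#' @param include_burst_noise logical; discrete bursts with second moment
#'   \eqn{\langle B^2\rangle} (otherwise deterministic accumulation at rate
#'   \eqn{k_x \langle B\rangle}).
#' @param include_partition_noise logical; random partitioning at division
#'   (otherwise exact halving).
#' @param duplication optional \code{\link{duplication_schedule}}.
#' @param degradation optional protein decay rate \eqn{\gamma_x} (time^-1).
#' @return object of class \code{model_flags}.
#' @export
model_flags <- function(include_burst_noise = TRUE,
                        include_partition_noise = TRUE,
                        duplication = NULL, degradation = NULL) {
  if (!is.null(duplication)) {
    stopifnot(inherits(duplication, "duplication_schedule"))
  }
  if (!is.null(degradation)) stopifnot(degradation > 0)
  structure(
    list(include_burst_noise = isTRUE(include_burst_noise),
         include_partition_noise = isTRUE(include_partition_noise),
         duplication = duplication, degradation = degradation),
    class = "model_flags"
  )
}

# Stage table for the (possibly two-phase) Markov chain.  One row per stage
# G_ij; columns: phase, branch (Erlang order), step, exit_rate, kx_mult,
# terminal ("dup" feeds the duplication transition, "div" the division).
stage_table <- function(clock, flags) {
  one_phase <- function(m, phase, kx_mult) {
    do.call(rbind, lapply(seq_along(m$orders), function(ii) {
      i <- m$orders[ii]
      data.frame(phase = phase, branch = i, step = seq_len(i),
                 exit_rate = i * m$rate_scale, kx_mult = kx_mult,
                 entry_prob = c(m$probs[ii], rep(0, i - 1L)))
    }))
  }
  if (is.null(flags$duplication)) {
    st <- one_phase(clock, 1L, 1)
    st$terminal <- ifelse(st$step == st$branch, "div", "none")
  } else {
    d <- flags$duplication
    st <- rbind(one_phase(d$t1_clock, 1L, 1),
                one_phase(d$t2_clock, 2L, d$f))
    st$terminal <- ifelse(st$step == st$branch,
                          ifelse(st$phase == 1L, "dup", "div"), "none")
  }
  st
}

#' Assemble the closed linear moment system
#'
#' Builds the exact (automatically closed) linear ODE system for the stage
#' occupancies \eqn{\langle g_{ij}\rangle}, conditional first moments
#' \eqn{\langle x g_{ij}\rangle} and second moments
#' \eqn{\langle x^2 g_{ij}\rangle}.  Because the stage indicators are
#' binary, no moment-closure approximation is needed: the system is closed
#' exactly and \eqn{dm/dt = A m} reproduces the master-equation moment
#' dynamics term by term.  Division transitions carry coefficient 1/2 on the
#' first moment and 1/4 on the second, plus \eqn{\alpha/4} coupling to the
#' first moment when partitioning noise is on; a duplication transition
#' leaves the protein level untouched but raises the burst rate to
#' \eqn{f k_x}.
#'
#' The state ordering is: occupancy block, first-moment block, second-moment
#' block; within each block stages are sorted phase-major by (branch, step),
#' so the matrix is inspectable.
#'
#' @param clock an \code{\link{erlang_mixture}} cell-cycle clock (ignored if
#'   \code{flags$duplication} supplies the two phase clocks).
#' @param b a \code{\link{burst_model}}.
#' @param p a \code{\link{partition_model}}.
#' @param flags a \code{\link{model_flags}}.
#' @return object of class \code{moment_system}: list with the generator
#'   \code{A}, constant offset \code{c} (identically zero for these models,
#'   kept for interface stability), the stage table \code{stages}, and
#'   \code{n_stages}.
#' @export
build_moment_system <- function(clock, b, p, flags = model_flags()) {
  stopifnot(inherits(b, "burst_model"), inherits(p, "partition_model"),
            inherits(flags, "model_flags"))
  if (is.null(flags$duplication)) stopifnot(inherits(clock, "erlang_mixture"))
  st <- stage_table(clock, flags)
  S <- nrow(st)
  A <- matrix(0, 3 * S, 3 * S)
  O <- seq_len(S); Fst <- S + O; Snd <- 2 * S + O

  kx_s <- b$kx * st$kx_mult
  kB <- kx_s * b$burst_mean
  kB2 <- kx_s * b$burst_second_moment
  alpha <- p$alpha
  use_part <- flags$include_partition_noise
  use_burst <- flags$include_burst_noise
  gam <- flags$degradation %||% 0

  # entry stages of each phase (division re-enters phase 1, duplication
  # enters phase 2; with a single phase division re-enters phase 1)
  entries <- function(phase) which(st$phase == phase & st$entry_prob > 0)
  div_entries <- entries(1L)
  dup_entries <- entries(2L)

  for (s in seq_len(S)) {
    r <- st$exit_rate[s]
    # production
    A[Fst[s], O[s]] <- A[Fst[s], O[s]] + kB[s]
    A[Snd[s], Fst[s]] <- A[Snd[s], Fst[s]] + 2 * kB[s]
    if (use_burst) A[Snd[s], O[s]] <- A[Snd[s], O[s]] + kB2[s]
    # degradation (discrete decay events in the full model contribute the
    # +gamma <x g> jump term; deterministic decay in the hybrids does not)
    if (gam > 0) {
      A[Fst[s], Fst[s]] <- A[Fst[s], Fst[s]] - gam
      A[Snd[s], Snd[s]] <- A[Snd[s], Snd[s]] - 2 * gam
      if (use_burst) A[Snd[s], Fst[s]] <- A[Snd[s], Fst[s]] + gam
    }
    # stage exit
    A[O[s], O[s]] <- A[O[s], O[s]] - r
    A[Fst[s], Fst[s]] <- A[Fst[s], Fst[s]] - r
    A[Snd[s], Snd[s]] <- A[Snd[s], Snd[s]] - r
    if (st$terminal[s] == "none") {
      nxt <- s + 1L  # next step of the same branch (rows are step-ordered)
      A[O[nxt], O[s]] <- A[O[nxt], O[s]] + r
      A[Fst[nxt], Fst[s]] <- A[Fst[nxt], Fst[s]] + r
      A[Snd[nxt], Snd[s]] <- A[Snd[nxt], Snd[s]] + r
    } else if (st$terminal[s] == "dup") {
      for (e in dup_entries) {
        pr <- st$entry_prob[e] * r
        A[O[e], O[s]] <- A[O[e], O[s]] + pr
        A[Fst[e], Fst[s]] <- A[Fst[e], Fst[s]] + pr
        A[Snd[e], Snd[s]] <- A[Snd[e], Snd[s]] + pr
      }
    } else {  # division
      for (e in div_entries) {
        pr <- st$entry_prob[e] * r
        A[O[e], O[s]] <- A[O[e], O[s]] + pr
        A[Fst[e], Fst[s]] <- A[Fst[e], Fst[s]] + pr / 2
        A[Snd[e], Snd[s]] <- A[Snd[e], Snd[s]] + pr / 4
        if (use_part) {
          if (p$variance_law == "proportional") {
            A[Snd[e], Fst[s]] <- A[Snd[e], Fst[s]] + pr * alpha / 4
          } else {
            A[Snd[e], O[s]] <- A[Snd[e], O[s]] + pr * alpha
          }
        }
      }
    }
  }
  structure(
    list(A = A, c = rep(0, 3 * S), stages = st, n_stages = S),
    class = "moment_system"
  )
}

#' @export
print.moment_system <- function(x, ...) {
  cat("Moment system:", x$n_stages, "stages,",
      nrow(x$A), "coupled linear ODEs\n")
  invisible(x)
}

#' Exact steady-state moments by direct linear solve
#'
#' Solves the stationary moment equations block by block: the occupancy
#' balance (with one redundant row replaced by the normalization
#' \eqn{\sum \langle g_{ij}\rangle = 1}), then the first-moment and
#' second-moment blocks.  This is exact (up to linear-algebra roundoff) and
#' avoids long-time integration.
#'
#' @param system a \code{\link{build_moment_system}} result.
#' @return object of class \code{stage_moments}: the stage table plus
#'   \code{occupancy}, \code{first}, \code{second} vectors and aggregate
#'   \code{mean_x}, \code{second_x}, \code{cv2}.
#' @export
steady_state_moments <- function(system) {
  stopifnot(inherits(system, "moment_system"))
  S <- system$n_stages
  O <- seq_len(S); Fst <- S + O; Snd <- 2 * S + O
  A <- system$A

  Aocc <- A[O, O, drop = FALSE]
  Aocc[1, ] <- 1  # replace a redundant balance row by the normalization
  rhs <- c(1, rep(0, S - 1))
  occ <- tryCatch(solve(Aocc, rhs), error = function(e) {
    stop("singular occupancy system (condition number ",
         format(kappa(Aocc)), "): ", conditionMessage(e))
  })

  x1 <- solve(A[Fst, Fst, drop = FALSE], -A[Fst, O, drop = FALSE] %*% occ)
  x2 <- solve(A[Snd, Snd, drop = FALSE],
              -(A[Snd, O, drop = FALSE] %*% occ +
                  A[Snd, Fst, drop = FALSE] %*% x1))
  mean_x <- sum(x1)
  second_x <- sum(x2)
  structure(
    list(stages = system$stages, occupancy = as.numeric(occ),
         first = as.numeric(x1), second = as.numeric(x2),
         mean_x = mean_x, second_x = second_x,
         cv2 = second_x / mean_x^2 - 1),
    class = "stage_moments"
  )
}

#' @export
print.stage_moments <- function(x, ...) {
  cat("Steady-state stage moments (", nrow(x$stages), "stages )\n")
  cat("  <x> =", format(x$mean_x), "  <x^2> =", format(x$second_x),
      "  CV^2 =", format(x$cv2), "\n")
  invisible(x)
}

#' Transient moment trajectories
#'
#' Integrates \eqn{dm/dt = A m} with a stiff-capable implicit scheme
#' (\code{deSolve::lsoda} with the exact constant Jacobian) at relative
#' tolerance 1e-10; large Erlang orders make the linear system stiff.
#'
#' @param system a \code{\link{build_moment_system}} result.
#' @param initial initial state: either a full numeric vector of length
#'   \code{3 * n_stages} (occupancy, first, second blocks), a
#'   \code{stage_moments} object, or \code{NULL} for "newborn lineage with
#'   no protein" (occupancy on the phase-1 entry stages, x = 0).
#' @param horizon final time.
#' @param n_points number of equally spaced output times.
#' @return data.frame with columns \code{time}, \code{mean_x},
#'   \code{second_x}, \code{occ_total}, plus the full state matrix as
#'   attribute \code{"states"}.
#' @export
transient_moments <- function(system, initial = NULL, horizon,
                              n_points = 200L) {
  stopifnot(inherits(system, "moment_system"))
  S <- system$n_stages
  if (is.null(initial)) {
    y0 <- rep(0, 3 * S)
    y0[seq_len(S)] <- system$stages$entry_prob *
      (system$stages$phase == 1L)
  } else if (inherits(initial, "stage_moments")) {
    y0 <- c(initial$occupancy, initial$first, initial$second)
  } else {
    stopifnot(length(initial) == 3 * S)
    y0 <- as.numeric(initial)
  }
  A <- system$A
  times <- seq(0, horizon, length.out = n_points)
  sol <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    jacfunc = function(t, y, parms) A,
    jactype = "fullusr", method = "lsoda",
    rtol = 1e-10, atol = 1e-12
  )
  states <- unclass(sol)[, -1, drop = FALSE]
  if (any(!is.finite(states))) {
    stop("non-finite values in transient integration; horizon = ", horizon)
  }
  out <- data.frame(
    time = sol[, 1],
    mean_x = rowSums(states[, S + seq_len(S), drop = FALSE]),
    second_x = rowSums(states[, 2 * S + seq_len(S), drop = FALSE]),
    occ_total = rowSums(states[, seq_len(S), drop = FALSE])
  )
  attr(out, "states") <- states
  out
}

#' Numeric three-way noise decomposition via hybrid-model subtraction
#'
#' Computes the decomposition without any closed form, by solving the
#' steady-state moment system for the three model variants and
#' subtracting: \eqn{CV_E^2} is the CV^2 of hybrid B (timing noise only),
#' \eqn{CV_R^2} is hybrid C minus hybrid B, and \eqn{CV_P^2} is the full
#' model minus hybrid C.  Additivity is exact by construction.  This is the
#' route for dosage factors other than 2 and for phase clocks with no
#' closed form.
#'
#' @param clock an \code{\link{erlang_mixture}} (ignored when
#'   \code{duplication} is given).
#' @param b a \code{\link{burst_model}}.
#' @param p a \code{\link{partition_model}}.
#' @param duplication optional \code{\link{duplication_schedule}}.
#' @param degradation optional decay rate \eqn{\gamma_x}.
#' @return a \code{\link{noise_decomposition}}.
#' @export
decompose_numeric <- function(clock = NULL, b, p, duplication = NULL,
                              degradation = NULL) {
  cv2_of <- function(burst, part) {
    fl <- model_flags(burst, part, duplication = duplication,
                      degradation = degradation)
    steady_state_moments(build_moment_system(clock, b, p, fl))
  }
  hb <- cv2_of(FALSE, FALSE)
  hc <- cv2_of(FALSE, TRUE)
  fm <- cv2_of(TRUE, TRUE)
  noise_decomposition(
    mean_x = fm$mean_x,
    cv2_ext = hb$cv2,
    cv2_part = hc$cv2 - hb$cv2,
    cv2_prod = fm$cv2 - hc$cv2
  )
}

#' Dump a moment-system generator in sparse triplet form
#'
#' Writes the nonzero entries of \code{A} (row, col, value) and the offset
#' vector to a plain-text file for inspection.
#'
#' @param system a \code{moment_system}.
#' @param path output file path.
#' @return invisibly, the triplet data.frame.
#' @export
write_system_triplets <- function(system, path) {
  nz <- which(system$A != 0, arr.ind = TRUE)
  trip <- data.frame(row = nz[, 1], col = nz[, 2],
                     value = system$A[nz])
  trip <- trip[order(trip$row, trip$col), ]
  utils::write.table(trip, path, row.names = FALSE, quote = FALSE,
                     sep = "\t")
  invisible(trip)
}
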