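# Fixed-step explicit time steppers shared by the mean-field and PDE
# solvers. Deliberately fixed-step: the explicit Euler scheme with the
# model's stated dt is part of the numerical contract, and every step may be
# followed by a state-space projection.

euler_step <- function(rhs, t, y, dt) y + dt * rhs(t, y)

rk4_step <- function(rhs, t, y, dt) {
  k1 <- rhs(t, y)
  k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
  k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
  k4 <- rhs(t + dt, y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# rhs: function(t, Y) -> same shape as Y (matrix n x s).
# post: optional projection applied after every step.
# Records the state at multiples of dt nearest to `record_times`
# (default: every step).
integrate_fixed <- function(rhs, y0, t_end, dt,
                            method = c("rk4", "euler"),
                            record_times = NULL, post = NULL) {
  method <- match.arg(method)
  step <- switch(method, rk4 = rk4_step, euler = euler_step)
  if (dt <= 0) stop("`dt` must be positive")
  n_steps <- max(1L, as.integer(round(t_end / dt)))
  times <- seq_len(n_steps) * (t_end / n_steps)
  dt_eff <- t_end / n_steps
  if (is.null(record_times)) {
    rec_idx <- 0:n_steps
  } else {
    rec_idx <- unique(pmin(n_steps, pmax(0L, as.integer(round(record_times / dt_eff)))))
  }
  rec_set <- logical(n_steps + 1L)
  rec_set[rec_idx + 1L] <- TRUE

  y <- y0
  out_times <- numeric(0)
  out_states <- list()
  record <- function(tt) {
    out_times[[length(out_times) + 1L]] <<- tt
    out_states[[length(out_states) + 1L]] <<- y
  }
  if (rec_set[1L]) record(0)
  t <- 0
  for (k in seq_len(n_steps)) {
    y <- step(rhs, t, y, dt_eff)
    if (!all(is.finite(y))) stop("non-finite state at t = ", t + dt_eff,
                                 "; reduce dt")
    if (!is.null(post)) y <- post(y)
    t <- times[k]
    if (rec_set[k + 1L]) record(t)
  }
  arr <- array(unlist(out_states),
               dim = c(nrow(y0), ncol(y0), length(out_times)))
  list(times = unlist(out_times), states = arr)
}

# Renormalize the simplex block of a state matrix against floating-point
# drift. The drifts of all shipped models are tangent to K analytically;
# this guards accumulation of rounding error only.
project_simplex_rows <- function(Y, m = ncol(Y), tol = 1e-12, clip = 1e-10) {
  V <- Y[, seq_len(m), drop = FALSE]
  if (any(V < 0)) {
    if (any(V < -clip)) {
      warning("simplex states clipped by more than ", clip)
    }
    V[V < 0] <- 0
  }
  rs <- rowSums(V)
  off <- abs(rs - 1) > tol
  if (any(off)) V[off, ] <- V[off, , drop = FALSE] / rs[off]
  Y[, seq_len(m)] <- V
  Y
}

nk_trajectory <- function(times, states, x, kind, ...) {
  structure(
    c(list(times = times, states = states, x = x, kind = kind), list(...)),
    class = "nk_trajectory"
  )
}

#' Extract one time slice of a trajectory
#'
#' @param traj an `nk_trajectory` as returned by the solvers.
#' @param t requested time (nearest recorded time is used).
#' @return the state matrix at that time.
#' @export
trajectory_state <- function(traj, t) {
  stopifnot(inherits(traj, "nk_trajectory"))
  i <- which.min(abs(traj$times - t))
  out <- traj$states[, , i, drop = FALSE]
  dim(out) <- dim(traj$states)[1:2]
  out
}
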