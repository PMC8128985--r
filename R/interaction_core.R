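# Generic N-agent stochastic simulator: exact (event-driven) realization of
# the master-equation jump process with mean-field pair rates w(x_i,x_j)/N,
# plus the interaction-rule contract the concrete models implement.

#' Agent ensemble on a fixed network
#'
#' `N` agents with immutable structural positions `x` and mutable states.
#' Positions never change during simulation: the network is the fixed
#' substrate of the dynamics, which is what makes the spatial marginal
#' exactly stationary.
#'
#' @param x numeric positions in \eqn{[0,1)} (or node indices for matrix
#'   kernels); one per agent.
#' @param states numeric vector or matrix (one row per agent) of initial
#'   states.
#' @param state_space one of `"simplex"` (rows on the probability simplex
#'   `K`), `"simplex_s"` (simplex plus a trailing nonnegative scalar),
#'   `"categorical"` (integer codes) or `"numeric"` (unconstrained).
#' @return an object of class `nk_ensemble` with fields `N`, `x`, `states`,
#'   `state_space`.
#' @export
agent_ensemble <- function(x, states,
                           state_space = c("simplex", "simplex_s",
                                           "categorical", "numeric")) {
  state_space <- match.arg(state_space)
  if (!is.matrix(states)) states <- matrix(states, ncol = 1)
  if (length(x) != nrow(states)) stop("`x` and `states` disagree on N")
  check_state_space(states, state_space)
  structure(
    list(N = length(x), x = as.numeric(x), states = unname(states),
         state_space = state_space),
    class = "nk_ensemble"
  )
}

check_state_space <- function(states, state_space, tol = 1e-8) {
  switch(state_space,
    simplex = {
      if (any(states < -tol) || any(abs(rowSums(states) - 1) > tol)) {
        stop("states must lie on the probability simplex K")
      }
    },
    simplex_s = {
      M <- ncol(states) - 1L
      if (M < 1) stop("simplex_s states need at least two columns")
      v <- states[, seq_len(M), drop = FALSE]
      if (any(v < -tol) || any(abs(rowSums(v) - 1) > tol)) {
        stop("weight part of states must lie on the simplex K")
      }
      if (any(states[, M + 1L] < -tol)) stop("interaction count s must be nonnegative")
    },
    categorical = {
      if (any(states != round(states)) || any(states < 1)) {
        stop("categorical states must be positive integer codes")
      }
    },
    numeric = invisible(NULL)
  )
  invisible(TRUE)
}

#' Define a pairwise interaction rule
#'
#' An interaction rule specifies, for an ordered pair (active, passive), the
#' distribution \eqn{\nu_{z,\tilde z}} of state increments \eqn{(a, b)}: a
#' sampler used by the stochastic simulator, and its first and second
#' moments used by the mean-field (Vlasov) approximations. All three shipped
#' models (dialect, social construction, SIR) are instances; custom rules can
#' be built directly.
#'
#' @param name short identifier.
#' @param state_space as in [agent_ensemble()].
#' @param update_pair `function(v_active, v_passive)` returning
#'   `list(active = , passive = )`, the post-event states. This is what the
#'   simulator applies; for increment rules it is `v + a`, `v + b`.
#' @param mean_a,mean_b `function(v_active, v_passive)` returning the mean
#'   increment \eqn{\int a\, d\nu} resp. \eqn{\int b\, d\nu} of the active /
#'   passive agent. May be `NULL` for rules without numeric moments
#'   (categorical states).
#' @param second_a,second_b `function(v_active, v_passive)` returning the
#'   second-moment matrices \eqn{\int a \otimes a\, d\nu},
#'   \eqn{\int b \otimes b\, d\nu}.
#' @param rescale the small factor by which one event moves the passive
#'   state; mean-field time is simulator time multiplied by this factor
#'   (dialect: \eqn{\gamma/(1+\gamma)}; social: \eqn{h}).
#' @param drift_terms optional vectorized `function(v, V_mat)` returning, for
#'   a focal state `v` and a matrix of partner states (one per row), the
#'   rescaled drift contributions
#'   \eqn{(\int a\, d\nu_{z,\tilde z} + \int b\, d\nu_{\tilde z, z}) /}
#'   `rescale` as a matrix. Derived from the moment functions when omitted.
#' @param relaxation_g optional `function(V_mat)`; when the rescaled drift
#'   has the relaxation form \eqn{g(\tilde v) - v} the mean-field solvers use
#'   a fast matrix path.
#' @param unary optional single-agent channel (an extension of the pure
#'   pairwise framework, used by the SIR removal): `list(rate =
#'   function(states_matrix) per-agent rates, update = function(v) new
#'   state)`.
#' @param params list of model parameters, kept for reference.
#' @return an object of class `nk_rule`.
#' @export
interaction_rule <- function(name, state_space, update_pair,
                             mean_a = NULL, mean_b = NULL,
                             second_a = NULL, second_b = NULL,
                             rescale = 1, drift_terms = NULL,
                             relaxation_g = NULL, unary = NULL,
                             params = list()) {
  rule <- structure(
    list(name = name, state_space = state_space, update_pair = update_pair,
         mean_a = mean_a, mean_b = mean_b,
         second_a = second_a, second_b = second_b,
         rescale = rescale, drift_terms = drift_terms,
         relaxation_g = relaxation_g, unary = unary, params = params),
    class = "nk_rule"
  )
  if (is.null(rule$drift_terms) && !is.null(mean_a) && !is.null(mean_b)) {
    rule$drift_terms <- function(v, V_mat) {
      out <- t(vapply(seq_len(nrow(V_mat)), function(q) {
        (rule$mean_a(v, V_mat[q, ]) + rule$mean_b(V_mat[q, ], v)) / rule$rescale
      }, numeric(length(v))))
      out
    }
  }
  rule
}

#' Total pairwise event rate
#'
#' The aggregate rate \eqn{\Lambda = \sum_{i \neq j} w(x_i, x_j)/N} of the
#' jump process under the mean-field scaling \eqn{\omega^N = w/N}. Because
#' positions are fixed, \eqn{\Lambda} is constant along every trajectory.
#'
#' @param ensemble an `nk_ensemble`.
#' @param kernel an `nk_kernel`.
#' @param periodic use the wrapped distance on the unit interval.
#' @return a nonnegative scalar (zero when `N < 2`).
#' @export
total_pair_rate <- function(ensemble, kernel, periodic = TRUE) {
  stopifnot(inherits(ensemble, "nk_ensemble"))
  if (ensemble$N < 2) return(0)
  Wp <- pair_rate_matrix(ensemble$x, kernel, periodic)
  sum(Wp)
}

pair_rate_matrix <- function(x, kernel, periodic = TRUE) {
  N <- length(x)
  Wp <- outer(x, x, function(a, b) evaluate_kernel(kernel, a, b, periodic)) / N
  diag(Wp) <- 0
  if (any(!is.finite(Wp)) || any(Wp < 0)) {
    stop("pair rates must be finite and nonnegative")
  }
  Wp
}

#' Simulate the N-agent jump process (Gillespie algorithm)
#'
#' Exact event-driven simulation of the master-equation dynamics: waiting
#' times are exponential with the total rate, the ordered pair `(i, j)` (`i`
#' active, `j` passive) is chosen with probability proportional to
#' \eqn{w(x_i, x_j)/N}, and the increments are drawn from the rule's
#' \eqn{\nu_{z_i, z_j}}. Single-agent (unary) channels, when present, compete
#' with the pair events at their own rates. Positions are never touched.
#'
#' @param ensemble an `nk_ensemble`.
#' @param rule an `nk_rule` whose state space matches the ensemble.
#' @param kernel an `nk_kernel`.
#' @param t_end simulation horizon (unrescaled time); may be `Inf` when
#'   `max_events` is finite.
#' @param max_events optional cap on the number of events.
#' @param seed optional integer seed; given the seed the run is reproducible.
#' @param snapshot_times times at which to record the full state matrix.
#' @param snapshot_every_events record a snapshot every so many events.
#' @param record_events keep a per-event log (time, active, passive, type).
#' @param periodic use wrapped distances.
#' @return an object of class `nk_sim`: final `ensemble`, elapsed `t`,
#'   `n_events`, a list `snapshots` (`times`, `states` array), and `events`
#'   (data frame or `NULL`).
#' @export
simulate_boltzmann <- function(ensemble, rule, kernel, t_end = Inf,
                               max_events = Inf, seed = NULL,
                               snapshot_times = NULL,
                               snapshot_every_events = NULL,
                               record_events = FALSE, periodic = TRUE) {
  stopifnot(inherits(ensemble, "nk_ensemble"), inherits(rule, "nk_rule"))
  if (!identical(ensemble$state_space, rule$state_space)) {
    stop("rule state space (", rule$state_space,
         ") does not match ensemble (", ensemble$state_space, ")")
  }
  if (!is.finite(t_end) && !is.finite(max_events)) {
    stop("one of `t_end`, `max_events` must be finite")
  }
  if (!is.null(seed)) set.seed(seed)

  N <- ensemble$N
  states <- ensemble$states
  x <- ensemble$x
  Wp <- if (N >= 2) pair_rate_matrix(x, kernel, periodic) else matrix(0, N, N)
  lambda_pair <- sum(Wp)
  row_rate <- rowSums(Wp)

  snap_times <- numeric(0)
  snap_states <- list()
  pending <- sort(snapshot_times)
  take_snapshot <- function(at) {
    snap_times[[length(snap_times) + 1L]] <<- at
    snap_states[[length(snap_states) + 1L]] <<- states
  }
  flush_snapshots <- function(up_to) {
    while (length(pending) && pending[1] <= up_to) {
      take_snapshot(pending[1])
      pending <<- pending[-1]
    }
  }
  if (!is.null(snapshot_every_events)) take_snapshot(0)

  ev_time <- numeric(0); ev_i <- integer(0); ev_j <- integer(0); ev_type <- character(0)
  t <- 0
  n_events <- 0L
  repeat {
    if (n_events >= max_events) break
    u_rates <- if (!is.null(rule$unary)) rule$unary$rate(states) else numeric(N)
    total <- lambda_pair + sum(u_rates)
    if (total <= 0) {
      if (is.finite(t_end)) t <- t_end
      break
    }
    t_next <- t + stats::rexp(1, total)
    if (t_next > t_end) {
      t <- t_end
      break
    }
    flush_snapshots(t_next)
    t <- t_next
    if (stats::runif(1) * total < lambda_pair) {
      i <- sample.int(N, 1L, prob = row_rate)
      j <- sample.int(N, 1L, prob = Wp[i, ])
      upd <- rule$update_pair(states[i, ], states[j, ])
      states[i, ] <- upd$active
      states[j, ] <- upd$passive
      type <- "pair"
    } else {
      i <- sample.int(N, 1L, prob = u_rates)
      j <- NA_integer_
      states[i, ] <- rule$unary$update(states[i, ])
      type <- "unary"
    }
    n_events <- n_events + 1L
    if (record_events) {
      ev_time[[n_events]] <- t; ev_i[[n_events]] <- i
      ev_j[[n_events]] <- j; ev_type[[n_events]] <- type
    }
    if (!is.null(snapshot_every_events) &&
        n_events %% snapshot_every_events == 0L) {
      take_snapshot(t)
    }
  }
  flush_snapshots(t)

  out_ens <- ensemble
  out_ens$states <- states
  snaps <- NULL
  if (length(snap_times)) {
    arr <- array(unlist(snap_states),
                 dim = c(nrow(states), ncol(states), length(snap_times)))
    snaps <- list(times = unlist(snap_times), states = arr)
  }
  structure(
    list(ensemble = out_ens, t = t, n_events = n_events, snapshots = snaps,
         events = if (record_events) {
           data.frame(time = ev_time, active = ev_i, passive = ev_j,
                      type = ev_type)
         } else NULL),
    class = "nk_sim"
  )
}

#' Empirical spatial marginal and binned state means
#'
#' Projects an ensemble onto the structural variable: the histogram
#' \eqn{\eta} of positions (which is exactly invariant along every
#' simulation, since positions never move) and the per-bin mean state where
#' bins are occupied.
#'
#' @param ensemble an `nk_ensemble`.
#' @param bins number of equal-width bins on \eqn{[0,1)}, a vector of break
#'   points, or `"nodes"` to group by the exact distinct positions.
#' @return a list with `eta` (masses summing to one), `counts`, `mean_state`
#'   (matrix, `NA` rows for empty bins), `mids` and `breaks` (`NULL` for
#'   node binning).
#' @export
empirical_marginals <- function(ensemble, bins = 20) {
  stopifnot(inherits(ensemble, "nk_ensemble"))
  x <- ensemble$x
  states <- ensemble$states
  if (identical(bins, "nodes")) {
    nodes <- sort(unique(x))
    idx <- match(x, nodes)
    breaks <- NULL
    mids <- nodes
    nb <- length(nodes)
  } else {
    breaks <- if (length(bins) == 1L) seq(0, 1, length.out = bins + 1L) else bins
    nb <- length(breaks) - 1L
    idx <- findInterval(x, breaks, rightmost.closed = FALSE, left.open = FALSE)
    idx[idx > nb] <- nb
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  counts <- tabulate(idx, nbins = nb)
  mean_state <- matrix(NA_real_, nb, ncol(states))
  for (b in which(counts > 0)) {
    mean_state[b, ] <- colMeans(states[idx == b, , drop = FALSE])
  }
  list(eta = counts / length(x), counts = counts, mean_state = mean_state,
       mids = mids, breaks = breaks)
}
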