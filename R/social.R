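# Social-norm construction on a discrete node network: rescaled
# weight/count states, the argmax action rule, interaction updates, and the
# time-inhomogeneous monokinetic ODE system.

#' Social-construction model parameters
#'
#' Agents hold integer weights \eqn{\omega_i} over `M` mental
#' representations of a social action plus an interaction count `I`;
#' rescaled states are \eqn{v_i = \omega_i / \sum_j \omega_j} and
#' \eqn{s = I/J} with increment \eqn{h = 1/J}. Agents live on a discrete
#' node network with interaction weights \eqn{w_{k\ell}} and node densities
#' \eqn{\rho_k}.
#'
#' @param M number of mental representations.
#' @param J rescaling constant \eqn{\ge 1}; `h = 1/J` is the per-event
#'   increment of `s`.
#' @param network an `nk_network`.
#' @param s0 initial rescaled interaction counts, one per node (positive;
#'   recycled).
#' @return an object of class `social_params` (fields include `h`).
#' @export
social_params <- function(M, J, network, s0 = 1) {
  if (M < 2 || M != round(M)) stop("`M` must be an integer >= 2")
  if (J < 1) stop("`J` must be >= 1")
  stopifnot(inherits(network, "nk_network"))
  s0 <- rep_len(s0, network$n_nodes)
  if (any(s0 <= 0)) stop("`s0` must be positive")
  structure(
    list(M = as.integer(M), J = J, h = 1 / J, network = network, s0 = s0),
    class = "social_params"
  )
}

#' Rescale integer weights and interaction count
#'
#' \eqn{v_i = \omega_i/\sum_j \omega_j}, \eqn{s = I/J}.
#'
#' @param omega nonnegative integer weight vector with positive sum.
#' @param I interaction count.
#' @param J rescaling constant.
#' @return list with simplex state `v` and rescaled count `s`.
#' @export
rescale_states <- function(omega, I, J) {
  if (any(omega < 0)) stop("weights must be nonnegative")
  tot <- sum(omega)
  if (tot <= 0) stop("weights must have positive sum")
  list(v = omega / tot, s = I / J)
}

#' Action distribution of a weight state
#'
#' The action with the highest weight is played; ties are broken uniformly
#' over the maximizers. Equality is decided after rounding to 12 decimals,
#' so states that differ only by floating-point noise tie. This is the
#' concentrated counterpart of the dialect choice probabilities.
#'
#' @param v simplex state (vector) or matrix of states.
#' @return uniform distribution over the argmax components, same shape.
#' @export
action_distribution <- function(v) {
  vec <- !is.matrix(v)
  V <- if (vec) matrix(v, nrow = 1) else v
  Vr <- round(V, 12)
  mx <- apply(Vr, 1L, max)
  P <- (Vr == mx) * 1
  P <- P / rowSums(P)
  if (vec) as.vector(P) else P
}

#' Passive-agent update of the social model
#'
#' After observing action `i` the weights and count update as
#' \deqn{v' = \frac{s}{s+h} v + \frac{h}{s+h} e_i, \qquad s' = s + h,}
#' which is exactly "add one to \eqn{\omega_i} and one to `I`" in the
#' unrescaled representation (with `h = 1/J`).
#'
#' @param state list with simplex state `v` and count `s >= 0`.
#' @param i observed action index.
#' @param h increment `1/J`.
#' @return the updated `list(v, s)`.
#' @export
social_update <- function(state, i, h) {
  v <- state$v; s <- state$s
  if (i < 1 || i > length(v)) stop("invalid action index")
  if (s < 0) stop("`s` must be nonnegative")
  e <- numeric(length(v)); e[i] <- 1
  list(v = s / (s + h) * v + h / (s + h) * e, s = s + h)
}

#' Social-construction interaction rule
#'
#' States are `(v, s)` with `v` on the simplex and `s` the rescaled
#' interaction count (stored as the trailing component). The active agent
#' plays an action from [action_distribution()] of its own `v` and is
#' unchanged; the passive agent applies [social_update()]. Mean increments
#' are \eqn{\frac{h}{s+h}(\bar p(v_{\mathrm{act}}) - v_{\mathrm{pas}})} in
#' `v` and `h` in `s`; the rescale factor is `h`.
#'
#' @param params a [social_params()].
#' @return an `nk_rule` on the `simplex_s` state space.
#' @export
social_rule <- function(params) {
  stopifnot(inherits(params, "social_params"))
  M <- params$M
  h <- params$h
  split_vs <- function(z) list(v = z[seq_len(M)], s = z[M + 1L])
  interaction_rule(
    name = "social",
    state_space = "simplex_s",
    update_pair = function(z_act, z_pas) {
      act <- split_vs(z_act)
      i <- sample.int(M, 1L, prob = action_distribution(act$v))
      pas <- social_update(split_vs(z_pas), i, h)
      list(active = z_act, passive = c(pas$v, pas$s))
    },
    mean_a = function(z_act, z_pas) numeric(M + 1L),
    mean_b = function(z_act, z_pas) {
      act <- split_vs(z_act); pas <- split_vs(z_pas)
      c(h / (pas$s + h) * (action_distribution(act$v) - pas$v), h)
    },
    second_a = function(z_act, z_pas) matrix(0, M + 1L, M + 1L),
    second_b = function(z_act, z_pas) {
      act <- split_vs(z_act); pas <- split_vs(z_pas)
      p <- action_distribution(act$v)
      B <- matrix(0, M + 1L, M + 1L)
      for (i in which(p > 0)) {
        e <- numeric(M); e[i] <- 1
        b <- c(h / (pas$s + h) * (e - pas$v), h)
        B <- B + p[i] * tcrossprod(b)
      }
      B
    },
    rescale = h,
    drift_terms = function(z, Z_mat) {
      v <- z[seq_len(M)]; s <- z[M + 1L]
      P <- action_distribution(Z_mat[, seq_len(M), drop = FALSE])
      cbind(sweep(P, 2L, v) / s, 1)
    },
    params = params
  )
}

#' Monokinetic right-hand side of the social model
#'
#' With the closed-form count \eqn{s_k(t) = s_k^0 + \lambda_k t},
#' \eqn{\lambda_k = \sum_\ell w_{k\ell}\rho_\ell}, the per-node states obey
#' the non-autonomous system
#' \deqn{\frac{dV_k}{dt} = \sum_\ell w_{k\ell}\,
#'   \frac{1}{s_k^0 + \lambda_k t}\,\big(p(V_\ell) - V_k\big).}
#' The `1/s` factor encodes the stiffening of established norms: influence
#' of new interactions decays like `1/t`.
#'
#' @param V per-node state matrix (nodes x M), rows in `K`.
#' @param t time.
#' @param params a [social_params()].
#' @param p_fun the action map: a function of a state matrix (see
#'   [solve_social_monokinetic()] for the shipped choices).
#' @return matrix of time derivatives.
#' @export
social_monokinetic_rhs <- function(V, t, params, p_fun = action_distribution) {
  stopifnot(inherits(params, "social_params"))
  net <- params$network
  W <- net$weights
  lambda <- as.vector(W %*% net$rho)
  s_t <- params$s0 + lambda * t
  pV <- p_fun(V)
  (W %*% pV - rowSums(W) * V) / s_t
}

#' Solve the monokinetic social-construction system
#'
#' Integrates [social_monokinetic_rhs()] on the node network. Because the
#' argmax action map is discontinuous (solutions need not be unique), two
#' variants are offered: `"argmax"` integrates the discontinuous field with
#' a fixed small step, and `"smooth"` regularizes it by the power-law choice
#' map with a large exponent (which concentrates on the maximizer).
#'
#' @param V0 initial per-node states (nodes x M), rows in `K`.
#' @param params a [social_params()].
#' @param t_end,dt horizon and step.
#' @param p_variant `"argmax"` or `"smooth"`.
#' @param alpha_smooth exponent of the smooth regularization.
#' @param method `"rk4"` or `"euler"`.
#' @param record_times times to record.
#' @return an `nk_trajectory` with kind `"social_monokinetic"`.
#' @export
solve_social_monokinetic <- function(V0, params, t_end, dt,
                                     p_variant = c("argmax", "smooth"),
                                     alpha_smooth = 40,
                                     method = c("rk4", "euler"),
                                     record_times = NULL) {
  stopifnot(inherits(params, "social_params"))
  p_variant <- match.arg(p_variant)
  if (!is.matrix(V0)) V0 <- matrix(V0, nrow = params$network$n_nodes)
  p_fun <- if (p_variant == "argmax") {
    action_distribution
  } else {
    function(V) choice_probabilities(V, alpha_smooth)
  }
  rhs <- function(t, V) social_monokinetic_rhs(V, t, params, p_fun)
  sol <- integrate_fixed(rhs, V0, t_end, dt, method, record_times,
                         post = project_simplex_rows)
  nk_trajectory(sol$times, sol$states,
                seq_len(params$network$n_nodes), "social_monokinetic",
                p_variant = p_variant)
}
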