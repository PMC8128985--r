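# Dialect evolution on the memory simplex: variant-choice probabilities,
# listener memory updates, the Boltzmann interaction rule, the nonlocal
# monokinetic (reaction-diffusion) equations, and their spatially local
# limits.

#' Dialect model parameters
#'
#' An agent's state is its memory \eqn{v \in K = \{v \ge 0, \sum v_i = 1\}}
#' of `M` variants of a linguistic variable. In a conversation the speaker
#' (active agent) utters variant `i` with probability \eqn{p_i(v)} and the
#' listener's memory relaxes toward the heard variant with weight
#' \eqn{\gamma/(1+\gamma)}.
#'
#' @param M number of variants (\eqn{\ge 2}).
#' @param gamma memory weight \eqn{\gamma > 0} of a single heard utterance;
#'   naturally small.
#' @param alpha_exp conformity exponent \eqn{\alpha \ge 1} of the choice
#'   probabilities; \eqn{\alpha > 1} overweights the majority variant and
#'   makes the simplex corners the stable states.
#' @return an object of class `dialect_params`.
#' @export
dialect_params <- function(M, gamma, alpha_exp = 2) {
  if (M < 2 || M != round(M)) stop("`M` must be an integer >= 2")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (alpha_exp < 1) stop("`alpha_exp` must be >= 1")
  structure(list(M = as.integer(M), gamma = gamma, alpha_exp = alpha_exp),
            class = "dialect_params")
}

#' Variant choice probabilities
#'
#' \deqn{p_i(v) = \frac{v_i^\alpha}{\sum_j v_j^\alpha},}
#' the probability that an agent with memory `v` utters variant `i`. For
#' \eqn{\alpha > 1} the map overweights frequent variants; at
#' \eqn{\alpha = 1} it is the identity on `K`. Corners use the convention
#' \eqn{0^\alpha = 0} with renormalization over the nonzero entries, so each
#' corner is a fixed point (continuous extension from the interior).
#'
#' @param v simplex state (vector) or matrix of states (one per row).
#' @param alpha_exp exponent \eqn{\alpha \ge 1}.
#' @return object of the same shape as `v`, rows on the simplex.
#' @export
choice_probabilities <- function(v, alpha_exp) {
  vec <- !is.matrix(v)
  V <- if (vec) matrix(v, nrow = 1) else v
  if (any(V < 0)) {
    # integrator trial substeps may dip infinitesimally below zero before
    # the post-step projection; tolerate that, reject genuine negatives
    if (min(V) < -1e-9) stop("states must be nonnegative")
    V[V < 0] <- 0
  }
  P <- V^alpha_exp
  s <- rowSums(P)
  if (any(s == 0)) stop("choice probabilities undefined for all-zero state")
  P <- P / s
  if (vec) as.vector(P) else P
}

#' Inverse of the choice-probability map
#'
#' Closed-form inverse \eqn{V_i(P) = P_i^{1/\alpha}/\sum_j P_j^{1/\alpha}}:
#' the memory state whose choice probabilities are `P`.
#'
#' @param P simplex state or matrix of states.
#' @param alpha_exp exponent \eqn{\alpha \ge 1}.
#' @return the preimage state(s), on the simplex.
#' @export
inverse_choice_map <- function(P, alpha_exp) {
  if (alpha_exp == 0) stop("alpha_exp = 0 is not invertible")
  choice_probabilities(P, 1 / alpha_exp)
}

#' Listener memory update and its inverse
#'
#' Post-collisional memory after hearing variant `i`:
#' \deqn{v' = \frac{1}{1+\gamma} v + \frac{\gamma}{1+\gamma} e_i,}
#' a convex combination that keeps the state in `K`; `pre_collision` is the
#' exact inverse \eqn{v^* = (1+\gamma) v - \gamma e_i}.
#'
#' @param v simplex state.
#' @param i heard variant index.
#' @param gamma memory weight.
#' @return the updated (resp. pre-collisional) state.
#' @export
collision_update <- function(v, i, gamma) {
  if (i < 1 || i > length(v)) stop("invalid variant index")
  out <- v / (1 + gamma)
  out[i] <- out[i] + gamma / (1 + gamma)
  out
}

#' @rdname collision_update
#' @export
pre_collision <- function(v, i, gamma) {
  if (i < 1 || i > length(v)) stop("invalid variant index")
  out <- (1 + gamma) * v
  out[i] <- out[i] - gamma
  out
}

#' Dialect interaction rule
#'
#' The Boltzmann-level rule: the active agent draws a variant
#' \eqn{i \sim p(v_{\mathrm{active}})} and does not change; the passive
#' agent jumps by \eqn{b = \frac{\gamma}{1+\gamma}(e_i - v_{\mathrm{passive}})}.
#' Mean and second moments are the exact atom sums, and the rescale factor
#' is \eqn{\gamma/(1+\gamma)} (the per-event step size), so mean-field time
#' is simulator time times \eqn{\gamma/(1+\gamma)}.
#'
#' @param params a [dialect_params()].
#' @return an `nk_rule` on the simplex state space.
#' @export
dialect_rule <- function(params) {
  stopifnot(inherits(params, "dialect_params"))
  M <- params$M
  gp <- params$gamma / (1 + params$gamma)
  a_exp <- params$alpha_exp
  zero <- numeric(M)
  zero_mat <- matrix(0, M, M)
  interaction_rule(
    name = "dialect",
    state_space = "simplex",
    update_pair = function(v_act, v_pas) {
      i <- sample.int(M, 1L, prob = choice_probabilities(v_act, a_exp))
      list(active = v_act, passive = collision_update(v_pas, i, params$gamma))
    },
    mean_a = function(v_act, v_pas) zero,
    mean_b = function(v_act, v_pas) {
      gp * (choice_probabilities(v_act, a_exp) - v_pas)
    },
    second_a = function(v_act, v_pas) zero_mat,
    second_b = function(v_act, v_pas) {
      p <- choice_probabilities(v_act, a_exp)
      B <- zero_mat
      for (i in seq_len(M)) {
        e <- zero; e[i] <- 1
        b <- gp * (e - v_pas)
        B <- B + p[i] * tcrossprod(b)
      }
      B
    },
    rescale = gp,
    drift_terms = function(v, V_mat) {
      sweep(choice_probabilities(V_mat, a_exp), 2L, v)
    },
    relaxation_g = function(V_mat) choice_probabilities(V_mat, a_exp),
    params = params
  )
}

#' Right-hand side of the nonlocal monokinetic dialect equations
#'
#' For `model = "network"` the monokinetic closure of the Vlasov equation,
#' in reaction-diffusion form
#' \deqn{\partial_t V = -\kappa(x)\,(V - p(V)) + \int w(x,\tilde x)
#'   \rho(\tilde x)\big(p(V(\tilde x)) - p(V(x))\big)\, d\tilde x,}
#' a bistable reaction plus a nonlocal diffusion acting on \eqn{p(V)}. For
#' `model = "standard_rd"` the comparison model with the *linear* nonlocal
#' term in \eqn{V} in place of \eqn{p(V)}. Either way the components sum to
#' zero pointwise: the flow is tangent to the simplex.
#'
#' @param V state matrix (points x variants), rows in `K`.
#' @param km an `nk_kernel_matrix` (its density, default one, is \eqn{\rho}).
#' @param params a [dialect_params()].
#' @param model `"network"` or `"standard_rd"`.
#' @return matrix of time derivatives \eqn{\partial_t V}.
#' @export
dialect_monokinetic_rhs <- function(V, km, params,
                                    model = c("network", "standard_rd")) {
  stopifnot(inherits(km, "nk_kernel_matrix"), inherits(params, "dialect_params"))
  model <- match.arg(model)
  if (!is.matrix(V)) V <- matrix(V, nrow = nrow(km$matrix))
  n <- nrow(km$matrix)
  if (nrow(V) != n) stop("V does not match the discretization of km")
  rho <- if (is.null(km$density)) rep(1, n) else km$density
  kappa <- as.vector(km$matrix %*% rho)
  pV <- choice_probabilities(V, params$alpha_exp)
  if (model == "network") {
    km$matrix %*% (rho * pV) - kappa * V
  } else {
    -kappa * (V - pV) + km$matrix %*% (rho * V) - kappa * V
  }
}

#' Solve the nonlocal monokinetic dialect equation
#'
#' Method-of-lines integration of [dialect_monokinetic_rhs()] with simplex
#' renormalization after each step.
#'
#' @inheritParams dialect_monokinetic_rhs
#' @param V0 initial state matrix, rows in `K`.
#' @param t_end,dt horizon and step (mean-field time).
#' @param method `"rk4"` or `"euler"`.
#' @param record_times times to record.
#' @return an `nk_trajectory` with kind `"dialect_monokinetic"`.
#' @export
solve_dialect_monokinetic <- function(V0, km, params, t_end, dt,
                                      model = c("network", "standard_rd"),
                                      method = c("rk4", "euler"),
                                      record_times = NULL) {
  model <- match.arg(model)
  rhs <- function(t, V) dialect_monokinetic_rhs(V, km, params, model)
  sol <- integrate_fixed(rhs, V0, t_end, dt, method, record_times,
                         post = project_simplex_rows)
  nk_trajectory(sol$times, sol$states, km$points, "dialect_monokinetic",
                model = model, density = km$density,
                quad_weights = km$quad_weights)
}

#' Local-limit configuration for the dialect PDEs
#'
#' @param kappa interaction rate \eqn{\kappa \ge 0} (scalar or one value per
#'   grid point); the reaction strength.
#' @param sigma diffusion length \eqn{\sigma = \sqrt{C}\varepsilon \ge 0}
#'   from [local_limit_sigma()].
#' @param variant which local PDE to advance, see [solve_local_pde()].
#' @param alpha_exp conformity exponent of the underlying choice map.
#' @return an object of class `dialect_local_config`.
#' @export
dialect_local_config <- function(kappa, sigma,
                                 variant = c("burridge", "allen_cahn_V",
                                             "allen_cahn_P"),
                                 alpha_exp = 2) {
  if (any(kappa < 0) || sigma < 0) stop("kappa and sigma must be nonnegative")
  structure(
    list(kappa = kappa, sigma = sigma, variant = match.arg(variant),
         alpha_exp = alpha_exp),
    class = "dialect_local_config"
  )
}

#' Solve the local (spatially concentrated) dialect PDEs
#'
#' Three local limits of the nonlocal monokinetic equation on the periodic
#' unit interval, advanced by method of lines with a second-order central
#' Laplacian (\eqn{\rho \equiv 1} is assumed throughout):
#' \describe{
#'   \item{`burridge`}{\eqn{\partial_t V = -\kappa(V - p(V)) +
#'     \tfrac{\sigma^2}{2}\Delta p(V)} — the nonlinear reaction-diffusion
#'     model of dialect coarsening.}
#'   \item{`allen_cahn_V`}{\eqn{\partial_t V = -\kappa(V - p(V)) +
#'     \tfrac{\sigma^2}{2}\Delta V} — the Allen-Cahn-type approximation,
#'     valid to leading order when \eqn{\kappa \gg \sigma^2}.}
#'   \item{`allen_cahn_P`}{\eqn{\partial_t P = -\kappa(V(P) - P) +
#'     \tfrac{\sigma^2}{2}\Delta P}, advanced in the probability variable
#'     `P` with `V(P)` the inverse choice map; the output is converted back
#'     to `V`.}
#' }
#'
#' @param V0 initial memory field (points x variants), rows in `K`.
#' @param config a [dialect_local_config()].
#' @param grid an `nk_grid` (must be periodic).
#' @param t_end horizon.
#' @param dt step; default \eqn{0.2\, h^2/\sigma^2}. A warning is issued
#'   when the explicit diffusion stability bound
#'   \eqn{\sigma^2 dt / (2h^2) \le 1/2} is violated.
#' @param method `"rk4"` or `"euler"`.
#' @param record_times times to record.
#' @return an `nk_trajectory` (kind `"dialect_local"`) of the `V` field.
#' @export
solve_local_pde <- function(V0, config, grid, t_end, dt = NULL,
                            method = c("rk4", "euler"), record_times = NULL) {
  stopifnot(inherits(config, "dialect_local_config"), inherits(grid, "nk_grid"))
  if (!grid$periodic) stop("local dialect PDEs require a periodic grid")
  if (!is.matrix(V0)) V0 <- matrix(V0, nrow = length(grid$points))
  h <- grid$h
  sig2 <- config$sigma^2
  if (is.null(dt)) {
    if (sig2 == 0) stop("`dt` must be given when sigma = 0")
    dt <- 0.2 * h^2 / sig2
  }
  if (sig2 > 0 && sig2 * dt / (2 * h^2) > 0.5) {
    warning("dt exceeds the explicit diffusion stability bound h^2/sigma^2; ",
            "expect instability")
  }
  lap <- function(Y) {
    n <- nrow(Y)
    (Y[c(2:n, 1L), , drop = FALSE] + Y[c(n, 1:(n - 1L)), , drop = FALSE] -
       2 * Y) / h^2
  }
  kap <- config$kappa
  a_exp <- config$alpha_exp
  rhs <- switch(config$variant,
    burridge = function(t, V) {
      pV <- choice_probabilities(V, a_exp)
      -kap * (V - pV) + sig2 / 2 * lap(pV)
    },
    allen_cahn_V = function(t, V) {
      -kap * (V - choice_probabilities(V, a_exp)) + sig2 / 2 * lap(V)
    },
    allen_cahn_P = function(t, P) {
      -kap * (inverse_choice_map(P, a_exp) - P) + sig2 / 2 * lap(P)
    }
  )
  y0 <- if (config$variant == "allen_cahn_P") {
    choice_probabilities(V0, a_exp)
  } else {
    V0
  }
  sol <- integrate_fixed(rhs, y0, t_end, dt, method, record_times,
                         post = project_simplex_rows)
  if (config$variant == "allen_cahn_P") {
    for (k in seq_along(sol$times)) {
      sol$states[, , k] <- inverse_choice_map(sol$states[, , k], a_exp)
    }
  }
  nk_trajectory(sol$times, sol$states, grid$points, "dialect_local",
                variant = config$variant, h = h)
}
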