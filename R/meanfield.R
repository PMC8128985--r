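# Mean-field level: Vlasov drift / Fokker-Planck coefficients assembled from
# an interaction rule, the particle (characteristics) solver for the Vlasov
# equation, and the generic monokinetic equation on a grid or node set.

#' Vlasov and Fokker-Planck coefficients of an interaction rule
#'
#' Assembles the mean-field drift
#' \deqn{W(z,\tilde z) = w(x,\tilde x)\Big(\int a\, d\nu_{z,\tilde z} +
#'   \int b\, d\nu_{\tilde z, z}\Big)}
#' and the diffusion matrix
#' \deqn{A(z,\tilde z) = \tfrac12 w(x,\tilde x)\Big(\int a\otimes a\,
#'   d\nu_{z,\tilde z} + \int b\otimes b\, d\nu_{\tilde z, z}\Big)}
#' from the rule's moment functions. With `rescaled = TRUE` (the default,
#' matching the small-increment asymptotics in which the mean-field models
#' are posed) both are divided by the rule's rescale factor, so that
#' mean-field time equals simulator time times that factor.
#'
#' The Fokker-Planck PDE itself is not solved here; `A` is exposed for
#' inspection and is tested for symmetry and positive semidefiniteness
#' against the rule's sampled second moments.
#'
#' @param rule an `nk_rule` exposing `mean_a`/`mean_b` (and, for `A`,
#'   `second_a`/`second_b`).
#' @param kernel an `nk_kernel`.
#' @param rescaled divide by the rule's rescale factor.
#' @param periodic use wrapped distances.
#' @return an object of class `nk_vlasov` with function fields
#'   `drift(x, v, x_tilde, v_tilde)` and `diffusion(x, v, x_tilde, v_tilde)`.
#' @export
vlasov_coefficients <- function(rule, kernel, rescaled = TRUE,
                                periodic = TRUE) {
  stopifnot(inherits(rule, "nk_rule"), inherits(kernel, "nk_kernel"))
  if (is.null(rule$mean_a) || is.null(rule$mean_b)) {
    stop("rule does not expose mean increments; Vlasov coefficients undefined")
  }
  fac <- if (rescaled) 1 / rule$rescale else 1
  drift <- function(x, v, x_tilde, v_tilde) {
    w <- evaluate_kernel(kernel, x, x_tilde, periodic)
    fac * w * (rule$mean_a(v, v_tilde) + rule$mean_b(v_tilde, v))
  }
  diffusion <- function(x, v, x_tilde, v_tilde) {
    if (is.null(rule$second_a) || is.null(rule$second_b)) {
      stop("rule does not expose second moments")
    }
    w <- evaluate_kernel(kernel, x, x_tilde, periodic)
    fac * 0.5 * w * (rule$second_a(v, v_tilde) + rule$second_b(v_tilde, v))
  }
  structure(
    list(rule = rule, kernel = kernel, rescaled = rescaled,
         periodic = periodic, drift = drift, diffusion = diffusion),
    class = "nk_vlasov"
  )
}

#' Mean-field particle cloud
#'
#' A weighted particle representation of the one-agent measure: fixed
#' positions, mutable states, masses summing to one. Used as the initial
#' datum for the characteristics (particle) solution of the Vlasov equation.
#'
#' @param x particle positions (fixed for all time).
#' @param states state matrix, one row per particle.
#' @param masses nonnegative masses; normalized to sum to one.
#' @return an object of class `nk_particles`.
#' @export
meanfield_particles <- function(x, states, masses = NULL) {
  if (!is.matrix(states)) states <- matrix(states, ncol = 1)
  P <- length(x)
  if (nrow(states) != P) stop("`x` and `states` disagree on particle count")
  if (is.null(masses)) masses <- rep(1 / P, P)
  if (length(masses) != P || any(masses < 0) || sum(masses) <= 0) {
    stop("masses must be nonnegative with positive total")
  }
  structure(
    list(x = as.numeric(x), states = unname(states),
         masses = masses / sum(masses)),
    class = "nk_particles"
  )
}

# Build the P x s drift field for a particle cloud; Wk is the kernel matrix
# w(x_p, x_q) (mass weights applied here, not in Wk).
particle_drift_rhs <- function(rule, Wk, masses, fac) {
  if (!is.null(rule$relaxation_g)) {
    g <- rule$relaxation_g
    kappa <- as.vector(Wk %*% masses)
    function(t, V) fac * (Wk %*% (masses * g(V)) - kappa * V)
  } else {
    function(t, V) {
      out <- matrix(0, nrow(V), ncol(V))
      for (p in seq_len(nrow(V))) {
        D <- rule$drift_terms(V[p, ], V)
        out[p, ] <- colSums(masses * Wk[p, ] * D)
      }
      fac * out
    }
  }
}

rule_projection <- function(rule) {
  switch(rule$state_space,
    simplex = function(Y) project_simplex_rows(Y),
    simplex_s = function(Y) project_simplex_rows(Y, m = ncol(Y) - 1L),
    NULL
  )
}

#' Solve the Vlasov equation along characteristics (particle method)
#'
#' Each particle's state follows the mass-weighted pairwise drift
#' \deqn{\frac{dV_p}{dt} = \sum_q m_q\, W(x_p, V_p, x_q, V_q),}
#' which is the method of characteristics for the drift-only kinetic
#' equation: positions and masses are constant, only states move. For
#' relaxation-type rules (drift \eqn{g(\tilde v) - v}) a vectorized matrix
#' path is used.
#'
#' @param particles an `nk_particles`.
#' @param coeffs an `nk_vlasov` from [vlasov_coefficients()].
#' @param t_end,dt horizon and step (in mean-field time when the
#'   coefficients are rescaled).
#' @param method `"rk4"` (default) or `"euler"`.
#' @param record_times times to record (default every step).
#' @param project renormalize simplex states after each step.
#' @return an `nk_trajectory` (`states` is particles x components x times)
#'   carrying `x` and `masses`.
#' @export
solve_vlasov_particles <- function(particles, coeffs, t_end, dt,
                                   method = c("rk4", "euler"),
                                   record_times = NULL, project = TRUE) {
  stopifnot(inherits(particles, "nk_particles"), inherits(coeffs, "nk_vlasov"))
  rule <- coeffs$rule
  Wk <- outer(particles$x, particles$x,
              function(a, b) evaluate_kernel(coeffs$kernel, a, b, coeffs$periodic))
  fac <- if (coeffs$rescaled) 1 else rule$rescale
  rhs <- particle_drift_rhs(rule, Wk, particles$masses, fac)
  post <- if (project) rule_projection(rule) else NULL
  sol <- integrate_fixed(rhs, particles$states, t_end, dt, method,
                         record_times, post)
  nk_trajectory(sol$times, sol$states, particles$x, "vlasov_particles",
                masses = particles$masses)
}

#' Solve the generic monokinetic equation
#'
#' Monokinetic solutions concentrate the mean-field measure at one state
#' \eqn{V(x, t)} per position over the stationary spatial density
#' \eqn{\eta}; the closed equation is
#' \deqn{\partial_t V(x,t) = \int W(x, V(x,t), \tilde x, V(\tilde x, t))\,
#'   \eta(d\tilde x),}
#' integrated here by the method of lines on the discretization carried by
#' `km` (its quadrature weights times the attached density supply
#' \eqn{\eta}).
#'
#' @param V0 state matrix, one row per discretization point of `km`.
#' @param km an `nk_kernel_matrix`; its `density` (default one) provides
#'   \eqn{\rho}.
#' @param rule an `nk_rule` (drift taken rescaled).
#' @param t_end,dt,method,record_times,project as in
#'   [solve_vlasov_particles()].
#' @param rescaled use rescaled (mean-field time) drift.
#' @return an `nk_trajectory` with kind `"monokinetic"`.
#' @export
solve_monokinetic <- function(V0, km, rule, t_end, dt,
                              method = c("rk4", "euler"),
                              record_times = NULL, project = TRUE,
                              rescaled = TRUE) {
  stopifnot(inherits(km, "nk_kernel_matrix"), inherits(rule, "nk_rule"))
  if (!is.matrix(V0)) V0 <- matrix(V0, ncol = 1)
  n <- nrow(km$matrix)
  if (nrow(V0) != n) stop("V0 does not match the discretization")
  rho <- if (is.null(km$density)) rep(1, n) else km$density
  fac <- if (rescaled) 1 else rule$rescale
  if (!is.null(rule$relaxation_g)) {
    g <- rule$relaxation_g
    kappa <- as.vector(km$matrix %*% rho)
    rhs <- function(t, V) fac * (km$matrix %*% (rho * g(V)) - kappa * V)
  } else {
    rhs <- function(t, V) {
      out <- matrix(0, n, ncol(V))
      for (i in seq_len(n)) {
        D <- rule$drift_terms(V[i, ], V)
        out[i, ] <- colSums(rho * km$matrix[i, ] * D)
      }
      fac * out
    }
  }
  post <- if (project) rule_projection(rule) else NULL
  sol <- integrate_fixed(rhs, V0, t_end, dt, method, record_times, post)
  nk_trajectory(sol$times, sol$states, km$points, "monokinetic",
                density = rho, quad_weights = km$quad_weights)
}
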