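# Shared fixture builders; everything is generated in code under fixed seeds.

random_simplex <- function(n, M, seed = NULL, shape = 2) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(n * M, shape), n, M)
  g / rowSums(g)
}

# Particle cloud with `per` particles on each of `n_nodes` equispaced nodes.
node_cloud <- function(n_nodes, per, M = 2, seed = 1) {
  x <- rep((seq_len(n_nodes) - 1) / n_nodes, each = per)
  meanfield_particles(x, random_simplex(length(x), M, seed))
}

# Toy linear relaxation rule dV/dt -> sum m_q w (V_q - V_p); closed-form
# solvable, used to pin the particle solver against analytics.
linear_relaxation_rule <- function(s = 1L) {
  interaction_rule(
    name = "linear_toy", state_space = "numeric",
    update_pair = function(a, b) list(active = a, passive = b + 0.1 * (a - b)),
    mean_a = function(va, vp) numeric(s),
    mean_b = function(va, vp) 0.1 * (va - vp),
    second_a = function(va, vp) matrix(0, s, s),
    second_b = function(va, vp) 0.1^2 * tcrossprod(va - vp),
    rescale = 0.1,
    relaxation_g = function(V) V
  )
}
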