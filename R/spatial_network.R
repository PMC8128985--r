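# Structural variable: grids, node networks, interaction kernels and the
# nonlocal operators built from them.

#' Uniform spatial grid on the periodic unit interval
#'
#' Node-centred grid on the half-open domain \eqn{\Omega = [0,1)} with
#' rectangle-rule quadrature weights equal to the grid spacing. Agents and
#' mean-field unknowns live on these points; the grid never changes during a
#' simulation.
#'
#' @param n number of grid points; spacing is `1/n`.
#' @param periodic logical; if `TRUE` distances wrap around the unit interval.
#' @return an object of class `nk_grid` with fields `points`, `h`,
#'   `periodic` and `quad_weights`.
#' @examples
#' g <- spatial_grid(100)
#' g$h            # 0.01
#' sum(g$quad_weights)  # 1
#' @export
spatial_grid <- function(n, periodic = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer")
  }
  n <- as.integer(n)
  h <- 1 / n
  structure(
    list(points = (seq_len(n) - 1L) * h, h = h, periodic = periodic,
         quad_weights = rep(h, n)),
    class = "nk_grid"
  )
}

#' Discrete node network
#'
#' A finite set of structural variables: `n_nodes` nodes carrying a
#' nonnegative interaction weight matrix \eqn{w_{k\ell}} and a nonnegative
#' node density \eqn{\rho_k}. Used by the social-construction model and by
#' any model posed on a discrete structure rather than a continuum grid.
#'
#' @param weights square nonnegative matrix of interaction weights.
#' @param rho nonnegative node densities (default all one).
#' @param x optional node coordinates (purely decorative for discrete models).
#' @param include_diagonal logical; whether self-weights `w_kk` take part in
#'   interaction sums. The default `FALSE` matches agent-pair sums over
#'   \eqn{i \neq j}; set `TRUE` for continuum-derived discretizations.
#' @return an object of class `nk_network`.
#' @export
node_network <- function(weights, rho = NULL, x = NULL, include_diagonal = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("`weights` must be square")
  if (any(weights < 0)) stop("network weights must be nonnegative")
  n <- nrow(weights)
  if (is.null(rho)) rho <- rep(1, n)
  if (length(rho) != n || any(rho < 0)) stop("`rho` must be nonnegative, one per node")
  if (!include_diagonal) diag(weights) <- 0
  structure(
    list(n_nodes = n, weights = weights, rho = as.numeric(rho), x = x,
         include_diagonal = include_diagonal),
    class = "nk_network"
  )
}

# ---- kernels ---------------------------------------------------------------

new_kernel <- function(form, ...) {
  structure(c(list(form = form), list(...)), class = "nk_kernel")
}

#' Interaction kernels
#'
#' Constructors for the interaction weight \eqn{w(x, \tilde x)} between two
#' structural positions. Four forms are provided:
#' \describe{
#'   \item{`triangular_kernel(amplitude, cutoff)`}{\eqn{w(x,y) =
#'     a\,(x_0 - d(x,y))_+} with amplitude \eqn{a} and cutoff \eqn{x_0};
#'     the kernel of the epidemic scenario.}
#'   \item{`constant_kernel(value)`}{\eqn{w \equiv} `value` (all-to-all
#'     coupling).}
#'   \item{`scaled_local_kernel(eps, profile)`}{\eqn{w(x,y) =
#'     \varepsilon^{-1} k(d(x,y)/\varepsilon)} with an even, nonnegative,
#'     unit-mass profile \eqn{k}; concentrates as \eqn{\varepsilon \to 0} and
#'     drives the local (reaction-diffusion) limits. Profiles: `"box"`
#'     (\eqn{k = 1/2} on \eqn{[-1,1]}, second moment \eqn{C = 1/3}),
#'     `"triangle"` (\eqn{k = (1-|y|)_+}, \eqn{C = 1/6}), `"epanechnikov"`
#'     (\eqn{k = \tfrac34 (1-y^2)_+}, \eqn{C = 1/5}).}
#'   \item{`matrix_kernel(weights)`}{discrete weights indexed by node; `x`
#'     and `y` passed to [evaluate_kernel()] are then node indices.}
#' }
#'
#' @param amplitude,cutoff triangular kernel rate amplitude and support
#'   radius; both must be nonnegative.
#' @param value constant kernel value.
#' @param eps locality scale \eqn{\varepsilon > 0}.
#' @param profile profile name, see above.
#' @param weights nonnegative square matrix for `matrix_kernel`.
#' @return an object of class `nk_kernel`.
#' @examples
#' k <- triangular_kernel(amplitude = 0.3, cutoff = 0.2)
#' evaluate_kernel(k, 0.1, 0.25)  # 0.3 * (0.2 - 0.15) = 0.015
#' @name kernels
NULL

#' @rdname kernels
#' @export
triangular_kernel <- function(amplitude, cutoff) {
  if (amplitude < 0 || cutoff < 0) stop("amplitude and cutoff must be nonnegative")
  new_kernel("triangular", amplitude = amplitude, cutoff = cutoff)
}

#' @rdname kernels
#' @export
constant_kernel <- function(value = 1) {
  if (value < 0) stop("kernel value must be nonnegative")
  new_kernel("constant", value = value)
}

#' @rdname kernels
#' @export
scaled_local_kernel <- function(eps,
                                profile = c("box", "triangle", "epanechnikov")) {
  if (eps < 0) stop("`eps` must be nonnegative")
  profile <- match.arg(profile)
  k_fun <- switch(profile,
    box = function(y) 0.5 * (abs(y) <= 1),
    triangle = function(y) pmax(1 - abs(y), 0),
    epanechnikov = function(y) 0.75 * pmax(1 - y^2, 0)
  )
  C <- switch(profile, box = 1 / 3, triangle = 1 / 6, epanechnikov = 1 / 5)
  new_kernel("scaled_local", eps = eps, profile = profile,
             base_profile = k_fun, second_moment = C)
}

#' @rdname kernels
#' @export
matrix_kernel <- function(weights) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("kernel weights must be nonnegative")
  new_kernel("matrix", weights = weights)
}

periodic_distance <- function(x, y, periodic = TRUE) {
  d <- abs(x - y)
  if (periodic) pmin(d, 1 - d) else d
}

#' Evaluate an interaction kernel
#'
#' Computes \eqn{w(x, y)}, vectorized over positions. With `periodic = TRUE`
#' the distance is \eqn{d(x,y) = \min(|x-y|, 1-|x-y|)} on the unit interval.
#' All provided forms are symmetric in `(x, y)` and nonnegative.
#'
#' @param kernel an `nk_kernel`.
#' @param x,y positions in \eqn{[0,1)} (node indices for a matrix kernel).
#' @param periodic logical, use the wrapped distance.
#' @return nonnegative rate(s).
#' @export
evaluate_kernel <- function(kernel, x, y, periodic = TRUE) {
  stopifnot(inherits(kernel, "nk_kernel"))
  switch(kernel$form,
    constant = rep(kernel$value, length.out = max(length(x), length(y))),
    triangular = {
      d <- periodic_distance(x, y, periodic)
      kernel$amplitude * pmax(kernel$cutoff - d, 0)
    },
    scaled_local = {
      d <- periodic_distance(x, y, periodic)
      if (kernel$eps == 0) stop("scaled_local kernel with eps = 0 cannot be evaluated pointwise")
      kernel$base_profile(d / kernel$eps) / kernel$eps
    },
    matrix = kernel$weights[cbind(as.integer(x), as.integer(y))],
    stop("unknown kernel form: ", kernel$form)
  )
}

#' Local-limit diffusion scale of a concentrating kernel
#'
#' For the scaled local kernel \eqn{w = \varepsilon^{-1} k(\cdot/\varepsilon)}
#' the nonlocal operator approaches \eqn{\frac{C\varepsilon^2}{2}\Delta} with
#' \eqn{C} the second moment of \eqn{k}; the induced diffusion length is
#' \eqn{\sigma = \sqrt{C}\,\varepsilon}.
#'
#' @param kernel an `nk_kernel` of form `scaled_local`.
#' @return the scalar \eqn{\sigma}.
#' @export
local_limit_sigma <- function(kernel) {
  stopifnot(inherits(kernel, "nk_kernel"))
  if (kernel$form != "scaled_local") {
    stop("local_limit_sigma is only defined for scaled_local kernels")
  }
  sqrt(kernel$second_moment) * kernel$eps
}

# ---- kernel discretization -------------------------------------------------

#' Discretize a kernel on a grid or node network
#'
#' Builds the quadrature matrix \eqn{W_{ij} = w(x_i, x_j)\, h_j} (rectangle
#' rule), its row integrals \eqn{\alpha(x_i) = \int w(x_i,\tilde x)d\tilde x}
#' and, when a density is attached, the stationary coefficient
#' \eqn{\kappa(x_i) = \int w(x_i, \tilde x)\rho(\tilde x) d\tilde x}.
#'
#' @param kernel an `nk_kernel`.
#' @param grid an `nk_grid`, or an `nk_network` (whose weights then serve as
#'   the kernel values with unit quadrature weights).
#' @param density optional density values \eqn{\rho} per point; defaults to
#'   the network's `rho` for networks, otherwise none.
#' @param include_diagonal logical; include the \eqn{\tilde x = x} entry.
#'   Continuum integrals include it, agent-pair sums exclude it.
#' @return an object of class `nk_kernel_matrix` with fields `matrix`,
#'   `row_integral`, `kappa` (or `NULL`), `points`, `quad_weights`, `density`.
#' @export
discretize_kernel <- function(kernel, grid, density = NULL,
                              include_diagonal = TRUE) {
  if (inherits(grid, "nk_network")) {
    W <- grid$weights
    if (!include_diagonal) diag(W) <- 0
    if (is.null(density)) density <- grid$rho
    pts <- if (is.null(grid$x)) seq_len(grid$n_nodes) else grid$x
    qw <- rep(1, grid$n_nodes)
  } else {
    stopifnot(inherits(grid, "nk_grid"))
    pts <- grid$points
    qw <- grid$quad_weights
    W <- outer(pts, pts, function(a, b) evaluate_kernel(kernel, a, b, grid$periodic))
    if (!include_diagonal) diag(W) <- 0
    W <- sweep(W, 2L, qw, "*")
  }
  kappa <- if (!is.null(density)) as.vector(W %*% density) else NULL
  structure(
    list(matrix = W, row_integral = rowSums(W), kappa = kappa,
         points = pts, quad_weights = qw, density = density),
    class = "nk_kernel_matrix"
  )
}

#' Nonlocal Laplacian
#'
#' Applies \eqn{\Delta_w \varphi(x) = \int w(x,\tilde x)(\varphi(\tilde x) -
#' \varphi(x))\, d\tilde x}, the diffusion-like operator induced by an
#' interaction kernel. Annihilates constants; for symmetric kernels the
#' quadrature-weighted sum of the output vanishes for any field.
#'
#' @param km an `nk_kernel_matrix`.
#' @param field values on the discretization points (vector, or matrix with
#'   one column per state component).
#' @return object of the same shape as `field`.
#' @export
nonlocal_laplacian <- function(km, field) {
  stopifnot(inherits(km, "nk_kernel_matrix"))
  if (is.matrix(field)) {
    if (nrow(field) != nrow(km$matrix)) stop("field size does not match kernel matrix")
    km$matrix %*% field - km$row_integral * field
  } else {
    if (length(field) != nrow(km$matrix)) stop("field size does not match kernel matrix")
    as.vector(km$matrix %*% field) - km$row_integral * field
  }
}

# ---- network CSV interfaces ------------------------------------------------

#' Read and write node networks as CSV
#'
#' Edge lists have columns `i, j, weight` (1-based node indices); node tables
#' have columns `i, x, rho`. Missing edges have weight zero.
#'
#' @param edges_path,nodes_path CSV file paths.
#' @param net an `nk_network`.
#' @return `read_node_network` returns an `nk_network`; the writer returns
#'   the two paths invisibly.
#' @export
read_node_network <- function(edges_path, nodes_path) {
  edges <- utils::read.csv(edges_path)
  nodes <- utils::read.csv(nodes_path)
  n <- nrow(nodes)
  W <- matrix(0, n, n)
  W[cbind(edges$i, edges$j)] <- edges$weight
  node_network(W, rho = nodes$rho, x = nodes$x, include_diagonal = TRUE)
}

#' @rdname read_node_network
#' @export
write_node_network <- function(net, edges_path, nodes_path) {
  stopifnot(inherits(net, "nk_network"))
  idx <- which(net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], weight = net$weights[idx])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  x <- if (is.null(net$x)) rep(NA_real_, net$n_nodes) else net$x
  nodes <- data.frame(i = seq_len(net$n_nodes), x = x, rho = net$rho)
  utils::write.csv(edges, edges_path, row.names = FALSE)
  utils::write.csv(nodes, nodes_path, row.names = FALSE)
  invisible(c(edges_path, nodes_path))
}
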