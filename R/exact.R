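#' Exact flat-metric solver for discrete measures
#'
#' Computes \eqn{\rho_F(\mu,\nu) = \sup_{\|f\|_{BL} \le 1} \int f \, d(\mu-\nu)}
#' exactly for discrete nonnegative measures. For atomic measures the supremum
#' is attained on the union support, so the dual is a finite LP; it is solved
#' through its primal equivalent, a balanced transportation problem with
#' ground cost \eqn{\min(\|x-y\|, 2)} augmented by a dummy source/sink pair at
#' unit cost that prices mass creation and deletion (the transport-versus-
#' deletion decomposition of the flat metric). An optimal admissible test
#' function is recovered from the optimal node potentials by a clipped
#' c-transform, so the returned `test_values` satisfy \eqn{|f| \le 1}, the
#' Lipschitz constraints, and \eqn{\sum_k f(x_k)(\mu-\nu)(x_k) = value}.
#'
#' @param mu,nu `discrete_measure` objects of equal dimension.
#' @return An object of class `exact_result`: list with `value` (the flat
#'   distance), `test_values` (optimal f on the stacked support, mu atoms
#'   first), `support` (the stacked support matrix), `status`.
#' @examples
#' mu <- make_dirac(0, 1); nu <- make_dirac(3, 1)
#' flat_exact(mu, nu)$value # 2: deletion + creation beats transport beyond 2
#' @seealso [wasserstein_exact()], [tv_distance()], [one_point_flat()]
#' @export
flat_exact <- function(mu, nu) {
  stopifnot_measure(mu); stopifnot_measure(nu)
  check_same_dim(mu, nu)
  p <- n_atoms(mu); q <- n_atoms(nu)
  tvm <- tv_norm(mu); tvn <- tv_norm(nu)
  support <- rbind(mu$points, nu$points)
  if (p + q == 0L) {
    return(new_exact_result(0, numeric(0), support))
  }
  # sources: mu atoms + dummy (creation); sinks: nu atoms + dummy (deletion)
  dmat <- if (p > 0L && q > 0L) pairwise_distances(mu$points, nu$points) else
    matrix(0, p, q)
  cost <- rbind(cbind(pmin(dmat, 2), rep(1, p)),
                c(rep(1, q), 0))
  res <- mcf_transport(cost, c(mu$weights, tvn), c(nu$weights, tvm))
  # dual potentials -> optimal f via clipped c-transform from the nu side
  shift <- res$potential_source[p + 1L]
  if (q > 0L) {
    b <- shift - res$potential_sink[seq_len(q)]
    f <- function(z) {
      dz <- pmin(pairwise_distances(z, nu$points), 2)
      pmax(-1, pmin(1, apply(dz + rep(b, each = nrow(z)), 1L, min)))
    }
    tv_vals <- if (nrow(support)) f(support) else numeric(0)
  } else {
    tv_vals <- rep(1, nrow(support))
  }
  new_exact_result(res$cost, tv_vals, support)
}

new_exact_result <- function(value, test_values, support, status = "optimal") {
  structure(list(value = value, test_values = test_values,
                 support = support, status = status),
            class = "exact_result")
}

#' @export
print.exact_result <- function(x, ...) {
  cat(sprintf("<exact_result: value %.8g, %d support points, status %s>\n",
              x$value, nrow(x$support), x$status))
  invisible(x)
}

#' Exact Wasserstein-1 distance for equal-mass discrete measures
#'
#' Solves the balanced transportation problem with Euclidean ground cost. The
#' W1 dual drops the sup-norm bound of the flat metric, so it is only defined
#' when the total masses agree; with `normalize = TRUE` both measures are
#' first rescaled to unit mass (separate normalization).
#'
#' @param mu,nu `discrete_measure` objects of equal dimension.
#' @param normalize if `TRUE`, rescale each measure to total mass 1 first.
#' @return An `exact_result`; `value` is \eqn{W_1}.
#' @export
wasserstein_exact <- function(mu, nu, normalize = FALSE) {
  stopifnot_measure(mu); stopifnot_measure(nu)
  check_same_dim(mu, nu)
  tvm <- tv_norm(mu); tvn <- tv_norm(nu)
  if (normalize) {
    if (tvm == 0 || tvn == 0) stop("cannot normalize an empty measure")
    mu <- measure_scale(mu, 1 / tvm)
    nu <- measure_scale(nu, 1 / tvn)
    tvm <- tvn <- 1
  } else if (abs(tvm - tvn) > 1e-8 * max(1, tvm, tvn)) {
    stop("W1 requires equal total masses (conservative problems only); ",
         "pass normalize = TRUE to compare the separately normalized measures")
  }
  support <- rbind(mu$points, nu$points)
  if (tvm == 0) return(new_exact_result(0, rep(0, nrow(support)), support))
  dmat <- pairwise_distances(mu$points, nu$points)
  res <- mcf_transport(dmat, mu$weights, nu$weights)
  b <- -res$potential_sink
  f <- function(z) {
    dz <- pairwise_distances(z, nu$points)
    apply(dz + rep(b, each = nrow(z)), 1L, min)
  }
  new_exact_result(res$cost, f(support), support)
}

#' Total variation distance between discrete measures
#'
#' Sum over the union support of the absolute weight differences (the Jordan
#' decomposition of \eqn{\mu - \nu} for atomic measures). Blind to geometry:
#' two distinct unit Diracs are always at TV distance 2.
#'
#' @param mu,nu `discrete_measure` objects of equal dimension.
#' @return Nonnegative scalar.
#' @export
tv_distance <- function(mu, nu) {
  stopifnot_measure(mu); stopifnot_measure(nu)
  check_same_dim(mu, nu)
  key_m <- apply(mu$points, 1L, paste, collapse = "\r")
  key_n <- apply(nu$points, 1L, paste, collapse = "\r")
  keys <- union(key_m, key_n)
  wm <- stats::setNames(rep(0, length(keys)), keys)
  wn <- wm
  wm[key_m] <- mu$weights
  wn[key_n] <- nu$weights
  sum(abs(wm - wn))
}

#' Closed-form flat distance for the Dirac sphere configuration
#'
#' Flat distance between \eqn{\mu = m\,\delta_0} and \eqn{\nu} consisting of
#' total mass n placed anywhere on the sphere of radius r around the origin:
#' \deqn{\rho_F = |m - n| + \min(m, n)\,\min(r, 2).}
#' The mass imbalance must always be created/deleted at unit cost; the shared
#' mass is transported while the radius is below the crossover separation 2
#' and created/deleted beyond it. Independent of dimension and of where on
#' the sphere the mass sits.
#'
#' @param m,n nonnegative masses of the central and spherical measure.
#' @param r nonnegative sphere radius.
#' @return The flat distance.
#' @export
dirac_sphere_flat <- function(m, n, r) {
  if (any(c(m, n, r) < 0)) stop("m, n, r must be nonnegative")
  abs(m - n) + pmin(m, n) * pmin(r, 2)
}

#' Closed-form flat distance between a measure and a single Dirac
#'
#' Flat distance between \eqn{\mu} (atoms with weights \eqn{w_i} at radii
#' \eqn{r_i} from `center`) and \eqn{\nu = m\,\delta_{center}}. The optimal
#' test function takes some value \eqn{a \in [-1, 1]} at the center and grows
#' at unit slope until it saturates at 1, so
#' \deqn{\rho_F = \max_{a \in [-1,1]} \sum_i w_i \min(1, a + r_i) - m a,}
#' a concave piecewise-linear problem solved exactly by scanning the
#' breakpoints \eqn{a \in \{-1, 1\} \cup \{1 - r_i\}}.
#'
#' @param mu a `discrete_measure`.
#' @param center coordinate vector of the Dirac's location.
#' @param m nonnegative Dirac mass.
#' @return The flat distance; equals `flat_exact` on the same instance.
#' @export
one_point_flat <- function(mu, center, m) {
  stopifnot_measure(mu)
  if (m < 0) stop("m must be nonnegative")
  if (length(center) != measure_dim(mu) && n_atoms(mu) > 0L)
    stop("center dimension mismatch")
  if (n_atoms(mu) == 0L) return(m)
  r <- sqrt(colSums((t(mu$points) - as.numeric(center))^2))
  breaks <- unique(pmin(1, pmax(-1, c(-1, 1, 1 - r))))
  vals <- vapply(breaks,
                 function(a) sum(mu$weights * pmin(1, a + r)) - m * a,
                 numeric(1))
  max(vals)
}

#' Brute-force check of the transport/deletion decomposition
#'
#' Minimizes, over partial transport plans discretized on a weight grid, the
#' decomposition cost: transported mass pays Euclidean distance, untransported
#' mass of either measure pays its TV norm (deletion/creation at unit cost).
#' As the grid refines this converges to the flat distance. Combinatorial
#' oracle only: the union support may hold at most 4 atoms.
#'
#' @param mu,nu `discrete_measure` objects of equal dimension.
#' @param grid_steps number of grid levels per plan entry.
#' @return List with `value` (minimal discretized cost) and
#'   `transported_mass` (total mass moved at the optimum).
#' @export
decomposition_bruteforce <- function(mu, nu, grid_steps = 20) {
  stopifnot_measure(mu); stopifnot_measure(nu)
  check_same_dim(mu, nu)
  p <- n_atoms(mu); q <- n_atoms(nu)
  tvm <- tv_norm(mu); tvn <- tv_norm(nu)
  if (p + q > 4L) stop("brute-force oracle limited to <= 4 support atoms")
  if (p == 0L || q == 0L) {
    return(list(value = tvm + tvn, transported_mass = 0))
  }
  d <- pairwise_distances(mu$points, nu$points)
  unit <- outer(mu$weights, nu$weights, pmin) / grid_steps
  grids <- rep(list(0:grid_steps), p * q)
  combos <- as.matrix(do.call(expand.grid, grids))
  gamma <- combos %*% diag(as.numeric(unit), nrow = p * q) # row-major over (i,j)
  # feasibility: row sums within supplies, column sums within demands
  ok <- rep(TRUE, nrow(gamma))
  idx <- matrix(seq_len(p * q), p, q)
  for (i in seq_len(p)) {
    ok <- ok & rowSums(gamma[, idx[i, ], drop = FALSE]) <= mu$weights[i] + 1e-12
  }
  for (j in seq_len(q)) {
    ok <- ok & rowSums(gamma[, idx[, j], drop = FALSE]) <= nu$weights[j] + 1e-12
  }
  gamma <- gamma[ok, , drop = FALSE]
  transported <- rowSums(gamma)
  costs <- gamma %*% as.numeric(d) + (tvm - transported) + (tvn - transported)
  k <- which.min(costs)
  list(value = costs[k], transported_mass = transported[k])
}
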