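#' Solver configuration for the constrained graph-TV model
#'
#' Constants for the Douglas-Rachford iteration solving
#' \deqn{\min_u \|u\|_{TV} \quad \mathrm{s.t.} \quad \|u - u_0\|_2 \le \varepsilon.}
#'
#' @param ball_radius Radius \eqn{\varepsilon} of the L2 fidelity ball.
#' @param gamma Positive proximal scale \eqn{\gamma}.
#' @param relax Relaxation step \eqn{\lambda_n}, constant over
#'   iterations, constrained to `[relax_margin, 2 - relax_margin]`.
#' @param relax_margin Margin keeping the relaxation step away from the
#'   endpoints of `(0, 2)`; in `[0, 1)`.
#' @param tol Relative-change stopping tolerance for the outer loop.
#' @param max_iter Maximum number of outer iterations.
#' @param inner_iter Iteration cap for the inner TV-proximal solver.
#' @param inner_tol Relative duality-gap tolerance for the inner solver.
#' @return An object of class `npgtv_solver_config`.
#' @export
solver_config <- function(ball_radius, gamma = 0.1, relax = 1.0,
                          relax_margin = 0.01, tol = 1e-4, max_iter = 200L,
                          inner_iter = 50L, inner_tol = 1e-6) {
  if (!is.numeric(ball_radius) || length(ball_radius) != 1L ||
      !is.finite(ball_radius) || ball_radius < 0) {
    stop("`ball_radius` must be a nonnegative number", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma <= 0 || !is.finite(gamma)) {
    stop("`gamma` must be positive", call. = FALSE)
  }
  if (!is.numeric(relax_margin) || relax_margin < 0 || relax_margin >= 1) {
    stop("`relax_margin` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(relax) || relax < relax_margin ||
      relax > 2 - relax_margin) {
    stop("`relax` must lie in [relax_margin, 2 - relax_margin]",
         call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0 || !is.numeric(inner_tol) ||
      inner_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (!is.numeric(max_iter) || max_iter < 1 || !is.numeric(inner_iter) ||
      inner_iter < 1) {
    stop("iteration counts must be positive integers", call. = FALSE)
  }
  structure(list(ball_radius = ball_radius, gamma = gamma, relax = relax,
                 relax_margin = relax_margin, tol = tol,
                 max_iter = as.integer(max_iter),
                 inner_iter = as.integer(inner_iter),
                 inner_tol = inner_tol),
            class = "npgtv_solver_config")
}

#' @export
print.npgtv_solver_config <- function(x, ...) {
  cat(sprintf(
    "<npgtv_solver_config> eps = %g, gamma = %g, relax = %g, tol = %g, max_iter = %d\n",
    x$ball_radius, x$gamma, x$relax, x$tol, x$max_iter))
  invisible(x)
}

#' Projection onto an L2 ball
#'
#' Proximal operator of the indicator of
#' \eqn{\{u : \|u - c\|_2 \le r\}}: points inside the ball are returned
#' unchanged, points outside are radially scaled onto the sphere.
#'
#' @param y Numeric vector to project.
#' @param center Ball center, same length as `y`.
#' @param radius Nonnegative radius.
#' @return The projected vector, always feasible.
#' @export
project_l2_ball <- function(y, center, radius) {
  if (length(y) != length(center)) {
    stop("`y` and `center` must have the same length", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 0) {
    stop("`radius` must be a nonnegative number", call. = FALSE)
  }
  d <- sqrt(sum((y - center)^2))
  if (d <= radius) {
    y
  } else {
    center + radius * (y - center) / d
  }
}

#' Proximal operator of the graph total variation
#'
#' Approximately solves
#' \deqn{\mathrm{prox}_{\gamma TV}(y) = \arg\min_u \tfrac12 \|u - y\|_2^2 + \gamma \|u\|_{TV}}
#' with an accelerated primal-dual (Chambolle-Pock) scheme on the
#' weighted incidence operator: the dual variable carries one value per
#' directed edge, constrained to a \eqn{\gamma}-radius Euclidean ball
#' per node's gradient block. The quadratic term is 1-strongly convex,
#' so the accelerated step-size schedule gives \eqn{O(1/k^2)}
#' convergence; iteration stops once the duality gap certifies the
#' objective is within `inner_tol * (1 + |objective|)` of the optimum,
#' or after `inner_iter` iterations.
#'
#' @param y Numeric graph signal.
#' @param gamma Nonnegative proximal weight; 0 returns `y` unchanged.
#' @param graph A `npgtv_graph`.
#' @param inner_iter Maximum iterations.
#' @param inner_tol Relative duality-gap tolerance.
#' @return The proximal point, same length as `y`.
#' @export
prox_graph_tv <- function(y, gamma, graph, inner_iter = 2000L,
                          inner_tol = 1e-8) {
  check_signal(y, graph)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("`gamma` must be a nonnegative number", call. = FALSE)
  }
  prox_tv_pd(y, gamma, graph, inner_iter, inner_tol)$u
}

# accelerated Chambolle-Pock on min_u 0.5||u - y||^2 + gamma * TV(u);
# q0 warm-starts the dual (one value per directed edge); returns the
# primal point, final dual, and certified duality gap
prox_tv_pd <- function(y, gamma, graph, inner_iter, inner_tol, q0 = NULL) {
  nd <- length(graph$src)
  if (gamma == 0 || nd == 0L || graph$opnorm == 0) {
    return(list(u = y, q = numeric(nd), gap = 0))
  }
  L <- graph$opnorm
  tau <- 0.99 / L
  sig <- 0.99 / L
  Kop <- graph$K
  grp <- graph$src
  u <- y
  ubar <- y
  q <- if (is.null(q0)) numeric(nd) else q0
  Ky <- as.vector(Kop %*% y)
  gap_every <- 10L
  gap <- Inf
  for (it in seq_len(inner_iter)) {
    q <- q + sig * as.vector(Kop %*% ubar)
    # project each node's dual block onto the gamma-ball
    gn <- rowsum(q^2, grp)
    norms <- sqrt(gn[, 1L])
    scale <- gamma / pmax(gamma, norms)
    full <- rep(1, graph$n)
    full[as.integer(rownames(gn))] <- scale
    q <- q * full[grp]
    Ktq <- as.vector(Matrix::crossprod(Kop, q))
    u_new <- (u - tau * Ktq + tau * y) / (1 + tau)
    theta <- 1 / sqrt(1 + 2 * tau)
    tau <- tau * theta
    sig <- sig / theta
    ubar <- u_new + theta * (u_new - u)
    u <- u_new
    if (it %% gap_every == 0L || it == inner_iter) {
      primal <- 0.5 * sum((u - y)^2) + gamma * tv_value(u, graph)
      dual <- sum(q * Ky) - 0.5 * sum(Ktq^2)
      gap <- primal - dual
      if (gap <= inner_tol * (1 + abs(primal))) break
    }
  }
  list(u = u, q = q, gap = gap)
}

#' Heuristic fidelity-ball radius from the noise level
#'
#' For i.i.d. Gaussian noise of standard deviation \eqn{\sigma/255} per
#' pixel, the expected squared norm of the noise over `n` pixels is
#' \eqn{n (\sigma/255)^2}; the radius is set to
#' \eqn{\tau \cdot (\sigma/255) \sqrt{n}} so that, at `tau = 1`, the
#' clean image is expected to sit on the boundary of the ball.
#'
#' @param noise A [noise_model()].
#' @param n Number of pixels.
#' @param tau Positive scale factor.
#' @return A nonnegative radius.
#' @export
ball_radius_heuristic <- function(noise, n, tau = 1.0) {
  stopifnot(inherits(noise, "npgtv_noise"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be positive", call. = FALSE)
  }
  tau * (noise$sigma / 255) * sqrt(n)
}

#' Douglas-Rachford splitting for the constrained graph-TV model
#'
#' Minimizes the graph total variation over the L2 fidelity ball
#' \eqn{\|u - u_0\|_2 \le \varepsilon} by Douglas-Rachford splitting
#' between the ball indicator (proximal operator: radial projection)
#' and the TV term (proximal operator: [prox_graph_tv()]):
#' \deqn{x_n = P_{ball}(y_n), \qquad
#'       y_{n+1} = y_n + \lambda_n (\mathrm{prox}_{\gamma TV}(2 x_n - y_n) - x_n)}
#' starting from \eqn{y_0 = u_0}, stopping when the relative change
#' \eqn{\|y_{n+1} - y_n\| / \|y_{n+1}\|} falls below `tol` (absolute
#' change if the denominator vanishes) or after `max_iter` iterations.
#' The returned signal is the *feasible* iterate
#' \eqn{x = P_{ball}(y)}, so the fidelity constraint holds exactly.
#'
#' @param u0 Observed graph signal (ball center).
#' @param graph A `npgtv_graph` with as many nodes as `u0` has entries.
#' @param config A [solver_config()].
#' @return A list with `x` (the feasible solution) and `state`, a list
#'   of class `npgtv_drs_state` carrying `y`, `iterations`, `converged`,
#'   `rel_change` and the per-iteration `tv_trace` / `rel_trace`.
#' @export
drs_solve <- function(u0, graph, config) {
  check_signal(u0, graph)
  stopifnot(inherits(config, "npgtv_solver_config"))
  eps <- config$ball_radius
  if (eps == 0) {
    # the ball is the single point u0
    st <- structure(list(y = u0, iterations = 0L, converged = TRUE,
                         rel_change = 0,
                         tv_trace = tv_value(u0, graph),
                         rel_trace = numeric(0)),
                    class = "npgtv_drs_state")
    return(list(x = u0, state = st))
  }
  y <- u0
  tvs <- numeric(0)
  rels <- numeric(0)
  converged <- FALSE
  rel <- Inf
  it <- 0L
  qwarm <- NULL  # warm-started dual of the TV prox across outer iterations
  for (it in seq_len(config$max_iter)) {
    x <- project_l2_ball(y, u0, eps)
    pz <- prox_tv_pd(2 * x - y, config$gamma, graph,
                     inner_iter = config$inner_iter,
                     inner_tol = config$inner_tol, q0 = qwarm)
    z <- pz$u
    qwarm <- pz$q
    y_new <- y + config$relax * (z - x)
    if (!all(is.finite(y_new))) {
      stop(sprintf("non-finite values in Douglas-Rachford iterate at iteration %d",
                   it), call. = FALSE)
    }
    ny <- sqrt(sum(y_new^2))
    dy <- sqrt(sum((y_new - y)^2))
    rel <- if (ny > 0) dy / ny else dy
    tvs <- c(tvs, tv_value(x, graph))
    rels <- c(rels, rel)
    y <- y_new
    if (rel < config$tol) {
      converged <- TRUE
      break
    }
  }
  x <- project_l2_ball(y, u0, eps)
  st <- structure(list(y = y, iterations = it, converged = converged,
                       rel_change = rel, tv_trace = tvs, rel_trace = rels),
                  class = "npgtv_drs_state")
  list(x = x, state = st)
}

#' @export
print.npgtv_drs_state <- function(x, ...) {
  cat(sprintf("<npgtv_drs_state> %d iterations, converged = %s, rel_change = %.3g\n",
              x$iterations, x$converged, x$rel_change))
  invisible(x)
}
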