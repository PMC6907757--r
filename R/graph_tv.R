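#' Edge derivative of a graph signal
#'
#' Directional derivative of `f` along the edge `(i, j)`:
#' \eqn{\sqrt{W_{ij}} (f(j) - f(i))}. The square-root convention makes
#' the local variation at a node equal the Euclidean norm of its edge
#' derivatives.
#'
#' @param f Numeric graph signal, one value per node.
#' @param graph A `npgtv_graph`.
#' @param i,j Endpoints of an existing edge.
#' @return A scalar, antisymmetric under swapping `i` and `j`.
#' @export
edge_derivative <- function(f, graph, i, j) {
  check_signal(f, graph)
  w <- graph$W[i, j]
  if (w == 0) {
    stop(sprintf("(%d, %d) is not an edge of the graph", i, j),
         call. = FALSE)
  }
  sqrt(w) * (f[j] - f[i])
}

check_signal <- function(f, graph) {
  stopifnot(inherits(graph, "npgtv_graph"))
  if (!is.numeric(f) || length(f) != graph$n) {
    stop("signal length must equal the graph's node count", call. = FALSE)
  }
  if (!all(is.finite(f))) {
    stop("signal values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

# squared local variation for all nodes: sum_j W_ij (f_i - f_j)^2
local_variation_sq <- function(f, graph) {
  out <- numeric(graph$n)
  if (length(graph$src) == 0L) return(out)
  diff2 <- graph$w_dir * (f[graph$src] - f[graph$dst])^2
  agg <- rowsum(diff2, graph$src)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Local variation of a graph signal
#'
#' The local variation at node `i` is
#' \eqn{\|\nabla_i f\|_2 = [\sum_{j \in N_i} W_{ij} (f(i)-f(j))^2]^{1/2}},
#' a per-node measure of signal roughness.
#'
#' @param f Numeric graph signal.
#' @param graph A `npgtv_graph`.
#' @param i Optional node index; if omitted, the full length-`n` vector
#'   of local variations is returned.
#' @return Nonnegative scalar or vector.
#' @export
local_variation <- function(f, graph, i = NULL) {
  check_signal(f, graph)
  lv <- sqrt(local_variation_sq(f, graph))
  if (is.null(i)) lv else lv[i]
}

#' Graph total variation
#'
#' The total variation of a signal on a weighted graph is the sum over
#' nodes of the local variation,
#' \eqn{\|f\|_{TV} = \sum_i \|\nabla_i f\|_2}. It is zero exactly when
#' the signal is constant on every connected component.
#'
#' @param f Numeric graph signal.
#' @param graph A `npgtv_graph`.
#' @return A list of class `npgtv_variation` with `tv` (scalar) and
#'   `local_variations` (length-`n` vector).
#' @export
total_variation <- function(f, graph) {
  check_signal(f, graph)
  lv <- sqrt(local_variation_sq(f, graph))
  structure(list(tv = sum(lv), local_variations = lv),
            class = "npgtv_variation")
}

#' @export
print.npgtv_variation <- function(x, ...) {
  cat(sprintf("<npgtv_variation> tv = %g over %d nodes\n",
              x$tv, length(x$local_variations)))
  invisible(x)
}

# bare scalar TV, used in inner loops
tv_value <- function(f, graph) {
  sum(sqrt(local_variation_sq(f, graph)))
}

#' Discrete p-Dirichlet form
#'
#' Graph smoothness family \eqn{S_p(f) = \frac1p \sum_i \|\nabla_i f\|_2^p}
#' for \eqn{p \ge 1}; at `p = 1` it coincides with the graph total
#' variation, at `p = 2` with the graph Laplacian quadratic form.
#'
#' @param f Numeric graph signal.
#' @param graph A `npgtv_graph`.
#' @param p Exponent, at least 1.
#' @return Nonnegative scalar.
#' @export
p_dirichlet <- function(f, graph, p) {
  check_signal(f, graph)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1) {
    stop("`p` must be a number >= 1", call. = FALSE)
  }
  lv <- sqrt(local_variation_sq(f, graph))
  sum(lv^p) / p
}
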