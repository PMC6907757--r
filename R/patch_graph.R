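#' Patch-graph construction parameters
#'
#' Settings for turning an image into a non-local patch graph: an
#' \eqn{s \times s} patch around each pixel is vectorized and augmented
#' with its center coordinates scaled by the spatial-constraint weight
#' \eqn{\lambda}; nodes are then joined to their K nearest neighbours in
#' this feature space and weighted by a Gaussian kernel
#' \eqn{w(i,j) = \exp(-d^2(i,j)/\sigma^2)}.
#'
#' @param s Odd patch side length in pixels, at least 3.
#' @param k Number of nearest neighbours per node, at least 1.
#' @param lambda_spatial Nonnegative weight \eqn{\lambda} multiplying the
#'   appended patch-center coordinates; 0 recovers a purely
#'   intensity-based non-local graph.
#' @param sigma_kernel Gaussian kernel bandwidth \eqn{\sigma}, or
#'   `"auto"` to derive it from the noise level via
#'   [auto_kernel_bandwidth()].
#' @param coord_mode `"raw"` appends \eqn{\lambda \cdot i_{row}},
#'   \eqn{\lambda \cdot i_{col}} with 0-based pixel indices;
#'   `"normalized"` first divides the indices by \eqn{m-1}, \eqn{l-1} so
#'   the coordinates share the gray-level range.
#' @return An object of class `npgtv_patch_config`.
#' @export
patch_config <- function(s = 5L, k = 5L, lambda_spatial = 0.05,
                         sigma_kernel = "auto",
                         coord_mode = c("raw", "normalized")) {
  coord_mode <- match.arg(coord_mode)
  if (!is.numeric(s) || length(s) != 1L || s != round(s) || s < 3 ||
      s %% 2 == 0) {
    stop("patch side `s` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(lambda_spatial) || length(lambda_spatial) != 1L ||
      !is.finite(lambda_spatial) || lambda_spatial < 0) {
    stop("`lambda_spatial` must be a nonnegative number", call. = FALSE)
  }
  if (is.character(sigma_kernel)) {
    if (!identical(sigma_kernel, "auto")) {
      stop("`sigma_kernel` must be a positive number or \"auto\"",
           call. = FALSE)
    }
  } else if (!is.numeric(sigma_kernel) || length(sigma_kernel) != 1L ||
             !is.finite(sigma_kernel) || sigma_kernel <= 0) {
    stop("`sigma_kernel` must be a positive number or \"auto\"",
         call. = FALSE)
  }
  structure(list(s = as.integer(s), k = as.integer(k),
                 lambda_spatial = lambda_spatial,
                 sigma_kernel = sigma_kernel, coord_mode = coord_mode),
            class = "npgtv_patch_config")
}

#' @export
print.npgtv_patch_config <- function(x, ...) {
  cat(sprintf(
    "<npgtv_patch_config> s = %d, k = %d, lambda = %g, sigma = %s, coords = %s\n",
    x$s, x$k, x$lambda_spatial,
    if (is.character(x$sigma_kernel)) x$sigma_kernel else
      format(x$sigma_kernel), x$coord_mode))
  invisible(x)
}

# symmetric (mirror, edge included) padding of a matrix by r pixels
pad_symmetric <- function(px, r) {
  m <- nrow(px); l <- ncol(px)
  if (r >= m || r >= l) {
    stop("padding exceeds image size", call. = FALSE)
  }
  ri <- c(rev(seq_len(r)), seq_len(m), m - seq_len(r) + 1L)
  ci <- c(rev(seq_len(r)), seq_len(l), l - seq_len(r) + 1L)
  px[ri, ci, drop = FALSE]
}

#' Extract coordinate-augmented patch features
#'
#' Every pixel owns one overlapping \eqn{s \times s} patch (stride 1,
#' borders completed by symmetric reflection). Row `i` of the returned
#' feature matrix is the patch around pixel `i` in row-major scan order,
#' vectorized row-major, followed by the two spatially weighted center
#' coordinates \eqn{\lambda c(i_{row})}, \eqn{\lambda c(i_{col})}.
#'
#' @param image Image matrix, at least `s` pixels in each dimension.
#' @param config A [patch_config()].
#' @return An object of class `npgtv_features`: list with `features`
#'   (an \eqn{n \times (s^2+2)} matrix, `n = m*l`, nodes in row-major
#'   pixel order), `m`, `l` and the config used.
#' @export
extract_patch_features <- function(image, config = patch_config()) {
  px <- as_pixels(image_grid(as_pixels(image)))
  stopifnot(inherits(config, "npgtv_patch_config"))
  s <- config$s
  m <- nrow(px); l <- ncol(px)
  if (s > min(m, l)) {
    stop("patch side `s` exceeds the image dimensions", call. = FALSE)
  }
  r <- (s - 1L) %/% 2L
  pp <- pad_symmetric(px, r)
  n <- m * l
  feat <- matrix(0, n, s * s + 2L)
  # column (pi-1)*s + pj holds patch entry (pi, pj): patch vectorized row-major
  for (pi in seq_len(s)) {
    for (pj in seq_len(s)) {
      block <- pp[pi:(pi + m - 1L), pj:(pj + l - 1L), drop = FALSE]
      feat[, (pi - 1L) * s + pj] <- as.vector(t(block))  # row-major node order
    }
  }
  rows0 <- rep(seq_len(m) - 1L, each = l)
  cols0 <- rep(seq_len(l) - 1L, times = m)
  if (config$coord_mode == "normalized") {
    rows0 <- rows0 / (m - 1L)
    cols0 <- cols0 / (l - 1L)
  }
  feat[, s * s + 1L] <- config$lambda_spatial * rows0
  feat[, s * s + 2L] <- config$lambda_spatial * cols0
  structure(list(features = feat, m = m, l = l, config = config),
            class = "npgtv_features")
}

#' Exact K-nearest-neighbour edges in feature space
#'
#' For every node, finds its `k` nearest *other* nodes under the
#' Euclidean distance between augmented patch vectors, breaking distance
#' ties by ascending node index. Both backends are exact and return the
#' same edges: `"brute"` scans all pairwise distances, `"kdtree"` uses a
#' k-d tree with branch-and-bound pruning.
#'
#' @param features An [extract_patch_features()] result, or a plain
#'   numeric matrix with one feature row per node.
#' @param k Number of out-neighbours per node; must be smaller than the
#'   number of nodes.
#' @param backend `"brute"` or `"kdtree"`.
#' @return A data frame with columns `from`, `to` (1-based node
#'   indices) and `dist`, `k` rows per node.
#' @export
knn_edges <- function(features, k, backend = c("brute", "kdtree")) {
  backend <- match.arg(backend)
  X <- if (inherits(features, "npgtv_features")) features$features else features
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k >= n) {
    stop("`k` must be smaller than the number of nodes", call. = FALSE)
  }
  k <- as.integer(k)
  if (backend == "brute") knn_brute(X, k) else knn_kdtree(X, k)
}

knn_brute <- function(X, k) {
  n <- nrow(X)
  to <- matrix(0L, n, k)
  dist <- matrix(0, n, k)
  Xt <- t(X)
  for (i in seq_len(n)) {
    d2 <- colSums((Xt - X[i, ])^2)
    d2[i] <- Inf
    ord <- order(d2, seq_len(n))[seq_len(k)]
    to[i, ] <- ord
    dist[i, ] <- sqrt(d2[ord])
  }
  data.frame(from = rep(seq_len(n), each = k),
             to = as.vector(t(to)),
             dist = as.vector(t(dist)))
}

# exact k-d tree KNN; ties broken by ascending node index, matching the
# brute-force scan (candidates at equal distance compared on index)
knn_kdtree <- function(X, k) {
  n <- nrow(X); d <- ncol(X)
  leaf_size <- 8L

  build <- function(idx, depth) {
    if (length(idx) <= leaf_size) {
      return(list(leaf = TRUE, idx = idx))
    }
    spreads <- apply(X[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    dim <- which.max(spreads)
    vals <- X[idx, dim]
    med <- stats::median(vals)
    left <- idx[vals < med]
    right <- idx[vals >= med]
    if (length(left) == 0L || length(right) == 0L) {
      # degenerate split (many equal coordinates): fall back to a leaf
      return(list(leaf = TRUE, idx = idx))
    }
    list(leaf = FALSE, dim = dim, split = med,
         left = build(left, depth + 1L), right = build(right, depth + 1L))
  }
  tree <- build(seq_len(n), 0L)

  search_one <- function(qi) {
    q <- X[qi, ]
    best_d2 <- rep(Inf, k)
    best_ix <- rep(0L, k)

    consider <- function(cand) {
      cand <- cand[cand != qi]
      if (length(cand) == 0L) return()
      d2 <- colSums((t(X[cand, , drop = FALSE]) - q)^2)
      for (t in seq_along(cand)) {
        dd <- d2[t]; ii <- cand[t]
        worst <- best_d2[k]
        if (dd < worst || (dd == worst && ii < best_ix[k])) {
          # insert keeping (distance, index) lexicographic order
          pos <- k
          while (pos > 1L && (best_d2[pos - 1L] > dd ||
                 (best_d2[pos - 1L] == dd && best_ix[pos - 1L] > ii))) {
            best_d2[pos] <<- best_d2[pos - 1L]
            best_ix[pos] <<- best_ix[pos - 1L]
            pos <- pos - 1L
          }
          best_d2[pos] <<- dd
          best_ix[pos] <<- ii
        }
      }
    }

    recurse <- function(node) {
      if (node$leaf) {
        consider(node$idx)
        return()
      }
      delta <- q[node$dim] - node$split
      first <- if (delta < 0) node$left else node$right
      second <- if (delta < 0) node$right else node$left
      recurse(first)
      # descend the far side unless it provably cannot improve the k-th
      # best; equality must descend so index tie-breaks stay exact
      if (delta^2 <= best_d2[k]) recurse(second)
    }
    recurse(tree)
    list(ix = best_ix, d = sqrt(best_d2))
  }

  to <- matrix(0L, n, k)
  dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    res <- search_one(i)
    to[i, ] <- res$ix
    dist[i, ] <- res$d
  }
  data.frame(from = rep(seq_len(n), each = k),
             to = as.vector(t(to)),
             dist = as.vector(t(dist)))
}

#' Noise-adaptive Gaussian kernel bandwidth
#'
#' Sets the kernel bandwidth from the noise level: the squared bandwidth
#' equals 20% of the noise variance summed over one \eqn{s \times s}
#' patch, \eqn{\sigma^2 = 0.2 \, s^2 (\sigma_{noise}/255)^2}. A
#' noise-free input falls back to a fixed default bandwidth instead of
#' the degenerate zero.
#'
#' @param noise A [noise_model()].
#' @param config A [patch_config()] supplying the patch side `s`.
#' @param fallback Bandwidth returned when `noise$sigma == 0`.
#' @return A positive bandwidth \eqn{\sigma}.
#' @export
auto_kernel_bandwidth <- function(noise, config, fallback = 0.1) {
  stopifnot(inherits(noise, "npgtv_noise"),
            inherits(config, "npgtv_patch_config"))
  if (noise$sigma == 0) {
    return(fallback)
  }
  sqrt(0.2 * config$s^2 * (noise$sigma / 255)^2)
}

#' Build the weighted undirected graph from KNN edges
#'
#' Symmetrizes the directed KNN edge list by union (an undirected edge
#' exists if either direction was found) and assigns Gaussian kernel
#' weights \eqn{w(i,j) = \exp(-d^2(i,j)/\sigma^2)}. Weights that
#' underflow to zero are never stored.
#'
#' @param edges Data frame with columns `from`, `to`, `dist` as returned
#'   by [knn_edges()].
#' @param sigma_kernel Positive kernel bandwidth.
#' @param n Number of nodes; defaults to the largest index present.
#' @return A `npgtv_graph` object; see [weighted_graph()].
#' @export
build_weighted_graph <- function(edges, sigma_kernel,
                                 n = max(edges$from, edges$to)) {
  if (!is.numeric(sigma_kernel) || length(sigma_kernel) != 1L ||
      !is.finite(sigma_kernel) || sigma_kernel <= 0) {
    stop("`sigma_kernel` must be a positive number", call. = FALSE)
  }
  if (!all(c("from", "to", "dist") %in% names(edges))) {
    stop("`edges` must have columns from, to, dist", call. = FALSE)
  }
  i <- pmin(edges$from, edges$to)
  j <- pmax(edges$from, edges$to)
  key <- paste(i, j)
  keep <- !duplicated(key)
  i <- i[keep]; j <- j[keep]
  d <- edges$dist[keep]
  w <- exp(-(d^2) / sigma_kernel^2)
  weighted_graph(i, j, w, n)
}

#' Construct a weighted graph from undirected edge triples
#'
#' Core graph container: a sparse symmetric nonnegative weight matrix
#' with zero diagonal, plus the directed-edge arrays and weighted
#' incidence operator used by the total-variation machinery. Zero
#' weights are dropped; duplicate pairs are rejected.
#'
#' @param i,j 1-based endpoint indices (any orientation).
#' @param w Positive edge weights.
#' @param n Number of nodes.
#' @return An object of class `npgtv_graph` with elements `n`, `W`
#'   (sparse symmetric `dgCMatrix`), `edges` (canonical `i < j` triples)
#'   and internal operator fields.
#' @export
weighted_graph <- function(i, j, w, n) {
  if (length(i) != length(j) || length(i) != length(w)) {
    stop("edge vectors must have equal length", call. = FALSE)
  }
  if (any(i < 1 | i > n | j < 1 | j > n)) {
    stop("edge endpoints out of range", call. = FALSE)
  }
  if (any(i == j)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("edge weights must be finite and nonnegative", call. = FALSE)
  }
  ii <- pmin(i, j); jj <- pmax(i, j)
  keep <- w > 0
  ii <- ii[keep]; jj <- jj[keep]; w <- w[keep]
  o <- order(ii, jj)
  ii <- ii[o]; jj <- jj[o]; w <- w[o]
  if (anyDuplicated(paste(ii, jj))) {
    stop("duplicate edges in input", call. = FALSE)
  }
  ne <- length(ii)
  if (ne > 0L) {
    W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                              dims = c(n, n))
  } else {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  # directed edge arrays, sorted by source node: one row per (i -> j)
  src <- c(ii, jj); dst <- c(jj, ii); ww <- c(w, w)
  o2 <- order(src, dst)
  src <- src[o2]; dst <- dst[o2]; ww <- ww[o2]
  sw <- sqrt(ww)
  nd <- length(src)
  K <- if (nd > 0L) {
    Matrix::sparseMatrix(i = c(seq_len(nd), seq_len(nd)),
                         j = c(src, dst), x = c(sw, -sw),
                         dims = c(nd, n))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0L, n))
  }
  g <- list(n = as.integer(n),
            W = W,
            edges = data.frame(i = ii, j = jj, w = w),
            src = src, dst = dst, w_dir = ww, sw = sw,
            K = K, opnorm = NULL)
  g$opnorm <- operator_norm(g)
  structure(g, class = "npgtv_graph")
}

#' @export
print.npgtv_graph <- function(x, ...) {
  cat(sprintf("<npgtv_graph> %d nodes, %d undirected edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

# spectral norm of the weighted incidence operator K by power iteration;
# deterministic start vector so repeated runs are bit-identical
operator_norm <- function(graph, iters = 60L) {
  n <- graph$n
  if (nrow(graph$K) == 0L) return(0)
  v <- sin(seq_len(n)) + 1.1
  v <- v / sqrt(sum(v^2))
  est <- 0
  for (it in seq_len(iters)) {
    u <- as.vector(graph$K %*% v)
    v <- as.vector(Matrix::crossprod(graph$K, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    est <- sqrt(nv)
    v <- v / nv
  }
  est * 1.01  # small safety margin for step-size selection
}

#' Local grid graph over the pixel lattice
#'
#' Unit-weight 4- or 8-connected lattice over `m * l` pixels in
#' row-major node order — the classical local graph on which graph total
#' variation reduces to ordinary discrete TV.
#'
#' @param m,l Image dimensions, both at least 2.
#' @param connectivity 4 (rook) or 8 (rook + diagonals).
#' @return A `npgtv_graph`.
#' @export
grid_graph <- function(m, l, connectivity = 4L) {
  if (!is.numeric(m) || !is.numeric(l) || m < 2 || l < 2 ||
      m != round(m) || l != round(l)) {
    stop("`m` and `l` must be integers >= 2", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  m <- as.integer(m); l <- as.integer(l)
  node <- function(r, c) (r - 1L) * l + c
  rows <- rep(seq_len(m), each = l)
  cols <- rep(seq_len(l), times = m)
  # horizontal and vertical neighbours
  hi <- node(rows[cols < l], cols[cols < l])
  hj <- hi + 1L
  vi <- node(rows[rows < m], cols[rows < m])
  vj <- vi + l
  i <- c(hi, vi); j <- c(hj, vj)
  if (connectivity == 8L) {
    sel <- rows < m & cols < l
    d1i <- node(rows[sel], cols[sel]); d1j <- d1i + l + 1L
    sel2 <- rows < m & cols > 1L
    d2i <- node(rows[sel2], cols[sel2]); d2j <- d2i + l - 1L
    i <- c(i, d1i, d2i); j <- c(j, d1j, d2j)
  }
  weighted_graph(i, j, rep(1, length(i)), m * l)
}

#' Write / read a graph as a plain-text edge list
#'
#' Three whitespace-separated columns `i j w` (1-based canonical
#' `i < j` orientation), one line per undirected edge; a header comment
#' records the node count.
#'
#' @param graph A `npgtv_graph`.
#' @param path File path.
#' @return `read_edge_list` returns a `npgtv_graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "npgtv_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes %d", graph$n), con)
  utils::write.table(graph$edges, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  n <- as.integer(sub("^# nodes ", "", first))
  if (is.na(n)) stop("missing '# nodes' header in edge list", call. = FALSE)
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("i", "j", "w"))
  weighted_graph(df$i, df$j, df$w, n)
}
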