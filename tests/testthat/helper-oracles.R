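# Independent reference implementations used as oracles. Everything in
# this file deliberately avoids the package's own computational paths:
# dense matrices, double loops, and dual-only algorithms with
# certificate-based stopping.

# random weighted graph: each of the n*(n-1)/2 pairs kept with
# probability p_edge, weights uniform in (0.2, 1.5]
random_graph <- function(n, seed, p_edge = 0.5) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  i <- pairs[keep, 1]; j <- pairs[keep, 2]
  w <- runif(length(i), 0.2, 1.5)
  weighted_graph(i, j, w, n)
}

# random connected graph: random spanning tree plus extra random edges
random_connected_graph <- function(n, seed, extra = n) {
  set.seed(seed)
  perm <- sample.int(n)
  ti <- perm[-1]
  tj <- vapply(2:n, function(k) perm[sample.int(k - 1L, 1L)], integer(1))
  i <- ti; j <- tj
  for (e in seq_len(extra)) {
    a <- sample.int(n, 2L)
    i <- c(i, a[1]); j <- c(j, a[2])
  }
  ii <- pmin(i, j); jj <- pmax(i, j)
  keep <- !duplicated(paste(ii, jj)) & ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  w <- runif(length(ii), 0.2, 1.5)
  weighted_graph(ii, jj, w, n)
}

# double-loop graph TV over the dense weight matrix
tv_bruteforce <- function(f, graph) {
  W <- as.matrix(graph$W)
  n <- graph$n
  total <- 0
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (W[i, j] != 0) acc <- acc + W[i, j] * (f[i] - f[j])^2
    }
    total <- total + sqrt(acc)
  }
  total
}

# per-node local variations by double loop
lv_bruteforce <- function(f, graph) {
  W <- as.matrix(graph$W)
  sapply(seq_len(graph$n), function(i) {
    acc <- 0
    for (j in seq_len(graph$n)) {
      if (W[i, j] != 0) acc <- acc + W[i, j] * (f[i] - f[j])^2
    }
    sqrt(acc)
  })
}

# dense weighted incidence operator (one row per directed edge) and the
# directed-edge source grouping, built independently from dense W
dense_incidence <- function(graph) {
  W <- as.matrix(graph$W)
  n <- graph$n
  src <- integer(0); dst <- integer(0); sw <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && W[i, j] != 0) {
        src <- c(src, i); dst <- c(dst, j); sw <- c(sw, sqrt(W[i, j]))
      }
    }
  }
  K <- matrix(0, length(src), n)
  for (e in seq_along(src)) {
    K[e, src[e]] <- sw[e]
    K[e, dst[e]] <- -sw[e]
  }
  list(K = K, src = src)
}

# reference prox of gamma * TV at y: FISTA (projected accelerated
# gradient) on the dual  min_{||q_i|| <= gamma} 0.5||K'q||^2 - q'Ky,
# primal recovered as u = y - K'q; stops on a duality-gap certificate,
# so the returned objective is within `gap_tol` of the true minimum
prox_tv_reference <- function(y, gamma, graph, gap_tol = 1e-10,
                              max_iter = 200000L) {
  di <- dense_incidence(graph)
  K <- di$K; grp <- di$src
  nd <- nrow(K)
  if (nd == 0L || gamma == 0) {
    return(list(u = y, objective = 0.5 * sum((y - y)^2)))
  }
  L2 <- max(svd(K)$d)^2
  Ky <- K %*% y
  project <- function(q) {
    nrm <- sqrt(tapply(q^2, grp, sum))
    sc <- gamma / pmax(nrm, gamma)  # nrm first: pmax keeps its names
    q * as.vector(sc[as.character(grp)])
  }
  obj <- function(u) 0.5 * sum((u - y)^2) + gamma * tv_bruteforce(u, graph)
  q <- numeric(nd); qp <- q; tk <- 1
  gap <- Inf
  for (it in seq_len(max_iter)) {
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- q + ((tk - 1) / tk1) * (q - qp)
    grad <- as.vector(K %*% crossprod(K, z)) - as.vector(Ky)
    qp <- q
    q <- project(z - grad / L2)
    tk <- tk1
    if (it %% 20L == 0L) {
      u <- y - as.vector(crossprod(K, q))
      primal <- obj(u)
      dual <- sum(q * Ky) - 0.5 * sum(as.vector(crossprod(K, q))^2)
      gap <- primal - dual
      if (gap <= gap_tol) break
    }
  }
  u <- y - as.vector(crossprod(K, q))
  list(u = u, objective = obj(u), gap = gap)
}

# reference solution of  min TV(u) s.t. ||u - u0|| <= eps  on a
# connected graph, via the Lagrangian path: ||prox_{gamma TV}(u0) - u0||
# grows monotonically in gamma, so bisect for the gamma whose proximal
# point sits on the ball boundary; by strong duality that point is the
# constrained minimizer. Returns the mean signal when it is feasible.
constrained_tv_reference <- function(u0, graph, eps, tol = 1e-9) {
  mu <- mean(u0)
  if (sqrt(sum((u0 - mu)^2)) <= eps) {
    return(list(u = rep(mu, length(u0)), tv = 0))
  }
  dist_at <- function(gamma) {
    u <- prox_tv_reference(u0, gamma, graph, gap_tol = 1e-12)$u
    sqrt(sum((u - u0)^2))
  }
  hi <- 1
  while (dist_at(hi) < eps) hi <- hi * 2
  lo <- 0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (dist_at(mid) < eps) lo <- mid else hi <- mid
  }
  u <- prox_tv_reference(u0, (lo + hi) / 2, graph, gap_tol = 1e-12)$u
  list(u = u, tv = tv_bruteforce(u, graph))
}

# memoized end-to-end run on the standard 64x64 piecewise phantom at
# sigma = 25 with default parameters; shared across test files so the
# expensive pipeline runs once per session
.e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  clean <- make_phantom("piecewise", 64, 64, num_regions = 4, seed = 7)
  nz <- noise_model(25, seed = 8)
  noisy <- add_awgn(clean, nz)
  fit <- npgtv_denoise(noisy, noise = nz)
  grid <- baseline_grid_tv(noisy, noise = nz)
  .e2e_cache$res <- list(clean = clean, noisy = noisy, noise = nz,
                         npgtv = fit, grid = grid)
  .e2e_cache$res
}
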