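# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (igraph, vectorised labeling, closed forms).

# Plain O(V^2) Dijkstra over the 8-connected foreground of a mask;
# weights 1 / sqrt(2). Returns the distance in pixel units, Inf if
# unreachable.
oracle_dijkstra <- function(mask, p1, p2) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  pos <- integer(H * W); pos[idx] <- seq_along(idx)
  n <- length(idx)
  dist <- rep(Inf, n); visited <- rep(FALSE, n)
  src <- pos[(p1[2] - 1) * H + p1[1]]
  dst <- pos[(p2[2] - 1) * H + p2[1]]
  if (src == 0 || dst == 0) return(Inf)
  dist[src] <- 0
  moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  wts <- ifelse(abs(moves[, 1]) + abs(moves[, 2]) == 2, sqrt(2), 1)
  repeat {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!length(u) || !is.finite(dist[u])) break
    if (u == dst) break
    visited[u] <- TRUE
    ui <- idx[u]
    ur <- (ui - 1) %% H + 1; uc <- (ui - 1) %/% H + 1
    for (m in seq_len(8)) {
      vr <- ur + moves[m, 1]; vc <- uc + moves[m, 2]
      if (vr < 1 || vr > H || vc < 1 || vc > W) next
      vi <- pos[(vc - 1) * H + vr]
      if (vi == 0 || visited[vi]) next
      nd <- dist[u] + wts[m]
      if (nd < dist[vi]) dist[vi] <- nd
    }
  }
  dist[dst]
}

# Random connected mask on an H x W grid: a random walk union small discs,
# guaranteeing a single component containing the walk.
random_connected_mask <- function(H = 64, W = 64, n_steps = 200) {
  mask <- matrix(FALSE, H, W)
  r <- sample(5:(H - 5), 1); c <- sample(5:(W - 5), 1)
  pts <- matrix(0L, n_steps, 2)
  for (i in seq_len(n_steps)) {
    mask[r, c] <- TRUE
    pts[i, ] <- c(r, c)
    dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    r <- min(max(r + dr, 1), H); c <- min(max(c + dc, 1), W)
  }
  list(mask = mask, pts = pts)
}

# Direct dense convolution with reflective boundaries (oracle for
# gaussian_denoise).
oracle_conv_reflect <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  rad <- (nrow(kernel) - 1) / 2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1) rr <- 1L - rr            # symmetric (even) reflection
      if (rr > H) rr <- 2L * H + 1L - rr
      if (cc < 1) cc <- 1L - cc
      if (cc > W) cc <- 2L * W + 1L - cc
      acc <- acc + img[rr, cc] * kernel[dr + rad + 1, dc + rad + 1]
    }
    out[r, c] <- acc
  }
  out
}

# Brute-force exact two-sided Mann-Whitney p via enumeration of all
# assignments (recomputing ranks per assignment -- slower but independent
# of the package's single-ranking shortcut).
oracle_mw_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - m * (m + 1) / 2
  }
  obs <- u_of(seq_len(m))
  centre <- m * n / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  mean(abs(us - centre) >= abs(obs - centre) - 1e-9)
}

# Smallest default movie that still exercises waves + tracking quickly.
quick_movie <- function(seed = 1, duration_min = 40, ...) {
  simulate_movie(sim_movie_params(duration_min = duration_min,
                                  rng_seed = seed, ...))
}
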