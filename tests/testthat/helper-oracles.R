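# Independent oracles and tiny fixtures, kept deliberately naive: each
# re-derives a quantity by brute force so that the package's optimized
# path is checked against a second route.

# Kendall's W by direct rank-sum arithmetic, one series at a time.
oracle_kendalls_w <- function(series, tie_correction = TRUE) {
  k <- nrow(series); n <- ncol(series)
  r <- matrix(NA_real_, k, n)
  for (i in seq_len(k)) r[i, ] <- rank(series[i, ])
  ri <- colSums(r)
  s <- sum((ri - mean(ri))^2)
  tie_sum <- 0
  for (i in seq_len(k)) {
    tb <- table(r[i, ])
    tie_sum <- tie_sum + sum(tb^3 - tb)
  }
  denom <- k^2 * (n^3 - n) - if (tie_correction) k * tie_sum else 0
  if (denom <= 0) return(0)
  min(max(12 * s / denom, 0), 1)
}

# Benjamini-Hochberg by exhaustive threshold search: try every observed
# p-value as the rejection threshold and keep the largest valid one.
oracle_bh <- function(pvals, q) {
  m <- length(pvals)
  best <- -Inf
  for (thr in sort(pvals)) {
    k <- sum(pvals <= thr)
    if (thr <= k * q / m) best <- max(best, thr)
  }
  pvals <= best
}

# Dense all-pairs shortest paths (Floyd-Warshall) over the mesh edge
# graph with Euclidean edge weights.
oracle_geodesics <- function(mesh) {
  v <- nrow(mesh$vertices)
  d <- matrix(Inf, v, v)
  diag(d) <- 0
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  for (i in seq_len(nrow(e))) {
    d[e[i, 1], e[i, 2]] <- len[i]
    d[e[i, 2], e[i, 1]] <- len[i]
  }
  for (k in seq_len(v)) for (i in seq_len(v)) {
    upd <- d[i, k] + d[k, ]
    better <- upd < d[i, ]
    d[i, better] <- upd[better]
  }
  d
}

# breadth-first ring sets over an adjacency list
oracle_kring <- function(mesh, vertex, k) {
  adj <- mesh_adjacency(mesh)
  dist <- rep(NA_integer_, length(adj))
  dist[vertex] <- 0L
  frontier <- vertex
  ring <- 0L
  while (length(frontier) && ring < k) {
    ring <- ring + 1L
    nxt <- setdiff(unique(unlist(adj[frontier])), which(!is.na(dist)))
    dist[nxt] <- ring
    frontier <- nxt
  }
  sort(which(dist >= 1L))
}

# planar sheet of equilateral triangles (edge length h), for kernel-width
# measurements away from curvature
flat_grid_mesh <- function(nx = 21, ny = 21, h = 2) {
  xs <- outer(seq_len(nx) * h, rep(1, ny))
  shift <- matrix(rep((seq_len(ny) %% 2) * h / 2, each = nx), nx, ny)
  verts <- cbind(as.vector(xs + shift),
                 rep(seq_len(ny) * h * sqrt(3) / 2, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    if (j %% 2 == 1) {
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      tris[[length(tris) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    } else {
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  triangle_mesh(verts, do.call(rbind, tris))
}

dice_coef <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
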