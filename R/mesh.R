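#' Triangulated surface mesh
#'
#' Constructs a validated triangle mesh: the geometric substrate for
#' neighborhood statistics, vertex areas, geodesic smoothing and cluster
#' extraction. Coordinates are in millimetres, RAS orientation. Vertex
#' indices are 1-based throughout the package (R convention); file readers
#' and writers convert from/to the 0-based convention of FreeSurfer and
#' GIFTI on the way in and out.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates (mm).
#' @param triangles integer F x 3 matrix of 1-based vertex indices.
#' @param hemisphere one of "left", "right", "none".
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `triangles`, `hemisphere`.
#' @export
triangle_mesh <- function(vertices, triangles, hemisphere = c("none", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an F x 3 matrix")
  if (nrow(vertices) < 3L) stop("mesh must contain at least 3 vertices")
  if (nrow(triangles) < 1L) stop("mesh must contain at least one triangle")
  v <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > v))
    stop("triangle indices out of range [1, ", v, "]")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop("degenerate triangle: repeated vertex index within a face")
  structure(list(vertices = vertices, triangles = triangles,
                 hemisphere = hemisphere),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, hemisphere=%s\n",
              n_vertices(x), nrow(x$triangles), x$hemisphere))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `triangle_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Cortex mask
#'
#' Boolean per-vertex flags marking cortical vertices (TRUE) versus
#' excluded vertices such as the medial wall (FALSE). All map-level
#' statistics are restricted to masked-in vertices.
#'
#' @param keep logical vector, one entry per mesh vertex.
#' @param mesh optional `triangle_mesh` to validate the length against.
#' @return object of class `cortex_mask`.
#' @export
cortex_mask <- function(keep, mesh = NULL) {
  keep <- as.logical(keep)
  if (anyNA(keep)) stop("mask must not contain NA")
  if (!any(keep)) stop("mask must keep at least one vertex")
  if (!is.null(mesh) && length(keep) != n_vertices(mesh))
    stop("mask length (", length(keep), ") != vertex count (", n_vertices(mesh), ")")
  structure(list(keep = keep), class = "cortex_mask")
}

#' Full cortex mask for a mesh (all vertices kept)
#' @param mesh a `triangle_mesh`.
#' @return `cortex_mask` keeping every vertex.
#' @export
full_mask <- function(mesh) cortex_mask(rep(TRUE, n_vertices(mesh)))

#' Per-vertex scalar map bound to a mesh
#'
#' Container for any per-vertex scalar field (a 2dReHo map, a t map,
#' a p map). Masked-out vertices carry `NA`, never a silently mixed-in
#' number.
#'
#' @param values numeric vector of length V; entries at masked-out
#'   vertices are forced to `NA`.
#' @param mesh the `triangle_mesh` the values live on.
#' @param mask a `cortex_mask` (default: full mask).
#' @param smoothed_fwhm FWHM in mm if the map has been smoothed, else NA.
#' @return object of class `surface_map`.
#' @export
surface_map <- function(values, mesh, mask = full_mask(mesh), smoothed_fwhm = NA_real_) {
  values <- as.double(values)
  if (length(values) != n_vertices(mesh))
    stop("values length (", length(values), ") != vertex count (", n_vertices(mesh), ")")
  if (length(mask$keep) != n_vertices(mesh))
    stop("mask length != vertex count")
  values[!mask$keep] <- NA_real_
  structure(list(values = values, mesh = mesh, mask = mask,
                 smoothed_fwhm = smoothed_fwhm),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  v <- x$values[x$mask$keep]
  cat(sprintf("surface_map: %d vertices (%d in mask), range [%.4g, %.4g]%s\n",
              length(x$values), sum(x$mask$keep),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              if (is.finite(x$smoothed_fwhm))
                sprintf(", smoothed FWHM=%g mm", x$smoothed_fwhm) else ""))
  invisible(x)
}

#' Per-vertex time-series matrix bound to a mesh
#'
#' @param data numeric V x T matrix: one row per vertex, one column per
#'   acquired volume.
#' @param mesh the `triangle_mesh` the rows correspond to.
#' @param tr repetition time in seconds.
#' @return object of class `surface_timeseries`.
#' @export
surface_timeseries <- function(data, mesh, tr) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != n_vertices(mesh))
    stop("row count (", nrow(data), ") != mesh vertex count (", n_vertices(mesh), ")")
  if (ncol(data) < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar (seconds)")
  structure(list(data = data, mesh = mesh, tr = as.double(tr)),
            class = "surface_timeseries")
}

#' @export
print.surface_timeseries <- function(x, ...) {
  cat(sprintf("surface_timeseries: %d vertices x %d volumes, TR=%g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

# ---- topology ---------------------------------------------------------------

#' Undirected edge list of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer E x 2 matrix of unique undirected edges (col1 < col2).
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency list of the mesh edge graph
#'
#' @param mesh a `triangle_mesh`.
#' @return list of length V; element v is the sorted integer vector of
#'   vertices sharing an edge with v.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  v <- n_vertices(mesh)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(v)))
  lapply(adj, function(x) sort(unique(as.integer(x))))
}

#' k-ring neighborhood of a vertex
#'
#' All vertices at edge-graph distance 1..k from the seed, seed excluded.
#' On a regular (degree-6) interior vertex the one-ring has 6 members and
#' the two-ring 18 — the neighborhood over which 2dReHo is computed
#' (19 series including the seed).
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex 1-based seed vertex index.
#' @param k maximum ring (graph distance), k >= 1.
#' @param adj optional precomputed adjacency list from [mesh_adjacency()].
#' @return sorted integer vector of neighbor indices.
#' @export
kring_neighbors <- function(mesh, vertex, k = 2L, adj = NULL) {
  v <- n_vertices(mesh)
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > v)
    stop("vertex index out of range [1, ", v, "]")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (is.null(adj)) adj <- mesh_adjacency(mesh)
  seen <- logical(v)
  seen[vertex] <- TRUE
  frontier <- vertex
  out <- integer(0)
  for (ring in seq_len(k)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (length(nxt) == 0L) break
    seen[nxt] <- TRUE
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Neighborhood incidence matrix for ring-k neighborhoods
#'
#' Sparse V x V logical incidence: row v flags `{v} union kring(v, k)`.
#' Used by the vectorized 2dReHo map computation.
#'
#' @param mesh a `triangle_mesh`.
#' @param k ring radius.
#' @return a `Matrix::sparseMatrix` (dgCMatrix) of 0/1 weights.
#' @export
kring_incidence <- function(mesh, k = 2L) {
  adj <- mesh_adjacency(mesh)
  v <- n_vertices(mesh)
  nb <- lapply(seq_len(v), function(i) c(i, kring_neighbors(mesh, i, k, adj = adj)))
  lens <- lengths(nb)
  Matrix::sparseMatrix(i = rep.int(seq_len(v), lens),
                       j = unlist(nb, use.names = FALSE),
                       x = 1, dims = c(v, v))
}

# ---- geometry ---------------------------------------------------------------

triangle_area_vec <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the area of every incident triangle,
#' so the vertex areas partition the total mesh surface area. Needed to
#' report cluster sizes in mm^2.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of length V (mm^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_area_vec(mesh$vertices, mesh$triangles)
  if (any(ta == 0))
    warning(sum(ta == 0), " zero-area triangle(s) contribute no area")
  v <- n_vertices(mesh)
  share <- rep(ta / 3, 3L)
  idx <- as.integer(mesh$triangles)
  as.numeric(rowsum(share, idx, reorder = TRUE)[match(seq_len(v), sort(unique(idx)))]) ->
    out
  out[is.na(out)] <- 0
  out
}

#' Total surface area of a mesh
#' @param mesh a `triangle_mesh`.
#' @return total area (mm^2).
#' @export
mesh_surface_area <- function(mesh) sum(triangle_area_vec(mesh$vertices, mesh$triangles))

mesh_igraph <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  w <- sqrt(rowSums(d^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n_vertices(mesh))
    g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  g
}

#' Truncated geodesic distances from seed vertices
#'
#' Shortest-path distances along mesh edges (edge weight = Euclidean
#' length), truncated at `cutoff`: vertices farther than the cutoff are
#' absent from the result. This edge-graph Dijkstra approximation is
#' adequate at smoothing scales much larger than the edge length.
#'
#' @param mesh a `triangle_mesh`.
#' @param seed 1-based seed vertex index (scalar).
#' @param cutoff maximum distance in mm (> 0).
#' @return named numeric vector: distances (<= cutoff) indexed by vertex;
#'   includes the seed at distance 0.
#' @export
geodesic_distances <- function(mesh, seed, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  v <- n_vertices(mesh)
  seed <- as.integer(seed)
  if (seed < 1L || seed > v) stop("seed vertex out of range")
  g <- mesh_igraph(mesh)
  d <- as.numeric(igraph::distances(g, v = seed, algorithm = "dijkstra"))
  keep <- is.finite(d) & d <= cutoff
  stats::setNames(d[keep], which(keep))
}

#' Sparse truncated all-pairs geodesic weight structure
#'
#' Computes, in row chunks, all geodesic distances up to `cutoff` and
#' returns them as a sparse matrix of distances. Internal workhorse for
#' [surface_smooth()].
#'
#' @param mesh a `triangle_mesh`.
#' @param cutoff truncation distance (mm).
#' @param chunk number of seed rows per igraph call.
#' @return sparse V x V dsCMatrix-like dgCMatrix of distances; structural
#'   zeros mean "beyond cutoff", explicit diagonal entries are absent
#'   (distance zero).
#' @keywords internal
geodesic_neighbor_distances <- function(mesh, cutoff, chunk = 512L) {
  g <- mesh_igraph(mesh)
  v <- n_vertices(mesh)
  is <- list(); js <- list(); xs <- list()
  starts <- seq(1L, v, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, v)
    d <- igraph::distances(g, v = rows, algorithm = "dijkstra")
    hit <- which(is.finite(d) & d <= cutoff & d > 0, arr.ind = TRUE)
    is[[length(is) + 1L]] <- rows[hit[, 1]]
    js[[length(js) + 1L]] <- hit[, 2]
    xs[[length(xs) + 1L]] <- d[hit]
  }
  Matrix::sparseMatrix(i = unlist(is), j = unlist(js), x = unlist(xs),
                       dims = c(v, v))
}

# ---- icosphere --------------------------------------------------------------

#' Subdivided icosahedron ("icosphere") mesh
#'
#' Recursive 4-to-1 subdivision of the regular icosahedron with vertices
#' projected to the requested radius: the standard synthetic stand-in for
#' an average cortical sphere (fsaverage-style meshes share the same
#' topology). The result has `10 * 4^s + 2` vertices, exactly 12 of
#' degree 5 and the rest of degree 6.
#'
#' @param subdivisions non-negative integer s.
#' @param radius sphere radius in mm.
#' @param hemisphere hemisphere tag to attach.
#' @return a `triangle_mesh`.
#' @export
icosphere <- function(subdivisions = 3L, radius = 50, hemisphere = "none") {
  s <- as.integer(subdivisions)
  if (is.na(s) || s < 0L) stop("subdivisions must be a non-negative integer")
  if (radius <= 0) stop("radius must be > 0")
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(s)) {
    nv <- nrow(verts)
    e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- unique(e)
    key <- function(m) (m[, 1] - 1) * nv + m[, 2]
    mid_idx <- stats::setNames(nv + seq_len(nrow(ue)), key(ue))
    mids <- (verts[ue[, 1], , drop = FALSE] + verts[ue[, 2], , drop = FALSE]) / 2
    verts <- rbind(verts, mids)
    m12 <- mid_idx[as.character(key(cbind(pmin(faces[, 1], faces[, 2]), pmax(faces[, 1], faces[, 2]))))]
    m23 <- mid_idx[as.character(key(cbind(pmin(faces[, 2], faces[, 3]), pmax(faces[, 2], faces[, 3]))))]
    m13 <- mid_idx[as.character(key(cbind(pmin(faces[, 1], faces[, 3]), pmax(faces[, 1], faces[, 3]))))]
    faces <- rbind(cbind(faces[, 1], m12, m13),
                   cbind(faces[, 2], m23, m12),
                   cbind(faces[, 3], m13, m23),
                   cbind(m12, m23, m13))
  }
  verts <- verts / sqrt(rowSums(verts^2)) * radius
  triangle_mesh(verts, faces, hemisphere = hemisphere)
}
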