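# Hierarchical icosahedral meshes and the index structures the rest of the
# package consumes: ordered 1-ring neighbor tables, order-prefix pooling,
# spherical resampling and geodesic-Voronoi parcellations.

#' Construct a hierarchical icosahedral sphere
#'
#' Builds an icosphere by `order` rounds of 4-to-1 triangle subdivision of a
#' fixed base icosahedron (poles at +/- z, golden-ratio latitude rings),
#' re-projecting every vertex to the unit sphere. Subdivision stores parent
#' vertices first and edge midpoints in sorted-edge order, so the first
#' `10 * 4^(k-1) + 2` vertices of an order-`k` sphere are exactly the order
#' `k-1` sphere (the prefix property that order-prefix pooling relies on).
#'
#' @param order Non-negative integer subdivision level (0 = base icosahedron,
#'   6 = the 40962-vertex mesh used for full-resolution cortical maps). Orders
#'   above 8 are refused as a memory guard.
#' @return An object of class `ico_sphere` with components:
#'   \describe{
#'     \item{order}{the subdivision level}
#'     \item{vertices}{V x 3 matrix of unit vertices}
#'     \item{faces}{F x 3 integer matrix of vertex indices (1-based)}
#'     \item{neighbor_table}{V x 6 integer matrix of 1-ring neighbors in
#'       canonical azimuthal order; for the 12 valence-5 vertices the sixth
#'       slot repeats the vertex's own index (the pentagon pad)}
#'     \item{valence}{integer vector of true ring sizes (5 or 6)}
#'     \item{vertex_counts}{vertex count at each order `0..order`}
#'   }
#' @examples
#' ico <- ico_sphere(2)
#' nrow(ico$vertices)  # 162
#' @export
ico_sphere <- function(order) {
  if (length(order) != 1L || is.na(order) || order < 0 || order != floor(order))
    stop("'order' must be a single non-negative integer")
  if (order > 8)
    stop("'order' above 8 is not supported (memory guard)")
  order <- as.integer(order)

  base <- base_icosahedron()
  vertices <- base$vertices
  faces <- base$faces
  if (order > 0) {
    for (k in seq_len(order)) {
      sub <- subdivide_once(vertices, faces)
      vertices <- sub$vertices
      faces <- sub$faces
    }
  }
  nbr <- neighbor_ordering(vertices, faces)
  structure(list(
    order = order,
    vertices = vertices,
    faces = faces,
    neighbor_table = nbr$table,
    valence = nbr$valence,
    vertex_counts = ico_vertex_count(0:order)
  ), class = "ico_sphere")
}

#' Vertex, face and edge counts of an icosphere order
#'
#' Closed forms `V = 10 * 4^k + 2`, `F = 20 * 4^k`, `E = 30 * 4^k`.
#' @param order Integer vector of subdivision levels.
#' @return Integer vector of counts.
#' @export
ico_vertex_count <- function(order) as.integer(10 * 4^order + 2)

#' @rdname ico_vertex_count
#' @export
ico_face_count <- function(order) as.integer(20 * 4^order)

#' @rdname ico_vertex_count
#' @export
ico_edge_count <- function(order) as.integer(30 * 4^order)

# Base icosahedron with poles on the z-axis and two latitude rings of five
# vertices at z = +/- 1/sqrt(5); fixed orientation so meshes are reproducible.
base_icosahedron <- function() {
  z <- 1 / sqrt(5)
  r <- 2 / sqrt(5)
  top <- c(0, 0, 1)
  bottom <- c(0, 0, -1)
  ang_up <- 2 * pi * (0:4) / 5
  ang_lo <- ang_up + pi / 5
  upper <- cbind(r * cos(ang_up), r * sin(ang_up), z)
  lower <- cbind(r * cos(ang_lo), r * sin(ang_lo), -z)
  vertices <- rbind(top, upper, lower, bottom)
  dimnames(vertices) <- NULL
  # indices: 1 = north pole, 2:6 upper ring, 7:11 lower ring, 12 = south pole
  up <- function(i) 2L + (i %% 5L)
  lo <- function(i) 7L + (i %% 5L)
  faces <- matrix(0L, 20, 3)
  for (i in 0:4) {
    faces[i + 1L, ] <- c(1L, up(i), up(i + 1L))                 # north cap
    faces[i + 6L, ] <- c(up(i), lo(i), up(i + 1L))              # upper band
    faces[i + 11L, ] <- c(up(i + 1L), lo(i), lo(i + 1L))        # lower band
    faces[i + 16L, ] <- c(12L, lo(i + 1L), lo(i))               # south cap
  }
  list(vertices = vertices, faces = faces)
}

# One 4-to-1 subdivision round. New vertices are the midpoints of the unique
# edges taken in lexicographic (min, max) order, appended after the parents and
# normalized to the sphere: this is what guarantees the prefix property.
subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  a <- faces[, 1]; b <- faces[, 2]; c <- faces[, 3]
  e1 <- cbind(pmin(a, b), pmax(a, b))
  e2 <- cbind(pmin(b, c), pmax(b, c))
  e3 <- cbind(pmin(c, a), pmax(c, a))
  all_edges <- rbind(e1, e2, e3)
  key <- (all_edges[, 1] - 1) * nv + all_edges[, 2]   # unique integer per edge
  ord_keys <- sort(unique(key))
  mid_index <- match(key, ord_keys) + nv              # index of each face edge's midpoint
  i1 <- (ord_keys - 1) %/% nv + 1
  i2 <- (ord_keys - 1) %% nv + 1
  mids <- (vertices[i1, , drop = FALSE] + vertices[i2, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(faces)
  mab <- mid_index[seq_len(nf)]
  mbc <- mid_index[nf + seq_len(nf)]
  mca <- mid_index[2 * nf + seq_len(nf)]
  new_faces <- rbind(
    cbind(a, mab, mca),
    cbind(b, mbc, mab),
    cbind(c, mca, mbc),
    cbind(mab, mbc, mca)
  )
  storage.mode(new_faces) <- "integer"
  dimnames(new_faces) <- NULL
  list(vertices = rbind(vertices, mids), faces = new_faces)
}

# Canonically ordered 1-ring neighbor table. Each vertex is rotated to the
# north pole (Rz(-phi) then Ry(-theta)); its neighbors are sorted by ascending
# azimuth in that tangent frame, starting from the smallest azimuth, ties
# broken by smaller vertex index. Valence-5 vertices get their own index as a
# sixth pad slot.
neighbor_ordering <- function(vertices, faces) {
  nv <- nrow(vertices)
  edges <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  # undirected adjacency: each directed half-edge appears once per face
  i <- edges[, 1]; j <- edges[, 2]
  key <- pmin(i, j) * (nv + 1) + pmax(i, j)
  dup <- duplicated(key)
  i2 <- c(i[!dup], j[!dup])
  j2 <- c(j[!dup], i[!dup])
  if (anyDuplicated(cbind(i2, j2)))
    stop("non-manifold mesh: duplicated adjacency")

  p <- vertices[i2, , drop = FALSE]
  q <- vertices[j2, , drop = FALSE]
  phi <- atan2(p[, 2], p[, 1])
  theta <- acos(pmin(pmax(p[, 3], -1), 1))
  # q' = Ry(-theta) Rz(-phi) q, vectorized
  cph <- cos(phi); sph <- sin(phi); cth <- cos(theta); sth <- sin(theta)
  qx1 <- cph * q[, 1] + sph * q[, 2]
  qy1 <- -sph * q[, 1] + cph * q[, 2]
  qz1 <- q[, 3]
  qx2 <- cth * qx1 - sth * qz1
  az <- atan2(qy1, qx2) %% (2 * pi)

  ord <- order(i2, az, j2)
  i_ord <- i2[ord]
  j_ord <- j2[ord]
  valence <- tabulate(i_ord, nbins = nv)
  if (any(valence < 5L | valence > 6L))
    stop("non-manifold mesh: unexpected vertex valence")
  tab <- matrix(NA_integer_, nv, 6)
  slot <- sequence(valence)
  tab[cbind(i_ord, slot)] <- j_ord
  pent <- which(valence == 5L)
  tab[cbind(pent, 6L)] <- pent
  list(table = tab, valence = valence)
}

#' @export
print.ico_sphere <- function(x, ...) {
  cat(sprintf(
    "Icosphere of order %d: %d vertices, %d faces, %d edges (12 pentagons)\n",
    x$order, nrow(x$vertices), nrow(x$faces), ico_edge_count(x$order)))
  invisible(x)
}

#' Order-prefix pooling of per-vertex data
#'
#' Downsamples a per-vertex channel matrix from icosphere order `k` to `k-1`
#' by keeping only the vertices of the coarser sphere (the prefix of the
#' vertex list); no averaging is performed. The adjoint operation [ico_unpool()]
#' zero-pads the vertices added between the orders.
#'
#' @param values Matrix (or vector) with one row per vertex at some order `k >= 1`.
#' @return The first `10 * 4^(k-1) + 2` rows of `values`.
#' @export
ico_pool <- function(values) {
  values <- as_vertex_matrix(values)
  k <- order_from_vertex_count(nrow(values))
  if (k < 1) stop("cannot pool below order 0")
  values[seq_len(ico_vertex_count(k - 1)), , drop = FALSE]
}

#' @rdname ico_pool
#' @export
ico_unpool <- function(values) {
  values <- as_vertex_matrix(values)
  k <- order_from_vertex_count(nrow(values))
  out <- matrix(0, ico_vertex_count(k + 1), ncol(values))
  out[seq_len(nrow(values)), ] <- values
  colnames(out) <- colnames(values)
  out
}

as_vertex_matrix <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values
}

order_from_vertex_count <- function(nv) {
  k <- round(log((nv - 2) / 10, base = 4))
  if (k < 0 || ico_vertex_count(k) != nv)
    stop(sprintf("%d rows is not an icosphere vertex count", nv))
  as.integer(k)
}

#' Resample per-vertex data between spherical meshes
#'
#' Projects each destination vertex onto the source spherical triangulation and
#' interpolates. `method = "barycentric"` locates the containing source triangle
#' and uses barycentric weights (exact for fields linear in the embedding
#' coordinates within a triangle); `method = "nearest"` copies the value of the
#' closest source vertex and is the right choice for label maps.
#'
#' @param values Per-vertex matrix or vector on the source mesh.
#' @param src_vertices Source unit vertices (V x 3).
#' @param src_faces Source triangle index matrix (1-based).
#' @param dst Destination `ico_sphere` (or any list with unit `$vertices`).
#' @param method `"barycentric"` (default) or `"nearest"`.
#' @return Per-vertex matrix on the destination mesh.
#' @export
resample_to_icosphere <- function(values, src_vertices, src_faces, dst,
                                  method = c("barycentric", "nearest")) {
  method <- match.arg(method)
  values <- as_vertex_matrix(values)
  if (nrow(values) != nrow(src_vertices))
    stop("'values' rows must match source vertex count")
  dv <- dst$vertices
  # nearest source vertex by max dot product, chunked to bound memory
  nearest <- integer(nrow(dv))
  chunk <- 2048L
  for (s in seq(1, nrow(dv), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(dv))
    dots <- dv[s:e, , drop = FALSE] %*% t(src_vertices)
    nearest[s:e] <- max.col(dots, ties.method = "first")
  }
  if (method == "nearest")
    return(values[nearest, , drop = FALSE])

  # incident faces per source vertex
  nf <- nrow(src_faces)
  face_of <- rep(seq_len(nf), 3)
  vert_of <- as.vector(src_faces)
  inc <- split(face_of, vert_of)

  out <- matrix(NA_real_, nrow(dv), ncol(values))
  colnames(out) <- colnames(values)
  for (d in seq_len(nrow(dv))) {
    p <- dv[d, ]
    cand_v <- c(nearest[d], vert_of[face_of %in% inc[[as.character(nearest[d])]]])
    cand_f <- unique(unlist(inc[as.character(unique(cand_v))], use.names = FALSE))
    hit <- locate_in_faces(p, src_vertices, src_faces, cand_f, tol = 1e-10)
    if (is.null(hit)) # widen: all faces, then relax tolerance
      hit <- locate_in_faces(p, src_vertices, src_faces, seq_len(nf), tol = 1e-10)
    if (is.null(hit))
      hit <- locate_in_faces(p, src_vertices, src_faces, seq_len(nf), tol = 1e-6)
    if (is.null(hit))
      stop(sprintf("destination vertex %d not locatable in any source triangle", d))
    out[d, ] <- hit$w %*% values[src_faces[hit$face, ], , drop = FALSE]
  }
  out
}

# Barycentric location of the central projection of p among candidate faces.
# Solves [va vb vc] lambda = p; valid when all lambda >= -tol after
# normalization. Returns the face with the least-negative minimum weight.
locate_in_faces <- function(p, vertices, faces, cand, tol) {
  best <- NULL
  best_min <- -Inf
  for (f in cand) {
    tri <- t(vertices[faces[f, ], , drop = FALSE])
    lam <- tryCatch(solve(tri, p), error = function(e) NULL)
    if (is.null(lam)) next
    s <- sum(lam)
    if (s <= 0) next
    w <- lam / s
    m <- min(w)
    if (m > best_min) {
      best_min <- m
      best <- list(face = f, w = pmax(w, 0) / sum(pmax(w, 0)))
    }
  }
  if (!is.null(best) && best_min >= -tol) best else NULL
}

#' Geodesic-Voronoi parcellation of an icosphere
#'
#' Splits the sphere into `n_rois` regions by farthest-point sampling of seed
#' vertices (graph geodesic distances along mesh edges) followed by a Voronoi
#' assignment to the nearest seed. A synthetic stand-in for an anatomical
#' atlas parcellation such as Desikan-Killiany (34 regions per hemisphere).
#'
#' @param ico An `ico_sphere`.
#' @param n_rois Number of regions (1 to vertex count).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Object of class `parcellation`: list with `labels` (per-vertex
#'   integer in `0:(n_rois-1)`), `n_rois`, and `names`.
#' @export
make_parcellation <- function(ico, n_rois, seed = 1L) {
  nv <- nrow(ico$vertices)
  if (n_rois < 1 || n_rois > nv)
    stop("'n_rois' must be between 1 and the vertex count")
  edges <- unique_edges(ico$faces)
  len <- sqrt(rowSums((ico$vertices[edges[, 1], ] - ico$vertices[edges[, 2], ])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  seeds <- integer(n_rois)
  seeds[1] <- with_seed_(seed, sample.int(nv, 1))
  if (n_rois > 1) {
    d <- igraph::distances(g, v = seeds[1], weights = len)[1, ]
    for (r in 2:n_rois) {
      seeds[r] <- which.max(d)  # deterministic: first index at the max
      d <- pmin(d, igraph::distances(g, v = seeds[r], weights = len)[1, ])
    }
  }
  dmat <- igraph::distances(g, v = seeds, weights = len)
  labels <- max.col(-t(dmat), ties.method = "first") - 1L
  structure(list(
    labels = as.integer(labels),
    n_rois = as.integer(n_rois),
    names = sprintf("roi_%02d", seq_len(n_rois) - 1L)
  ), class = "parcellation")
}

unique_edges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d ROIs over %d vertices\n",
              x$n_rois, length(x$labels)))
  invisible(x)
}

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
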