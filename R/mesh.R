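# Closed triangle meshes for deformable-surface skull stripping. Vertices are
# world RAS mm; triangles are 1-based index triplets with consistent outward
# winding.

#' Icosphere tessellation
#'
#' Subdivides an icosahedron and projects vertices onto a sphere; vertex
#' count is \code{10 * 4^subdivisions + 2}.
#'
#' @param sphere list with \code{cog} (length-3 mm) and \code{radius} (mm),
#'   e.g. from \code{\link{estimate_sphere}}.
#' @param subdivisions subdivision count, >= 0.
#' @return A \code{surface_mesh}: list with \code{vertices} (V x 3),
#'   \code{triangles} (F x 3, 1-based, outward winding).
#' @export
tessellate_sphere <- function(sphere, subdivisions = 4) {
  stopifnot(subdivisions >= 0, sphere$radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (subdivisions > 0) {
    for (s in seq_len(subdivisions)) {
      nv <- nrow(v)
      edge_key <- function(a, b) ifelse(a < b, a * (nv + 1L) + b, b * (nv + 1L) + a)
      e1 <- edge_key(f[, 1], f[, 2]); e2 <- edge_key(f[, 2], f[, 3])
      e3 <- edge_key(f[, 3], f[, 1])
      keys <- unique(c(e1, e2, e3))
      midid <- setNames(seq_along(keys) + nv, keys)
      ka <- keys %/% (nv + 1L); kb <- keys %% (nv + 1L)
      mids <- (v[ka, , drop = FALSE] + v[kb, , drop = FALSE]) / 2
      mids <- mids / sqrt(rowSums(mids^2))
      v <- rbind(v, mids)
      m1 <- midid[as.character(e1)]; m2 <- midid[as.character(e2)]
      m3 <- midid[as.character(e3)]
      f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
                 cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
    }
  }
  verts <- sweep(v * sphere$radius, 2L, sphere$cog, "+")
  mesh <- structure(list(vertices = verts,
                         triangles = matrix(as.integer(f), ncol = 3)),
                    class = "surface_mesh")
  orient_outward(mesh, sphere$cog)
}

# Flip triangles whose normal points toward `center` (ensures outward winding
# for star-shaped meshes).
orient_outward <- function(mesh, center) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c3 <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  out <- rowSums(n * sweep(c3, 2L, center)) < 0
  if (any(out)) mesh$triangles[out, ] <- mesh$triangles[out, c(1, 3, 2)]
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

# Precomputed connectivity reused across evolution iterations.
mesh_topology <- function(mesh) {
  f <- mesh$triangles
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  deg <- tabulate(edges[, 1], nbins = nrow(mesh$vertices))
  list(edges = edges, degree = deg)
}

# Mean position of each vertex's 1-ring neighbours.
neighbor_centroid <- function(vertices, topo) {
  s <- rowsum(vertices[topo$edges[, 2], , drop = FALSE], topo$edges[, 1],
              reorder = TRUE)
  s / topo$degree
}

# Angle-agnostic area-weighted vertex normals (unit, outward for outward
# winding).
vertex_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 2], ] - vertices[triangles[, 1], ]
  b <- vertices[triangles[, 3], ] - vertices[triangles[, 1], ]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    s <- rowsum(fn, triangles[, k], reorder = FALSE)
    ids <- as.integer(rownames(s))
    vn[ids, ] <- vn[ids, ] + s
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-12)
}

# Verify each edge is shared by exactly two triangles (closed 2-manifold).
mesh_is_closed <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Rasterize a closed mesh to a binary mask
#'
#' Voxel centers strictly inside the surface (ray-crossing parity) are set.
#'
#' @param mesh a closed \code{surface_mesh}.
#' @param geom target \code{\link{image_grid}} geometry.
#' @return Binary \code{\link{image_grid}} (0/1).
#' @export
mesh_to_mask <- function(mesh, geom) {
  if (!mesh_is_closed(mesh)) stop("mesh_to_mask requires a closed mesh")
  vx <- world_to_voxel(geom, mesh$vertices)
  m <- cpp_mesh_mask(vx, mesh$triangles - 1L, grid_dim(geom))
  with_voxels(geom, array(as.numeric(m), grid_dim(geom)))
}

# Cheap broad-phase self-intersection screen: counts non-adjacent triangle
# pairs with overlapping bounding boxes beyond what the closed surface's
# natural adjacency explains. Used only to attach a warning flag.
mesh_self_intersection_suspect <- function(mesh, cell = 4) {
  v <- mesh$vertices; f <- mesh$triangles
  c3 <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  r <- sqrt(pmax(rowSums((v[f[, 1], ] - c3)^2),
                 rowSums((v[f[, 2], ] - c3)^2),
                 rowSums((v[f[, 3], ] - c3)^2)))
  key <- paste(floor(c3[, 1] / cell), floor(c3[, 2] / cell),
               floor(c3[, 3] / cell))
  dens <- table(key)
  # heuristic: a folded surface doubles local triangle density
  max(dens) > 4 * stats::median(dens) + 8
}
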