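#' Tetrahedral mesh container
#'
#' A `tet_mesh` is the spatial substrate for the forward and inverse
#' problems: node coordinates in millimetres, tetrahedral connectivity,
#' the extracted boundary triangles, and a per-tetrahedron tissue label.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z (mm).
#' @param tets integer matrix, one row per tetrahedron, four 1-based
#'   node indices, positively oriented.
#' @param region character vector of tissue labels, one per tetrahedron.
#' @param spacing nominal edge length of the generating grid (mm); used
#'   as the degeneracy floor for region-of-interest half-lengths.
#'
#' @return An object of class `tet_mesh` with elements `nodes`, `tets`,
#'   `boundary_faces`, `region`, `spacing`.
#' @export
tet_mesh <- function(nodes, tets, region = NULL, spacing = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 coordinate matrix")
  if (ncol(tets) != 4L) stop("tets must be a t x 4 index matrix")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tetrahedron refers to a node index outside the mesh")
  vols <- tet_volumes_signed(nodes, tets)
  if (any(vols <= 0))
    stop("mesh contains degenerate or negatively oriented tetrahedra")
  if (is.null(region)) region <- rep("Muscle", nrow(tets))
  if (length(region) != nrow(tets))
    stop("region must supply one tissue label per tetrahedron")
  if (is.null(spacing)) {
    e <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
    spacing <- stats::median(sqrt(rowSums(e^2)))
  }
  structure(
    list(nodes = nodes, tets = tets,
         boundary_faces = boundary_face_census(tets),
         region = as.character(region), spacing = spacing),
    class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary faces\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_faces)))
  cat(sprintf("  volume %.4g mm^3, regions: %s\n",
              sum(tet_volumes(x)), paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

# Signed volumes det([b-a; c-a; d-a])/6 for each tet, vectorized.
tet_volumes_signed <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  u <- nodes[tets[, 2L], , drop = FALSE] - a
  v <- nodes[tets[, 3L], , drop = FALSE] - a
  w <- nodes[tets[, 4L], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Tetrahedron volumes
#' @param mesh a [tet_mesh()].
#' @return numeric vector of volumes (mm^3), one per tetrahedron.
#' @export
tet_volumes <- function(mesh) {
  abs(tet_volumes_signed(mesh$nodes, mesh$tets))
}

#' Tetrahedron centroids
#' @param mesh a [tet_mesh()].
#' @return numeric t x 3 matrix of centroids (mm).
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

# Faces occurring in exactly one tet are the surface. Returns an f x 3
# matrix of sorted node triples.
boundary_face_census <- function(tets) {
  f1 <- tets[, c(2L, 3L, 4L), drop = FALSE]
  f2 <- tets[, c(1L, 3L, 4L), drop = FALSE]
  f3 <- tets[, c(1L, 2L, 4L), drop = FALSE]
  f4 <- tets[, c(1L, 2L, 3L), drop = FALSE]
  faces <- rbind(f1, f2, f3, f4)
  faces <- t(apply(faces, 1L, sort.int))
  key <- paste(faces[, 1L], faces[, 2L], faces[, 3L])
  counts <- table(key)
  if (any(counts > 2L))
    stop("non-manifold mesh: a face is shared by more than two tetrahedra")
  single <- names(counts)[counts == 1L]
  out <- faces[match(single, key), , drop = FALSE]
  storage.mode(out) <- "integer"
  out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE]
}

#' Build a structured tetrahedral box mesh
#'
#' Fills an axis-aligned box with a regular hexahedral grid and splits
#' every cell into six tetrahedra along the main diagonal (Kuhn
#' subdivision), which is conforming across neighbouring cells. This is
#' the synthetic stand-in for a segmented-anatomy mesh: the
#' reconstruction machinery is mesh-agnostic.
#'
#' @param extent length-3 numeric, box edge lengths (mm).
#' @param spacing grid spacing (mm); each extent dimension must be an
#'   integer multiple of it and at least twice it.
#' @param origin length-3 numeric, minimum corner (mm).
#' @return a [tet_mesh()] with all tets labelled `"Muscle"`.
#' @export
build_structured_tet_mesh <- function(extent, spacing, origin = c(0, 0, 0)) {
  extent <- as.numeric(extent)
  if (length(extent) != 3L || any(!is.finite(extent)))
    stop("extent must be three finite box dimensions (mm)")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (any(extent < spacing - 1e-9))
    stop("degenerate extent: each dimension must hold at least one cell")
  ncell <- round(extent / spacing)
  if (any(abs(ncell * spacing - extent) > 1e-6 * spacing))
    stop("each extent dimension must be an integer multiple of spacing")
  nx <- ncell[1L] + 1L; ny <- ncell[2L] + 1L; nz <- ncell[3L] + 1L

  xs <- origin[1L] + spacing * (0:ncell[1L])
  ys <- origin[2L] + spacing * (0:ncell[2L])
  zs <- origin[3L] + spacing * (0:ncell[3L])
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  colnames(nodes) <- c("x", "y", "z")

  nid <- function(i, j, k) i + nx * (j + ny * k) + 1L
  ci <- rep(0:(ncell[1L] - 1L), times = ncell[2L] * ncell[3L])
  cj <- rep(rep(0:(ncell[2L] - 1L), each = ncell[1L]), times = ncell[3L])
  ck <- rep(0:(ncell[3L] - 1L), each = ncell[1L] * ncell[2L])

  # Kuhn split: one tet per permutation of the unit steps ex, ey, ez,
  # each containing the main diagonal; odd permutations are re-oriented.
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  even <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  steps <- diag(3L)
  tet_list <- vector("list", 6L)
  for (p in seq_len(6L)) {
    s1 <- steps[perms[p, 1L], ]
    s2 <- s1 + steps[perms[p, 2L], ]
    v0 <- nid(ci, cj, ck)
    v1 <- nid(ci + s1[1L], cj + s1[2L], ck + s1[3L])
    v2 <- nid(ci + s2[1L], cj + s2[2L], ck + s2[3L])
    v3 <- nid(ci + 1L, cj + 1L, ck + 1L)
    tet_list[[p]] <- if (even[p]) cbind(v0, v1, v2, v3) else cbind(v0, v2, v1, v3)
  }
  tets <- do.call(rbind, tet_list)
  tet_mesh(nodes, tets, spacing = spacing)
}

#' Source and organ geometries
#'
#' Simple solid primitives used both for embedding ground-truth sources
#' and for carving tissue regions out of a phantom. The cylinder axis is
#' z.
#'
#' @param shape one of `"sphere"`, `"cube"`, `"cylinder"`, `"ellipsoid"`.
#' @param center length-3 numeric centre (mm).
#' @param dims shape parameters (mm): sphere `radius`; cube `side`;
#'   cylinder `c(radius, height)`; ellipsoid semi-axes `c(a, b, c)`.
#' @return an object of class `source_geometry`.
#' @export
source_geometry <- function(shape = c("sphere", "cube", "cylinder", "ellipsoid"),
                            center, dims) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  dims <- as.numeric(dims)
  if (length(center) != 3L) stop("center must be a 3D point")
  need <- c(sphere = 1L, cube = 1L, cylinder = 2L, ellipsoid = 3L)[[shape]]
  if (length(dims) != need)
    stop(sprintf("shape '%s' needs %d dimension parameter(s)", shape, need))
  if (any(dims <= 0)) stop("all geometry dimensions must be > 0")
  structure(list(shape = shape, center = center, dims = dims),
            class = "source_geometry")
}

#' Point-in-geometry test
#'
#' @param geom a [source_geometry()].
#' @param pts numeric n x 3 matrix of points (mm).
#' @param strict logical; if `TRUE` points on the surface are excluded.
#' @return logical vector of containment flags.
#' @export
geometry_contains <- function(geom, pts, strict = FALSE) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  d <- sweep(pts, 2L, geom$center)
  cmp <- if (strict) function(a, b) a < b else function(a, b) a <= b
  switch(geom$shape,
    sphere = cmp(sqrt(rowSums(d^2)), geom$dims[1L]),
    cube = {
      h <- geom$dims[1L] / 2
      cmp(abs(d[, 1L]), h) & cmp(abs(d[, 2L]), h) & cmp(abs(d[, 3L]), h)
    },
    cylinder = {
      r <- geom$dims[1L]; h <- geom$dims[2L] / 2
      cmp(sqrt(d[, 1L]^2 + d[, 2L]^2), r) & cmp(abs(d[, 3L]), h)
    },
    ellipsoid = cmp(d[, 1L]^2 / geom$dims[1L]^2 +
                    d[, 2L]^2 / geom$dims[2L]^2 +
                    d[, 3L]^2 / geom$dims[3L]^2, 1))
}

#' Label mesh tetrahedra with tissue regions
#'
#' Each tetrahedron is labelled by the last region whose geometry
#' contains its centroid; tets in no region keep `default_tissue`.
#' Centroid containment is deterministic and leaves no ties.
#'
#' @param mesh a [tet_mesh()].
#' @param regions list of `list(geometry = <source_geometry>, tissue =
#'   <name>)` entries, applied in order.
#' @param default_tissue tissue name for uncovered tets.
#' @param optics optics table used to validate tissue names (default
#'   [tissue_optics()]).
#' @return the mesh with an updated `region` field.
#' @export
assign_regions <- function(mesh, regions = list(), default_tissue = "Muscle",
                           optics = tissue_optics()) {
  tissues <- c(default_tissue, vapply(regions, `[[`, "", "tissue"))
  unknown <- setdiff(tissues, rownames(optics))
  if (length(unknown))
    stop("unknown tissue name(s): ", paste(unknown, collapse = ", "))
  lab <- rep(default_tissue, nrow(mesh$tets))
  cent <- tet_centroids(mesh)
  for (rg in regions) {
    inside <- geometry_contains(rg$geometry, cent)
    lab[inside] <- rg$tissue
  }
  mesh$region <- lab
  mesh
}

#' Ground-truth source nodes and volume
#'
#' Finds all mesh nodes strictly inside a source geometry. The source
#' volume `V_T` is computed by fractional vertex counting: a tetrahedron
#' with k of its 4 vertices in the node set contributes k/4 of its
#' volume, so sources near the mesh resolution are not quantized to
#' zero.
#'
#' @param mesh a [tet_mesh()].
#' @param src a [source_geometry()].
#' @return list with `nodes` (sorted indices of the truth set T),
#'   `indicator` (0/1 vector over all mesh nodes), `volume` (`V_T`,
#'   mm^3) and `center` (the geometry centre).
#' @export
true_source_nodes <- function(mesh, src) {
  inside <- geometry_contains(src, mesh$nodes, strict = TRUE)
  idx <- which(inside)
  if (length(idx) == 0L)
    stop("source smaller than mesh resolution; refine spacing")
  indicator <- as.numeric(inside)
  list(nodes = idx, indicator = indicator,
       volume = node_set_volume(mesh, idx), center = src$center)
}

#' Fractional-vertex volume of a node set
#'
#' Shared volume rule for the truth set `V_T` and the reconstructed set
#' `V_R`: each tetrahedron contributes (vertices in set)/4 of its
#' volume.
#'
#' @param mesh a [tet_mesh()].
#' @param nodes integer vector of node indices.
#' @return total volume (mm^3).
#' @export
node_set_volume <- function(mesh, nodes) {
  inset <- logical(nrow(mesh$nodes))
  inset[nodes] <- TRUE
  k <- inset[mesh$tets[, 1L]] + inset[mesh$tets[, 2L]] +
       inset[mesh$tets[, 3L]] + inset[mesh$tets[, 4L]]
  sum(tet_volumes(mesh) * k) / 4
}
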