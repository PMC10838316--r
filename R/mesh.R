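#' @importFrom stats median quantile rnorm runif setNames complete.cases
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE
utils::globalVariables(".N") # data.table group-size symbol

TISSUE_LABELS <- c("skin", "skull", "csf", "gray", "white", "lesion")

#' Labeled tetrahedral mesh
#'
#' Container for an unstructured tetrahedral volume mesh with one tissue
#' label per element and an explicit outer (skin) boundary surface.
#' Coordinates are millimetres in RAS orientation (x right, y anterior,
#' z superior), origin at the model centre.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per tetrahedron, four node indices.
#' @param boundary integer matrix, one row per boundary triangle, three
#'   node indices; must form a closed surface.
#' @param labels character vector, one tissue label per tetrahedron, drawn
#'   from `skin`, `skull`, `csf`, `gray`, `white`, `lesion`.
#' @param validate check mesh invariants (positive volumes, watertight
#'   boundary, node coverage, label set) after construction.
#'
#' @return An object of class `tet_mesh`: a list with elements `nodes`,
#'   `tets`, `boundary`, `labels`. Tetrahedra are reoriented so all signed
#'   volumes are strictly positive.
#' @export
tet_mesh <- function(nodes, tets, boundary, labels, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  boundary <- as.matrix(boundary)
  storage.mode(boundary) <- "integer"
  labels <- as.character(labels)
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns (x, y, z in mm)")
  if (ncol(tets) != 4L) stop("`tets` must have 4 columns")
  if (ncol(boundary) != 3L) stop("`boundary` must have 3 columns")
  if (length(labels) != nrow(tets)) {
    stop("`labels` must have one entry per tetrahedron")
  }
  mesh <- structure(
    list(nodes = nodes, tets = tets, boundary = boundary, labels = labels),
    class = "tet_mesh"
  )
  mesh <- fix_tet_orientation(mesh)
  if (validate) validate_tet_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "<tet_mesh> %d nodes, %d tets, %d boundary facets\n",
    nrow(x$nodes), nrow(x$tets), nrow(x$boundary)
  ))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Signed volumes (mm^3) of all tets; positive for correctly oriented elements.
tet_signed_volumes <- function(mesh) {
  p1 <- mesh$nodes[mesh$tets[, 1L], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2L], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$tets[, 3L], , drop = FALSE] - p1
  c <- mesh$nodes[mesh$tets[, 4L], , drop = FALSE] - p1
  det3_rows(a, b, c) / 6
}

# Row-wise determinant of the 3x3 matrices stacked as rows of a, b, c.
det3_rows <- function(a, b, c) {
  a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
    a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
    a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
}

fix_tet_orientation <- function(mesh) {
  v <- tet_signed_volumes(mesh)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- mesh$tets[neg, 3L]
    mesh$tets[neg, 3L] <- mesh$tets[neg, 4L]
    mesh$tets[neg, 4L] <- tmp
  }
  mesh
}

#' Tetrahedron volumes
#' @param mesh a [tet_mesh()].
#' @return numeric vector of element volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  abs(tet_signed_volumes(mesh))
}

#' Tetrahedron centroids
#' @param mesh a [tet_mesh()].
#' @return numeric matrix (n_tets x 3), mm.
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
}

facet_vertices <- function(mesh, facets = mesh$boundary) {
  list(
    p1 = mesh$nodes[facets[, 1L], , drop = FALSE],
    p2 = mesh$nodes[facets[, 2L], , drop = FALSE],
    p3 = mesh$nodes[facets[, 3L], , drop = FALSE]
  )
}

#' Boundary facet areas, centroids and outward normals
#'
#' Outward orientation is fixed by pointing each facet normal away from the
#' volume centroid of the mesh (valid for star-shaped scalp surfaces).
#'
#' @param mesh a [tet_mesh()].
#' @return list with `areas` (mm^2), `centroids` (F x 3), `normals`
#'   (F x 3 unit rows).
#' @export
boundary_geometry <- function(mesh) {
  fv <- facet_vertices(mesh)
  e1 <- fv$p2 - fv$p1
  e2 <- fv$p3 - fv$p1
  cr <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  areas <- 0.5 * sqrt(rowSums(cr^2))
  centroids <- (fv$p1 + fv$p2 + fv$p3) / 3
  normals <- cr / sqrt(rowSums(cr^2))
  centre <- colMeans(mesh$nodes)
  outward <- rowSums(normals * sweep(centroids, 2L, centre)) < 0
  normals[outward, ] <- -normals[outward, , drop = FALSE]
  list(areas = areas, centroids = centroids, normals = normals)
}

# All faces of all tets as a data.table keyed by sorted node triple,
# with the owning tet index and the opposite (4th) node.
tet_faces_table <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  face_idx <- rbind(
    cbind(tets[, 2L], tets[, 3L], tets[, 4L], tets[, 1L]),
    cbind(tets[, 1L], tets[, 3L], tets[, 4L], tets[, 2L]),
    cbind(tets[, 1L], tets[, 2L], tets[, 4L], tets[, 3L]),
    cbind(tets[, 1L], tets[, 2L], tets[, 3L], tets[, 4L])
  )
  f1 <- face_idx[, 1L]; f2 <- face_idx[, 2L]; f3 <- face_idx[, 3L]
  lo <- pmin(f1, f2, f3)
  hi <- pmax(f1, f2, f3)
  mid <- f1 + f2 + f3 - lo - hi
  data.table::data.table(
    a = lo, b = mid, c = hi,
    opposite = face_idx[, 4L],
    tet = rep.int(seq_len(m), 4L)
  )
}

# Faces appearing exactly once across all tets = the outer boundary.
boundary_from_tets <- function(mesh) {
  ft <- tet_faces_table(mesh)
  a <- b <- c <- NULL # data.table NSE
  counts <- ft[, list(n = .N), by = list(a, b, c)]
  single <- counts[counts$n == 1L, ]
  as.matrix(single[, list(a, b, c)])
}

#' Validate mesh invariants
#'
#' Checks strictly positive element volumes, a closed (watertight) boundary
#' surface in which every boundary edge is shared by exactly two boundary
#' triangles, full node coverage, and labels drawn from the tissue set.
#'
#' @param mesh a [tet_mesh()].
#' @return `invisible(TRUE)`; stops with a descriptive error otherwise.
#' @export
validate_tet_mesh <- function(mesh) {
  v <- tet_signed_volumes(mesh)
  if (any(v <= 0)) {
    stop(sprintf("mesh has %d non-positive tet volumes", sum(v <= 0)))
  }
  used <- unique(as.vector(mesh$tets))
  if (length(used) != nrow(mesh$nodes)) {
    stop("mesh has nodes not referenced by any tetrahedron")
  }
  bad <- setdiff(unique(mesh$labels), TISSUE_LABELS)
  if (length(bad)) {
    stop("unknown tissue labels: ", paste(bad, collapse = ", "))
  }
  tri <- mesh$boundary
  edges <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  key <- paste(edges[, 1L], edges[, 2L])
  tab <- table(key)
  if (any(tab != 2L)) {
    stop("boundary surface is not watertight (edge shared by != 2 facets)")
  }
  invisible(TRUE)
}

# Euclidean norms of matrix rows.
row_norms <- function(x) sqrt(rowSums(x^2))

# Intersect rays from `origin` along unit `directions` (k x 3) with the
# boundary surface; returns k x 3 matrix of intersection points.
# Moller-Trumbore, vectorized over facets for each ray.
ray_surface_points <- function(mesh, directions, origin = colMeans(mesh$nodes)) {
  directions <- rbind(directions)
  fv <- facet_vertices(mesh)
  e1 <- fv$p2 - fv$p1
  e2 <- fv$p3 - fv$p1
  out <- matrix(NA_real_, nrow(directions), 3L)
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    d <- d / sqrt(sum(d^2))
    pvec <- cbind(
      d[2L] * e2[, 3L] - d[3L] * e2[, 2L],
      d[3L] * e2[, 1L] - d[1L] * e2[, 3L],
      d[1L] * e2[, 2L] - d[2L] * e2[, 1L]
    )
    det <- rowSums(e1 * pvec)
    tvec <- sweep(fv$p1, 2L, origin, "-")
    tvec <- -tvec
    u <- rowSums(tvec * pvec) / det
    qvec <- cbind(
      tvec[, 2L] * e1[, 3L] - tvec[, 3L] * e1[, 2L],
      tvec[, 3L] * e1[, 1L] - tvec[, 1L] * e1[, 3L],
      tvec[, 1L] * e1[, 2L] - tvec[, 2L] * e1[, 1L]
    )
    tt <- rowSums(e2 * qvec) / det
    v <- (d[1L] * qvec[, 1L] + d[2L] * qvec[, 2L] + d[3L] * qvec[, 3L]) / det
    eps <- 1e-9
    hit <- which(is.finite(det) & abs(det) > 1e-12 &
                   u >= -eps & v >= -eps & (u + v) <= 1 + eps & tt > 0)
    if (!length(hit)) {
      stop("ray does not intersect the boundary surface")
    }
    t_hit <- max(tt[hit]) # outermost intersection = skin
    out[k, ] <- origin + t_hit * d
  }
  out
}
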