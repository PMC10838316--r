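#' Default tissue conductivities (S/m)
#'
#' Isotropic conductivities per tissue compartment: gray matter 0.265,
#' white matter 0.126, CSF 1.65, skull 0.010, skin 0.465 and stroke
#' lesion 0.8087 S/m (the latter an average over reference values for
#' chronic brain lesions, distinguishing lesioned tissue from CSF).
#'
#' @param ... named overrides, e.g. `lesion = 1.0`.
#' @return named numeric vector, label -> conductivity (S/m).
#' @export
#' @examples
#' conductivity_map()
#' conductivity_map(skull = 0.008)
conductivity_map <- function(...) {
  sigma <- c(
    skin = 0.465, skull = 0.010, csf = 1.65,
    gray = 0.265, white = 0.126, lesion = 0.8087
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(sigma))
    if (length(bad)) stop("unknown tissue labels: ", paste(bad, collapse = ", "))
    sigma[names(over)] <- unlist(over)
  }
  if (any(sigma <= 0)) stop("conductivities must be strictly positive")
  sigma
}

# Geodesic triangulation of the unit sphere: icosahedron with each face
# subdivided at frequency n (n^2 triangles per face), vertices projected
# onto the sphere. Returns list(vertices = V x 3, triangles = T x 3).
icosphere <- function(n) {
  stopifnot(n >= 1)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # barycentric lattice points (i, j, k >= 0, i + j + k = n) on each face,
  # deduplicated across shared edges/corners via rounded coordinate keys
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  vlist <- list()
  nv <- 0L
  tri <- matrix(0L, nrow = 20L * n * n, ncol = 3L)
  nt <- 0L
  get_vertex <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(sprintf("%.9f", round(p, 9)), collapse = ",")
    idx <- key_env[[key]]
    if (is.null(idx)) {
      nv <<- nv + 1L
      vlist[[nv]] <<- p
      key_env[[key]] <- nv
      idx <- nv
    }
    idx
  }
  for (f in seq_len(nrow(faces))) {
    a <- verts[faces[f, 1L], ]
    b <- verts[faces[f, 2L], ]
    c <- verts[faces[f, 3L], ]
    # index grid of lattice points on this face
    idx <- matrix(0L, n + 1L, n + 1L)
    for (i in 0:n) {
      for (j in 0:(n - i)) {
        p <- (i * a + j * b + (n - i - j) * c) / n
        idx[i + 1L, j + 1L] <- get_vertex(p)
      }
    }
    for (i in 0:(n - 1L)) {
      for (j in 0:(n - 1L - i)) {
        nt <- nt + 1L
        tri[nt, ] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
        if (j < n - 1L - i) {
          nt <- nt + 1L
          tri[nt, ] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
        }
      }
    }
  }
  list(
    vertices = do.call(rbind, vlist[seq_len(nv)]),
    triangles = tri[seq_len(nt), , drop = FALSE]
  )
}

# Radial layer schedule: all interface radii, with intermediate layers so
# that no radial gap exceeds mesh_size, ending at an innermost layer of
# radius ~mesh_size that is closed by a central vertex fan.
radial_layers <- function(layer_radii, mesh_size) {
  radii <- c()
  bounds <- c(layer_radii, 0)
  for (i in seq_along(layer_radii)) {
    lo <- bounds[i + 1L]
    hi <- bounds[i]
    if (i == length(layer_radii)) lo <- max(mesh_size, 1e-6)
    nseg <- max(1L, ceiling((hi - lo) / mesh_size))
    radii <- c(radii, seq(hi, lo, length.out = nseg + 1L)[-(nseg + 1L)])
  }
  c(radii, max(mesh_size, 1e-6))
}

#' Build a layered-sphere synthetic head model
#'
#' Constructs a five-compartment spherical volume conductor (skin, skull,
#' CSF, gray matter, white matter) as a conforming tetrahedral mesh:
#' concentric geodesic sphere surfaces, with every tissue interface an
#' explicit mesh surface, connected by consistently split triangular
#' prisms and a central vertex fan. Fiducials (nasion, inion, left/right
#' preauricular) are placed at the anatomical poles of the RAS axes and
#' the hand-motor target inside the gray-matter shell on the affected
#' side, beneath the C3/C4 position.
#'
#' @param layer_radii strictly decreasing outer radii (mm) of the skin,
#'   skull, CSF, gray and white compartments. Default `c(92, 86, 80, 78, 70)`.
#' @param conductivities named label -> S/m map, see [conductivity_map()].
#' @param mesh_size target element edge length (mm).
#' @param affected_side `"left"` or `"right"`: hemisphere carrying the
#'   stroke lesion and the stimulation target.
#' @param seed integer; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return An object of class `head_model`: list with `mesh`
#'   ([tet_mesh()]), `conductivities`, `fiducials` (named 4 x 3 matrix),
#'   `target` (mm, snapped inside a gray element), `affected_side`,
#'   `layer_radii`, `mesh_size`, `seed`.
#' @export
#' @examples
#' head <- build_layered_sphere_head(mesh_size = 14)
#' head$mesh
build_layered_sphere_head <- function(layer_radii = c(92, 86, 80, 78, 70),
                                      conductivities = conductivity_map(),
                                      mesh_size = 8,
                                      affected_side = c("left", "right"),
                                      seed = 1L) {
  affected_side <- match.arg(affected_side)
  if (length(layer_radii) != 5L) {
    stop("`layer_radii` must give 5 shell radii (skin, skull, csf, gray, white)")
  }
  if (any(diff(layer_radii) >= 0)) {
    stop("invalid geometry: `layer_radii` must be strictly decreasing")
  }
  if (mesh_size <= 0) stop("`mesh_size` must be positive")
  if (mesh_size > min(layer_radii)) {
    stop("resolution error: `mesh_size` exceeds the innermost shell radius")
  }
  shells <- c("skin", "skull", "csf", "gray", "white")
  missing_sigma <- setdiff(shells, names(conductivities))
  if (length(missing_sigma)) {
    stop("missing conductivities for: ", paste(missing_sigma, collapse = ", "))
  }

  r_outer <- layer_radii[1L]
  freq <- max(3L, ceiling(1.05 * r_outer / mesh_size))
  ico <- icosphere(freq)
  sv <- ico$vertices
  tri <- ico$triangles
  nv <- nrow(sv)

  radii <- radial_layers(layer_radii, mesh_size)
  n_layers <- length(radii)

  nodes <- matrix(0, n_layers * nv + 1L, 3L)
  for (k in seq_len(n_layers)) {
    nodes[((k - 1L) * nv + 1L):(k * nv), ] <- sv * radii[k]
  }
  centre_idx <- n_layers * nv + 1L
  nodes[centre_idx, ] <- c(0, 0, 0)

  # sort triangle vertices ascending: makes prism diagonal splits agree
  # across shared quadrilateral faces of adjacent prisms
  tri_sorted <- t(apply(tri, 1L, sort.int))
  v0 <- tri_sorted[, 1L]; v1 <- tri_sorted[, 2L]; v2 <- tri_sorted[, 3L]

  tets_list <- vector("list", n_layers)
  for (k in seq_len(n_layers - 1L)) {
    top <- (k - 1L) * nv
    bot <- k * nv
    tets_list[[k]] <- rbind(
      cbind(top + v0, top + v1, top + v2, bot + v0),
      cbind(top + v1, top + v2, bot + v0, bot + v1),
      cbind(top + v2, bot + v0, bot + v1, bot + v2)
    )
  }
  core_off <- (n_layers - 1L) * nv
  tets_list[[n_layers]] <- cbind(
    core_off + tri[, 1L], core_off + tri[, 2L], core_off + tri[, 3L],
    centre_idx
  )
  tets <- do.call(rbind, tets_list)

  boundary <- tri # layer 1 node indices are 1..nv
  mesh <- tet_mesh(nodes, tets, boundary,
                   labels = rep("white", nrow(tets)), validate = FALSE)

  # label by centroid radius against interface radii
  cen_r <- row_norms(tet_centroids(mesh))
  lab_idx <- findInterval(-cen_r, -layer_radii) # 1=skin .. 5=white
  lab_idx[lab_idx > 5L] <- 5L
  lab_idx[lab_idx < 1L] <- 1L
  mesh$labels <- shells[lab_idx]
  validate_tet_mesh(mesh)
  if (!all(shells %in% mesh$labels)) {
    stop("resolution error: mesh too coarse, some tissue shells are empty")
  }

  fiducials <- rbind(
    nasion = c(0, r_outer, 0),
    inion = c(0, -r_outer, 0),
    left_preauricular = c(-r_outer, 0, 0),
    right_preauricular = c(r_outer, 0, 0)
  )

  # hand-knob direction: beneath C3 (left) / C4 (right), 20% of the
  # ear-to-ear arc from the vertex
  theta <- 0.2 * pi
  sgn <- if (affected_side == "left") -1 else 1
  dir <- c(sgn * sin(theta), 0, cos(theta))
  r_target <- (layer_radii[4L] + layer_radii[5L]) / 2 # mid-gray depth
  target_raw <- dir * r_target
  target <- snap_to_gray(mesh, target_raw)

  structure(
    list(
      mesh = mesh, conductivities = conductivities, fiducials = fiducials,
      target = target, affected_side = affected_side,
      layer_radii = layer_radii, mesh_size = mesh_size, seed = as.integer(seed)
    ),
    class = "head_model"
  )
}

# Snap a coordinate to the centroid of the nearest gray-matter element,
# guaranteeing the target lies inside a gray tetrahedron.
snap_to_gray <- function(mesh, point) {
  gray <- which(mesh$labels == "gray")
  if (!length(gray)) stop("mesh has no gray-matter elements")
  cen <- tet_centroids(mesh)[gray, , drop = FALSE]
  d2 <- rowSums(sweep(cen, 2L, point)^2)
  cen[which.min(d2), ]
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf(
    "<head_model> shells %s mm, mesh_size %g mm, affected side %s\n",
    paste(x$layer_radii, collapse = "/"), x$mesh_size, x$affected_side
  ))
  print(x$mesh)
  cat(sprintf("  target: (%.1f, %.1f, %.1f) mm\n",
              x$target[1L], x$target[2L], x$target[3L]))
  invisible(x)
}

#' Per-element conductivities of a head model
#' @param head a `head_model`.
#' @return numeric vector, S/m, one entry per tetrahedron.
#' @export
element_conductivities <- function(head) {
  sigma <- head$conductivities[head$mesh$labels]
  if (anyNA(sigma)) {
    stop("missing conductivity for labels: ",
         paste(setdiff(unique(head$mesh$labels), names(head$conductivities)),
               collapse = ", "))
  }
  unname(sigma)
}
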