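#' Locate 10-20 scalp positions from fiducials
#'
#' Constructs head axes from the four fiducials (nasion, inion, left and
#' right preauricular points) and places standard 10-20 positions by arc
#' fractions: `Cz` at the crossing of the 50% nasion-inion and 50%
#' ear-to-ear arcs, `C3`/`C4` at 20% of the ear-to-ear arc from `Cz`
#' toward the left/right preauricular point (T3/T4 at 40%), and `Fz`,
#' `Pz`, `Oz` along the mid-sagittal arc. All points are projected onto
#' the boundary surface along rays from the head centre.
#'
#' @param head a `head_model`.
#' @return named list of scalp coordinates (mm).
#' @export
locate_ten_twenty_positions <- function(head) {
  fid <- head$fiducials
  needed <- c("nasion", "inion", "left_preauricular", "right_preauricular")
  if (is.null(fid) || !all(needed %in% rownames(fid))) {
    stop("fiducial error: head model must carry all four fiducials")
  }
  origin <- colMeans(head$mesh$nodes)
  yv <- fid["nasion", ] - origin
  yv <- yv / sqrt(sum(yv^2))
  xv <- fid["right_preauricular", ] - origin
  xv <- xv - sum(xv * yv) * yv
  xv <- xv / sqrt(sum(xv^2))
  zv <- c(
    xv[2L] * yv[3L] - xv[3L] * yv[2L],
    xv[3L] * yv[1L] - xv[1L] * yv[3L],
    xv[1L] * yv[2L] - xv[2L] * yv[1L]
  )
  zv <- zv / sqrt(sum(zv^2))
  ang <- function(frac) frac * pi # fraction of a half-circumference arc
  dirs <- rbind(
    Cz = zv,
    C3 = cos(ang(0.2)) * zv - sin(ang(0.2)) * xv,
    C4 = cos(ang(0.2)) * zv + sin(ang(0.2)) * xv,
    T3 = cos(ang(0.4)) * zv - sin(ang(0.4)) * xv,
    T4 = cos(ang(0.4)) * zv + sin(ang(0.4)) * xv,
    Fz = cos(ang(0.2)) * zv + sin(ang(0.2)) * yv,
    Pz = cos(ang(0.2)) * zv - sin(ang(0.2)) * yv,
    Oz = cos(ang(0.4)) * zv - sin(ang(0.4)) * yv
  )
  pts <- ray_surface_points(head$mesh, dirs, origin = origin)
  rownames(pts) <- rownames(dirs)
  out <- lapply(seq_len(nrow(pts)), function(i) pts[i, ])
  names(out) <- rownames(pts)
  out
}

# Local tangent frame at a scalp point: outward normal along the ray from
# the head centre, first tangent axis toward the nasion (fixed rectangle
# orientation convention), second completing a right-handed frame.
tangent_frame <- function(head, point) {
  origin <- colMeans(head$mesh$nodes)
  n <- point - origin
  n <- n / sqrt(sum(n^2))
  toward_nasion <- head$fiducials["nasion", ] - point
  e1 <- toward_nasion - sum(toward_nasion * n) * n
  if (sqrt(sum(e1^2)) < 1e-8) { # point at/near nasion: fall back to superior
    up <- c(0, 0, 1)
    e1 <- up - sum(up * n) * n
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2L] * e1[3L] - n[3L] * e1[2L],
    n[3L] * e1[1L] - n[1L] * e1[3L],
    n[1L] * e1[2L] - n[2L] * e1[1L]
  )
  list(normal = n, e1 = e1, e2 = e2, origin = origin)
}

# Snap a point onto the skin surface along the ray from the head centre.
snap_to_surface <- function(head, point, snap_tol = Inf) {
  origin <- colMeans(head$mesh$nodes)
  d <- point - origin
  if (sqrt(sum(d^2)) < 1e-9) stop("placement error: point at the head centre")
  snapped <- ray_surface_points(head$mesh, rbind(d), origin = origin)[1L, ]
  if (sqrt(sum((snapped - point)^2)) > snap_tol) {
    stop(sprintf(
      "placement error: point is %.1f mm from the skin surface (tolerance %.1f mm)",
      sqrt(sum((snapped - point)^2)), snap_tol
    ))
  }
  snapped
}

#' Construct a rectangular electrode patch on the skin surface
#'
#' Snaps the requested centre onto the scalp, builds a local tangent
#' frame (first axis toward the nasion), and selects the boundary facets
#' whose centroids project inside the `size` rectangle in that frame and
#' lie within a normal-offset band that accommodates scalp curvature.
#'
#' @param head a `head_model`.
#' @param center requested centre (mm); must lie within `snap_tol` of the
#'   skin surface.
#' @param size width x height (mm); default `c(50, 50)` (5 x 5 cm pad).
#' @param current signed injected current (mA); positive = anode.
#' @param snap_tol maximum centre-to-surface snap distance (mm).
#' @param normal_band half-width (mm) of the accepted offset band along
#'   the patch normal.
#' @return An object of class `electrode_patch`: `center` (snapped),
#'   `size`, `facet_ids`, `area` (mm^2), `current`, `frame`.
#' @export
make_patch <- function(head, center, size = c(50, 50), current,
                       snap_tol = 15, normal_band = 12) {
  if (length(size) == 1L) size <- c(size, size)
  if (missing(current) || current == 0) {
    stop("montage error: patch current must be nonzero")
  }
  center <- snap_to_surface(head, center, snap_tol = snap_tol)
  frame <- tangent_frame(head, center)
  geo <- boundary_geometry(head$mesh)
  d <- sweep(geo$centroids, 2L, center)
  offset <- as.numeric(d %*% frame$normal)
  u <- as.numeric(d %*% frame$e1)
  v <- as.numeric(d %*% frame$e2)
  sel <- which(abs(u) <= size[1L] / 2 & abs(v) <= size[2L] / 2 &
                 abs(offset) <= normal_band)
  if (!length(sel)) {
    stop("resolution error: no boundary facets under the electrode patch")
  }
  structure(
    list(
      center = center, size = size, facet_ids = sel,
      area = sum(geo$areas[sel]), current = current, frame = frame
    ),
    class = "electrode_patch"
  )
}

#' @export
print.electrode_patch <- function(x, ...) {
  cat(sprintf(
    "<electrode_patch> %g x %g mm at (%.1f, %.1f, %.1f), %d facets, %.0f mm^2, %+g mA\n",
    x$size[1L], x$size[2L], x$center[1L], x$center[2L], x$center[3L],
    length(x$facet_ids), x$area, x$current
  ))
  invisible(x)
}

#' Pair two electrode patches into a montage
#'
#' @param anode an `electrode_patch` with positive current.
#' @param cathode an `electrode_patch` with current `-anode$current`.
#' @param label `"conventional"`, `"optimized"` or `"custom"`.
#' @return An object of class `montage`.
#' @export
make_montage <- function(anode, cathode,
                         label = c("custom", "conventional", "optimized")) {
  label <- match.arg(label)
  if (is.null(anode) || is.null(cathode)) {
    stop("montage error: both anode and cathode are required")
  }
  if (anode$current <= 0) stop("montage error: anode current must be positive")
  if (abs(anode$current + cathode$current) > 1e-12) {
    stop("montage error: currents must sum to zero")
  }
  if (length(intersect(anode$facet_ids, cathode$facet_ids))) {
    stop("montage error: anode and cathode facets overlap")
  }
  structure(list(anode = anode, cathode = cathode, label = label),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage:%s> %+g mA\n", x$label, x$anode$current))
  print(x$anode)
  print(x$cathode)
  invisible(x)
}

#' Conventional bi-hemispheric C3/C4 montage
#'
#' Places the anode over the M1 hand area of the affected hemisphere (C3
#' for a left-sided stroke, C4 for right) and the cathode over the
#' contralesional M1 hand area, as 5 x 5 cm pads carrying `current` mA.
#'
#' @param head a `head_model`.
#' @param current anode current (mA), default 2.
#' @param size electrode size (mm), default `c(50, 50)`.
#' @return a `montage` labeled `"conventional"`.
#' @export
conventional_montage <- function(head, current = 2, size = c(50, 50)) {
  pos <- locate_ten_twenty_positions(head)
  if (head$affected_side == "left") {
    anode_pos <- pos$C3; cathode_pos <- pos$C4
  } else {
    anode_pos <- pos$C4; cathode_pos <- pos$C3
  }
  make_montage(
    make_patch(head, anode_pos, size = size, current = current),
    make_patch(head, cathode_pos, size = size, current = -current),
    label = "conventional"
  )
}

#' Build a candidate-electrode grid on the skin surface
#'
#' Lays an evenly spaced square lattice in the tangent plane at the
#' reference position (default spacing 11.11 mm) covering `±extent`,
#' projects every lattice point onto the skin surface along rays from
#' the head centre, and deduplicates points that land closer than half
#' the spacing. The reference position itself is always the first grid
#' point.
#'
#' @param head a `head_model`.
#' @param reference scalp coordinate the grid is centred on.
#' @param extent half-width of the lattice (mm); default 44.44 (a 9 x 9
#'   grid at the default spacing).
#' @param spacing nominal inter-candidate distance (mm), default 11.11.
#' @param snap_tol snap tolerance for the reference (mm).
#' @return An object of class `candidate_grid`: `points` (k x 3 matrix),
#'   `spacing`, `reference`.
#' @export
build_candidate_grid <- function(head, reference, extent = 44.44,
                                 spacing = 11.11, snap_tol = 15) {
  if (extent < 0) stop("`extent` must be >= 0")
  reference <- snap_to_surface(head, reference, snap_tol = snap_tol)
  frame <- tangent_frame(head, reference)
  if (extent == 0) {
    pts <- rbind(reference)
  } else {
    ticks <- unique(c(0, seq(spacing, extent + 1e-9, by = spacing)))
    ticks <- sort(unique(c(-ticks, ticks)))
    uv <- expand.grid(u = ticks, v = ticks)
    ord <- order(uv$u^2 + uv$v^2) # reference (0,0) first
    uv <- uv[ord, ]
    raw <- sweep(outer(uv$u, frame$e1) + outer(uv$v, frame$e2), 2L,
                 reference, "+")
    dirs <- sweep(raw, 2L, frame$origin)
    pts <- ray_surface_points(head$mesh, dirs, origin = frame$origin)
    keep <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))[-1L]) {
      prior <- pts[which(keep[seq_len(i - 1L)]), , drop = FALSE]
      if (min(row_norms(sweep(prior, 2L, pts[i, ]))) < spacing / 2) {
        keep[i] <- FALSE
      }
    }
    pts <- pts[keep, , drop = FALSE]
  }
  structure(
    list(points = unname(pts), spacing = spacing, reference = reference,
         extent = extent),
    class = "candidate_grid"
  )
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat(sprintf(
    "<candidate_grid> %d points, spacing %.2f mm, reference (%.1f, %.1f, %.1f)\n",
    nrow(x$points), x$spacing, x$reference[1L], x$reference[2L], x$reference[3L]
  ))
  invisible(x)
}
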