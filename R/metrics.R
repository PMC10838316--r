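#' Region-of-interest specification
#'
#' A spherical gray-matter target region: default radius 2 mm around the
#' hand-knob coordinate.
#'
#' @param center target coordinate (mm).
#' @param radius sphere radius (mm), > 0; default 2.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(center, radius = 2) {
  if (radius <= 0) stop("ROI radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 tissue_filter = "gray"),
            class = "roi_spec")
}

# Gray-matter elements whose centroids fall inside the ROI sphere,
# with their volumes. Errors (naming the nearest gray-centroid distance)
# if the sphere captures none.
roi_elements <- function(head, roi) {
  gray <- which(head$mesh$labels %in% roi$tissue_filter)
  if (!length(gray)) stop("roi error: mesh has no gray-matter elements")
  cen <- tet_centroids(head$mesh)[gray, , drop = FALSE]
  d <- row_norms(sweep(cen, 2L, roi$center))
  inside <- d <= roi$radius
  if (!any(inside)) {
    stop(sprintf(
      "roi error: no gray-matter element centroid within %.2f mm of the ROI centre (nearest at %.2f mm)",
      roi$radius, min(d)
    ))
  }
  list(elements = gray[inside], volumes = tet_volumes(head$mesh)[gray[inside]])
}

# Outward normal of the gray-matter outer surface (gray/CSF interface)
# at the surface point nearest `point`. Faces are oriented from the
# owning gray element toward the CSF side.
gray_surface_normal <- function(head, point) {
  mesh <- head$mesh
  ft <- tet_faces_table(mesh)
  lab <- mesh$labels[ft$tet]
  a <- b <- c <- NULL # data.table NSE
  ft$lab <- lab
  tet <- NULL # data.table NSE
  pairs <- ft[, list(n = .N, lab1 = lab[1L], lab2 = lab[.N],
                     tet_a = tet[1L], tet_b = tet[.N]), by = list(a, b, c)]
  iface <- pairs[pairs$n == 2L &
                   ((pairs$lab1 == "gray" & pairs$lab2 == "csf") |
                      (pairs$lab1 == "csf" & pairs$lab2 == "gray")), ]
  if (!nrow(iface)) stop("roi error: mesh has no gray/CSF interface")
  tri <- as.matrix(iface[, list(a, b, c)])
  p1 <- mesh$nodes[tri[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3L], , drop = FALSE]
  cen <- (p1 + p2 + p3) / 3
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  nrm <- nrm / row_norms(nrm)
  # orient outward (from gray toward CSF): flip any normal pointing toward
  # the centroid of the gray-owning tetrahedron
  gray_tet <- ifelse(iface$lab1 == "gray", iface$tet_a, iface$tet_b)
  tc <- tet_centroids(mesh)
  towards_gray <- rowSums(nrm * (tc[gray_tet, , drop = FALSE] - cen)) > 0
  nrm[towards_gray, ] <- -nrm[towards_gray, , drop = FALSE]
  i <- which.min(row_norms(sweep(cen, 2L, as.numeric(point))))
  list(normal = nrm[i, ], surface_point = cen[i, ])
}

#' Summarize the electric field in a gray-matter ROI
#'
#' Field strength at the target is the volume-weighted mean of the
#' element field magnitudes over the gray-matter elements whose centroids
#' fall inside the ROI sphere. The normal component is the volume-weighted
#' mean of the projection of the element field vectors onto the outward
#' normal of the gray-matter surface at the surface point nearest the ROI
#' centre (the physiologically polarizing direction).
#'
#' @param solution a `field_solution`.
#' @param head the `head_model` the solution was computed on.
#' @param roi a [roi_spec()].
#' @return object of class `roi_field_summary`: `mean_magnitude` (V/m),
#'   `normal_component` (signed V/m), `n_elements`, `normal_direction`.
#' @export
roi_summary <- function(solution, head, roi) {
  sel <- roi_elements(head, roi)
  w <- sel$volumes / sum(sel$volumes)
  E <- solution$field[sel$elements, , drop = FALSE]
  gs <- gray_surface_normal(head, roi$center)
  structure(
    list(
      mean_magnitude = sum(w * row_norms(E)),
      normal_component = sum(w * as.numeric(E %*% gs$normal)),
      n_elements = length(sel$elements),
      normal_direction = gs$normal
    ),
    class = "roi_field_summary"
  )
}

#' @export
print.roi_field_summary <- function(x, ...) {
  cat(sprintf(
    "<roi_field_summary> mean |E| = %.4g V/m, normal component = %+.4g V/m (%d elements)\n",
    x$mean_magnitude, x$normal_component, x$n_elements
  ))
  invisible(x)
}

#' Percent improvement of the optimized over the conventional field
#'
#' `((optimized - conventional) / conventional) * 100`.
#'
#' @param conventional_field field strength under the conventional
#'   montage (V/m); must be positive.
#' @param optimized_field field strength under the optimized montage (V/m).
#' @return percent improvement (positive = optimized stronger).
#' @export
#' @examples
#' improvement_pct(0.30, 0.36) # 20
improvement_pct <- function(conventional_field, optimized_field) {
  if (any(conventional_field <= 0)) {
    stop("domain error: conventional field must be positive")
  }
  (optimized_field - conventional_field) / conventional_field * 100
}

#' Distances between conventional and optimized montages
#'
#' Euclidean distances between electrode centres: anode-to-anode
#' (`d_anode`), cathode-to-cathode (`d_cathode`), their sum (`d_total`),
#' and the within-montage anode-cathode distances of both montages.
#'
#' @param conventional,optimized `montage` objects on the same head.
#' @return one-row tibble with columns `d_anode`, `d_cathode`, `d_total`,
#'   `within_conventional`, `within_optimized` (mm).
#' @export
montage_distances <- function(conventional, optimized) {
  dist3 <- function(p, q) sqrt(sum((p - q)^2))
  d_anode <- dist3(conventional$anode$center, optimized$anode$center)
  d_cathode <- dist3(conventional$cathode$center, optimized$cathode$center)
  tibble::tibble(
    d_anode = d_anode,
    d_cathode = d_cathode,
    d_total = d_anode + d_cathode,
    within_conventional = dist3(conventional$anode$center,
                                conventional$cathode$center),
    within_optimized = dist3(optimized$anode$center, optimized$cathode$center)
  )
}
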