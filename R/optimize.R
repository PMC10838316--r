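# Sparse operator extracting ROI-element field vectors from a nodal
# potential: F = G %*% v, stacked per element (3 rows each), in V/m.
roi_field_operator <- function(system, roi_sel) {
  mesh <- system$head$mesh
  els <- roi_sel$elements
  k <- length(els)
  ii <- jj <- integer(12L * k)
  xx <- numeric(12L * k)
  pos <- 0L
  for (i in 1:4) {
    g <- system$gradients[[i]][els, , drop = FALSE]
    for (d in 1:3) {
      idx <- (pos * k + 1L):((pos + 1L) * k)
      ii[idx] <- (seq_len(k) - 1L) * 3L + d
      jj[idx] <- mesh$tets[els, i]
      xx[idx] <- -1000 * g[, d]
      pos <- pos + 1L
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3L * k, nrow(mesh$nodes)))
}

# Volume-weighted mean |E| over ROI elements from a stacked field vector.
roi_score_from_stacked <- function(fvec, weights) {
  E <- matrix(fvec, ncol = 3L, byrow = TRUE)
  sum(weights * sqrt(rowSums(E^2)))
}

#' Score a montage: mean field magnitude in the target ROI
#'
#' Solves the head model under the montage and returns the
#' volume-weighted mean electric-field magnitude (V/m) over gray-matter
#' elements inside the ROI sphere — the optimization objective.
#'
#' @param head a `head_model`.
#' @param montage a `montage`.
#' @param roi a [roi_spec()].
#' @param system optional preassembled `tdcs_system` for this head.
#' @param factor optional [factorize_system()] result (direct solve).
#' @param tol CG tolerance when no factor is given.
#' @return scalar score (V/m).
#' @export
score_montage <- function(head, montage, roi, system = NULL, factor = NULL,
                          tol = 1e-9) {
  if (is.null(system)) system <- assemble_system(head)
  system <- apply_montage_currents(system, montage)
  if (all(system$load == 0)) return(0)
  sol <- solve_potential(system, tol = tol, factor = factor)
  roi_summary(sol, head, roi)$mean_magnitude
}

#' Compute lead fields for a candidate grid
#'
#' Solves the head once per candidate electrode (candidate at `+I`
#' against a shared reference return patch at `-I`). By linearity the
#' field of any candidate pair (a, c) is the difference of their lead
#' solutions, enabling exhaustive pair scoring at the cost of one solve
#' per candidate instead of one per pair.
#'
#' @param head a `head_model`.
#' @param candidates a `candidate_grid`.
#' @param reference an `electrode_patch` (the shared return), disjoint
#'   from every candidate patch.
#' @param system optional preassembled system.
#' @param factor optional prefactorization (strongly recommended for
#'   more than a couple of candidates).
#' @param size electrode size (mm) for candidate patches.
#' @param current lead current magnitude (mA).
#' @return object of class `lead_field_set`: `potentials` (nodes x k
#'   matrix), `patches` (list of `electrode_patch`), `reference`,
#'   `current`, `n_solves`.
#' @export
compute_lead_fields <- function(head, candidates, reference,
                                system = NULL, factor = NULL,
                                size = c(50, 50), current = 2) {
  if (!nrow(candidates$points)) stop("candidate grid is empty")
  if (is.null(system)) system <- assemble_system(head)
  if (is.null(factor)) factor <- factorize_system(system)
  k <- nrow(candidates$points)
  patches <- vector("list", k)
  n <- nrow(system$stiffness)
  loads <- matrix(0, n, k)
  for (i in seq_len(k)) {
    patch <- make_patch(head, candidates$points[i, ], size = size,
                        current = current)
    if (length(intersect(patch$facet_ids, reference$facet_ids))) {
      stop("montage error: candidate patch overlaps the reference patch")
    }
    patches[[i]] <- patch
    m <- make_montage(patch, ref_as_cathode(reference, -current))
    sys_i <- apply_montage_currents(system, m)
    loads[, i] <- sys_i$load
  }
  potentials <- solve_with_factor(factor, loads)
  potentials <- matrix(potentials, nrow = n)
  structure(
    list(potentials = potentials, patches = patches, reference = reference,
         current = current, n_solves = k),
    class = "lead_field_set"
  )
}

ref_as_cathode <- function(reference, current) {
  reference$current <- current
  reference
}

#' Optimize electrode placement by grid search with re-centering
#'
#' Exhaustively scores every admissible (anode, cathode) candidate pair
#' of the two grids using lead-field superposition, then re-centres both
#' grids on the incumbent best pair (keeping spacing and extent) and
#' repeats until the relative score improvement drops below `rel_tol` or
#' `max_iterations` is reached. Pairs whose electrode centres are closer
#' than `min_separation` are excluded to prevent pad contact. Among
#' score ties (within 1e-9 relative) the pair closest to the
#' conventional montage (then lowest candidate index) wins, which makes
#' the search fully deterministic.
#'
#' @param head a `head_model`.
#' @param roi a [roi_spec()].
#' @param anode_grid,cathode_grid `candidate_grid` objects.
#' @param config list of options: `current` (mA, default 2), `size`
#'   (electrode mm, default c(50, 50)), `min_separation` (mm, default 70),
#'   `max_iterations` (default 10), `rel_tol` (default 1e-4),
#'   `reference` (scalp point of the shared lead-field return patch;
#'   default the inion), `conventional` (montage used for tie-breaking).
#' @param system optional preassembled system; @param factor optional
#'   prefactorization.
#' @return object of class `optimization_result`: `montage` (labelled
#'   `"optimized"`), `score` (V/m), `n_evaluated`, `iterations`, `trace`
#'   (per-iteration best scores), `anode_grid`, `cathode_grid`.
#' @export
optimize_montage <- function(head, roi, anode_grid, cathode_grid,
                             config = list(), system = NULL, factor = NULL) {
  cfg <- utils::modifyList(
    list(current = 2, size = c(50, 50), min_separation = 70,
         max_iterations = 10L, rel_tol = 1e-4, reference = NULL,
         conventional = NULL),
    config
  )
  if (is.null(system)) system <- assemble_system(head)
  if (is.null(factor)) factor <- factorize_system(system)
  roi_sel <- roi_elements(head, roi)
  G <- roi_field_operator(system, roi_sel)
  w <- roi_sel$volumes / sum(roi_sel$volumes)

  ref_point <- cfg$reference %||% head$fiducials["inion", ]
  reference <- make_patch(head, ref_point, size = cfg$size,
                          current = -cfg$current)
  conv_centers <- if (!is.null(cfg$conventional)) {
    rbind(cfg$conventional$anode$center, cfg$conventional$cathode$center)
  } else {
    NULL
  }

  lead_cache <- new.env(hash = TRUE, parent = emptyenv())
  roi_fields_for <- function(grid) {
    pts <- grid$points
    keys <- apply(round(pts, 6), 1L, paste, collapse = ",")
    miss <- !vapply(keys, function(k) !is.null(lead_cache[[k]]), logical(1L))
    if (any(miss)) {
      sub <- grid
      sub$points <- pts[miss, , drop = FALSE]
      lf <- compute_lead_fields(head, sub, reference, system = system,
                                factor = factor, size = cfg$size,
                                current = cfg$current)
      Fm <- as.matrix(G %*% lf$potentials)
      mk <- keys[miss]
      for (i in seq_along(mk)) {
        lead_cache[[mk[i]]] <- list(f = Fm[, i], patch = lf$patches[[i]])
      }
    }
    list(
      f = vapply(keys, function(k) lead_cache[[k]]$f,
                 numeric(3L * length(roi_sel$elements))),
      patches = lapply(keys, function(k) lead_cache[[k]]$patch)
    )
  }

  best <- list(score = -Inf, anode = NULL, cathode = NULL)
  trace <- numeric(0)
  n_evaluated <- 0L
  ag <- anode_grid
  cg <- cathode_grid
  iter <- 0L
  repeat {
    iter <- iter + 1L
    la <- roi_fields_for(ag)
    lc <- roi_fields_for(cg)
    na <- ncol(la$f); nc <- ncol(lc$f)
    a_centers <- t(vapply(la$patches, function(p) p$center, numeric(3L)))
    c_centers <- t(vapply(lc$patches, function(p) p$center, numeric(3L)))
    sep <- outer(seq_len(na), seq_len(nc), function(i, j) {
      sqrt((a_centers[i, 1L] - c_centers[j, 1L])^2 +
             (a_centers[i, 2L] - c_centers[j, 2L])^2 +
             (a_centers[i, 3L] - c_centers[j, 3L])^2)
    })
    admissible <- sep >= cfg$min_separation
    if (!any(admissible)) {
      stop("search error: no admissible candidate pair (all overlap-excluded)")
    }
    scores <- matrix(-Inf, na, nc)
    for (i in seq_len(na)) {
      for (j in seq_len(nc)) {
        if (!admissible[i, j]) next
        scores[i, j] <- roi_score_from_stacked(la$f[, i] - lc$f[, j], w)
        n_evaluated <- n_evaluated + 1L
      }
    }
    smax <- max(scores)
    tie <- which(scores >= smax * (1 - 1e-9) & is.finite(scores),
                 arr.ind = TRUE)
    if (nrow(tie) > 1L) {
      if (!is.null(conv_centers)) {
        dconv <- apply(tie, 1L, function(ij) {
          sqrt(sum((a_centers[ij[1L], ] - conv_centers[1L, ])^2)) +
            sqrt(sum((c_centers[ij[2L], ] - conv_centers[2L, ])^2))
        })
        tie <- tie[order(dconv, tie[, 1L], tie[, 2L]), , drop = FALSE]
      } else {
        tie <- tie[order(tie[, 1L], tie[, 2L]), , drop = FALSE]
      }
    }
    pick <- tie[1L, ]
    iter_best <- scores[pick[1L], pick[2L]]
    improved <- iter_best > best$score * (1 + cfg$rel_tol) ||
      !is.finite(best$score)
    if (iter_best > best$score) {
      best <- list(score = iter_best,
                   anode = la$patches[[pick[1L]]],
                   cathode = lc$patches[[pick[2L]]])
    }
    trace <- c(trace, best$score)
    recenter_unchanged <-
      sum((best$anode$center - ag$reference)^2) < 1e-12 &&
      sum((best$cathode$center - cg$reference)^2) < 1e-12
    if (!improved || recenter_unchanged || iter >= cfg$max_iterations) break
    ag <- build_candidate_grid(head, best$anode$center, extent = grid_extent(ag),
                               spacing = ag$spacing)
    cg <- build_candidate_grid(head, best$cathode$center, extent = grid_extent(cg),
                               spacing = cg$spacing)
  }

  anode <- best$anode
  cathode <- best$cathode
  cathode$current <- -cfg$current
  anode$current <- cfg$current
  montage <- make_montage(anode, cathode, label = "optimized")
  structure(
    list(montage = montage, score = best$score, n_evaluated = n_evaluated,
         iterations = iter, trace = trace),
    class = "optimization_result"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Half-extent of a grid's tangent lattice; falls back to the maximum
# chord distance from the reference for grids built elsewhere.
grid_extent <- function(grid) {
  if (!is.null(grid$extent)) return(grid$extent)
  if (nrow(grid$points) == 1L) return(0)
  max(row_norms(sweep(grid$points, 2L, grid$reference)))
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> score %.4g V/m after %d iteration(s), %d pairs evaluated\n",
    x$score, x$iterations, x$n_evaluated
  ))
  print(x$montage)
  invisible(x)
}
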