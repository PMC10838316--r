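#' Assemble the FEM Laplace system for a head model
#'
#' Discretizes the current-conservation Laplace problem
#' `div(sigma grad V) = 0` on the labeled tetrahedral domain with linear
#' (P1) elements and piecewise-constant conductivity, under natural
#' (insulating) boundary conditions: the normal current density vanishes
#' on the scalp except under the electrodes. Units: coordinates mm,
#' conductivity S/m, injected current mA; the resulting potential is in
#' volts with no further scaling.
#'
#' @param head a `head_model` from [build_layered_sphere_head()].
#' @return An object of class `tdcs_system`: list with the sparse
#'   symmetric `stiffness` (dsCMatrix), zero `load` vector (mA per node),
#'   the element gradient data needed for field recovery, and the head.
#' @export
assemble_system <- function(head) {
  mesh <- head$mesh
  sigma <- element_conductivities(head)
  if (any(sigma <= 0)) stop("all conductivities must be strictly positive")
  v_signed <- tet_signed_volumes(mesh)
  if (any(v_signed <= 0)) stop("degenerate tetrahedron in mesh")

  grads <- element_gradients(mesh)
  vols <- v_signed # orientation already fixed, all positive
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)

  coef <- sigma * vols
  ii <- jj <- integer(16L * m)
  xx <- numeric(16L * m)
  k <- 0L
  for (i in 1:4) {
    gi <- grads[[i]]
    for (j in 1:4) {
      gj <- grads[[j]]
      idx <- (k * m + 1L):((k + 1L) * m)
      ii[idx] <- mesh$tets[, i]
      jj[idx] <- mesh$tets[, j]
      xx[idx] <- coef * rowSums(gi * gj)
      k <- k + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  structure(
    list(
      stiffness = K,
      load = numeric(n),
      head = head,
      gradients = grads,
      volumes = vols,
      montage = NULL
    ),
    class = "tdcs_system"
  )
}

# Per-element gradients of the four P1 basis functions (1/mm): list of
# four m x 3 matrices.
element_gradients <- function(mesh) {
  p1 <- mesh$nodes[mesh$tets[, 1L], , drop = FALSE]
  a <- mesh$nodes[mesh$tets[, 2L], , drop = FALSE] - p1
  b <- mesh$nodes[mesh$tets[, 3L], , drop = FALSE] - p1
  c <- mesh$nodes[mesh$tets[, 4L], , drop = FALSE] - p1
  det <- det3_rows(a, b, c) # = 6 * signed volume
  cross_rows <- function(u, v) {
    cbind(
      u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
      u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
      u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
    )
  }
  g2 <- cross_rows(b, c) / det
  g3 <- cross_rows(c, a) / det
  g4 <- cross_rows(a, b) / det
  g1 <- -(g2 + g3 + g4)
  list(g1, g2, g3, g4)
}

#' Apply montage currents to an assembled system
#'
#' Converts a montage's electrode patches to consistent nodal loads:
#' each patch carries a uniform current density (total current / patch
#' area) over its boundary facets, each facet's share distributed equally
#' to its three nodes. The anode receives `+I`, the cathode `-I`; the
#' total load sums to zero and all non-electrode boundary nodes stay
#' unloaded (natural insulation).
#'
#' @param system a `tdcs_system` from [assemble_system()].
#' @param montage a `montage` from [conventional_montage()] or
#'   [make_montage()].
#' @return the system with its `load` vector (mA) populated.
#' @export
apply_montage_currents <- function(system, montage) {
  stopifnot(inherits(system, "tdcs_system"))
  if (!inherits(montage, "montage")) stop("montage error: not a montage object")
  if (is.null(montage$anode) || is.null(montage$cathode)) {
    stop("montage error: montage must have both anode and cathode")
  }
  if (length(intersect(montage$anode$facet_ids, montage$cathode$facet_ids))) {
    stop("montage error: anode and cathode patches overlap")
  }
  if (abs(montage$anode$current + montage$cathode$current) > 1e-12) {
    stop("montage error: anode and cathode currents must cancel")
  }
  n <- length(system$load)
  load <- numeric(n)
  geo <- boundary_geometry(system$head$mesh)
  for (patch in list(montage$anode, montage$cathode)) {
    fid <- patch$facet_ids
    areas <- geo$areas[fid]
    total_area <- sum(areas)
    if (total_area <= 0) stop("montage error: patch has zero area")
    facet_current <- patch$current * areas / total_area
    tri <- system$head$mesh$boundary[fid, , drop = FALSE]
    for (col in 1:3) {
      load <- load + tapply_add(tri[, col], facet_current / 3, n)
    }
  }
  system$load <- load
  system$montage <- montage
  system
}

# Sum `values` into a length-n accumulator at integer positions `index`.
tapply_add <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Solve for the tDCS-induced potential
#'
#' Solves the assembled, loaded system for the nodal potential. The
#' default solver is preconditioned conjugate gradients (Jacobi
#' preconditioner) on the zero-mean-augmented operator, which removes the
#' Neumann null space without singling out a node; `method = "direct"`
#' uses a sparse Cholesky factorization with one pinned node instead and
#' is preferable when many load vectors share one head. Both return
#' zero-mean potentials and identical fields to solver tolerance.
#'
#' @param system a loaded `tdcs_system`.
#' @param tol relative residual tolerance (default 1e-9).
#' @param max_iter CG iteration cap; default `max(2000, 10 * sqrt(n))`.
#' @param method `"cg"` or `"direct"`.
#' @param factor optional prefactorization from [factorize_system()]
#'   (implies `method = "direct"`).
#' @return An object of class `field_solution`: list with `potential`
#'   (volts, zero mean), `field` (n_tets x 3, V/m), `magnitude` (V/m),
#'   `residual` (relative), `iterations`, `method`.
#' @export
solve_potential <- function(system, tol = 1e-9, max_iter = NULL,
                            method = c("cg", "direct"), factor = NULL) {
  method <- if (!is.null(factor)) "direct" else match.arg(method)
  if (tol <= 0) stop("`tol` must be positive")
  f <- system$load
  if (all(f == 0)) {
    v <- numeric(length(f))
    return(new_field_solution(system, v, residual = 0, iterations = 0L,
                              method = method))
  }
  if (abs(sum(f)) > 1e-9 * max(abs(f))) {
    stop("system is not grounded: load does not sum to zero")
  }
  if (method == "cg") {
    res <- cg_solve(system$stiffness, f, tol = tol, max_iter = max_iter)
    v <- res$x - mean(res$x)
    new_field_solution(system, v, residual = res$residual,
                       iterations = res$iterations, method = "cg")
  } else {
    if (is.null(factor)) factor <- factorize_system(system)
    v <- solve_with_factor(factor, f)
    r <- as.numeric(system$stiffness %*% v) - f
    new_field_solution(system, v, residual = sqrt(sum(r^2) / sum(f^2)),
                       iterations = NA_integer_, method = "direct")
  }
}

# Jacobi-preconditioned CG on the zero-mean augmented operator
# A x = K x + alpha * mean(x) * 1.
cg_solve <- function(K, f, tol = 1e-9, max_iter = NULL) {
  n <- length(f)
  if (is.null(max_iter)) max_iter <- max(2000L, ceiling(10 * sqrt(n)))
  d <- Matrix::diag(K)
  alpha_reg <- mean(d)
  matvec <- function(x) as.numeric(K %*% x) + alpha_reg * mean(x)
  x <- numeric(n)
  r <- f # f has zero sum, so augmented residual equals plain residual
  z <- r / d
  p <- z
  rz <- sum(r * z)
  fnorm <- sqrt(sum(f^2))
  it <- 0L
  repeat {
    it <- it + 1L
    Ap <- matvec(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / fnorm
    if (rel <= tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "convergence error: CG stalled at relative residual %.3e after %d iterations",
        rel, it
      ))
    }
    z <- r / d
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, residual = rel, iterations = it)
}

#' Prefactorize a system for repeated direct solves
#'
#' Sparse Cholesky (CHOLMOD) factorization of the stiffness matrix with
#' the first node pinned to zero potential; solutions are demeaned
#' afterwards, so fields are unaffected by the pin choice.
#'
#' @param system a `tdcs_system`.
#' @return opaque factor object for [solve_potential()]'s `factor=` or
#'   [solve_with_factor()].
#' @export
factorize_system <- function(system) {
  n <- nrow(system$stiffness)
  K11 <- system$stiffness[-1L, -1L]
  ch <- Matrix::Cholesky(K11, LDL = FALSE, super = TRUE)
  structure(list(chol = ch, n = n), class = "tdcs_factor")
}

#' Solve prefactorized system for one or more load vectors
#' @param factor a `tdcs_factor` from [factorize_system()].
#' @param loads numeric vector or matrix (nodes x k) of nodal currents (mA),
#'   each column summing to zero.
#' @return zero-mean potential vector or matrix (volts).
#' @export
solve_with_factor <- function(factor, loads) {
  loads <- as.matrix(loads)
  x <- matrix(0, factor$n, ncol(loads))
  sol <- Matrix::solve(factor$chol, loads[-1L, , drop = FALSE], system = "A")
  x[-1L, ] <- as.matrix(sol)
  x <- sweep(x, 2L, colMeans(x))
  if (ncol(x) == 1L) as.numeric(x) else x
}

new_field_solution <- function(system, potential, residual, iterations, method) {
  E <- element_fields(potential, system$head$mesh, gradients = system$gradients)
  structure(
    list(
      potential = potential,
      field = E,
      magnitude = row_norms(E),
      residual = residual,
      iterations = iterations,
      method = method
    ),
    class = "field_solution"
  )
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> %d nodes, %d elements, |E| max %.4g V/m, residual %.2e (%s)\n",
    length(x$potential), nrow(x$field), max(x$magnitude), x$residual, x$method
  ))
  invisible(x)
}

#' Per-element electric fields from a nodal potential
#'
#' The electric field is minus the gradient of the linear interpolant,
#' constant on each tetrahedron. With coordinates in mm and potential in
#' volts, the gradient is in V/mm and is converted to V/m by a single
#' factor of 1000.
#'
#' @param potential numeric vector of nodal potentials (volts).
#' @param mesh a [tet_mesh()].
#' @param gradients optional precomputed [element_gradients()] output.
#' @return n_tets x 3 matrix of field vectors (V/m).
#' @export
element_fields <- function(potential, mesh, gradients = NULL) {
  if (length(potential) != nrow(mesh$nodes)) {
    stop("shape error: potential length must equal the number of nodes")
  }
  if (is.null(gradients)) gradients <- element_gradients(mesh)
  E <- matrix(0, nrow(mesh$tets), 3L)
  for (i in 1:4) {
    E <- E + gradients[[i]] * potential[mesh$tets[, i]]
  }
  -E * 1000 # V/mm -> V/m
}
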