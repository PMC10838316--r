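#' Analytic potential of a multi-layer sphere with two surface electrodes
#'
#' Legendre-series solution of the piecewise-homogeneous Laplace problem
#' in concentric spherical shells, driven by two point current sources
#' (`+I` and `-I`) on the outer surface. Within shell `j` each harmonic
#' is `A_j (r/R)^l + B_j (R/r)^(l+1)`; coefficients are matched by
#' continuity of potential and radial current density at every interface,
#' regularity at the centre, and the surface point-source condition.
#' The monopole term cancels between the paired sources, so the series
#' starts at `l = 1`. Units follow the package convention (mm, S/m, mA,
#' volts).
#'
#' @param layer_radii strictly decreasing outer radii of the shells (mm).
#' @param layer_conductivities one conductivity (S/m) per shell,
#'   outermost first.
#' @param electrode_points 2 x 3 matrix: positions of the source (`+I`,
#'   row 1) and sink (`-I`, row 2); both are radially projected onto the
#'   outer surface.
#' @param query_points k x 3 matrix of evaluation points (inside or on
#'   the sphere).
#' @param current injected current I (mA), default 2.
#' @param truncation_order number of Legendre terms (default 120).
#' @param cap_half_angle if positive, model each electrode as a uniform
#'   current density over a spherical cap of this half-angle (radians)
#'   instead of a point source; each harmonic is damped by the cap
#'   factor `(P_(l-1)(x0) - P_(l+1)(x0)) / ((1 - x0) (2l + 1))` with
#'   `x0 = cos(cap_half_angle)`, which tends to 1 as the cap shrinks.
#' @return numeric vector of potentials (volts), zero-mean over the
#'   harmonic series by construction.
#' @export
analytic_layered_sphere_potential <- function(layer_radii,
                                              layer_conductivities,
                                              electrode_points,
                                              query_points,
                                              current = 2,
                                              truncation_order = 120L,
                                              cap_half_angle = 0) {
  if (any(diff(layer_radii) >= 0)) {
    stop("`layer_radii` must be strictly decreasing")
  }
  if (length(layer_conductivities) != length(layer_radii)) {
    stop("need one conductivity per layer")
  }
  if (truncation_order < 1L) stop("`truncation_order` must be >= 1")
  electrode_points <- rbind(electrode_points)
  if (nrow(electrode_points) != 2L) stop("exactly two electrode points required")
  query_points <- rbind(query_points)
  R <- layer_radii[1L]
  qr <- row_norms(query_points)
  if (any(qr > R * (1 + 1e-9))) {
    stop("domain error: query point outside the outer radius")
  }

  L <- length(layer_radii)
  lmax <- as.integer(truncation_order)
  coefs <- radial_coefficients(layer_radii, layer_conductivities, current, lmax)
  gl <- cap_factors(lmax, cap_half_angle)

  src <- electrode_points / row_norms(electrode_points) # unit directions
  qdir <- query_points / pmax(qr, 1e-300)
  mu_pos <- as.numeric(qdir %*% src[1L, ])
  mu_neg <- as.numeric(qdir %*% src[2L, ])
  mu_pos <- pmin(1, pmax(-1, mu_pos))
  mu_neg <- pmin(1, pmax(-1, mu_neg))

  # radial shell index per query point (1 = outermost)
  shell <- findInterval(-qr, -layer_radii) # 0 means outside shell 1 boundary
  shell[shell < 1L] <- 1L
  shell[shell > L] <- L

  r_out <- layer_radii[shell]
  r_in <- c(layer_radii[-1L], 0)[shell]
  Pp_prev <- rep(1, length(qr)); Pn_prev <- rep(1, length(qr)) # P_0
  Pp <- mu_pos; Pn <- mu_neg # P_1
  V <- numeric(length(qr))
  for (l in seq_len(lmax)) {
    A <- coefs$A[l, shell]
    B <- coefs$B[l, shell]
    u <- (qr / r_out)^l
    w <- ifelse(qr > 0, (r_in / qr)^(l + 1), 0)
    radial <- A * u + B * w
    V <- V + gl[l] * radial * (Pp - Pn)
    if (l < lmax) {
      Pp_new <- ((2 * l + 1) * mu_pos * Pp - l * Pp_prev) / (l + 1)
      Pn_new <- ((2 * l + 1) * mu_neg * Pn - l * Pn_prev) / (l + 1)
      Pp_prev <- Pp; Pp <- Pp_new
      Pn_prev <- Pn; Pn <- Pn_new
    }
  }
  V
}

# Solve the per-harmonic interface conditions for all l = 1..lmax, in the
# per-shell scaled basis u_j(r) = (r/r_j)^l, w_j(r) = (r_(j+1)/r)^(l+1)
# (both bounded by 1 inside shell j), which keeps the interface system
# well conditioned at high harmonic order.
# Returns list(A = lmax x L, B = lmax x L) with B[, L] = 0.
radial_coefficients <- function(layer_radii, sigma, current, lmax) {
  L <- length(layer_radii)
  R <- layer_radii[1L]
  r_in_of <- c(layer_radii[-1L], 0)
  A <- matrix(0, lmax, L)
  B <- matrix(0, lmax, L)
  for (l in seq_len(lmax)) {
    nunk <- 2L * L - 1L # A_1..A_L, B_1..B_{L-1}
    M <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    a_idx <- function(j) j
    b_idx <- function(j) L + j # valid for j < L
    row <- 1L
    # outer Neumann: sigma_1 dV/dr(R) = current * (2l+1) / (4 pi R^2);
    # at r = R: u_1 = 1, u_1' = l/R, w_1 = (r_2/R)^(l+1), w_1' = -(l+1)/R w_1
    M[row, a_idx(1L)] <- sigma[1L] * l / R
    if (L > 1L) {
      M[row, b_idx(1L)] <- -sigma[1L] * (l + 1) / R * (r_in_of[1L] / R)^(l + 1)
    }
    rhs[row] <- current * (2 * l + 1) / (4 * pi * R^2)
    if (L > 1L) {
      for (j in seq_len(L - 1L)) {
        r <- layer_radii[j + 1L] # interface: inner of shell j, outer of j+1
        uj <- (r / layer_radii[j])^l
        wj <- 1 # (r_in_of[j] / r)^(l+1) with r == r_in_of[j]
        uj1 <- 1
        wj1 <- if (j + 1L < L) (r_in_of[j + 1L] / r)^(l + 1) else 0
        dup_j <- l / r * uj
        dwp_j <- -(l + 1) / r * wj
        dup_j1 <- l / r * uj1
        dwp_j1 <- -(l + 1) / r * wj1
        # potential continuity; B_L = 0 (regularity at the centre)
        row <- row + 1L
        M[row, a_idx(j)] <- uj
        M[row, a_idx(j + 1L)] <- -uj1
        M[row, b_idx(j)] <- wj
        if (j + 1L < L) M[row, b_idx(j + 1L)] <- -wj1
        # radial current-density continuity
        row <- row + 1L
        M[row, a_idx(j)] <- sigma[j] * dup_j
        M[row, a_idx(j + 1L)] <- -sigma[j + 1L] * dup_j1
        M[row, b_idx(j)] <- sigma[j] * dwp_j
        if (j + 1L < L) M[row, b_idx(j + 1L)] <- -sigma[j + 1L] * dwp_j1
      }
    }
    sol <- solve(M, rhs)
    A[l, ] <- sol[seq_len(L)]
    if (L > 1L) B[l, seq_len(L - 1L)] <- sol[(L + 1L):nunk]
  }
  list(A = A, B = B)
}

# Harmonic damping factors for a uniform-current spherical-cap source of
# half-angle theta0; all 1 for a point source (theta0 = 0).
cap_factors <- function(lmax, theta0) {
  if (theta0 <= 0) return(rep(1, lmax))
  x0 <- cos(theta0)
  # P_l(x0) for l = 0..lmax+1 by recurrence
  P <- numeric(lmax + 2L)
  P[1L] <- 1
  P[2L] <- x0
  for (l in 1:lmax) {
    P[l + 2L] <- ((2 * l + 1) * x0 * P[l + 1L] - l * P[l]) / (l + 1)
  }
  l <- seq_len(lmax)
  (P[l] - P[l + 2L]) / ((1 - x0) * (2 * l + 1))
}
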