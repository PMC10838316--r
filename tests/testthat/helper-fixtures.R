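# Shared fixtures: small head models are expensive enough to build once
# per test run and reuse across files.

fixture_env <- new.env(parent = emptyenv())

# Coarse default-geometry head (fast; ~20k tets).
small_head <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- build_layered_sphere_head(mesh_size = 12)
  }
  fixture_env$small
}

small_system <- function() {
  if (is.null(fixture_env$small_sys)) {
    fixture_env$small_sys <- assemble_system(small_head())
  }
  fixture_env$small_sys
}

small_factor <- function() {
  if (is.null(fixture_env$small_fac)) {
    fixture_env$small_fac <- factorize_system(small_system())
  }
  fixture_env$small_fac
}

# Finer head for surface-resolution-sensitive checks (patch areas).
medium_head <- function() {
  if (is.null(fixture_env$medium)) {
    fixture_env$medium <- build_layered_sphere_head(mesh_size = 8)
  }
  fixture_env$medium
}

# Full 21-subject synthetic study under the default configuration
# (coarse mesh, full candidate grids); computed once and reused.
acceptance_study <- function() {
  if (is.null(fixture_env$study)) {
    fixture_env$study <- run_study(default_run_config(seed = 1L),
                                   progress = FALSE)
  }
  fixture_env$study
}

# Minimal single-tetrahedron "head" for local-stiffness checks.
unit_tet_head <- function(sigma = 1) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- rbind(1:4)
  boundary <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  structure(
    list(
      mesh = tet_mesh(nodes, tets, boundary, labels = "gray"),
      conductivities = c(gray = sigma)
    ),
    class = "head_model"
  )
}

# Closed-form potential of a point current source on the surface of a
# homogeneous sphere (independent oracle for the Legendre series):
# V = I / (4 pi sigma R) * [2 (g - 1) + ln(2 / (1 - t mu + 1/g))],
# g = (1 - 2 t mu + t^2)^(-1/2), t = r / R.
homog_sphere_point_source <- function(R, sigma, src, q, current) {
  r <- sqrt(sum(q^2))
  t <- r / R
  mu <- if (r > 0) sum(q * src) / (r * sqrt(sum(src^2))) else 0
  h <- sqrt(1 - 2 * t * mu + t^2)
  current / (4 * pi * sigma * R) * (2 * (1 / h - 1) + log(2 / (1 - t * mu + h)))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign
# assignments (no ties, no zeros).
wilcoxon_enum_p <- function(a, b) {
  d <- b - a
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  mean_w <- n * (n + 1) / 4
  mean(abs(w_all - mean_w) >= abs(w_obs - mean_w) - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
mann_whitney_enum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  na <- length(a)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2L, u_of)
  mean_u <- na * length(b) / 2
  mean(abs(u_all - mean_u) >= abs(u_obs - mean_u) - 1e-12)
}

# Exact two-sided Spearman p over all rank permutations.
spearman_enum_p <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(rank(x), rank(y))
  perms <- permutations_of(n)
  rx <- rank(x)
  rho_all <- apply(perms, 1L, function(p) cor(rx, p))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Montage stub with given electrode centres (for distance metrics that
# only use centres).
stub_montage <- function(anode_center, cathode_center, label = "custom") {
  patch <- function(center, current) {
    structure(list(center = center, size = c(50, 50), facet_ids = integer(0),
                   area = 2500, current = current),
              class = "electrode_patch")
  }
  structure(list(anode = patch(anode_center, 2),
                 cathode = patch(cathode_center, -2), label = label),
            class = "montage")
}
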