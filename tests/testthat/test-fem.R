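test_that("stiffness rows sum to zero and match the reference element", {
  K <- small_system()$stiffness
  rs <- abs(Matrix::rowSums(K))
  expect_lt(max(rs) / max(abs(K@x)), 1e-10)

  # unit reference tetrahedron, unit conductivity: K = V * G G^T with
  # gradients (-1,-1,-1), e1, e2, e3 and V = 1/6
  Kt <- as.matrix(assemble_system(unit_tet_head())$stiffness)
  G <- rbind(c(-1, -1, -1), diag(3))
  expect_equal(Kt, (G %*% t(G)) / 6, tolerance = 1e-12,
               ignore_attr = TRUE)
  # conductivity scales linearly
  expect_equal(as.matrix(assemble_system(unit_tet_head(2.5))$stiffness),
               2.5 * Kt, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(assemble_system(unit_tet_head(0)), "positive")
})

test_that("montage loads are conservative and sized by the injected current", {
  head <- small_head()
  montage <- conventional_montage(head, current = 2)
  sys <- apply_montage_currents(small_system(), montage)
  expect_lt(abs(sum(sys$load)), 1e-12 * 2)
  expect_equal(sum(sys$load[sys$load > 0]), 2, tolerance = 1e-12)
  # loads only on electrode-facet nodes
  el_nodes <- unique(as.vector(
    head$mesh$boundary[c(montage$anode$facet_ids, montage$cathode$facet_ids), ]
  ))
  expect_true(all(which(sys$load != 0) %in% el_nodes))
  expect_error(apply_montage_currents(small_system(), list(anode = 1)),
               "montage")
})

test_that("element fields obey the unit convention and vanish for constant V", {
  mesh <- small_head()$mesh
  # V = x (volts, coordinates in mm) => E = (-1000, 0, 0) V/m
  E <- element_fields(mesh$nodes[, 1], mesh)
  expect_equal(max(abs(E[, 1] + 1000)), 0, tolerance = 1e-6)
  expect_equal(max(abs(E[, 2:3])), 0, tolerance = 1e-6)
  expect_equal(max(abs(element_fields(rep(3.7, nrow(mesh$nodes)), mesh))), 0,
               tolerance = 1e-8)
  expect_error(element_fields(1:5, mesh), "shape")
})

test_that("solutions are linear in the injected current", {
  head <- small_head()
  fac <- small_factor()
  m1 <- conventional_montage(head, current = 2)
  m2 <- conventional_montage(head, current = 4)
  s1 <- solve_potential(apply_montage_currents(small_system(), m1), factor = fac)
  s2 <- solve_potential(apply_montage_currents(small_system(), m2), factor = fac)
  expect_lt(max(abs(s2$field - 2 * s1$field)) / max(abs(s2$field)), 1e-8)
  expect_lt(max(abs(s2$potential - 2 * s1$potential)) /
              max(abs(s2$potential)), 1e-8)
})

test_that("CG and direct solvers agree and honour the tolerance", {
  head <- small_head()
  sys <- apply_montage_currents(small_system(),
                                conventional_montage(head, current = 2))
  sol_cg <- solve_potential(sys, tol = 1e-10, method = "cg")
  expect_lte(sol_cg$residual, 1e-10)
  sol_dir <- solve_potential(sys, factor = small_factor())
  expect_lt(max(abs(sol_cg$field - sol_dir$field)) / max(sol_dir$magnitude),
            1e-6)
  expect_error(solve_potential(sys, tol = 1e-9, max_iter = 3L),
               "convergence error")
})

test_that("reciprocity holds across two patch pairs", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  fac <- small_factor()
  mk <- function(p, q) {
    make_montage(make_patch(head, p, size = c(30, 30), current = 2),
                 make_patch(head, q, size = c(30, 30), current = -2))
  }
  m_pq <- mk(pos$C3, pos$C4)
  m_rs <- mk(pos$Fz, pos$Oz)
  sys_pq <- apply_montage_currents(small_system(), m_pq)
  sys_rs <- apply_montage_currents(small_system(), m_rs)
  sol_pq <- solve_potential(sys_pq, factor = fac)
  sol_rs <- solve_potential(sys_rs, factor = fac)
  # load-weighted potential difference across (R,S) due to injection at
  # (P,Q) equals that across (P,Q) due to injection at (R,S)
  v1 <- sum(sol_pq$potential * sys_rs$load) / 2
  v2 <- sum(sol_rs$potential * sys_pq$load) / 2
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("superposition: a pair solve equals the difference of lead solves", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  fac <- small_factor()
  ref <- make_patch(head, pos$Oz, current = -2)
  mk_pair <- function(a, c) {
    solve_potential(apply_montage_currents(
      small_system(),
      make_montage(make_patch(head, a, current = 2),
                   make_patch(head, c, current = -2))
    ), factor = fac)
  }
  lead <- function(p) {
    solve_potential(apply_montage_currents(
      small_system(),
      make_montage(make_patch(head, p, current = 2), ref)
    ), factor = fac)
  }
  direct <- mk_pair(pos$C3, pos$C4)
  sup <- lead(pos$C3)$potential - lead(pos$C4)$potential
  sup <- sup - mean(sup)
  expect_lt(max(abs(direct$potential - sup)) / max(abs(direct$potential)),
            1e-9)
})

test_that("rigid rotation leaves field magnitudes unchanged", {
  head <- unit_tet_head()
  # scale to a realistic size to exercise the mm -> m conversion too
  head$mesh$nodes <- head$mesh$nodes * 10
  v <- head$mesh$nodes[, 1] + 2 * head$mesh$nodes[, 2]
  E <- element_fields(v, head$mesh)
  theta <- 0.7
  Q <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rot <- head
  rot$mesh$nodes <- head$mesh$nodes %*% t(Q)
  v_rot <- rot$mesh$nodes %*% Q %*% c(1, 2, 0) # same linear form, rotated
  E_rot <- element_fields(as.numeric(v_rot), rot$mesh)
  expect_equal(sqrt(rowSums(E_rot^2)), sqrt(rowSums(E^2)), tolerance = 1e-8)
})
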