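test_that("ROI summaries reproduce imposed uniform and mixed fields", {
  head <- small_head()
  roi <- roi_spec(head$target, radius = 15)
  # uniform field E0 via the linear potential V = -E0 . x / 1000
  e0 <- c(0.2, -0.1, 0.25)
  v <- -as.numeric(head$mesh$nodes %*% e0) / 1000
  sol <- list(field = element_fields(v, head$mesh))
  sol$magnitude <- sqrt(rowSums(sol$field^2))
  s <- roi_summary(sol, head, roi)
  expect_equal(s$mean_magnitude, sqrt(sum(e0^2)), tolerance = 1e-8)
  expect_equal(s$normal_component, sum(e0 * s$normal_direction),
               tolerance = 1e-8)
  expect_equal(sqrt(sum(s$normal_direction^2)), 1, tolerance = 1e-12)
  # the gray surface normal at the target of a sphere head is radial
  expect_equal(s$normal_direction,
               head$target / sqrt(sum(head$target^2)), tolerance = 0.15)
  # |normal component| never exceeds the max element magnitude
  expect_lte(abs(s$normal_component), max(sol$magnitude))
  expect_error(roi_summary(sol, head, roi_spec(c(0, 0, 90), radius = 0.01)),
               "roi error")
})

test_that("volume weighting averages element magnitudes correctly", {
  # two-element mesh with equal volumes: |E| = 1 and 3 must average to 2
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(2, 2, 2) / 3)
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  mesh <- tet_mesh(nodes, tets, boundary_from_tets(
    structure(list(tets = tets), class = "tet_mesh")
  ), labels = c("gray", "gray"), validate = FALSE)
  head <- structure(list(mesh = mesh, conductivities = c(gray = 1)),
                    class = "head_model")
  vols <- tet_volumes(mesh)
  expect_equal(vols[1], vols[2], tolerance = 1e-12)
  sel <- tdcsim:::roi_elements(head, roi_spec(c(0.4, 0.4, 0.4), radius = 2))
  w <- sel$volumes / sum(sel$volumes)
  E <- rbind(c(1, 0, 0), c(0, 3, 0))
  expect_equal(sum(w * sqrt(rowSums(E^2))), 2)
})

test_that("improvement percentage follows the within-subject formula", {
  expect_equal(improvement_pct(0.30, 0.36), 20, tolerance = 1e-9)
  expect_equal(improvement_pct(0.42, 0.42), 0)
  expect_equal(improvement_pct(0.40, 0.20), -50)
  expect_error(improvement_pct(0, 0.3), "domain error")
  expect_error(improvement_pct(-0.1, 0.3), "domain error")
})

test_that("montage distances are additive and Euclidean", {
  conv <- stub_montage(c(-54, 0, 74), c(54, 0, 74))
  same <- montage_distances(conv, conv)
  expect_equal(same$d_anode, 0)
  expect_equal(same$d_cathode, 0)
  expect_equal(same$d_total, 0)
  moved <- stub_montage(c(-54, 0, 74) + c(3, 4, 0), c(54, 0, 74))
  d <- montage_distances(conv, moved)
  expect_equal(d$d_anode, 5)
  expect_equal(d$d_cathode, 0)
  expect_equal(d$d_total, 5)
  # additivity holds exactly for random montages
  set.seed(5)
  for (k in 1:20) {
    m1 <- stub_montage(rnorm(3, sd = 40), rnorm(3, sd = 40))
    m2 <- stub_montage(rnorm(3, sd = 40), rnorm(3, sd = 40))
    dd <- montage_distances(m1, m2)
    expect_identical(dd$d_total, dd$d_anode + dd$d_cathode)
    expect_gte(dd$d_anode, 0)
    expect_gte(dd$d_cathode, 0)
  }
})
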