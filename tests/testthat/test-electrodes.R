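test_that("patches cover the nominal pad area with boundary facets only", {
  head <- medium_head()
  pos <- locate_ten_twenty_positions(head)
  patch <- make_patch(head, pos$Cz, size = c(50, 50), current = 2)
  expect_equal(patch$area, 2500, tolerance = 0.10)
  expect_true(all(patch$facet_ids %in% seq_len(nrow(head$mesh$boundary))))
  # coarse surfaces under-resolve the pad; refinement tightens the area
  patch12 <- make_patch(small_head(), c(0, 0, 92), size = c(50, 50),
                        current = 2)
  expect_lt(abs(patch$area - 2500) / 2500,
            abs(patch12$area - 2500) / 2500 + 0.02)
  expect_error(make_patch(head, c(0, 0, 130), current = 2), "placement error")
  expect_error(make_patch(head, pos$Cz, current = 0), "nonzero")
})

test_that("conventional montage lateralizes with the affected side", {
  head_l <- small_head()
  pos <- locate_ten_twenty_positions(head_l)
  m_l <- conventional_montage(head_l, current = 2)
  expect_equal(m_l$anode$center, pos$C3, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m_l$cathode$center, pos$C4, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m_l$anode$current, 2)
  expect_equal(m_l$cathode$current, -2)

  head_r <- build_layered_sphere_head(mesh_size = 12, affected_side = "right")
  m_r <- conventional_montage(head_r, current = 2)
  expect_gt(m_r$anode$center[1], 0) # C4 is on the right
  expect_lt(m_r$cathode$center[1], 0)

  # anode-cathode distance equals the chord of the C3-C4 arc (72 degrees)
  r <- sqrt(sum(m_l$anode$center^2))
  chord <- 2 * r * sin(0.4 * pi / 2)
  expect_equal(sqrt(sum((m_l$anode$center - m_l$cathode$center)^2)), chord,
               tolerance = 0.01)
})

test_that("candidate grids are evenly spaced on the scalp and keep their reference", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  grid <- build_candidate_grid(head, pos$C3, extent = 22.22, spacing = 11.11)
  expect_equal(grid$points[1, ], unname(pos$C3), tolerance = 1e-9)
  expect_equal(nrow(grid$points), 25)
  nn <- as.matrix(dist(grid$points))
  diag(nn) <- Inf
  expect_true(all(abs(apply(nn, 1, min) - 11.11) / 11.11 < 0.10))
  # all points on the skin surface: radius matches local boundary radius
  r_pts <- sqrt(rowSums(grid$points^2))
  expect_true(all(abs(r_pts - 92) < 2))
  g0 <- build_candidate_grid(head, pos$C3, extent = 0)
  expect_equal(nrow(g0$points), 1)
  expect_error(build_candidate_grid(head, c(0, 0, 200)), "placement error")
})

test_that("montage construction enforces paired, disjoint, balanced patches", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  a <- make_patch(head, pos$C3, current = 2)
  b <- make_patch(head, pos$C4, current = -2)
  expect_s3_class(make_montage(a, b, "conventional"), "montage")
  expect_error(make_montage(a, NULL), "montage error")
  bad <- make_patch(head, pos$C3, current = -2) # overlaps the anode
  expect_error(make_montage(a, bad), "overlap")
  unbalanced <- make_patch(head, pos$C4, current = -1)
  expect_error(make_montage(a, unbalanced), "sum to zero")
})
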