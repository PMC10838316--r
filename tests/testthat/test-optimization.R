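test_that("montage scoring matches the ROI summary and is zero without current", {
  head <- small_head()
  roi <- roi_spec(head$target, radius = head$mesh_size)
  conv <- conventional_montage(head, current = 2)
  fac <- small_factor()
  s <- score_montage(head, conv, roi, system = small_system(), factor = fac)
  sol <- solve_potential(apply_montage_currents(small_system(), conv),
                         factor = fac)
  expect_equal(s, roi_summary(sol, head, roi)$mean_magnitude,
               tolerance = 1e-12)
  zero <- solve_potential(small_system(), factor = fac) # no load
  expect_equal(roi_summary(zero, head, roi)$mean_magnitude, 0)
})

test_that("lead fields reconstruct pair solves and cancel with themselves", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  ag <- build_candidate_grid(head, pos$C3, extent = 11.11)
  cg <- build_candidate_grid(head, pos$C4, extent = 11.11)
  ref <- make_patch(head, pos$Oz, current = -2)
  lfa <- compute_lead_fields(head, ag, ref, system = small_system(),
                             factor = small_factor())
  lfc <- compute_lead_fields(head, cg, ref, system = small_system(),
                             factor = small_factor())
  expect_equal(lfa$n_solves, nrow(ag$points))
  expect_equal(ncol(lfa$potentials), nrow(ag$points))
  # L(a) - L(a) is identically zero
  expect_equal(max(abs(lfa$potentials[, 1] - lfa$potentials[, 1])), 0)
  # reconstructed cross-grid pair equals the direct pair simulation
  cathode <- lfc$patches[[1]]
  cathode$current <- -2
  pair <- make_montage(lfa$patches[[1]], cathode)
  direct <- solve_potential(apply_montage_currents(small_system(), pair),
                            factor = small_factor())
  sup <- lfa$potentials[, 1] - lfc$potentials[, 1]
  sup <- sup - mean(sup)
  expect_lt(max(abs(direct$potential - sup)) / max(abs(direct$potential)),
            1e-9)
})

test_that("single-iteration grid search equals exhaustive enumeration", {
  head <- small_head()
  roi <- roi_spec(head$target, radius = head$mesh_size)
  conv <- conventional_montage(head, current = 2)
  ag <- build_candidate_grid(head, conv$anode$center, extent = 11.11)
  cg <- build_candidate_grid(head, conv$cathode$center, extent = 11.11)
  sys <- small_system()
  fac <- small_factor()
  opt <- optimize_montage(head, roi, ag, cg,
                          config = list(max_iterations = 1L,
                                        conventional = conv),
                          system = sys, factor = fac)
  # independent oracle: score every admissible pair by direct solves
  best_score <- -Inf
  best_pair <- NULL
  for (i in seq_len(nrow(ag$points))) {
    for (j in seq_len(nrow(cg$points))) {
      a <- make_patch(head, ag$points[i, ], current = 2)
      c <- make_patch(head, cg$points[j, ], current = -2)
      if (sqrt(sum((a$center - c$center)^2)) < 70) next
      s <- score_montage(head, make_montage(a, c), roi, system = sys,
                         factor = fac)
      if (s > best_score) {
        best_score <- s
        best_pair <- list(a = a$center, c = c$center)
      }
    }
  }
  expect_equal(opt$score, best_score, tolerance = 1e-6)
  expect_equal(opt$montage$anode$center, best_pair$a, tolerance = 1e-9)
  expect_equal(opt$montage$cathode$center, best_pair$c, tolerance = 1e-9)
  # returned score is reproduced by a direct solve of the returned montage
  expect_equal(score_montage(head, opt$montage, roi, system = sys,
                             factor = fac),
               opt$score, tolerance = 1e-6)
})

test_that("optimizer dominates the conventional montage and is deterministic", {
  head <- small_head()
  roi <- roi_spec(head$target, radius = head$mesh_size)
  conv <- conventional_montage(head, current = 2)
  s_conv <- score_montage(head, conv, roi, system = small_system(),
                          factor = small_factor())
  ag <- build_candidate_grid(head, conv$anode$center, extent = 11.11)
  cg <- build_candidate_grid(head, conv$cathode$center, extent = 11.11)
  run <- function() {
    optimize_montage(head, roi, ag, cg,
                     config = list(max_iterations = 3L, conventional = conv),
                     system = small_system(), factor = small_factor())
  }
  o1 <- run()
  o2 <- run()
  expect_gte(o1$score, s_conv) # grids contain the conventional centres
  expect_identical(o1$score, o2$score)
  expect_identical(o1$montage$anode$center, o2$montage$anode$center)
  expect_identical(o1$trace, o2$trace)
  expect_true(all(diff(o1$trace) >= 0))
})

test_that("degenerate grids fall back to the only admissible pair or error", {
  head <- small_head()
  roi <- roi_spec(head$target, radius = head$mesh_size)
  conv <- conventional_montage(head, current = 2)
  ag <- build_candidate_grid(head, conv$anode$center, extent = 0)
  cg <- build_candidate_grid(head, conv$cathode$center, extent = 0)
  opt <- optimize_montage(head, roi, ag, cg,
                          config = list(max_iterations = 5L),
                          system = small_system(), factor = small_factor())
  expect_equal(opt$montage$anode$center, unname(conv$anode$center),
               tolerance = 1e-9)
  expect_equal(opt$iterations, 1L)
  # all pairs overlap-excluded
  expect_error(
    optimize_montage(head, roi, ag, ag,
                     config = list(max_iterations = 1L),
                     system = small_system(), factor = small_factor()),
    "search error"
  )
})
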