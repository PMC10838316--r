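test_that("layered sphere head satisfies construction invariants", {
  head <- small_head()
  mesh <- head$mesh
  expect_true(all(tet_volumes(mesh) > 0))
  expect_silent(validate_tet_mesh(mesh))
  expect_setequal(unique(mesh$labels), c("skin", "skull", "csf", "gray", "white"))
  # total volume close to the analytic ball volume
  expect_equal(sum(tet_volumes(mesh)), 4 / 3 * pi * 92^3, tolerance = 0.05)
  # fiducials on the boundary surface
  bn <- unique(as.vector(mesh$boundary))
  for (f in rownames(head$fiducials)) {
    d <- min(sqrt(rowSums(sweep(mesh$nodes[bn, ], 2, head$fiducials[f, ])^2)))
    expect_lt(d, 12) # within one element size of the surface
  }
  # target inside a gray element (snapped to a gray centroid)
  cen <- tet_centroids(mesh)
  i <- which.min(rowSums(sweep(cen, 2, head$target)^2))
  expect_identical(mesh$labels[i], "gray")
})

test_that("finer meshes approach the analytic ball volume", {
  v8 <- sum(tet_volumes(build_layered_sphere_head(mesh_size = 8)$mesh))
  v12 <- sum(tet_volumes(small_head()$mesh))
  exact <- 4 / 3 * pi * 92^3
  expect_lt(abs(v8 - exact), abs(v12 - exact))
  expect_lt(abs(v8 / exact - 1), 0.05)
})

test_that("invalid geometry and resolution inputs are rejected", {
  expect_error(build_layered_sphere_head(layer_radii = c(80, 86, 80, 78, 70)),
               "strictly decreasing")
  expect_error(build_layered_sphere_head(mesh_size = -1), "positive")
  expect_error(build_layered_sphere_head(mesh_size = 75), "resolution")
})

test_that("lesion insertion relabels by centroid and conserves volume", {
  head <- small_head()
  les <- lesion_spec(c(0, 0, 30), 15, "subcortical")
  lesioned <- insert_lesion(head, les)
  expect_identical(lesioned$mesh$nodes, head$mesh$nodes)
  expect_identical(lesioned$mesh$tets, head$mesh$tets)
  expect_equal(sum(tet_volumes(lesioned$mesh)), sum(tet_volumes(head$mesh)))
  relabeled <- lesioned$mesh$labels == "lesion"
  expect_gt(sum(relabeled), 0)
  # all relabeled centroids inside the sphere, and conductivity is 0.8087
  cen <- tet_centroids(lesioned$mesh)[relabeled, , drop = FALSE]
  expect_true(all(sqrt(rowSums(sweep(cen, 2, les$center)^2)) <= 15))
  expect_equal(unique(element_conductivities(lesioned)[relabeled]), 0.8087)
  # relabeled volume approximates the analytic sphere volume
  vol <- sum(tet_volumes(lesioned$mesh)[relabeled])
  expect_equal(vol, 4 / 3 * pi * 15^3, tolerance = 0.30)
  # zero radius is a no-op; centre outside the head errors
  expect_identical(insert_lesion(head, lesion_spec(c(0, 0, 30), 0,
                                                   "subcortical"))$mesh$labels,
                   head$mesh$labels)
  expect_error(insert_lesion(head, lesion_spec(c(0, 0, 200), 5, "cortical")),
               "out-of-domain")
})

test_that("synthetic cohort reproduces class structure and is deterministic", {
  co1 <- generate_synthetic_cohort(seed = 7, build_heads = FALSE)
  co2 <- generate_synthetic_cohort(seed = 7, build_heads = FALSE)
  expect_identical(co1$covariates, co2$covariates)
  expect_equal(nrow(co1$covariates), 21)
  expect_equal(sum(co1$covariates$class == "cortical"), 8)
  expect_equal(sum(co1$covariates$class == "subcortical"), 11)
  expect_equal(sum(co1$covariates$class == "brainstem"), 2)
  expect_true(all(co1$covariates$fma_ue >= 0 & co1$covariates$fma_ue <= 66))
  expect_error(generate_synthetic_cohort(n = 5,
                                         class_counts = c(cortical = 1,
                                                          subcortical = 1,
                                                          brainstem = 1)),
               "config error")
})

test_that("larger lesions drive lower FMA-UE scores", {
  co <- generate_synthetic_cohort(
    n = 200, class_counts = c(cortical = 70, subcortical = 100, brainstem = 30),
    seed = 11, build_heads = FALSE
  )
  rho <- cor(co$covariates$lesion_volume, co$covariates$fma_ue,
             method = "spearman")
  expect_lt(rho, 0)
})

test_that("cohort lesion geometry matches its location class", {
  co <- generate_synthetic_cohort(seed = 3, build_heads = FALSE)
  cv <- co$covariates
  r_les <- sqrt(cv$lesion_x^2 + cv$lesion_y^2 + cv$lesion_z^2)
  cortical <- cv$class == "cortical"
  subcortical <- cv$class == "subcortical"
  # cortical spheres straddle the gray shell [70, 78]
  expect_true(all(r_les[cortical] + cv$lesion_r[cortical] > 70))
  # subcortical spheres confined to the white core (r < 70)
  expect_true(all(r_les[subcortical] + cv$lesion_r[subcortical] <= 70))
  # lesion on the affected side
  sgn <- ifelse(cv$affected_side == "left", -1, 1)
  expect_true(all((sgn * cv$lesion_x)[cortical | subcortical] > 0))
})

test_that("10-20 positions follow the fiducial arc construction", {
  head <- small_head()
  pos <- locate_ten_twenty_positions(head)
  expect_true(all(c("Cz", "C3", "C4") %in% names(pos)))
  # Cz at the superior pole of a symmetric sphere
  expect_lt(sqrt(sum((pos$Cz[1:2] - c(0, 0))^2)), 1)
  expect_gt(pos$Cz[3], 88)
  # C3/C4 mirror-symmetric across the mid-sagittal plane
  expect_equal(pos$C3 * c(-1, 1, 1), pos$C4, tolerance = 1e-6)
  # arc length Cz -> C3 is 20% of the ear-to-ear arc (spherical oracle)
  r_c3 <- sqrt(sum(pos$C3^2))
  ang <- acos(sum(pos$C3 * pos$Cz) / (r_c3 * sqrt(sum(pos$Cz^2))))
  expect_equal(ang, 0.2 * pi, tolerance = 0.01)
  head_nofid <- head
  head_nofid$fiducials <- head$fiducials[1:2, ]
  expect_error(locate_ten_twenty_positions(head_nofid), "fiducial")
})
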