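test_that("contact frames follow the 1-3-3-1 directional layout", {
  lead <- canonical_lead()
  cf <- contact_frames(lead)
  # level centroids at 0.75, 2.75, 4.75, 6.75 mm from the tip (2 mm pitch)
  expect_equal(unlist(cf[cf$contact == 1, c("cx", "cy", "cz")]),
               c(cx = 0, cy = 0, cz = 0.75))
  expect_equal(unlist(cf[cf$contact == 8, c("cx", "cy", "cz")]),
               c(cx = 0, cy = 0, cz = 6.75))
  # segment outward directions at 0/120/240 degrees from the marker
  expect_equal(unlist(cf[cf$contact == 2, c("ox", "oy", "oz")]),
               c(ox = 1, oy = 0, oz = 0))
  expect_equal(unlist(cf[cf$contact == 3, c("ox", "oy", "oz")]),
               c(ox = -0.5, oy = sqrt(3) / 2, oz = 0))
  # segment centroids displaced by the lead radius along outward
  expect_equal(unlist(cf[cf$contact == 2, c("cx", "cy", "cz")]),
               c(cx = 0.635, cy = 0, cz = 2.75))
  expect_identical(cf$kind, c("ring", rep("segment", 6), "ring"))
  expect_identical(cf$level, c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L))
})

test_that("marker rotation rotates segment outward directions equivariantly", {
  cf_pi <- contact_frames(lead_model(c(0, 0, 0), c(0, 0, 1), rotation = pi))
  expect_equal(unlist(cf_pi[cf_pi$contact == 2, c("ox", "oy", "oz")]),
               c(ox = -1, oy = 0, oz = 0), tolerance = 1e-12)
  # centroid ordering along the axis is preserved under arbitrary poses
  set.seed(2)
  for (i in 1:10) {
    lead <- lead_model(stats::rnorm(3, 0, 10), stats::rnorm(3),
                       stats::runif(1, 0, 2 * pi))
    cf <- contact_frames(lead)
    proj <- as.matrix(cf[c("cx", "cy", "cz")]) %*% lead$axis
    expect_true(all(diff(proj[c(1, 2, 5, 8)]) > 0))
  }
  expect_error(lead_model(c(0, 0, 0), c(0, 0, 0)), "zero-length")
})

test_that("point-source radius follows the thresholded-field closed form", {
  p <- vta_params()
  # oracle: densely sample E(r) = I / (4 pi sigma r^2) and find where it
  # crosses the activation threshold
  r_grid <- seq(0.01, 10, by = 0.01)
  numeric_radius <- function(amp) {
    E <- amp / (4 * pi * p$sigma * r_grid^2)
    max(r_grid[E >= p$e_threshold])
  }
  expect_equal(vta_radius_point_source(1, p), 1.098, tolerance = 1e-3)
  expect_equal(vta_radius_point_source(1, p), numeric_radius(1),
               tolerance = 0.01)
  expect_equal(vta_radius_point_source(4, p) / vta_radius_point_source(1, p), 2)
  expect_identical(vta_radius_point_source(0, p), 0)
  expect_error(vta_radius_point_source(-1, p), ">= 0")
})

test_that("setting VTAs place ring spheres and clipped segment sectors", {
  lead <- canonical_lead()
  p <- vta_params()
  # level 1 is the distal ring: pseudoring L1 and contact C1 coincide
  v_l1 <- vta_for_setting(lead, "L1", 2, p)
  v_c1 <- vta_for_setting(lead, "C1", 2, p)
  expect_equal(v_l1$center, v_c1$center)
  expect_equal(v_l1$radius, v_c1$radius)
  # C2 sector contains points along outward and excludes the opposite side
  v_c2 <- vta_for_setting(lead, "C2", 2, p)
  ctr <- v_c2$center
  expect_true(point_in_vta(ctr + 0.5 * c(1, 0, 0), v_c2))
  expect_false(point_in_vta(ctr - 2 * c(1, 0, 0), v_c2))
  expect_true(point_in_vta(ctr, v_c2))
  expect_false(point_in_vta(ctr + c(v_c2$radius + 1e-6, 0, 0), v_c2))
  expect_error(vta_for_setting(lead, "C9", 2, p), "config_id")
})

test_that("VTAs are nested in amplitude for every configuration", {
  lead <- canonical_lead()
  p <- vta_params()
  set.seed(3)
  probes <- matrix(stats::rnorm(3000, 0, 3), ncol = 3)
  probes <- sweep(probes, 2, c(0, 0, 3), "+")
  grid <- amplitude_grid()
  for (cfg in c("C1", "C2", "C5", "C8", "L2", "L3")) {
    inside_prev <- rep(FALSE, nrow(probes))
    for (amp in grid) {
      v <- vta_for_setting(lead, cfg, amp, p)
      inside <- vapply(seq_len(nrow(probes)),
                       function(i) point_in_vta(probes[i, ], v), TRUE)
      expect_true(all(inside[inside_prev]),
                  label = sprintf("nesting at %s %.1f mA", cfg, amp))
      inside_prev <- inside
    }
  }
})

test_that("three 360-degree segment sectors cover the pseudoring sphere", {
  lead <- canonical_lead()
  # degenerate check: without the radial centroid offset a 360-degree sector
  # sphere coincides with the pseudoring sphere
  p <- vta_params(sector_width_deg = 360, radial_offset_fraction = 0)
  vs <- lapply(c("C2", "C3", "C4"), vta_for_setting, lead = lead,
               amplitude = 2, params = p)
  ring <- vta_for_setting(lead, "L2", 2, vta_params())
  set.seed(4)
  dirs <- matrix(stats::rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  on_sphere <- sweep(dirs * (0.99 * ring$radius), 2, ring$center, "+")
  covered <- vapply(seq_len(nrow(on_sphere)), function(i)
    any(vapply(vs, function(v) point_in_vta(on_sphere[i, ], v), TRUE)), TRUE)
  expect_true(all(covered))
})

test_that("voxelized VTAs agree with the analytic membership test", {
  lead <- canonical_lead()
  v <- vta_for_setting(lead, "C5", 3, vta_params())
  vm <- voxelize_vta(v, voxel_size = 0.2)
  set.seed(6)
  probes <- sweep(matrix(stats::runif(30000, -1, 1) * (v$radius + 2), ncol = 3),
                  2, v$center, "+")
  agree <- vapply(seq_len(nrow(probes)), function(i)
    point_in_vta(probes[i, ], v) == point_in_vta(probes[i, ], vm), TRUE)
  expect_gte(mean(agree), 0.99)
})
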