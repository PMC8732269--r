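test_that("sweeping a constant image samples the constant", {
  img <- image_plane(matrix(7.5, 100, 100))
  mask <- matrix(FALSE, 100, 100)
  mask[40:60, 40:60] <- TRUE   # keeps r_max well inside the image
  pm <- sweep_polar(img, c(50.5, 50.5), theta_step = 2, radial_step = 0.5,
                    cell_mask = mask)
  expect_true(all(abs(pm$values - 7.5) < 1e-9))
  expect_equal(nrow(pm$values), 180)
  expect_error(sweep_polar(img, c(-3, 50)), "outside the image")
  expect_error(sweep_polar(img, c(50, 50), theta_step = 0.7), "divide 360")
})

test_that("polar sums conserve the Cartesian integral of a uniform disk", {
  ph <- disk_phantom(R = 60, size = 160L)
  total <- sum(ph$image$pixels)
  pm <- sweep_polar(ph$image, ph$center, theta_step = 0.5,
                    cell_mask = ph$masks$cell)
  expect_lt(abs(weighted_total(pm) - total) / total, 0.02)
})

test_that("boundary tracing recovers analytic radii", {
  # concentric circles
  geom <- cell_geometry(image_shape = c(200L, 200L), nucleus_center = c(100.5, 100.5),
                        nucleus_semiaxes = c(30, 30), cell_radius_base = 80)
  m <- generate_masks(geom)
  b <- boundary_radii(m, m$center, theta_step = 1)
  expect_lt(max(abs(b$r_ne - 30)), 1)
  expect_lt(max(abs(b$r_edge - 80)), 1)
  expect_true(all(b$r_ne < b$r_edge))

  # rotated ellipse nucleus against its closed-form polar radius
  g2 <- cell_geometry(image_shape = c(200L, 200L), nucleus_center = c(100.5, 100.5),
                      nucleus_semiaxes = c(35, 18), nucleus_angle = 0.8,
                      cell_radius_base = 80)
  m2 <- generate_masks(g2)
  b2 <- boundary_radii(m2, m2$center, theta_step = 1)
  th <- b2$theta_deg * pi / 180
  expect_lt(max(abs(b2$r_ne - nucleus_boundary_radius(g2, th))), 1)

  # star-convex outline with harmonics
  g3 <- cell_geometry(image_shape = c(240L, 240L), nucleus_center = c(120.5, 120.5),
                      nucleus_semiaxes = c(25, 25), cell_radius_base = 80,
                      cell_shape_coeffs = list(c(3, 0.2, 0.3)))
  m3 <- generate_masks(g3)
  b3 <- boundary_radii(m3, m3$center, theta_step = 1)
  expect_lt(max(abs(b3$r_edge - cell_boundary_radius(g3, th))), 1)

  # a ray that never crosses the nucleus
  empty_nuc <- structure(list(nucleus = matrix(FALSE, 50, 50) ,
                              cell = m$cell[1:50, 1:50],
                              exclusion = matrix(FALSE, 50, 50),
                              center = c(25, 25)), class = "cell_masks")
  expect_error(boundary_radii(empty_nuc, c(25, 25), theta_step = 10),
               "degenerate geometry")
})

test_that("radial normalization preserves uniformity and total intensity", {
  geom <- small_geometry()
  fld <- noise_free(w_perinuclear = 0, w_uniform = 1)
  img <- render_image(geom, fld)
  masks <- generate_masks(geom)
  pm <- sweep_polar(img, masks$center, theta_step = 0.5, cell_mask = masks$cell)
  b <- boundary_radii(masks, masks$center, theta_step = 0.5)
  nm <- normalize_radial(pm, b)

  # a constant image stays constant on the u grid at every angle
  flat <- image_plane(matrix(3.2, 160, 160))
  pmc <- sweep_polar(flat, masks$center, theta_step = 0.5, cell_mask = masks$cell)
  nmc <- normalize_radial(pmc, b)
  gvals <- nmc$values[nmc$weights > 0 & col(nmc$values) %in% which(nmc$u > -20 & nmc$u < 95)]
  expect_lt(max(abs(gvals - 3.2)), 1e-6)

  # mass per u bin uniform over the cytoplasm once aliasing is averaged out
  cyt <- nm$u > 5 & nm$u < 95
  mass_u <- colSums(nm$weights * nm$values)[cyt]
  sm <- stats::filter(mass_u, rep(1 / 9, 9))
  sm <- sm[!is.na(sm)]
  expect_lt(sd(sm) / mean(sm), 0.03)

  # conservation: Cartesian vs polar vs normalized, pairwise within 2%
  total <- sum(img$pixels[masks$cell])
  expect_lt(abs(weighted_total(pm) - total) / total, 0.02)
  expect_lt(abs(weighted_total(nm) - total) / total, 0.02)
  expect_lt(abs(weighted_total(nm) - weighted_total(pm)) / weighted_total(pm), 0.02)
})

test_that("perinuclear mass maps near u = 0 and matches the oracle mean", {
  geom <- small_geometry()
  fld <- noise_free(w_perinuclear = 1, w_uniform = 0, perinuclear_center = 20,
                    perinuclear_width = 5)
  img <- render_image(geom, fld)
  masks <- generate_masks(geom)
  m <- quantify_cell(img, masks, quick_config())
  gt <- ground_truth_metrics(geom, fld, check = FALSE)
  expect_lt(abs(m$mdr_normalized - gt$mdr_normalized) / gt$mdr_normalized, 0.02)
})

test_that("line-profile MDR agrees with the pixel-binning brute force", {
  set.seed(21)
  for (s in 1:3) {
    geom <- small_geometry(seed = s, cell_shape_coeffs = list(c(2, 0.1, s)))
    fld <- noise_free(w_perinuclear = 0.5, w_peripheral = 0.2, w_uniform = 0.3,
                      angular_kappa = s - 1)
    img <- render_image(geom, fld, seed = s)
    masks <- generate_masks(geom)
    cfg <- quick_config()
    m <- quantify_cell(img, masks, cfg, cell_id = as.character(s))
    b <- boundary_radii(masks, masks$center, cfg$theta_step)
    bf <- bruteforce_mdr_raw(img, masks, masks$center, b)
    expect_lt(abs(m$mdr_raw - bf) / bf, 0.02)
  }
})

test_that("halving the grid steps barely changes the metrics", {
  geom <- small_geometry(seed = 5L)
  fld <- noise_free(angular_kappa = 1)
  img <- render_image(geom, fld)
  masks <- generate_masks(geom)
  m1 <- quantify_cell(img, masks, polar_config(theta_step = 0.5, radial_step = 0.5))
  m2 <- quantify_cell(img, masks, polar_config(theta_step = 0.25, radial_step = 0.25))
  expect_lt(abs(m2$mdr_normalized - m1$mdr_normalized) / m1$mdr_normalized, 0.005)
  expect_lt(abs(m2$mdr_raw - m1$mdr_raw) / m1$mdr_raw, 0.005)
})

test_that("degenerate boundary orderings are refused", {
  geom <- small_geometry()
  masks <- generate_masks(geom)
  pm <- sweep_polar(image_plane(matrix(1, 160, 160)), masks$center,
                    theta_step = 1, cell_mask = masks$cell)
  b <- boundary_radii(masks, masks$center, theta_step = 1)
  swapped <- b
  swapped$r_ne <- b$r_edge
  swapped$r_edge <- b$r_ne
  expect_error(normalize_radial(pm, swapped), "degenerate")
  b2 <- boundary_radii(masks, masks$center, theta_step = 0.5)
  expect_error(normalize_radial(pm, b2), "theta grids")
})
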