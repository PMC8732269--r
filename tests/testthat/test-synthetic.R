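test_that("mask rasterization matches analytic areas and containment", {
  geom <- cell_geometry(image_shape = c(200L, 200L),
                        nucleus_center = c(100.5, 100.5),
                        nucleus_semiaxes = c(20, 20), cell_radius_base = 80)
  m <- generate_masks(geom)
  expect_lt(abs(sum(m$nucleus) - pi * 20^2) / (pi * 20^2), 0.02)
  expect_lt(abs(sum(m$cell) - pi * 80^2) / (pi * 80^2), 0.02)
  expect_true(all(m$cell[m$nucleus]))

  nb <- list(list(center = c(100.5, 195), semiaxes = c(15, 10),
                  angle = 0, intensity = 5))
  g2 <- cell_geometry(image_shape = c(200L, 200L),
                      nucleus_center = c(100.5, 100.5),
                      nucleus_semiaxes = c(20, 20), cell_radius_base = 60,
                      neighbor_specs = nb)
  m2 <- generate_masks(g2)
  expect_gt(sum(m2$exclusion), 0)
  expect_false(any(m2$exclusion & m2$nucleus))
})

test_that("invalid geometries are rejected", {
  # nucleus larger than the cell at some angle
  expect_error(cell_geometry(nucleus_semiaxes = c(95, 24), cell_radius_base = 90,
                             image_shape = c(256L, 256L)),
               "invalid geometry")
  # non-star-convex amplitude budget
  expect_error(cell_geometry(cell_shape_coeffs = list(c(2, 0.3, 0), c(3, 0.25, 0))),
               "star-convex")
  # nucleus sticking out of the image
  expect_error(cell_geometry(nucleus_center = c(10, 128), nucleus_semiaxes = c(30, 24)),
               "inside the image")
})

test_that("rendered images are normalized, symmetric when kappa=0, and deterministic", {
  geom <- small_geometry()
  fld <- noise_free(photon_budget = 1e6)
  img <- render_image(geom, fld, seed = 3)
  expect_lt(abs(sum(img$pixels) - 1e6) / 1e6, 0.01)
  expect_true(all(img$pixels >= 0))

  # angular marginal approximately uniform for kappa = 0
  masks <- generate_masks(geom)
  pm <- sweep_polar(img, masks$center, theta_step = 1, cell_mask = masks$cell)
  q <- rowSums(pm$weights * pm$values)
  expect_lt(sd(q) / mean(q), 0.1)

  # identical (geometry, field, seed) -> bit-identical image, with noise on
  fn <- organelle_field()
  i1 <- render_image(geom, fn, seed = 11)
  i2 <- render_image(geom, fn, seed = 11)
  expect_identical(i1$pixels, i2$pixels)
  i3 <- render_image(geom, fn, seed = 12)
  expect_false(identical(i1$pixels, i3$pixels))
})

test_that("quadrature oracle reproduces closed forms", {
  geom <- small_geometry()
  # uniform over cytoplasm -> normalized MDR exactly 50
  unif <- noise_free(w_perinuclear = 0, w_uniform = 1)
  gt <- ground_truth_metrics(geom, unif)
  expect_equal(gt$mdr_normalized, 50, tolerance = 1e-6)
  expect_lt(gt$asymmetry, 1e-10)

  # kappa = 2 -> asymmetry equals the von Mises mean resultant length
  vm <- noise_free(angular_kappa = 2, perinuclear_center = 20,
                   perinuclear_width = 5, w_perinuclear = 1, w_uniform = 0)
  gt2 <- ground_truth_metrics(geom, vm)
  expect_equal(gt2$asymmetry, besselI(2, 1) / besselI(2, 0), tolerance = 1e-6)

  # asymmetry invariant to the mean direction
  vm2 <- noise_free(angular_kappa = 2, angular_mu = 2.2, perinuclear_center = 20,
                    perinuclear_width = 5, w_perinuclear = 1, w_uniform = 0)
  expect_equal(ground_truth_metrics(geom, vm2)$asymmetry, gt2$asymmetry,
               tolerance = 1e-9)

  # normalized MDR independent of the geometry (field lives in u)
  g2 <- cell_geometry(image_shape = c(300L, 300L), nucleus_center = c(150, 150),
                      nucleus_semiaxes = c(40, 22), nucleus_angle = 0.7,
                      cell_radius_base = 110,
                      cell_shape_coeffs = list(c(2, 0.2, 1)))
  expect_equal(ground_truth_metrics(g2, vm)$mdr_normalized, gt2$mdr_normalized,
               tolerance = 1e-9)
})

test_that("oracle raw MDR matches a naive double-sum on a tiny node grid", {
  geom <- small_geometry(cell_shape_coeffs = list(c(2, 0.15, 0.5)))
  fld <- noise_free(angular_kappa = 1.5)
  gt <- ground_truth_metrics(geom, fld, n_theta = 180, n_u = 150, check = FALSE)
  # naive tensor double sum over the same midpoint nodes
  du <- 125 / 150; u <- seq(-25 + du / 2, 100 - du / 2, by = du)
  dth <- 2 * pi / 180; th <- seq(dth / 2, 2 * pi - dth / 2, by = dth)
  gw <- cellsweep:::radial_density(u, fld) * du; gw <- gw / sum(gw)
  hw <- cellsweep:::angular_density(th, fld) * dth; hw <- hw / sum(hw)
  r_ne <- nucleus_boundary_radius(geom, th)
  r_edge <- cell_boundary_radius(geom, th)
  acc <- 0
  for (i in seq_along(th)) {
    r <- cellsweep:::r_from_u(u, r_ne[i], r_edge[i])
    acc <- acc + hw[i] * sum(gw * r)
  }
  expect_equal(gt$mdr_raw, acc * geom$pixel_size, tolerance = 1e-12)
})

test_that("phenotype panels order as designed and are reproducible", {
  wt <- make_phenotype_panel("wildtype", 20, 42, render = FALSE)
  di <- make_phenotype_panel("dispersed", 20, 42, render = FALSE)
  cl <- make_phenotype_panel("clustered", 20, 42, render = FALSE)
  expect_gt(mean(di$truth$mdr_normalized), mean(wt$truth$mdr_normalized))
  expect_gt(mean(cl$truth$asymmetry), mean(wt$truth$asymmetry))
  expect_true(all(cl$truth$asymmetry > 0.5))
  expect_lt(max(wt$truth$asymmetry), 1e-6)

  w2 <- make_phenotype_panel("wildtype", 1, 42, render = FALSE)
  w3 <- make_phenotype_panel("wildtype", 1, 42, render = FALSE)
  expect_identical(w2$truth[, c("mdr_normalized", "mdr_raw", "asymmetry")],
                   w3$truth[, c("mdr_normalized", "mdr_raw", "asymmetry")])
  expect_error(make_phenotype_panel("sideways", 5, 1), "unknown phenotype")
})

test_that("pipeline estimate converges to ground truth at high photon budget", {
  geom <- small_geometry(seed = 9L)
  fld <- organelle_field(photon_budget = 1e7, background = 0, read_noise_sd = 0,
                         angular_kappa = 1)
  gt <- ground_truth_metrics(geom, fld, check = FALSE)
  m <- quantify_cell(render_image(geom, fld, seed = 9),
                     generate_masks(geom), quick_config())
  expect_lt(abs(m$mdr_normalized - gt$mdr_normalized) / gt$mdr_normalized, 0.03)
  expect_lt(abs(m$asymmetry - gt$asymmetry) / gt$asymmetry, 0.03)
})
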