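# Shared fixtures: small, fast phantoms and independent brute-force oracles.

# Coarser sweep used by module tests where sub-percent angular resolution
# is not the thing under test.
quick_config <- function(...) polar_config(theta_step = 0.5, ...)

noise_free <- function(...) {
  organelle_field(..., background = 0, read_noise_sd = 0, shot_noise = FALSE)
}

small_geometry <- function(seed = 1L, ...) {
  cell_geometry(image_shape = c(160L, 160L), pixel_size = 0.1,
                nucleus_center = c(80.5, 80.5),
                nucleus_semiaxes = c(18, 15), cell_radius_base = 55,
                seed = seed, ...)
}

# Constant-intensity disk "cell" with a small concentric nucleus: the
# analytic uniform-disk phantom (raw MDR = 2R/3).
disk_phantom <- function(R = 80, nucleus_r = 16, size = 2L * R + 40L,
                         pixel_size = 0.125, value = 10) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size) - ctr
  cc <- t(rr)
  r <- sqrt(rr^2 + cc^2)
  cellm <- r <= R
  nucm <- r <= nucleus_r
  img <- image_plane(cellm * value, pixel_size)
  list(image = img,
       masks = cell_masks(nucm, cellm, center = c(ctr, ctr)),
       R_um = R * pixel_size, center = c(ctr, ctr))
}

# Brute-force raw-scale MDR: bin whole pixels by their exact radius about
# the centre, restricted to radii inside the per-angle cell edge. Entirely
# independent of the line-profile sweep.
bruteforce_mdr_raw <- function(image, masks, center, bnd) {
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  rr <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  r <- sqrt(rr^2 + cc^2)
  th <- (atan2(rr, cc) * 180 / pi) %% 360
  ti <- pmin(as.integer(round(th / bnd$theta_step)) %% length(bnd$theta_deg) + 1L,
             length(bnd$theta_deg))
  keep <- r <= bnd$r_edge[ti] & px > 0
  sum(px[keep] * r[keep]) / sum(px[keep]) * image$pixel_size
}

# A spatial PMF with all mass at one angle, built directly for degenerate-
# case checks of the asymmetry statistic.
single_angle_pmf <- function(theta_deg = 137, n_theta = 360, n_u = 20) {
  grid <- seq(0, 360 - 360 / n_theta, by = 360 / n_theta)
  p <- matrix(0, n_theta, n_u)
  i <- which.min(abs(grid - theta_deg))
  p[i, ] <- 1 / n_u
  structure(list(p = p, u = seq(2.5, by = 5, length.out = n_u),
                 r_um = matrix(1, n_theta, n_u), theta_deg = grid,
                 domain = "cytoplasm_only"), class = "spatial_pmf")
}

# Lossless 90-degree rotation (in the direction of increasing theta) of a
# matrix about the image centre of a square image.
rot90_mat <- function(m) t(m)[, rev(seq_len(nrow(m)))]
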