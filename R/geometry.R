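#' Specify the geometry of a synthetic cell
#'
#' A phantom cell consists of an elliptical nucleus inside a star-convex
#' outline given in polar form about the nucleus centre:
#' \deqn{r_{cell}(\theta) = R_0 \left(1 + \sum_k a_k \cos(k\theta + \phi_k)\right)}
#' Star-convexity about the centre (every ray crosses the boundary exactly
#' once) is what makes the per-angle radial normalization well defined, so
#' the amplitudes must satisfy \eqn{\sum_k |a_k| < 0.5}.
#'
#' Coordinates are 1-based, pixel-centre (pixel \code{[i, j]} sits at row
#' \code{i}, column \code{j}). Angles are measured with \eqn{\theta = 0}
#' along the +column axis, increasing with +row (\code{atan2(drow, dcol)}).
#'
#' @param image_shape integer (H, W) in pixels.
#' @param pixel_size micrometres per pixel.
#' @param nucleus_center subpixel (row, col) of the nucleus centre.
#' @param nucleus_semiaxes (a, b) ellipse semiaxes in pixels.
#' @param nucleus_angle ellipse rotation, radians.
#' @param cell_radius_base base radius \eqn{R_0} in pixels.
#' @param cell_shape_coeffs list of numeric triplets \code{c(k, a_k, phi_k)}
#'   (harmonic, amplitude, phase) perturbing the outline.
#' @param neighbor_specs optional list of neighbour-cell blobs, each a list
#'   with \code{center} (row, col), \code{semiaxes}, \code{angle},
#'   \code{intensity} (counts per pixel added by \code{render_image}).
#' @param seed integer recorded with the spec.
#' @return object of class \code{cell_geometry}.
#' @export
cell_geometry <- function(image_shape = c(256L, 256L),
                          pixel_size = 0.1,
                          nucleus_center = (image_shape + 1) / 2,
                          nucleus_semiaxes = c(30, 24),
                          nucleus_angle = 0,
                          cell_radius_base = 90,
                          cell_shape_coeffs = list(),
                          neighbor_specs = list(),
                          seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            pixel_size > 0,
            length(nucleus_center) == 2,
            length(nucleus_semiaxes) == 2, all(nucleus_semiaxes > 0),
            cell_radius_base > 0)
  coeffs <- lapply(cell_shape_coeffs, function(co) {
    stopifnot(length(co) == 3, co[1] >= 1, co[1] == round(co[1]))
    as.numeric(co)
  })
  amp_sum <- if (length(coeffs)) sum(abs(vapply(coeffs, `[`, 0, 2))) else 0
  if (amp_sum >= 0.5) {
    stop("invalid geometry: sum of |shape amplitudes| must be < 0.5 ",
         "to keep the outline star-convex", call. = FALSE)
  }
  geom <- structure(list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    nucleus_center = as.numeric(nucleus_center),
    nucleus_semiaxes = as.numeric(nucleus_semiaxes),
    nucleus_angle = as.numeric(nucleus_angle),
    cell_radius_base = as.numeric(cell_radius_base),
    cell_shape_coeffs = coeffs,
    neighbor_specs = neighbor_specs,
    seed = as.integer(seed)
  ), class = "cell_geometry")

  # nucleus fully inside the image
  amax <- max(geom$nucleus_semiaxes)
  if (geom$nucleus_center[1] - amax < 1 || geom$nucleus_center[1] + amax > image_shape[1] ||
      geom$nucleus_center[2] - amax < 1 || geom$nucleus_center[2] + amax > image_shape[2]) {
    stop("invalid geometry: nucleus not fully inside the image", call. = FALSE)
  }
  # strictly positive cytoplasm at every angle
  th <- seq(0, 2 * pi, length.out = 3601)[-3601]
  if (any(cell_boundary_radius(geom, th) <= nucleus_boundary_radius(geom, th))) {
    stop("invalid geometry: cell boundary must lie outside the nucleus at every angle",
         call. = FALSE)
  }
  geom
}

#' Polar radius of the cell outline at given angles
#' @param geometry a \code{cell_geometry}.
#' @param theta angles in radians.
#' @return radii in pixels.
#' @export
cell_boundary_radius <- function(geometry, theta) {
  r <- rep(1, length(theta))
  for (co in geometry$cell_shape_coeffs) {
    r <- r + co[2] * cos(co[1] * theta + co[3])
  }
  geometry$cell_radius_base * r
}

#' Polar radius of the nuclear envelope at given angles
#'
#' Closed-form polar equation of the (rotated) ellipse about its centre.
#' @inheritParams cell_boundary_radius
#' @return radii in pixels.
#' @export
nucleus_boundary_radius <- function(geometry, theta) {
  a <- geometry$nucleus_semiaxes[1]
  b <- geometry$nucleus_semiaxes[2]
  t <- theta - geometry$nucleus_angle
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

#' Specify the organelle fluorescence field of a synthetic cell
#'
#' The continuous density factorizes into an angular part (von Mises with
#' concentration \code{angular_kappa}; 0 means angularly uniform) and a
#' radial part expressed in the normalized coordinate u (% of cytoplasm;
#' nucleoplasm is -25..0). The radial part is a mixture of a perinuclear
#' Gaussian, a peripheral Gaussian and a uniform component on [0, 100],
#' each truncated to [-25, 100]. Because the radial density is specified
#' in u, the normalized-scale ground truth is independent of cell shape.
#'
#' @param w_perinuclear,w_peripheral,w_uniform mixture weights (nonnegative,
#'   sum to 1).
#' @param perinuclear_center,perinuclear_width centre/sd of the perinuclear
#'   component, in u units.
#' @param peripheral_center,peripheral_width centre/sd of the peripheral
#'   component, in u units.
#' @param angular_mu mean direction, radians.
#' @param angular_kappa von Mises concentration, >= 0.
#' @param photon_budget expected total signal photons per cell.
#' @param read_noise_sd Gaussian read noise sd, counts (0 disables).
#' @param background constant background, counts per pixel.
#' @param shot_noise logical; apply Poisson noise to the expected image.
#' @return object of class \code{organelle_field}.
#' @export
organelle_field <- function(w_perinuclear = 0.7,
                            w_peripheral = 0,
                            w_uniform = 0.3,
                            perinuclear_center = 15,
                            perinuclear_width = 8,
                            peripheral_center = 75,
                            peripheral_width = 12,
                            angular_mu = 0,
                            angular_kappa = 0,
                            photon_budget = 1e6,
                            read_noise_sd = 2,
                            background = 0.5,
                            shot_noise = TRUE) {
  w <- c(w_perinuclear, w_peripheral, w_uniform)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  stopifnot(angular_kappa >= 0, photon_budget > 0, read_noise_sd >= 0,
            background >= 0, perinuclear_width > 0, peripheral_width > 0)
  structure(list(
    w_perinuclear = w[1], w_peripheral = w[2], w_uniform = w[3],
    perinuclear_center = perinuclear_center,
    perinuclear_width = perinuclear_width,
    peripheral_center = peripheral_center,
    peripheral_width = peripheral_width,
    angular_mu = angular_mu, angular_kappa = angular_kappa,
    photon_budget = photon_budget, read_noise_sd = read_noise_sd,
    background = background, shot_noise = isTRUE(shot_noise)
  ), class = "organelle_field")
}

# Radial mixture density in u on [-25, 100]; integrates to 1.
radial_density <- function(u, field) {
  tn <- function(u, m, s) {
    z <- pnorm(100, m, s) - pnorm(-25, m, s)
    out <- dnorm(u, m, s) / z
    out[u < -25 | u > 100] <- 0
    out
  }
  unif <- ifelse(u >= 0 & u <= 100, 1 / 100, 0)
  field$w_perinuclear * tn(u, field$perinuclear_center, field$perinuclear_width) +
    field$w_peripheral * tn(u, field$peripheral_center, field$peripheral_width) +
    field$w_uniform * unif
}

# von Mises density on [0, 2*pi); exp-scaled Bessel keeps large kappa stable.
angular_density <- function(theta, field) {
  k <- field$angular_kappa
  if (k == 0) return(rep(1 / (2 * pi), length(theta)))
  exp(k * (cos(theta - field$angular_mu) - 1)) /
    (2 * pi * besselI(k, 0, expon.scaled = TRUE))
}

# Piecewise normalized radial coordinate: cytoplasm 0..100, nucleoplasm -25..0.
u_from_r <- function(r, r_ne, r_edge) {
  ifelse(r >= r_ne,
         100 * (r - r_ne) / (r_edge - r_ne),
         25 * (r / r_ne - 1))
}

# Inverse mapping: raw radius (pixels) from u given per-angle boundaries.
r_from_u <- function(u, r_ne, r_edge) {
  ifelse(u >= 0,
         r_ne + (u / 100) * (r_edge - r_ne),
         r_ne * (1 + u / 25))
}
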