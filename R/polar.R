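#' Bilinear interpolation of a matrix at fractional coordinates
#'
#' Samples outside the matrix are 0. Used both for the polar sweep and for
#' subpixel boundary localization on (0/1) masks.
#'
#' @param img numeric matrix.
#' @param row,col fractional coordinates (1-based, pixel-centre).
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  i0 <- floor(row); j0 <- floor(col)
  fr <- row - i0; fc <- col - j0
  val <- function(i, j) {
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    out <- numeric(length(i))
    out[ok] <- img[cbind(i[ok], j[ok])]
    out
  }
  val(i0, j0) * (1 - fr) * (1 - fc) +
    val(i0 + 1L, j0) * fr * (1 - fc) +
    val(i0, j0 + 1L) * (1 - fr) * fc +
    val(i0 + 1L, j0 + 1L) * fr * fc
}

#' Sweep the image through 360 degrees about the nucleus centre
#'
#' Takes a line profile at each angle (default 0.1-degree steps, i.e. 3600
#' profiles) by bilinear interpolation along rays from the centre out to
#' just past the furthest cell-mask pixel, producing an (r, theta)-space
#' representation of the cell's fluorescence. Each sample carries a
#' Jacobian area weight \eqn{w = r\,\Delta\theta\,\Delta r} so that
#' weighted polar sums estimate Cartesian integrals — this is the
#' correction for the square shape of the pixels versus the polar sampling
#' lattice.
#'
#' @param image an \code{\link{image_plane}}.
#' @param center subpixel (row, col) inside the image.
#' @param theta_step angular step in degrees; must divide 360.
#' @param radial_step radial step in pixels.
#' @param cell_mask logical matrix; defines \code{r_max} (furthest mask
#'   pixel plus a 2 px margin).
#' @return object of class \code{polar_map}: \code{values} (angles x radii),
#'   \code{weights} (same shape), \code{theta_deg}, \code{radii} (pixels,
#'   bin centres), \code{center}, \code{pixel_size}.
#' @export
sweep_polar <- function(image, center, theta_step = 0.1, radial_step = 0.5,
                        cell_mask = NULL) {
  stopifnot(inherits(image, "image_plane"))
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W) {
    stop("centre lies outside the image", call. = FALSE)
  }
  nt <- 360 / theta_step
  if (abs(nt - round(nt)) > 1e-9) {
    stop("theta_step must divide 360 evenly", call. = FALSE)
  }
  nt <- as.integer(round(nt))

  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, H, W)
  idx <- which(cell_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cell mask is empty", call. = FALSE)
  r_max <- sqrt(max((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)) + 2

  theta_deg <- seq(0, 360 - theta_step, by = theta_step)
  th <- theta_deg * pi / 180
  radii <- seq(radial_step / 2, r_max, by = radial_step)

  rows <- center[1] + outer(sin(th), radii)
  cols <- center[2] + outer(cos(th), radii)
  F <- matrix(bilinear_sample(image$pixels, as.vector(rows), as.vector(cols)),
              nt, length(radii))
  dth <- theta_step * pi / 180
  w <- matrix(radii * dth * radial_step, nt, length(radii), byrow = TRUE)

  structure(list(values = F, weights = w, theta_deg = theta_deg,
                 radii = radii, theta_step = theta_step,
                 radial_step = radial_step, r_max = r_max,
                 center = as.numeric(center), pixel_size = image$pixel_size),
            class = "polar_map")
}

#' Per-angle radii of the nuclear envelope and the cell edge
#'
#' For each ray from the centre, the boundary radius is the last crossing
#' of the (bilinearly interpolated, 0.5-thresholded) mask along the ray,
#' refined to subpixel precision by linear interpolation of the threshold
#' crossing. Using the last crossing makes the trace robust to holes in
#' the masks; a ray that never enters the nucleus or the cell raises a
#' degenerate-geometry error naming the angle.
#'
#' @param masks a \code{\link{cell_masks}}.
#' @param center subpixel (row, col).
#' @param theta_step angular step in degrees.
#' @param radial_step ray sampling step in pixels (finer than the sweep by
#'   default for boundary precision).
#' @param smooth_deg optional circular moving-average window in degrees
#'   (0 = off).
#' @return object of class \code{boundary_radii}: \code{theta_deg},
#'   \code{r_ne}, \code{r_edge} (pixels).
#' @export
boundary_radii <- function(masks, center, theta_step = 0.1,
                           radial_step = 0.25, smooth_deg = 0) {
  stopifnot(inherits(masks, "cell_masks"))
  nt <- as.integer(round(360 / theta_step))
  theta_deg <- seq(0, 360 - theta_step, by = theta_step)
  th <- theta_deg * pi / 180

  idx <- which(masks$cell, arr.ind = TRUE)
  r_max <- sqrt(max((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)) + 2
  radii <- seq(radial_step, r_max, by = radial_step)
  nr <- length(radii)

  rows <- center[1] + outer(sin(th), radii)
  cols <- center[2] + outer(cos(th), radii)
  trace_last <- function(mask, what) {
    v <- matrix(bilinear_sample(mask * 1.0, as.vector(rows), as.vector(cols)),
                nt, nr)
    inside <- v >= 0.5
    none <- !rowSums(inside)
    if (any(none)) {
      stop("degenerate geometry: ray at ", theta_deg[which(none)[1]],
           " degrees never crosses the ", what, " mask", call. = FALSE)
    }
    jl <- max.col(inside * col(inside), ties.method = "last")
    r0 <- radii[jl]
    # refine the 0.5-crossing between the last inside sample and the next
    v0 <- v[cbind(seq_len(nt), jl)]
    has_next <- jl < nr
    v1 <- ifelse(has_next, v[cbind(seq_len(nt), pmin(jl + 1L, nr))], 0)
    frac <- ifelse(v0 > v1, (v0 - 0.5) / pmax(v0 - v1, 1e-12), 0)
    r0 + pmin(pmax(frac, 0), 1) * radial_step
  }
  r_ne <- trace_last(masks$nucleus, "nucleus")
  r_edge <- trace_last(masks$cell, "cell")

  if (smooth_deg > 0) {
    k <- max(1L, as.integer(round(smooth_deg / theta_step)))
    r_ne <- circular_mean_filter(r_ne, k)
    r_edge <- circular_mean_filter(r_edge, k)
  }
  if (any(r_ne >= r_edge)) {
    bad <- theta_deg[which(r_ne >= r_edge)[1]]
    stop("degenerate geometry: nuclear envelope at or beyond the cell edge at ",
         bad, " degrees", call. = FALSE)
  }
  structure(list(theta_deg = theta_deg, r_ne = r_ne, r_edge = r_edge,
                 theta_step = theta_step), class = "boundary_radii")
}

circular_mean_filter <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  stats::filter(xx, rep(1 / (2 * half + 1), 2 * half + 1))[(half + 1):(half + n)]
}

#' Normalize the radial axis per angle
#'
#' Per angle, the cytoplasm between the nuclear envelope and the cell edge
#' is rescaled to 0..100% and the nucleoplasm linearly to -25..0 (a control
#' band). Each polar sample inside the cell edge deposits its weighted
#' intensity onto the fixed u grid by conservative linear (cloud-in-cell)
#' splitting, so total weighted intensity inside the cell is preserved;
#' samples beyond the cell edge are dropped. Values are intensities
#' (mass / deposited area), with the deposited area carried as the sample
#' weight.
#'
#' @param pmap a \code{\link{sweep_polar}} result.
#' @param radii a \code{\link{boundary_radii}} result on the same theta grid.
#' @param u_step grid step in percent (default 0.5).
#' @return object of class \code{normalized_polar_map}: \code{values} G
#'   (angles x u bins), \code{weights} (deposited Cartesian area),
#'   \code{u} (bin centres, -25..100), \code{r_px} (raw radius at each
#'   (angle, u) sample, pixels), \code{theta_deg}, \code{pixel_size}.
#' @export
normalize_radial <- function(pmap, radii, u_step = 0.5) {
  stopifnot(inherits(pmap, "polar_map"), inherits(radii, "boundary_radii"))
  if (length(pmap$theta_deg) != length(radii$theta_deg) ||
      max(abs(pmap$theta_deg - radii$theta_deg)) > 1e-9) {
    stop("polar map and boundary radii are on different theta grids", call. = FALSE)
  }
  if (any(radii$r_ne >= radii$r_edge)) {
    stop("degenerate geometry: r_ne >= r_edge", call. = FALSE)
  }
  nt <- length(pmap$theta_deg)
  nu <- as.integer(round(125 / u_step))
  u_centers <- seq(-25 + u_step / 2, by = u_step, length.out = nu)

  r <- matrix(pmap$radii, nt, length(pmap$radii), byrow = TRUE)
  keep <- r <= radii$r_edge            # recycles r_edge down columns
  u <- u_from_r(r, radii$r_ne, radii$r_edge)
  u <- pmin(pmax(u, -25), 100 - 1e-9)

  ang <- row(r)[keep]
  mass <- (pmap$weights * pmap$values)[keep]
  area <- pmap$weights[keep]
  pos <- (u[keep] - u_centers[1]) / u_step + 1
  k0 <- pmin(pmax(floor(pos), 1), nu)
  frac <- pmin(pmax(pos - k0, 0), 1)
  k1 <- pmin(k0 + 1L, nu)

  acc <- function(x) {
    as.matrix(sparseMatrix(
      i = c(ang, ang), j = c(k0, k1),
      x = c(x * (1 - frac), x * frac),
      dims = c(nt, nu)))
  }
  M <- acc(mass)
  A <- acc(area)
  G <- ifelse(A > 0, M / A, 0)

  r_px <- t(vapply(seq_len(nt), function(i)
    r_from_u(u_centers, radii$r_ne[i], radii$r_edge[i]),
    numeric(nu)))

  structure(list(values = G, weights = A, u = u_centers, r_px = r_px,
                 theta_deg = pmap$theta_deg, u_step = u_step,
                 pixel_size = pmap$pixel_size, center = pmap$center),
            class = "normalized_polar_map")
}

#' Total weighted intensity of a polar or normalized map
#'
#' \eqn{\sum w F}; on a \code{polar_map} this estimates the Cartesian
#' integral over the swept disk, on a \code{normalized_polar_map} the
#' integral inside the cell edge.
#' @param x a \code{polar_map} or \code{normalized_polar_map}.
#' @return scalar total.
#' @export
weighted_total <- function(x) {
  sum(x$weights * x$values)
}

#' Rotate an image plane about a centre (bilinear resampling)
#'
#' Inverse-mapping rotation used by the invariance checks; masks should be
#' rotated with \code{threshold = 0.5}.
#'
#' @param image an \code{\link{image_plane}} or logical matrix.
#' @param angle rotation in radians (direction of increasing theta).
#' @param center subpixel (row, col) pivot; defaults to the image centre.
#' @param threshold optional; if given, output is thresholded to logical.
#' @return rotated object of the same kind.
#' @export
rotate_plane <- function(image, angle, center = NULL, threshold = NULL) {
  px <- if (inherits(image, "image_plane")) image$pixels else image * 1.0
  H <- nrow(px); W <- ncol(px)
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  rr <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  ca <- cos(-angle); sa <- sin(-angle)
  src_r <- center[1] + (cc * sa + rr * ca)
  src_c <- center[2] + (cc * ca - rr * sa)
  out <- matrix(bilinear_sample(px, as.vector(src_r), as.vector(src_c)), H, W)
  if (!is.null(threshold)) return(out >= threshold)
  if (inherits(image, "image_plane")) {
    image_plane(out, image$pixel_size, paste(image$provenance, "(rotated)"))
  } else out
}
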