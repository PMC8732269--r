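#' Convert a normalized polar map into a spatial probability mass function
#'
#' Treats the image as a discrete spatial distribution: each (angle, u)
#' sample receives mass proportional to its area-weighted intensity, and
#' masses are normalized to sum to 1. The \code{full} domain spans
#' u in [-25, 100]; \code{cytoplasm_only} restricts to u >= 0. Negative
#' intensities (not expected) are clipped to 0 before normalizing.
#'
#' @param nmap a \code{\link{normalize_radial}} result.
#' @param domain \code{"full"} or \code{"cytoplasm_only"}.
#' @return object of class \code{spatial_pmf}: \code{p} (angles x u bins,
#'   sums to 1), \code{u} (%), \code{r_um} (raw radius per sample,
#'   micrometres), \code{theta_deg}, \code{domain}.
#' @export
to_pmf <- function(nmap, domain = c("full", "cytoplasm_only")) {
  stopifnot(inherits(nmap, "normalized_polar_map"))
  domain <- match.arg(domain)
  keep <- if (domain == "cytoplasm_only") nmap$u >= 0 else rep(TRUE, length(nmap$u))
  mass <- nmap$weights[, keep, drop = FALSE] * pmax(nmap$values[, keep, drop = FALSE], 0)
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0) {
    stop("empty signal: zero total intensity on the '", domain, "' domain",
         call. = FALSE)
  }
  structure(list(p = mass / tot,
                 u = nmap$u[keep],
                 r_um = nmap$r_px[, keep, drop = FALSE] * nmap$pixel_size,
                 theta_deg = nmap$theta_deg,
                 domain = domain), class = "spatial_pmf")
}

#' Mean distribution radius (MDR)
#'
#' The probability-weighted mean radial position of the signal,
#' \eqn{\sum_{i,k} p_{ik}\,\rho_{ik}}, with \eqn{\rho} either the
#' normalized coordinate u (% of cytoplasm; nucleoplasm counts negatively)
#' or the raw radius in micrometres. Higher MDR means more peripheral
#' ("dispersed") signal.
#'
#' @param pmf a \code{\link{to_pmf}} result.
#' @param scale \code{"normalized"} (%) or \code{"raw"} (micrometres).
#' @return scalar MDR.
#' @export
mean_distribution_radius <- function(pmf, scale = c("normalized", "raw")) {
  stopifnot(inherits(pmf, "spatial_pmf"))
  scale <- match.arg(scale)
  if (scale == "normalized") {
    sum(pmf$p %*% pmf$u)
  } else {
    sum(pmf$p * pmf$r_um)
  }
}

#' Angular asymmetry (circular mean resultant length)
#'
#' Collapses the PMF to its angular marginal \eqn{q(\theta_i) = \sum_k
#' p_{ik}} and computes the first circular moment
#' \eqn{\left|\sum_i q(\theta_i)\,e^{i\theta_i}\right|}. The magnitude is
#' 0 for angularly even signal and 1 when all mass sits at a single angle
#' — i.e. it measures how strongly the organelle collapses to one side of
#' the nucleus. The magnitude is rotation invariant; \code{mean_angle}
#' (the argument of the same sum) is rotation equivariant.
#'
#' @param pmf a \code{\link{to_pmf}} result.
#' @return list with \code{asymmetry} in [0,1] and \code{mean_angle}
#'   in radians.
#' @export
asymmetry <- function(pmf) {
  stopifnot(inherits(pmf, "spatial_pmf"))
  q <- rowSums(pmf$p)
  th <- pmf$theta_deg * pi / 180
  C <- sum(q * cos(th)); S <- sum(q * sin(th))
  list(asymmetry = sqrt(C^2 + S^2), mean_angle = atan2(S, C))
}

#' Quantify one cell end to end
#'
#' Deterministic composition of the pipeline stages:
#' neighbour exclusion, centre location, polar sweep, boundary tracing,
#' radial normalization, PMF conversion and the two summary statistics.
#' Errors from any stage are re-raised with the stage name attached.
#'
#' @param image an \code{\link{image_plane}}.
#' @param masks a \code{\link{cell_masks}}.
#' @param config a \code{\link{polar_config}}.
#' @param cell_id identifier copied into the output row.
#' @return one-row data.frame: \code{cell_id}, \code{mdr_normalized} (%),
#'   \code{mdr_raw} (micrometres), \code{asymmetry}, \code{mean_angle}
#'   (radians), \code{domain}.
#' @export
quantify_cell <- function(image, masks, config = polar_config(),
                          cell_id = NA_character_) {
  stopifnot(inherits(config, "polar_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  img <- stage("exclude_neighbors", exclude_neighbors(image, masks))
  ctr <- stage("locate_center", locate_center(masks, config$center_override))
  pmap <- stage("sweep_polar",
                sweep_polar(img, ctr, config$theta_step, config$radial_step,
                            cell_mask = masks$cell))
  bnd <- stage("boundary_radii",
               boundary_radii(masks, ctr, config$theta_step,
                              smooth_deg = config$smooth_deg))
  nmap <- stage("normalize_radial", normalize_radial(pmap, bnd, config$u_step))
  pmf <- stage("to_pmf", to_pmf(nmap, config$domain))
  asym <- asymmetry(pmf)
  data.frame(cell_id = cell_id,
             mdr_normalized = mean_distribution_radius(pmf, "normalized"),
             mdr_raw = mean_distribution_radius(pmf, "raw"),
             asymmetry = asym$asymmetry,
             mean_angle = asym$mean_angle,
             domain = pmf$domain,
             stringsAsFactors = FALSE)
}
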