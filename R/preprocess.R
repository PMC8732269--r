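#' Construct an image plane
#'
#' @param pixels numeric H x W matrix of nonnegative, finite intensities.
#' @param pixel_size micrometres per pixel.
#' @param provenance free-text description (projection method, channel).
#' @return object of class \code{image_plane}.
#' @export
image_plane <- function(pixels, pixel_size = 1, provenance = "") {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("image contains non-finite values", call. = FALSE)
  if (any(pixels < 0)) stop("image contains negative values", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance), class = "image_plane")
}

#' Construct a set of cell masks
#'
#' @param nucleus,cell,exclusion logical H x W matrices; nucleus must be
#'   contained in cell and disjoint from exclusion.
#' @param center subpixel (row, col); defaults to the nucleus centroid.
#' @return object of class \code{cell_masks}.
#' @export
cell_masks <- function(nucleus, cell, exclusion = NULL, center = NULL) {
  nucleus <- to_logical_mask(nucleus)
  cell <- to_logical_mask(cell)
  if (is.null(exclusion)) exclusion <- matrix(FALSE, nrow(cell), ncol(cell))
  exclusion <- to_logical_mask(exclusion)
  if (!all(dim(nucleus) == dim(cell)) || !all(dim(cell) == dim(exclusion))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (any(nucleus & !cell)) stop("nucleus mask not contained in cell mask", call. = FALSE)
  if (any(nucleus & exclusion)) stop("exclusion mask overlaps the nucleus", call. = FALSE)
  m <- structure(list(nucleus = nucleus, cell = cell, exclusion = exclusion,
                      center = center), class = "cell_masks")
  if (is.null(center)) m$center <- locate_center(m)
  m
}

to_logical_mask <- function(x) {
  x <- as.matrix(x)
  mode(x) <- "logical"
  x
}

#' Sum-project a z-stack to a single plane
#'
#' Per-pixel sum over planes in floating point, with no clipping or integer
#' rounding, so that downstream quantification keeps full precision.
#'
#' @param stack 3D numeric array (H x W x Z) or list of H x W matrices.
#' @param pixel_size micrometres per pixel of the stack.
#' @return an \code{\link{image_plane}}.
#' @export
sum_project <- function(stack, pixel_size = 1) {
  if (is.list(stack)) {
    if (length(stack) == 0) stop("empty stack", call. = FALSE)
    stack <- simplify2array(stack)
  }
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1L)
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("stack must have at least one plane", call. = FALSE)
  }
  image_plane(rowSums(stack, dims = 2), pixel_size,
              provenance = sprintf("sum projection of %d planes", dim(stack)[3]))
}

#' Zero the signal of neighbouring cells
#'
#' Pixels under the exclusion mask are set to zero; everything else is
#' untouched, so the total intensity drops by exactly the excluded sum.
#' Zeroing (rather than flagging missing) keeps the probability mass
#' function definition simple; if the exclusion region overlaps the
#' analysed cell, its peripheral mass is slightly deflated.
#'
#' @param image an \code{\link{image_plane}}.
#' @param masks a \code{\link{cell_masks}} (its \code{exclusion} is used).
#' @return an \code{\link{image_plane}} with excluded pixels zeroed.
#' @export
exclude_neighbors <- function(image, masks) {
  stopifnot(inherits(image, "image_plane"), inherits(masks, "cell_masks"))
  if (!all(dim(image$pixels) == dim(masks$exclusion))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  px <- image$pixels
  px[masks$exclusion] <- 0
  image_plane(px, image$pixel_size, image$provenance)
}

#' Locate the nucleus centre
#'
#' Returns the manual override when given, else the unweighted centroid of
#' the nucleus mask. The result must lie inside the nucleus mask (this can
#' fail for strongly non-convex masks); in that case an error asks for a
#' manual override.
#'
#' @param masks a \code{\link{cell_masks}} (only \code{nucleus} is used).
#' @param override optional subpixel (row, col), returned verbatim.
#' @return subpixel (row, col).
#' @export
locate_center <- function(masks, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2)
    return(as.numeric(override))
  }
  nuc <- masks$nucleus
  if (!any(nuc)) stop("nucleus mask is empty", call. = FALSE)
  idx <- which(nuc, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ri <- min(max(round(ctr[1]), 1), nrow(nuc))
  ci <- min(max(round(ctr[2]), 1), ncol(nuc))
  if (!nuc[ri, ci]) {
    stop("nucleus centroid falls outside the nucleus mask (non-convex mask); ",
         "supply a manual centre override", call. = FALSE)
  }
  unname(ctr)
}
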