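#' Pipeline configuration
#'
#' Bundles the tunable parameters of the quantification. Defaults follow
#' the sweep convention of a 360-degree scan in 0.1-degree steps; the
#' radial and u steps of 0.5 oversample the pixel grid roughly twofold.
#'
#' @param theta_step angular step, degrees; must divide 360.
#' @param radial_step radial sampling step, pixels.
#' @param u_step normalized-radius grid step, percent.
#' @param domain PMF domain: \code{"full"} (-25..100, default) or
#'   \code{"cytoplasm_only"}.
#' @param smooth_deg circular smoothing window for boundary radii,
#'   degrees (0 = off).
#' @param center_override optional subpixel (row, col) manual centre.
#' @param seed optional integer recorded with outputs.
#' @return object of class \code{polar_config}.
#' @export
polar_config <- function(theta_step = 0.1, radial_step = 0.5, u_step = 0.5,
                         domain = c("full", "cytoplasm_only"),
                         smooth_deg = 0, center_override = NULL, seed = NULL) {
  domain <- match.arg(domain)
  nt <- 360 / theta_step
  if (abs(nt - round(nt)) > 1e-9) stop("theta_step must divide 360", call. = FALSE)
  stopifnot(theta_step > 0, radial_step > 0, u_step > 0, smooth_deg >= 0)
  structure(list(theta_step = theta_step, radial_step = radial_step,
                 u_step = u_step, domain = domain, smooth_deg = smooth_deg,
                 center_override = center_override, seed = seed),
            class = "polar_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the version-2 serialization of the parameter list; embedded in
#' batch outputs so any metrics table can be traced to the exact settings.
#'
#' @param config a \code{\link{polar_config}}.
#' @return character MD5 hex digest.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "polar_config"))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(unclass(config), NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json holding any subset of
#'   the \code{\link{polar_config}} fields.
#' @return a \code{polar_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(polar_config, vals)
}

#' Read a single-plane or multi-page TIFF as an image plane
#'
#' @param path TIFF file; multi-page stacks are sum-projected.
#' @param pixel_size micrometres per pixel; when NULL, taken from the
#'   \code{.json} sidecar if present, else 1.
#' @return an \code{\link{image_plane}}.
#' @export
read_image_tiff <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  meta <- read_sidecar(path)
  sc <- meta$intensity_scale %||% 1
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size %||% 1
  sum_project(lapply(pages, function(p) p * sc), pixel_size)
}

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side) else list()
}

#' Write an image plane as a 32-bit TIFF with a JSON intensity sidecar
#'
#' TIFF samples are stored on [0, 1] at 32-bit depth (relative precision
#' ~1e-9); the original intensity scale is recorded in a \code{.json}
#' sidecar next to the file and reapplied by \code{\link{read_image_tiff}},
#' so the round trip preserves absolute counts.
#'
#' @param image an \code{\link{image_plane}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "image_plane"))
  sc <- max(image$pixels, 1e-12)
  tiff::writeTIFF(image$pixels / sc, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(intensity_scale = sc,
                            pixel_size = image$pixel_size,
                            provenance = image$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 0/255 (or 0/1) mask image
#'
#' @param path PNG or TIFF file.
#' @return logical matrix (value >= half the maximum is inside).
#' @export
read_mask <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m >= max(m) / 2
}

#' Write a logical mask as an 8-bit 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Quantify a batch of cells from a file manifest
#'
#' One cell per manifest row; per-cell failures are logged (stage and
#' reason) and the run continues, so one corrupt input never loses a
#' batch. The returned table carries the failure log and the config hash
#' as attributes.
#'
#' @param manifest data.frame or CSV path with columns \code{image},
#'   \code{nucleus}, \code{cell}, optional \code{exclusion}, \code{group},
#'   \code{cell_id}, optional \code{pixel_size}.
#' @param config a \code{\link{polar_config}}.
#' @param quiet suppress per-cell progress messages.
#' @return data.frame of per-cell metrics (one row per successful cell)
#'   with attributes \code{failures} (data.frame of cell_id, error) and
#'   \code{config_hash}.
#' @export
run_batch <- function(manifest, config = polar_config(), quiet = TRUE) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("unreadable manifest: ", manifest, call. = FALSE)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("image", "nucleus", "cell", "group", "cell_id")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      ps <- if (!is.null(row$pixel_size) && !is.na(row$pixel_size)) row$pixel_size else NULL
      img <- read_image_tiff(row$image, pixel_size = ps)
      excl <- if (!is.null(row$exclusion) && !is.na(row$exclusion) &&
                  nzchar(row$exclusion)) read_mask(row$exclusion) else NULL
      masks <- cell_masks(read_mask(row$nucleus), read_mask(row$cell), excl)
      m <- quantify_cell(img, masks, config, cell_id = row$cell_id)
      m$group <- row$group
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- data.frame(
        cell_id = row$cell_id, error = conditionMessage(res),
        stringsAsFactors = FALSE)
      if (!quiet) message("FAILED ", row$cell_id, ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
      if (!quiet) message("done ", row$cell_id)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), mdr_normalized = numeric(),
               mdr_raw = numeric(), asymmetry = numeric(),
               mean_angle = numeric(), domain = character(),
               group = character(), stringsAsFactors = FALSE)
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(cell_id = character(), error = character(), stringsAsFactors = FALSE)
  attr(out, "config_hash") <- config_hash(config)
  out
}

#' Simulate a phenotype panel and write it to disk
#'
#' Writes, per cell, a float TIFF image and 0/255 PNG masks, plus a batch
#' manifest (\code{manifest.csv}) and the ground-truth table
#' (\code{ground_truth.csv}). Re-running with the same arguments
#' reproduces identical files.
#'
#' @inheritParams make_phenotype_panel
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
simulate_panel_files <- function(phenotype, n_cells, seed, out_dir,
                                 with_neighbors = FALSE, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- make_phenotype_panel(phenotype, n_cells, seed, render = TRUE,
                                with_neighbors = with_neighbors, ...)
  man <- lapply(panel$cells, function(cell) {
    base <- file.path(out_dir, cell$cell_id)
    write_image_tiff(cell$image, paste0(base, ".tif"))
    write_mask(cell$masks$nucleus, paste0(base, "_nucleus.png"))
    write_mask(cell$masks$cell, paste0(base, "_cell.png"))
    excl <- paste0(base, "_exclusion.png")
    has_excl <- any(cell$masks$exclusion)
    if (has_excl) write_mask(cell$masks$exclusion, excl)
    data.frame(image = paste0(base, ".tif"),
               nucleus = paste0(base, "_nucleus.png"),
               cell = paste0(base, "_cell.png"),
               exclusion = if (has_excl) excl else "",
               group = phenotype, cell_id = cell$cell_id,
               pixel_size = cell$geometry$pixel_size,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, man)
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth <- panel$truth[, c("cell_id", "phenotype", "mdr_normalized",
                           "mdr_raw", "asymmetry", "seed")]
  write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(man)
}
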