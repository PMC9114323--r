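#' Construct a cell image set
#'
#' Bundles registered intensity channels with the per-cell label masks the
#' quantification needs: a whole-cell label image, a nucleus label image
#' using the same integer labels (0 = background), and a staining-free
#' background ROI used to estimate per-channel background means. All arrays
#' must share one shape; each nucleus mask must lie inside its whole-cell
#' mask; the background ROI must be disjoint from every cell.
#'
#' @param channels named list of numeric matrices (nonnegative intensities,
#'   arbitrary units).
#' @param cell_labels integer matrix of whole-cell labels (0 = background).
#' @param nucleus_labels integer matrix of nucleus labels (same label ids).
#' @param background_roi logical matrix marking a staining-free region.
#' @return An object of class `cell_image_set`.
#' @export
cell_image_set <- function(channels, cell_labels, nucleus_labels, background_roi) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list of matrices")
  }
  shp <- dim(cell_labels)
  for (nm in names(channels)) {
    if (!is.matrix(channels[[nm]])) stop("channel '", nm, "' is not a matrix")
    if (!identical(dim(channels[[nm]]), shp)) {
      stop("channel '", nm, "' shape differs from the label masks")
    }
    if (any(channels[[nm]] < 0)) stop("channel '", nm, "' has negative intensities")
  }
  if (!identical(dim(nucleus_labels), shp) || !identical(dim(background_roi), shp)) {
    stop("all masks must share the channel shape")
  }
  storage.mode(cell_labels) <- "integer"
  storage.mode(nucleus_labels) <- "integer"
  background_roi <- background_roi > 0

  labs <- setdiff(sort(unique(as.vector(cell_labels))), 0L)
  nuc_out <- nucleus_labels != 0L & nucleus_labels != cell_labels
  if (any(nuc_out)) stop("every nucleus mask must lie inside its whole-cell mask")
  if (!all(labs %in% nucleus_labels)) {
    stop("every cell label must have a nucleus region")
  }
  if (any(cell_labels[background_roi] != 0L)) {
    stop("background ROI must be disjoint from every cell mask")
  }
  structure(list(channels = channels, cell_labels = cell_labels,
                 nucleus_labels = nucleus_labels, background_roi = background_roi),
            class = "cell_image_set")
}

#' @export
print.cell_image_set <- function(x, ...) {
  labs <- setdiff(unique(as.vector(x$cell_labels)), 0L)
  cat(sprintf("<cell_image_set> %dx%d px, %d cell(s), channels: %s\n",
              nrow(x$cell_labels), ncol(x$cell_labels), length(labs),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Integrated density over a region
#'
#' Sum of pixel intensities over the mask — equivalently mean pixel intensity
#' times region area, the standard ImageJ "integrated density".
#'
#' @param channel numeric intensity matrix.
#' @param mask logical matrix (or coercible), nonempty.
#' @return the integrated density (a nonnegative number for nonnegative input).
#' @export
integrated_density <- function(channel, mask) {
  mask <- mask > 0
  if (!any(mask)) stop("integrated_density: mask is empty")
  if (!identical(dim(channel), dim(mask))) stop("channel and mask shapes differ")
  sum(channel[mask])
}

#' Background-adjust an integrated density
#'
#' Subtracts the expected background contribution, `background_mean *
#' mask_area`, from an integrated density. A negative adjusted value is
#' non-physical (the region is dimmer than the staining-free background), so
#' it is clamped to 0 and flagged in the `"clamped"` attribute.
#'
#' @param id_value integrated density (or vector thereof).
#' @param mask_area region area in pixels (>= 1).
#' @param background_mean mean intensity of the staining-free ROI.
#' @return adjusted value(s), clamped at 0, with logical attribute `clamped`.
#' @export
background_adjust <- function(id_value, mask_area, background_mean) {
  if (any(mask_area < 1)) stop("mask_area must be >= 1")
  if (any(background_mean < 0)) stop("background_mean must be nonnegative")
  adj <- id_value - background_mean * mask_area
  clamped <- adj < 0
  adj[clamped] <- 0
  attr(adj, "clamped") <- clamped
  adj
}

#' Cytoplasmic-to-nuclear ratio
#'
#' The cytoplasmic signal is the whole-cell integrated density minus the
#' nuclear integrated density; the ratio divides it by the nuclear integrated
#' density. Undefined (NA) when the nuclear signal is not positive; a whole
#' below nuclear (negative cytoplasm) yields a negative ratio and is left to
#' the caller to flag.
#'
#' @param adjusted_whole_id,adjusted_nuclear_id background-adjusted integrated
#'   densities of the whole cell and nucleus.
#' @return `(whole - nuclear) / nuclear`, or NA where nuclear <= 0.
#' @export
cytoplasmic_nuclear_ratio <- function(adjusted_whole_id, adjusted_nuclear_id) {
  out <- (adjusted_whole_id - adjusted_nuclear_id) / adjusted_nuclear_id
  out[adjusted_nuclear_id <= 0] <- NA_real_
  out
}

#' DAPI-normalized total level
#'
#' Normalizing a cell's total signal to its DAPI integrated density corrects
#' for uneven focal planes across a field. Undefined (NA) when the DAPI
#' integrated density is not positive.
#'
#' @param total_id total (whole-cell) integrated density of the channel.
#' @param dapi_id DAPI integrated density of the same cell.
#' @return `total_id / dapi_id`, NA where `dapi_id <= 0`.
#' @export
dapi_normalized_level <- function(total_id, dapi_id) {
  out <- total_id / dapi_id
  out[dapi_id <= 0] <- NA_real_
  out
}

#' Nuclear poly(A+) RNA concentration
#'
#' DAPI-adjusted nuclear signal per unit nuclear area:
#' `(nuclear_id / dapi_id) / nuclear_area`.
#'
#' @param nuclear_polyA_id nuclear integrated density of the poly(A+) channel.
#' @param dapi_id DAPI integrated density (> 0).
#' @param nuclear_area nucleus area in pixels (>= 1).
#' @return the concentration, NA where `dapi_id <= 0`.
#' @export
nuclear_polyA_concentration <- function(nuclear_polyA_id, dapi_id, nuclear_area) {
  if (any(nuclear_area < 1)) stop("nuclear_area must be >= 1")
  out <- (nuclear_polyA_id / dapi_id) / nuclear_area
  out[dapi_id <= 0] <- NA_real_
  out
}

.border_labels <- function(lab) {
  edge <- c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)])
  setdiff(unique(edge), 0L)
}

#' Per-cell fluorescence quantification
#'
#' For every cell label and requested channel, measures whole-cell and
#' nuclear integrated densities, subtracts the per-channel background
#' (mean intensity of the staining-free ROI times region area), and derives
#' the cytoplasmic integrated density, the cytoplasmic-to-nuclear ratio, and
#' — when a DAPI channel is named — the DAPI-normalized total and the
#' DAPI-adjusted nuclear concentration (per pixel of nucleus). The DAPI
#' integrated density is taken over the nuclear ROI, where the stain lives.
#' Cells whose whole-cell mask touches the image border are excluded (their
#' cytoplasm is truncated, which would bias ratios) and counted in a message.
#'
#' @param images a [cell_image_set()].
#' @param channels_to_measure character vector of channel names to quantify.
#' @param dapi_channel optional name of the DAPI channel.
#' @param background_correct subtract the staining-free-ROI background
#'   (default `TRUE`; with `FALSE`, raw integrated densities are used
#'   downstream unchanged).
#' @param dapi_use_adjusted use background-adjusted integrated densities in
#'   the DAPI normalization step (default `TRUE`); with `FALSE` the raw
#'   densities are normalized first and background is only reflected in the
#'   adjusted columns.
#' @return data.frame with one row per (cell, channel): areas, raw and
#'   adjusted integrated densities, `background_mean`, `clamped`, `cn_ratio`,
#'   `dapi_normalized_total`, `nuclear_concentration`.
#' @export
quantify_cells <- function(images, channels_to_measure = names(images$channels),
                           dapi_channel = NULL, background_correct = TRUE,
                           dapi_use_adjusted = TRUE) {
  stopifnot(inherits(images, "cell_image_set"))
  bad <- setdiff(c(channels_to_measure, dapi_channel), names(images$channels))
  if (length(bad) > 0L) stop("unknown channel(s): ", paste(bad, collapse = ", "))

  lab <- images$cell_labels
  nuc <- images$nucleus_labels
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(labs) == 0L) {
    warning("quantify_cells: no cells in the label mask")
    return(.empty_measurements())
  }
  border <- .border_labels(lab)
  if (length(border) > 0L) {
    message(sprintf("quantify_cells: excluded %d border-touching cell(s)", length(border)))
    labs <- setdiff(labs, border)
  }
  if (length(labs) == 0L) return(.empty_measurements())

  if (!any(images$background_roi)) stop("background ROI is empty")
  bg_mean <- vapply(images$channels,
                    function(ch) mean(ch[images$background_roi]), numeric(1))

  measure_one <- function(k, channel_name) {
    wm <- lab == k
    nm <- nuc == k
    whole_area <- sum(wm); nuclear_area <- sum(nm)
    ch <- images$channels[[channel_name]]
    whole_id <- integrated_density(ch, wm)
    nuclear_id <- integrated_density(ch, nm)
    bgm <- if (background_correct) bg_mean[[channel_name]] else 0
    adj_whole <- whole_id - bgm * whole_area
    adj_nuclear <- nuclear_id - bgm * nuclear_area
    adj_cyto <- adj_whole - adj_nuclear
    clamped <- adj_whole < 0 || adj_nuclear < 0 || adj_cyto < 0
    adj_whole <- max(adj_whole, 0); adj_nuclear <- max(adj_nuclear, 0)
    adj_cyto <- max(adj_cyto, 0)

    dapi_norm <- nuclear_conc <- NA_real_
    if (!is.null(dapi_channel)) {
      dch <- images$channels[[dapi_channel]]
      dapi_id <- integrated_density(dch, nm)
      if (background_correct && dapi_use_adjusted) {
        dapi_id <- max(dapi_id - bg_mean[[dapi_channel]] * nuclear_area, 0)
        dapi_norm <- dapi_normalized_level(adj_whole, dapi_id)
        nuclear_conc <- nuclear_polyA_concentration(adj_nuclear, dapi_id, nuclear_area)
      } else {
        dapi_norm <- dapi_normalized_level(whole_id, dapi_id)
        nuclear_conc <- nuclear_polyA_concentration(nuclear_id, dapi_id, nuclear_area)
      }
    }
    data.frame(
      cell_id = k, channel = channel_name,
      whole_area = whole_area, nuclear_area = nuclear_area,
      whole_id = whole_id, nuclear_id = nuclear_id, cyto_id = whole_id - nuclear_id,
      background_mean = bgm,
      adjusted_whole_id = adj_whole, adjusted_nuclear_id = adj_nuclear,
      adjusted_cyto_id = adj_cyto, clamped = clamped,
      cn_ratio = cytoplasmic_nuclear_ratio(adj_whole, adj_nuclear),
      dapi_normalized_total = dapi_norm, nuclear_concentration = nuclear_conc,
      stringsAsFactors = FALSE)
  }

  grid <- expand.grid(cell = labs, channel = channels_to_measure,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, Map(measure_one, grid$cell, grid$channel))
  rownames(out) <- NULL
  out
}

.empty_measurements <- function() {
  data.frame(cell_id = integer(), channel = character(),
             whole_area = integer(), nuclear_area = integer(),
             whole_id = numeric(), nuclear_id = numeric(), cyto_id = numeric(),
             background_mean = numeric(),
             adjusted_whole_id = numeric(), adjusted_nuclear_id = numeric(),
             adjusted_cyto_id = numeric(), clamped = logical(),
             cn_ratio = numeric(), dapi_normalized_total = numeric(),
             nuclear_concentration = numeric(), stringsAsFactors = FALSE)
}

#' Nucleus label mask from a DAPI channel (synthetic images)
#'
#' Convenience segmentation for simulated images only: a global intensity
#' threshold on the DAPI channel followed by connected-component labelling
#' (EBImage). Real data should come with curated ROI masks; this generator
#' makes no attempt at watershed splitting or illumination correction.
#'
#' @param dapi numeric DAPI intensity matrix.
#' @param threshold global threshold; default midway between the channel's
#'   minimum and maximum.
#' @return integer label matrix (0 = background).
#' @export
nucleus_mask_from_dapi <- function(dapi, threshold = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("nucleus_mask_from_dapi requires the EBImage package")
  }
  if (is.null(threshold)) threshold <- (min(dapi) + max(dapi)) / 2
  lab <- EBImage::bwlabel(dapi > threshold)
  storage.mode(lab) <- "integer"
  matrix(lab, nrow = nrow(dapi))
}

## TIFF plumbing --------------------------------------------------------------

#' Read an intensity channel or label mask from TIFF
#'
#' Counterpart of [write_image_tiff()]: reads the first plane and rescales
#' from the stored \[0,1\] range back to intensity units.
#'
#' @param path path to the TIFF file.
#' @param scale intensity corresponding to full scale (must match the value
#'   used at write time; default 65535).
#' @param integer round to integers (for label masks).
#' @return numeric (or integer) matrix.
#' @export
read_image_tiff <- function(path, scale = 65535, integer = FALSE) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img <- img * scale
  if (integer) {
    img <- round(img)
    storage.mode(img) <- "integer"
  }
  img
}

#' Write an intensity channel or label mask as 32-bit TIFF
#'
#' Intensities are stored as `x / scale` in 32-bit samples (relative
#' round-trip error ~1e-9 of full scale); integer label masks round-trip
#' exactly when read back with `integer = TRUE`.
#'
#' @param x numeric matrix with values in `[0, scale]`.
#' @param path destination path.
#' @param scale intensity corresponding to full scale (default 65535).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, scale = 65535) {
  if (max(x) > scale || min(x) < 0) {
    stop("intensities must lie in [0, scale]; raise `scale`")
  }
  tiff::writeTIFF(x / scale, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}
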