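#' Scene geometry for synthetic frame rendering
#'
#' @param width,height image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param cells tibble with one row per cell: `cell_id`, `cx`, `cy` (pixel
#'   coordinates of the nucleus center), `nucleus_radius_um`,
#'   `cyto_radius_um` (outer cytoplasm radius; must exceed the nucleus radius
#'   by at least the donut outer rim so donut pixels fall inside the
#'   cytoplasm).
#' @param background camera background level added to every pixel.
#' @param ampk_c0 raw-ratio offset used to encode the AMPK index (the raw
#'   cytoplasmic CFP/YFP ratio is rendered as `ampk_c0 - index`).
#' @return list of class `scene_geometry`.
#' @export
scene_geometry <- function(width = 96, height = 96, pixel_size = 0.5,
                           cells, background = 100, ampk_c0 = 3) {
  stopifnot(pixel_size > 0, nrow(cells) >= 0)
  need <- c("cell_id", "cx", "cy", "nucleus_radius_um", "cyto_radius_um")
  if (!all(need %in% names(cells))) {
    abort(paste("cells needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(cells) > 1) {
    for (i in seq_len(nrow(cells) - 1)) {
      for (j in (i + 1):nrow(cells)) {
        d <- sqrt((cells$cx[i] - cells$cx[j])^2 +
                    (cells$cy[i] - cells$cy[j])^2) * pixel_size
        if (d <= cells$nucleus_radius_um[i] + cells$nucleus_radius_um[j]) {
          abort("nuclei overlap in the scene geometry")
        }
      }
    }
  }
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 cells = as_tibble(cells), background = background,
                 ampk_c0 = ampk_c0),
            class = "scene_geometry")
}

#' Render synthetic microscopy frames from a trace set
#'
#' Draws each cell as a uniform nuclear disc surrounded by a uniform
#' cytoplasmic annulus and sets the channel intensities so that the index
#' formulas of [compute_index()] recover each cell's programmed trace value
#' exactly (before any added noise): nuclear YFP and RFP are fixed at 100,
#' nuclear T-Sapphire encodes the NADH index, cytoplasmic RFP the Akt index,
#' and cytoplasmic CFP encodes `ampk_c0 - AMPK` against cytoplasmic YFP 100.
#' Ground-truth nuclear label masks use the row order of `geometry$cells` as
#' stable label values.
#'
#' @param traces a `trace_tbl`; cell ids must match `geometry$cells$cell_id`.
#' @param geometry a [scene_geometry()].
#' @param noise_sd Gaussian camera-noise standard deviation (0 = noiseless).
#' @param seed seed for the noise draw.
#' @return list with `frames` (a [frame_set()], background included) and
#'   `masks` (integer label stack).
#' @export
render_synthetic_frames <- function(traces, geometry, noise_sd = 0, seed = 1) {
  stopifnot(inherits(geometry, "scene_geometry"))
  df <- as_tibble(traces)
  times <- sort(unique(df$time_min))
  nt <- length(times)
  h <- geometry$height
  w <- geometry$width
  reporters <- unique(df$reporter)
  channels_needed <- c("YFP",
                       if ("NADH" %in% reporters) "TSapphire",
                       if ("Akt" %in% reporters) "RFP",
                       if (any(c("AMPK", "AMPK_raw") %in% reporters)) "CFP")
  chans <- lapply(channels_needed, function(ch) array(0, dim = c(h, w, nt)))
  names(chans) <- channels_needed
  labels <- array(0L, dim = c(h, w, nt))

  xg <- matrix(rep(seq_len(w), each = h), nrow = h)
  yg <- matrix(rep(seq_len(h), times = w), nrow = h)
  cells <- geometry$cells
  val_of <- function(cid, rep_name, ti) {
    v <- df$value[df$cell_id == cid & df$reporter == rep_name &
                    df$time_min == times[ti]]
    if (length(v) == 0) NA_real_ else v[1]
  }
  nuc_masks <- cyt_masks <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d_px <- sqrt((xg - cells$cx[i])^2 + (yg - cells$cy[i])^2)
    nuc_masks[[i]] <- d_px * geometry$pixel_size <= cells$nucleus_radius_um[i]
    cyt_masks[[i]] <- d_px * geometry$pixel_size <= cells$cyto_radius_um[i] &
      !nuc_masks[[i]]
  }
  ampk_rep <- intersect(c("AMPK", "AMPK_raw"), reporters)[1]
  for (ti in seq_len(nt)) {
    for (i in seq_len(nrow(cells))) {
      nm <- nuc_masks[[i]]
      cm <- cyt_masks[[i]]
      lab_fr <- labels[, , ti]
      lab_fr[nm] <- i
      labels[, , ti] <- lab_fr
      alive <- FALSE
      put <- function(ch, mask, value) {
        img <- chans[[ch]][, , ti]
        img[mask] <- value
        chans[[ch]][, , ti] <<- img
      }
      if ("NADH" %in% reporters) {
        v <- val_of(cells$cell_id[i], "NADH", ti)
        if (!is.na(v)) {
          put("TSapphire", nm, 100 * v)
          alive <- TRUE
        }
      }
      if ("Akt" %in% reporters) {
        v <- val_of(cells$cell_id[i], "Akt", ti)
        if (!is.na(v)) {
          put("RFP", nm, 100)
          put("RFP", cm, 100 * v)
          alive <- TRUE
        }
      }
      if (!is.na(ampk_rep)) {
        v <- val_of(cells$cell_id[i], ampk_rep, ti)
        if (!is.na(v)) {
          put("CFP", cm, 100 * (geometry$ampk_c0 - v))
          alive <- TRUE
        }
      }
      if (alive) {
        put("YFP", nm, 100)
        put("YFP", cm, 100)
      }
    }
  }
  for (ch in names(chans)) chans[[ch]] <- chans[[ch]] + geometry$background
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    for (ch in names(chans)) {
      chans[[ch]] <- chans[[ch]] +
        array(rnorm(length(chans[[ch]]), 0, noise_sd), dim = dim(chans[[ch]]))
    }
  }
  bg <- stats::setNames(rep(geometry$background, length(chans)), names(chans))
  list(frames = frame_set(chans, geometry$pixel_size, background = bg,
                          times = times),
       masks = labels)
}

#' Write / read frame stacks as multipage TIFF
#'
#' Frames are stored as 16-bit multipage TIFF, one file per channel, with
#' intensities scaled by `scale` into the 16-bit range; label masks are
#' written unscaled as 16-bit integers.
#'
#' @param frames a [frame_set()].
#' @param dir output directory (created if needed).
#' @param scale intensity scale: stored value = `round(value / scale)`.
#' @return invisibly, the written file paths.
#' @export
write_frames_tiff <- function(frames, dir, scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(frames$channels)) {
    arr <- frames$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(t) {
      pmin(pmax(round(arr[, , t] / scale), 0), 65535) / 65535
    })
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_frames_tiff
#' @param path TIFF file path (one channel) or label-mask file.
#' @return `read_stack_tiff` returns a numeric `h x w x T` array of stored
#'   integer values (multiply by the original `scale` to recover
#'   intensities).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- round(pages[[t]] * 65535)
  arr
}

#' @rdname write_frames_tiff
#' @param masks integer label stack.
#' @export
write_masks_tiff <- function(masks, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(seq_len(dim(masks)[3]), function(t) masks[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
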