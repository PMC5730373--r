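#' Construct a frame set
#'
#' Container for multichannel time-lapse frames: a named list of
#' `height x width x T` arrays sharing dimensions, the pixel size, per-channel
#' background levels and the acquisition times.
#'
#' @param channels named list of 3-d numeric arrays (`h x w x T`).
#' @param pixel_size pixel size in micrometres per pixel.
#' @param background named numeric of per-channel background levels, a single
#'   scalar recycled across channels, or a logical matrix marking cell-free
#'   background pixels.
#' @param times acquisition times in minutes (length `T`).
#' @return object of class `frame_set`.
#' @export
frame_set <- function(channels, pixel_size, background = 0, times = NULL) {
  stopifnot(is.list(channels), length(channels) > 0, pixel_size > 0)
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort("all channels must share dimensions")
  }
  nt <- dims[[1]][3]
  if (is.null(times)) times <- seq_len(nt) - 1
  if (length(times) != nt) abort("times must match the frame count")
  structure(list(channels = channels, pixel_size = pixel_size,
                 background = background, times = times),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<frame_set>", paste(names(x$channels), collapse = ", "), "|",
      d[1], "x", d[2], "px x", d[3], "frames @", x$pixel_size, "um/px\n")
  invisible(x)
}

#' Subtract the background from every channel
#'
#' Subtracts a per-channel scalar background (or the per-frame mean over a
#' cell-free background region) from every pixel, clipping negative values
#' at zero.
#'
#' @param frames a [frame_set()].
#' @param background overrides the background stored in `frames`: a named (or
#'   scalar) numeric, or a logical matrix of cell-free pixels.
#' @return a `frame_set` with background-subtracted channels and
#'   `background = 0`.
#' @export
subtract_background <- function(frames, background = NULL) {
  stopifnot(inherits(frames, "frame_set"))
  bg <- background %||% frames$background
  out <- frames
  for (ch in names(frames$channels)) {
    arr <- frames$channels[[ch]]
    if (is.matrix(bg) && is.logical(bg)) {
      if (!any(bg)) abort("background region is empty")
      for (t in seq_len(dim(arr)[3])) {
        b <- mean(arr[, , t][bg])
        arr[, , t] <- pmax(arr[, , t] - b, 0)
      }
    } else {
      b <- if (length(bg) == 1L) bg else bg[[ch]]
      if (is.null(b) || is.na(b)) abort(paste("no background level for", ch))
      arr <- pmax(arr - b, 0)
    }
    out$channels[[ch]] <- arr
  }
  out$background <- 0
  out
}

disc_brush <- function(r_px) EBImage::makeBrush(2L * r_px + 1L, shape = "disc")

#' Derive eroded-nuclear and cytoplasmic donut masks
#'
#' From a stack of nuclear label images, erodes each nucleus by `erode_um`
#' (at least one pixel) to exclude cytoplasmic pixels from the nuclear mean,
#' and builds an annular cytoplasmic "donut" per cell. By default the donut
#' runs from the original nuclear boundary dilated by `donut_inner_um` out to
#' `donut_outer_um`; with `inner = "eroded_perimeter"` the inner rim is the
#' perimeter of the eroded nucleus instead. Donut pixels never overlap any
#' nucleus, and pixels claimed by two cells' donuts are assigned to the cell
#' with the nearer original nucleus.
#'
#' @param labels integer label image stack (`h x w x T`, 0 = background) with
#'   labels stable over time, or a single label matrix.
#' @param pixel_size micrometres per pixel.
#' @param erode_um nuclear erosion depth (default 1).
#' @param donut_inner_um,donut_outer_um donut rim distances from the original
#'   nuclear boundary (defaults 2.5 and 3.5).
#' @param inner `"dilated"` (default) or `"eroded_perimeter"`.
#' @return object of class `mask_set`: list with `labels`, `eroded`, `donut`
#'   label stacks, `pixel_size`, and `dropped` (labels annihilated by
#'   erosion, excluded from means).
#' @export
derive_masks <- function(labels, pixel_size, erode_um = 1,
                         donut_inner_um = 2.5, donut_outer_um = 3.5,
                         inner = c("dilated", "eroded_perimeter")) {
  inner <- match.arg(inner)
  if (pixel_size <= 0) abort("pixel_size must be positive")
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  er_px <- max(1L, as.integer(round(erode_um / pixel_size)))
  in_px <- as.integer(round(donut_inner_um / pixel_size))
  out_px <- max(in_px + 1L, as.integer(round(donut_outer_um / pixel_size)))
  nt <- dim(labels)[3]
  eroded <- donut <- array(0L, dim = dim(labels))
  dropped <- integer(0)
  for (t in seq_len(nt)) {
    lab <- labels[, , t]
    ids <- sort(unique(lab[lab > 0]))
    er_fr <- don_fr <- matrix(0L, nrow(lab), ncol(lab))
    best <- matrix(Inf, nrow(lab), ncol(lab))
    for (id in ids) {
      m <- lab == id
      er <- EBImage::erode(m, disc_brush(er_px)) > 0
      if (!any(er)) {
        dropped <- union(dropped, id)
        next
      }
      er_fr[er] <- id
      ring_out <- EBImage::dilate(m, disc_brush(out_px)) > 0
      ring_in <- if (inner == "dilated") {
        EBImage::dilate(m, disc_brush(in_px)) > 0
      } else {
        er
      }
      ring <- ring_out & !ring_in & lab == 0
      if (!any(ring)) next
      d <- EBImage::distmap(matrix(as.numeric(!m), nrow(m)))
      claim <- ring & d < best
      don_fr[claim] <- id
      best[claim] <- d[claim]
    }
    eroded[, , t] <- er_fr
    donut[, , t] <- don_fr
  }
  structure(list(labels = labels, eroded = eroded, donut = donut,
                 pixel_size = pixel_size, dropped = dropped),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  ids <- unique(x$labels[x$labels > 0])
  cat("<mask_set>", length(ids), "cells,", dim(x$labels)[3], "frames\n")
  invisible(x)
}

#' Per-cell nuclear and cytoplasmic channel means
#'
#' Mean pixel value of every (background-subtracted) channel within each
#' cell's eroded-nuclear mask and donut mask, per frame. Regions with zero
#' pixels yield missing values.
#'
#' @param frames a background-subtracted [frame_set()].
#' @param masks a `mask_set` from [derive_masks()].
#' @return tibble: `cell`, `frame`, `time_min`, `channel`, `nuclear_mean`,
#'   `cyto_mean`.
#' @export
extract_channel_means <- function(frames, masks) {
  stopifnot(inherits(frames, "frame_set"), inherits(masks, "mask_set"))
  nt <- dim(masks$labels)[3]
  rows <- list()
  for (t in seq_len(nt)) {
    er <- masks$eroded[, , t]
    don <- masks$donut[, , t]
    ids <- setdiff(sort(unique(masks$labels[, , t])), c(0L, masks$dropped))
    for (id in ids) {
      nuc_idx <- er == id
      don_idx <- don == id
      for (ch in names(frames$channels)) {
        img <- frames$channels[[ch]][, , t]
        rows[[length(rows) + 1L]] <- tibble(
          cell = id, frame = t, time_min = frames$times[t], channel = ch,
          nuclear_mean = if (any(nuc_idx)) mean(img[nuc_idx]) else NA_real_,
          cyto_mean = if (any(don_idx)) mean(img[don_idx]) else NA_real_)
      }
    }
  }
  bind_rows(rows)
}

#' Compute a reporter index from channel means
#'
#' Ratiometric reporter indices: `NADH` = nuclear T-Sapphire / nuclear YFP
#' (Peredox); `Akt` = cytoplasmic RFP / nuclear RFP (kinase translocation
#' reporter); `AMPK_raw` = cytoplasmic CFP / cytoplasmic YFP (FRET reporter,
#' still to be inverted and offset by [normalize_ampk_offset()]). Ratios with
#' a non-positive denominator are missing.
#'
#' @param means tibble from [extract_channel_means()].
#' @param reporter one of `"NADH"`, `"Akt"`, `"AMPK_raw"`.
#' @return tibble: `cell`, `frame`, `time_min`, `value`.
#' @export
compute_index <- function(means, reporter = c("NADH", "Akt", "AMPK_raw")) {
  reporter <- match.arg(reporter)
  need <- switch(reporter,
                 NADH = c("TSapphire", "YFP"),
                 Akt = c("RFP", "RFP"),
                 AMPK_raw = c("CFP", "YFP"))
  have <- unique(means$channel)
  if (!all(unique(need) %in% have)) {
    abort(paste0(reporter, " index needs channel(s): ",
                 paste(setdiff(unique(need), have), collapse = ", ")))
  }
  wide_col <- function(ch, col) {
    d <- means[means$channel == ch, c("cell", "frame", "time_min", col)]
    names(d)[4] <- "v"
    d
  }
  ratio_of <- function(num, den) {
    j <- left_join(num, den, by = c("cell", "frame", "time_min"),
                   suffix = c("_num", "_den"))
    val <- ifelse(!is.na(j$v_den) & j$v_den > 0, j$v_num / j$v_den, NA_real_)
    tibble(cell = j$cell, frame = j$frame, time_min = j$time_min, value = val)
  }
  switch(reporter,
    NADH = ratio_of(wide_col("TSapphire", "nuclear_mean"),
                    wide_col("YFP", "nuclear_mean")),
    Akt = ratio_of(wide_col("RFP", "cyto_mean"),
                   wide_col("RFP", "nuclear_mean")),
    AMPK_raw = ratio_of(wide_col("CFP", "cyto_mean"),
                        wide_col("YFP", "cyto_mean")))
}

#' Invert and offset-normalize the raw AMPK ratio
#'
#' The cytoplasmic CFP/YFP FRET ratio falls as AMPK activity rises, so the
#' raw ratio is inverted (`index = c - raw`) with the offset `c` chosen per
#' experiment (condition x replicate group) so that the lowest resulting
#' index is approximately zero. The offset is a high quantile of the raw
#' ratio, evaluated with the inverse-ECDF convention so small experiments use
#' the literal extreme while large ones are robust to stray values; offsets
#' are recorded in the `ampk_offsets` attribute.
#'
#' @param traces a `trace_tbl` whose `AMPK_raw` rows hold the raw ratio (rows
#'   for other reporters pass through untouched).
#' @param percentile tail mass trimmed from the offset (default 0.01).
#' @return the trace table with `AMPK_raw` rows replaced by normalized
#'   `AMPK` rows.
#' @export
normalize_ampk_offset <- function(traces, percentile = 0.01) {
  df <- as_tibble(traces)
  raw <- df$reporter == "AMPK_raw"
  if (!any(raw)) abort("no AMPK_raw rows to normalize")
  grp <- paste(df$condition, df$replicate, sep = "\r")
  offsets <- list()
  for (g in unique(grp[raw])) {
    sel <- raw & grp == g
    v <- df$value[sel]
    if (all(is.na(v))) abort("empty experiment group in AMPK normalization")
    c_off <- unname(quantile(v, 1 - percentile, type = 1, na.rm = TRUE))
    df$value[sel] <- c_off - df$value[sel]
    offsets[[g]] <- c_off
  }
  df$reporter[raw] <- "AMPK"
  out <- new_trace_tbl(df, spec = attr(traces, "spec"),
                       provenance = attr(traces, "provenance"))
  attr(out, "ampk_offsets") <- unlist(offsets)
  out
}

#' Full index-extraction pipeline for a frame set
#'
#' Background subtraction, mask derivation, channel means and index
#' computation for the requested reporters, returned as a long trace table.
#'
#' @param frames a [frame_set()].
#' @param labels nuclear label stack (or a `mask_set`, reused as is).
#' @param reporters reporters to extract (subset of `NADH`, `Akt`,
#'   `AMPK_raw`).
#' @param condition,replicate,treatment_time metadata stamped on the output.
#' @param ... passed to [derive_masks()].
#' @return a `trace_tbl` (AMPK remains `AMPK_raw`; run
#'   [normalize_ampk_offset()] afterwards).
#' @export
extract_indices <- function(frames, labels, reporters = c("AMPK_raw"),
                            condition = "unknown", replicate = "R1",
                            treatment_time = NA_real_, ...) {
  fs <- subtract_background(frames)
  masks <- if (inherits(labels, "mask_set")) {
    labels
  } else {
    derive_masks(labels, frames$pixel_size, ...)
  }
  means <- extract_channel_means(fs, masks)
  rows <- lapply(reporters, function(rep) {
    idx <- compute_index(means, rep)
    tibble(cell_id = sprintf("cell_%04d", idx$cell), time_min = idx$time_min,
           reporter = rep, value = idx$value, condition = condition,
           replicate = replicate, treatment_time_min = treatment_time)
  })
  new_trace_tbl(bind_rows(rows))
}
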