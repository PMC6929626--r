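#' 2D section image containers
#'
#' `autorad_image` holds a phosphor-screen autoradiography scan (non-negative
#' intensities, default 50 um pixels); `elemental_map` holds one isotope
#' channel of a laser-ablation ICP-MS image (default 60 um spot size).
#'
#' @param intensity Numeric matrix.
#' @param pixel_size_um Pixel size in micrometres.
#' @param isotope One of `"44Ca"`, `"65Cu"`, `"64Zn"`, `"55Mn"`, `"13C"`.
#' @return Classed list with `intensity`, `pixel_size_um` (and `isotope`).
#' @export
autorad_image <- function(intensity, pixel_size_um = 50) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0, na.rm = TRUE))
    stop("autoradiography intensities must be non-negative")
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um),
            class = "autorad_image")
}

#' @rdname autorad_image
#' @export
elemental_map <- function(intensity, isotope, pixel_size_um = 60) {
  isotope <- match.arg(isotope, isotope_names())
  structure(list(intensity = as.matrix(intensity), isotope = isotope,
                 pixel_size_um = pixel_size_um),
            class = "elemental_map")
}

#' @export
print.autorad_image <- function(x, ...) {
  cat(sprintf("<autorad_image> %d x %d px @ %g um\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um))
  invisible(x)
}

#' @export
print.elemental_map <- function(x, ...) {
  cat(sprintf("<elemental_map %s> %d x %d px @ %g um\n", x$isotope,
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um))
  invisible(x)
}

img_intensity <- function(x) {
  if (inherits(x, c("autorad_image", "elemental_map"))) x$intensity
  else as.matrix(x)
}

#' Detect islet spots in an autoradiography section
#'
#' Islets appear as bright single spots on the exocrine background.
#' Background level is the image median; spots are connected components
#' (8-connectivity) of pixels exceeding `background * threshold_k`;
#' components with equivalent-circle diameter below `min_diameter_um` are
#' discarded. The islet-to-exocrine ratio of each spot is its mean
#' intensity over the mean of non-spot tissue pixels (pixels above half the
#' median, i.e. excluding off-tissue background).
#'
#' @param img An [autorad_image()] or matrix.
#' @param min_diameter_um Minimum equivalent diameter to keep (um).
#' @param threshold_k Multiplicative threshold over the median background.
#' @param pixel_size_um Pixel size when `img` is a bare matrix.
#' @return data.frame of islet records: `id`, `centroid_row`,
#'   `centroid_col`, `area_px`, `equivalent_diameter_um`, `mean_signal`,
#'   `islet_to_exocrine_ratio`. Zero rows when nothing is detected (a
#'   constant image is not an error).
#' @export
detect_islets <- function(img, min_diameter_um = 100, threshold_k = 2,
                          pixel_size_um = NULL) {
  px <- if (!is.null(pixel_size_um)) pixel_size_um
        else if (inherits(img, "autorad_image")) img$pixel_size_um else 50
  m <- img_intensity(img)
  if (length(m) == 0L) stop("empty image")
  bg <- stats::median(m)
  empty <- data.frame(id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      equivalent_diameter_um = numeric(),
                      mean_signal = numeric(),
                      islet_to_exocrine_ratio = numeric())
  bw <- m > bg * threshold_k
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw)
  lab_v <- as.integer(lab)
  exo_mask <- !bw & m > 0.5 * bg
  exo_mean <- if (any(exo_mask)) mean(m[exo_mask]) else NA_real_
  idx <- which(lab_v > 0L)
  comp <- split(idx, lab_v[idx])
  rows <- lapply(seq_along(comp), function(i) {
    ii <- comp[[i]]
    area <- length(ii)
    diam_um <- 2 * sqrt(area / pi) * px
    rc <- arrayInd(ii, dim(m))
    data.frame(id = i,
               centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
               area_px = area, equivalent_diameter_um = diam_um,
               mean_signal = mean(m[ii]),
               islet_to_exocrine_ratio = mean(m[ii]) / exo_mean)
  })
  out <- do.call(rbind, rows)
  out <- out[out$equivalent_diameter_um >= min_diameter_um, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Islet-to-exocrine signal ratio
#'
#' @param img Section image (matrix, [autorad_image()] or
#'   [elemental_map()]).
#' @param islet_mask,exocrine_mask Non-empty logical matrices.
#' @return `mean(img[islet]) / mean(img[exocrine])`.
#' @export
islet_to_exocrine_ratio <- function(img, islet_mask, exocrine_mask) {
  m <- img_intensity(img)
  if (!any(islet_mask) || !any(exocrine_mask))
    stop("both masks must be non-empty")
  exo <- mean(m[exocrine_mask])
  if (!is.finite(exo) || exo == 0)
    stop("zero exocrine mean")
  mean(m[islet_mask]) / exo
}

#' Regress islet signal on islet diameter
#'
#' Ordinary least squares across detected islets of one section/animal,
#' assessing whether tracer uptake predicts islet size. Both orientations
#' are supported: by default the signal (ratio or mean intensity) is
#' regressed on equivalent diameter; `orientation = "diameter_on_signal"`
#' swaps predictor and response.
#'
#' @param records data.frame from [detect_islets()] (needs >= 3 rows with
#'   >= 2 distinct diameters).
#' @param response `"ratio"` (islet-to-exocrine ratio) or `"mean_signal"`.
#' @param orientation `"signal_on_diameter"` or `"diameter_on_signal"`.
#' @return Object of class `islet_regression`: `slope`, `intercept`,
#'   `r_squared`, `n`, the orientation, and the underlying `lm` fit.
#' @export
regress_signal_vs_diameter <- function(records,
                                       response = c("ratio", "mean_signal"),
                                       orientation = c("signal_on_diameter",
                                                       "diameter_on_signal")) {
  response <- match.arg(response)
  orientation <- match.arg(orientation)
  if (nrow(records) < 3L)
    stop("at least 3 islet records are required")
  sig <- if (response == "ratio") records$islet_to_exocrine_ratio
         else records$mean_signal
  d <- records$equivalent_diameter_um
  if (length(unique(d)) < 2L)
    stop("singular design: all islet diameters equal")
  df <- if (orientation == "signal_on_diameter")
    data.frame(y = sig, x = d) else data.frame(y = d, x = sig)
  fit <- stats::lm(y ~ x, data = df)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = rsq(fit),
                 n = nrow(records), response = response,
                 orientation = orientation, fit = fit),
            class = "islet_regression")
}

#' @export
print.islet_regression <- function(x, ...) {
  cat(sprintf("Islet regression (%s, %s): slope %.4g, intercept %.4g, R^2 = %.3f, n = %d\n",
              x$response, x$orientation, x$slope, x$intercept,
              x$r_squared, x$n))
  invisible(x)
}

#' Normalize a map to 8-bit levels
#'
#' `v -> floor(255 * (v - min) / (max - min))`; a constant map maps to all
#' zeros so that blank control channels do not break merging.
#'
#' @param map Matrix or [elemental_map()].
#' @return Integer matrix with values in 0..255.
#' @export
normalize_8bit <- function(map) {
  m <- img_intensity(map)
  if (any(!is.finite(m))) stop("map must be finite")
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(m), ncol(m)))
  out <- floor(255 * (m - rng[1]) / (rng[2] - rng[1]))
  matrix(as.integer(pmin(out, 255)), nrow(m))
}

#' Merge elemental maps into an additive RGB image
#'
#' 8-bit additive colour model: calcium-44 in the red channel, zinc-64 in
#' green, manganese-55 in blue, each independently normalized to 0..255.
#' Endocrine tissue (Ca+Zn high, Mn low) therefore appears yellow.
#'
#' @param ca,zn,mn [elemental_map()]s (or matrices) on identical grids.
#' @return Integer array `nrow x ncol x 3` with values in 0..255.
#' @export
merge_elements <- function(ca, zn, mn) {
  chans <- lapply(list(ca, zn, mn), img_intensity)
  d <- dim(chans[[1]])
  if (!all(vapply(chans, function(x) identical(dim(x), d), logical(1))))
    stop("grid mismatch: channels must share dimensions (resample first)")
  rgb <- array(0L, dim = c(d, 3L))
  rgb[, , 1] <- normalize_8bit(chans[[1]])
  rgb[, , 2] <- normalize_8bit(chans[[2]])
  rgb[, , 3] <- normalize_8bit(chans[[3]])
  rgb
}

#' Endocrine enrichment score of a section channel
#'
#' `mean(islet pixels) / mean(exocrine pixels)`; a score above 1 indicates
#' endocrine enrichment of the channel (the pattern expected for Ca and Zn
#' at all times and for retained Mn at late time points only).
#'
#' @param map Section image.
#' @param islet_mask,exocrine_mask Non-empty logical matrices.
#' @return Numeric score.
#' @export
islet_enrichment <- function(map, islet_mask, exocrine_mask) {
  islet_to_exocrine_ratio(map, islet_mask, exocrine_mask)
}

#' Write / read a 2D map as TIFF with a plain-text sidecar
#'
#' The TIFF stores the image as 32-bit float; the sidecar (`<path>.txt`)
#' records the pixel size and, for elemental maps, the isotope tag.
#'
#' @param map [autorad_image()], [elemental_map()] or matrix.
#' @param path Output `.tif` path.
#' @export
write_section <- function(map, path) {
  m <- img_intensity(map)
  scale <- max(abs(m), 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  meta <- c(sprintf("pixel_size_um: %g",
                    if (inherits(map, c("autorad_image", "elemental_map")))
                      map$pixel_size_um else NA),
            sprintf("intensity_scale: %.17g", scale))
  if (inherits(map, "elemental_map"))
    meta <- c(meta, sprintf("isotope: %s", map$isotope))
  writeLines(meta, paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- readLines(paste0(path, ".txt"))
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(ln)) trimws(sub(".*?:", "", ln[1])) else NA
  }
  scale <- as.numeric(get_field("intensity_scale"))
  px <- as.numeric(get_field("pixel_size_um"))
  iso <- get_field("isotope")
  m <- m * scale
  if (!is.na(iso)) elemental_map(m, iso, px) else autorad_image(m, px)
}
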