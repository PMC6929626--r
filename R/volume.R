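#' Volumetric image container
#'
#' A lightweight 3D scalar grid carrying voxel-size metadata and a units tag.
#' This is the common currency of the MR and PET stages: phantom simulators
#' produce `image_volume` objects, the fitting and quantification stages
#' consume and return them, and [write_volume()]/[read_volume()] move them to
#' and from NIfTI-1 files.
#'
#' @param data Numeric 3D array.
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param units Character units tag (e.g. `"a.u."`, `"kBq/mL"`, `"s^-1"`).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_mm, units = "a.u.") {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive triple")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$units))
  rng <- range(x$data, finite = TRUE)
  cat(sprintf("  range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Write / read a volume as NIfTI-1
#'
#' Volumes are stored uncompressed (`.nii`) with the voxel size in the header
#' `pixdim` field, so that repeated runs of a deterministic pipeline produce
#' bit-identical files.
#'
#' @param vol An [image_volume()] (or bare 3D array for `write_volume`).
#' @param path Output/input file path (`.nii`).
#' @param voxel_size_mm Voxel size, used only when `vol` is a bare array.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [image_volume()].
#' @export
write_volume <- function(vol, path, voxel_size_mm = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data
    vs <- vol$voxel_size_mm
  } else {
    arr <- vol
    vs <- if (is.null(voxel_size_mm)) c(1, 1, 1) else voxel_size_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), vs)
}

# Pull the numeric array out of an image_volume or pass an array through.
vol_data <- function(x) {
  if (inherits(x, "image_volume")) x$data else x
}

vol_voxel <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) x$voxel_size_mm else default
}

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded simulators do not perturb the session stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Coefficient of determination without summary.lm (which warns on the
# exact linear series used for calibration checks).
rsq <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / tss
}

# Derive a deterministic stage-specific sub-seed (< 2^31) from a base seed
# and a string key, so each simulated modality draws an independent stream.
sub_seed <- function(seed, key) {
  v <- utf8ToInt(key)
  h <- sum(v * seq_along(v)) %% 100000L
  (abs(as.integer(seed)) + h * 7919L) %% .Machine$integer.max
}
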