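#' Resample a volume onto a reference grid
#'
#' Trilinear interpolation in world (mm) coordinates under a rigid or affine
#' transform mapping source world coordinates to reference world
#' coordinates. World coordinates are voxel centres, `(index - 0.5) * voxel`.
#' Reference voxels that map outside the source volume are set to `NA` and
#' flagged in the returned validity mask.
#'
#' @param volume Source [image_volume()].
#' @param transform 4x4 affine matrix (source world -> reference world, mm).
#'   Default identity.
#' @param reference Reference grid: an [image_volume()], a `label_volume`,
#'   or a list with `grid_shape` and `voxel_size_mm`.
#' @return An [image_volume()] on the reference grid with attribute
#'   `validity` (logical array).
#' @export
resample_to_reference <- function(volume, transform = diag(4),
                                  reference = volume) {
  transform <- as.matrix(transform)
  if (!identical(dim(transform), c(4L, 4L)))
    stop("transform must be a 4x4 matrix")
  if (abs(det(transform)) < .Machine$double.eps)
    stop("singular transform")
  src <- vol_data(volume)
  vs_src <- vol_voxel(volume)
  if (inherits(reference, "label_volume")) {
    d_ref <- dim(reference$labels); vs_ref <- reference$voxel_size_mm
  } else if (inherits(reference, "image_volume")) {
    d_ref <- dim(reference$data); vs_ref <- reference$voxel_size_mm
  } else {
    d_ref <- reference$grid_shape; vs_ref <- reference$voxel_size_mm
  }
  d_src <- dim(src)

  idx <- arrayInd(seq_len(prod(d_ref)), d_ref)
  w_ref <- sweep(idx - 0.5, 2, vs_ref, "*")
  inv <- solve(transform)
  w_src <- cbind(w_ref, 1) %*% t(inv)
  cvox <- sweep(w_src[, 1:3, drop = FALSE], 2, vs_src, "/") + 0.5

  eps <- 1e-9
  valid <- cvox[, 1] >= 1 - eps & cvox[, 1] <= d_src[1] + eps &
    cvox[, 2] >= 1 - eps & cvox[, 2] <= d_src[2] + eps &
    cvox[, 3] >= 1 - eps & cvox[, 3] <= d_src[3] + eps
  out <- rep(NA_real_, prod(d_ref))
  if (any(valid)) {
    cv <- cvox[valid, , drop = FALSE]
    cv <- pmin(pmax(cv, 1), matrix(d_src, nrow(cv), 3, byrow = TRUE))
    i0 <- pmin(floor(cv), matrix(pmax(d_src - 1L, 1L), nrow(cv), 3,
                                 byrow = TRUE))
    fr <- cv - i0
    i1 <- pmin(i0 + 1, matrix(d_src, nrow(cv), 3, byrow = TRUE))
    lin <- function(i, j, k)
      src[cbind(i, j, k)]
    v <- lin(i0[, 1], i0[, 2], i0[, 3]) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
      lin(i1[, 1], i0[, 2], i0[, 3]) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
      lin(i0[, 1], i1[, 2], i0[, 3]) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
      lin(i1[, 1], i1[, 2], i0[, 3]) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
      lin(i0[, 1], i0[, 2], i1[, 3]) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
      lin(i1[, 1], i0[, 2], i1[, 3]) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
      lin(i0[, 1], i1[, 2], i1[, 3]) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
      lin(i1[, 1], i1[, 2], i1[, 3]) * fr[, 1] * fr[, 2] * fr[, 3]
    out[valid] <- v
  }
  res <- image_volume(array(out, d_ref), vs_ref,
                      units = if (inherits(volume, "image_volume"))
                        volume$units else "a.u.")
  attr(res, "validity") <- array(valid, d_ref)
  res
}

#' Block-downsample VOI voxels
#'
#' Reduces co-registration mismatch by averaging non-overlapping blocks of
#' `factors` voxels per dimension (each factor in 1..8; factor 1 is a
#' pass-through). Blocks are anchored at the corner of the VOI bounding box
#' for reproducibility. The value of a block is the mean of its in-mask
#' voxels; blocks whose in-mask fraction falls below `min_fraction` are
#' dropped.
#'
#' @param volumes A single volume/array or a named list of them (all on the
#'   mask's grid); each becomes a column in the output.
#' @param mask Logical 3D array (the VOI).
#' @param factors Integer triple of block edge lengths (1 to 8); a scalar is
#'   recycled.
#' @param min_fraction Minimum in-mask voxel fraction to keep a block.
#' @return data.frame with one row per retained block: block indices
#'   `bi, bj, bk`, per-volume mean columns, `n_voxels` and `fraction`.
#' @export
downsample_blocks <- function(volumes, mask, factors = c(2, 2, 2),
                              min_fraction = 0.5) {
  factors <- as.integer(round(factors))
  if (length(factors) == 1L) factors <- rep(factors, 3L)
  if (length(factors) != 3L || any(factors < 1L) || any(factors > 8L))
    stop("downsampling factors must lie between 1 and 8 per dimension")
  if (!is.list(volumes) || inherits(volumes, "image_volume"))
    volumes <- list(value = volumes)
  arrs <- lapply(volumes, vol_data)
  if (is.null(names(arrs)))
    names(arrs) <- paste0("v", seq_along(arrs))
  if (!any(mask)) stop("empty VOI mask")
  idx <- which(mask, arr.ind = TRUE)
  corner <- apply(idx, 2, min)
  block <- sweep(idx, 2, corner, "-")
  block <- sweep(block, 2, factors, "%/%")
  key <- paste(block[, 1], block[, 2], block[, 3], sep = "_")
  split_idx <- split(seq_len(nrow(idx)), key)
  flat <- (idx[, 3] - 1) * dim(mask)[1] * dim(mask)[2] +
    (idx[, 2] - 1) * dim(mask)[1] + idx[, 1]
  n_block <- prod(factors)
  rows <- lapply(split_idx, function(ii) {
    frac <- length(ii) / n_block
    means <- vapply(arrs, function(a) mean(a[flat[ii]]), numeric(1))
    c(bi = block[ii[1], 1], bj = block[ii[1], 2], bk = block[ii[1], 3],
      means, n_voxels = length(ii), fraction = frac)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out[out$fraction >= min_fraction, , drop = FALSE]
}

#' Pearson correlation of PET and MR quantities
#'
#' Correlates paired PET (%ID/mL) and MR (R1) values, region means or
#' voxel/block values, after an optional log10 transform. Pairs where
#' either member is non-positive under log10 are excluded pairwise and
#' counted. Two-sided p from the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param pet,mr Paired numeric vectors.
#' @param level `"voxelwise"` or `"region_mean"` (metadata tag).
#' @param transform `"log10"` or `"none"`.
#' @return Object of class `correlation_result`: `r`, `p`, `n`, `df`,
#'   `statistic`, `level`, `transform`, `n_excluded`.
#' @export
correlate_pet_mr <- function(pet, mr, level = c("voxelwise", "region_mean"),
                             transform = c("log10", "none")) {
  level <- match.arg(level)
  transform <- match.arg(transform)
  if (length(pet) != length(mr))
    stop("pet and mr vectors must be paired")
  keep <- is.finite(pet) & is.finite(mr)
  if (transform == "log10") keep <- keep & pet > 0 & mr > 0
  n_excluded <- sum(!keep)
  x <- pet[keep]; y <- mr[keep]
  if (transform == "log10") { x <- log10(x); y <- log10(y) }
  if (length(x) < 3L)
    stop("fewer than 3 retained pairs after transform filtering")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(x), df = unname(ct$parameter),
                 statistic = unname(ct$statistic),
                 level = level, transform = transform,
                 n_excluded = n_excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation (%s, transform %s): r = %.3f, t(%d) = %.3f, p = %.4g, n = %d (%d pairs excluded)\n",
              x$level, x$transform, x$r, x$df, x$statistic, x$p, x$n,
              x$n_excluded))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Two-sample t test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), two-sided.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values; at
#'   least one group must have positive variance.
#' @return Object of class `test_result`: `statistic`, `df`, `p`, `test`,
#'   `n`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 test = "Welch two-sample t",
                 n = c(length(group_a), length(group_b))),
            class = "test_result")
}

#' Wilcoxon rank sum test
#'
#' Midrank ties; exact two-sided p when the combined sample size is at most
#' 10 and there are no ties, otherwise the normal approximation with
#' continuity correction. Degenerate all-identical data returns p = 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return Object of class `test_result` (no `df` for the rank-sum test).
#' @export
rank_sum <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("each group must be non-empty")
  combined <- c(group_a, group_b)
  if (length(unique(combined)) == 1L) {
    return(structure(list(statistic = length(group_a) * length(group_b) / 2,
                          df = NULL, p = 1, test = "Wilcoxon rank sum",
                          n = c(length(group_a), length(group_b))),
                     class = "test_result"))
  }
  has_ties <- anyDuplicated(combined) > 0
  use_exact <- (length(combined) <= 10L) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = use_exact,
                                            correct = TRUE))
  structure(list(statistic = unname(wt$statistic), df = NULL,
                 p = wt$p.value, test = "Wilcoxon rank sum",
                 n = c(length(group_a), length(group_b))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (is.null(x$df))
    cat(sprintf("%s: W = %.4g, p = %.4g (n = %d, %d)\n", x$test,
                x$statistic, x$p, x$n[1], x$n[2]))
  else
    cat(sprintf("%s: t(%.2f) = %.4g, p = %.4g (n = %d, %d)\n", x$test,
                x$df, x$statistic, x$p, x$n[1], x$n[2]))
  invisible(x)
}

#' Read / write a 4x4 world-coordinate transform as text
#'
#' Row-major whitespace-separated values, world (mm) coordinates.
#'
#' @param transform 4x4 matrix.
#' @param path File path.
#' @export
write_transform <- function(transform, path) {
  utils::write.table(format(transform, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("expected a 4x4 transform")
  m
}
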