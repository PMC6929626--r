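#' Spoiled gradient-echo acquisition parameters
#'
#' @param tr_ms Repetition time, ms (default 10 as in the protocol this
#'   pipeline targets).
#' @param te_ms Echo time, ms (not used by the signal model: with TE much
#'   shorter than tissue T2*, the TE decay is absorbed into the effective
#'   magnetization scale).
#' @param flip_deg 2 or 3 distinct flip angles in (0, 90] degrees. The two
#'   standard protocols are `c(4, 22)` and `c(4, 14, 27)`.
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr_ms = 10, te_ms = 1.9, flip_deg = c(4, 22)) {
  if (tr_ms <= 0) stop("tr_ms must be positive")
  flip_deg <- as.numeric(flip_deg)
  if (length(flip_deg) < 2L)
    stop("at least 2 flip angles are required")
  if (anyDuplicated(flip_deg))
    stop("flip angles must be distinct")
  if (any(flip_deg <= 0 | flip_deg > 90))
    stop("flip angles must lie in (0, 90] degrees")
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg),
            class = "acquisition_params")
}

#' Steady-state spoiled-GRE signal
#'
#' `S = m0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))` with
#' `E1 = exp(-TR/T1)`, assuming ideal spoiling; TE relaxation is folded
#' into `m0`.
#'
#' @param t1_s T1 in seconds (scalar or array), must be positive.
#' @param m0 Equilibrium magnetization scale (>= 0).
#' @param acq An [acquisition_params()] (supplies TR).
#' @param flip_deg Flip angle in degrees.
#' @return Signal, same shape as `t1_s`.
#' @export
spgr_signal <- function(t1_s, m0, acq, flip_deg) {
  if (any(t1_s <= 0, na.rm = TRUE)) stop("t1_s must be positive")
  if (any(m0 < 0)) stop("m0 must be non-negative")
  a <- flip_deg * pi / 180
  e1 <- exp(-(acq$tr_ms / 1000) / t1_s)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Profiled residual sum of squares of the VFA model at candidate E1:
# m0 is profiled out in closed form. `S` is an n x k signal matrix.
# Returns list(rss, m0).
vfa_profile_rss <- function(S, e1, sin_a, cos_a) {
  sf <- numeric(nrow(S)); ff <- numeric(nrow(S)); ss <- numeric(nrow(S))
  for (k in seq_along(sin_a)) {
    f <- sin_a[k] * (1 - e1) / (1 - e1 * cos_a[k])
    sf <- sf + S[, k] * f
    ff <- ff + f * f
    ss <- ss + S[, k]^2
  }
  m0 <- ifelse(ff > 0, sf / ff, 0)
  list(rss = pmax(ss - m0^2 * ff, 0), m0 = m0)
}

#' Fit T1 from variable-flip-angle stacks
#'
#' With two flip angles the linearized DESPOT1 relation is exactly
#' determined: plotting `S/sin(a)` against `S/tan(a)` gives a line of slope
#' `E1 = exp(-TR/T1)`. With three angles the slope is first estimated by
#' least squares on the linearized form and then polished by a profiled
#' 1-D golden-section minimization of the nonlinear residual in `E1` (the
#' magnetization scale is profiled out in closed form). Voxels with
#' non-physical `E1` (<= 0 or >= 1) or all-zero signal are flagged invalid,
#' never silently defaulted.
#'
#' @param stacks Named list of per-angle volumes ([image_volume()]s or 3D
#'   arrays), in the same order as `acq$flip_deg`.
#' @param acq An [acquisition_params()].
#' @return Object of class `t1_map`: fields `t1_s`, `m0`, `validity`,
#'   `fit_residual` (per-voxel residual sum of squares), `acq`,
#'   `voxel_size_mm`, `n_invalid`.
#' @export
fit_t1_vfa <- function(stacks, acq) {
  if (!inherits(acq, "acquisition_params"))
    acq <- do.call(acquisition_params, acq)
  k <- length(acq$flip_deg)
  if (length(stacks) != k)
    stop("number of stacks must match the number of flip angles")
  arrs <- lapply(stacks, vol_data)
  dims <- lapply(arrs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("shape error: per-angle volumes are on mismatched grids")
  vs <- vol_voxel(stacks[[1]])
  d <- dims[[1]]
  n <- prod(d)
  S <- vapply(arrs, as.numeric, numeric(n))
  a <- acq$flip_deg * pi / 180
  sin_a <- sin(a); cos_a <- cos(a); tan_a <- tan(a)
  tr_s <- acq$tr_ms / 1000

  Y <- sweep(S, 2, sin_a, "/")
  X <- sweep(S, 2, tan_a, "/")
  if (k == 2L) {
    dx <- X[, 2] - X[, 1]
    e1 <- ifelse(dx != 0, (Y[, 2] - Y[, 1]) / dx, NA_real_)
  } else {
    xbar <- rowMeans(X); ybar <- rowMeans(Y)
    sxx <- rowSums((X - xbar)^2)
    sxy <- rowSums((X - xbar) * (Y - ybar))
    e1 <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  }
  all_zero <- rowSums(abs(S)) == 0
  valid <- is.finite(e1) & e1 > 0 & e1 < 1 & !all_zero

  if (k > 2L && any(valid)) {
    # golden-section polish of the profiled nonlinear residual in E1
    eps <- 1e-9
    lo <- pmax(e1[valid] - 0.2, eps)
    hi <- pmin(e1[valid] + 0.2, 1 - eps)
    Sv <- S[valid, , drop = FALSE]
    gr <- (sqrt(5) - 1) / 2
    for (it in seq_len(60L)) {
      c1 <- hi - gr * (hi - lo)
      c2 <- lo + gr * (hi - lo)
      f1 <- vfa_profile_rss(Sv, c1, sin_a, cos_a)$rss
      f2 <- vfa_profile_rss(Sv, c2, sin_a, cos_a)$rss
      take1 <- f1 <= f2
      hi <- ifelse(take1, c2, hi)
      lo <- ifelse(take1, lo, c1)
    }
    e1[valid] <- (lo + hi) / 2
  }

  t1 <- rep(NA_real_, n)
  t1[valid] <- -tr_s / log(e1[valid])
  valid <- valid & !is.na(t1) & is.finite(t1) & t1 > 0
  t1[!valid] <- NA_real_
  pr <- vfa_profile_rss(S, ifelse(is.finite(e1), pmin(pmax(e1, 1e-12),
                                                      1 - 1e-12), 0.5),
                        sin_a, cos_a)
  m0 <- pr$m0
  m0[!valid] <- NA_real_
  rss <- pr$rss
  rss[!valid] <- NA_real_

  structure(list(t1_s = array(t1, d),
                 m0 = array(m0, d),
                 validity = array(valid, d),
                 fit_residual = array(rss, d),
                 acq = acq, voxel_size_mm = vs,
                 n_invalid = sum(!valid)),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  cat(sprintf("<t1_map> %s voxels, %d invalid\n",
              paste(dim(x$t1_s), collapse = " x "), x$n_invalid))
  if (any(x$validity))
    cat(sprintf("  T1 (valid): median %.3f s, range [%.3f, %.3f] s\n",
                stats::median(x$t1_s[x$validity]),
                min(x$t1_s[x$validity]), max(x$t1_s[x$validity])))
  invisible(x)
}

#' @export
summary.t1_map <- function(object, ...) {
  v <- object$t1_s[object$validity]
  out <- list(n_voxels = length(object$t1_s),
              n_valid = sum(object$validity),
              n_invalid = object$n_invalid,
              t1_quartiles_s = if (length(v)) stats::quantile(v) else NULL,
              flip_deg = object$acq$flip_deg, tr_ms = object$acq$tr_ms)
  class(out) <- "summary.t1_map"
  out
}

#' @export
print.summary.t1_map <- function(x, ...) {
  cat(sprintf("VFA T1 fit (TR %.3g ms, angles %s)\n", x$tr_ms,
              paste0(x$flip_deg, "°", collapse = ", ")))
  cat(sprintf("  %d voxels, %d valid, %d invalid\n",
              x$n_voxels, x$n_valid, x$n_invalid))
  if (!is.null(x$t1_quartiles_s)) {
    cat("  T1 quartiles (s):\n")
    print(round(x$t1_quartiles_s, 4))
  }
  invisible(x)
}

#' @export
plot.t1_map <- function(x, z = ceiling(dim(x$t1_s)[3] / 2), ...) {
  sl <- x$t1_s[, , z]
  sl[!x$validity[, , z]] <- NA
  graphics::image(sl, asp = dim(sl)[2] / dim(sl)[1], axes = FALSE,
                  main = sprintf("T1 map, slice %d", z), ...)
  invisible(x)
}

#' Convert a T1 map to a filtered R1 map
#'
#' `R1 = 1/T1` on valid voxels; voxels with R1 outside the closed interval
#' `[r1_min, r1_max]` (defaults 0.4 and 10 s^-1, the physiological window
#' used for quantification) are flagged invalid and counted.
#'
#' @param t1map A `t1_map` from [fit_t1_vfa()].
#' @param r1_min,r1_max Filter bounds in s^-1 (closed interval).
#' @return Object of class `r1_map`: `r1_s_inv`, `validity`,
#'   `n_filtered` (valid-T1 voxels excluded by the filter), `voxel_size_mm`.
#' @export
t1_to_r1 <- function(t1map, r1_min = 0.4, r1_max = 10) {
  stopifnot(inherits(t1map, "t1_map"))
  r1 <- 1 / t1map$t1_s
  inside <- t1map$validity & is.finite(r1) & r1 >= r1_min & r1 <= r1_max
  n_filtered <- sum(t1map$validity & !inside)
  if (n_filtered > 0)
    message(sprintf("R1 filter [%g, %g] s^-1 excluded %d voxels",
                    r1_min, r1_max, n_filtered))
  r1[!inside] <- NA_real_
  structure(list(r1_s_inv = r1, validity = inside,
                 r1_range = c(r1_min, r1_max),
                 n_filtered = n_filtered,
                 voxel_size_mm = t1map$voxel_size_mm),
            class = "r1_map")
}

#' @export
print.r1_map <- function(x, ...) {
  cat(sprintf("<r1_map> %s voxels, %d valid (filter [%g, %g] s^-1, %d excluded)\n",
              paste(dim(x$r1_s_inv), collapse = " x "), sum(x$validity),
              x$r1_range[1], x$r1_range[2], x$n_filtered))
  invisible(x)
}

#' Calibrate the relaxivity of a contrast solution
#'
#' Ordinary least squares of measured relaxation rates on concentration for
#' a phantom dilution series: `R1 = intercept + r1 * [Mn]`. The intercept is
#' fitted, not forced through the diluent rate.
#'
#' @param mn_mM Concentrations (mM), or a 2-column data.frame/matrix
#'   `(mn_mM, r1_s_inv)`.
#' @param r1_s_inv Measured R1 (s^-1); omit when `mn_mM` is 2-column.
#' @return Object of class `relaxivity`: `r1_per_mM`, `intercept`,
#'   `r_squared`, plus the underlying `lm` fit.
#' @export
calibrate_relaxivity <- function(mn_mM, r1_s_inv = NULL) {
  if (is.null(r1_s_inv)) {
    ser <- as.data.frame(mn_mM)
    mn_mM <- ser[[1]]
    r1_s_inv <- ser[[2]]
  }
  if (length(mn_mM) != length(r1_s_inv))
    stop("concentration and rate vectors must have equal length")
  if (length(unique(mn_mM)) < 3L)
    stop("calibration requires at least 3 distinct concentrations")
  fit <- stats::lm(r1_s_inv ~ mn_mM)
  structure(list(r1_per_mM = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = rsq(fit),
                 fit = fit,
                 series = data.frame(mn_mM = mn_mM, r1_s_inv = r1_s_inv)),
            class = "relaxivity")
}

#' @export
print.relaxivity <- function(x, ...) {
  cat(sprintf("Relaxivity calibration: r1 = %.4g s^-1 mM^-1, intercept %.4g s^-1, R^2 = %.4f (n = %d)\n",
              x$r1_per_mM, x$intercept, x$r_squared, nrow(x$series)))
  invisible(x)
}

#' @export
coef.relaxivity <- function(object, ...) {
  c(intercept = object$intercept, r1_per_mM = object$r1_per_mM)
}

#' @export
predict.relaxivity <- function(object, mn_mM, ...) {
  object$intercept + object$r1_per_mM * mn_mM
}

#' @export
plot.relaxivity <- function(x, ...) {
  graphics::plot(x$series$mn_mM, x$series$r1_s_inv,
                 xlab = "[Mn] (mM)", ylab = expression(R[1] ~ (s^-1)),
                 main = "Relaxivity calibration", ...)
  graphics::abline(x$intercept, x$r1_per_mM, col = "red3")
  invisible(x)
}

#' Estimate manganese concentration from pre/post R1 maps
#'
#' Voxelwise mode: `[Mn] = (R1_post - R1_pre) / r1` on jointly valid voxels.
#' Region-mean mode (used for the 24 h index, where the pre and post VOIs
#' may be drawn independently on differently positioned anatomies):
#' `[Mn] = (mean(R1_post in VOI_post) - mean(R1_pre in VOI_pre)) / r1`.
#' Negative estimates are preserved, not clipped (they diagnose
#' registration or noise problems); their count is reported with a warning.
#'
#' @param r1_pre,r1_post `r1_map`s from [t1_to_r1()].
#' @param rel A `relaxivity` object or a positive numeric slope
#'   (s^-1 mM^-1).
#' @param mode `"voxelwise"` or `"region_mean_24h"`.
#' @param voi_pre,voi_post Logical masks for region-mean mode (default: all
#'   valid voxels of the respective map).
#' @param clip_negative If `TRUE`, negative voxelwise estimates are set to 0
#'   (explicit opt-in).
#' @return Voxelwise: object of class `mn_map` (`mn_mM`, `validity`,
#'   `n_negative`, `mode`). Region-mean: a single numeric index (mM) with
#'   attributes `n_pre`/`n_post`.
#' @export
estimate_mn <- function(r1_pre, r1_post, rel,
                        mode = c("voxelwise", "region_mean_24h"),
                        voi_pre = NULL, voi_post = NULL,
                        clip_negative = FALSE) {
  mode <- match.arg(mode)
  slope <- if (inherits(rel, "relaxivity")) rel$r1_per_mM else as.numeric(rel)
  if (!is.finite(slope) || slope <= 0)
    stop("calibration error: relaxivity slope must be positive")
  if (mode == "region_mean_24h") {
    if (is.null(voi_pre)) voi_pre <- r1_pre$validity
    if (is.null(voi_post)) voi_post <- r1_post$validity
    pre_vals <- r1_pre$r1_s_inv[voi_pre & r1_pre$validity]
    post_vals <- r1_post$r1_s_inv[voi_post & r1_post$validity]
    if (length(pre_vals) == 0L || length(post_vals) == 0L)
      stop("empty-result error: no valid voxels in one of the VOIs")
    idx <- (mean(post_vals) - mean(pre_vals)) / slope
    attr(idx, "n_pre") <- length(pre_vals)
    attr(idx, "n_post") <- length(post_vals)
    return(idx)
  }
  if (!identical(dim(r1_pre$r1_s_inv), dim(r1_post$r1_s_inv)))
    stop("shape error: pre and post R1 maps are on mismatched grids")
  joint <- r1_pre$validity & r1_post$validity
  if (!any(joint))
    stop("empty-result error: no jointly valid voxels")
  mn <- (r1_post$r1_s_inv - r1_pre$r1_s_inv) / slope
  mn[!joint] <- NA_real_
  n_neg <- sum(mn < 0, na.rm = TRUE)
  if (n_neg > 0 && !clip_negative)
    warning(sprintf("%d voxels with negative [Mn] estimates (preserved)",
                    n_neg))
  if (clip_negative) mn <- pmax(mn, 0)
  structure(list(mn_mM = mn, validity = joint, n_negative = n_neg,
                 mode = mode, voxel_size_mm = r1_pre$voxel_size_mm),
            class = "mn_map")
}

#' @export
print.mn_map <- function(x, ...) {
  v <- x$mn_mM[x$validity]
  cat(sprintf("<mn_map> %s voxels, %d valid, %d negative; median %.4g mM\n",
              paste(dim(x$mn_mM), collapse = " x "), sum(x$validity),
              x$n_negative, stats::median(v)))
  invisible(x)
}
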