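#' Physical half-life of copper-64 (hours)
#' @export
CU64_HALF_LIFE_H <- 12.7

#' Decay-correct measured activity back to injection time
#'
#' `corrected = measured * 2^(elapsed_h / half_life_h)`.
#'
#' @param activity_kbq_per_ml Measured activity (scalar, vector or array).
#' @param elapsed_h Hours between injection and the frame (>= 0).
#' @param half_life_h Isotope half-life in hours (default: copper-64).
#' @return Corrected activity, same shape as the input.
#' @export
decay_correct <- function(activity_kbq_per_ml, elapsed_h,
                          half_life_h = CU64_HALF_LIFE_H) {
  if (half_life_h <= 0) stop("half_life_h must be positive")
  if (any(elapsed_h < 0)) stop("elapsed_h must be non-negative")
  activity_kbq_per_ml * 2^(elapsed_h / half_life_h)
}

#' Percent injected dose per millilitre
#'
#' Converts a reconstructed PET activity volume (kBq/mL) into a
#' decay-corrected %ID/mL map:
#' `pid = 100 * decay_correct(activity, frame_time_h) / injected_dose_kBq`.
#'
#' @param activity_volume [image_volume()] or 3D array in kBq/mL.
#' @param injected_dose_kBq Injected activity (kBq), > 0.
#' @param frame_time_h Hours post injection of the (static) frame.
#' @param decay_to_injection If `FALSE`, no decay correction is applied and
#'   the map refers to frame time.
#' @param half_life_h Isotope half-life (hours).
#' @return Object of class `tracer_map`: `pid_per_ml` (array),
#'   `frame_time_h`, `injected_dose_kBq`, `decay_corrected`,
#'   `voxel_size_mm`.
#' @export
percent_id_per_ml <- function(activity_volume, injected_dose_kBq,
                              frame_time_h,
                              decay_to_injection = TRUE,
                              half_life_h = CU64_HALF_LIFE_H) {
  if (injected_dose_kBq <= 0)
    stop("injected_dose_kBq must be positive")
  act <- vol_data(activity_volume)
  if (decay_to_injection)
    act <- decay_correct(act, frame_time_h, half_life_h)
  pid <- 100 * act / injected_dose_kBq
  structure(list(pid_per_ml = pid,
                 frame_time_h = frame_time_h,
                 injected_dose_kBq = injected_dose_kBq,
                 decay_corrected = decay_to_injection,
                 voxel_size_mm = vol_voxel(activity_volume)),
            class = "tracer_map")
}

#' @export
print.tracer_map <- function(x, ...) {
  cat(sprintf("<tracer_map> %s voxels, frame %.3g h, dose %.4g kBq%s\n",
              paste(dim(x$pid_per_ml), collapse = " x "), x$frame_time_h,
              x$injected_dose_kBq,
              if (x$decay_corrected) ", decay-corrected to injection" else ""))
  cat(sprintf("  %%ID/mL median %.4g\n", stats::median(x$pid_per_ml)))
  invisible(x)
}
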