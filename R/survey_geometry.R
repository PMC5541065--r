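# Deterministic survey-planning arithmetic: how altitude, swath, speed and
# frame spacing translate into pixel sizes, areal coverage, data rate and
# transect data volume for a push-broom imager.

#' Define a survey plan
#'
#' @param altitude Imaging altitude above the seafloor, m.
#' @param swath Width of the imaged line of view, m (set by altitude and the
#'   front optics; supplied directly, not derived).
#' @param speed Swim speed, m/min.
#' @param frame_spacing Along-track distance between successive lines, m.
#' @param transect_length Transect length, m.
#' @param spatial_pixels Pixels per line (default 640).
#' @param bands Spectral bands per pixel (default 480).
#' @param bytes_per_sample Bytes per stored sample (default 2, a 16-bit ADC).
#' @return An object of class `survey_plan`.
#' @export
survey_plan <- function(altitude, swath, speed, frame_spacing,
                        transect_length, spatial_pixels = 640L,
                        bands = 480L, bytes_per_sample = 2L) {
  p <- list(altitude = altitude, swath = swath, speed = speed,
            frame_spacing = frame_spacing, transect_length = transect_length,
            spatial_pixels = as.integer(spatial_pixels),
            bands = as.integer(bands),
            bytes_per_sample = as.integer(bytes_per_sample))
  if (any(unlist(p) <= 0)) stop("all survey plan parameters must be positive")
  structure(p, class = "survey_plan")
}

#' Derived survey geometry and data-volume summary
#'
#' All quantities follow from the plan by elementary geometry:
#' lateral pixel = swath / spatial pixels; transverse pixel = frame spacing;
#' coverage = speed x swath; frame rate = (speed/60) / frame spacing;
#' data rate = frame rate x pixels x bands x bytes; duration =
#' length / (speed/60); volume = (length / frame spacing) x pixels x bands x
#' bytes. At the reference operating point (1 m altitude, 1.28 m swath,
#' 20 m/min, 2 cm spacing) this gives 0.2 x 2 cm pixels, ~10 MB/s, and
#' ~1.5 GB for a 50 m transect. GB are reported as 10^9 bytes.
#'
#' @param plan A [survey_plan].
#' @return Named list: `lateral_pixel_cm`, `transverse_pixel_cm`,
#'   `coverage_m2_per_min`, `frame_rate_hz`, `data_rate_bytes_per_s`,
#'   `duration_s`, `transect_volume_bytes`, `transect_volume_gb`.
#' @export
plan_summary <- function(plan) {
  stopifnot(inherits(plan, "survey_plan"))
  speed_ms <- plan$speed / 60
  frame_rate <- speed_ms / plan$frame_spacing
  bytes_per_frame <- plan$spatial_pixels * plan$bands * plan$bytes_per_sample
  volume <- (plan$transect_length / plan$frame_spacing) * bytes_per_frame
  list(
    lateral_pixel_cm = 100 * plan$swath / plan$spatial_pixels,
    transverse_pixel_cm = 100 * plan$frame_spacing,
    coverage_m2_per_min = plan$speed * plan$swath,
    frame_rate_hz = frame_rate,
    data_rate_bytes_per_s = frame_rate * bytes_per_frame,
    duration_s = plan$transect_length / speed_ms,
    transect_volume_bytes = volume,
    transect_volume_gb = volume / 1e9)
}

#' @export
print.survey_plan <- function(x, ...) {
  s <- plan_summary(x)
  cat(sprintf("<survey_plan> %gm altitude, %gm swath, %g m/min, %gm transect\n",
              x$altitude, x$swath, x$speed, x$transect_length))
  cat(sprintf("  pixels %.2g x %.2g cm | %.3g m2/min | %.3g MB/s | %.3g GB in %.0f s\n",
              s$lateral_pixel_cm, s$transverse_pixel_cm, s$coverage_m2_per_min,
              s$data_rate_bytes_per_s / 1e6, s$transect_volume_gb, s$duration_s))
  invisible(x)
}
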