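# Diver sensor tracks, seafloor topographic profiles and arc-chord rugosity.
#
# The instrument logs its own depth (pressure gauge, positive down) and its
# altitude above the seafloor (single-beam acoustic altimeter) at 1 Hz, plus
# optional PAR / O2 / pH. Bottom depth is their sum; along-track distance is
# assigned by a constant-swim-speed assumption — the dominant approximation,
# since the system carries no positioning beyond heading/acceleration.

#' Construct or read a sensor track
#'
#' @param timestamps Seconds, strictly increasing, nominally 1 Hz.
#' @param depth Instrument depth, m, positive down; `NA` for missing.
#' @param altitude Instrument-to-seafloor altitude, m, positive; `NA` for
#'   missing.
#' @param par,o2,ph Optional water-column series (PAR in umol photons
#'   m^-2 s^-1; O2 in mg/L or % sat; pH).
#' @return An object of class `sensor_track` (a data.frame with columns
#'   `t_s, depth_m, altitude_m` and any chemistry columns supplied).
#' @export
sensor_track <- function(timestamps, depth, altitude,
                         par = NULL, o2 = NULL, ph = NULL) {
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be >= 0 (positive down)")
  if (any(altitude <= 0, na.rm = TRUE))
    stop("altitude must be > 0 where present")
  df <- data.frame(t_s = as.numeric(timestamps), depth_m = as.numeric(depth),
                   altitude_m = as.numeric(altitude))
  if (!is.null(par)) df$par <- as.numeric(par)
  if (!is.null(o2)) df$o2 <- as.numeric(o2)
  if (!is.null(ph)) df$ph <- as.numeric(ph)
  class(df) <- c("sensor_track", "data.frame")
  df
}

#' @rdname sensor_track
#' @param path CSV with columns `t_s, depth_m, altitude_m` and optional
#'   `par, o2, ph`.
#' @export
read_sensor_track <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "depth_m", "altitude_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sensor CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  sensor_track(df$t_s, df$depth_m, df$altitude_m,
               par = df$par, o2 = df$o2, ph = df$ph)
}

#' @rdname sensor_track
#' @param track A `sensor_track`.
#' @export
write_sensor_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Fuse depth and altitude into a seafloor profile
#'
#' Bottom depth is `depth(t) + altitude(t)`; along-track distance maps time
#' linearly onto `[0, transect_length]` (constant swim speed). Missing
#' samples in gaps of at most `max_gap_s` seconds are linearly interpolated;
#' leading/trailing missing samples are dropped; longer interior gaps split
#' the profile into segments (rugosity is then reported per segment).
#'
#' @param track A [sensor_track].
#' @param transect_length Transect length in m.
#' @param max_gap_s Longest gap (s) bridged by interpolation (default 5).
#' @return A `topo_profile`: data.frame with columns `distance_m` (strictly
#'   increasing), `bottom_depth_m` (positive down) and `segment` (integer).
#' @export
fuse_bottom_profile <- function(track, transect_length, max_gap_s = 5) {
  if (transect_length <= 0) stop("transect_length must be > 0")
  if (any(diff(track$t_s) <= 0)) stop("timestamps must be strictly increasing")
  ok <- is.finite(track$depth_m) & is.finite(track$altitude_m)
  if (sum(ok) < 2L)
    stop("need at least 2 valid (depth, altitude) pairs, got ", sum(ok))
  # drop leading/trailing gaps
  keep <- seq(min(which(ok)), max(which(ok)))
  t <- track$t_s[keep]; dep <- track$depth_m[keep]; alt <- track$altitude_m[keep]
  ok <- ok[keep]
  # interior gaps: interpolate short ones, split on long ones
  fill <- function(x) stats::approx(t[ok], x[ok], xout = t)$y
  dep <- fill(dep); alt <- fill(alt)
  bottom <- dep + alt
  t0 <- t[1]; tN <- t[length(t)]
  dist <- transect_length * (t - t0) / (tN - t0)
  # a gap longer than max_gap_s between consecutive valid samples splits
  gap_after <- diff(t[ok])
  seg_of_valid <- cumsum(c(1, as.integer(gap_after > max_gap_s)))
  seg <- rep(NA_integer_, length(t))
  seg[ok] <- seg_of_valid
  # interpolated (short-gap) samples inherit the enclosing segment; samples
  # inside long gaps are dropped
  seg <- .fill_segment(seg, t, max_gap_s)
  keep2 <- !is.na(seg)
  prof <- data.frame(distance_m = dist[keep2], bottom_depth_m = bottom[keep2],
                     segment = seg[keep2])
  if (nrow(prof) < 2L) stop("profile degenerate after gap handling")
  class(prof) <- c("topo_profile", "data.frame")
  prof
}

.fill_segment <- function(seg, t, max_gap_s) {
  valid <- which(!is.na(seg))
  for (i in which(is.na(seg))) {
    prev <- valid[valid < i]; nxt <- valid[valid > i]
    if (length(prev) && length(nxt)) {
      p <- max(prev); n <- min(nxt)
      if (seg[p] == seg[n] && (t[n] - t[p]) <= max_gap_s) seg[i] <- seg[p]
    }
  }
  seg
}

#' Arc-chord rugosity of a topographic profile
#'
#' The ratio of contoured (along-profile) length to planar (chord) length:
#' `sum(sqrt(d_dist^2 + d_depth^2)) / (end - start)`. 1 for a flat bottom,
#' larger for structurally complex terrain. With `window = "whole"` one index
#' per profile segment is returned (and their chord-weighted combination when
#' there are several segments); a numeric window (m) gives a series over
#' non-overlapping windows, the last partial window dropped.
#'
#' @param profile A `topo_profile` from [fuse_bottom_profile()], or any
#'   data.frame with `distance_m` and `bottom_depth_m`.
#' @param window `"whole"` (default) or window length in m.
#' @return For `"whole"`: a scalar (attribute `per_segment` holds the
#'   per-segment values when the profile is split). Otherwise a data.frame
#'   with `start_m`, `end_m`, `rugosity`.
#' @export
rugosity <- function(profile, window = "whole") {
  d <- profile$distance_m; z <- profile$bottom_depth_m
  if (length(d) < 2L) stop("profile must have >= 2 points")
  if (any(diff(d) <= 0)) stop("profile distance must be strictly increasing")
  seg <- if (!is.null(profile$segment)) profile$segment else rep(1L, length(d))
  arc_chord <- function(dd, zz) {
    chord <- dd[length(dd)] - dd[1]
    if (chord <= 0) stop("zero planar span")
    sum(sqrt(diff(dd)^2 + diff(zz)^2)) / chord
  }
  if (identical(window, "whole")) {
    segs <- unique(seg)
    vals <- chords <- numeric(length(segs))
    for (i in seq_along(segs)) {
      sel <- seg == segs[i]
      if (sum(sel) < 2L) next
      vals[i] <- arc_chord(d[sel], z[sel])
      chords[i] <- max(d[sel]) - min(d[sel])
    }
    keep <- chords > 0
    out <- sum(vals[keep] * chords[keep]) / sum(chords[keep])
    if (sum(keep) > 1L) attr(out, "per_segment") <- vals[keep]
    return(out)
  }
  window <- as.numeric(window)
  span <- d[length(d)] - d[1]
  if (window > span) stop("window exceeds profile span")
  starts <- seq(d[1], d[1] + span - window, by = window)
  res <- data.frame(start_m = starts, end_m = starts + window,
                    rugosity = NA_real_)
  for (i in seq_along(starts)) {
    sel <- d >= starts[i] & d <= starts[i] + window
    if (sum(sel) >= 2L) res$rugosity[i] <- arc_chord(d[sel], z[sel])
  }
  res
}

#' Export a topographic profile and its rugosity
#'
#' Writes the profile as CSV and a JSON summary (span, depth range, arc-chord
#' rugosity).
#'
#' @param profile A `topo_profile`.
#' @param path Output stem: writes `<path>.csv` and `<path>.json`.
#' @return Invisibly, the JSON path.
#' @export
write_topo_summary <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), paste0(path, ".csv"),
                   row.names = FALSE)
  rug <- rugosity(profile)
  out <- list(
    n_points = nrow(profile),
    span_m = max(profile$distance_m) - min(profile$distance_m),
    depth_range_m = range(profile$bottom_depth_m),
    rugosity = as.numeric(rug))
  if (!is.null(attr(rug, "per_segment")))
    out$rugosity_per_segment <- attr(rug, "per_segment")
  jsonlite::write_json(out, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(path, ".json"))
}
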