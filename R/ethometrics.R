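# Behavioral readouts from zone-labeled trajectories: dwell tables, the
# risk-assessment indices, transition/HEH statistics, stretch-attend and
# protected head-dip detection, locomotion, and the per-animal profile.

#' Per-frame zone labels for a trajectory
#'
#' Labels every frame with the containing zone via [locate_points()],
#' optionally smoothed with a running median over the integer zone codes
#' (window must be odd; 1 disables smoothing, the default).
#'
#' @param traj a trajectory.
#' @param zonemap a [build_zonemap()] object for the same arena.
#' @param smooth_window odd integer median-filter window (frames).
#' @return character vector, one zone name (or `"off_arena"`) per frame.
#' @export
zone_timeseries <- function(traj, zonemap, smooth_window = 1) {
  if (nrow(traj) == 0) stop("empty trajectory")
  ak <- attr(traj, "arena_kind")
  if (!is.null(ak) && !is.na(ak) && ak != zonemap$arena_kind) {
    stop("trajectory arena (", ak, ") does not match zonemap (",
         zonemap$arena_kind, ")")
  }
  lab <- locate_points(traj$x, traj$y, zonemap)
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
    lev <- c(names(zonemap$zones), "off_arena")
    code <- match(lab, lev)
    code <- as.integer(stats::runmed(code, smooth_window, endrule = "keep"))
    lab <- lev[code]
  }
  lab
}

#' Zone dwell times
#'
#' Seconds spent in each zone: `count(zone) / frame_rate`. All zones of the
#' map (plus `off_arena`) appear in the result, zeros included, so the
#' conservation invariant `sum(dwell) == n_frames / frame_rate` holds.
#'
#' @param labels per-frame zone labels from [zone_timeseries()].
#' @param frame_rate sampling rate in Hz.
#' @param zonemap optional zone map; when given, the result carries a
#'   `roles` attribute used by the index functions and missing zones are
#'   filled with 0.
#' @return named numeric vector of seconds, class `zone_dwell`.
#' @export
dwell_times <- function(labels, frame_rate, zonemap = NULL) {
  if (!length(labels)) stop("labels must be non-empty")
  stopifnot(frame_rate > 0)
  cnt <- table(labels)
  d <- as.numeric(cnt) / frame_rate
  names(d) <- names(cnt)
  if (!is.null(zonemap)) {
    full <- stats::setNames(numeric(length(zonemap$zones) + 1),
                            c(names(zonemap$zones), "off_arena"))
    full[names(d)] <- d
    d <- full
    attr(d, "roles") <- c(zone_roles(zonemap), off_arena = "off_arena")
  }
  class(d) <- "zone_dwell"
  d
}

# Sum dwell seconds over zones of a role, using the roles attribute when
# present and canonical zone-name patterns otherwise.
role_dwell <- function(dwell, role) {
  roles <- attr(dwell, "roles")
  if (is.null(roles)) {
    pattern <- switch(role,
      center = "^center$", entry = "(^|_)entry",
      open_distal = "^open_distal", hidden = "^hidden$",
      light_core = "^light_core$", closed = "^closed",
      stop("unknown role ", role))
    sum(unclass(dwell)[grepl(pattern, names(dwell))])
  } else {
    sum(unclass(dwell)[names(roles)[roles == role]], na.rm = TRUE)
  }
}

#' Elevated-plus-maze risk-assessment index
#'
#' The fraction of open-area time spent assessing rather than committed:
#' with `i` the center time, `ii` the summed open-arm entry-zone time and
#' `iii` the summed distal open-arm time, the index is
#' `(i + ii) / (i + ii + iii)`. Returns `NA` (undefined) when the animal
#' never visited the open area, i.e. the denominator is 0.
#'
#' @param dwell a [dwell_times()] table from an EPM trial.
#' @return index in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' d <- c(center = 60, open_entry_east = 30, open_entry_west = 30,
#'        open_distal_east = 90, open_distal_west = 90)
#' epm_risk_index(d)  # (60 + 60) / (60 + 60 + 180) = 0.4
epm_risk_index <- function(dwell) {
  i <- role_dwell(dwell, "center")
  ii <- role_dwell(dwell, "entry")
  iii <- role_dwell(dwell, "open_distal")
  denom <- i + ii + iii
  if (denom <= 0) return(NA_real_)
  (i + ii) / denom
}

#' Dark/light-box risk-assessment index
#'
#' Time in the light-side entry band relative to the entire light zone:
#' `entry / (entry + light_core)`. `NA` (undefined) when the animal never
#' entered the light side.
#'
#' @param dwell a [dwell_times()] table from a DL trial.
#' @return index in `[0, 1]`, or `NA` when undefined.
#' @export
dl_risk_index <- function(dwell) {
  e <- role_dwell(dwell, "entry")
  l <- role_dwell(dwell, "light_core")
  if (e + l <= 0) return(NA_real_)
  e / (e + l)
}

#' Run-length compression of zone labels and entry counts
#'
#' Compresses the label series into visits (runs). An "entry" into a zone
#' is a run of that zone other than the run that starts the trial
#' (the initial placement is not an entry).
#'
#' @param labels per-frame zone labels.
#' @param frame_rate optional Hz; when given, runs carry enter/exit times.
#' @return list of class `zone_runs`: `runs` (data frame with `zone`,
#'   `start_frame`, `end_frame`, and times when `frame_rate` is given) and
#'   `entries` (named count vector over observed zones).
#' @export
transition_runs <- function(labels, frame_rate = NULL) {
  if (!length(labels)) stop("labels must be non-empty")
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(zone = r$values, start_frame = starts, end_frame = ends,
                     stringsAsFactors = FALSE)
  if (!is.null(frame_rate)) {
    runs$enter_t <- (starts - 1L) / frame_rate
    runs$exit_t <- ends / frame_rate
  }
  zones <- unique(r$values)
  entries <- vapply(zones, function(z) sum(r$values[-1L] == z), integer(1))
  structure(list(runs = runs, entries = entries), class = "zone_runs")
}

#' @export
print.zone_runs <- function(x, ...) {
  cat("Zone run sequence:", nrow(x$runs), "runs\n")
  print(utils::head(x$runs, 5))
  cat("entries:", paste(names(x$entries), x$entries, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Hidden-entry-hidden (HEH) transition frequency
#'
#' In the dark/light box, the fraction of hidden-to-entry excursions that
#' return straight to the hidden zone: the count of consecutive run triples
#' (hidden, entry, hidden) divided by the count of (hidden, entry) run
#' pairs. Lower values indicate more risk-taking (the animal presses on
#' into the light). `NA` when the animal never moved hidden-to-entry.
#'
#' @param runs a [transition_runs()] object, or a character vector of
#'   consecutive run zones.
#' @param hidden,entry zone names for the hidden compartment and entry band.
#' @return frequency in `[0, 1]`, or `NA` when undefined.
#' @export
heh_frequency <- function(runs, hidden = "hidden", entry = "entry") {
  z <- if (inherits(runs, "zone_runs")) runs$runs$zone else as.character(runs)
  n <- length(z)
  if (n < 2) return(NA_real_)
  is_pair <- z[-n] == hidden & z[-1] == entry
  pairs <- sum(is_pair)
  if (pairs == 0) return(NA_real_)
  idx <- which(is_pair)
  triples <- sum(idx <= n - 2 & z[idx + 2] == hidden)
  triples / pairs
}

# Per-frame centroid speed (cm/s): forward difference, last value repeated.
frame_speed <- function(traj) {
  n <- nrow(traj)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  sp <- step / diff(traj$t)
  c(sp, sp[n - 1L])
}

#' Detect stretch-attend postures
#'
#' A stretch-attend posture (SAP) is an elongated, slow interval: body
#' elongation (nose to tail-base distance over the trial-median baseline)
#' at least `elong_factor` while centroid speed is at most `speed_max`,
#' sustained for at least `min_dur` seconds. Events are stamped with the
#' zone (and role) of their midpoint frame when a zone map is supplied.
#'
#' @param traj trajectory with body points.
#' @param zonemap optional zone map for event zone stamping.
#' @param elong_factor elongation threshold (default 1.2, unitless).
#' @param speed_max speed ceiling in cm/s (default 2).
#' @param min_dur minimum duration in seconds (default 0.5).
#' @return data frame of events: `start_t`, `end_t`, `duration`, `mid_t`,
#'   and `zone`, `role` when `zonemap` is given.
#' @export
detect_stretch_attend <- function(traj, zonemap = NULL, elong_factor = 1.2,
                                  speed_max = 2, min_dur = 0.5) {
  if (!has_body_points(traj)) stop("trajectory has no body points")
  fr <- attr(traj, "frame_rate")
  len <- sqrt((traj$nose_x - traj$tail_x)^2 + (traj$nose_y - traj$tail_y)^2)
  baseline <- stats::median(len)
  if (baseline <= 0) stop("degenerate body length")
  ok <- (len / baseline >= elong_factor) & (frame_speed(traj) <= speed_max)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fr >= min_dur)
  ev <- data.frame(start_t = traj$t[starts[keep]], end_t = traj$t[ends[keep]],
                   duration = r$lengths[keep] / fr)
  mid <- floor((starts[keep] + ends[keep]) / 2)
  ev$mid_t <- traj$t[mid]
  if (!is.null(zonemap) && nrow(ev)) {
    ev$zone <- locate_points(traj$x[mid], traj$y[mid], zonemap)
    roles <- c(zone_roles(zonemap), off_arena = "off_arena")
    ev$role <- unname(roles[ev$zone])
  } else if (!is.null(zonemap)) {
    ev$zone <- character(0)
    ev$role <- character(0)
  }
  ev
}

#' Relative stretch-attend frequency in the risk-assessment zone
#'
#' Fraction of stretch-attend events whose midpoint lies in a
#' risk-assessment zone (center or open-arm entry zones) out of all events
#' in the maze. `NA` when no events occurred.
#'
#' @param events event data frame from [detect_stretch_attend()] (needs the
#'   `role` column, i.e. detection with a zone map).
#' @param risk_roles role tags counting as risk-assessment zones.
#' @return fraction in `[0, 1]`, or `NA` when undefined.
#' @export
sap_relative_frequency <- function(events, risk_roles = c("center", "entry")) {
  if (nrow(events) == 0) return(NA_real_)
  if (is.null(events$role)) stop("events lack zone roles; detect with a zonemap")
  mean(events$role %in% risk_roles)
}

#' Count protected head dips
#'
#' A protected head dip is a maximal interval in which the nose point lies
#' outside the maze footprint (over an open-arm edge) while the centroid
#' remains in a protected zone (center, open-arm entry, or closed arm).
#' Alternatively a pre-annotated event table can be supplied, in which case
#' its rows are counted.
#'
#' @param traj EPM trajectory with body points.
#' @param zonemap EPM zone map.
#' @param events optional pre-annotated event data frame (one row per dip).
#' @param min_dur minimum duration in seconds (default 0: any interval).
#' @return integer count.
#' @export
detect_protected_head_dips <- function(traj, zonemap, events = NULL,
                                       min_dur = 0) {
  if (!is.null(events)) return(nrow(events))
  if (!has_body_points(traj)) stop("trajectory has no body points and no annotation")
  fr <- attr(traj, "frame_rate")
  nose_out <- !point_in_polygon(traj$nose_x, traj$nose_y, zonemap$footprint)
  roles <- c(zone_roles(zonemap), off_arena = "off_arena")
  centroid_role <- unname(roles[locate_points(traj$x, traj$y, zonemap)])
  ok <- nose_out & centroid_role %in% c("center", "entry", "closed")
  r <- rle(ok)
  sum(r$values & (r$lengths / fr >= min_dur))
}

#' Locomotion summary
#'
#' @param traj a trajectory.
#' @return list with `total_distance` (cm, sum of Euclidean step lengths)
#'   and `mean_velocity` (cm/s, distance over elapsed time).
#' @export
#' @examples
#' traj <- as_trajectory(data.frame(t = c(0, 1), x = c(0, 3), y = c(0, 4)))
#' locomotion_summary(traj)$total_distance  # 5
locomotion_summary <- function(traj) {
  if (nrow(traj) < 2) stop("need at least 2 samples")
  dist <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  list(total_distance = dist,
       mean_velocity = dist / (traj$t[nrow(traj)] - traj$t[1]))
}

#' Per-animal behavioral profile
#'
#' Assembles the arena's full metric set from one trajectory. Undefined
#' ratios (e.g. the EPM risk index for an animal that never left the closed
#' arms) are reported as `NA`, never silently zero. Metrics requiring body
#' points are `NA` when the trajectory has none.
#'
#' EPM profiles report open-arm time (entry + distal), open- and
#' closed-arm entry counts, the risk index, relative stretch-attend
#' frequency and count, protected head dips, and locomotion. DL profiles
#' report light-zone time and entries, the risk index, HEH frequency, and
#' locomotion. OF profiles report center time and locomotion.
#'
#' @param traj a trajectory.
#' @param zonemap matching zone map.
#' @param smooth_window label smoothing window, see [zone_timeseries()].
#' @param sap_elong,sap_speed_max,sap_min_dur stretch-attend thresholds,
#'   see [detect_stretch_attend()].
#' @return one-row data frame of metrics.
#' @export
behavioral_profile <- function(traj, zonemap, smooth_window = 1,
                               sap_elong = 1.2, sap_speed_max = 2,
                               sap_min_dur = 0.5) {
  fr <- attr(traj, "frame_rate")
  labels <- zone_timeseries(traj, zonemap, smooth_window)
  dwell <- dwell_times(labels, fr, zonemap)
  loco <- locomotion_summary(traj)
  roles <- c(zone_roles(zonemap), off_arena = "off_arena")
  role_labels <- unname(roles[labels])
  kind <- zonemap$arena_kind

  if (kind == "epm") {
    region <- ifelse(role_labels %in% c("entry", "open_distal"), "open_arm",
                     role_labels)
    region_runs <- transition_runs(region)
    sap <- if (has_body_points(traj)) {
      detect_stretch_attend(traj, zonemap, sap_elong, sap_speed_max, sap_min_dur)
    } else NULL
    out <- data.frame(
      open_arm_time = role_dwell(dwell, "entry") + role_dwell(dwell, "open_distal"),
      open_arm_entries = unname(region_runs$entries["open_arm"] %||% NA_integer_),
      closed_arm_entries = unname(region_runs$entries["closed"] %||% NA_integer_),
      epm_risk_index = epm_risk_index(dwell),
      sap_count = if (is.null(sap)) NA_integer_ else nrow(sap),
      sap_relative = if (is.null(sap)) NA_real_ else sap_relative_frequency(sap),
      protected_head_dips = if (has_body_points(traj))
        detect_protected_head_dips(traj, zonemap) else NA_integer_
    )
    out$open_arm_entries[is.na(out$open_arm_entries)] <- 0L
    out$closed_arm_entries[is.na(out$closed_arm_entries)] <- 0L
  } else if (kind == "dl") {
    region <- ifelse(role_labels %in% c("entry", "light_core"), "light",
                     role_labels)
    region_runs <- transition_runs(region)
    runs <- transition_runs(labels)
    out <- data.frame(
      light_time = role_dwell(dwell, "entry") + role_dwell(dwell, "light_core"),
      light_entries = unname(region_runs$entries["light"] %||% NA_integer_),
      dl_risk_index = dl_risk_index(dwell),
      heh_frequency = heh_frequency(runs)
    )
    out$light_entries[is.na(out$light_entries)] <- 0L
  } else {
    out <- data.frame(of_center_time = role_dwell(dwell, "center"))
  }
  out$total_distance <- loco$total_distance
  out$mean_velocity <- loco$mean_velocity
  out
}

#' Profile a list of trajectories
#'
#' @param trajs list of trajectories.
#' @param zonemap shared zone map.
#' @param group optional group label recycled across animals.
#' @param ... passed to [behavioral_profile()].
#' @return data frame, one row per animal, with `animal` (and `group`)
#'   identifier columns.
#' @export
profile_trajectories <- function(trajs, zonemap, group = NULL, ...) {
  rows <- lapply(trajs, behavioral_profile, zonemap = zonemap, ...)
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(animal = seq_along(trajs)), out)
  if (!is.null(group)) out <- cbind(data.frame(group = rep(group, length.out = nrow(out))), out)
  rownames(out) <- NULL
  out
}
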