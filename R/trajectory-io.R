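# Trajectory container and plain-text input/output.

#' Construct a trajectory object
#'
#' A trajectory is a data frame of time-stamped positions in cm: columns
#' `t` (seconds, strictly increasing), `x`, `y`, and optionally `nose_x`,
#' `nose_y`, `tail_x`, `tail_y` body points.
#'
#' @param df data frame with at least `t`, `x`, `y`.
#' @param arena_kind optional arena tag (`"epm"`, `"dl"`, `"of"`).
#' @param frame_rate sampling rate in Hz; inferred from `t` when omitted.
#' @return the data frame with class `trajectory` and attributes
#'   `arena_kind`, `frame_rate`.
#' @export
as_trajectory <- function(df, arena_kind = NULL, frame_rate = NULL) {
  stopifnot(is.data.frame(df), all(c("t", "x", "y") %in% names(df)))
  if (nrow(df) < 2) stop("a trajectory needs at least 2 samples")
  dts <- diff(df$t)
  if (any(dts <= 0)) stop("time stamps must be strictly increasing")
  med_dt <- stats::median(dts)
  if (any(abs(dts - med_dt) > 0.01 * med_dt + 1e-9)) {
    warning("sampling is non-uniform beyond 1% jitter")
  }
  if (is.null(frame_rate)) frame_rate <- 1 / med_dt
  structure(df, class = c("trajectory", "data.frame"),
            arena_kind = arena_kind, frame_rate = frame_rate)
}

has_body_points <- function(traj) {
  all(c("nose_x", "nose_y", "tail_x", "tail_y") %in% names(traj))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %.1f s at %.1f Hz%s%s\n",
              nrow(x), x$t[nrow(x)] - x$t[1], attr(x, "frame_rate"),
              if (!is.null(attr(x, "arena_kind")))
                paste0(", arena ", toupper(attr(x, "arena_kind"))) else "",
              if (has_body_points(x)) ", with body points" else ""))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Read / write trajectory CSV
#'
#' CSV with header `t,x,y` and optional `nose_x,nose_y,tail_x,tail_y`
#' columns; seconds and cm.
#'
#' @param path file path.
#' @param arena_kind optional arena tag stored on the returned object.
#' @return `read_trajectory` returns a `trajectory`; `write_trajectory`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path, arena_kind = NULL) {
  df <- utils::read.csv(path)
  as_trajectory(df, arena_kind = arena_kind)
}

#' @rdname read_trajectory
#' @param traj a trajectory object.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-animal behavioral profiles as TSV
#'
#' One row per animal, one column per metric; undefined metrics are `NA`.
#'
#' @param profiles data frame of profiles (rows = animals).
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
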