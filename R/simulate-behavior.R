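# Synthetic trajectory generator: a two-level model in which a zone-level
# Markov chain sets where the animal is and for how long, and a bounded
# correlated random walk moves it within the current zone. Dwell times in
# the risk-assessment zones (center, open-arm entry, light-side entry band)
# scale with `risk_propensity`; transitions into exposed zones are weighted
# by `open_preference`, so the two knobs control the risk indices and the
# overall open/closed occupancy independently of the speed process.

#' Parameters for the trajectory simulator
#'
#' @param arena_kind `"epm"`, `"dl"` or `"of"`.
#' @param duration trial length in seconds. Defaults to the standard
#'   protocol length: 300 s for EPM and DL, 600 s for the open field.
#' @param frame_rate sampling rate in Hz (default 25, typical video
#'   tracking).
#' @param risk_propensity in `[0, 1]`; scales the mean per-visit dwell in
#'   the risk-assessment zones (center / entry).
#' @param open_preference in `[0, 1]`; probability weight on transitions
#'   into exposed zones (center, entry, open arm, light side). At 0 the
#'   animal never leaves the sheltered start zone.
#' @param speed_mean,speed_sd per-frame speed draw, cm/s (truncated at 0).
#' @param body_length nose-to-tail-base distance in cm (default 8).
#' @param body_points logical; generate nose and tail-base coordinates.
#' @param sap_rate stretch-attend bout rate, bouts per minute (default 6).
#' @param head_dip_rate protected head-dip bout rate while in the EPM
#'   risk-assessment zones, bouts per minute (default 3; EPM only).
#' @param seed integer seed.
#' @return an object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(arena_kind = c("epm", "dl", "of"),
                                duration = NULL, frame_rate = 25,
                                risk_propensity = 0.5, open_preference = 0.5,
                                speed_mean = 6, speed_sd = 2,
                                body_length = 8, body_points = TRUE,
                                sap_rate = 6, head_dip_rate = 3, seed = 1L) {
  arena_kind <- match.arg(tolower(arena_kind), c("epm", "dl", "of"))
  if (is.null(duration)) duration <- if (arena_kind == "of") 600 else 300
  stopifnot(duration > 0, frame_rate > 0,
            risk_propensity >= 0, risk_propensity <= 1,
            open_preference >= 0, open_preference <= 1,
            speed_mean > 0, speed_sd >= 0, body_length > 0, sap_rate >= 0,
            head_dip_rate >= 0)
  structure(list(arena_kind = arena_kind, duration = duration,
                 frame_rate = frame_rate, risk_propensity = risk_propensity,
                 open_preference = open_preference, speed_mean = speed_mean,
                 speed_sd = speed_sd, body_length = body_length,
                 body_points = isTRUE(body_points), sap_rate = sap_rate,
                 head_dip_rate = head_dip_rate, seed = as.integer(seed)),
            class = "behavior_sim_params")
}

# Zone transition structure per arena kind. Exposed zones receive weight
# `open_preference`, sheltered ones `1 - open_preference`.
zone_graph <- function(kind) {
  switch(kind,
    epm = list(
      start = "closed_north",
      exposed = c("center", "open_entry_east", "open_entry_west",
                  "open_distal_east", "open_distal_west"),
      neighbors = list(
        center = c("closed_north", "closed_south",
                   "open_entry_east", "open_entry_west"),
        open_entry_east = c("center", "open_distal_east"),
        open_entry_west = c("center", "open_distal_west"),
        open_distal_east = "open_entry_east",
        open_distal_west = "open_entry_west",
        closed_north = "center",
        closed_south = "center"
      )
    ),
    dl = list(
      start = "hidden",
      exposed = c("entry", "light_core"),
      neighbors = list(
        hidden = "entry",
        entry = c("hidden", "light_core"),
        light_core = "entry"
      )
    ),
    of = list(
      start = "surround",
      exposed = "center",
      neighbors = list(surround = "center", center = "surround")
    )
  )
}

# Mean per-visit dwell (s) by zone role.
dwell_mean <- function(role, risk_propensity) {
  switch(role,
    center = ,
    entry = 0.5 + 7.5 * risk_propensity,
    open_distal = ,
    light_core = 4,
    10  # sheltered: closed arms, hidden compartment, OF periphery
  )
}

zone_inset_bbox <- function(zone, inset = 0.2) {
  b <- zone$bbox
  c(xmin = b[["xmin"]] + inset, xmax = b[["xmax"]] - inset,
    ymin = b[["ymin"]] + inset, ymax = b[["ymax"]] - inset)
}

# Midpoint of the shared edge between two rectangular zones, nudged into
# the target zone.
gate_point <- function(from, to, nudge = 0.3) {
  x0 <- max(from$bbox[["xmin"]], to$bbox[["xmin"]])
  x1 <- min(from$bbox[["xmax"]], to$bbox[["xmax"]])
  y0 <- max(from$bbox[["ymin"]], to$bbox[["ymin"]])
  y1 <- min(from$bbox[["ymax"]], to$bbox[["ymax"]])
  g <- c((x0 + x1) / 2, (y0 + y1) / 2)
  ctr_from <- c(mean(from$bbox[c("xmin", "xmax")]), mean(from$bbox[c("ymin", "ymax")]))
  ctr_to <- c(mean(to$bbox[c("xmin", "xmax")]), mean(to$bbox[c("ymin", "ymax")]))
  dir <- ctr_to - ctr_from
  dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
  g + nudge * dir
}

# Push points that fell into a rectangular hole out to its nearest edge
# (used for the open-field periphery, whose bounding box spans the arena).
push_out_of_rect <- function(x, y, hx0, hx1, hy0, hy1, eps = 0.05) {
  inside <- x > hx0 & x < hx1 & y > hy0 & y < hy1
  if (!any(inside)) return(list(x = x, y = y))
  xi <- x[inside]; yi <- y[inside]
  d <- cbind(xi - hx0, hx1 - xi, yi - hy0, hy1 - yi)
  side <- max.col(-d)  # nearest edge
  xi[side == 1] <- hx0 - eps
  xi[side == 2] <- hx1 + eps
  yi[side == 3] <- hy0 - eps
  yi[side == 4] <- hy1 + eps
  x[inside] <- xi; y[inside] <- yi
  list(x = x, y = y)
}

#' Simulate one tracking trajectory
#'
#' Generates a centroid (and optionally nose / tail-base) time series from
#' the two-level zone chain / random walk model described in
#' [behavior_sim_params()]. The animal starts in the sheltered zone of its
#' arena (a closed arm, the dark compartment, or the open-field periphery).
#' Stretch-attend bouts are produced by an alternating renewal process
#' during which the speed drops near zero and the nose offset is elongated
#' by a factor 1.5.
#'
#' @param params a [behavior_sim_params()] object.
#' @param zonemap matching [build_zonemap()]; built from defaults when
#'   omitted.
#' @return a `trajectory`: data frame with columns `t`, `x`, `y` and, when
#'   `params$body_points`, `nose_x`, `nose_y`, `tail_x`, `tail_y`;
#'   attributes `arena_kind` and `frame_rate`.
#' @export
#' @examples
#' p <- behavior_sim_params("epm", duration = 60, seed = 7)
#' traj <- simulate_trajectory(p)
#' head(traj)
simulate_trajectory <- function(params, zonemap = build_zonemap(params$arena_kind)) {
  stopifnot(inherits(params, "behavior_sim_params"))
  if (zonemap$arena_kind != params$arena_kind) {
    stop("zonemap arena kind (", zonemap$arena_kind,
         ") does not match params (", params$arena_kind, ")")
  }
  with_seed(params$seed, simulate_trajectory_impl(params, zonemap))
}

simulate_trajectory_impl <- function(params, zonemap) {
  fr <- params$frame_rate
  n <- max(2L, round(params$duration * fr))
  dt <- 1 / fr
  graph <- zone_graph(params$arena_kind)
  roles <- zone_roles(zonemap)
  hole <- if (params$arena_kind == "of") zonemap$zones$center$bbox else NULL

  # stretch-attend bout schedule (alternating renewal, vectorized)
  bout <- rep(FALSE, n)
  if (params$sap_rate > 0) {
    t_cur <- stats::rexp(1, params$sap_rate / 60)
    while (t_cur < params$duration) {
      len <- stats::runif(1, 0.6, 1.2)
      i0 <- max(1L, ceiling(t_cur * fr)); i1 <- min(n, floor((t_cur + len) * fr))
      if (i0 <= i1) bout[i0:i1] <- TRUE
      t_cur <- t_cur + len + stats::rexp(1, params$sap_rate / 60)
    }
  }

  x <- numeric(n); y <- numeric(n)
  cur <- graph$start
  bb <- zone_inset_bbox(zonemap$zones[[cur]])
  x[1] <- mean(bb[c("xmin", "xmax")]); y[1] <- mean(bb[c("ymin", "ymax")])
  theta <- stats::runif(1, -pi, pi)
  i <- 1L

  draw_speed <- function(k, idx) {
    s <- pmax(0, stats::rnorm(k, params$speed_mean, params$speed_sd))
    s[bout[idx]] <- s[bout[idx]] * 0.02
    s * dt
  }

  while (i < n) {
    # --- dwell phase: confined correlated walk in the current zone -------
    mean_dwell <- dwell_mean(roles[[cur]], params$risk_propensity)
    ndw <- min(n - i, max(1L, round(stats::rexp(1, 1 / mean_dwell) * fr)))
    idx <- i + seq_len(ndw)
    dth <- stats::rnorm(ndw, 0, 2 * sqrt(dt))
    th <- theta + cumsum(dth)
    sp <- draw_speed(ndw, idx)
    bb <- zone_inset_bbox(zonemap$zones[[cur]])
    xs <- reflect_into(x[i] + cumsum(sp * cos(th)), bb[["xmin"]], bb[["xmax"]])
    ys <- reflect_into(y[i] + cumsum(sp * sin(th)), bb[["ymin"]], bb[["ymax"]])
    if (!is.null(hole) && cur == "surround") {
      adj <- push_out_of_rect(xs, ys, hole[["xmin"]], hole[["xmax"]],
                              hole[["ymin"]], hole[["ymax"]])
      xs <- adj$x; ys <- adj$y
    }
    x[idx] <- xs; y[idx] <- ys
    theta <- th[ndw]
    i <- i + ndw
    if (i >= n) break

    # --- choose next zone ------------------------------------------------
    nb <- graph$neighbors[[cur]]
    w <- ifelse(nb %in% graph$exposed, params$open_preference,
                1 - params$open_preference)
    if (sum(w) <= 0) next  # nowhere to go: stay and redraw a dwell
    nxt <- if (length(nb) == 1L) nb else sample(nb, 1L, prob = w)

    # --- transit phase: straight dash to the shared-edge gate -----------
    g <- gate_point(zonemap$zones[[cur]], zonemap$zones[[nxt]])
    d <- sqrt((g[1] - x[i])^2 + (g[2] - y[i])^2)
    if (d > 1e-9) {
      max_tr <- n - i
      sp <- draw_speed(max_tr, i + seq_len(max_tr))
      sp <- pmax(sp, 1e-3)  # a paused animal still completes the crossing
      trav <- pmin(cumsum(sp), d)
      ntr <- min(max_tr, which(trav >= d)[1])
      if (is.na(ntr)) ntr <- max_tr
      frac <- trav[seq_len(ntr)] / d
      x[i + seq_len(ntr)] <- x[i] + frac * (g[1] - x[i])
      y[i + seq_len(ntr)] <- y[i] + frac * (g[2] - y[i])
      theta <- atan2(g[2] - y[i], g[1] - x[i])
      i <- i + ntr
    }
    cur <- nxt
  }

  traj <- data.frame(t = (seq_len(n) - 1L) * dt, x = x, y = y)
  if (params$body_points) {
    dx <- c(diff(x), 0); dy <- c(diff(y), 0)
    moved <- sqrt(dx^2 + dy^2) > 1e-9
    h <- rep(NA_real_, n)
    h[moved] <- atan2(dy[moved], dx[moved])
    if (is.na(h[1])) h[1] <- 0
    for (k in seq_len(n)[-1]) if (is.na(h[k])) h[k] <- h[k - 1]
    half <- params$body_length / 2
    elong <- ifelse(bout, 1.5, 1)
    nose_x <- x + half * elong * cos(h)
    nose_y <- y + half * elong * sin(h)
    tail_x <- x - half * cos(h)
    tail_y <- y - half * sin(h)
    # walls and floor edges block the body: pull body points that project
    # outside the footprint back to the boundary, slightly inside
    clamp_in <- function(bx, by) {
      # shrink the body offset toward the centroid until the point is
      # inside the (non-convex) footprint
      for (iter in 1:10) {
        out <- !point_in_polygon(bx, by, zonemap$footprint)
        if (!any(out)) break
        bx[out] <- x[out] + 0.7 * (bx[out] - x[out])
        by[out] <- y[out] + 0.7 * (by[out] - y[out])
      }
      list(x = bx, y = by)
    }
    nc <- clamp_in(nose_x, nose_y); tc <- clamp_in(tail_x, tail_y)
    nose_x <- nc$x; nose_y <- nc$y; tail_x <- tc$x; tail_y <- tc$y
    # explicit protected head-dip bouts: while paused in an open-arm entry
    # zone, the nose reaches 1 cm past the arm's side edge
    if (params$arena_kind == "epm" && params$head_dip_rate > 0) {
      half_w <- zonemap$dims$arm_width / 2
      in_entry <- startsWith(locate_points(x, y, zonemap), "open_entry")
      t_cur <- stats::rexp(1, params$head_dip_rate / 60)
      while (t_cur < params$duration) {
        len <- stats::runif(1, 0.4, 0.8)
        side <- sample(c(-1, 1), 1)
        i0 <- max(1L, ceiling(t_cur * fr)); i1 <- min(n, floor((t_cur + len) * fr))
        if (i0 <= i1) {
          act <- seq.int(i0, i1)
          act <- act[in_entry[act]]
          if (length(act)) {
            on_x_arm <- abs(x[act]) > abs(y[act])
            nose_y[act[on_x_arm]] <- side * (half_w + 1)
            nose_x[act[on_x_arm]] <- x[act[on_x_arm]]
            nose_x[act[!on_x_arm]] <- side * (half_w + 1)
            nose_y[act[!on_x_arm]] <- y[act[!on_x_arm]]
          }
        }
        t_cur <- t_cur + len + stats::rexp(1, params$head_dip_rate / 60)
      }
    }
    traj$nose_x <- nose_x; traj$nose_y <- nose_y
    traj$tail_x <- tail_x; traj$tail_y <- tail_y
  }
  as_trajectory(traj, arena_kind = params$arena_kind, frame_rate = fr)
}

#' Simulate a two-group cohort of trajectories
#'
#' Per-animal seeds are derived deterministically from `seed`, so the whole
#' cohort is reproducible and each animal's trajectory is independent of
#' cohort size ordering.
#'
#' @param params_a,params_b [behavior_sim_params()] for the two groups
#'   (their own `seed` fields are ignored).
#' @param n_per_group animals per group (at least 2).
#' @param seed master seed.
#' @param zonemap optional shared [build_zonemap()].
#' @return list with elements `a` and `b`, each a list of trajectories.
#' @export
simulate_cohort <- function(params_a, params_b, n_per_group, seed,
                            zonemap = build_zonemap(params_a$arena_kind)) {
  stopifnot(inherits(params_a, "behavior_sim_params"),
            inherits(params_b, "behavior_sim_params"))
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (params_a$arena_kind != params_b$arena_kind) {
    stop("both groups must use the same arena kind")
  }
  seeds <- derive_seeds(seed, 2L * n_per_group)
  sim_one <- function(p, s) {
    p$seed <- s
    simulate_trajectory(p, zonemap)
  }
  list(
    a = lapply(seeds[seq_len(n_per_group)], function(s) sim_one(params_a, s)),
    b = lapply(seeds[n_per_group + seq_len(n_per_group)],
               function(s) sim_one(params_b, s))
  )
}
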