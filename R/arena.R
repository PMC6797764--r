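# Maze geometry: zone maps for the elevated plus maze (EPM), dark/light box
# (DL) and open field (OF), and point-to-zone assignment.

#' Default arena dimensions (cm)
#'
#' Standard apparatus dimensions: EPM with a 5 x 5 cm center, 30.5 x 5 cm
#' open and closed arms; DL box with a 14 x 27 cm dark compartment and a
#' 30 x 27 cm light compartment; 50 x 50 cm open field with a 25 x 25 cm
#' center region.
#'
#' @param kind one of `"epm"`, `"dl"`, `"of"`.
#' @return named list of dimensions in cm.
#' @export
#' @examples
#' arena_dims("epm")
arena_dims <- function(kind = c("epm", "dl", "of")) {
  kind <- match.arg(tolower(kind), c("epm", "dl", "of"))
  switch(kind,
    epm = list(center_side = 5, arm_length = 30.5, arm_width = 5),
    dl  = list(dark_width = 14, light_width = 30, depth = 27),
    of  = list(side = 50, center_side = 25)
  )
}

new_zone <- function(name, role, polys) {
  polys <- if (is.matrix(polys)) list(polys) else polys
  bb <- do.call(rbind, polys)
  list(name = name, role = role, polys = polys,
       bbox = c(xmin = min(bb[, 1]), xmax = max(bb[, 1]),
                ymin = min(bb[, 2]), ymax = max(bb[, 2])))
}

#' Build a named zone map for a maze
#'
#' Partitions the arena footprint into named, non-overlapping zones with
#' role tags used by the behavioral metrics.
#'
#' * **EPM** (arena-centered coordinates, open arms on the x axis, closed
#'   arms on the y axis): `center` (role `center`), per-arm open-arm entry
#'   zones of depth `entry_depth` (role `entry`), the remaining distal open
#'   arm (role `open_distal`) and two closed arms (role `closed`).
#' * **DL** (corner origin at the dark compartment's outer corner): the dark
#'   compartment (`hidden`), an entry band of depth `entry_depth` spanning
#'   the full divider width on the light side (`entry`), and the remaining
#'   light compartment (`light_core`).
#' * **OF** (corner origin): the center square (`center`) and the
#'   peripheral frame (`wall`).
#'
#' @param kind arena kind, `"epm"`, `"dl"` or `"of"`.
#' @param dims dimensions as returned by [arena_dims()].
#' @param entry_depth depth in cm of the open-arm / light-side entry zones
#'   (unused for the open field). Default 5 cm, equal to the arm width.
#' @return an object of class `zonemap`: list with `arena_kind`, `zones`
#'   (ordered list; order is the containment tie-break priority),
#'   `footprint` polygon and `entry_depth`.
#' @export
#' @examples
#' zm <- build_zonemap("epm")
#' locate_points(0, 0, zm)
build_zonemap <- function(kind = c("epm", "dl", "of"),
                          dims = arena_dims(kind), entry_depth = 5) {
  kind <- match.arg(tolower(kind), c("epm", "dl", "of"))
  if (kind != "of") {
    max_depth <- if (kind == "epm") dims$arm_length else dims$light_width
    if (!is.numeric(entry_depth) || entry_depth <= 0 || entry_depth >= max_depth) {
      stop("entry_depth must lie strictly between 0 and ", max_depth, " cm")
    }
  }
  if (any(unlist(dims) <= 0)) stop("all dimensions must be positive")

  if (kind == "epm") {
    h <- dims$center_side / 2          # 2.5
    L <- dims$arm_length               # 30.5
    w <- dims$arm_width / 2            # 2.5
    ed <- entry_depth
    zones <- list(
      new_zone("center", "center", rect_poly(-h, -h, h, h)),
      new_zone("open_entry_east", "entry", rect_poly(h, -w, h + ed, w)),
      new_zone("open_entry_west", "entry", rect_poly(-h - ed, -w, -h, w)),
      new_zone("open_distal_east", "open_distal", rect_poly(h + ed, -w, h + L, w)),
      new_zone("open_distal_west", "open_distal", rect_poly(-h - L, -w, -h - ed, w)),
      new_zone("closed_north", "closed", rect_poly(-w, h, w, h + L)),
      new_zone("closed_south", "closed", rect_poly(-w, -h - L, w, -h))
    )
    footprint <- cbind(
      c(h, h + L, h + L, h, h, w, w, -w, -w, -h, -h, -h - L,
        -h - L, -h, -h, -w, -w, w, w, h),
      c(h, w, -w, -h, -h, -h, -h - L, -h - L, -h, -h, -w, -w,
        w, w, h, h, h + L, h + L, h, h)
    )
  } else if (kind == "dl") {
    dw <- dims$dark_width; lw <- dims$light_width; dp <- dims$depth
    ed <- entry_depth
    zones <- list(
      new_zone("hidden", "hidden", rect_poly(0, 0, dw, dp)),
      new_zone("entry", "entry", rect_poly(dw, 0, dw + ed, dp)),
      new_zone("light_core", "light_core", rect_poly(dw + ed, 0, dw + lw, dp))
    )
    footprint <- rect_poly(0, 0, dw + lw, dp)
  } else {
    s <- dims$side; cs <- dims$center_side
    m0 <- (s - cs) / 2; m1 <- (s + cs) / 2
    zones <- list(
      new_zone("center", "center", rect_poly(m0, m0, m1, m1)),
      new_zone("surround", "wall", list(
        rect_poly(0, 0, m0, s), rect_poly(m1, 0, s, s),
        rect_poly(m0, 0, m1, m0), rect_poly(m0, m1, m1, s)
      ))
    )
    footprint <- rect_poly(0, 0, s, s)
  }
  names(zones) <- vapply(zones, `[[`, "", "name")
  structure(
    list(arena_kind = kind, zones = zones, footprint = footprint,
         entry_depth = if (kind == "of") NA_real_ else entry_depth,
         dims = dims),
    class = "zonemap"
  )
}

#' @export
print.zonemap <- function(x, ...) {
  cat("Zone map:", toupper(x$arena_kind), "\n")
  for (z in x$zones) {
    cat(sprintf("  %-18s role=%-12s bbox=[%.1f,%.1f]x[%.1f,%.1f] cm\n",
                z$name, z$role, z$bbox["xmin"], z$bbox["xmax"],
                z$bbox["ymin"], z$bbox["ymax"]))
  }
  invisible(x)
}

#' Zone names and roles of a zone map
#'
#' @param zonemap a [build_zonemap()] object.
#' @return named character vector mapping zone name to role tag.
#' @export
zone_roles <- function(zonemap) {
  vapply(zonemap$zones, `[[`, "", "role")
}

#' Assign points to zones
#'
#' Each point is assigned to the first zone (in the map's stated order)
#' whose polygon contains it, boundaries inclusive. Points inside the
#' footprint but captured by no zone polygon (possible only with custom
#' maps that do not tile the footprint) are assigned to the nearest zone by
#' Euclidean distance; points outside the footprint are labeled
#' `"off_arena"`.
#'
#' @param x,y coordinates in cm.
#' @param zonemap a [build_zonemap()] object.
#' @return character vector of zone names (or `"off_arena"`).
#' @export
locate_points <- function(x, y, zonemap) {
  stopifnot(length(x) == length(y))
  lab <- rep(NA_character_, length(x))
  for (z in zonemap$zones) {
    todo <- which(is.na(lab))
    if (!length(todo)) break
    hit <- rep(FALSE, length(todo))
    for (poly in z$polys) {
      hit <- hit | point_in_polygon(x[todo], y[todo], poly)
    }
    lab[todo[hit]] <- z$name
  }
  todo <- which(is.na(lab))
  if (length(todo)) {
    inside <- point_in_polygon(x[todo], y[todo], zonemap$footprint)
    lab[todo[!inside]] <- "off_arena"
    strays <- todo[inside]
    if (length(strays)) {
      dmat <- vapply(zonemap$zones, function(z) {
        d <- rep(Inf, length(strays))
        for (poly in z$polys) d <- pmin(d, dist_to_polygon(x[strays], y[strays], poly))
        d
      }, numeric(length(strays)))
      dmat <- matrix(dmat, nrow = length(strays))
      lab[strays] <- names(zonemap$zones)[apply(dmat, 1, which.min)]
    }
  }
  lab
}

#' Single-point zone lookup
#'
#' @param p numeric length-2 vector `c(x, y)` in cm.
#' @inheritParams locate_points
#' @return zone name (or `"off_arena"`).
#' @export
locate_point <- function(p, zonemap) locate_points(p[1], p[2], zonemap)

#' Serialize / read a zone map
#'
#' Writes the zone list (name, role, vertex lists) and footprint as JSON.
#'
#' @param zonemap a zonemap object.
#' @param path file path.
#' @return `write_zonemap` returns `path` invisibly; `read_zonemap` returns
#'   a `zonemap` object.
#' @export
write_zonemap <- function(zonemap, path) {
  obj <- list(
    arena_kind = zonemap$arena_kind,
    entry_depth = zonemap$entry_depth,
    dims = zonemap$dims,
    footprint = unname(apply(zonemap$footprint, 1, as.numeric, simplify = FALSE)),
    zones = lapply(unname(zonemap$zones), function(z) {
      list(name = z$name, role = z$role,
           polys = lapply(z$polys, function(p)
             unname(apply(p, 1, as.numeric, simplify = FALSE))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zonemap
#' @export
read_zonemap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(v) do.call(rbind, lapply(v, function(p) unlist(p)))
  zones <- lapply(obj$zones, function(z)
    new_zone(z$name, z$role, lapply(z$polys, to_mat)))
  names(zones) <- vapply(zones, `[[`, "", "name")
  structure(
    list(arena_kind = obj$arena_kind, zones = zones,
         footprint = to_mat(obj$footprint),
         entry_depth = obj$entry_depth %||% NA_real_,
         dims = obj$dims),
    class = "zonemap"
  )
}
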