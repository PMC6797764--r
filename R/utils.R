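# Internal helpers: seeded evaluation and planar geometry primitives.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their parameters and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive n child seeds deterministically from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Vectorised point-in-polygon (even-odd rule, boundary inclusive).
# poly is an m x 2 matrix of vertices, not closed.
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  m <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_boundary <- rep(FALSE, length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    cross <- (px - xi) * dy - (py - yi) * dx
    within_bbox <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    on_boundary <- on_boundary |
      (abs(cross) <= tol * (abs(dx) + abs(dy) + 1) & within_bbox)
    crosses <- ((yi > py) != (yj > py)) &
      (px < dx * (py - yi) / (yj - yi + (yj == yi)) + xi)
    crosses[yj == yi] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_boundary
}

# Minimum Euclidean distance from points to a polygon's boundary.
dist_to_polygon <- function(px, py, poly) {
  m <- nrow(poly)
  d <- rep(Inf, length(px))
  j <- m
  for (i in seq_len(m)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
    d <- pmin(d, sqrt((px - (ax + t * abx))^2 + (py - (ay + t * aby))^2))
    j <- i
  }
  d
}

# Nearest point on a polygon boundary for each query point.
nearest_point_on_polygon <- function(px, py, poly) {
  m <- nrow(poly)
  best_d <- rep(Inf, length(px))
  bx <- px; by <- py
  j <- m
  for (i in seq_len(m)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    cx <- poly[j, 1]; cy <- poly[j, 2]
    abx <- cx - ax; aby <- cy - ay
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
    qx <- ax + t * abx; qy <- ay + t * aby
    d <- (px - qx)^2 + (py - qy)^2
    upd <- d < best_d
    best_d[upd] <- d[upd]; bx[upd] <- qx[upd]; by[upd] <- qy[upd]
    j <- i
  }
  cbind(bx, by)
}

# Axis-aligned rectangle as an open polygon matrix.
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Fold an unconstrained coordinate path into [a, b] (reflecting boundaries).
reflect_into <- function(x, a, b) {
  w <- b - a
  if (w <= 0) stop("degenerate interval")
  y <- (x - a) %% (2 * w)
  a + ifelse(y > w, 2 * w - y, y)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
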