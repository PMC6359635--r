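# Geometric engine: point-to-polyline projection and arc distances along
# membrane contours. Everything is per-section 2-D in nm.

# Segment endpoints of a contour as two matrices (closing segment included
# for closed contours).
contour_segments <- function(contour) {
  v <- contour$vertices
  n <- nrow(v)
  if (contour$closed)
    list(a = v, b = rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]))
  else
    list(a = v[-n, , drop = FALSE], b = v[-1L, , drop = FALSE])
}

#' Project points onto a membrane contour
#'
#' For each query point, finds the globally nearest point on the polyline
#' (over all segments, including the closing segment of closed contours) and
#' returns its arc-length coordinate `s`, the Euclidean distance `d` and the
#' index of the segment containing the foot point. Ties between equidistant
#' segments are broken deterministically towards the smallest `s`.
#'
#' @param contour A [membrane_contour()].
#' @param pts Two-column matrix of query points (nm); a length-2 vector is
#'   treated as one point.
#' @return Data frame with columns `s`, `d`, `segment_index`.
#' @export
project_points <- function(contour, pts) {
  stopifnot(inherits(contour, "membrane_contour"))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    stop("project_points: non-finite query point")
  seg <- contour_segments(contour)
  nseg <- nrow(seg$a)
  m <- nrow(pts)
  len2 <- contour$seg_len^2
  # t (m x nseg): clamped projection parameter on each segment
  abx <- matrix(seg$b[, 1L] - seg$a[, 1L], m, nseg, byrow = TRUE)
  aby <- matrix(seg$b[, 2L] - seg$a[, 2L], m, nseg, byrow = TRUE)
  apx <- outer(pts[, 1L], seg$a[, 1L], "-")
  apy <- outer(pts[, 2L], seg$a[, 2L], "-")
  tt <- (apx * abx + apy * aby) / matrix(len2, m, nseg, byrow = TRUE)
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  dx <- apx - tt * abx
  dy <- apy - tt * aby
  d2 <- dx * dx + dy * dy
  smat <- matrix(contour$cum_s[seq_len(nseg)], m, nseg, byrow = TRUE) +
    tt * matrix(contour$seg_len, m, nseg, byrow = TRUE)
  s <- numeric(m); d <- numeric(m); si <- integer(m)
  for (i in seq_len(m)) {
    dmin <- min(d2[i, ])
    cand <- which(d2[i, ] <= dmin + 1e-9)
    j <- cand[which.min(smat[i, cand])]
    s[i] <- smat[i, j]; d[i] <- sqrt(d2[i, j]); si[i] <- j
  }
  data.frame(s = s, d = d, segment_index = si)
}

#' Project a single point onto a contour
#'
#' @inheritParams project_points
#' @param p Length-2 numeric point (nm).
#' @return List with `s` (arc coordinate, nm), `d` (Euclidean distance, nm)
#'   and `segment_index`.
#' @export
project_point <- function(contour, p) {
  r <- project_points(contour, matrix(p, ncol = 2L))
  list(s = r$s[1L], d = r$d[1L], segment_index = r$segment_index[1L])
}

in_interval <- function(s, interval) {
  a <- interval$s_start_nm; b <- interval$s_end_nm
  if (interval$wraps) s >= a | s <= b else s >= a & s <= b
}

#' Arc distance from a membrane position to a synapse interval
#'
#' Distance measured along the membrane from arc position `s` to the nearest
#' edge of the interval; 0 if `s` lies inside the interval. On closed
#' contours the shorter way around is taken, so the result never exceeds
#' half the contour length.
#'
#' @param contour A [membrane_contour()].
#' @param s Numeric vector of arc positions (nm), each in `[0, arc length]`.
#' @param interval A [synapse_interval()] on `contour`.
#' @return Numeric vector of arc distances (nm).
#' @export
arc_distance_to_interval <- function(contour, s, interval) {
  stopifnot(inherits(contour, "membrane_contour"),
            inherits(interval, "synapse_interval"))
  L <- contour$arc_length
  if (max(interval$s_start_nm, interval$s_end_nm) > L + 1e-9)
    stop("arc_distance_to_interval: interval exceeds contour arc length")
  if (interval$wraps && !contour$closed)
    stop("arc_distance_to_interval: wrapping interval on open contour")
  if (any(!is.finite(s)) || any(s < -1e-9) || any(s > L + 1e-9))
    stop("arc_distance_to_interval: s outside [0, arc length]")
  a <- interval$s_start_nm; b <- interval$s_end_nm
  if (contour$closed) {
    da <- abs(s - a); da <- pmin(da, L - da)
    db <- abs(s - b); db <- pmin(db, L - db)
    d <- pmin(da, db)
  } else {
    d <- pmin(abs(s - a), abs(s - b))
  }
  d[in_interval(s, interval)] <- 0
  d
}

#' Arc distance to the nearest PSD edge of a profile
#'
#' Minimum of [arc_distance_to_interval()] over all asymmetric synapse
#' intervals of the profile; the synaptic flag is `TRUE` iff the position
#' projects inside a PSD interval (distance 0). Profiles without an
#' asymmetric synapse return `NA` distances (such particles are excluded
#' from the PSD-distance analysis).
#'
#' @param profile A [compartment_profile()].
#' @param s Numeric vector of arc positions (nm) on the profile membrane.
#' @return Data frame with columns `distance` (nm or `NA`) and `synaptic`.
#' @export
nearest_psd_distance <- function(profile, s) {
  stopifnot(inherits(profile, "compartment_profile"))
  asym <- Filter(function(x) x$type == "asymmetric", profile$synapses)
  if (length(asym) == 0)
    return(data.frame(distance = rep(NA_real_, length(s)),
                      synaptic = rep(FALSE, length(s))))
  d <- Reduce(pmin, lapply(asym, function(iv)
    arc_distance_to_interval(profile$membrane, s, iv)))
  data.frame(distance = d, synaptic = d == 0)
}

# Point, tangent and inward normal at arc position s on a contour (internal;
# used by the synthetic generator). Inward is defined for closed contours by
# the polygon orientation.
contour_point_at <- function(contour, s) {
  L <- contour$arc_length
  s <- pmin(pmax(s, 0), L)
  nseg <- length(contour$seg_len)
  idx <- findInterval(s, contour$cum_s, rightmost.closed = TRUE)
  idx[idx > nseg] <- nseg
  seg <- contour_segments(contour)
  t <- (s - contour$cum_s[idx]) / contour$seg_len[idx]
  dir <- (seg$b[idx, , drop = FALSE] - seg$a[idx, , drop = FALSE]) /
    contour$seg_len[idx]
  pt <- seg$a[idx, , drop = FALSE] + t * (seg$b[idx, , drop = FALSE] -
                                            seg$a[idx, , drop = FALSE])
  ccw <- if (contour$closed) signed_area_nm2(contour) > 0 else TRUE
  inward <- if (ccw) cbind(-dir[, 2L], dir[, 1L]) else cbind(dir[, 2L], -dir[, 1L])
  list(point = pt, tangent = dir, inward = inward, segment_index = idx)
}
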