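# Fixtures and independent oracles, built in code.

square_contour <- function(side = 1000, origin = c(0, 0)) {
  membrane_contour(rbind(origin,
                         origin + c(side, 0),
                         origin + c(side, side),
                         origin + c(0, side)))
}

# A scene with one square spine (side 1000 nm, asymmetric synapse on
# [200, 300] nm of arc) and arbitrary particles.
square_spine_scene <- function(particles = NULL, synapse = TRUE) {
  prof <- compartment_profile(
    "sp1", "spine", square_contour(),
    synapses = if (synapse) list(synapse_interval(200, 300, "asymmetric"))
               else list())
  ultrastructure_scene("sq1", "CA1", "Kv4.2", "b1", list(prof), particles)
}

particle_df <- function(x, y) {
  data.frame(particle_id = sprintf("p%03d", seq_along(x)),
             x_nm = x, y_nm = y, stringsAsFactors = FALSE)
}

# Random polyline for geometry tests (a jittered closed star shape or an
# open random walk; arbitrary, possibly self-intersecting).
random_contour <- function(n_vertices = 20, closed = TRUE) {
  if (closed) {
    t <- sort(stats::runif(n_vertices, 0, 2 * pi))
    r <- stats::runif(n_vertices, 300, 900)
    membrane_contour(cbind(r * cos(t), r * sin(t)), closed = TRUE)
  } else {
    membrane_contour(apply(matrix(stats::runif(2 * n_vertices, -150, 150),
                                  ncol = 2), 2, cumsum), closed = FALSE)
  }
}

# Independent dense-resampling projection oracle: walks every segment in
# steps of `step` nm and returns the closest sampled point. Implemented
# from the raw vertex list only.
oracle_project <- function(contour, p, step = 0.1) {
  v <- contour$vertices
  n <- nrow(v)
  segs <- if (contour$closed) cbind(1:n, c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  best <- list(d = Inf, s = NA_real_)
  s0 <- 0
  for (k in seq_len(nrow(segs))) {
    a <- v[segs[k, 1], ]; b <- v[segs[k, 2], ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, len, by = step)
    if (tt[length(tt)] < len) tt <- c(tt, len)
    px <- a[1] + (b[1] - a[1]) * tt / len
    py <- a[2] + (b[2] - a[2]) * tt / len
    d <- sqrt((px - p[1])^2 + (py - p[2])^2)
    i <- which.min(d)
    if (d[i] < best$d) best <- list(d = d[i], s = s0 + tt[i])
    s0 <- s0 + len
  }
  best
}

# Exhaustive two-sample KS oracle: max ECDF gap over all pooled points.
oracle_ks_stat <- function(x, y) {
  max(vapply(c(x, y), function(t) abs(mean(x <= t) - mean(y <= t)), 0))
}
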