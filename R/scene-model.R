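# Domain types for annotated EM scenes: membrane contours with arc-length
# parameterisation, synapse intervals, compartment profiles, particle tables,
# and bit-exact JSON/CSV readers and writers (schema "goldmap-scene/1").

SCENE_SCHEMA <- "goldmap-scene/1"

PROFILE_KINDS <- c("spine", "dendritic_shaft", "main_dendrite",
                   "spiny_branchlet", "soma", "axon_terminal")
SCENE_REGIONS <- c("CA1", "CA3", "DG")
SCENE_CHANNELS <- c("Kv4.2", "Kv4.3")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Membrane contour
#'
#' An ordered 2-D polyline in nanometres (image coordinates, y increasing
#' downward) representing a stretch of plasma membrane. Closed contours
#' describe whole profile outlines and include the implied closing segment in
#' their arc length; open contours are partial membrane segments at the
#' micrograph border. Arc-length bookkeeping (per-segment lengths, cumulative
#' arc positions) is precomputed at construction time.
#'
#' @param vertices Two-column numeric matrix (or coercible) of vertex
#'   coordinates in nm. At least 2 vertices; consecutive vertices must be
#'   distinct. For closed contours a duplicated final vertex equal to the
#'   first is dropped.
#' @param closed Logical; whether the contour is a closed outline.
#' @return An object of class `membrane_contour` with fields `vertices`,
#'   `closed`, `seg_len`, `cum_s` (arc position of each vertex, starting at 0)
#'   and `arc_length`.
#' @export
membrane_contour <- function(vertices, closed = TRUE) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  if (ncol(v) != 2L)
    stop("membrane_contour: 'vertices' must have two columns (x_nm, y_nm)")
  if (!all(is.finite(v)))
    stop("membrane_contour: non-finite coordinate in 'vertices'")
  if (isTRUE(closed) && nrow(v) > 2L &&
      all(v[1L, ] == v[nrow(v), ]))
    v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 2L)
    stop("membrane_contour: at least 2 vertices required")
  a <- v
  b <- if (closed) rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
       else v[-1L, , drop = FALSE]
  if (!closed) a <- v[-n, , drop = FALSE]
  seg_len <- sqrt(rowSums((b - a)^2))
  if (any(seg_len == 0))
    stop("membrane_contour: consecutive vertices must be distinct (zero-length segment)")
  cum_s <- c(0, cumsum(seg_len))
  structure(
    list(vertices = v, closed = isTRUE(closed), seg_len = seg_len,
         cum_s = cum_s, arc_length = cum_s[length(cum_s)]),
    class = "membrane_contour")
}

#' Total arc length of a membrane contour (nm)
#'
#' For closed contours the implied closing segment is included.
#'
#' @param contour A [membrane_contour()].
#' @return Arc length in nm.
#' @export
arc_length <- function(contour) {
  stopifnot(inherits(contour, "membrane_contour"))
  contour$arc_length
}

#' @export
print.membrane_contour <- function(x, ...) {
  cat(sprintf("<membrane_contour: %d vertices, %s, arc length %.1f nm>\n",
              nrow(x$vertices), if (x$closed) "closed" else "open",
              x$arc_length))
  invisible(x)
}

#' Synapse interval on a membrane contour
#'
#' A synaptic specialisation stored as an arc-length interval on its parent
#' contour. Asymmetric intervals mark excitatory (glutamatergic) synapses
#' whose lateral edge is the reference point for PSD-distance measurements;
#' symmetric intervals mark inhibitory (GABAergic) synapses. On closed
#' contours an interval may wrap through arc position 0, flagged explicitly
#' with `wraps = TRUE` (in which case `s_start_nm > s_end_nm` and the
#' interval covers `[s_start, L] U [0, s_end]`).
#'
#' @param s_start_nm,s_end_nm Arc positions (nm) of the interval limits.
#' @param type `"asymmetric"` or `"symmetric"`.
#' @param wraps Logical; interval wraps through arc position 0 (closed
#'   contours only).
#' @return An object of class `synapse_interval`.
#' @export
synapse_interval <- function(s_start_nm, s_end_nm,
                             type = c("asymmetric", "symmetric"),
                             wraps = FALSE) {
  type <- match.arg(type)
  s_start_nm <- as.numeric(s_start_nm)
  s_end_nm <- as.numeric(s_end_nm)
  if (!is.finite(s_start_nm) || !is.finite(s_end_nm) ||
      s_start_nm < 0 || s_end_nm < 0)
    stop("synapse_interval: s_start_nm and s_end_nm must be finite and >= 0")
  if (!isTRUE(wraps) && s_end_nm <= s_start_nm)
    stop("synapse_interval: s_end_nm must exceed s_start_nm (interval length > 0)")
  if (isTRUE(wraps) && s_start_nm <= s_end_nm)
    stop("synapse_interval: wrapping interval requires s_start_nm > s_end_nm")
  structure(list(s_start_nm = s_start_nm, s_end_nm = s_end_nm,
                 type = type, wraps = isTRUE(wraps)),
            class = "synapse_interval")
}

interval_length <- function(interval, contour_length) {
  if (interval$wraps)
    contour_length - interval$s_start_nm + interval$s_end_nm
  else
    interval$s_end_nm - interval$s_start_nm
}

#' Area enclosed by a closed contour
#'
#' Shoelace (signed polygon) area of a closed membrane contour, returned as
#' an absolute value so it is independent of vertex orientation, converted
#' from nm^2 to um^2. This is the cross-section area used for areal particle
#' densities.
#'
#' @param contour A closed [membrane_contour()].
#' @return Area in um^2.
#' @export
polygon_area <- function(contour) {
  stopifnot(inherits(contour, "membrane_contour"))
  if (!contour$closed)
    stop("polygon_area: unsupported operation for open contours")
  v <- contour$vertices
  abs(pracma::polyarea(v[, 1L], v[, 2L])) / 1e6
}

# Signed polygon area in nm^2 (orientation carrier; internal).
signed_area_nm2 <- function(contour) {
  v <- contour$vertices
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Compartment profile
#'
#' One annotated subcellular profile: a membrane contour, the compartment
#' kind, its (optional) cross-section area and the synaptic specialisations
#' on its membrane. The synaptic side is implied by the kind: axon terminals
#' are presynaptic, all other kinds (spines, shafts, main dendrites, spiny
#' branchlets, somata) postsynaptic. For dentate-gyrus granule-cell analyses
#' an optional `layer` tag (`"inner"`/`"outer"` molecular layer) refines
#' spines and spiny branchlets into the six somato-dendritic domains.
#'
#' @param profile_id Identifier, unique within a scene.
#' @param kind One of `r paste(PROFILE_KINDS, collapse = ", ")`.
#' @param membrane A [membrane_contour()].
#' @param synapses List of [synapse_interval()] objects on the membrane.
#' @param area_um2 Cross-section area in um^2. May be supplied by the
#'   annotator (partial profiles at the micrograph border cannot be closed);
#'   computed by [polygon_area()] when absent and the contour is closed.
#' @param layer Optional molecular-layer tag, `"inner"` or `"outer"`.
#' @return An object of class `compartment_profile`.
#' @export
compartment_profile <- function(profile_id, kind, membrane,
                                synapses = list(), area_um2 = NULL,
                                layer = NULL) {
  if (!is.character(profile_id) || length(profile_id) != 1L || !nzchar(profile_id))
    stop("compartment_profile: 'profile_id' must be a non-empty string")
  if (!kind %in% PROFILE_KINDS)
    stop(sprintf("compartment_profile: unknown kind '%s' (profile '%s')",
                 kind, profile_id))
  stopifnot(inherits(membrane, "membrane_contour"))
  L <- membrane$arc_length
  for (syn in synapses) {
    stopifnot(inherits(syn, "synapse_interval"))
    if (syn$wraps && !membrane$closed)
      stop(sprintf("compartment_profile: wrapping synapse on open contour (profile '%s')",
                   profile_id))
    if (max(syn$s_start_nm, syn$s_end_nm) > L + 1e-9)
      stop(sprintf(
        "compartment_profile: synapse interval exceeds contour arc length (field 's_end_nm', profile '%s')",
        profile_id))
  }
  if (is.null(area_um2)) {
    area_um2 <- if (membrane$closed) polygon_area(membrane) else NA_real_
  } else {
    area_um2 <- as.numeric(area_um2)
  }
  if (!is.na(area_um2) && area_um2 <= 0)
    stop(sprintf("compartment_profile: area_um2 must be > 0 (profile '%s')", profile_id))
  if (!is.null(layer) && !is.na(layer) && !layer %in% c("inner", "outer"))
    stop(sprintf("compartment_profile: layer must be 'inner' or 'outer' (profile '%s')",
                 profile_id))
  structure(
    list(profile_id = profile_id, kind = kind,
         side = if (kind == "axon_terminal") "presynaptic" else "postsynaptic",
         membrane = membrane, synapses = synapses, area_um2 = area_um2,
         layer = if (is.null(layer)) NA_character_ else as.character(layer)),
    class = "compartment_profile")
}

#' Somato-dendritic domain label of a profile
#'
#' Combines the compartment kind with the molecular-layer tag (when present)
#' into the domain names used by the density-gradient analysis, e.g.
#' `"spine_inner"`, `"spiny_branchlet_outer"`, `"soma"`.
#'
#' @param profile A [compartment_profile()].
#' @return Character domain label.
#' @export
domain_label <- function(profile) {
  if (is.na(profile$layer)) profile$kind
  else paste(profile$kind, profile$layer, sep = "_")
}

empty_particles <- function() {
  data.frame(particle_id = character(0), x_nm = numeric(0), y_nm = numeric(0),
             stringsAsFactors = FALSE)
}

#' Annotated ultrastructure scene
#'
#' One annotated micrograph region: a set of compartment profiles and the
#' gold-particle coordinates observed in it, together with the hippocampal
#' region, immunolabelling channel and the animal/block identifier used as
#' the unit for pooling tests and between-block SEMs.
#'
#' @param scene_id Identifier string.
#' @param region `"CA1"`, `"CA3"` or `"DG"`.
#' @param channel `"Kv4.2"` or `"Kv4.3"`.
#' @param animal_id Block identifier (one animal = one block).
#' @param profiles List of [compartment_profile()] objects with unique ids.
#' @param particles Data frame with columns `particle_id`, `x_nm`, `y_nm`
#'   (derived classification columns may be present and are preserved).
#' @return An object of class `ultrastructure_scene`.
#' @export
ultrastructure_scene <- function(scene_id, region, channel, animal_id,
                                 profiles, particles = NULL) {
  if (!region %in% SCENE_REGIONS)
    stop(sprintf("ultrastructure_scene: unknown region '%s' (field 'region')", region))
  if (!channel %in% SCENE_CHANNELS)
    stop(sprintf("ultrastructure_scene: unknown channel '%s' (field 'channel')", channel))
  stopifnot(is.list(profiles))
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  if (anyDuplicated(ids))
    stop("ultrastructure_scene: duplicate profile_id within scene")
  if (is.null(particles)) particles <- empty_particles()
  particles <- as.data.frame(particles, stringsAsFactors = FALSE)
  req <- c("particle_id", "x_nm", "y_nm")
  if (!all(req %in% names(particles)))
    stop("ultrastructure_scene: particles must have columns particle_id, x_nm, y_nm")
  if (nrow(particles) > 0 &&
      !all(is.finite(particles$x_nm) & is.finite(particles$y_nm)))
    stop("ultrastructure_scene: non-finite particle coordinate")
  if (length(profiles) > 0 && nrow(particles) > 0) {
    allv <- do.call(rbind, lapply(profiles, function(p) p$membrane$vertices))
    pad <- 1000  # nm of slack around the annotated extent
    if (any(particles$x_nm < min(allv[, 1]) - pad |
            particles$x_nm > max(allv[, 1]) + pad |
            particles$y_nm < min(allv[, 2]) - pad |
            particles$y_nm > max(allv[, 2]) + pad))
      stop("ultrastructure_scene: particle outside the scene bounding box")
  }
  structure(
    list(scene_id = as.character(scene_id), region = region, channel = channel,
         animal_id = as.character(animal_id), profiles = profiles,
         particles = particles),
    class = "ultrastructure_scene")
}

#' @export
print.ultrastructure_scene <- function(x, ...) {
  cat(sprintf("<ultrastructure_scene '%s': %s/%s, block %s, %d profiles, %d particles>\n",
              x$scene_id, x$region, x$channel, x$animal_id,
              length(x$profiles), nrow(x$particles)))
  invisible(x)
}

DERIVED_COLS <- c("profile_id", "kind", "pre_post", "location_class",
                  "proj_s_nm", "proj_d_nm", "psd_distance_nm", "synaptic_flag")

# ---- JSON scene I/O ---------------------------------------------------------

profile_to_list <- function(p) {
  out <- list(
    profile_id = p$profile_id,
    kind = p$kind,
    membrane = list(vertices = unname(p$membrane$vertices),
                    closed = p$membrane$closed),
    synapses = lapply(p$synapses, function(s) {
      sl <- list(type = s$type, s_start_nm = s$s_start_nm,
                 s_end_nm = s$s_end_nm)
      if (s$wraps) sl$wraps <- TRUE
      sl
    }))
  if (!is.na(p$area_um2)) out$area_um2 <- p$area_um2
  if (!is.na(p$layer)) out$layer <- p$layer
  out
}

particle_rows_to_list <- function(particles) {
  has_derived <- all(c("location_class") %in% names(particles))
  lapply(seq_len(nrow(particles)), function(i) {
    row <- particles[i, ]
    out <- list(particle_id = row$particle_id, x_nm = row$x_nm,
                y_nm = row$y_nm)
    if (has_derived && !is.na(row$location_class)) {
      der <- list(profile_id = row$profile_id, kind = row$kind,
                  pre_post = row$pre_post,
                  location_class = row$location_class,
                  proj_s_nm = row$proj_s_nm, proj_d_nm = row$proj_d_nm)
      if (!is.na(row$psd_distance_nm)) {
        der$psd_distance_nm <- row$psd_distance_nm
        der$synaptic_flag <- isTRUE(row$synaptic_flag)
      }
      out$derived <- der
    }
    out
  })
}

#' Write a scene to JSON (schema "goldmap-scene/1")
#'
#' Serialisation is lossless: all schema fields round-trip bit-exactly
#' through [read_scene()]. Derived particle classification, when present, is
#' written under a per-particle `"derived"` key; it is informational and is
#' recomputed (not trusted) by [classify_particles()]. An empty particle list
#' is emitted as `"particles": []`, never omitted.
#'
#' @param scene An [ultrastructure_scene()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ultrastructure_scene"))
  obj <- list(schema = SCENE_SCHEMA,
              scene_id = scene$scene_id,
              region = scene$region,
              channel = scene$channel,
              animal_id = scene$animal_id,
              profiles = lapply(scene$profiles, profile_to_list),
              particles = particle_rows_to_list(scene$particles))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, null = "null")
  invisible(path)
}

num_field <- function(x, field, where) {
  if (is.null(x))
    stop(sprintf("scene validation: missing field '%s' in %s", field, where))
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("scene data error: non-finite value in field '%s' (%s)", field, where))
  x
}

#' Read a scene from JSON (schema "goldmap-scene/1")
#'
#' Validates the file against the scene schema, reporting the offending
#' field on violation, rebuilds all domain objects (arc lengths are
#' precomputed; units are nm throughout) and preserves any `"derived"`
#' particle fields as data-frame columns.
#'
#' @param path Path to a scene JSON file.
#' @return An [ultrastructure_scene()].
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_scene: file not found: %s", path))
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(js$schema, SCENE_SCHEMA))
    stop("scene validation: missing or unsupported field 'schema' (expected 'goldmap-scene/1')")
  for (f in c("scene_id", "region", "channel", "animal_id", "profiles", "particles"))
    if (is.null(js[[f]]))
      stop(sprintf("scene validation: missing field '%s'", f))
  profiles <- lapply(js$profiles, function(p) {
    where <- sprintf("profile '%s'", p$profile_id %||% "?")
    if (is.null(p$profile_id))
      stop("scene validation: missing field 'profile_id' in profile")
    if (is.null(p$membrane) || is.null(p$membrane$vertices))
      stop(sprintf("scene validation: missing field 'membrane.vertices' in %s", where))
    verts <- t(vapply(p$membrane$vertices, function(v) {
      v <- unlist(v)
      if (length(v) != 2L || !all(is.finite(as.numeric(v))))
        stop(sprintf("scene data error: non-finite coordinate in %s", where))
      as.numeric(v)
    }, numeric(2)))
    contour <- membrane_contour(verts, closed = isTRUE(p$membrane$closed))
    synapses <- lapply(p$synapses %||% list(), function(s) {
      synapse_interval(
        s_start_nm = num_field(s$s_start_nm, "s_start_nm", where),
        s_end_nm = num_field(s$s_end_nm, "s_end_nm", where),
        type = s$type %||% stop(sprintf(
          "scene validation: missing field 'type' in synapse of %s", where)),
        wraps = isTRUE(s$wraps))
    })
    compartment_profile(
      profile_id = p$profile_id, kind = p$kind %||% stop(sprintf(
        "scene validation: missing field 'kind' in %s", where)),
      membrane = contour, synapses = synapses,
      area_um2 = if (is.null(p$area_um2)) NULL else
        num_field(p$area_um2, "area_um2", where),
      layer = p$layer)
  })
  particles <- if (length(js$particles) == 0) empty_particles() else {
    base <- data.frame(
      particle_id = vapply(js$particles, function(q) as.character(q$particle_id),
                           character(1)),
      x_nm = vapply(js$particles, function(q)
        num_field(q$x_nm, "x_nm", "particle"), numeric(1)),
      y_nm = vapply(js$particles, function(q)
        num_field(q$y_nm, "y_nm", "particle"), numeric(1)),
      stringsAsFactors = FALSE)
    if (any(vapply(js$particles, function(q) !is.null(q$derived), logical(1)))) {
      der <- lapply(js$particles, function(q) q$derived)
      base$profile_id <- vapply(der, function(d)
        if (is.null(d)) NA_character_ else as.character(d$profile_id), character(1))
      base$kind <- vapply(der, function(d)
        if (is.null(d)) NA_character_ else as.character(d$kind), character(1))
      base$pre_post <- vapply(der, function(d)
        if (is.null(d)) NA_character_ else as.character(d$pre_post), character(1))
      base$location_class <- vapply(der, function(d)
        if (is.null(d)) NA_character_ else as.character(d$location_class), character(1))
      base$proj_s_nm <- vapply(der, function(d)
        if (is.null(d)) NA_real_ else as.numeric(d$proj_s_nm), numeric(1))
      base$proj_d_nm <- vapply(der, function(d)
        if (is.null(d)) NA_real_ else as.numeric(d$proj_d_nm), numeric(1))
      base$psd_distance_nm <- vapply(der, function(d)
        if (is.null(d) || is.null(d$psd_distance_nm)) NA_real_
        else as.numeric(d$psd_distance_nm), numeric(1))
      base$synaptic_flag <- vapply(der, function(d)
        if (is.null(d) || is.null(d$synaptic_flag)) NA
        else isTRUE(d$synaptic_flag), logical(1))
    }
    base
  }
  ultrastructure_scene(scene_id = js$scene_id, region = js$region,
                       channel = js$channel, animal_id = js$animal_id,
                       profiles = profiles, particles = particles)
}

# ---- particle CSV dialect ---------------------------------------------------

#' Write particle coordinates as CSV
#'
#' Dialect: header `scene_id,particle_id,x_nm,y_nm`, UTF-8, LF line endings,
#' `.` decimal separator.
#'
#' @param scenes An [ultrastructure_scene()] or list of scenes.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_particle_csv <- function(scenes, path) {
  if (inherits(scenes, "ultrastructure_scene")) scenes <- list(scenes)
  df <- do.call(rbind, lapply(scenes, function(sc)
    data.frame(scene_id = rep(sc$scene_id, nrow(sc$particles)),
               sc$particles[, c("particle_id", "x_nm", "y_nm")],
               stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(scene_id = character(0), particle_id = character(0),
                                    x_nm = numeric(0), y_nm = numeric(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("scene_id,particle_id,x_nm,y_nm", con, sep = "\n")
  if (nrow(df) > 0)
    writeLines(sprintf("%s,%s,%s,%s", df$scene_id, df$particle_id,
                       format(df$x_nm, digits = 17, trim = TRUE, scientific = FALSE),
                       format(df$y_nm, digits = 17, trim = TRUE, scientific = FALSE)),
               con, sep = "\n")
  invisible(path)
}

#' Read a particle CSV
#'
#' @param path CSV path in the dialect of [write_particle_csv()].
#' @return Data frame with columns `scene_id`, `particle_id`, `x_nm`, `y_nm`.
#' @export
read_particle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("scene_id", "particle_id", "x_nm", "y_nm")
  if (!identical(names(df), req))
    stop("read_particle_csv: header must be 'scene_id,particle_id,x_nm,y_nm'")
  if (nrow(df) > 0 && !all(is.finite(df$x_nm) & is.finite(df$y_nm)))
    stop("read_particle_csv: non-finite coordinate")
  df
}
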