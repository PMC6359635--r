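# Synthetic ultrastructure scenes and histoblot phantoms with the
# statistical structure the analysis assumes, plus named presets frozen to
# the reference study's printed counts, percentages and densities.

# ---- contour factories ------------------------------------------------------

make_ellipse_contour <- function(cx, cy, perimeter, aspect, rot = 0, n = 40L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cos(t); y <- aspect * sin(t)
  xr <- x * cos(rot) - y * sin(rot)
  yr <- x * sin(rot) + y * cos(rot)
  p0 <- sum(sqrt(diff(c(xr, xr[1]))^2 + diff(c(yr, yr[1]))^2))
  s <- perimeter / p0
  membrane_contour(cbind(cx + s * xr, cy + s * yr), closed = TRUE)
}

make_rect_contour <- function(cx, cy, w, h) {
  membrane_contour(cbind(cx + c(-1, 1, 1, -1) * w / 2,
                         cy + c(-1, -1, 1, 1) * h / 2), closed = TRUE)
}

make_circle_contour <- function(cx, cy, r, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  membrane_contour(cbind(cx + r * cos(t), cy + r * sin(t)), closed = TRUE)
}

# ---- placement model --------------------------------------------------------

#' Particle placement model
#'
#' The generative model behind synthetic scenes: a particle is
#' membrane-associated with probability `p_membrane`; a membrane particle
#' sits on a presynaptic axon terminal with probability `p_presynaptic`; a
#' spine membrane particle lies within 300 nm (arc length) of the PSD edge
#' with probability `p_within_300`, with uniform placement inside `[0, 300)`
#' nm and uniform placement beyond 300 nm up to the spine's maximal arc
#' extent (half the extrasynaptic membrane length). Membrane particles are
#' offset perpendicular to the membrane towards the cytoplasmic face
#' (pre-embedding immunogold labels intracellular epitopes) by a uniform
#' distance within `membrane_offset_range_nm`; intracellular particles are
#' placed uniformly in the profile interior at more than
#' `intracellular_min_depth_nm` from the membrane.
#'
#' @param p_membrane Probability a particle is membrane-associated.
#' @param p_presynaptic Probability a membrane particle is presynaptic.
#' @param p_within_300 Probability a spine membrane particle lies within
#'   300 nm of the PSD edge.
#' @param domain_intensities Optional named vector of areal intensities
#'   (particles/um^2) for the six granule-cell domains.
#' @param membrane_offset_range_nm Inward offset range for membrane
#'   particles (nm); default `c(2, 20)`, comfortably inside the default
#'   25-nm membrane threshold.
#' @param intracellular_min_depth_nm Minimum membrane distance of
#'   intracellular particles (nm); default 30, beyond the threshold.
#' @return An object of class `placement_model`.
#' @export
placement_model <- function(p_membrane = 0.5, p_presynaptic = 0.01,
                            p_within_300 = 0.5, domain_intensities = NULL,
                            membrane_offset_range_nm = c(2, 20),
                            intracellular_min_depth_nm = 30) {
  for (p in c(p_membrane, p_presynaptic, p_within_300))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("placement_model: probabilities must lie in [0, 1]")
  if (!is.null(domain_intensities) && any(domain_intensities < 0))
    stop("placement_model: intensities must be >= 0")
  structure(list(p_membrane = p_membrane, p_presynaptic = p_presynaptic,
                 p_within_300 = p_within_300,
                 domain_intensities = domain_intensities,
                 membrane_offset_range_nm = membrane_offset_range_nm,
                 intracellular_min_depth_nm = intracellular_min_depth_nm),
            class = "placement_model")
}

# ---- spine field ------------------------------------------------------------

#' Generate a field of dendritic-spine profiles
#'
#' Builds `n_spines` closed, roughly elliptical spine contours (perimeter
#' uniform in `perimeter_range_nm`), each bearing exactly one asymmetric
#' synapse interval of length uniform in `psd_length_range_nm`, laid out on
#' a grid so profiles never overlap. Unless disabled, an apposed axon
#' terminal profile is built opposite each PSD, separated by a 30-nm
#' synaptic cleft. Deterministic given the RNG state (pass `seed`, or seed
#' the session RNG).
#'
#' @param n_spines Number of spines (>= 1).
#' @param seed Optional integer seed.
#' @param perimeter_range_nm Spine membrane perimeter range (nm).
#' @param psd_length_range_nm PSD interval length range (nm).
#' @param spacing_nm Grid pitch (nm).
#' @param origin Grid origin, length-2 (nm).
#' @param terminals Logical; build apposed axon terminals.
#' @param layer Optional molecular-layer tag for the spines.
#' @param id_prefix Prefix for profile ids.
#' @return List of [compartment_profile()] objects (spines, then their
#'   terminals when requested).
#' @export
generate_spine_field <- function(n_spines, seed = NULL,
                                 perimeter_range_nm = c(1500, 3000),
                                 psd_length_range_nm = c(150, 300),
                                 spacing_nm = 4000, origin = c(0, 0),
                                 terminals = TRUE, layer = NULL,
                                 id_prefix = "sp") {
  stopifnot(n_spines >= 1)
  if (!is.null(seed)) set.seed(seed)
  ncols <- ceiling(sqrt(n_spines))
  spines <- vector("list", n_spines)
  terms <- vector("list", if (terminals) n_spines else 0L)
  for (i in seq_len(n_spines)) {
    cx <- origin[1] + ((i - 1L) %% ncols) * spacing_nm
    cy <- origin[2] + ((i - 1L) %/% ncols) * spacing_nm
    contour <- make_ellipse_contour(
      cx, cy,
      perimeter = stats::runif(1, perimeter_range_nm[1], perimeter_range_nm[2]),
      aspect = stats::runif(1, 0.6, 0.95),
      rot = stats::runif(1, 0, 2 * pi))
    L <- contour$arc_length
    psd_len <- stats::runif(1, psd_length_range_nm[1], psd_length_range_nm[2])
    s0 <- stats::runif(1, 0, L - psd_len)
    syn <- synapse_interval(s0, s0 + psd_len, "asymmetric")
    spines[[i]] <- compartment_profile(
      sprintf("%s%03d", id_prefix, i), "spine", contour,
      synapses = list(syn), layer = layer)
    if (terminals) {
      ss <- s0 + seq(0, 1, length.out = 9L) * psd_len
      cp <- contour_point_at(contour, ss)
      outward <- -cp$inward
      inner <- cp$point + 30 * outward    # cleft width
      outer <- cp$point + 380 * outward   # terminal depth
      terms[[i]] <- compartment_profile(
        sprintf("%s%03d_at", id_prefix, i), "axon_terminal",
        membrane_contour(rbind(inner, outer[rev(seq_len(nrow(outer))), ]),
                         closed = TRUE))
    }
  }
  c(spines, terms)
}

# ---- particle placement -----------------------------------------------------

# TRUE where arc position s is within tol of a polyline vertex (wrap-aware).
near_vertex <- function(contour, s, tol = 3) {
  d <- abs(outer(s, contour$cum_s, "-"))
  if (contour$closed) d <- pmin(d, contour$arc_length - d)
  apply(d, 1L, min) < tol
}

# Membrane particles on one profile. If dist_model = TRUE the profile must
# carry one asymmetric synapse; arc positions are drawn by PSD distance,
# otherwise uniformly. Placements are kept >= 3 nm (arc) from polyline
# vertices so the inward offset projects back to the same membrane position.
place_membrane_on_profile <- function(profile, n, model, dist_model = FALSE) {
  contour <- profile$membrane
  L <- contour$arc_length
  if (n == 0L)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      true_distance_nm = numeric(0)))
  draw <- function(m) {
    if (dist_model) {
      syn <- Filter(function(x) x$type == "asymmetric", profile$synapses)[[1]]
      E <- L - interval_length(syn, L)
      if (model$p_within_300 < 1 && E / 2 <= 300)
        stop("place_particles: profile too small to host the requested particles")
      within <- stats::runif(m) < model$p_within_300
      d <- ifelse(within, stats::runif(m, 0, 300), stats::runif(m, 300, E / 2))
      u <- ifelse(stats::runif(m) < 0.5, d, E - d)
      list(s = (syn$s_end_nm + u) %% L, d = d)
    } else {
      list(s = stats::runif(m, 0, L), d = rep(NA_real_, m))
    }
  }
  dr <- draw(n)
  bad <- near_vertex(contour, dr$s)
  while (any(bad)) {
    rep_dr <- draw(sum(bad))
    dr$s[bad] <- rep_dr$s
    dr$d[bad] <- rep_dr$d
    bad <- near_vertex(contour, dr$s)
  }
  h <- stats::runif(n, model$membrane_offset_range_nm[1],
                    model$membrane_offset_range_nm[2])
  cp <- contour_point_at(contour, dr$s)
  pos <- cp$point + h * cp$inward
  data.frame(x_nm = pos[, 1L], y_nm = pos[, 2L], true_distance_nm = dr$d)
}

# Uniform interior points at > min_depth from the membrane.
place_interior_on_profile <- function(profile, n, model) {
  if (n == 0L)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      true_distance_nm = rep(NA_real_, 0)))
  contour <- profile$membrane
  v <- contour$vertices
  out <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(32L, 4L * (n - nrow(out)))
    x <- stats::runif(m, min(v[, 1]), max(v[, 1]))
    y <- stats::runif(m, min(v[, 2]), max(v[, 2]))
    ok <- pracma::inpolygon(x, y, v[, 1], v[, 2])
    if (any(ok)) {
      pr <- project_points(contour, cbind(x[ok], y[ok]))
      deep <- pr$d >= model$intracellular_min_depth_nm
      out <- rbind(out, cbind(x[ok][deep], y[ok][deep]))
    }
    tries <- tries + 1L
    if (tries > 200L)
      stop(sprintf("place_particles: profile '%s' too small to host requested particles",
                   profile$profile_id))
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(x_nm = out[, 1L], y_nm = out[, 2L],
             true_distance_nm = rep(NA_real_, n))
}

#' Place gold particles on a set of profiles
#'
#' Draws particle positions and ground-truth labels under a
#' [placement_model()]. Counts may be given as a single total (split by the
#' model's probabilities, rounded) or as an explicit named list with any of
#' `membrane_spine`, `membrane_shaft`, `membrane_terminal`, `intracellular`
#' -- explicit counts are honoured exactly. Spine membrane particles follow
#' the PSD-distance model; shaft and terminal membrane particles are placed
#' uniformly along the membrane; intracellular particles are placed in
#' spine/shaft interiors (area-weighted).
#'
#' @param profiles List of [compartment_profile()] objects.
#' @param model A [placement_model()].
#' @param counts Integer total or named list of category counts.
#' @param seed Optional integer seed.
#' @return List with `particles` (data frame `particle_id`, `x_nm`, `y_nm`)
#'   and `truth` (ground-truth labels: `true_class`, `true_compartment`,
#'   `true_pre_post`, `true_distance_nm`, `profile_id`, `domain`).
#' @export
place_particles <- function(profiles, model, counts, seed = NULL) {
  stopifnot(inherits(model, "placement_model"))
  if (!is.null(seed)) set.seed(seed)
  kinds <- vapply(profiles, function(p) p$kind, character(1))
  spines <- which(kinds == "spine")
  shafts <- which(kinds %in% c("dendritic_shaft", "main_dendrite",
                               "spiny_branchlet", "soma"))
  termis <- which(kinds == "axon_terminal")
  if (is.numeric(counts) && length(counts) == 1L) {
    n_total <- as.integer(counts)
    n_mem <- round(n_total * model$p_membrane)
    n_pre <- round(n_mem * model$p_presynaptic)
    counts <- list(membrane_spine = n_mem - n_pre, membrane_terminal = n_pre,
                   intracellular = n_total - n_mem)
  }
  n_sp <- counts$membrane_spine %||% 0L
  n_sh <- counts$membrane_shaft %||% 0L
  n_at <- counts$membrane_terminal %||% 0L
  n_ic <- counts$intracellular %||% 0L
  if (n_sp > 0 && length(spines) == 0) stop("place_particles: no spine profiles")
  if (n_sh > 0 && length(shafts) == 0) stop("place_particles: no shaft profiles")
  if (n_at > 0 && length(termis) == 0) stop("place_particles: no terminal profiles")

  rows <- list()
  add <- function(profile_idx, df, class, compartment) {
    p <- profiles[[profile_idx]]
    if (nrow(df) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      x_nm = df$x_nm, y_nm = df$y_nm, true_class = class,
      true_compartment = compartment,
      true_pre_post = p$side,
      true_distance_nm = df$true_distance_nm,
      profile_id = p$profile_id, domain = domain_label(p),
      stringsAsFactors = FALSE)
  }
  place_group <- function(idx_pool, n, class, membrane, dist_model = FALSE) {
    if (n == 0L) return()
    pick <- idx_pool[sample.int(length(idx_pool), n, replace = TRUE)]
    for (k in unique(pick)) {
      nk <- sum(pick == k)
      p <- profiles[[k]]
      df <- if (membrane) place_membrane_on_profile(p, nk, model, dist_model)
            else place_interior_on_profile(p, nk, model)
      add(k, df, class, p$kind)
    }
  }
  place_group(spines, n_sp, "membrane", TRUE, dist_model = TRUE)
  place_group(shafts, n_sh, "membrane", TRUE)
  place_group(termis, n_at, "membrane", TRUE)
  if (n_ic > 0L) {
    pool <- c(spines, shafts)
    if (length(pool) == 0) stop("place_particles: no interior profiles")
    w <- vapply(profiles[pool], function(p) p$area_um2, numeric(1))
    pick <- pool[sample.int(length(pool), n_ic, replace = TRUE, prob = w)]
    for (k in unique(pick)) {
      df <- place_interior_on_profile(profiles[[k]], sum(pick == k), model)
      add(k, df, "intracellular", profiles[[k]]$kind)
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth))
    return(list(particles = empty_particles(), truth = data.frame()))
  truth$particle_id <- sprintf("p%05d", seq_len(nrow(truth)))
  truth <- truth[, c("particle_id", "x_nm", "y_nm", "true_class",
                     "true_compartment", "true_pre_post",
                     "true_distance_nm", "profile_id", "domain")]
  list(particles = truth[, c("particle_id", "x_nm", "y_nm")], truth = truth)
}

# ---- frozen presets ---------------------------------------------------------

# Frozen reference parameters (printed counts, percentages and densities of
# the emulated study conditions). A checksum test asserts these never drift.
.goldmap_presets <- list(
  `ca1-kv42` = list(type = "spine_field", region = "CA1", channel = "Kv4.2",
                    n_total = 1355L, p_membrane = 0.5381, p_post = 0.9882,
                    n_spines = 93L, n_mem_spine = 354L, p_within_300 = 0.47),
  `ca3-kv42` = list(type = "spine_field", region = "CA3", channel = "Kv4.2",
                    n_total = 1223L, p_membrane = 0.5895, p_post = 0.9886,
                    n_spines = 93L, n_mem_spine = 313L, p_within_300 = 0.46),
  `dg-kv42` = list(type = "spine_field", region = "DG", channel = "Kv4.2",
                   n_total = 1037L, p_membrane = 0.5969, p_post = 0.9894,
                   n_spines = 93L, n_mem_spine = 376L, p_within_300 = 0.45),
  `ca3-kv43` = list(type = "spine_field", region = "CA3", channel = "Kv4.3",
                    n_total = 3075L, p_membrane = 0.5890, p_post = 0.9828,
                    n_spines = 93L, n_mem_spine = 371L, p_within_300 = 0.51),
  `dg-kv43` = list(type = "spine_field", region = "DG", channel = "Kv4.3",
                   n_total = 2607L, p_membrane = 0.5953, p_post = 0.9831,
                   n_spines = 93L, n_mem_spine = 389L, p_within_300 = 0.53),
  `dg-granule-kv42` = list(type = "granule", region = "DG", channel = "Kv4.2",
                           intensities = c(soma = 0.09, main_dendrite = 0.87,
                                           spiny_branchlet_inner = 2.57,
                                           spiny_branchlet_outer = 2.28,
                                           spine_inner = 8.47,
                                           spine_outer = 8.23)),
  `dg-granule-kv43` = list(type = "granule", region = "DG", channel = "Kv4.3",
                           intensities = c(soma = 0.04, main_dendrite = 0.74,
                                           spiny_branchlet_inner = 2.12,
                                           spiny_branchlet_outer = 1.99,
                                           spine_inner = 7.39,
                                           spine_outer = 7.92)))

#' Parameters of a named synthetic preset
#'
#' @param name Preset name; see [goldmap_presets()].
#' @return List of frozen preset parameters.
#' @export
goldmap_preset <- function(name) {
  p <- .goldmap_presets[[name]]
  if (is.null(p))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(.goldmap_presets), collapse = ", ")))
  p
}

#' Available synthetic presets
#'
#' @return Character vector of preset names.
#' @export
goldmap_presets <- function() names(.goldmap_presets)

# Deterministic count decomposition of a spine-field preset: membrane count
# from the membrane fraction, presynaptic count from the postsynaptic
# fraction of membrane particles, the printed membrane-spine count taken as
# the spine subset, the remainder of postsynaptic membrane on shafts.
preset_counts <- function(pp) {
  n_mem <- round(pp$n_total * pp$p_membrane)
  n_pre <- round(n_mem * (1 - pp$p_post))
  n_post <- n_mem - n_pre
  stopifnot(n_post >= pp$n_mem_spine)
  list(membrane_spine = pp$n_mem_spine,
       membrane_shaft = n_post - pp$n_mem_spine,
       membrane_terminal = n_pre,
       intracellular = pp$n_total - n_mem)
}

granule_profiles_one_animal <- function() {
  profs <- list(
    compartment_profile("gc_soma1", "soma", make_circle_contour(0, 0, 2330)),
    compartment_profile("gc_soma2", "soma", make_circle_contour(6000, 0, 2330)),
    compartment_profile("gc_md1", "main_dendrite",
                        make_rect_contour(12000, 0, 1500, 5000)),
    compartment_profile("gc_sbi1", "spiny_branchlet",
                        make_rect_contour(16000, 0, 500, 4000), layer = "inner"),
    compartment_profile("gc_sbi2", "spiny_branchlet",
                        make_rect_contour(18000, 0, 500, 4000), layer = "inner"),
    compartment_profile("gc_sbo1", "spiny_branchlet",
                        make_rect_contour(20000, 0, 500, 4000), layer = "outer"),
    compartment_profile("gc_sbo2", "spiny_branchlet",
                        make_rect_contour(22000, 0, 500, 4000), layer = "outer"))
  sp_in <- generate_spine_field(20, origin = c(0, 8000), terminals = FALSE,
                                layer = "inner", id_prefix = "spi")
  sp_out <- generate_spine_field(20, origin = c(0, 32000), terminals = FALSE,
                                 layer = "outer", id_prefix = "spo")
  c(profs, sp_in, sp_out)
}

#' Build the scenes of a named preset
#'
#' Generates the full synthetic dataset of a preset at a given seed: three
#' scenes, one per synthetic animal/block (mirroring a three-animal,
#' multi-block sampling design so the pooling rule is exercised), with
#' ground-truth labels attached as the `"truth"` attribute.
#'
#' Spine-field presets (`ca1-kv42`, `ca3-kv42`, `dg-kv42`, `ca3-kv43`,
#' `dg-kv43`) emit 93 spines with apposed axon terminals plus dendritic
#' shafts, and place the frozen particle counts: the printed membrane-spine
#' count exactly, the remaining postsynaptic membrane particles on shafts,
#' the presynaptic share on terminals, and the intracellular remainder in
#' spine/shaft interiors. Granule-cell presets (`dg-granule-kv42`,
#' `dg-granule-kv43`) emit the six somato-dendritic domains and draw
#' membrane particle counts per profile as Poisson with the frozen areal
#' intensities.
#'
#' @param name Preset name (see [goldmap_presets()]).
#' @param seed Integer seed; scenes are bit-reproducible given
#'   `(name, seed)`.
#' @return List of three [ultrastructure_scene()] objects with attributes
#'   `truth` (data frame) and `preset` (parameter list).
#' @export
build_preset_scene <- function(name, seed = 1L) {
  pp <- goldmap_preset(name)
  set.seed(as.integer(seed))
  animals <- c("b1", "b2", "b3")
  scenes <- vector("list", 3L)
  truth_all <- list()
  if (pp$type == "spine_field") {
    per_animal <- rep(pp$n_spines %/% 3L, 3L)
    per_animal[seq_len(pp$n_spines %% 3L)] <- per_animal[seq_len(pp$n_spines %% 3L)] + 1L
    # profiles per animal: spine field + 4 shafts below the grid
    prof_sets <- lapply(seq_len(3L), function(ai) {
      field <- generate_spine_field(per_animal[ai])
      grid_rows <- ceiling(per_animal[ai] / ceiling(sqrt(per_animal[ai])))
      y_sh <- grid_rows * 4000 + 4000
      shafts <- lapply(1:4, function(j)
        compartment_profile(sprintf("sh%d", j), "dendritic_shaft",
                            make_rect_contour((j - 1) * 6000, y_sh + 2000,
                                              1000, 4000)))
      c(field, shafts)
    })
    model <- placement_model(p_membrane = pp$p_membrane,
                             p_presynaptic = 1 - pp$p_post,
                             p_within_300 = pp$p_within_300)
    counts <- preset_counts(pp)
    # split category counts across animals in proportion to their spines
    split_count <- function(n) {
      as.vector(stats::rmultinom(1, n, prob = per_animal / sum(per_animal)))
    }
    spl <- lapply(counts, split_count)
    for (ai in seq_len(3L)) {
      placed <- place_particles(
        prof_sets[[ai]], model,
        counts = list(membrane_spine = spl$membrane_spine[ai],
                      membrane_shaft = spl$membrane_shaft[ai],
                      membrane_terminal = spl$membrane_terminal[ai],
                      intracellular = spl$intracellular[ai]))
      sid <- sprintf("%s-s%d-%s", name, as.integer(seed), animals[ai])
      placed$truth$particle_id <- sprintf("%s_%s", animals[ai],
                                          placed$truth$particle_id)
      placed$particles$particle_id <- placed$truth$particle_id
      scenes[[ai]] <- ultrastructure_scene(
        sid, pp$region, pp$channel, animals[ai], prof_sets[[ai]],
        placed$particles)
      placed$truth <- cbind(scene_id = sid, placed$truth,
                            stringsAsFactors = FALSE)
      truth_all[[ai]] <- placed$truth
    }
  } else {
    model <- placement_model()
    for (ai in seq_len(3L)) {
      profs <- granule_profiles_one_animal()
      doms <- vapply(profs, domain_label, character(1))
      n_per_prof <- vapply(seq_along(profs), function(k) {
        lambda <- pp$intensities[[doms[k]]] * profs[[k]]$area_um2
        stats::rpois(1, lambda)
      }, integer(1))
      rows <- list()
      for (k in seq_along(profs)) {
        if (n_per_prof[k] == 0L) next
        df <- place_membrane_on_profile(profs[[k]], n_per_prof[k], model)
        rows[[length(rows) + 1L]] <- data.frame(
          x_nm = df$x_nm, y_nm = df$y_nm, true_class = "membrane",
          true_compartment = profs[[k]]$kind,
          true_pre_post = profs[[k]]$side,
          true_distance_nm = NA_real_,
          profile_id = profs[[k]]$profile_id, domain = doms[k],
          stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
      sid <- sprintf("%s-s%d-%s", name, as.integer(seed), animals[ai])
      if (is.null(truth)) {
        particles <- NULL
      } else {
        truth$particle_id <- sprintf("%s_p%05d", animals[ai], seq_len(nrow(truth)))
        particles <- truth[, c("particle_id", "x_nm", "y_nm")]
        truth <- cbind(scene_id = sid,
                       truth[, c("particle_id", "x_nm", "y_nm", "true_class",
                                 "true_compartment", "true_pre_post",
                                 "true_distance_nm", "profile_id", "domain")],
                       stringsAsFactors = FALSE)
      }
      scenes[[ai]] <- ultrastructure_scene(sid, pp$region, pp$channel,
                                           animals[ai], profs, particles)
      truth_all[[ai]] <- truth
    }
  }
  structure(scenes, truth = do.call(rbind, truth_all), preset = pp)
}

# ---- histoblot phantom ------------------------------------------------------

#' Generate a histoblot phantom image
#'
#' Builds a grayscale phantom: labelled rectangular regions with known grey
#' levels on a uniform background, optional Gaussian pixel noise, a
#' matching circular-cursor ROI set (one region cursor centered in each
#' rectangle, eight background cursors on plain background), and the
#' ground-truth corrected densities.
#'
#' @param region_levels Named numeric vector of true region grey levels
#'   (0-255 arbitrary units).
#' @param noise_sd Gaussian pixel noise SD (grey levels).
#' @param seed Optional integer seed.
#' @param background_level Background grey level.
#' @param pixel_size_mm Physical pixel size (mm); default 0.01.
#' @param cursor_diameter_mm Cursor diameter (mm); default 0.10.
#' @return List with `image` (matrix), `roi_set`, `truth` (data frame with
#'   `region`, `level`, `expected_corrected`) and `background_level`.
#' @export
generate_histoblot_phantom <- function(region_levels = c(hippocampus = 150,
                                                         cortex = 90,
                                                         cerebellum = 180,
                                                         thalamus = 120,
                                                         septum = 60,
                                                         caudate_putamen = 100),
                                       noise_sd = 0, seed = NULL,
                                       background_level = 30,
                                       pixel_size_mm = 0.01,
                                       cursor_diameter_mm = 0.10) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(region_levels)
  if (n < 1) stop("generate_histoblot_phantom: no regions")
  ncols <- min(3L, n)
  nrows <- ceiling(n / ncols)
  rw <- 60L; rh <- 40L; gap <- 20L
  width <- ncols * (rw + gap) + gap
  height <- nrows * (rh + gap) + gap + 40L  # bottom strip for background ROIs
  rects <- data.frame(
    name = names(region_levels),
    x0 = gap + ((seq_len(n) - 1L) %% ncols) * (rw + gap),
    y0 = gap + ((seq_len(n) - 1L) %/% ncols) * (rh + gap),
    level = as.numeric(region_levels), stringsAsFactors = FALSE)
  rects$x1 <- rects$x0 + rw - 1L
  rects$y1 <- rects$y0 + rh - 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && rects$x0[i] <= rects$x1[j] && rects$x1[i] >= rects$x0[j] &&
        rects$y0[i] <= rects$y1[j] && rects$y1[i] >= rects$y0[j])
      stop("generate_histoblot_phantom: regions overlapping")
  }
  img <- matrix(background_level, nrow = height, ncol = width)
  for (i in seq_len(n))
    img[rects$y0[i]:rects$y1[i], rects$x0[i]:rects$x1[i]] <- rects$level[i]
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow = height)
  bg_y <- height - 15
  bg_x <- round(seq(15, width - 15, length.out = 8L))
  rois <- rbind(
    data.frame(name = rects$name, cx = (rects$x0 + rects$x1) / 2,
               cy = (rects$y0 + rects$y1) / 2, kind = "region",
               stringsAsFactors = FALSE),
    data.frame(name = sprintf("bg%d", 1:8), cx = bg_x, cy = bg_y,
               kind = "background", stringsAsFactors = FALSE))
  rs <- roi_set("phantom", pixel_size_mm, rois, cursor_diameter_mm)
  list(image = img, roi_set = rs,
       truth = data.frame(region = rects$name, level = rects$level,
                          expected_corrected = pmax(0, rects$level - background_level),
                          stringsAsFactors = FALSE),
       background_level = background_level)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Values are clamped to 0-255 and scaled to the PNG range.
#'
#' @param image Numeric matrix in 0-255 units.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_histoblot_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}
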