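# The three quantification schemes: particle classification and compartment
# percentages, PSD-edge arc-distance binning, and per-domain density
# gradients.

#' Quantification configuration
#'
#' @param membrane_threshold_nm Maximum point-to-contour distance (nm) for a
#'   particle to be called membrane-associated. Default 25 nm, reflecting the
#'   localisation accuracy of silver-enhanced 1.4-nm gold particles relative
#'   to the antigen; the pre-embedding method places particles on the
#'   cytoplasmic face of the membrane.
#' @param bin_width_nm Width of PSD-distance histogram bins (nm); 60-nm
#'   membrane segments by default.
#' @param proximity_radius_nm Radius (nm) of the "near-PSD" annulus summed by
#'   [fraction_within()]; must be an integer multiple of `bin_width_nm`.
#' @param density_mode Which per-domain density to report by default:
#'   `"areal"` (particles/um^2 of profile cross-section), `"linear"`
#'   (particles/um of membrane) or `"both"`. Both are always computed.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(membrane_threshold_nm = 25, bin_width_nm = 60,
                         proximity_radius_nm = 300,
                         density_mode = c("areal", "linear", "both")) {
  density_mode <- match.arg(density_mode)
  if (membrane_threshold_nm <= 0 || bin_width_nm <= 0 || proximity_radius_nm <= 0)
    stop("quant_config: all thresholds must be strictly positive")
  k <- proximity_radius_nm / bin_width_nm
  if (abs(k - round(k)) > 1e-9)
    stop("quant_config: proximity_radius_nm must be an integer multiple of bin_width_nm")
  structure(list(membrane_threshold_nm = membrane_threshold_nm,
                 bin_width_nm = bin_width_nm,
                 proximity_radius_nm = proximity_radius_nm,
                 density_mode = density_mode),
            class = "quant_config")
}

profile_bbox <- function(p) {
  v <- p$membrane$vertices
  c(min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L]))
}

#' Classify gold particles in a scene
#'
#' Assigns each particle to a compartment profile and derives its
#' classification. Assignment is by polygon containment (a particle inside a
#' closed contour belongs to that profile); particles contained in no profile
#' are assigned to the profile with the nearest membrane if that membrane is
#' within `membrane_threshold_nm`, and are otherwise flagged unassignable and
#' excluded (their count is reported in a message and recorded in the
#' returned scene). Ties are resolved towards the lower `profile_id`.
#'
#' A particle is membrane-associated iff its projection distance onto its
#' profile's membrane is at most the threshold, and intracellular otherwise.
#' The pre/postsynaptic side follows the profile kind. For membrane particles
#' on spines or dendritic shafts bearing at least one asymmetric synapse, the
#' arc distance from the projected position to the nearest PSD edge is
#' computed; particles projecting inside the PSD are retained with distance 0
#' and `synaptic_flag = TRUE`.
#'
#' @param scene An [ultrastructure_scene()].
#' @param cfg A [quant_config()].
#' @return The scene with derived particle columns (`profile_id`, `kind`,
#'   `pre_post`, `location_class`, `proj_s_nm`, `proj_d_nm`,
#'   `psd_distance_nm`, `synaptic_flag`) filled in and an `n_unassigned`
#'   field recording excluded particles.
#' @export
classify_particles <- function(scene, cfg = quant_config()) {
  stopifnot(inherits(scene, "ultrastructure_scene"),
            inherits(cfg, "quant_config"))
  pts <- scene$particles
  m <- nrow(pts)
  pts$profile_id <- NA_character_
  pts$kind <- NA_character_
  pts$pre_post <- NA_character_
  pts$location_class <- NA_character_
  pts$proj_s_nm <- NA_real_
  pts$proj_d_nm <- NA_real_
  pts$psd_distance_nm <- NA_real_
  pts$synaptic_flag <- NA
  scene$n_unassigned <- 0L
  if (m == 0L) {
    scene$particles <- pts
    scene$classified <- TRUE
    return(scene)
  }
  ord <- order(vapply(scene$profiles, function(p) p$profile_id, character(1)))
  profs <- scene$profiles[ord]
  assigned <- rep(NA_integer_, m)
  # containment pass
  for (k in seq_along(profs)) {
    p <- profs[[k]]
    if (!p$membrane$closed) next
    bb <- profile_bbox(p)
    un <- which(is.na(assigned) &
                  pts$x_nm >= bb[1] & pts$x_nm <= bb[2] &
                  pts$y_nm >= bb[3] & pts$y_nm <= bb[4])
    if (length(un) == 0) next
    v <- p$membrane$vertices
    inside <- pracma::inpolygon(pts$x_nm[un], pts$y_nm[un], v[, 1L], v[, 2L],
                                boundary = TRUE)
    assigned[un[inside]] <- k
  }
  # nearest-membrane fallback for uncontained particles
  un <- which(is.na(assigned))
  if (length(un) > 0) {
    best_d <- rep(Inf, length(un))
    best_k <- rep(NA_integer_, length(un))
    for (k in seq_along(profs)) {
      pr <- project_points(profs[[k]]$membrane,
                           cbind(pts$x_nm[un], pts$y_nm[un]))
      better <- pr$d < best_d - 1e-9  # strict: ties keep the lower profile_id
      best_d[better] <- pr$d[better]
      best_k[better] <- k
    }
    ok <- best_d <= cfg$membrane_threshold_nm
    assigned[un[ok]] <- best_k[ok]
    scene$n_unassigned <- sum(!ok)
    if (scene$n_unassigned > 0)
      message(sprintf("classify_particles: %d unassignable particle(s) excluded in scene '%s'",
                      scene$n_unassigned, scene$scene_id))
  }
  # projection and derived fields, per profile
  for (k in unique(assigned[!is.na(assigned)])) {
    p <- profs[[k]]
    idx <- which(assigned == k)
    pr <- project_points(p$membrane, cbind(pts$x_nm[idx], pts$y_nm[idx]))
    pts$profile_id[idx] <- p$profile_id
    pts$kind[idx] <- p$kind
    pts$pre_post[idx] <- p$side
    pts$proj_s_nm[idx] <- pr$s
    pts$proj_d_nm[idx] <- pr$d
    mem <- pr$d <= cfg$membrane_threshold_nm
    pts$location_class[idx] <- ifelse(mem, "membrane", "intracellular")
    if (p$kind %in% c("spine", "dendritic_shaft") &&
        any(vapply(p$synapses, function(s) s$type == "asymmetric", logical(1)))) {
      memidx <- idx[mem]
      if (length(memidx) > 0) {
        nd <- nearest_psd_distance(p, pts$proj_s_nm[memidx])
        pts$psd_distance_nm[memidx] <- nd$distance
        pts$synaptic_flag[memidx] <- nd$synaptic
      }
    }
  }
  scene$particles <- pts
  scene$classified <- TRUE
  scene$quant_config <- cfg
  scene
}

as_scene_list <- function(scenes) {
  if (inherits(scenes, "ultrastructure_scene")) scenes <- list(scenes)
  if (!is.list(scenes) || length(scenes) == 0)
    stop("expected one or more ultrastructure scenes")
  for (sc in scenes) {
    stopifnot(inherits(sc, "ultrastructure_scene"))
    if (!isTRUE(sc$classified))
      stop("scenes must be classified first (see classify_particles)")
  }
  scenes
}

classified_particles <- function(scenes) {
  do.call(rbind, lapply(scenes, function(sc) {
    df <- sc$particles
    df <- df[!is.na(df$profile_id), , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    cbind(data.frame(scene_id = sc$scene_id, region = sc$region,
                     channel = sc$channel, animal_id = sc$animal_id,
                     stringsAsFactors = FALSE), df)
  }))
}

#' Compartment breakdown of classified particles
#'
#' Aggregates particle counts over scenes per hippocampal region and
#' channel, by synaptic side (pre/post), location class
#' (membrane/intracellular) and compartment kind, and computes the summary
#' percentages with the denominator conventions of the study design:
#' membrane vs intracellular percentages are taken over all assigned
#' particles, while the post- vs presynaptic split is taken over membrane
#' particles only. Denominators are recorded explicitly in the result.
#'
#' @param scenes A classified scene or list of classified scenes.
#' @param cfg A [quant_config()] (recorded in the result).
#' @return An object of class `compartment_breakdown` with elements `cells`
#'   (counts and percent-of-total per region/channel/side/location/
#'   compartment), `summary` (per region/channel totals and the headline
#'   percentages; `zero_membrane_denominator` flags region/channel cells
#'   with no membrane particles, whose pre/post percentages are `NA`), and
#'   `denominators` describing the conventions.
#' @export
compartment_breakdown <- function(scenes, cfg = quant_config()) {
  scenes <- as_scene_list(scenes)
  df <- classified_particles(scenes)
  if (is.null(df) || nrow(df) == 0)
    stop("compartment_breakdown: no classified particles")
  cells <- stats::aggregate(
    list(count = rep(1L, nrow(df))),
    by = list(region = df$region, channel = df$channel,
              pre_post = df$pre_post, location_class = df$location_class,
              compartment = df$kind),
    FUN = sum)
  tot <- stats::aggregate(list(total = cells$count),
                          by = list(region = cells$region, channel = cells$channel),
                          FUN = sum)
  cells <- merge(cells, tot, by = c("region", "channel"))
  cells$pct_of_total <- 100 * cells$count / cells$total
  cells <- cells[order(cells$region, cells$channel, cells$pre_post,
                       cells$location_class, cells$compartment), ]
  rownames(cells) <- NULL

  summ <- lapply(split(df, list(df$region, df$channel), drop = TRUE), function(g) {
    n <- nrow(g)
    nmem <- sum(g$location_class == "membrane")
    npost <- sum(g$location_class == "membrane" & g$pre_post == "postsynaptic")
    data.frame(region = g$region[1], channel = g$channel[1],
               total_particles = n, n_membrane = nmem,
               n_intracellular = n - nmem,
               membrane_pct = 100 * nmem / n,
               intracellular_pct = 100 * (n - nmem) / n,
               n_membrane_postsynaptic = npost,
               postsynaptic_pct_of_membrane = if (nmem > 0) 100 * npost / nmem else NA_real_,
               presynaptic_pct_of_membrane = if (nmem > 0) 100 * (nmem - npost) / nmem else NA_real_,
               zero_membrane_denominator = nmem == 0,
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  structure(list(
    cells = cells, summary = summ,
    denominators = list(
      membrane_intracellular = "all assigned particles",
      post_pre = "membrane-associated particles only"),
    config = cfg),
    class = "compartment_breakdown")
}

#' @export
print.compartment_breakdown <- function(x, ...) {
  cat("Compartment breakdown (percent denominators:",
      "membrane/intracellular over all particles;",
      "post/pre over membrane particles)\n")
  print(x$summary)
  invisible(x)
}

#' PSD-distance table for membrane particles on spines
#'
#' One row per membrane-associated particle located on a dendritic-spine
#' profile bearing at least one asymmetric synapse, with the arc distance
#' (nm) from the particle's projected membrane position to the nearest PSD
#' edge. Particles projecting inside the PSD are retained with distance 0.
#'
#' @param scenes A classified scene or list of classified scenes.
#' @param cfg A [quant_config()].
#' @return Data frame with columns `scene_id`, `animal_id`, `particle_id`,
#'   `profile_id`, `distance_nm`, `synaptic_flag`.
#' @export
psd_distance_table <- function(scenes, cfg = quant_config()) {
  scenes <- as_scene_list(scenes)
  df <- classified_particles(scenes)
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(scene_id = character(0), animal_id = character(0),
                      particle_id = character(0), profile_id = character(0),
                      distance_nm = numeric(0), synaptic_flag = logical(0)))
  keep <- df$kind == "spine" & df$location_class == "membrane" &
    !is.na(df$psd_distance_nm)
  out <- df[keep, c("scene_id", "animal_id", "particle_id", "profile_id",
                    "psd_distance_nm", "synaptic_flag"), drop = FALSE]
  names(out)[names(out) == "psd_distance_nm"] <- "distance_nm"
  rownames(out) <- NULL
  out
}

#' Relative-frequency histogram of PSD distances
#'
#' Bins arc distances from the PSD edge into half-open bins
#' `[0, w), [w, 2w), ...` of width `bin_width_nm` starting at the edge of
#' the synaptic specialisation, and returns relative frequencies. The
#' half-open convention makes boundary handling deterministic: a distance
#' exactly at a bin edge falls in the upper bin.
#'
#' @param distances Numeric vector of distances (nm), or the data frame
#'   returned by [psd_distance_table()].
#' @param cfg A [quant_config()].
#' @param n_spines Optional number of spines contributing (metadata).
#' @return An object of class `distance_histogram`: data frame with columns
#'   `bin_lo`, `bin_hi`, `count`, `rel_freq`, plus attributes `n_particles`,
#'   `n_spines` and `bin_width_nm`.
#' @export
distance_histogram <- function(distances, cfg = quant_config(), n_spines = NA) {
  if (is.data.frame(distances)) distances <- distances$distance_nm
  if (length(distances) == 0)
    stop("distance_histogram: no distances")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distance_histogram: distances must be finite and >= 0")
  w <- cfg$bin_width_nm
  idx <- floor(distances / w) + 1L
  nbin <- max(idx, cfg$proximity_radius_nm / w)
  counts <- tabulate(idx, nbins = nbin)
  out <- data.frame(bin_lo = (seq_len(nbin) - 1L) * w,
                    bin_hi = seq_len(nbin) * w,
                    count = counts,
                    rel_freq = counts / length(distances))
  structure(out, class = c("distance_histogram", "data.frame"),
            n_particles = length(distances), n_spines = n_spines,
            bin_width_nm = w)
}

#' Fraction of particles within the near-PSD annulus
#'
#' Sum of the first `proximity_radius_nm / bin_width_nm` bin frequencies of
#' a PSD-distance histogram. Under the half-open bin convention this equals
#' direct counting of distances strictly below the radius (a distance
#' exactly at the radius falls outside).
#'
#' @param hist A [distance_histogram()].
#' @param cfg A [quant_config()]; `proximity_radius_nm` must be divisible by
#'   the histogram's bin width.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_within <- function(hist, cfg = quant_config()) {
  stopifnot(inherits(hist, "distance_histogram"))
  w <- attr(hist, "bin_width_nm")
  k <- cfg$proximity_radius_nm / w
  if (abs(k - round(k)) > 1e-9)
    stop("fraction_within: proximity radius not divisible by histogram bin width")
  k <- as.integer(round(k))
  sum(hist$rel_freq[seq_len(min(k, nrow(hist)))])
}

DOMAIN_ORDER <- c("soma", "main_dendrite", "spiny_branchlet_inner",
                  "spiny_branchlet_outer", "spine_inner", "spine_outer",
                  "spine", "dendritic_shaft", "spiny_branchlet",
                  "main_dendrite_inner", "main_dendrite_outer", "axon_terminal")

#' Per-domain membrane-particle densities
#'
#' Pools membrane-associated particle counts, profile cross-section areas
#' and membrane lengths per somato-dendritic domain (see [domain_label()])
#' over all scenes, and computes both the areal density (particles/um^2 of
#' profile area, as plotted for the granule-cell gradient) and the linear
#' density (particles/um of membrane). Between-block variability is
#' summarised by the SEM of per-block areal densities, with `animal_id` as
#' the block unit (the average from one animal counts as one n).
#'
#' @param scenes A classified scene or list of classified scenes.
#' @param cfg A [quant_config()]; `density_mode` selects the default
#'   reported density (both are always present in the result).
#' @return An object of class `domain_density`: data frame with columns
#'   `domain`, `particle_count`, `total_area_um2`, `total_membrane_um`,
#'   `density_areal`, `density_linear`, `sem_areal`, `n_blocks`.
#' @export
domain_density <- function(scenes, cfg = quant_config()) {
  scenes <- as_scene_list(scenes)
  prof <- do.call(rbind, lapply(scenes, function(sc)
    do.call(rbind, lapply(sc$profiles, function(p)
      data.frame(scene_id = sc$scene_id, animal_id = sc$animal_id,
                 profile_id = p$profile_id, domain = domain_label(p),
                 area_um2 = p$area_um2,
                 membrane_um = p$membrane$arc_length / 1000,
                 stringsAsFactors = FALSE)))))
  df <- classified_particles(scenes)
  mem <- df[df$location_class == "membrane", , drop = FALSE]
  key <- paste(mem$scene_id, mem$profile_id)
  pkey <- paste(prof$scene_id, prof$profile_id)
  mem$domain <- prof$domain[match(key, pkey)]

  out <- lapply(split(prof, prof$domain), function(pg) {
    dom <- pg$domain[1]
    cnt <- sum(mem$domain == dom, na.rm = TRUE)
    area <- sum(pg$area_um2, na.rm = TRUE)
    memb <- sum(pg$membrane_um)
    if (area <= 0) {
      warning(sprintf("domain_density: domain '%s' has zero total area; excluded", dom))
      return(NULL)
    }
    blocks <- unique(pg$animal_id)
    per_block <- vapply(blocks, function(b) {
      a <- sum(pg$area_um2[pg$animal_id == b], na.rm = TRUE)
      if (a <= 0) return(NA_real_)
      sum(mem$domain == dom & mem$animal_id == b, na.rm = TRUE) / a
    }, numeric(1))
    per_block <- per_block[!is.na(per_block)]
    data.frame(domain = dom, particle_count = cnt, total_area_um2 = area,
               total_membrane_um = memb,
               density_areal = cnt / area,
               density_linear = cnt / memb,
               sem_areal = if (length(per_block) > 1)
                 stats::sd(per_block) / sqrt(length(per_block)) else NA_real_,
               n_blocks = length(per_block),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ord <- order(match(out$domain, DOMAIN_ORDER))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("domain_density", "data.frame"),
            density_mode = cfg$density_mode)
}
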