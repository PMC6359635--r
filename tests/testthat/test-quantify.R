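# Particle classification, compartment percentages, PSD-distance binning
# and domain densities.

test_that("classification separates membrane from intracellular at the threshold", {
  sc <- classify_particles(
    square_spine_scene(particle_df(c(12, 500, 976), c(500, 500, 500))))
  p <- sc$particles
  expect_equal(p$location_class, c("membrane", "intracellular", "membrane"))
  expect_equal(p$kind, rep("spine", 3))
  expect_equal(p$pre_post, rep("postsynaptic", 3))
  # membrane particle gets a PSD distance, intracellular does not
  expect_false(any(is.na(p$psd_distance_nm[c(1, 3)])))
  expect_true(is.na(p$psd_distance_nm[2]))

  # a tighter threshold reclassifies the 12-nm particle
  sc2 <- classify_particles(
    square_spine_scene(particle_df(12, 500)),
    quant_config(membrane_threshold_nm = 10))
  expect_equal(sc2$particles$location_class, "intracellular")
})

test_that("particles outside every contour fall back to the nearest membrane", {
  # 10 nm outside the square: not contained, but within the 25-nm threshold
  sc <- classify_particles(square_spine_scene(particle_df(-10, 500)))
  expect_equal(sc$particles$location_class, "membrane")
  expect_equal(sc$particles$profile_id, "sp1")
  expect_equal(sc$n_unassigned, 0L)

  # far outside: unassignable, excluded with a logged count
  expect_message(
    sc2 <- classify_particles(square_spine_scene(particle_df(-900, 500))),
    "unassignable")
  expect_equal(sc2$n_unassigned, 1L)
  expect_true(is.na(sc2$particles$location_class))
})

test_that("compartment breakdown reproduces a hand count with its denominators", {
  profs <- list(
    compartment_profile("sp1", "spine", square_contour(),
                        synapses = list(synapse_interval(200, 300, "asymmetric"))),
    compartment_profile("sh1", "dendritic_shaft",
                        square_contour(origin = c(3000, 0))),
    compartment_profile("at1", "axon_terminal",
                        square_contour(origin = c(6000, 0))))
  sc <- ultrastructure_scene("s", "CA1", "Kv4.2", "b1", profs,
                             particle_df(c(12, 3500, 6012), c(500, 500, 500)))
  bd <- compartment_breakdown(classify_particles(sc))
  s <- bd$summary
  expect_equal(s$total_particles, 3)
  expect_equal(s$membrane_pct, 200 / 3)
  expect_equal(s$intracellular_pct, 100 / 3)
  expect_equal(s$postsynaptic_pct_of_membrane, 50)
  expect_equal(s$presynaptic_pct_of_membrane, 50)
  # cell percentages over all cells sum to 100
  expect_equal(sum(bd$cells$pct_of_total), 100, tolerance = 1e-9)
  expect_equal(sum(bd$cells$count), 3)
})

test_that("all-intracellular input flags the zero membrane denominator", {
  sc <- classify_particles(square_spine_scene(particle_df(500, 500)))
  bd <- compartment_breakdown(sc)
  expect_true(bd$summary$zero_membrane_denominator)
  expect_true(is.na(bd$summary$postsynaptic_pct_of_membrane))
  expect_equal(bd$summary$membrane_pct, 0)
  expect_error(compartment_breakdown(list()), "scenes")
})

test_that("breakdown percentages are invariant to scene order and splitting", {
  scenes <- lapply(build_preset_scene("ca1-kv42", seed = 4), classify_particles)
  ref <- compartment_breakdown(scenes)$summary
  perm <- compartment_breakdown(scenes[c(3, 1, 2)])$summary
  expect_equal(perm, ref)
  # split the first scene's particles into two scenes
  a <- scenes[[1]]; b <- scenes[[1]]
  n <- nrow(a$particles)
  a$particles <- a$particles[seq_len(n %/% 2), ]
  b$particles <- b$particles[(n %/% 2 + 1):n, ]
  b$scene_id <- "split-half"
  split_bd <- compartment_breakdown(c(list(a, b), scenes[2:3]))$summary
  expect_equal(split_bd, ref)
})

test_that("classification recovers generator ground truth away from boundaries", {
  scenes <- build_preset_scene("ca1-kv42", seed = 3)
  truth <- attr(scenes, "truth")
  cl <- lapply(scenes, classify_particles)
  df <- do.call(rbind, lapply(cl, function(s)
    cbind(scene_id = s$scene_id, s$particles)))
  m <- merge(truth, df, by = c("scene_id", "particle_id"))
  expect_equal(nrow(m), 1355)
  expect_equal(m$location_class, m$true_class)
  expect_equal(m$profile_id.y, m$profile_id.x)
  expect_equal(m$pre_post, m$true_pre_post)
  # PSD distances match the generator to better than 1 nm
  sp <- m[m$true_class == "membrane" & m$true_compartment == "spine", ]
  expect_lt(max(abs(sp$psd_distance_nm - sp$true_distance_nm)), 1)
})

test_that("PSD-distance table keeps synaptic particles at distance 0", {
  sc <- square_spine_scene(particle_df(c(240, 390, 12), c(12, 12, 500)))
  # arc positions ~240 (inside PSD [200,300]), ~390 (90 nm past the edge)
  tab <- psd_distance_table(classify_particles(sc))
  tab <- tab[order(tab$particle_id), ]
  expect_equal(nrow(tab), 3)
  expect_equal(tab$distance_nm[1], 0)
  expect_true(tab$synaptic_flag[1])
  expect_equal(tab$distance_nm[2], 90, tolerance = 1e-6)
  # particle 3 projects onto the left edge (s = 3500); the shorter way
  # around the closed contour reaches the PSD edge at s = 200 in 700 nm
  expect_equal(tab$distance_nm[3], 700)
})

test_that("distance histogram uses half-open 60-nm bins", {
  h <- distance_histogram(c(0, 59.9, 60, 300))
  expect_equal(h$rel_freq[1], 0.5)   # 0 and 59.9
  expect_equal(h$rel_freq[2], 0.25)  # 60 goes up
  expect_equal(h$rel_freq[6], 0.25)  # 300 goes into [300, 360)
  expect_equal(sum(h$rel_freq), 1, tolerance = 1e-9)
  expect_equal(attr(h, "n_particles"), 4)

  h1 <- distance_histogram(rep(10, 7))
  expect_equal(h1$rel_freq[1], 1.0)
  expect_error(distance_histogram(numeric(0)), "no distances")
})

test_that("uniform distances fill bins uniformly within binomial error", {
  set.seed(9)
  d <- runif(1e4, 0, 600)
  h <- distance_histogram(d)
  se <- sqrt(0.1 * 0.9 / 1e4)
  expect_true(all(abs(h$rel_freq[1:10] - 0.1) <= 3 * se))
})

test_that("fraction_within sums the first five bins and matches direct counting", {
  # uniform histogram over 10 bins, radius 300 -> 0.5
  d <- (0:9) * 60 + 30
  expect_equal(fraction_within(distance_histogram(d)), 0.5)
  h1 <- distance_histogram(rep(10, 3))
  expect_equal(fraction_within(h1), 1.0)

  set.seed(21)
  d <- c(runif(500, 0, 700), 300, 300)  # exact boundary values fall outside
  expect_identical(fraction_within(distance_histogram(d)), mean(d < 300))
  expect_error(
    fraction_within(distance_histogram(d),
                    quant_config(proximity_radius_nm = 250, bin_width_nm = 50)),
    "divisible")
})

test_that("quant_config validates its fields", {
  expect_error(quant_config(membrane_threshold_nm = 0), "positive")
  expect_error(quant_config(proximity_radius_nm = 290), "multiple")
})

test_that("domain densities: unit case, pooling and the area scaling law", {
  # one soma of 10 um^2 (rect 2000 x 5000 nm) with one membrane particle
  soma <- compartment_profile(
    "so1", "soma",
    membrane_contour(rbind(c(0, 0), c(2000, 0), c(2000, 5000), c(0, 5000))))
  expect_equal(soma$area_um2, 10)
  sc <- ultrastructure_scene("s", "DG", "Kv4.2", "b1", list(soma),
                             particle_df(10, 2500))
  dd <- domain_density(classify_particles(sc))
  expect_equal(dd$domain, "soma")
  expect_equal(dd$density_areal, 0.1)
  expect_equal(dd$density_linear, 1 / 14)  # 14 um of membrane
  expect_equal(dd$particle_count, 1L)

  # doubling every profile area (counts fixed) halves every areal density
  scenes <- lapply(build_preset_scene("dg-granule-kv42", 5), classify_particles)
  d1 <- domain_density(scenes)
  doubled <- lapply(scenes, function(s) {
    s$profiles <- lapply(s$profiles, function(p) {
      p$area_um2 <- 2 * p$area_um2
      p
    })
    s
  })
  d2 <- domain_density(doubled)
  expect_equal(d2$density_areal, d1$density_areal / 2)
  expect_equal(d2$particle_count, d1$particle_count)
  # between-block SEM present with 3 blocks
  expect_equal(unique(d1$n_blocks), 3L)
  expect_true(all(is.finite(d1$sem_areal)))
})
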