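# Scene generator, placement model and frozen presets.

test_that("spine fields honour their geometric contracts and determinism", {
  f1 <- generate_spine_field(93, seed = 1)
  spines <- Filter(function(p) p$kind == "spine", f1)
  terms <- Filter(function(p) p$kind == "axon_terminal", f1)
  expect_length(spines, 93)
  expect_length(terms, 93)
  for (sp in spines) {
    expect_length(sp$synapses, 1)
    expect_equal(sp$synapses[[1]]$type, "asymmetric")
    per <- arc_length(sp$membrane)
    expect_gte(per, 1500); expect_lte(per, 3000)
    expect_true(sp$membrane$closed)
  }
  f2 <- generate_spine_field(93, seed = 1)
  expect_identical(lapply(f1, function(p) p$membrane$vertices),
                   lapply(f2, function(p) p$membrane$vertices))
})

test_that("particle placement honours count contracts and the degenerate model", {
  field <- generate_spine_field(10, seed = 2)
  model <- placement_model(p_within_300 = 1)
  placed <- place_particles(field, model,
                            counts = list(membrane_spine = 354), seed = 3)
  expect_equal(nrow(placed$particles), 354)
  expect_true(all(placed$truth$true_distance_nm < 300))
  expect_true(all(placed$truth$true_class == "membrane"))

  # mixed categories are honoured exactly
  shaft <- compartment_profile("sh1", "dendritic_shaft",
                               square_contour(origin = c(-8000, 0)))
  placed2 <- place_particles(c(field, list(shaft)), placement_model(),
                             counts = list(membrane_spine = 20,
                                           membrane_shaft = 7,
                                           membrane_terminal = 3,
                                           intracellular = 10), seed = 4)
  expect_equal(table(placed2$truth$true_class)[["membrane"]], 30)
  expect_equal(table(placed2$truth$true_class)[["intracellular"]], 10)
  expect_equal(sum(placed2$truth$true_compartment == "axon_terminal"), 3)
})

test_that("preset parameters are frozen at the reference values", {
  expect_identical(sort(goldmap_presets()),
                   sort(c("ca1-kv42", "ca3-kv42", "dg-kv42", "ca3-kv43",
                          "dg-kv43", "dg-granule-kv42", "dg-granule-kv43")))
  p <- goldmap_preset("ca1-kv42")
  expect_identical(p[c("n_total", "n_spines", "n_mem_spine")],
                   list(n_total = 1355L, n_spines = 93L, n_mem_spine = 354L))
  expect_identical(p[c("p_membrane", "p_post", "p_within_300")],
                   list(p_membrane = 0.5381, p_post = 0.9882,
                        p_within_300 = 0.47))
  expect_identical(goldmap_preset("ca3-kv42")$n_mem_spine, 313L)
  expect_identical(goldmap_preset("dg-kv42")$n_mem_spine, 376L)
  q <- goldmap_preset("ca3-kv43")
  expect_identical(q[c("n_total", "n_mem_spine", "p_membrane", "p_post",
                       "p_within_300")],
                   list(n_total = 3075L, n_mem_spine = 371L,
                        p_membrane = 0.5890, p_post = 0.9828,
                        p_within_300 = 0.51))
  expect_identical(goldmap_preset("dg-kv43")$p_within_300, 0.53)
  expect_identical(
    goldmap_preset("dg-granule-kv42")$intensities,
    c(soma = 0.09, main_dendrite = 0.87, spiny_branchlet_inner = 2.57,
      spiny_branchlet_outer = 2.28, spine_inner = 8.47, spine_outer = 8.23))
  expect_identical(goldmap_preset("dg-granule-kv43")$intensities[["soma"]],
                   0.04)
  expect_error(goldmap_preset("nope"), "available")
})

test_that("preset scenes are bit-reproducible and carry exact counts", {
  s1 <- build_preset_scene("ca1-kv42", seed = 7)
  s2 <- build_preset_scene("ca1-kv42", seed = 7)
  expect_identical(lapply(s1, function(s) s$particles),
                   lapply(s2, function(s) s$particles))
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))
  truth <- attr(s1, "truth")
  expect_equal(nrow(truth), 1355)
  expect_equal(sum(truth$true_class == "membrane" &
                     truth$true_compartment == "spine"), 354)
  expect_equal(sum(vapply(s1, function(s)
    sum(vapply(s$profiles, function(p) p$kind == "spine", logical(1))),
    integer(1))), 93)
  # three blocks for the pooling rule
  expect_equal(sort(unique(vapply(s1, function(s) s$animal_id, ""))),
               c("b1", "b2", "b3"))
})

test_that("within-300 placement matches its Bernoulli parameter across seeds", {
  p <- goldmap_preset("ca1-kv42")
  fr <- vapply(1:6, function(seed) {
    truth <- attr(build_preset_scene("ca1-kv42", seed), "truth")
    d <- truth$true_distance_nm[!is.na(truth$true_distance_nm)]
    mean(d < 300)
  }, numeric(1))
  se_mean <- sqrt(p$p_within_300 * (1 - p$p_within_300) / p$n_mem_spine) / sqrt(6)
  expect_lt(abs(mean(fr) - p$p_within_300), 3 * se_mean)
})

test_that("granule preset draws Poisson counts on the six domains", {
  scenes <- build_preset_scene("dg-granule-kv42", seed = 2)
  truth <- attr(scenes, "truth")
  expect_identical(sort(unique(truth$domain)),
                   sort(names(goldmap_preset("dg-granule-kv42")$intensities)))
  expect_true(all(truth$true_class == "membrane"))
  # soma pooled area is ~100 um^2 per seed (>= 2000 um^2 over 20 seeds)
  soma_area <- sum(vapply(scenes, function(s)
    sum(vapply(s$profiles, function(p)
      if (p$kind == "soma") p$area_um2 else 0, numeric(1))), numeric(1)))
  expect_gt(soma_area, 95)
})

test_that("histoblot phantom is deterministic given the seed", {
  p1 <- generate_histoblot_phantom(noise_sd = 2, seed = 9)
  p2 <- generate_histoblot_phantom(noise_sd = 2, seed = 9)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$roi_set$rois, p2$roi_set$rois)
})
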