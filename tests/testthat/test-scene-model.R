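# Domain types, invariants and scene/CSV serialisation.

test_that("contour construction enforces invariants and precomputes arc length", {
  sq <- square_contour()
  expect_equal(arc_length(sq), 4000)
  expect_true(sq$closed)

  expect_error(membrane_contour(matrix(c(0, 0), ncol = 2)), "at least 2")
  expect_error(membrane_contour(rbind(c(0, 0), c(0, 0), c(1, 1))), "distinct")
  expect_error(membrane_contour(rbind(c(0, 0), c(NA, 1))), "non-finite")

  open <- membrane_contour(rbind(c(0, 0), c(1000, 0), c(1000, 500)),
                           closed = FALSE)
  expect_equal(arc_length(open), 1500)

  # arc length equals the sum of segment lengths (relative error <= 1e-6)
  set.seed(11)
  for (i in 1:20) {
    ct <- random_contour(15, closed = i %% 2 == 0)
    v <- ct$vertices
    idx <- if (ct$closed) rbind(cbind(1:nrow(v), c(2:nrow(v), 1)))
           else cbind(1:(nrow(v) - 1), 2:nrow(v))
    manual <- sum(sqrt(rowSums((v[idx[, 2], ] - v[idx[, 1], ])^2)))
    expect_lt(abs(arc_length(ct) - manual) / manual, 1e-6)
  }
})

test_that("synapse intervals validate their bounds and wrapping flag", {
  expect_error(synapse_interval(300, 300, "asymmetric"), "length > 0")
  expect_error(synapse_interval(300, 200, "asymmetric"), "exceed")
  expect_error(synapse_interval(100, 200, "asymmetric", wraps = TRUE),
               "wrapping")
  wrapped <- synapse_interval(3800, 100, "asymmetric", wraps = TRUE)
  expect_true(wrapped$wraps)
  # interval must fit on the parent contour
  expect_error(
    compartment_profile("x", "spine", square_contour(),
                        synapses = list(synapse_interval(3900, 4100, "asymmetric"))),
    "s_end_nm")
})

test_that("polygon area: unit shapes, orientation and vertex-order invariance", {
  expect_equal(polygon_area(square_contour()), 1.0)
  tri <- membrane_contour(rbind(c(0, 0), c(1000, 0), c(0, 2000)))
  expect_equal(polygon_area(tri), 1.0)
  expect_error(polygon_area(membrane_contour(rbind(c(0, 0), c(1, 1)),
                                             closed = FALSE)),
               "unsupported")

  set.seed(7)
  poly <- random_contour(12)
  a <- polygon_area(poly)
  v <- poly$vertices
  expect_equal(polygon_area(membrane_contour(v[rev(seq_len(nrow(v))), ])), a)
  rot <- rbind(v[5:nrow(v), ], v[1:4, ])  # cyclic rotation
  expect_equal(polygon_area(membrane_contour(rot)), a)
})

test_that("polygon area agrees with a rejection-sampling oracle on a random 12-gon", {
  set.seed(42)
  poly <- random_contour(12)
  v <- poly$vertices
  n <- 1e6
  x <- runif(n, min(v[, 1]), max(v[, 1]))
  y <- runif(n, min(v[, 2]), max(v[, 2]))
  box <- (max(v[, 1]) - min(v[, 1])) * (max(v[, 2]) - min(v[, 2])) / 1e6
  mc <- mean(pracma::inpolygon(x, y, v[, 1], v[, 2])) * box
  expect_lt(abs(polygon_area(poly) - mc) / mc, 0.01)
})

test_that("scene JSON round-trip is lossless for all schema fields", {
  spine <- compartment_profile(
    "sp1", "spine", square_contour(),
    synapses = list(synapse_interval(200, 300, "asymmetric"),
                    synapse_interval(3800, 100, "symmetric", wraps = TRUE)),
    layer = "inner")
  border <- compartment_profile(
    "sh1", "dendritic_shaft",
    membrane_contour(rbind(c(2000, 0), c(3000, 0), c(3000, 700)),
                     closed = FALSE),
    area_um2 = 0.42)
  sc <- ultrastructure_scene("s1", "CA3", "Kv4.3", "b2",
                             list(spine, border),
                             particle_df(c(500, 2990.25), c(12.5, 100)))
  f <- tempfile(fileext = ".json")
  write_scene(sc, f)
  back <- read_scene(f)
  expect_equal(back$scene_id, "s1")
  expect_equal(back$region, "CA3")
  expect_equal(back$animal_id, "b2")
  expect_equal(back$profiles[[1]]$membrane$vertices,
               sc$profiles[[1]]$membrane$vertices)
  expect_equal(back$profiles[[1]]$synapses, sc$profiles[[1]]$synapses)
  expect_equal(back$profiles[[1]]$layer, "inner")
  expect_equal(back$profiles[[2]]$area_um2, 0.42)
  expect_false(back$profiles[[2]]$membrane$closed)
  expect_equal(back$particles, sc$particles)
  # second round trip is bit-stable
  f2 <- tempfile(fileext = ".json")
  write_scene(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("derived particle fields serialise under 'derived' and empty lists are explicit", {
  sc <- classify_particles(
    square_spine_scene(particle_df(c(12, 500), c(500, 500))))
  f <- tempfile(fileext = ".json")
  write_scene(sc, f)
  raw <- paste(readLines(f), collapse = "")
  expect_match(raw, "\"derived\"")
  back <- read_scene(f)
  expect_equal(back$particles$location_class, c("membrane", "intracellular"))
  expect_equal(back$particles$psd_distance_nm, sc$particles$psd_distance_nm)

  empty <- square_spine_scene()
  fe <- tempfile(fileext = ".json")
  write_scene(empty, fe)
  expect_match(paste(readLines(fe), collapse = ""), "\"particles\":\\s*\\[\\]")
  expect_equal(nrow(read_scene(fe)$particles), 0)
})

test_that("scene validation names the offending field", {
  sc <- square_spine_scene(particle_df(10, 10))
  f <- tempfile(fileext = ".json")
  write_scene(sc, f)
  js <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  js$profiles[[1]]$synapses[[1]]$s_end_nm <- 4100  # beyond arc length
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(js, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scene(f2), "s_end_nm")

  js$schema <- NULL
  jsonlite::write_json(js, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scene(f2), "schema")

  js2 <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  js2$particles[[1]]$x_nm <- "oops"
  jsonlite::write_json(js2, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scene(f2), "non-finite|x_nm")
})

test_that("particle CSV dialect round-trips with the exact header", {
  sc <- square_spine_scene(particle_df(c(10.5, 990), c(1, 2)))
  f <- tempfile(fileext = ".csv")
  write_particle_csv(sc, f)
  lines <- readLines(f)
  expect_identical(lines[1], "scene_id,particle_id,x_nm,y_nm")
  back <- read_particle_csv(f)
  expect_equal(back$x_nm, c(10.5, 990))
  expect_equal(back$scene_id, rep("sq1", 2))
  # wrong header is rejected
  writeLines(c("a,b,c,d", "1,2,3,4"), f)
  expect_error(read_particle_csv(f), "header")
})

test_that("scenes reject duplicate profiles and out-of-extent particles", {
  p1 <- compartment_profile("a", "spine", square_contour())
  expect_error(
    ultrastructure_scene("s", "CA1", "Kv4.2", "b1", list(p1, p1)),
    "duplicate")
  expect_error(
    ultrastructure_scene("s", "CA1", "Kv4.2", "b1", list(p1),
                         particle_df(99999, 0)),
    "bounding box")
})
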