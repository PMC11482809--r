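test_that("ideal helix placement matches the matrix-composition oracle", {
  ref <- small_protomer()
  m <- build_ideal_filament(-167, 27, 3, reference = ref)
  step <- screw_transform(-167, 27)
  oracle <- compose_transform(step, step)
  expect_lt(max(abs(m$transforms[[3]]$rotation - oracle$rotation)), 1e-12)
  expect_lt(max(abs(m$transforms[[3]]$translation - oracle$translation)),
            1e-12)

  m0 <- build_ideal_filament(0, 27, 5, reference = ref)
  for (k in 1:5)
    expect_equal(m0$transforms[[k]]$rotation, diag(3))
  expect_equal(subunit_origins(m0)[, 3], (0:4) * 27)
})

test_that("curved generator degenerates to the ideal helix", {
  ref <- small_protomer()
  a <- make_curved_filament(curved_filament_spec(n_subunits = 10),
                            reference = ref)
  b <- build_ideal_filament(-167, 27, 10, reference = ref)
  expect_lt(max_frame_dev(a, b), 1e-9)
  expect_error(curved_filament_spec(n_subunits = 15, arc_radius = 100),
               "too tight")
})

test_that("decoration patterns produce the stated occupancy sets", {
  ref <- small_protomer()
  m23 <- build_ideal_filament(-167, 27, 23, reference = ref)

  expect_length(decorate(m23, decoration_state(23, "bare")), 0)
  expect_length(decorate(m23, decoration_state(23, "full")), 23)

  ss0 <- decoration_state(23, "single_strand", strand = 0)
  ss1 <- decoration_state(23, "single_strand", strand = 1)
  expect_equal(sum(ss0$occupied), 12)  # ceiling(23/2) on even parity
  expect_equal(sum(ss1$occupied), 11)
  expect_true(all(which(ss0$occupied) %% 2 == 1))  # 0-based even indices

  # Bernoulli occupancy concentrates near p (binomial oracle)
  pr <- decoration_state(1000, "partial_random", p_occupied = 0.5,
                         seed = 42)
  expect_lt(abs(mean(pr$occupied) - 0.5), 0.05)
  # determinism under the seed
  pr2 <- decoration_state(1000, "partial_random", p_occupied = 0.5,
                          seed = 42)
  expect_identical(pr$occupied, pr2$occupied)
  expect_error(decoration_state(5, "full", orientation_id = 4),
               "orientation_id")
})

test_that("rasterization integrates to the weighted point count", {
  v1 <- rasterize(matrix(0, 1, 3), voxel_size = 0.5, sigma = 1)
  expect_equal(volume_integral(v1), 1, tolerance = 0.01)

  # doubling sigma preserves the integral
  v2 <- rasterize(matrix(0, 1, 3), voxel_size = 0.5, sigma = 2)
  expect_equal(volume_integral(v2), 1, tolerance = 0.01)

  # linearity: two superposed identical models double the volume
  pts <- matrix(rnorm(15, sd = 3), 5, 3)
  gs_src <- rasterize(pts, voxel_size = 1, sigma = 1.5)
  both <- rasterize(list(pts, pts), voxel_size = 1, sigma = 1.5,
                    grid_spec = list(dim = dim(gs_src$grid),
                                     origin = gs_src$origin))
  expect_equal(both$grid, 2 * gs_src$grid, tolerance = 1e-12)

  expect_error(rasterize(list()), "empty")
  expect_error(rasterize(pts, voxel_size = 4, sigma = 1), "sigma")
})

test_that("library enumeration matches its configured factorization", {
  cfg <- library_config(curvatures = 0, orientations = 1, n_partial = 1,
                        n_subunits = 5, voxel_size = 4, sigma = 3)
  lib <- make_library(cfg)
  expect_length(lib, 3)  # bare, full, one partial
  expect_setequal(vapply(lib, function(e) e$meta$pattern, character(1)),
                  c("bare", "full", "partial_random"))

  # the default design enumerates the full 312-volume library
  expect_equal(library_size(library_config()), 312)
  # formula holds across designs, including bare dedup
  cfg2 <- library_config(curvatures = c(0, 1e-4), orientations = 1:3,
                         n_partial = 2, n_subunits = 5, dedup_bare = TRUE)
  expect_length(make_library(cfg2), library_size(cfg2))
})

test_that("library regeneration from config and seeds is voxel-identical", {
  cfg <- library_config(curvatures = c(0, 2e-4), orientations = 1:2,
                        n_partial = 1, n_subunits = 6,
                        voxel_size = 4, sigma = 3, seed = 9L)
  a <- make_library(cfg)
  b <- make_library(cfg)
  expect_identical(lapply(a, function(e) e$volume$grid),
                   lapply(b, function(e) e$volume$grid))
  expect_identical(lapply(a, `[[`, "meta"), lapply(b, `[[`, "meta"))

  # MRC + JSON sidecars round-trip
  d <- withr::local_tempdir()
  paths <- write_library(a[1:2], d)
  expect_length(list.files(d), 4)
  back <- read_volume(file.path(d, "volume_0001.mrc"))
  expect_equal(back$grid, a[[1]]$volume$grid, tolerance = 1e-6)
})

test_that("trajectory frames ramp curvature and convex-strand decoration", {
  frames <- make_trajectory(n_frames = 4, max_curvature = 2e-4,
                            n_subunits = 9, voxel_size = 3.5, sigma = 2.5)
  expect_length(frames, 4)
  # frame 0: straight, zero complex amplitude
  expect_equal(frames[[1]]$weight, 0)
  expect_lt(max(axis_curvature(frames[[1]]$model)$curvature), 1e-6)
  # final frame: full weight, curvature at the configured maximum
  last <- frames[[4]]
  expect_equal(last$weight, 1)
  expect_equal(median(axis_curvature(last$model)$curvature), 2e-4,
               tolerance = 0.1 * 2e-4)
  # decoration sits on the convex strand only
  expect_equal(last$state$pattern, "single_strand")
  expect_equal(last$state$strand, convex_strand(last$model))
  # frames share one grid
  dims <- lapply(frames, function(f) dim(f$volume$grid))
  expect_length(unique(dims), 1)
})
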