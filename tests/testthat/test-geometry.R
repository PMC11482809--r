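test_that("ideal filament reports its generating twist and rise everywhere", {
  m <- build_ideal_filament(-167, 27, 37, reference = small_protomer())
  prof <- local_twist_rise(m, window = 10)
  expect_equal(nrow(prof), 36)
  expect_lt(max(abs(prof$twist + 167)), 1e-6)
  expect_lt(max(abs(prof$rise - 27)), 1e-6)
  expect_equal(sum(prof$central), 10)
  expect_equal(prof$strand, prof$index %% 2L)

  # generic parameters, not just the canonical ones
  for (tw in c(12.5, -90, 179)) {
    m2 <- build_ideal_filament(tw, 13.7, 8, reference = small_protomer())
    p2 <- local_twist_rise(m2, window = 4)
    expect_lt(max(abs(p2$twist - tw)), 1e-6)
    expect_lt(max(abs(p2$rise - 13.7)), 1e-6)
  }
})

test_that("two-subunit translation model yields a pure-rise step", {
  ref <- small_protomer()
  m <- filament_model(list(rigid_transform(),
                           rigid_transform(diag(3), c(0, 0, 27))), ref)
  s <- screw_decompose(step_transform(m, 0, 1))
  expect_equal(s$twist, 0)
  expect_equal(s$rise, 27, tolerance = 1e-9)
})

test_that("same-strand (two-subunit) screw matches the composition oracle", {
  m <- build_ideal_filament(-167, 27, 9, reference = small_protomer())
  one <- step_transform(m, 3, 4)
  two <- step_transform(m, 3, 5)
  oracle <- compose_transform(one, one)  # composing the one-step screw
  expect_lt(max(abs(two$rotation - oracle$rotation)), 1e-8)
  s <- screw_decompose(two)
  expect_equal(s$twist, 26, tolerance = 1e-6)  # 2*(-167) + 360
  expect_equal(s$rise, 54, tolerance = 1e-6)
  # identity case
  id <- step_transform(m, 4, 4)
  expect_equal(id$rotation, diag(3))
  expect_equal(id$translation, c(0, 0, 0))
})

test_that("filament extension triples the model minus the overlaps", {
  ref <- small_protomer()
  m15 <- build_ideal_filament(-167, 27, 15, reference = ref)
  ext <- extend_filament(m15, overlap = 4)
  expect_equal(n_subunits(ext), 37)  # 3*15 - 2*4

  m5 <- build_ideal_filament(100, 10, 5, reference = ref)
  expect_equal(n_subunits(extend_filament(m5, overlap = 1)), 13)
  expect_error(extend_filament(m5, overlap = 3), "more than")

  # extending an exact helix preserves the lattice exactly
  prof <- local_twist_rise(ext, window = 10)
  expect_lt(max(abs(prof$twist + 167)), 1e-6)
  expect_lt(max(abs(prof$rise - 27)), 1e-6)
  expect_equal(sum(prof$central), 10)
})

test_that("strand summaries separate antisymmetric per-strand deltas", {
  ref <- small_protomer()
  # uniform filament: strand means agree
  sp0 <- strand_profile(local_twist_rise(
    build_ideal_filament(-167, 27, 15, reference = ref)))
  expect_lt(abs(sp0$strand_means$mean_twist[1] -
                  sp0$strand_means$mean_twist[2]), 1e-6)

  # antisymmetric rise delta: means split by 2*delta around the mean
  md <- make_curved_filament(
    curved_filament_spec(n_subunits = 15, strand_rise_delta = 0.5),
    reference = ref)
  sp <- strand_profile(local_twist_rise(md))
  expect_equal(sp$strand_means$mean_rise[sp$strand_means$strand == 0], 27.5,
               tolerance = 1e-6)
  expect_equal(sp$strand_means$mean_rise[sp$strand_means$strand == 1], 26.5,
               tolerance = 1e-6)
  expect_equal(unname(sp$overall["rise"]), 27, tolerance = 1e-6)

  # strand twists (-165, -169): the under-twisted strand is detected
  mt <- make_curved_filament(
    curved_filament_spec(n_subunits = 15, strand_twist_delta = 2),
    reference = ref)
  spt <- strand_profile(local_twist_rise(mt))
  tw <- spt$strand_means$mean_twist
  expect_equal(tw[1], -165, tolerance = 0.1)
  expect_equal(tw[2], -169, tolerance = 0.1)
  expect_lt(abs(tw[1]), abs(tw[2]))  # strand 0 is under-twisted
})

test_that("curvature recovers the generating arc radius and vanishes when straight", {
  ref <- small_protomer()
  straight <- build_ideal_filament(-167, 27, 15, reference = ref)
  expect_lt(max(axis_curvature(straight)$curvature), 1e-6)

  bent <- make_curved_filament(
    curved_filament_spec(n_subunits = 15, arc_radius = 5000),
    reference = ref)
  cv <- axis_curvature(bent)
  expect_equal(median(cv$curvature), 2e-4, tolerance = 0.1 * 2e-4)
})

test_that("lattice measurements are invariant under global rigid motion", {
  ref <- small_protomer()
  m <- make_curved_filament(
    curved_filament_spec(n_subunits = 13, arc_radius = 8000,
                         strand_twist_delta = 1.5, strand_rise_delta = 0.3),
    reference = ref)
  g <- random_transform(77)
  mg <- transform_model(m, g)

  p1 <- local_twist_rise(m, window = 8)
  p2 <- local_twist_rise(mg, window = 8)
  expect_lt(max(abs(p1$twist - p2$twist)), 1e-8)
  expect_lt(max(abs(p1$rise - p2$rise)), 1e-8)

  c1 <- axis_curvature(m); c2 <- axis_curvature(mg)
  expect_lt(max(abs(c1$curvature - c2$curvature)), 1e-9)
})

test_that("short models and degenerate references are rejected", {
  ref <- small_protomer()
  m <- build_ideal_filament(-167, 27, 5, reference = ref)
  expect_error(local_twist_rise(m, window = 10), "window")
  line <- cbind(1:5, 0, 0)
  expect_error(filament_model(list(rigid_transform(), rigid_transform()),
                              line), "collinear")
})
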