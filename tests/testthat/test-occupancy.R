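# One small decorated filament reused across occupancy tests.
occ_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- reference_protomer()
      m <- build_ideal_filament(-167, 27, 8, reference = ref)
      st <- decoration_state(8, "full")
      placed <- decorate(m, st)
      actin <- lapply(seq_len(8) - 1L, function(i) placed_coords(m, i))
      vol <- rasterize(c(actin, placed), voxel_size = 3, sigma = 1.5)
      cache <<- list(model = m, placed = placed, actin = actin, vol = vol,
                     placements = site_placements(m, 1))
    }
    cache
  }
})

test_that("zone partition is exclusive, exhaustive and conserves integrals", {
  fx <- occ_fixture()
  part <- split_map(fx$vol, fx$placements, zone_radius = 3)
  expect_identical(dim(part$labels), dim(fx$vol$grid))

  # per-label sums equal the masked-union sum exactly (partition property)
  labs <- sort(unique(as.integer(part$labels)))
  per_label <- vapply(labs[labs > 0],
                      function(l) sum(fx$vol$grid[part$labels == l]),
                      numeric(1))
  union_sum <- sum(fx$vol$grid[part$labels > 0])
  expect_equal(sum(per_label), union_sum, tolerance = 1e-12)
  expect_error(split_map(fx$vol, fx$placements, zone_radius = 0),
               "positive")
})

test_that("well-separated blobs get clean disjoint labels", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(30, 0, 0), 1, 3)
  vol <- rasterize(list(a, b), voxel_size = 1, sigma = 1.5)
  fake <- structure(list(list(index = 0L, strand = 0L, actin = a,
                              complex = b)), class = "site_placements")
  part <- split_map(vol, fake, zone_radius = 4)
  fil <- which(part$labels == 1L, arr.ind = TRUE)
  cx <- which(part$labels == 2L, arr.ind = TRUE)
  expect_gt(nrow(fil), 0); expect_gt(nrow(cx), 0)
  # labels sit on opposite sides of the midplane between the blobs
  xs <- vol$origin[1] + (seq_len(dim(vol$grid)[1]) - 1) * vol$voxel_size
  expect_true(all(xs[fil[, 1]] < 15))
  expect_true(all(xs[cx[, 1]] > 15))
})

test_that("each complex zone captures nearly all of its site's density", {
  fx <- occ_fixture()
  part <- split_map(fx$vol, fx$placements, zone_radius = 3)
  gs <- list(dim = dim(fx$vol$grid), origin = fx$vol$origin)
  for (i in c(0L, 3L, 7L)) {
    own <- rasterize(fx$placed[[paste0("site_", i)]], voxel_size = 3,
                     sigma = 1.5, grid_spec = gs)
    captured <- sum(own$grid[part$labels == (2L + i)]) / sum(own$grid)
    expect_gte(captured, 0.95)
  }
})

test_that("occupancy normalizes to the strongest site and tracks amplitude", {
  ref <- reference_protomer()
  m <- build_ideal_filament(-167, 27, 4, reference = ref)
  placed <- decorate(m, decoration_state(4, "full"))
  actin <- lapply(0:3, function(i) placed_coords(m, i))
  # site amplitudes 1, 0.5, 1, 0.25
  amps <- c(1, 0.5, 1, 0.25)
  vol <- rasterize(c(actin, placed), voxel_size = 3, sigma = 1.5,
                   weights = c(rep(1, 4), amps))
  part <- split_map(vol, site_placements(m, 1), zone_radius = 3)
  occ <- site_occupancy(vol, part)
  expect_equal(max(occ$occupancy), 1)
  expect_equal(occ$occupancy[2], 0.5, tolerance = 0.05)
  expect_equal(occ$occupancy[4], 0.25, tolerance = 0.05)
  expect_true(all(occ$occupancy >= 0))

  # all-equal sites: every occupancy is within rasterization error of 1
  fx <- occ_fixture()
  occ_full <- site_occupancy(fx$vol,
                             split_map(fx$vol, fx$placements, 3))
  expect_equal(max(occ_full$occupancy), 1)
  expect_gt(min(occ_full$occupancy), 0.9)
})

test_that("local site refinement recovers a perturbed placement", {
  ref <- reference_protomer()
  m <- build_ideal_filament(-167, 27, 5, reference = ref)
  placed <- decorate(m, decoration_state(5, "full"))
  actin <- lapply(0:4, function(i) placed_coords(m, i))
  vol <- rasterize(c(actin, placed), voxel_size = 2, sigma = 2.5)
  truth <- site_placements(m, 1)

  # unperturbed initial placement stays put
  same <- fit_site_models(vol, structure(truth[3], class = "site_placements"),
                          sigma = 2.5)
  expect_lt(sqrt(sum(same[[1]]$shift^2)), 0.05)

  # 2 A / 4 degree perturbation is pulled back onto the truth
  pert <- truth[3]
  R <- rotation_about_axis(c(0, 0, 1), 4)
  ctr <- colMeans(rbind(pert[[1]]$actin, pert[[1]]$complex))
  mv <- function(p) sweep(sweep(p, 2, ctr) %*% t(R), 2, ctr + c(2, 0, 0), "+")
  pert[[1]]$actin <- mv(pert[[1]]$actin)
  pert[[1]]$complex <- mv(pert[[1]]$complex)
  ref3 <- fit_site_models(vol, structure(pert, class = "site_placements"),
                          sigma = 2.5)
  resid <- ref3[[1]]$actin - truth[[3]]$actin
  expect_lt(sqrt(mean(rowSums(resid^2))), 0.2)
  expect_false(ref3[[1]]$flagged)
})

test_that("strand means expose single-strand decoration and the ramp", {
  frames <- make_trajectory(n_frames = 5, max_curvature = 2e-4,
                            n_subunits = 11)
  profs <- lapply(frames, function(fr) {
    pl <- site_placements(fr$model,
                          orientation_id = fr$state$orientation_id)
    site_occupancy(fr$volume, split_map(fr$volume, pl, 3), fr$frame)
  })

  # per-frame normalization: max is exactly 1; on a fully decorated frame
  # the bare strand stays below 5 percent
  last <- profs[[5]]
  expect_equal(max(last$occupancy), 1)
  conv <- frames[[5]]$state$strand
  expect_lt(max(last$occupancy[last$strand != conv]), 0.05)
  expect_gt(mean(last$occupancy[last$strand == conv]) /
              mean(last$occupancy[last$strand != conv]), 10)

  # across frames: decorated-strand mean follows the generator ramp
  sm <- strand_frame_means(normalize_across_frames(profs))
  dec <- sm$mean_occupancy[sm$strand == conv]
  expect_equal(cor(dec, seq_along(dec), method = "spearman"), 1)

  # and survives 5 percent voxel noise (Spearman >= 0.9)
  profs_n <- lapply(frames, function(fr) {
    noisy <- add_volume_noise(fr$volume, 0.05, seed = 500 + fr$frame)
    pl <- site_placements(fr$model,
                          orientation_id = fr$state$orientation_id)
    site_occupancy(noisy, split_map(noisy, pl, 3), fr$frame)
  })
  smn <- strand_frame_means(normalize_across_frames(profs_n))
  decn <- smn$mean_occupancy[smn$strand == conv]
  expect_gte(cor(decn, seq_along(decn), method = "spearman"), 0.9)
})

test_that("occupancy/geometry pairing reproduces constructed couplings", {
  ref <- small_protomer()
  m <- make_curved_filament(
    curved_filament_spec(n_subunits = 15, strand_twist_delta = 2,
                         strand_rise_delta = 0.5),
    reference = ref)
  prof <- local_twist_rise(m, window = 10)

  mk_occ <- function(values) {
    out <- data.frame(site = seq_along(values) - 1L,
                      strand = (seq_along(values) - 1L) %% 2L,
                      intensity = values, occupancy = values / max(values),
                      frame = 0L)
    class(out) <- c("occupancy_profile", "data.frame")
    out
  }

  # occupancy proportional to (rise - min rise): Spearman vs rise = 1
  rise_occ <- mk_occ((prof$rise - min(prof$rise) + 1e-3))
  r <- occupancy_vs_geometry(rise_occ, prof)
  expect_equal(unname(r$correlations["spearman_rise"]), 1)

  # occupancy high where |twist| is low: negative twist-magnitude rank corr
  tw_occ <- mk_occ(max(abs(prof$twist)) - abs(prof$twist) + 1e-3)
  r2 <- occupancy_vs_geometry(tw_occ, prof)
  expect_lt(unname(r2$correlations["spearman_twist_mag"]), 0)

  # constant occupancy: correlation undefined, reported as NA
  r3 <- occupancy_vs_geometry(mk_occ(rep(1, 15)), prof)
  expect_true(all(is.na(r3$correlations)))
})
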