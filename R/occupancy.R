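# Occupancy quantification: zone segmentation of decorated-filament
# volumes, per-site integrated intensities normalized to the strongest
# site, per-strand/per-frame aggregation, and correlation of occupancy
# with local lattice geometry.

#' Per-site model placements for a decorated filament
#'
#' Bundles everything the occupancy stage needs to segment a volume: for
#' every site (actin subunit) the placed actin model and the placed
#' complex model at the chosen orientation. These serve as initial
#' placements for [fit_site_models()] and as the segmentation models for
#' [split_map()].
#'
#' @param model A `filament_model`.
#' @param orientation_id complex orientation (1..3).
#' @param complex_coords complex point model; defaults to the bundled
#'   synthetic stand-in.
#' @param orientations list of three orientation transforms.
#' @return Object of class `site_placements`: list of per-site records
#'   with `index`, `strand`, `actin` and `complex` coordinate matrices.
#' @export
site_placements <- function(model, orientation_id = 1L,
                            complex_coords = synthetic_complex_coords(),
                            orientations = default_orientations()) {
  stopifnot(inherits(model, "filament_model"), orientation_id %in% 1:3)
  orient <- orientations[[orientation_id]]
  sites <- lapply(seq_len(n_subunits(model)) - 1L, function(i) {
    tf <- model$transforms[[i + 1L]]
    list(index = i, strand = i %% 2L,
         actin = apply_transform(tf, model$reference),
         complex = apply_transform(compose_transform(tf, orient),
                                   complex_coords))
  })
  structure(sites, class = "site_placements")
}

#' Locally refine site placements against a volume
#'
#' For each site, finds the small rigid perturbation (bounded +-`max_shift`
#' Angstrom and +-`max_rot` degrees about the site centroid) that
#' maximizes the real-space correlation between the rasterized site model
#' (actin subunit plus complex) and the volume over the site's bounding
#' box. Sites without complex density are driven by the actin density,
#' which dominates the correlation. If the correlation is non-finite
#' (empty zone) the placement is returned unchanged with `flagged = TRUE`.
#'
#' @param volume A `synthetic_volume`.
#' @param placements A `site_placements` object (initial placements).
#' @param sigma Gaussian width used to rasterize the trial models
#'   (Angstrom); match the width used to generate the volume.
#' @param max_shift,max_rot search bounds (Angstrom, degrees).
#' @return A refined `site_placements` object; each site additionally
#'   carries `shift` (Angstrom), `rot` (degrees), `correlation` and
#'   `flagged`.
#' @export
fit_site_models <- function(volume, placements, sigma = 2.5,
                            max_shift = 5, max_rot = 10) {
  stopifnot(inherits(placements, "site_placements"))
  vs <- volume$voxel_size
  dims <- dim(volume$grid)
  refined <- lapply(placements, function(site) {
    pts <- rbind(site$actin, site$complex)
    n_act <- nrow(site$actin)
    ctr <- colMeans(pts)
    pad <- 4 * sigma + max_shift
    lo <- pmax(1L, floor((apply(pts, 2, min) - pad - volume$origin) / vs) + 1L)
    hi <- pmin(dims, ceiling((apply(pts, 2, max) + pad - volume$origin) / vs) + 1L)
    if (any(lo > hi)) {
      site$flagged <- TRUE; site$correlation <- NA_real_
      site$shift <- c(0, 0, 0); site$rot <- c(0, 0, 0)
      return(site)
    }
    sub <- volume$grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    gs <- list(dim = dim(sub), origin = volume$origin + (lo - 1) * vs)
    subv <- as.numeric(sub)
    if (stats::sd(subv) == 0 || !all(is.finite(subv))) {
      site$flagged <- TRUE; site$correlation <- NA_real_
      site$shift <- c(0, 0, 0); site$rot <- c(0, 0, 0)
      return(site)
    }
    move_pts <- function(par) {
      R <- rotation_about_axis(c(1, 0, 0), par[4]) %*%
        rotation_about_axis(c(0, 1, 0), par[5]) %*%
        rotation_about_axis(c(0, 0, 1), par[6])
      moved <- sweep(pts, 2, ctr) %*% t(R)
      sweep(moved, 2, ctr + par[1:3], "+")
    }
    objective <- function(par) {
      trial <- rasterize(move_pts(par), voxel_size = vs, sigma = sigma,
                         grid_spec = gs)
      cc <- suppressWarnings(stats::cor(as.numeric(trial$grid), subv))
      if (!is.finite(cc)) return(1e6)
      -cc
    }
    fit <- stats::optim(rep(0, 6), objective, method = "L-BFGS-B",
                        lower = c(rep(-max_shift, 3), rep(-max_rot, 3)),
                        upper = c(rep(max_shift, 3), rep(max_rot, 3)),
                        control = list(factr = 1e7))
    moved <- move_pts(fit$par)
    site$actin <- moved[seq_len(n_act), , drop = FALSE]
    site$complex <- moved[-seq_len(n_act), , drop = FALSE]
    site$shift <- fit$par[1:3]
    site$rot <- fit$par[4:6]
    site$correlation <- -fit$value
    site$flagged <- !is.finite(fit$value) || fit$value >= 1e6
    site
  })
  structure(refined, class = "site_placements")
}

#' Partition a volume into filament, per-site complex, and background
#'
#' Zone segmentation: every voxel whose center lies within `zone_radius`
#' of any model point is labeled by its nearest point's parent — the
#' filament (any site's actin points) or complex site `k`. Remaining
#' voxels are background. Ties are broken deterministically: the filament
#' wins over sites, and lower site indices win over higher (points are
#' scanned in that order and only a strictly smaller distance reassigns a
#' voxel).
#'
#' @param volume A `synthetic_volume`.
#' @param placements A `site_placements` object.
#' @param zone_radius zone radius in Angstrom (> 0), default 3.
#' @return Object of class `site_partition`: list with `labels` (integer
#'   array over the grid: 0 background, 1 filament, `k + 1` for complex
#'   site `k + 1`), `site_index` (0-based site index per label), and
#'   `zone_radius`.
#' @export
split_map <- function(volume, placements, zone_radius = 3) {
  if (zone_radius <= 0) stop("zone_radius must be positive")
  stopifnot(inherits(placements, "site_placements"))
  dims <- dim(volume$grid)
  vs <- volume$voxel_size
  org <- volume$origin
  best <- array(Inf, dims)
  labels <- array(0L, dims)

  paint <- function(pts, lab) {
    for (p in seq_len(nrow(pts))) {
      lo <- pmax(1L, ceiling((pts[p, ] - zone_radius - org) / vs) + 1L)
      hi <- pmin(dims, floor((pts[p, ] + zone_radius - org) / vs) + 1L)
      if (any(lo > hi)) next
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      dx2 <- (org[1] + (ix - 1) * vs - pts[p, 1])^2
      dy2 <- (org[2] + (iy - 1) * vs - pts[p, 2])^2
      dz2 <- (org[3] + (iz - 1) * vs - pts[p, 3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      inside <- d2 <= zone_radius^2
      cur <- best[ix, iy, iz]
      upd <- inside & d2 < cur
      if (any(upd)) {
        cur[upd] <- d2[upd]
        best[ix, iy, iz] <<- cur
        curl <- labels[ix, iy, iz]
        curl[upd] <- lab
        labels[ix, iy, iz] <<- curl
      }
    }
  }

  for (site in placements) paint(unname(site$actin), 1L)
  for (site in placements) paint(unname(site$complex), 2L + site$index)

  structure(list(labels = labels,
                 site_index = vapply(placements, `[[`, integer(1), "index"),
                 site_strand = vapply(placements, `[[`, integer(1), "strand"),
                 zone_radius = zone_radius),
            class = "site_partition")
}

#' Per-site occupancy profile from a partitioned volume
#'
#' Computes each complex site's integrated intensity (the plain sum of
#' voxel values labeled to that site — no thresholding) and normalizes to
#' the site with the highest integrated intensity, yielding a proxy
#' occupancy in `[0, 1]` whose maximum is exactly 1.
#'
#' @param volume A `synthetic_volume`.
#' @param partition A `site_partition` from [split_map()].
#' @param frame optional frame id recorded in the profile.
#' @return Object of class `occupancy_profile`: data frame with columns
#'   `site`, `strand`, `intensity` (voxel-value sum), `occupancy`
#'   (normalized) and `frame`.
#' @export
site_occupancy <- function(volume, partition, frame = 0L) {
  stopifnot(inherits(partition, "site_partition"))
  sites <- partition$site_index
  lab <- partition$labels
  g <- volume$grid
  intensity <- vapply(sites, function(i) sum(g[lab == (2L + i)]), numeric(1))
  if (all(intensity <= 0)) stop("no complex density in any site zone")
  occ <- intensity / max(intensity)
  out <- data.frame(site = sites, strand = partition$site_strand,
                    intensity = intensity, occupancy = occ,
                    frame = as.integer(frame))
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Renormalize occupancy profiles across a volume series
#'
#' For a trajectory of frames the meaningful reference is the single
#' strongest site of the whole series, not of each frame: frames with
#' little bound density would otherwise be rescaled to their own noise
#' ceiling. This rescales every profile's occupancy by the global maximum
#' integrated intensity, so exactly one site in the whole series has
#' occupancy 1.
#'
#' @param profiles list of `occupancy_profile` objects from the frames of
#'   one volume series.
#' @return The list with `occupancy` rescaled to the series-wide maximum.
#' @export
normalize_across_frames <- function(profiles) {
  if (inherits(profiles, "occupancy_profile")) profiles <- list(profiles)
  gmax <- max(vapply(profiles, function(p) max(p$intensity), numeric(1)))
  if (gmax <= 0) stop("no complex density in any frame")
  lapply(profiles, function(p) {
    p$occupancy <- p$intensity / gmax
    p
  })
}

#' Per-strand, per-frame mean occupancy
#'
#' Aggregates occupancy profiles from a volume series: the arithmetic
#' mean normalized intensity for each strand of each frame.
#'
#' @param profiles list of `occupancy_profile` objects (or a single one).
#' @return Data frame with columns `frame`, `strand`, `mean_occupancy`,
#'   sorted by frame then strand.
#' @export
strand_frame_means <- function(profiles) {
  if (inherits(profiles, "occupancy_profile")) profiles <- list(profiles)
  all <- do.call(rbind, profiles)
  agg <- stats::aggregate(occupancy ~ frame + strand, data = all, FUN = mean)
  names(agg)[names(agg) == "occupancy"] <- "mean_occupancy"
  agg <- agg[order(agg$frame, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Correlate occupancy with local lattice geometry
#'
#' Pairs each site's occupancy with the helical step starting at the same
#' index (step `i -> i+1` is paired with site `i`), restricted to the
#' profile's central window, and reports Spearman rank correlations of
#' occupancy against twist magnitude and against rise. With fewer than 3
#' paired rows, or constant inputs, the correlation is undefined and
#' reported as `NA`.
#'
#' @param occupancy An `occupancy_profile`.
#' @param helical A `helical_profile` from [local_twist_rise()].
#' @return A list with `table` (data frame: index, strand, twist, rise,
#'   occupancy) and `correlations` (named vector: `spearman_twist_mag`,
#'   `spearman_rise`).
#' @export
occupancy_vs_geometry <- function(occupancy, helical) {
  stopifnot(inherits(occupancy, "occupancy_profile"),
            inherits(helical, "helical_profile"))
  cen <- helical[helical$central, , drop = FALSE]
  merged <- merge(cen, occupancy, by.x = "index", by.y = "site",
                  suffixes = c("_step", "_site"))
  tab <- data.frame(index = merged$index, strand = merged$strand_step,
                    twist = merged$twist, rise = merged$rise,
                    occupancy = merged$occupancy)
  tab <- tab[order(tab$index), , drop = FALSE]
  rownames(tab) <- NULL
  spear <- function(x, y) {
    if (nrow(tab) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  list(table = tab,
       correlations = c(spearman_twist_mag = spear(abs(tab$twist),
                                                   tab$occupancy),
                        spearman_rise = spear(tab$rise, tab$occupancy)))
}
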