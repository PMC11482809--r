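# Synthetic volume libraries (segmentation-training-style collections) and
# curvature/occupancy-coupled volume trajectories emulating a
# conformational-variability frame series.

#' Configure a synthetic volume library
#'
#' A library enumerates decorated-filament volumes over a factorial design:
#' for each curvature and each of the three complex orientations, one bare
#' filament, one fully decorated filament, and `n_partial` partially
#' decorated filaments with random occupancies. With `dedup_bare = TRUE`
#' the (orientation-independent) bare filament is emitted once per
#' curvature instead of once per curvature-orientation cell.
#'
#' The default design — 13 curvatures x 3 orientations x (bare + full +
#' 6 partial) — enumerates 312 volumes.
#'
#' @param curvatures numeric vector of arc curvatures (reciprocal
#'   Angstrom; 0 means straight).
#' @param orientations integer vector of orientation ids (subset of 1:3).
#' @param n_partial number of random partial decorations per cell.
#' @param p_occupied Bernoulli occupancy probability for partial patterns.
#' @param n_subunits subunits per filament (default 23, the per-filament
#'   site count used in symmetry expansion).
#' @param twist,rise 1-start helical parameters.
#' @param voxel_size,sigma rasterization parameters (Angstrom).
#' @param dedup_bare emit one bare filament per curvature rather than per
#'   cell.
#' @param seed integer master seed; per-volume seeds derive from it.
#' @return A list of class `library_config`.
#' @export
library_config <- function(curvatures = c(0, 1 / seq(20000, 5000,
                                                     length.out = 12)),
                           orientations = 1:3, n_partial = 6,
                           p_occupied = 0.5, n_subunits = 23,
                           twist = -167, rise = 27,
                           voxel_size = 4, sigma = 3,
                           dedup_bare = FALSE, seed = 1L) {
  stopifnot(all(orientations %in% 1:3), n_partial >= 0)
  structure(list(curvatures = curvatures,
                 orientations = as.integer(orientations),
                 n_partial = as.integer(n_partial),
                 p_occupied = p_occupied, n_subunits = as.integer(n_subunits),
                 twist = twist, rise = rise, voxel_size = voxel_size,
                 sigma = sigma, dedup_bare = isTRUE(dedup_bare),
                 seed = as.integer(seed)),
            class = "library_config")
}

#' Number of volumes a library configuration enumerates
#'
#' @param config A `library_config`.
#' @return Integer library size: `|curvatures| * |orientations| *
#'   (2 + n_partial)` without bare dedup, or
#'   `|curvatures| * (|orientations| * (1 + n_partial) + 1)` with it.
#' @examples
#' library_size(library_config())  # 312
#' @export
library_size <- function(config) {
  nc <- length(config$curvatures)
  no <- length(config$orientations)
  k <- config$n_partial
  if (config$dedup_bare) nc * (no * (1 + k) + 1L) else nc * no * (2L + k)
}

# deterministic per-volume seed below 2^31
.derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Generate a synthetic volume library
#'
#' Enumerates the configuration's design and rasterizes one decorated
#' filament volume per entry. Every entry carries sidecar metadata
#' (pattern, orientation, curvature, seed) sufficient to regenerate it
#' bit-identically.
#'
#' @param config A `library_config`.
#' @return A list of entries, each a list with `volume`
#'   (`synthetic_volume`) and `meta` (named list).
#' @export
make_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  entries <- list()
  ref <- reference_protomer()
  cx <- synthetic_complex_coords()
  for (ci in seq_along(config$curvatures)) {
    curv <- config$curvatures[ci]
    radius <- if (curv <= 0) Inf else 1 / curv
    fil <- make_curved_filament(
      curved_filament_spec(twist = config$twist, rise = config$rise,
                           n_subunits = config$n_subunits,
                           arc_radius = radius),
      reference = ref)
    cell_patterns <- function(oid) {
      pats <- list(list(pattern = "full", rep = 0L))
      if (!config$dedup_bare || oid == config$orientations[1])
        pats <- c(list(list(pattern = "bare", rep = 0L)), pats)
      c(pats, lapply(seq_len(config$n_partial),
                     function(r) list(pattern = "partial_random", rep = r)))
    }
    for (oid in config$orientations) {
      for (pat in cell_patterns(oid)) {
        vseed <- .derive_seed(config$seed, ci, oid, pat$pattern, pat$rep)
        state <- decoration_state(config$n_subunits, pat$pattern,
                                  orientation_id = oid,
                                  p_occupied = config$p_occupied,
                                  seed = vseed)
        placed <- decorate(fil, state, complex_coords = cx)
        pieces <- c(lapply(seq_len(config$n_subunits) - 1L,
                           function(i) placed_coords(fil, i)),
                    placed)
        vol <- rasterize(pieces, voxel_size = config$voxel_size,
                         sigma = config$sigma)
        # bare entries emitted under the cell's orientation id but flagged
        meta <- list(pattern = pat$pattern, orientation = oid,
                     curvature = curv, seed = vseed, rep = pat$rep,
                     n_occupied = sum(state$occupied))
        entries[[length(entries) + 1L]] <- list(volume = vol, meta = meta)
      }
    }
  }
  entries
}

#' Write a volume library to disk
#'
#' Writes each entry as an MRC map plus a JSON metadata sidecar.
#'
#' @param entries output of [make_library()].
#' @param dir output directory (created if missing).
#' @return Character vector of MRC paths, invisibly.
#' @export
write_library <- function(entries, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(entries))
  for (i in seq_along(entries)) {
    base <- file.path(dir, sprintf("volume_%04d", i))
    write_volume(entries[[i]]$volume, paste0(base, ".mrc"))
    jsonlite::write_json(entries[[i]]$meta, paste0(base, ".json"),
                         auto_unbox = TRUE, digits = NA)
    paths[i] <- paste0(base, ".mrc")
  }
  invisible(paths)
}

#' Generate a curvature/occupancy-coupled volume trajectory
#'
#' Emulates a conformational-variability volume series in which filament
#' curvature and single-strand decoration grow together: frame `j`
#' (0-based) has curvature `j / (n_frames - 1) * max_curvature` and
#' complexes on the convex strand only, rendered with density amplitude
#' `occupancy_ramp(j)` in `[0, 1]`; the other strand stays bare.
#'
#' @param n_frames number of frames (>= 2).
#' @param max_curvature curvature of the final frame (reciprocal
#'   Angstrom).
#' @param occupancy_ramp function of the 0-based frame index returning the
#'   complex amplitude weight in `[0, 1]`; defaults to a linear ramp.
#' @param n_subunits subunits per filament.
#' @param twist,rise 1-start helical parameters.
#' @param voxel_size,sigma rasterization parameters (Angstrom).
#' @param seed integer seed recorded in each frame.
#' @return A list of frames, each a list with `volume`, `model`
#'   (`filament_model`), `state` (`decoration_state`), `weight` (the ramp
#'   value) and `frame` (0-based index). All frames share one grid so
#'   they are voxel-comparable.
#' @export
make_trajectory <- function(n_frames, max_curvature,
                            occupancy_ramp = function(j) j / (n_frames - 1),
                            n_subunits = 11, twist = -167, rise = 27,
                            voxel_size = 3, sigma = 2.5, seed = 1L) {
  stopifnot(n_frames >= 2)
  ref <- reference_protomer()
  cx <- synthetic_complex_coords()
  # fix one grid covering the most-curved frame (largest footprint)
  specs <- lapply(seq_len(n_frames) - 1L, function(j) {
    curv <- (j / (n_frames - 1)) * max_curvature
    curved_filament_spec(twist = twist, rise = rise,
                         n_subunits = n_subunits,
                         arc_radius = if (curv <= 0) Inf else 1 / curv,
                         seed = seed)
  })
  models <- lapply(specs, make_curved_filament, reference = ref)
  all_pts <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, c(lapply(seq_len(n_subunits) - 1L,
                            function(i) unname(placed_coords(m, i))),
                     lapply(unname(decorate(m, decoration_state(
                       n_subunits, "full"), complex_coords = cx)), unname)))
  }))
  pad <- 4 * sigma
  lo <- apply(all_pts, 2, min) - pad
  hi <- apply(all_pts, 2, max) + pad
  gs <- list(dim = pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L),
             origin = lo)

  lapply(seq_len(n_frames) - 1L, function(j) {
    m <- models[[j + 1L]]
    conv <- convex_strand(m)
    state <- decoration_state(n_subunits, "single_strand", strand = conv,
                              seed = seed)
    w <- occupancy_ramp(j)
    stopifnot(w >= 0, w <= 1)
    actin <- lapply(seq_len(n_subunits) - 1L, function(i) placed_coords(m, i))
    placed <- decorate(m, state, complex_coords = cx)
    pieces <- c(actin, placed)
    weights <- c(rep(1, length(actin)), rep(w, length(placed)))
    vol <- rasterize(pieces, voxel_size = voxel_size, sigma = sigma,
                     weights = weights, grid_spec = gs)
    list(volume = vol, model = m, state = state, weight = w, frame = j)
  })
}
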