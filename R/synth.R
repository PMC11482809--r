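# Synthetic structure generators: ideal and curved filament models,
# decoration states, and the coarse two-lobe complex stand-in used to
# decorate them. All generators are deterministic given their arguments
# (and seed, where one applies).

# Deterministic quasi-uniform points on a sphere (Fibonacci lattice); used
# to build synthetic point models without consuming RNG state.
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.fib_ball <- function(shells, center = c(0, 0, 0)) {
  pts <- rbind(c(0, 0, 0),
               do.call(rbind, lapply(seq_along(shells), function(k)
                 .fib_sphere(max(6, round(2 * shells[k]^2)), shells[k]))))
  sweep(pts, 2, center, "+")
}

#' Synthetic reference protomer coordinates
#'
#' A deterministic coarse point model standing in for one actin subunit's
#' C-alpha trace: a filled quasi-spherical blob of pseudo-atoms whose
#' centroid is offset radially from the filament axis (as the actin
#' subunit's center of mass is). Point labels are `CA_1 ... CA_n`.
#'
#' @param radius blob radius in Angstrom (default 9, roughly an actin
#'   subunit).
#' @param offset radial centroid offset from the helical axis in Angstrom
#'   (default 10).
#' @return Labeled coordinate matrix (Angstrom).
#' @export
reference_protomer <- function(radius = 9, offset = 10) {
  pts <- .fib_ball(c(radius / 2, radius), center = c(offset, 0, 0))
  rownames(pts) <- paste0("CA_", seq_len(nrow(pts)))
  pts
}

#' Synthetic coarse complex coordinates
#'
#' A deterministic two-lobe pseudo-atom blob standing in for the coarse
#' cadherin-catenin complex model used to decorate synthetic filaments
#' (one lobe for the alpha-catenin actin-binding domain, one for the
#' afadin coiled-coil region). This bundled stand-in is synthetic; real
#' coordinates may be supplied to [decorate()] instead.
#'
#' @return Labeled coordinate matrix (Angstrom), centered near the origin.
#' @export
synthetic_complex_coords <- function() {
  lobe1 <- .fib_ball(c(2, 4, 5.5), center = c(0, 0, -3))
  lobe2 <- .fib_ball(c(2, 4), center = c(4, 0, 5))
  pts <- rbind(lobe1, lobe2)
  rownames(pts) <- paste0("CX_", seq_len(nrow(pts)))
  pts
}

#' Build an ideal 1-start helical filament model
#'
#' Places `n` copies of a reference protomer by the exact 1-start screw:
#' subunit `k` is the reference rotated by `k * twist` degrees about `+z`
#' and translated by `k * rise` Angstrom along `+z`. Canonical F-actin
#' corresponds to twist -167 degrees, rise 27 Angstrom.
#'
#' @param twist 1-start helical twist in degrees (right-hand rule about
#'   the pointed-to-barbed axis).
#' @param rise 1-start helical rise in Angstrom (> 0).
#' @param n number of subunits (>= 2).
#' @param reference labeled protomer coordinates; defaults to
#'   [reference_protomer()].
#' @return A `filament_model`.
#' @examples
#' m <- build_ideal_filament(-167, 27, 15)
#' @export
build_ideal_filament <- function(twist, rise, n,
                                 reference = reference_protomer()) {
  stopifnot(n >= 2, rise > 0)
  step <- screw_transform(twist, rise)
  tfs <- vector("list", n)
  tfs[[1]] <- rigid_transform()
  for (k in seq_len(n - 1))
    tfs[[k + 1]] <- compose_transform(step, tfs[[k]])
  filament_model(tfs, reference)
}

#' Specify a curved, strand-asymmetric synthetic filament
#'
#' Parameters for [make_curved_filament()]: mean 1-start twist/rise, arc
#' curvature, and antisymmetric per-strand twist and rise offsets. The
#' deltas alternate sign with step parity, so strand means differ by twice
#' the delta while the overall mean is unchanged — emulating the lattice
#' signature of twist-bend coupling (one strand under-twisted, increased
#' rise along one strand and decreased along the other).
#'
#' @param twist mean 1-start twist (degrees).
#' @param rise mean 1-start rise (Angstrom, > 0).
#' @param n_subunits number of subunits.
#' @param arc_radius bending radius in Angstrom; `Inf` for a straight
#'   filament. Must exceed `10 * n_subunits * rise / (2 * pi)` (gentle
#'   nanoscale curvature only).
#' @param strand_twist_delta degrees added on even-parity steps and
#'   subtracted on odd-parity steps.
#' @param strand_rise_delta Angstrom, likewise antisymmetric.
#' @param seed integer recorded with the spec (the construction itself is
#'   deterministic).
#' @return An object of class `curved_filament_spec`.
#' @export
curved_filament_spec <- function(twist = -167, rise = 27, n_subunits = 15,
                                 arc_radius = Inf, strand_twist_delta = 0,
                                 strand_rise_delta = 0, seed = 1L) {
  stopifnot(rise > 0, n_subunits >= 2)
  min_radius <- 10 * (n_subunits * rise) / (2 * pi)
  if (is.finite(arc_radius) && arc_radius <= min_radius)
    stop(sprintf("arc_radius %.1f A too tight: must exceed %.1f A for this filament length",
                 arc_radius, min_radius))
  structure(list(twist = twist, rise = rise, n_subunits = n_subunits,
                 arc_radius = arc_radius,
                 strand_twist_delta = strand_twist_delta,
                 strand_rise_delta = strand_rise_delta,
                 seed = as.integer(seed)),
            class = "curved_filament_spec")
}

#' Generate a curved, strand-asymmetric filament model
#'
#' Builds per-step screws with `twist_k = twist + (-1)^k * strand_twist_delta`
#' and `rise_k = rise + (-1)^k * strand_rise_delta`, composes them
#' sequentially along `+z`, then bends the accumulated axis onto a
#' circular arc of radius `arc_radius` in the x-z plane (each frame is
#' carried rigidly to its arc-length position, so measured mean curvature
#' is 1/arc_radius).
#'
#' @param spec A `curved_filament_spec`.
#' @param reference labeled protomer coordinates; defaults to
#'   [reference_protomer()].
#' @return A `filament_model`.
#' @examples
#' m <- make_curved_filament(curved_filament_spec(arc_radius = 5000))
#' @export
make_curved_filament <- function(spec, reference = reference_protomer()) {
  stopifnot(inherits(spec, "curved_filament_spec"))
  n <- spec$n_subunits
  tfs <- vector("list", n)
  tfs[[1]] <- rigid_transform()
  z <- numeric(n)  # accumulated axial position of each frame
  for (k in seq_len(n - 1)) {
    sgn <- if ((k - 1) %% 2 == 0) 1 else -1
    tw <- spec$twist + sgn * spec$strand_twist_delta
    ri <- spec$rise + sgn * spec$strand_rise_delta
    tfs[[k + 1]] <- compose_transform(screw_transform(tw, ri), tfs[[k]])
    z[k + 1] <- z[k] + ri
  }
  if (is.finite(spec$arc_radius)) {
    R <- spec$arc_radius
    ctr <- c(-R, 0, 0)  # bend center; convex side faces +x
    tfs <- lapply(seq_len(n), function(k) {
      phi <- .rad2deg(z[k] / R)
      bend <- compose_transform(
        rigid_transform(diag(3), ctr),
        compose_transform(
          rigid_transform(rotation_about_axis(c(0, 1, 0), phi), c(0, 0, 0)),
          compose_transform(rigid_transform(diag(3), -ctr),
                            rigid_transform(diag(3), c(0, 0, -z[k])))))
      compose_transform(bend, tfs[[k]])
    })
  }
  filament_model(tfs, reference)
}

#' Identify the convex strand of a bent filament
#'
#' Returns the strand parity (0 or 1) whose subunit centroids lie, on
#' average, farther from the filament's bending center — the convex side
#' of the arc. For a straight filament the result is arbitrary but
#' deterministic.
#'
#' @param model A `filament_model`.
#' @return Integer 0 or 1.
#' @export
convex_strand <- function(model) {
  n <- n_subunits(model)
  cents <- t(vapply(seq_len(n) - 1L,
                    function(i) colMeans(placed_coords(model, i)),
                    numeric(3)))
  origins <- subunit_origins(model)
  # radial excursion of the protomer centroid relative to the local axis
  excess <- sqrt(rowSums((cents - origins)^2))
  curv <- tryCatch(.circle_curvature(origins), error = function(e) 0)
  if (curv > 1e-9) {
    # distance of centroids from the global bend center
    ctr <- colMeans(origins)
    x0 <- sweep(origins, 2, ctr)
    sv <- svd(x0)
    u <- x0 %*% sv$v[, 1]; v <- x0 %*% sv$v[, 2]
    A <- cbind(2 * u, 2 * v, 1)
    sol <- qr.solve(A, u^2 + v^2)
    center3 <- ctr + sol[1] * sv$v[, 1] + sol[2] * sv$v[, 2]
    d <- sqrt(rowSums(sweep(cents, 2, center3)^2))
  } else {
    d <- excess
  }
  strands <- subunit_strands(model)
  m0 <- mean(d[strands == 0L]); m1 <- mean(d[strands == 1L])
  if (m0 >= m1) 0L else 1L
}

#' Specify a decoration state for a filament
#'
#' Per-site occupancy flags for synthetic decorated filaments. Patterns:
#' `bare` (no site occupied), `full` (all sites), `single_strand` (one
#' index-parity class only), and `partial_random` (i.i.d. Bernoulli
#' occupancy with probability `p_occupied`, drawn with `seed`).
#'
#' @param n_sites number of sites (one per actin subunit).
#' @param pattern one of `"bare"`, `"full"`, `"partial_random"`,
#'   `"single_strand"`.
#' @param orientation_id which of the three complex orientations to use
#'   (integer in 1..3).
#' @param p_occupied Bernoulli probability for `partial_random`.
#' @param strand strand parity decorated under `single_strand` (0 or 1).
#' @param seed integer RNG seed for `partial_random`.
#' @return An object of class `decoration_state` with logical vector
#'   `occupied`.
#' @export
decoration_state <- function(n_sites, pattern = c("bare", "full",
                                                  "partial_random",
                                                  "single_strand"),
                             orientation_id = 1L, p_occupied = 0.5,
                             strand = 0L, seed = 1L) {
  pattern <- match.arg(pattern)
  if (!orientation_id %in% 1:3)
    stop("orientation_id must be 1, 2 or 3")
  idx <- seq_len(n_sites) - 1L
  occupied <- switch(pattern,
    bare = rep(FALSE, n_sites),
    full = rep(TRUE, n_sites),
    single_strand = idx %% 2L == as.integer(strand),
    partial_random = {
      rng <- .with_seed(seed, stats::runif(n_sites))
      rng < p_occupied
    })
  structure(list(occupied = occupied, pattern = pattern,
                 orientation_id = as.integer(orientation_id),
                 p_occupied = p_occupied, strand = as.integer(strand),
                 seed = as.integer(seed)),
            class = "decoration_state")
}

# Evaluate `expr` under a local RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default complex orientations relative to a subunit
#'
#' Three rigid placements of the complex frame relative to its actin
#' subunit frame: a fixed radial offset (so the complex sits on the outer
#' filament surface) combined with rotations of 0, 120 and 240 degrees
#' about the subunit's radial axis.
#'
#' @param radial_offset distance from the subunit frame origin to the
#'   complex center, Angstrom (default 22).
#' @return List of three `rigid_transform` objects.
#' @export
default_orientations <- function(radial_offset = 26) {
  lapply(c(0, 120, 240), function(a)
    compose_transform(
      rigid_transform(rotation_about_axis(c(1, 0, 0), a),
                      c(radial_offset, 0, 0)),
      rigid_transform()))
}

#' Place complex copies on a decorated filament
#'
#' For each occupied site, one copy of the complex point model is placed
#' by composing the site's subunit frame with the chosen orientation
#' transform.
#'
#' @param model A `filament_model`.
#' @param state A `decoration_state` with one site per subunit.
#' @param complex_coords labeled complex point model; defaults to the
#'   bundled synthetic stand-in [synthetic_complex_coords()].
#' @param orientations list of three `rigid_transform`s (complex frame
#'   relative to a subunit frame); defaults to [default_orientations()].
#' @return Named list of placed complex coordinate matrices, one per
#'   occupied site, names `site_<index>`.
#' @export
decorate <- function(model, state,
                     complex_coords = synthetic_complex_coords(),
                     orientations = default_orientations()) {
  stopifnot(inherits(model, "filament_model"),
            inherits(state, "decoration_state"))
  if (length(state$occupied) != n_subunits(model))
    stop("decoration state has a different number of sites than the model")
  if (length(orientations) != 3)
    stop("orientations must be a table of 3 rigid transforms")
  orient <- orientations[[state$orientation_id]]
  sites <- which(state$occupied) - 1L
  out <- lapply(sites, function(i) {
    tf <- compose_transform(model$transforms[[i + 1L]], orient)
    apply_transform(tf, complex_coords)
  })
  names(out) <- if (length(sites)) paste0("site_", sites) else character(0)
  out
}
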