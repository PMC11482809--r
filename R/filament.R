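# Filament models: ordered per-subunit rigid frames over a single reference
# protomer, plus the lattice measurements made on them (local twist/rise,
# strand decomposition, curvature, extension).

#' Construct a filament model
#'
#' A filament model is an ordered list of per-subunit rigid frames placing
#' copies of one reference protomer (a labeled C-alpha point set) along the
#' filament. Subunit 0 sits at the pointed end and indices increase toward
#' the barbed end; the two long-pitch strands correspond to index parity
#' (strand = index mod 2) in the 1-start indexing.
#'
#' @param transforms list of `rigid_transform` objects, one per subunit, in
#'   pointed-to-barbed order.
#' @param reference numeric matrix of labeled 3D points (Angstrom) for one
#'   protomer; row names are point labels (e.g. residue identifiers). Must
#'   be non-empty and non-collinear.
#' @return An object of class `filament_model`.
#' @seealso [build_ideal_filament()], [local_twist_rise()],
#'   [extend_filament()]
#' @export
filament_model <- function(transforms, reference) {
  stopifnot(is.list(transforms), length(transforms) >= 2)
  for (tf in transforms)
    if (!inherits(tf, "rigid_transform"))
      stop("every subunit frame must be a rigid_transform")
  reference <- rbind(reference)
  if (nrow(reference) < 3) stop("reference protomer needs >= 3 points")
  if (.is_collinear(reference))
    stop("reference protomer coordinates are collinear")
  if (is.null(rownames(reference)))
    rownames(reference) <- paste0("P", seq_len(nrow(reference)))
  structure(list(transforms = transforms, reference = reference),
            class = "filament_model")
}

.is_collinear <- function(coords, tol = 1e-8) {
  c0 <- sweep(rbind(coords), 2, colMeans(coords))
  sv <- svd(c0, nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("<filament_model> %d subunits, %d reference points\n",
              n_subunits(x), nrow(x$reference)))
  invisible(x)
}

#' @export
length.filament_model <- function(x) length(x$transforms)

#' Number of subunits in a filament model
#' @param model A `filament_model`.
#' @return Integer subunit count.
#' @export
n_subunits <- function(model) length(model$transforms)

#' Strand label of each subunit
#'
#' Strand membership follows index parity in the 1-start indexing: subunit
#' `i` belongs to strand `i %% 2`.
#'
#' @param model A `filament_model`.
#' @return Integer vector of 0/1 strand labels, one per subunit.
#' @export
subunit_strands <- function(model) (seq_len(n_subunits(model)) - 1L) %% 2L

#' Placed coordinates of one subunit
#'
#' @param model A `filament_model`.
#' @param i subunit index (0-based).
#' @return Matrix of the reference protomer points placed by subunit `i`'s
#'   frame.
#' @export
placed_coords <- function(model, i) {
  stopifnot(i >= 0, i < n_subunits(model))
  apply_transform(model$transforms[[i + 1L]], model$reference)
}

#' Subunit frame origins
#' @param model A `filament_model`.
#' @return n x 3 matrix of frame translation components (Angstrom).
#' @export
subunit_origins <- function(model) {
  t(vapply(model$transforms, function(tf) tf$translation, numeric(3)))
}

#' Inter-subunit transform by superposition
#'
#' Returns the rigid transform mapping the placed coordinates of subunit
#' `i` onto subunit `j`, computed by least-squares (Kabsch) superposition
#' of the two placed copies of the reference protomer. For exact frames
#' this equals `transform(j) o transform(i)^-1`.
#'
#' @param model A `filament_model`.
#' @param i,j subunit indices (0-based).
#' @return A `rigid_transform`.
#' @examples
#' m <- build_ideal_filament(-167, 27, 5)
#' screw_decompose(step_transform(m, 0, 1))$twist
#' @export
step_transform <- function(model, i, j) {
  n <- n_subunits(model)
  stopifnot(i >= 0, i < n, j >= 0, j < n)
  if (i == j) return(rigid_transform())
  kabsch(placed_coords(model, i), placed_coords(model, j))$transform
}

#' Local helical twist and rise profile
#'
#' Measures the instantaneous helical parameters of a filament model: for
#' each consecutive subunit pair `(i, i+1)` the inter-subunit transform is
#' computed by superposition and screw-decomposed into a local twist
#' (degrees) and rise (Angstrom). The step `i -> i+1` is assigned to index
#' `i` and inherits its strand label (`i %% 2`). To avoid edge effects a
#' central window of `window` steps is flagged; downstream summaries
#' restrict to it. When the number of excess steps is odd the window
#' shifts one step toward the pointed end.
#'
#' @param model A `filament_model` with at least `window + 1` subunits.
#' @param window central window size (number of retained steps), default 10.
#' @return An object of class `helical_profile`: a data frame with columns
#'   `index`, `strand`, `twist` (degrees), `rise` (Angstrom) and `central`
#'   (logical), one row per step.
#' @examples
#' prof <- local_twist_rise(build_ideal_filament(-167, 27, 37))
#' mean(prof$twist[prof$central])
#' @export
local_twist_rise <- function(model, window = 10) {
  n <- n_subunits(model)
  if (n < window + 1)
    stop(sprintf("model has %d subunits; local_twist_rise needs at least window + 1 = %d",
                 n, window + 1))
  n_steps <- n - 1L
  twist <- rise <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    s <- screw_decompose(step_transform(model, i - 1L, i))
    twist[i] <- s$twist
    rise[i] <- s$rise
  }
  central <- rep(FALSE, n_steps)
  start <- floor((n_steps - window) / 2)  # tie toward the pointed end
  central[(start + 1):(start + window)] <- TRUE
  out <- data.frame(index = seq_len(n_steps) - 1L,
                    strand = (seq_len(n_steps) - 1L) %% 2L,
                    twist = twist, rise = rise, central = central)
  attr(out, "window") <- window
  class(out) <- c("helical_profile", "data.frame")
  out
}

#' @export
print.helical_profile <- function(x, ...) {
  cen <- x[x$central, ]
  cat(sprintf("<helical_profile> %d steps (%d central): mean twist %.3f deg, mean rise %.3f A\n",
              nrow(x), nrow(cen), mean(cen$twist), mean(cen$rise)))
  NextMethod()
}

#' Per-strand helical parameter summary
#'
#' Summarizes a helical profile per long-pitch strand, restricted to the
#' central window: mean twist and rise for strand 0, strand 1, and overall,
#' plus the per-index series for plotting. Distinct strand means indicate
#' strand-asymmetric lattice deformation (e.g. an under-twisted strand
#' under twist-bend coupling).
#'
#' @param profile A `helical_profile`.
#' @return A list with `strand_means` (data frame: strand, mean_twist,
#'   mean_rise, n_steps), `overall` (mean twist/rise over the central
#'   window) and `series` (the central-window rows of the profile).
#' @export
strand_profile <- function(profile) {
  stopifnot(inherits(profile, "helical_profile"), nrow(profile) > 0)
  cen <- profile[profile$central, , drop = FALSE]
  if (nrow(cen) == 0) cen <- profile
  sm <- do.call(rbind, lapply(c(0L, 1L), function(s) {
    rows <- cen[cen$strand == s, , drop = FALSE]
    data.frame(strand = s,
               mean_twist = mean(rows$twist),
               mean_rise = mean(rows$rise),
               n_steps = nrow(rows))
  }))
  list(strand_means = sm,
       overall = c(twist = mean(cen$twist), rise = mean(cen$rise)),
       series = cen)
}

#' Extend a filament model by self-concatenation
#'
#' Chains three copies of the model into one longer filament, mirroring
#' the construction used to mitigate edge effects in lattice measurements:
#' the second copy's `overlap` pointed-end subunits are superposed (Kabsch,
#' on all placed reference points of those subunits) onto the first copy's
#' `overlap` barbed-end subunits, the third copy likewise onto the extended
#' pair, and the duplicated overlap subunits of the added copies are
#' deleted. A model of `n` subunits yields `3n - 2*overlap` subunits,
#' re-indexed from 0.
#'
#' @param model A `filament_model` with more than `2 * overlap` subunits.
#' @param overlap number of subunits used for terminal alignment, default 4.
#' @return The extended `filament_model`.
#' @examples
#' n_subunits(extend_filament(build_ideal_filament(-167, 27, 15)))  # 37
#' @export
extend_filament <- function(model, overlap = 4) {
  n <- n_subunits(model)
  if (n <= 2 * overlap)
    stop(sprintf("model has %d subunits; extension needs more than 2*overlap = %d",
                 n, 2 * overlap))
  stack_pts <- function(tfs, idx) {
    do.call(rbind, lapply(idx, function(i)
      unname(apply_transform(tfs[[i + 1L]], model$reference))))
  }
  chain_once <- function(tfs) {
    m <- length(tfs)
    target <- stack_pts(tfs, (m - overlap):(m - 1L))
    source <- stack_pts(model$transforms, 0:(overlap - 1L))
    g <- kabsch(source, target)$transform
    moved <- lapply(model$transforms, function(tf) compose_transform(g, tf))
    c(tfs, moved[(overlap + 1L):n])  # drop the duplicated overlap subunits
  }
  tfs <- chain_once(chain_once(model$transforms))
  filament_model(tfs, model$reference)
}

#' Filament axis curvature by sliding circle fit
#'
#' Estimates local filament curvature from the 3D trace of subunit frame
#' origins: a circle is fit (least squares, in the best-fit plane of the
#' window) to each sliding window of `arc_window` consecutive origins and
#' the reciprocal radius is assigned to the window's central index.
#' Straight segments report (near-)zero curvature; exactly collinear
#' windows report 0.
#'
#' @param model A `filament_model` with at least `arc_window` subunits.
#' @param arc_window odd window size >= 3, default 5.
#' @return Data frame with columns `index` (subunit index at window
#'   center) and `curvature` (reciprocal Angstrom).
#' @export
axis_curvature <- function(model, arc_window = 5) {
  stopifnot(arc_window >= 3, arc_window %% 2 == 1)
  n <- n_subunits(model)
  if (n < arc_window)
    stop(sprintf("model has %d subunits; curvature needs at least arc_window = %d",
                 n, arc_window))
  origins <- subunit_origins(model)
  half <- (arc_window - 1L) %/% 2L
  centers <- (half):(n - 1L - half)
  curv <- vapply(centers, function(c0) {
    w <- origins[(c0 - half + 1L):(c0 + half + 1L), , drop = FALSE]
    .circle_curvature(w)
  }, numeric(1))
  data.frame(index = centers, curvature = curv)
}

# Least-squares circle fit in the best-fit plane of a 3D point window.
.circle_curvature <- function(pts) {
  ctr <- colMeans(pts)
  x0 <- sweep(pts, 2, ctr)
  sv <- svd(x0)
  # in-plane coordinates (first two principal directions)
  u <- x0 %*% sv$v[, 1]
  v <- x0 %*% sv$v[, 2]
  scale <- max(abs(u), 1)
  if (max(abs(v)) < 1e-8 * scale) return(0)  # collinear within tolerance
  # Kasa fit: u^2 + v^2 = 2 a u + 2 b v + c
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) return(0)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(0)
  1 / sqrt(r2)
}

#' Apply a global rigid motion to a filament model
#'
#' Useful for testing measurement invariance: all lattice measurements
#' (twist, rise, curvature) are invariant under a global rigid motion of
#' the model.
#'
#' @param model A `filament_model`.
#' @param transform A `rigid_transform` applied to every subunit frame.
#' @return The moved `filament_model`.
#' @export
transform_model <- function(model, transform) {
  filament_model(lapply(model$transforms,
                        function(tf) compose_transform(transform, tf)),
                 model$reference)
}
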