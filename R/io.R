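# Structured I/O: coordinate files (PDB/mmCIF via bio3d), TIFF images,
# and CSV tables. Synthetic subunit chain identifiers are assigned
# A, B, C, ... (then a-z, 0-9) in subunit-index order.

.chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Write a filament model as a PDB file
#'
#' Each subunit's placed reference points are written as C-alpha atoms of
#' one chain; chains are lettered `A, B, C, ...` in pointed-to-barbed
#' subunit order. Optional decoration complexes are appended as
#' additional chains after the subunits.
#'
#' @param model A `filament_model`.
#' @param path output PDB path.
#' @param decorations optional list of placed complex coordinate matrices
#'   (e.g. from [decorate()]).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, decorations = NULL) {
  stopifnot(inherits(model, "filament_model"))
  n <- n_subunits(model)
  pieces <- lapply(seq_len(n) - 1L, function(i) placed_coords(model, i))
  pieces <- c(pieces, decorations)
  if (length(pieces) > length(.chain_alphabet))
    stop("too many chains for the PDB chain alphabet (max 62)")
  coords <- do.call(rbind, lapply(pieces, unname))
  chain <- rep(.chain_alphabet[seq_along(pieces)],
               vapply(pieces, nrow, integer(1)))
  resno <- unlist(lapply(pieces, function(p) seq_len(nrow(p))))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords)),
                   type = rep("ATOM", nrow(coords)),
                   resno = resno,
                   resid = rep("ALA", nrow(coords)),
                   eleno = seq_len(nrow(coords)),
                   elety = rep("CA", nrow(coords)),
                   chain = chain)
  invisible(path)
}

# read a PDB or mmCIF file into a bio3d pdb object
.read_any_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    suppressWarnings(suppressMessages(
      if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
      else bio3d::read.pdb(path))),
    error = function(e)
      stop(sprintf("unparseable structure file '%s': %s", path,
                   conditionMessage(e))))
  pdb
}

#' Read per-chain C-alpha coordinates from a structure file
#'
#' @param path PDB or mmCIF file path (by extension).
#' @return Named list of labeled coordinate matrices, one per chain in
#'   order of appearance; row labels are residue numbers.
#' @export
read_chain_coords <- function(path) {
  pdb <- .read_any_structure(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  chains <- unique(at$chain)
  out <- lapply(chains, function(ch) {
    rows <- at[at$chain == ch, , drop = FALSE]
    m <- as.matrix(rows[, c("x", "y", "z")])
    rownames(m) <- as.character(rows$resno)
    m
  })
  names(out) <- chains
  out
}

#' Read a filament model from a structure file
#'
#' Reads a multi-chain coordinate file in which every chain is one placed
#' subunit (pointed-to-barbed in chain order) and reconstructs the
#' per-subunit rigid frames by superposing the reference protomer onto
#' each chain (matching points by residue label). Without a reference,
#' the first chain is used as the reference protomer.
#'
#' @param path PDB or mmCIF file path.
#' @param reference optional labeled reference protomer coordinates.
#' @param expected_chains optional integer; error if the file has fewer
#'   chains (the error lists the expected chain letters).
#' @return A `filament_model`.
#' @export
read_structure <- function(path, reference = NULL, expected_chains = NULL) {
  chains <- read_chain_coords(path)
  if (!is.null(expected_chains) && length(chains) < expected_chains) {
    expected <- .chain_alphabet[seq_len(expected_chains)]
    stop(sprintf("structure '%s' has %d chains; expected %d (%s); missing: %s",
                 path, length(chains), expected_chains,
                 paste(expected, collapse = ""),
                 paste(setdiff(expected, names(chains)), collapse = ", ")))
  }
  if (is.null(reference)) reference <- chains[[1]]
  # chains are written in reference point order with sequential residue
  # numbers, so match by row order (labels are preserved on the model)
  ref_ordered <- unname(reference)
  tfs <- lapply(chains, function(ch) {
    if (nrow(ch) != nrow(ref_ordered))
      stop("chain size does not match the reference protomer")
    superpose_rmsd(ref_ordered, unname(ch))$transform
  })
  filament_model(unname(tfs), reference)
}

#' Select labeled points by residue number range
#'
#' @param coords labeled coordinate matrix (row names are residue
#'   numbers, as from [read_chain_coords()]).
#' @param residues integer vector of residue numbers to keep.
#' @return The subset coordinate matrix.
#' @export
select_residues <- function(coords, residues) {
  keep <- rownames(coords) %in% as.character(residues)
  coords[keep, , drop = FALSE]
}

#' Write a helical profile (with curvature) as CSV
#'
#' Columns: `index`, `strand`, `twist_deg`, `rise_ang`,
#' `curvature_inv_ang` (NA where no full curvature window exists) and
#' `central` (0/1).
#'
#' @param profile A `helical_profile`.
#' @param path output CSV path.
#' @param curvature optional data frame from [axis_curvature()].
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, curvature = NULL) {
  out <- data.frame(index = profile$index, strand = profile$strand,
                    twist_deg = profile$twist, rise_ang = profile$rise,
                    curvature_inv_ang = NA_real_,
                    central = as.integer(profile$central))
  if (!is.null(curvature)) {
    m <- match(out$index, curvature$index)
    out$curvature_inv_ang <- curvature$curvature[m]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write occupancy profiles as CSV
#'
#' Columns: `frame`, `site`, `strand`, `intensity`, `occupancy`.
#'
#' @param profiles list of `occupancy_profile`s (or one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(profiles, path) {
  if (inherits(profiles, "occupancy_profile")) profiles <- list(profiles)
  all <- do.call(rbind, profiles)
  utils::write.csv(all[, c("frame", "site", "strand", "intensity",
                           "occupancy")], path, row.names = FALSE)
  invisible(path)
}

#' Write a channel image as a 16-bit TIFF
#'
#' Intensities are stored as 16-bit counts (values above 65535 are
#' clipped); integer-valued images below that ceiling round-trip
#' exactly.
#'
#' @param img a `channel_image` or numeric matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  px <- .as_pixels(img)
  scaled <- pmin(pmax(px, 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a 16-bit TIFF written by [write_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size pixel edge in micrometres for the returned image.
#' @param channel channel name.
#' @return A `channel_image` with intensities on the count scale.
#' @export
read_tiff <- function(path, pixel_size = 0.16, channel = "actin") {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  channel_image(round(m * 65535), pixel_size, channel)
}
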