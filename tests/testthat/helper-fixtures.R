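# Shared fixtures: small deterministic models, random rigid transforms,
# and independent brute-force oracles.

# a random proper rigid transform (rotation via QR of a Gaussian matrix)
random_transform <- function(seed, max_shift = 20) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, runif(3, -max_shift, max_shift))
}

# small protomer for fast geometry tests
small_protomer <- function() reference_protomer(radius = 6, offset = 8)

# independent Yen oracle: exhaustive criterion maximization over all
# candidate bin splits, computed with naive per-threshold sums
yen_brute_force <- function(values, n_bins = 256) {
  lo <- min(values); hi <- max(values)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, breaks,
                                       rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(n_bins - 1)) {
    p1 <- sum(p[1:t]); p2 <- 1 - p1
    g1 <- sum(p[1:t]^2); g2 <- sum(p[(t + 1):n_bins]^2)
    if (g1 <= 0 || g2 <= 0 || p1 <= 0 || p2 <= 0) next
    crit <- -log(g1 * g2) + 2 * log(p1 * p2)
    if (crit > best) { best <- crit; best_t <- t }
  }
  breaks[best_t + 1]
}

# hand-written minimal mmCIF encoding of per-chain CA coordinates
write_minimal_cif <- function(chains, path) {
  lines <- c("data_synthetic", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
             "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  k <- 0
  for (cn in names(chains)) {
    m <- chains[[cn]]
    for (r in seq_len(nrow(m))) {
      k <- k + 1
      lines <- c(lines, sprintf(
        "ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s CA 1",
        k, cn, r, m[r, 1], m[r, 2], m[r, 3], r, cn))
    }
  }
  writeLines(lines, path)
  path
}

# maximum frame-wise deviation between two filament models
max_frame_dev <- function(a, b) {
  max(vapply(seq_len(n_subunits(a)), function(k) {
    max(abs(a$transforms[[k]]$rotation - b$transforms[[k]]$rotation)) +
      max(abs(a$transforms[[k]]$translation - b$transforms[[k]]$translation))
  }, numeric(1)))
}
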