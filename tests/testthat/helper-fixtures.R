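# Programmatic fixtures: tiny alignments, toy structures, ideal helices.

tiny_msa <- function() {
  new_msa(c("s1", "s2", "s3", "s4"),
          c("NPFAWKDGEL", "NPFVWKDGEL", "NPYAWKEGEL", "NPFAWRDGEL"))
}

small_synth <- function(seed = 1, ...) generate_family(synth_config(seed = seed, ...))

# A hand-built vector_map (for geometry tests that need exact coordinates).
make_map <- function(coords, ids = NULL) {
  ids <- ids %||% paste0("p", seq_len(nrow(coords)))
  dimnames(coords) <- list(ids, paste0("D", seq_len(ncol(coords))))
  structure(list(ids = ids, coords = coords,
                 eigenvalues = rev(sort(colSums(coords^2))),
                 residual = 0, iterations = 0L),
            class = "vector_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a minimal PDB file from a coordinate table.
write_toy_pdb <- function(path, atoms) {
  # atoms: data.frame(elety, resid, chain, resno, x, y, z, b)
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, name, a$resid, a$chain, a$resno, a$x, a$y, a$z, 1.00, a$b)
  }
  writeLines(c(lines, "END"), path)
  path
}

# The same toy model as mmCIF.
write_toy_cif <- function(path, atoms) {
  head <- c("data_toy", "#", "loop_",
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
  rows <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    rows[i] <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
      i, substr(a$elety, 1, 1), a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$b, a$resno, a$resid, a$chain, a$elety)
  }
  writeLines(c(head, rows, "#"), path)
  path
}

toy_ca_atoms <- function() {
  data.frame(elety = "CA", resid = c("ALA", "GLY", "SER"), chain = "A",
             resno = 1:3,
             x = c(0, 3.8, 7.6), y = c(0, 0.5, -0.2), z = c(0, 1.1, 2.0),
             b = 0)
}

# Build backbone coordinates from ideal internal geometry (NeRF chain
# extension), for dihedral tests. Returns atoms data.frame with N, CA, C per
# residue.
build_backbone <- function(n_res, phi, psi, omega = 180) {
  place <- function(p1, p2, p3, bond, angle, dihedral) {
    angle <- angle * pi / 180; dihedral <- dihedral * pi / 180
    b1 <- p2 - p1; b2 <- p3 - p2
    b2n <- b2 / sqrt(sum(b2^2))
    n <- c(b1[2] * b2[3] - b1[3] * b2[2],
           b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * b2n[3] - n[3] * b2n[2],
           n[3] * b2n[1] - n[1] * b2n[3],
           n[1] * b2n[2] - n[2] * b2n[1])
    d <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
           bond * sin(angle) * sin(dihedral))
    p3 + b2n * d[1] + m * d[2] + n * d[3]
  }
  # bond lengths (A) and angles (deg) of the peptide backbone
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- list(N1 = c(0, 0, 0), CA1 = c(b_nca, 0, 0))
  coords$C1 <- c(b_nca - b_cac * cos(a_ncac * pi / 180),
                 b_cac * sin(a_ncac * pi / 180), 0)
  atoms <- list(c("N", 1), c("CA", 1), c("C", 1))
  xyz <- list(coords$N1, coords$CA1, coords$C1)
  prev <- list(N = coords$N1, CA = coords$CA1, C = coords$C1)
  for (r in 2:n_res) {
    n_new <- place(prev$N, prev$CA, prev$C, b_cn, a_cacn, psi)
    ca_new <- place(prev$CA, prev$C, n_new, b_nca, a_cnca, omega)
    c_new <- place(prev$C, n_new, ca_new, b_cac, a_ncac, phi)
    xyz <- c(xyz, list(n_new, ca_new, c_new))
    atoms <- c(atoms, list(c("N", r), c("CA", r), c("C", r)))
    prev <- list(N = n_new, CA = ca_new, C = c_new)
  }
  m <- do.call(rbind, xyz)
  data.frame(elety = vapply(atoms, `[`, "", 1),
             resid = "ALA", chain = "A",
             resno = as.integer(vapply(atoms, `[`, "", 2)),
             x = m[, 1], y = m[, 2], z = m[, 3], b = 0)
}
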