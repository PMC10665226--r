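# Structure-side utilities: PDB/mmCIF reading (via bio3d), Kabsch
# superposition, NCS-copy comparison, conservation-to-B-factor mapping,
# backbone dihedrals and the extended-linker length estimate.

#' Read a structure model from PDB or mmCIF
#'
#' Thin wrapper over bio3d's readers. Only the first alternate location
#' (blank or `'A'`) is kept; a model without C-alpha atoms is an error.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @return A `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  model <- if (ext %in% c("cif", "mmcif"))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  keep <- model$atom$alt %in% c(NA, "", " ", "A")
  if (!all(keep)) model <- bio3d::trim.pdb(model, inds = list(
    atom = which(keep), xyz = bio3d::atom2xyz(which(keep))))
  if (!any(model$atom$elety == "CA"))
    stop("no C-alpha atoms in ", path)
  model
}

# C-alpha coordinate matrix for a chain / residue span, with resno rownames.
#' @noRd
ca_coords <- function(model, chain = NULL, resno = NULL) {
  at <- model$atom
  sel <- at$elety == "CA"
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  if (any(sel & !is.na(at$insert) & at$insert != ""))
    stop("insertion codes in selected span are not supported")
  m <- as.matrix(at[sel, c("x", "y", "z")])
  rownames(m) <- at$resno[sel]
  m
}

#' Kabsch superposition of two coordinate sets
#'
#' Least-squares optimal rigid-body superposition (translation plus proper
#' rotation; reflections are disallowed as molecules are chiral) of `B` onto
#' `A`.
#'
#' @param A,B Numeric n x 3 matrices of matched atom coordinates (n >= 3).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (applied as `B %*% rotation + translation`), `rmsd`,
#'   `n_atoms`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in length (",
                               nrow(A), " vs ", nrow(B), ")")
  if (nrow(A) < 3L) stop("need at least 3 atom pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Bc, Ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  structure(list(rotation = R, translation = ca - drop(cb %*% R),
                 rmsd = rmsd, n_atoms = nrow(A)),
            class = "superposition")
}

#' Per-domain C-alpha RMSD between two NCS copies
#'
#' For each domain span, pairs C-alpha atoms of the two copies by residue
#' number offset within the span, superposes them (Kabsch) and reports the
#' RMSD. Residues missing from either copy are skipped with a warning; more
#' than 10% skipped in a domain is an error.
#'
#' @param model A `pdb` model containing both copies.
#' @param domain_ranges Data frame with columns `domain`, `chain1`, `start1`,
#'   `end1`, `chain2`, `start2`, `end2` (residue spans of equal length).
#' @return Data frame `domain`, `rmsd`, `n_atoms`, `n_skipped`.
#' @export
ncs_copy_rmsd <- function(model, domain_ranges) {
  need <- c("domain", "chain1", "start1", "end1", "chain2", "start2", "end2")
  stopifnot(all(need %in% names(domain_ranges)))
  out <- lapply(seq_len(nrow(domain_ranges)), function(i) {
    r <- domain_ranges[i, ]
    span1 <- r$start1:r$end1
    span2 <- r$start2:r$end2
    if (length(span1) != length(span2))
      stop("domain ", r$domain, ": spans differ in length")
    m1 <- ca_coords(model, r$chain1, span1)
    m2 <- ca_coords(model, r$chain2, span2)
    off1 <- span1[span1 %in% as.integer(rownames(m1))]
    off2 <- span2[span2 %in% as.integer(rownames(m2))]
    common <- intersect(off1 - r$start1, off2 - r$start2)
    skipped <- length(span1) - length(common)
    if (skipped > 0)
      warning(sprintf("domain %s: %d unmatched residue(s) skipped",
                      r$domain, skipped))
    if (skipped > 0.1 * length(span1))
      stop("domain ", r$domain, ": more than 10% of residues unmatched")
    A <- m1[match(common + r$start1, as.integer(rownames(m1))), , drop = FALSE]
    B <- m2[match(common + r$start2, as.integer(rownames(m2))), , drop = FALSE]
    fit <- kabsch_superpose(A, B)
    data.frame(domain = r$domain, rmsd = fit$rmsd, n_atoms = fit$n_atoms,
               n_skipped = skipped)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write residue conservation scores into the B-factor column
#'
#' Sets the B-factor of every atom of each listed residue to its score and
#' all other atoms to 0, then writes a PDB file. Coordinates and every other
#' column are carried over unchanged.
#'
#' @param model A `pdb` model.
#' @param chain Chain identifier the scores refer to.
#' @param scores Named numeric vector, names = residue numbers; or a data
#'   frame with columns `resno`, `score`.
#' @param out Output PDB path.
#' @return `out` invisibly; unresolvable residues are reported in a warning.
#' @export
map_conservation_to_bfactor <- function(model, chain, scores, out) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$resno)
  resno <- as.integer(names(scores))
  at <- model$atom
  b <- rep(0, nrow(at))
  unresolved <- integer(0)
  for (k in seq_along(resno)) {
    hit <- at$chain == chain & at$resno == resno[k]
    if (!any(hit)) unresolved <- c(unresolved, resno[k]) else
      b[hit] <- scores[k]
  }
  if (length(unresolved) > 0L)
    warning("residue(s) not found in chain ", chain, ": ",
            paste(unresolved, collapse = ", "))
  model$atom$b <- b
  bio3d::write.pdb(model, file = out)
  invisible(out)
}

# Signed dihedral angle (degrees) defined by four points.
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals over a residue span
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1). Angles
#' are reported in degrees in (-180, 180]; terminal residues (or residues
#' with missing backbone atoms, flagged) yield `NA` for the undefined angle.
#'
#' @param model A `pdb` model.
#' @param chain Chain identifier.
#' @param resno Integer vector of residue numbers (a contiguous span).
#' @return Data frame `resno`, `phi`, `psi`, `incomplete`.
#' @export
backbone_dihedrals <- function(model, chain, resno) {
  at <- model$atom
  get_atom <- function(rn, name) {
    hit <- which(at$chain == chain & at$resno == rn & at$elety == name)
    if (length(hit) == 0L) return(NULL)
    as.numeric(at[hit[1], c("x", "y", "z")])
  }
  resno <- sort(unique(as.integer(resno)))
  out <- data.frame(resno = resno, phi = NA_real_, psi = NA_real_,
                    incomplete = FALSE)
  for (i in seq_along(resno)) {
    rn <- resno[i]
    n <- get_atom(rn, "N"); ca <- get_atom(rn, "CA"); c <- get_atom(rn, "C")
    if (is.null(n) || is.null(ca) || is.null(c)) {
      out$incomplete[i] <- TRUE
      next
    }
    c_prev <- get_atom(rn - 1L, "C")
    n_next <- get_atom(rn + 1L, "N")
    if (!is.null(c_prev)) out$phi[i] <- dihedral_angle(c_prev, n, ca, c)
    if (!is.null(n_next)) out$psi[i] <- dihedral_angle(n, ca, c, n_next)
  }
  out
}

#' Extended-chain length of interdomain linkers
#'
#' A linker of `n_res` residues in extended (beta-strand-like) conformation
#' spans roughly `n_res * rise_per_res` nanometres; summed over the linkers
#' of a zone this estimates how much chain length their presence adds (or
#' their deletion removes). With the defaults, one three-residue linker
#' accounts for ~1 nm and the ten C-zone super-repeat copies for ~10 nm.
#'
#' @param n_res Residues per linker.
#' @param rise_per_res Rise per residue in nm (default 0.34, beta-strand).
#' @param n_linkers Number of linkers.
#' @return List with `per_linker_nm` and `total_nm`.
#' @export
linker_extension_estimate <- function(n_res = 3, rise_per_res = 0.34,
                                      n_linkers = 1) {
  stopifnot(n_res >= 0, rise_per_res > 0, n_linkers >= 0)
  per <- n_res * rise_per_res
  list(per_linker_nm = per, total_nm = per * n_linkers)
}
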