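#' Ligand-residue contact detection and scoring
#'
#' Contacts are typed heavy-atom pairs between a BW-annotated receptor
#' residue and the ligand. Each pair within the 4.63 Angstrom ceiling yields
#' at most one contact, typed by the highest-priority geometric rule it
#' satisfies (Covalent > Metal > Ionic > Hbond > Arene > Distance). The
#' distance-based interaction score is 1 at or below 3.23 Angstrom, 0 at or
#' above 4.63 Angstrom and linearly scaled in between; a score cutoff of 0.5
#' therefore keeps exactly the contacts closer than 3.93 Angstrom. Because
#' per-residue interaction energies from commercial docking software are not
#' reproducible, a documented surrogate assigns each contact the energy
#' -w(type) * score with fixed per-type well depths; downstream logic uses
#' only the ordering and sign of energies.
#'
#' @name contacts
NULL

.contact_types <- c("Covalent", "Metal", "Ionic", "Hbond", "Arene", "Distance")

#' Default surrogate well depths (kcal/mol scale)
#' @export
default_well_depths <- function() {
  c(Covalent = 10.0, Metal = 5.0, Ionic = 5.0, Hbond = 3.0, Arene = 2.0,
    Distance = 0.5)
}

#' Distance-based interaction score
#'
#' @param distance heavy-atom distance(s) in Angstrom; must be positive and
#'   finite.
#' @return score(s) in [0, 1]: 1 for d <= 3.23, 0 for d >= 4.63, linear
#'   in between ((4.63 - d) / 1.40).
#' @examples
#' interaction_score(c(3.0, 3.93, 5.0))  # 1, 0.5, 0
#' @export
interaction_score <- function(distance) {
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distance must be positive and finite")
  }
  pmin(1, pmax(0, (4.63 - distance) / 1.40))
}

#' Surrogate per-contact energy
#'
#' @param contact_type one of Covalent, Metal, Ionic, Hbond, Arene, Distance
#'   (vectorized).
#' @param score interaction score(s) in [0, 1].
#' @param well_depths named vector of per-type well depths.
#' @return energy = -w(type) * score, always <= 0.
#' @export
surrogate_energy <- function(contact_type, score,
                             well_depths = default_well_depths()) {
  if (any(!contact_type %in% names(well_depths))) {
    stop("unknown interaction type(s): ",
         paste(setdiff(contact_type, names(well_depths)), collapse = ", "))
  }
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]")
  -unname(well_depths[contact_type]) * score
}

# residue-template hydrogen-bond donor/acceptor roles (heavy atoms only)
.res_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1")
.res_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD")
# formally charged residue atoms at physiological pH (His treated neutral:
# its protonation is unknowable from a heavy-atom file)
.res_anions <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.res_cations <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
# aromatic ring atom sets per residue type
.res_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

.in_set <- function(resname, atom_name, tab) {
  tpl <- tab[[resname]]
  !is.null(tpl) && atom_name %in% tpl
}

#' Detect typed contacts in an annotated complex
#'
#' Only residues carrying a BW position emit contacts. Rules (heavy-atom
#' geometry; standard protein-ligand interaction fingerprint criteria):
#' Covalent d <= 1.9; Metal = ligand metal atom within 2.8 of residue O/N/S;
#' Ionic = opposite formal charges within 4.5 (Asp/Glu carboxylate oxygens
#' are anionic, Arg/Lys guanidinium/ammonium nitrogens cationic, ligand
#' charges from the file); Hbond = donor-acceptor pair within 3.5 with
#' template-derived residue roles, ligand N/O as both roles and S as
#' acceptor; Arene = both atoms in aromatic rings with centroid-centroid
#' distance <= 5.5, or a ring atom against a formal cation with
#' centroid-cation distance <= 5.0; Distance = any remaining pair within the
#' 4.63 ceiling.
#'
#' @param complex an annotated \code{gifp_complex}.
#' @param well_depths per-type surrogate well depths.
#' @return data.frame (class \code{gifp_contacts}): complex_id, bw_position,
#'   resname, residue_atom, ligand_atom, type, distance, score, energy.
#' @export
detect_contacts <- function(complex, well_depths = default_well_depths()) {
  stopifnot(inherits(complex, "gifp_complex"))
  res <- complex$residues
  if (all(is.na(res$bw))) stop("complex has no BW-annotated residues; ",
                               "run annotate_bw() first")
  la <- complex$ligand$atoms
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  lig_ring_of <- rep(NA_integer_, nrow(la))
  lig_centroids <- list()
  for (k in seq_along(complex$ligand$rings)) {
    idx <- complex$ligand$rings[[k]]
    lig_ring_of[idx] <- k
    lig_centroids[[k]] <- colMeans(lxyz[idx, , drop = FALSE])
  }

  akey <- .res_key(complex$atoms$chain, complex$atoms$resnum,
                   complex$atoms$icode)
  rkey <- .res_key(res$chain, res$resnum, res$icode)
  out <- vector("list", nrow(res))
  for (r in which(!is.na(res$bw))) {
    ra <- complex$atoms[akey == rkey[r], , drop = FALSE]
    rxyz <- as.matrix(ra[, c("x", "y", "z")])
    resname <- res$resname[r]
    ring_atoms <- .res_rings[[resname]]
    ring_centroid <- NULL
    if (!is.null(ring_atoms) && all(ring_atoms %in% ra$atom_name)) {
      ring_centroid <- colMeans(rxyz[match(ring_atoms, ra$atom_name), ,
                                     drop = FALSE])
    } else ring_atoms <- character(0)

    d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
    d2[d2 < 0] <- 0
    dmat <- sqrt(d2)
    hits <- which(dmat <= 4.63, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    rows <- vector("list", nrow(hits))
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]; j <- hits[h, 2]
      d <- dmat[i, j]
      ran <- ra$atom_name[i]; rel <- ra$element[i]
      lel <- la$element[j]; lchg <- la$charge[j]
      res_backbone_donor <- ran == "N" && resname != "PRO"
      res_donor <- res_backbone_donor || .in_set(resname, ran, .res_donors)
      res_acceptor <- ran == "O" || .in_set(resname, ran, .res_acceptors)
      res_anion <- .in_set(resname, ran, .res_anions)
      res_cation <- .in_set(resname, ran, .res_cations)
      lig_donor <- lel %in% c("N", "O")
      lig_acceptor <- lel %in% c("N", "O", "S")

      type <- "Distance"
      if (d <= 1.9) {
        type <- "Covalent"
      } else if (lel %in% .metal_elements && rel %in% c("O", "N", "S") &&
                 d <= 2.8) {
        type <- "Metal"
      } else if (d <= 4.5 &&
                 ((res_anion && lchg > 0) || (res_cation && lchg < 0))) {
        type <- "Ionic"
      } else if (d <= 3.5 &&
                 ((res_donor && lig_acceptor) || (res_acceptor && lig_donor))) {
        type <- "Hbond"
      } else {
        in_res_ring <- ran %in% ring_atoms
        in_lig_ring <- !is.na(lig_ring_of[j])
        arene <- FALSE
        if (in_res_ring && in_lig_ring) {
          cc <- sqrt(sum((ring_centroid - lig_centroids[[lig_ring_of[j]]])^2))
          arene <- cc <= 5.5
        }
        if (!arene && in_res_ring && lchg > 0) {
          arene <- sqrt(sum((ring_centroid - lxyz[j, ])^2)) <= 5.0
        }
        if (!arene && in_lig_ring && res_cation) {
          arene <- sqrt(sum((lig_centroids[[lig_ring_of[j]]] - rxyz[i, ])^2)) <= 5.0
        }
        if (arene) type <- "Arene"
      }
      rows[[h]] <- data.frame(bw_position = res$bw[r], resname = resname,
                              residue_atom = ran, ligand_atom = la$atom_name[j],
                              type = type, distance = d,
                              stringsAsFactors = FALSE)
    }
    out[[r]] <- do.call(rbind, rows)
  }
  ct <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ct)) {
    ct <- data.frame(bw_position = character(0), resname = character(0),
                     residue_atom = character(0), ligand_atom = character(0),
                     type = character(0), distance = numeric(0))
  }
  ct$score <- if (nrow(ct)) interaction_score(ct$distance) else numeric(0)
  ct$energy <- if (nrow(ct)) surrogate_energy(ct$type, ct$score, well_depths) else numeric(0)
  ct <- cbind(complex_id = rep(complex$complex_id, nrow(ct)), ct)
  rownames(ct) <- NULL
  class(ct) <- c("gifp_contacts", "data.frame")
  ct
}

#' Filter contacts by interaction score
#'
#' @param contacts a contacts data.frame.
#' @param cutoff score cutoff in [0, 1]; contacts with score >= cutoff are
#'   kept.
#' @return the filtered contacts.
#' @export
filter_by_score <- function(contacts, cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff >= 0, cutoff <= 1)
  contacts[contacts$score >= cutoff, , drop = FALSE]
}

#' Write/read a contacts table as TSV
#'
#' @param contacts contacts data.frame.
#' @param path file path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(complex_id = "character"))
  class(ct) <- c("gifp_contacts", "data.frame")
  ct
}
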