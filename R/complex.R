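#' Ligand-receptor complex container
#'
#' A \code{gifp_complex} bundles one receptor chain with one small-molecule
#' ligand: receptor heavy atoms (hydrogens are dropped on read; donor and
#' acceptor roles are assigned from heavy-atom templates so protonation-free
#' files work), a per-residue table carrying optional Ballesteros-Weinstein
#' annotations, the ligand atom/bond graph with aromatic rings, and metadata
#' used downstream by the classifier: \code{is_modeled} (1 for homology
#' models, 0 for experimental structures), \code{activation_state}
#' (active/inactive/intermediate/unknown) and \code{function_label}
#' (agonist/antagonist/inverse_agonist/inactive/unlabeled).
#'
#' @name gifp_complex
NULL

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

.activation_states <- c("active", "inactive", "intermediate", "unknown")
.function_labels <- c("agonist", "antagonist", "inverse_agonist", "inactive",
                      "unlabeled")

.res_key <- function(chain, resnum, icode) paste(chain, resnum, icode, sep = "|")

# unique residues of an atom table, in file order
.residue_table <- function(atoms) {
  key <- .res_key(atoms$chain, atoms$resnum, atoms$icode)
  first <- !duplicated(key)
  data.frame(chain = atoms$chain[first], resnum = atoms$resnum[first],
             icode = atoms$icode[first], resname = atoms$resname[first],
             bw = NA_character_, stringsAsFactors = FALSE)
}

# simple ring perception: chordless cycles of length 5 or 6 over C/N/O/S
.find_rings <- function(atoms, bonds) {
  if (nrow(bonds) == 0L || nrow(atoms) < 5L) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(atoms) - igraph::vcount(g)))
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(bonds$i[k], bonds$j[k])))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$i[k], to = bonds$j[k])$vpath[[1]])
    cyc <- as.integer(sp)
    if (length(cyc) %in% c(5L, 6L) &&
        all(atoms$element[cyc] %in% c("C", "N", "O", "S"))) {
      rings[[length(rings) + 1L]] <- sort(cyc)
    }
  }
  unique(rings)
}

.new_ligand <- function(ligand_id, atoms, bonds) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("ligand has no heavy atoms")
  rownames(atoms) <- NULL
  lig <- list(ligand_id = ligand_id,
              atoms = atoms[, c("atom_name", "element", "charge", "x", "y", "z")],
              bonds = bonds, rings = .find_rings(atoms, bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(atoms) - igraph::vcount(g)))
    if (igraph::components(g)$no > 1L) {
      warning("ligand bond graph is not connected over heavy atoms")
    }
  } else if (nrow(atoms) > 1L) {
    warning("ligand has multiple atoms but no bonds")
  }
  lig
}

.new_complex <- function(complex_id, receptor_id, atoms, ligand,
                         is_modeled = 0L, activation_state = "unknown",
                         function_label = "unlabeled") {
  stopifnot(is_modeled %in% c(0L, 1L),
            activation_state %in% .activation_states,
            function_label %in% .function_labels)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite receptor coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(complex_id = complex_id, receptor_id = receptor_id,
                 atoms = atoms, residues = .residue_table(atoms),
                 ligand = ligand, is_modeled = as.integer(is_modeled),
                 activation_state = activation_state,
                 function_label = function_label),
            class = "gifp_complex")
}

#' Read a receptor-ligand complex from a PDB file
#'
#' Retains one polymer chain and one small-molecule heteroatom group;
#' everything else (waters, ions, additional chains such as fusion partners,
#' lipids) is discarded. With \code{receptor_chain = "auto"} the chain with
#' the most residues is kept. With \code{ligand_selector = "auto"} the
#' heteroatom group with the most heavy atoms lying within 10 Angstrom of the
#' receptor is kept. Hydrogens are dropped; alternate locations are resolved
#' to the highest-occupancy conformer (ties to the first encountered). Ligand
#' bonds come from CONECT records when present, otherwise from a
#' covalent-radius distance rule (cutoff r_i + r_j + 0.45 Angstrom).
#'
#' @param pdb_path path to a PDB file.
#' @param ligand_selector heteroatom residue name, or \code{"auto"}.
#' @param receptor_chain chain identifier, or \code{"auto"}.
#' @param complex_id,receptor_id identifiers stored on the object; default to
#'   the file base name.
#' @param is_modeled 1 if the receptor is a homology model, 0 if experimental.
#' @param activation_state one of active, inactive, intermediate, unknown.
#' @param function_label ligand function: agonist, antagonist,
#'   inverse_agonist, inactive or unlabeled.
#' @return a \code{gifp_complex}.
#' @export
read_complex <- function(pdb_path, ligand_selector = "auto",
                         receptor_chain = "auto",
                         complex_id = sub("\\.[^.]*$", "", basename(pdb_path)),
                         receptor_id = complex_id,
                         is_modeled = 0L, activation_state = "unknown",
                         function_label = "unlabeled") {
  parsed <- read_pdb_atoms(pdb_path)
  atoms <- .resolve_altloc(parsed$atoms)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]

  poly <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0L) stop("no polymer chain in ", pdb_path)
  if (identical(receptor_chain, "auto")) {
    nres <- vapply(split(poly, poly$chain),
                   function(a) length(unique(.res_key(a$chain, a$resnum, a$icode))),
                   1L)
    receptor_chain <- names(nres)[which.max(nres)]
  }
  rec_atoms <- poly[poly$chain == receptor_chain, , drop = FALSE]
  if (nrow(rec_atoms) == 0L) stop("receptor chain ", receptor_chain, " not found")

  het <- atoms[atoms$record == "HETATM" & !(atoms$resname %in% .water_names), ,
               drop = FALSE]
  het <- het[!(het$element %in% .metal_elements &
                 ave(seq_len(nrow(het)),
                     .res_key(het$chain, het$resnum, het$icode),
                     FUN = length) == 1), , drop = FALSE]
  if (nrow(het) == 0L) stop("no candidate ligand heteroatom group in ", pdb_path)
  gkey <- paste(.res_key(het$chain, het$resnum, het$icode), het$resname)
  groups <- split(seq_len(nrow(het)), gkey)

  rxyz <- as.matrix(rec_atoms[, c("x", "y", "z")])
  near_receptor <- function(idx) {
    lxyz <- as.matrix(het[idx, c("x", "y", "z")])
    for (i in seq_len(nrow(lxyz))) {
      if (min(sqrt(colSums((t(rxyz) - lxyz[i, ])^2))) <= 10) return(TRUE)
    }
    FALSE
  }
  if (identical(ligand_selector, "auto")) {
    cand <- groups[vapply(groups, near_receptor, TRUE)]
    if (length(cand) == 0L) stop("no heteroatom group within 10 A of receptor")
    lig_idx <- cand[[which.max(vapply(cand, length, 1L))]]
  } else {
    cand <- groups[vapply(groups, function(i) het$resname[i[1]] == ligand_selector, TRUE)]
    if (length(cand) == 0L) stop("ligand '", ligand_selector, "' not found")
    if (length(cand) > 1L) {
      stop("ligand selector '", ligand_selector, "' matches multiple groups: ",
           paste(names(cand), collapse = "; "))
    }
    lig_idx <- cand[[1]]
  }
  lig_atoms <- het[lig_idx, , drop = FALSE]

  # bonds from CONECT when any pair references ligand serials, else inferred
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  con <- parsed$conect
  if (nrow(con)) {
    keep <- con[, 1] %in% lig_atoms$serial & con[, 2] %in% lig_atoms$serial
    con <- con[keep, , drop = FALSE]
    if (nrow(con)) {
      i <- match(con[, 1], lig_atoms$serial)
      j <- match(con[, 2], lig_atoms$serial)
      lo <- pmin(i, j); hi <- pmax(i, j)
      tab <- table(paste(lo, hi))
      ij <- do.call(rbind, strsplit(names(tab), " "))
      bonds <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                          order = pmax(1L, as.integer(round(as.integer(tab) / 2))))
      bonds <- bonds[bonds$i != bonds$j, , drop = FALSE]
    }
  }
  if (nrow(bonds) == 0L) bonds <- .infer_bonds(lig_atoms)

  ligand <- .new_ligand(lig_atoms$resname[1], lig_atoms, bonds)
  .new_complex(complex_id, receptor_id, rec_atoms, ligand,
               is_modeled = is_modeled, activation_state = activation_state,
               function_label = function_label)
}

#' Load a Ballesteros-Weinstein annotation table
#'
#' The table is a 4-column TSV (chain, author_number, insertion_code,
#' bw_position) with \code{"."} marking an empty insertion code and \code{"-"}
#' marking loop/terminal residues that carry no generic number. BW positions
#' must be unique within the table.
#'
#' @param annotation_path path to the TSV file.
#' @return data.frame with columns chain, resnum, icode, bw.
#' @export
load_bw_map <- function(annotation_path) {
  tab <- utils::read.delim(annotation_path, header = TRUE,
                           colClasses = "character", strip.white = TRUE)
  need <- c("chain", "author_number", "insertion_code", "bw_position")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[tab$bw_position != "-", , drop = FALSE]
  bw <- bw_position(tab$bw_position)
  if (anyDuplicated(bw)) {
    stop("duplicate BW position(s): ",
         paste(unique(bw[duplicated(bw)]), collapse = ", "))
  }
  data.frame(chain = tab$chain,
             resnum = as.integer(tab$author_number),
             icode = ifelse(tab$insertion_code == ".", "", tab$insertion_code),
             bw = bw, stringsAsFactors = FALSE)
}

#' Attach BW annotations to a complex
#'
#' Residues with no entry in the map are retained but flagged non-indexed
#' (bw = NA) and are excluded from contact profiles. Map rows referencing
#' residues absent from the complex only raise a warning. The operation is
#' idempotent.
#'
#' @param complex a \code{gifp_complex}.
#' @param bw_map data.frame from \code{\link{load_bw_map}}.
#' @return the annotated complex.
#' @export
annotate_bw <- function(complex, bw_map) {
  stopifnot(inherits(complex, "gifp_complex"))
  rk <- .res_key(complex$residues$chain, complex$residues$resnum,
                 complex$residues$icode)
  mk <- .res_key(bw_map$chain, bw_map$resnum, bw_map$icode)
  hit <- match(mk, rk)
  if (anyNA(hit)) {
    warning("annotation rows reference residues absent from complex: ",
            paste(mk[is.na(hit)], collapse = ", "))
  }
  complex$residues$bw <- NA_character_
  complex$residues$bw[hit[!is.na(hit)]] <- bw_map$bw[!is.na(hit)]
  assigned <- complex$residues$bw[!is.na(complex$residues$bw)]
  if (anyDuplicated(assigned)) stop("duplicate BW positions after annotation")
  complex
}

#' Serialize a complex to JSON (and back)
#'
#' @param complex a \code{gifp_complex}.
#' @param path output (input) file path.
#' @return \code{path} invisibly; \code{read_complex_json} returns the complex.
#' @export
write_complex_json <- function(complex, path) {
  stopifnot(inherits(complex, "gifp_complex"))
  obj <- unclass(complex)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_complex_json
#' @export
read_complex_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$residues$bw <- as.character(obj$residues$bw)
  obj$ligand$rings <- lapply(obj$ligand$rings, as.integer)
  if (is.null(obj$ligand$bonds) || length(obj$ligand$bonds) == 0L) {
    obj$ligand$bonds <- data.frame(i = integer(0), j = integer(0),
                                   order = integer(0))
  }
  structure(obj, class = "gifp_complex")
}

#' @export
print.gifp_complex <- function(x, ...) {
  nbw <- sum(!is.na(x$residues$bw))
  cat(sprintf("<gifp_complex> %s  receptor=%s  residues=%d (BW-indexed %d)\n",
              x$complex_id, x$receptor_id, nrow(x$residues), nbw))
  cat(sprintf("  ligand %s: %d heavy atoms, %d bonds, %d ring(s)\n",
              x$ligand$ligand_id, nrow(x$ligand$atoms), nrow(x$ligand$bonds),
              length(x$ligand$rings)))
  cat(sprintf("  is_modeled=%d  state=%s  label=%s\n", x$is_modeled,
              x$activation_state, x$function_label))
  invisible(x)
}
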