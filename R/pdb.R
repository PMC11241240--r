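#' Minimal fixed-width PDB reader/writer
#'
#' Supports ATOM/HETATM/TER/MODEL/ENDMDL/CONECT records, which is all the
#' package consumes. mmCIF is out of scope. Coordinates are in Angstrom,
#' author numbering (resSeq + insertion code) is preserved verbatim.
#'
#' @name pdb
#' @keywords internal
NULL

# single-bond covalent radii (Angstrom) used when CONECT records are absent;
# two atoms are bonded if d <= r_i + r_j + 0.45
.covalent_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, B = 0.84, SE = 1.20,
  NA. = 1.66, K = 2.03, MG = 1.41, CA = 1.76, ZN = 1.22, FE = 1.32,
  MN = 1.39, CU = 1.32, CO = 1.26, NI = 1.24
)

.metal_elements <- c("NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU", "CO", "NI")

.lookup_radius <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  r <- .covalent_radius[key]
  r[is.na(r)] <- 0.77
  unname(r)
}

.guess_element <- function(atom_name, resname) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("CL", "BR", "ZN", "FE", "MG", "MN", "CU", "CO", "NI", "SE", "NA", "CA", "K")
  # two-letter elements in PDB occupy columns 13-14; heuristically accept the
  # two-letter form only when it is a known element and not a common organic
  # atom-name prefix such as "CA" (alpha carbon) inside a standard residue
  el <- toupper(substr(nm, 1, 1))
  is_std_res <- resname %in% names(.aa3)
  use2 <- two %in% known2 & !(is_std_res & two %in% c("CA", "CL", "NA", "SE", "CO"))
  ifelse(use2, two, el)
}

.parse_charge <- function(txt) {
  txt <- trimws(txt)
  ifelse(grepl("^[0-9][+-]$", txt),
         as.integer(substr(txt, 1, 1)) * ifelse(substr(txt, 2, 2) == "-", -1L, 1L),
         ifelse(grepl("^[+-][0-9]$", txt),
                as.integer(substr(txt, 2, 2)) *
                  ifelse(substr(txt, 1, 1) == "-", -1L, 1L),
                0L))
}

#' Parse ATOM/HETATM records of a PDB file
#'
#' @param pdb_path path to a PDB file.
#' @param model which MODEL to read when the file is multi-model (default 1).
#' @return a list with \code{atoms} (data.frame: record, serial, atom_name,
#'   altloc, resname, chain, resnum, icode, x, y, z, occupancy, element,
#'   charge) and \code{conect} (two-column matrix of bonded serial pairs, with
#'   one row per bond occurrence so repeated pairs encode bond order).
#' @export
read_pdb_atoms <- function(pdb_path, model = 1L) {
  if (!file.exists(pdb_path)) stop("no such file: ", pdb_path)
  lines <- readLines(pdb_path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  has_models <- any(trimws(rec) == "MODEL")
  if (has_models) {
    starts <- which(trimws(rec) == "MODEL")
    ends <- which(trimws(rec) == "ENDMDL")
    if (model > length(starts)) stop("model ", model, " not present")
    keep_rng <- seq(starts[model] + 1L,
                    if (model <= length(ends)) ends[model] - 1L else length(lines))
    atom_idx <- intersect(which(rec %in% c("ATOM  ", "HETATM")), keep_rng)
  } else {
    atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  }
  if (length(atom_idx) == 0L) stop("no ATOM/HETATM records parsed from ", pdb_path)
  al <- lines[atom_idx]
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  al <- pad(al, 80)
  f <- function(a, b) substr(al, a, b)
  atoms <- data.frame(
    record = trimws(f(1, 6)),
    serial = suppressWarnings(as.integer(trimws(f(7, 11)))),
    atom_name = trimws(f(13, 16)),
    altloc = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resnum = suppressWarnings(as.integer(trimws(f(23, 26)))),
    icode = trimws(f(27, 27)),
    x = as.numeric(trimws(f(31, 38))),
    y = as.numeric(trimws(f(39, 46))),
    z = as.numeric(trimws(f(47, 54))),
    occupancy = {
      o <- suppressWarnings(as.numeric(trimws(f(55, 60))))
      ifelse(is.na(o), 1, o)
    },
    element = trimws(f(77, 78)),
    charge = .parse_charge(f(79, 80)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("non-numeric coordinates in ", pdb_path)
  }
  blank <- atoms$element == ""
  atoms$element[blank] <- .guess_element(atoms$atom_name[blank], atoms$resname[blank])
  atoms$element <- toupper(atoms$element)

  conect_idx <- which(rec == "CONECT")
  conect <- matrix(integer(0), ncol = 2)
  if (length(conect_idx)) {
    cl <- pad(lines[conect_idx], 31)
    base <- suppressWarnings(as.integer(trimws(substr(cl, 7, 11))))
    partner_cols <- list(c(12, 16), c(17, 21), c(22, 26), c(27, 31))
    pairs <- do.call(rbind, lapply(partner_cols, function(cc) {
      p <- suppressWarnings(as.integer(trimws(substr(cl, cc[1], cc[2]))))
      cbind(base, p)
    }))
    pairs <- pairs[!is.na(pairs[, 2]), , drop = FALSE]
    conect <- pairs
  }
  list(atoms = atoms, conect = conect)
}

# collapse altlocs: keep highest occupancy, tie -> first encountered
.resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$resname,
               atoms$atom_name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$occupancy[i])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

# infer bonds among a set of atoms by the covalent-radius distance rule
.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .lookup_radius(atoms$element)
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(xyz[(i + 1L):n, , drop = FALSE]) - xyz[i, ])^2))
    cutoff <- r[i] + r[(i + 1L):n] + 0.45
    hit <- which(d <= cutoff & d > 0.4)
    out_i <- c(out_i, rep.int(i, length(hit)))
    out_j <- c(out_j, i + hit)
  }
  data.frame(i = out_i, j = out_j, order = rep.int(1L, length(out_i)))
}

#' Write a complex back to PDB text
#'
#' Receptor residues are emitted as ATOM records, the ligand as HETATM
#' records followed by CONECT records for its bond graph.
#'
#' @param complex a \code{gifp_complex}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "gifp_complex"))
  fmt_atom <- function(record, serial, name, resname, chain, resnum, icode,
                       x, y, z, element, charge) {
    nm <- ifelse(nchar(name) < 4 & nchar(element) == 1, paste0(" ", name), name)
    chg <- ifelse(charge == 0, "  ",
                  paste0(abs(charge), ifelse(charge > 0, "+", "-")))
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
            record, serial, substr(nm, 1, 4), "", resname, chain, resnum, icode,
            x, y, z, 1, 0, element, chg)
  }
  a <- complex$atoms
  lines <- fmt_atom("ATOM", seq_len(nrow(a)), a$atom_name, a$resname, a$chain,
                    a$resnum, a$icode, a$x, a$y, a$z, a$element, 0L)
  lines <- c(lines, "TER")
  la <- complex$ligand$atoms
  off <- nrow(a) + 1L
  serial <- off + seq_len(nrow(la)) - 1L
  lines <- c(lines, fmt_atom("HETATM", serial, la$atom_name,
                             complex$ligand$ligand_id, "L",
                             rep.int(1L, nrow(la)), "",
                             la$x, la$y, la$z, la$element, la$charge))
  b <- complex$ligand$bonds
  if (nrow(b)) {
    con <- character(0)
    for (k in seq_len(nrow(b))) {
      # emit the pair once per bond order unit so order round-trips
      for (rep in seq_len(b$order[k])) {
        con <- c(con, sprintf("CONECT%5d%5d", serial[b$i[k]], serial[b$j[k]]),
                 sprintf("CONECT%5d%5d", serial[b$j[k]], serial[b$i[k]]))
      }
    }
    lines <- c(lines, con)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
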