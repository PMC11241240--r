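#' Synthetic fixtures: toy complexes, labeled profile tables, pose sets
#'
#' Every pipeline stage is testable without structure downloads. Toy
#' receptors are idealized single helices (3.6 residues per turn, 1.5
#' Angstrom rise) of glycines; residues hosting a planted contact carry a
#' single far-projected sidechain "tip" atom (or an aromatic ring) whose
#' chemistry matches the requested interaction type, and the ligand atom is
#' placed radially outward at exactly the planted distance. The geometry is
#' deliberately exaggerated (tips at 7 Angstrom from the helix axis) so that
#' the planted pair is the only atom pair within the 4.63 Angstrom contact
#' ceiling: contact detection on the generated file recovers exactly the
#' planted positions and types. Realism is unnecessary because downstream
#' code consumes only coordinates and annotations.
#'
#' @name synthetic
NULL

.helix_angle <- 100 * pi / 180  # 3.6 residues/turn
.helix_rise <- 1.5
.tip_radius <- 7.0

# residue template and legal distance window per planted interaction type;
# lower bounds avoid capture by a higher-priority rule (e.g. <= 1.9 is
# Covalent)
.plant_rules <- list(
  Covalent = list(resname = "CYS", tip = "SG", lig_el = "C", lig_chg = 0L,
                  dmin = 1.0, dmax = 1.9),
  Metal = list(resname = "ASN", tip = "OD1", lig_el = "ZN", lig_chg = 0L,
               dmin = 1.9, dmax = 2.8),
  Ionic = list(resname = "ASP", tip = "OD1", lig_el = "N", lig_chg = 1L,
               dmin = 1.9, dmax = 4.5),
  Hbond = list(resname = "SER", tip = "OG", lig_el = "O", lig_chg = 0L,
               dmin = 1.9, dmax = 3.5),
  Arene = list(resname = "PHE", tip = NA, lig_el = "C", lig_chg = 0L,
               dmin = 1.9, dmax = 4.63),
  Distance = list(resname = "ALA", tip = "CB", lig_el = "C", lig_chg = 0L,
                  dmin = 1.9, dmax = 4.63))

.phe_ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Generate a toy complex PDB with planted contacts
#'
#' @param planted_contacts data.frame with columns bw_position, type,
#'   distance (Angstrom, in (1, 6)). Distances beyond 4.63 produce no
#'   contact; distances inside the ceiling but incompatible with the
#'   requested type (e.g. an Hbond at 4.0) are rejected as geometrically
#'   unsatisfiable.
#' @param seed integer seed (used only for reproducible file naming jitter;
#'   the geometry is deterministic).
#' @param dir output directory (default \code{tempdir()}).
#' @param prefix file-name prefix.
#' @param n_residues helix length; enlarged automatically when many contacts
#'   are planted.
#' @return list(pdb_path, bw_path, planted) — paths to the PDB file and the
#'   matching BW annotation TSV.
#' @export
make_toy_complex <- function(planted_contacts = NULL, seed = 1L,
                             dir = tempdir(), prefix = NULL,
                             n_residues = 20L) {
  if (is.null(planted_contacts) || nrow(planted_contacts) == 0L) {
    planted_contacts <- data.frame(bw_position = character(0),
                                   type = character(0), distance = numeric(0))
  }
  np <- nrow(planted_contacts)
  if (np) {
    planted_contacts$bw_position <- bw_position(planted_contacts$bw_position)
    if (anyDuplicated(planted_contacts$bw_position)) {
      stop("duplicate planted BW positions")
    }
    for (k in seq_len(np)) {
      ty <- planted_contacts$type[k]
      d <- planted_contacts$distance[k]
      rule <- .plant_rules[[ty]]
      if (is.null(rule)) stop("unknown interaction type: ", ty)
      if (d <= 1.0 || d >= 6.0) stop("planted distance must lie in (1, 6)")
      if (d <= 4.63 && (d < rule$dmin || d > rule$dmax)) {
        stop(sprintf("geometrically unsatisfiable planting: %s at %.2f A (legal window %.2f-%.2f)",
                     ty, d, rule$dmin, rule$dmax))
      }
    }
  }
  n_res <- max(n_residues, 3L * np + 3L)
  plant_at <- if (np) 3L * seq_len(np) else integer(0)

  radial <- function(i, r, dz = 0) {
    th <- .helix_angle * i
    c(r * cos(th), r * sin(th), .helix_rise * i + dz)
  }
  atom_rows <- list()
  add_atom <- function(record, name, el, resname, resnum, xyz, chg = 0L) {
    atom_rows[[length(atom_rows) + 1L]] <<- data.frame(
      record = record, atom_name = name, element = el, resname = resname,
      resnum = resnum, x = xyz[1], y = xyz[2], z = xyz[3], charge = chg,
      stringsAsFactors = FALSE)
  }

  lig_atoms <- list()
  lig_serial <- 0L
  add_lig <- function(name, el, xyz, chg = 0L) {
    lig_serial <<- lig_serial + 1L
    lig_atoms[[lig_serial]] <<- data.frame(
      atom_name = name, element = el, x = xyz[1], y = xyz[2], z = xyz[3],
      charge = chg, stringsAsFactors = FALSE)
    lig_serial
  }
  lig_bonds <- list()
  add_bond <- function(i, j) {
    lig_bonds[[length(lig_bonds) + 1L]] <<- c(i, j)
  }

  for (i in seq_len(n_res)) {
    k <- match(i, plant_at)
    resname <- if (!is.na(k)) .plant_rules[[planted_contacts$type[k]]]$resname
               else "GLY"
    add_atom("ATOM", "N", "N", resname, i, radial(i - 0.3, 2.1))
    add_atom("ATOM", "CA", "C", resname, i, radial(i, 2.3))
    add_atom("ATOM", "C", "C", resname, i, radial(i + 0.3, 2.1))
    add_atom("ATOM", "O", "O", resname, i, radial(i + 0.35, 2.9, dz = 0.4))
    if (is.na(k)) next
    ty <- planted_contacts$type[k]
    d <- planted_contacts$distance[k]
    rule <- .plant_rules[[ty]]
    th <- .helix_angle * i
    u <- c(cos(th), sin(th), 0)                      # radial direction
    v <- c(-sin(th), cos(th), 0)                     # tangent
    w <- c(0, 0, 1)
    tip_center <- radial(i, .tip_radius)
    if (ty == "Arene") {
      # residue ring in the tangent plane, ligand ring parallel at distance d
      rr <- 1.4
      for (a in seq_along(.phe_ring)) {
        ang <- 2 * pi * (a - 1) / 6
        add_atom("ATOM", .phe_ring[a], "C", "PHE", i,
                 tip_center + rr * (cos(ang) * v + sin(ang) * w))
      }
      ring_ids <- integer(6)
      for (a in 1:6) {
        ang <- 2 * pi * (a - 1) / 6
        ring_ids[a] <- add_lig(paste0("C", lig_serial + 1L), "C",
                               tip_center + d * u +
                                 rr * (cos(ang) * v + sin(ang) * w))
      }
      for (a in 1:6) add_bond(ring_ids[a], ring_ids[a %% 6 + 1L])
      if (lig_serial > 6L) add_bond(ring_ids[1], 1L)
    } else {
      add_atom("ATOM", rule$tip, substr(rule$tip, 1, 1), rule$resname, i,
               tip_center)
      nm <- paste0(rule$lig_el, lig_serial + 1L)
      id <- add_lig(nm, rule$lig_el, tip_center + d * u, rule$lig_chg)
      if (id > 1L) add_bond(id, id - 1L)
    }
  }
  if (lig_serial == 0L) {
    mid <- n_res %/% 2L
    add_lig("C1", "C", radial(mid, 11.0))
  } else if (lig_serial == 1L &&
             lig_atoms[[1]]$element %in% .metal_elements) {
    # a lone metal atom would be discarded as an ion on read; tether a
    # carbon just beyond the contact ceiling so no extra contact appears
    i <- plant_at[1]
    th <- .helix_angle * i
    u <- c(cos(th), sin(th), 0)
    xyz1 <- c(lig_atoms[[1]]$x, lig_atoms[[1]]$y, lig_atoms[[1]]$z)
    id <- add_lig("C99", "C", xyz1 + 4.8 * u)
    add_bond(1L, id)
  }

  rec <- do.call(rbind, atom_rows)
  lig <- do.call(rbind, lig_atoms)

  # PDB text
  fmt <- function(record, serial, name, resname, chain, resnum, x, y, z, el, chg) {
    nm <- ifelse(nchar(name) < 4 & nchar(el) == 1, paste0(" ", name), name)
    chgtxt <- ifelse(chg == 0, "  ", paste0(abs(chg), ifelse(chg > 0, "+", "-")))
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
            record, serial, nm, resname, chain, resnum, x, y, z, 1, 0, el, chgtxt)
  }
  lines <- fmt("ATOM", seq_len(nrow(rec)), rec$atom_name, rec$resname, "A",
               rec$resnum, rec$x, rec$y, rec$z, rec$element, 0L)
  lines <- c(lines, "TER")
  off <- nrow(rec)
  lines <- c(lines, fmt("HETATM", off + seq_len(nrow(lig)), lig$atom_name,
                        "LIG", "L", 1L, lig$x, lig$y, lig$z, lig$element,
                        lig$charge))
  for (b in lig_bonds) {
    lines <- c(lines,
               sprintf("CONECT%5d%5d", off + b[1], off + b[2]),
               sprintf("CONECT%5d%5d", off + b[2], off + b[1]))
  }
  lines <- c(lines, "END")

  # BW annotation: planted residues keep their planted position, the rest
  # get filler numbers from segment 1 so spurious contacts stay visible
  bw <- character(n_res)
  bw[plant_at] <- planted_contacts$bw_position
  filler <- setdiff(paste0("1.", formatC(20:(19 + n_res + np), width = 2,
                                         flag = "0")),
                    planted_contacts$bw_position)
  bw[bw == ""] <- filler[seq_len(sum(bw == ""))]
  tsv <- c("chain\tauthor_number\tinsertion_code\tbw_position",
           sprintf("A\t%d\t.\t%s", seq_len(n_res), bw))

  if (is.null(prefix)) prefix <- sprintf("toy_%d_%d", seed, np)
  pdb_path <- file.path(dir, paste0(prefix, ".pdb"))
  bw_path <- file.path(dir, paste0(prefix, "_bw.tsv"))
  writeLines(lines, pdb_path)
  writeLines(tsv, bw_path)
  list(pdb_path = pdb_path, bw_path = bw_path, planted = planted_contacts)
}

#' Specification for a synthetic labeled profile dataset
#'
#' Defaults describe a corpus of 60 receptors with 10 complexes each (600
#' rows), four balanced functional classes, and strong class-specific
#' contact signatures: all three active classes share a favorable contact at
#' 3.32 (the classical class A anchor position) and each class additionally
#' has one distinctive position. Energies are Normal(mean, noise_sd)
#' truncated at zero; a small background contact probability and a fraction
#' of receptor-level absent positions exercise the NA semantics.
#'
#' @param n_receptors number of synthetic receptors.
#' @param complexes_per_receptor complexes per receptor.
#' @param positions BW position registry of the dataset.
#' @param class_signatures named list (one entry per function label) of
#'   data.frames with columns position, type, mean_energy.
#' @param noise_sd energy noise standard deviation (kcal/mol scale).
#' @param contact_prob_background probability of a spurious contact at a
#'   non-signature position.
#' @param na_fraction fraction of registry positions absent per receptor.
#' @param modeled_fraction fraction of receptors flagged as modeled.
#' @param seed integer seed.
#' @return list of class \code{gifp_synth_spec}.
#' @export
synthetic_spec <- function(n_receptors = 60L, complexes_per_receptor = 10L,
                           positions = c("2.53", "3.28", "3.32", "3.33",
                                         "3.36", "45.52", "5.42", "6.48",
                                         "6.51", "6.55", "7.39", "7.43"),
                           class_signatures = list(
                             agonist = data.frame(
                               position = c("3.32", "7.39"),
                               type = c("Ionic", "Hbond"),
                               mean_energy = c(-5, -6)),
                             antagonist = data.frame(
                               position = c("3.32", "6.55"),
                               type = c("Ionic", "Arene"),
                               mean_energy = c(-5, -6)),
                             inverse_agonist = data.frame(
                               position = c("3.32", "45.52"),
                               type = c("Ionic", "Hbond"),
                               mean_energy = c(-5, -6)),
                             inactive = data.frame(
                               position = "5.42", type = "Distance",
                               mean_energy = -0.4)),
                           noise_sd = 0.5, contact_prob_background = 0.05,
                           na_fraction = 0.15, modeled_fraction = 0.5,
                           seed = 1L) {
  stopifnot(contact_prob_background >= 0, contact_prob_background <= 1,
            na_fraction >= 0, na_fraction < 1, noise_sd >= 0,
            length(class_signatures) >= 2L)
  positions <- bw_sort(positions)
  for (sig in class_signatures) {
    if (!all(sig$position %in% positions)) {
      stop("signature references undeclared position(s)")
    }
    if (!all(sig$type %in% .contact_types)) stop("unknown signature type")
  }
  structure(list(n_receptors = as.integer(n_receptors),
                 complexes_per_receptor = as.integer(complexes_per_receptor),
                 positions = positions, class_signatures = class_signatures,
                 noise_sd = noise_sd,
                 contact_prob_background = contact_prob_background,
                 na_fraction = na_fraction,
                 modeled_fraction = modeled_fraction,
                 seed = as.integer(seed)),
            class = "gifp_synth_spec")
}

.trunc_neg <- function(n, mean, sd) pmin(0, stats::rnorm(n, mean, sd))

#' Generate a labeled synthetic feature table
#'
#' @param spec a \code{gifp_synth_spec}.
#' @return a \code{gifp_features} table with one row per complex and columns
#'   complex_id, label, is_modeled plus the five per-position fields.
#' @export
make_profile_dataset <- function(spec) {
  stopifnot(inherits(spec, "gifp_synth_spec"))
  labels <- names(spec$class_signatures)
  positions <- spec$positions
  .with_seed(spec$seed, {
    rows <- list()
    for (r in seq_len(spec$n_receptors)) {
      receptor <- sprintf("R%03d", r)
      absent <- sample(positions,
                       size = round(spec$na_fraction * length(positions)))
      modeled <- as.integer(stats::runif(1) < spec$modeled_fraction)
      for (c_i in seq_len(spec$complexes_per_receptor)) {
        label <- sample(labels, 1L)
        sig <- spec$class_signatures[[label]]
        vals <- list(
          complex_id = sprintf("%s_c%02d", receptor, c_i),
          label = label, is_modeled = modeled)
        for (pos in positions) {
          f <- function(suffix) paste0(pos, "_", suffix)
          if (pos %in% absent) {
            vals[[f("sum")]] <- NA_real_
            vals[[f("type1")]] <- "NA"; vals[[f("e1")]] <- NA_real_
            vals[[f("type2")]] <- "NA"; vals[[f("e2")]] <- NA_real_
            next
          }
          contacts <- data.frame(type = character(0), energy = numeric(0))
          si <- which(sig$position == pos)
          if (length(si)) {
            contacts <- rbind(contacts, data.frame(
              type = sig$type[si],
              energy = .trunc_neg(length(si), sig$mean_energy[si],
                                  spec$noise_sd)))
          }
          if (stats::runif(1) < spec$contact_prob_background) {
            contacts <- rbind(contacts, data.frame(
              type = sample(.contact_types, 1L),
              energy = -stats::runif(1, 0.2, 2)))
          }
          if (nrow(contacts) == 0L) {
            vals[[f("sum")]] <- 0
            vals[[f("type1")]] <- "None"; vals[[f("e1")]] <- 0
            vals[[f("type2")]] <- "None"; vals[[f("e2")]] <- 0
          } else {
            contacts <- contacts[order(contacts$energy,
                                       match(contacts$type, .contact_types)), ,
                                 drop = FALSE]
            vals[[f("sum")]] <- sum(contacts$energy)
            vals[[f("type1")]] <- contacts$type[1]
            vals[[f("e1")]] <- contacts$energy[1]
            if (nrow(contacts) >= 2L) {
              vals[[f("type2")]] <- contacts$type[2]
              vals[[f("e2")]] <- contacts$energy[2]
            } else {
              vals[[f("type2")]] <- "None"; vals[[f("e2")]] <- 0
            }
          }
        }
        rows[[length(rows) + 1L]] <-
          as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("gifp_features", "data.frame"),
              positions = positions)
  })
}

#' Generate a pose set at known displacements from a reference
#'
#' Each perturbation rotates the reference ligand about its centroid and
#' then translates it; a pure translation by t gives a ligand RMSD of
#' exactly t. Rotation axes and translation directions are drawn
#' reproducibly from the seed.
#'
#' @param reference a \code{gifp_complex} whose ligand is perturbed.
#' @param perturbations data.frame with columns rotation_deg and
#'   translation; one pose per row, in score order (first = best score).
#' @param seed integer seed.
#' @param n_top scoring-subset size.
#' @return a \code{gifp_pose_set}.
#' @export
make_pose_fixture <- function(reference, perturbations, seed = 1L,
                              n_top = 5L) {
  stopifnot(inherits(reference, "gifp_complex"), nrow(perturbations) >= 1L)
  xyz <- as.matrix(reference$ligand$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  .with_seed(seed, {
    poses <- lapply(seq_len(nrow(perturbations)), function(k) {
      ang <- perturbations$rotation_deg[k] * pi / 180
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                    axis[2], -axis[1], 0), 3, 3)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      sweep(sweep(xyz, 2, ctr) %*% t(R), 2,
            ctr + perturbations$translation[k] * dirv, "+")
    })
    pose_set(reference, poses, scores = seq_along(poses), n_top = n_top)
  })
}
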