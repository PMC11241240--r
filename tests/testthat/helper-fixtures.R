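# fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir()

# hand-built complex from residue/ligand atom specs (bypasses PDB parsing)
mini_complex <- function(residues, lig_atoms, lig_bonds = NULL,
                         complex_id = "mini", receptor_id = "MINI",
                         function_label = "unlabeled", is_modeled = 0L,
                         activation_state = "unknown") {
  atom_rows <- do.call(rbind, lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    data.frame(chain = "A", resnum = i, icode = "", resname = r$resname,
               atom_name = r$atoms$atom_name, element = r$atoms$element,
               x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
               stringsAsFactors = FALSE)
  }))
  if (is.null(lig_bonds)) {
    n <- nrow(lig_atoms)
    lig_bonds <- if (n >= 2) data.frame(i = seq_len(n - 1), j = 2:n,
                                        order = 1L)
    else data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  if (is.null(lig_atoms$charge)) lig_atoms$charge <- 0L
  lig <- gifp:::.new_ligand("LIG", lig_atoms, lig_bonds)
  cx <- gifp:::.new_complex(complex_id, receptor_id, atom_rows, lig,
                            is_modeled = is_modeled,
                            activation_state = activation_state,
                            function_label = function_label)
  cx$residues$bw <- vapply(residues, function(r)
    as.character(r$bw %||% NA), "")
  cx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

res_spec <- function(resname, bw, ...) {
  atoms <- data.frame(...)
  list(resname = resname, bw = bw, atoms = atoms)
}

atomdf <- function(atom_name, element, x, y, z, charge = 0L) {
  data.frame(atom_name = atom_name, element = element, x = x, y = y, z = z,
             charge = charge, stringsAsFactors = FALSE)
}

# minimal contacts row(s) for fingerprint/profile tests
fake_contacts <- function(bw, distance, type = "Distance",
                          complex_id = "cx") {
  score <- interaction_score(distance)
  data.frame(complex_id = complex_id, bw_position = bw, resname = "ALA",
             residue_atom = "CB",
             ligand_atom = paste0("C", seq_along(bw)), type = type,
             distance = distance, score = score,
             energy = surrogate_energy(type, score),
             stringsAsFactors = FALSE)
}

# random planted-contact spec for closed-loop tests (type-legal distances)
random_plant_spec <- function(n = 3L) {
  windows <- list(Covalent = c(1.2, 1.9), Metal = c(2.0, 2.8),
                  Ionic = c(2.0, 4.4), Hbond = c(2.0, 3.5),
                  Arene = c(2.5, 4.5), Distance = c(2.0, 4.5))
  types <- sample(names(windows), n, replace = TRUE)
  pool <- c(sprintf("2.%02d", 50:60), sprintf("3.%02d", 25:40),
            sprintf("45.%02d", 50:54), sprintf("6.%02d", 44:58),
            sprintf("7.%02d", 30:45))
  data.frame(
    bw_position = sample(pool, n),
    type = types,
    distance = vapply(types, function(t)
      round(stats::runif(1, windows[[t]][1], windows[[t]][2]), 2), 1.0),
    stringsAsFactors = FALSE)
}

# small labeled feature table with a perfectly separating planted column
toy_feature_table <- function(n_per_class = 30L, seed = 1L) {
  classes <- c("agonist", "antagonist", "inverse_agonist", "inactive")
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(classes), function(k) {
    n <- n_per_class
    data.frame(complex_id = sprintf("%s_%02d", classes[k], seq_len(n)),
               label = classes[k], is_modeled = rbinom(n, 1, 0.5),
               `3.32_sum` = rnorm(n, -2 * k, 0.3),
               `3.32_type1` = sample(c("Hbond", "Ionic"), n, replace = TRUE),
               `3.32_e1` = rnorm(n, -k, 0.3),
               `6.55_sum` = rnorm(n, 0, 1),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rows
}
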