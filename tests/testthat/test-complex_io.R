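pdb_line <- function(record, serial, name, resname, chain, resnum,
                     x, y, z, el, chg = "  ") {
  nm <- if (nchar(name) < 4 && nchar(el) == 1) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          record, serial, nm, resname, chain, resnum, x, y, z, 1, 0, el, chg)
}

# chain A: 20 GLY CA trace; chain B: 5 residues; two HET groups near chain A
two_chain_pdb <- function(path) {
  lines <- character(0)
  s <- 0L
  for (i in 1:20) {
    s <- s + 1L
    lines <- c(lines, pdb_line("ATOM", s, "CA", "GLY", "A", i, i * 3, 0, 0, "C"))
  }
  for (i in 1:5) {
    s <- s + 1L
    lines <- c(lines, pdb_line("ATOM", s, "CA", "GLY", "B", i, i * 3, 30, 0, "C"))
  }
  # 6-atom benzene-like group and a 12-atom group, both within 10 A
  for (a in 1:6) {
    s <- s + 1L
    lines <- c(lines, pdb_line("HETATM", s, paste0("C", a), "BNZ", "L", 1,
                               10 + 1.4 * cos(a * pi / 3), 5 + 1.4 * sin(a * pi / 3), 0, "C"))
  }
  for (a in 1:12) {
    s <- s + 1L
    lines <- c(lines, pdb_line("HETATM", s, paste0("C", a), "BIG", "L", 2,
                               20 + a, 5, 0, "C"))
  }
  # a water and a lone ion, both of which must be ignored
  s <- s + 1L
  lines <- c(lines, pdb_line("HETATM", s, "O", "HOH", "W", 1, 12, 5, 0, "O"))
  s <- s + 1L
  lines <- c(lines, pdb_line("HETATM", s, "NA", "NA", "I", 1, 14, 5, 0, "NA"))
  writeLines(c(lines, "END"), path)
  path
}

test_that("read_complex keeps the longest chain and the largest nearby ligand", {
  path <- two_chain_pdb(tempfile(fileext = ".pdb"))
  cx <- read_complex(path)
  expect_s3_class(cx, "gifp_complex")
  expect_equal(nrow(cx$residues), 20L)            # chain A won
  expect_true(all(cx$atoms$chain == "A"))
  expect_equal(nrow(cx$ligand$atoms), 12L)        # bigger group won
  expect_identical(cx$ligand$ligand_id, "BIG")
  # explicit selector picks the 6-atom group
  cx2 <- read_complex(path, ligand_selector = "BNZ")
  expect_equal(nrow(cx2$ligand$atoms), 6L)
  expect_error(read_complex(path, ligand_selector = "XYZ"), "not found")
})

test_that("ambiguous ligand selectors report their candidates", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
             pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3, 0, 0, "C"),
             pdb_line("ATOM", 3, "CA", "GLY", "A", 3, 6, 0, 0, "C"),
             pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 0, 5, 0, "C"),
             pdb_line("HETATM", 5, "C1", "LIG", "L", 2, 6, 5, 0, "C"),
             "END")
  writeLines(lines, path)
  expect_error(read_complex(path, ligand_selector = "LIG"),
               "matches multiple groups")
})

test_that("parse failures and empty het lists raise errors", {
  p <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", p)
  expect_error(read_complex(p), "no ATOM/HETATM")
  writeLines(c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"), "END"), p)
  expect_error(read_complex(p), "no candidate ligand")
  expect_error(read_complex(tempfile()), "no such file")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- tempfile(fileext = ".pdb")
  l1 <- pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C")
  substr(l1, 17, 17) <- "A"; substr(l1, 55, 60) <- "  0.40"
  l2 <- pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 9, 9, 9, "C")
  substr(l2, 17, 17) <- "B"; substr(l2, 55, 60) <- "  0.60"
  writeLines(c(l1, l2,
               pdb_line("ATOM", 3, "CA", "GLY", "A", 2, 3, 0, 0, "C"),
               pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 0, 5, 0, "C"),
               "END"), p)
  cx <- read_complex(p)
  ca <- cx$atoms[cx$atoms$resnum == 1, ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 9)
})

test_that("BW maps load with dot/dash conventions and reject duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tauthor_number\tinsertion_code\tbw_position",
               "A\t55\t.\t1.50", "A\t56\t.\t-", "A\t57\tA\t3.32"), p)
  m <- load_bw_map(p)
  expect_equal(nrow(m), 2L)  # the "-" row is dropped
  expect_equal(m$bw[m$resnum == 55], "1.50")
  expect_equal(m$icode[m$resnum == 57], "A")

  writeLines(c("chain\tauthor_number\tinsertion_code\tbw_position",
               "A\t1\t.\t3.32", "A\t2\t.\t3.32"), p)
  expect_error(load_bw_map(p), "duplicate BW position")
  writeLines(c("chain\tauthor_number\tinsertion_code\tbw_position",
               "A\t1\t.\tnot-a-bw"), p)
  expect_error(load_bw_map(p), "malformed")
})

test_that("annotation flags unmapped residues, warns on absent ones, and is idempotent", {
  fx <- make_toy_complex(seed = 2)
  cx <- read_complex(fx$pdb_path)
  map <- load_bw_map(fx$bw_path)
  map18 <- map[1:18, ]
  cx18 <- annotate_bw(cx, map18)
  expect_equal(sum(!is.na(cx18$residues$bw)), 18L)
  expect_equal(sum(is.na(cx18$residues$bw)), 2L)
  # idempotent
  expect_identical(annotate_bw(cx18, map18), cx18)
  # absent residue -> warning, otherwise unchanged
  map_bad <- rbind(map18, data.frame(chain = "A", resnum = 999L, icode = "",
                                     bw = "7.50"))
  expect_warning(cx_w <- annotate_bw(cx, map_bad), "absent from complex")
  expect_identical(cx_w$residues$bw, cx18$residues$bw)
  # empty map -> all non-indexed
  cx0 <- annotate_bw(cx, map[0, ])
  expect_true(all(is.na(cx0$residues$bw)))
})

test_that("PDB round-trip preserves counts and coordinates to 1e-3 A", {
  fx <- make_toy_complex(data.frame(bw_position = c("3.32", "6.55"),
                                    type = c("Hbond", "Arene"),
                                    distance = c(2.9, 3.8)), seed = 4)
  cx <- annotate_bw(read_complex(fx$pdb_path), load_bw_map(fx$bw_path))
  out <- tempfile(fileext = ".pdb")
  write_complex_pdb(cx, out)
  cx2 <- read_complex(out)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  expect_equal(nrow(cx2$residues), nrow(cx$residues))
  expect_equal(nrow(cx2$ligand$atoms), nrow(cx$ligand$atoms))
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               as.matrix(cx$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  expect_equal(as.matrix(cx2$ligand$atoms[, c("x", "y", "z")]),
               as.matrix(cx$ligand$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  # JSON round-trip preserves annotations and the bond graph
  js <- tempfile(fileext = ".json")
  write_complex_json(cx, js)
  cx3 <- read_complex_json(js)
  expect_equal(cx3$residues$bw, cx$residues$bw)
  expect_equal(cx3$ligand$bonds$order, cx$ligand$bonds$order)
  expect_equal(detect_contacts(cx3)$type, detect_contacts(cx)$type)
})

test_that("auto selection is deterministic for a fixed file", {
  path <- two_chain_pdb(tempfile(fileext = ".pdb"))
  a <- read_complex(path); b <- read_complex(path)
  expect_identical(a$ligand$atoms, b$ligand$atoms)
  expect_identical(a$residues, b$residues)
})
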