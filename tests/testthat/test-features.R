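profile_fixture <- function() {
  # one complex: 3.32 has Hbond (-3.0) + Distance (-0.4); 6.55 no contacts;
  # registry adds 7.39 which the receptor lacks
  cx <- mini_complex(
    residues = list(
      res_spec("SER", "3.32", atom_name = c("CA", "OG"),
               element = c("C", "O"), x = c(0, 4), y = 0, z = 0),
      res_spec("GLY", "6.55", atom_name = "CA", element = "C",
               x = 0, y = 30, z = 0)),
    lig_atoms = atomdf(c("O1", "C2"), c("O", "C"),
                       x = c(4, 4), y = c(3.23, -3.51), z = 0),
    complex_id = "fix1", function_label = "agonist")
  list(cx = cx, contacts = detect_contacts(cx))
}

test_that("profiles implement the NA / None / 0 semantics", {
  f <- profile_fixture()
  pr <- extract_profile(f$cx, f$contacts, registry = c("3.32", "6.55", "7.39"))
  p332 <- pr[pr$bw_position == "3.32", ]
  expect_equal(p332$type1, "Hbond")
  expect_equal(p332$energy1, -3.0, tolerance = 1e-6)
  expect_equal(p332$type2, "Distance")
  expect_equal(p332$energy2, surrogate_energy("Distance",
                                              interaction_score(3.51)),
               tolerance = 1e-6)
  expect_equal(p332$energy_sum, p332$energy1 + p332$energy2, tolerance = 1e-9)
  # present but contact-free -> zeros and None
  p655 <- pr[pr$bw_position == "6.55", ]
  expect_equal(unlist(p655[c("energy_sum", "energy1", "energy2")]),
               c(energy_sum = 0, energy1 = 0, energy2 = 0))
  expect_equal(c(p655$type1, p655$type2), c("None", "None"))
  # absent from receptor -> all NA
  p739 <- pr[pr$bw_position == "7.39", ]
  expect_true(all(is.na(unlist(p739[c("energy_sum", "energy1", "energy2")]))))
  expect_equal(c(p739$type1, p739$type2), c("NA", "NA"))
  # ordering invariant: energy1 <= energy2 <= 0, sum <= energy1
  expect_lte(p332$energy1, p332$energy2)
  expect_lte(p332$energy_sum, p332$energy1)
})

test_that("single-contact positions get a None second type", {
  f <- profile_fixture()
  one <- f$contacts[f$contacts$type == "Hbond", ]
  pr <- extract_profile(f$cx, one)
  p <- pr[pr$bw_position == "3.32", ]
  expect_equal(p$type1, "Hbond")
  expect_equal(p$type2, "None")
  expect_equal(p$energy2, 0)
})

test_that("profile extraction is permutation-invariant in contact order", {
  f <- profile_fixture()
  pr1 <- extract_profile(f$cx, f$contacts)
  pr2 <- extract_profile(f$cx, f$contacts[rev(seq_len(nrow(f$contacts))), ])
  expect_equal(pr1, pr2, ignore_attr = TRUE)
  expect_error(extract_profile(f$cx, fake_contacts("1.50", 3.0)),
               "absent from the complex")
})

make_profile <- function(id, sums, label = "agonist", modeled = 0L) {
  structure(data.frame(bw_position = names(sums), energy_sum = unname(sums),
                       type1 = ifelse(is.na(sums), "NA",
                                      ifelse(sums == 0, "None", "Hbond")),
                       energy1 = sums, type2 = ifelse(is.na(sums), "NA", "None"),
                       energy2 = ifelse(is.na(sums), NA, 0),
                       stringsAsFactors = FALSE),
            class = c("gifp_profile", "data.frame"), complex_id = id,
            is_modeled = modeled, function_label = label)
}

test_that("retention counts non-NA nonzero energy sums with a strict default", {
  mk <- function(n_active, n_total) {
    lapply(seq_len(n_total), function(i) {
      make_profile(paste0("c", i),
                   c("3.32" = if (i <= n_active) -2 else 0, "6.55" = 0))
    })
  }
  expect_equal(retained_positions(mk(11, 100)), "3.32")   # 11 > 10
  expect_equal(retained_positions(mk(10, 100)), character(0))  # strict
  expect_equal(retained_positions(mk(10, 100), strict = FALSE), "3.32")
  # all-NA position never retained
  pr <- list(make_profile("c1", c("3.32" = NA_real_)))
  expect_equal(retained_positions(pr, min_count = 0), character(0))
  # monotone growth: adding profiles never drops a retained position
  base <- mk(12, 20)
  more <- c(base, mk(12, 20))
  expect_true(all(retained_positions(base) %in% retained_positions(more)))
})

test_that("feature tables have the deterministic 5-per-position layout", {
  profs <- lapply(1:5, function(i)
    make_profile(paste0("c", i),
                 c("3.32" = -2, "6.55" = 0, "7.39" = NA),
                 label = c("agonist", "inactive")[1 + i %% 2],
                 modeled = i %% 2L))
  tab <- assemble_feature_table(profs, c("3.32", "6.55", "7.39"))
  expect_equal(nrow(tab), 5L)
  # 3 positions x 5 + is_modeled = 16 feature columns (+ complex_id, label)
  expect_equal(ncol(tab) - 2L, 16L)
  expect_equal(names(tab)[1:3], c("complex_id", "label", "is_modeled"))
  expect_equal(names(tab)[4:8],
               c("3.32_sum", "3.32_type1", "3.32_e1", "3.32_type2", "3.32_e2"))
  expect_equal(tab$is_modeled, c(1L, 0L, 1L, 0L, 1L))
  # empty position list -> metadata + is_modeled only
  tab0 <- assemble_feature_table(profs, character(0))
  expect_equal(names(tab0), c("complex_id", "label", "is_modeled"))
})

test_that("NA vs 0 survives a CSV round-trip bit-exactly", {
  profs <- list(make_profile("c1", c("3.32" = -2.25, "6.55" = 0)),
                make_profile("c2", c("3.32" = NA, "6.55" = -0.125)))
  tab <- assemble_feature_table(profs, c("3.32", "6.55"))
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(back$`3.32_sum`, tab$`3.32_sum`)
  expect_identical(back$`3.32_type1`, tab$`3.32_type1`)  # "NA" literal kept
  expect_identical(back$`6.55_e1`, tab$`6.55_e1`)
  expect_identical(attr(back, "positions"), attr(tab, "positions"))
})

test_that("class summaries expose planted differences", {
  profs <- c(
    lapply(1:6, function(i) make_profile(paste0("a", i), c("3.32" = -5),
                                         label = "agonist")),
    lapply(1:6, function(i) make_profile(paste0("i", i), c("3.32" = 0),
                                         label = "inactive")))
  tab <- assemble_feature_table(profs, "3.32")
  sm <- summarize_by_class(tab)
  a <- sm[sm$label == "agonist", ]; i <- sm[sm$label == "inactive", ]
  expect_equal(a$mean_energy_sum, -5)
  expect_equal(i$mean_energy_sum, 0)
  expect_equal(a$interaction_pct, 100)
  expect_equal(i$interaction_pct, 0)
  expect_equal(a$pct_Hbond, 100)
  expect_true(all(sm[, grep("^pct_", names(sm))] <= 100))
})
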