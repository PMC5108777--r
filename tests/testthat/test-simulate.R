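test_that("scaffold construction is deterministic and self-consistent", {
  a <- make_scaffold(scaffold_spec(seed = 4))
  b <- make_scaffold(scaffold_spec(seed = 4))
  expect_identical(a$record$residues, b$record$residues)
  c <- make_scaffold(scaffold_spec(seed = 5))
  expect_false(identical(a$record$residues, c$record$residues))

  chars <- strsplit(a$record$residues, "")[[1]]
  expect_equal(sum(chars == "W"), 14)
  expect_equal(paste(chars[284:288], collapse = ""), "GWRHT")
  expect_equal(paste(chars[410:411], collapse = ""), "VP")
  expect_equal(chars[43], "E")

  rep <- scan_sequence(a$record, a$annotation)
  expect_true(all(rep$calls$state == "EXACT"))

  expect_error(make_scaffold(scaffold_spec(length = 300)), "too short")
  expect_error(scaffold_spec(background = c(A = 1)), "19 non-W")
})

test_that("zero-rate evolution copies the scaffold to every leaf", {
  sc <- scaffold_fixture()
  fam <- evolve_family(sc, evolution_params(n_leaves = 5, subst_prob = 0,
                                            indel_rate = 0, seed = 2))
  expect_equal(nrow(fam$records), 5)
  expect_true(all(fam$records$residues == sc$record$residues))
  expect_true(all(fam$truth$knockout_sites == ""))
})

test_that("evolution is deterministic given the seed", {
  sc <- scaffold_fixture()
  p <- evolution_params(n_leaves = 6, subst_prob = 0.05, indel_rate = 0.5,
                        seed = 11)
  f1 <- evolve_family(sc, p)
  f2 <- evolve_family(sc, p)
  expect_identical(f1$records$residues, f2$records$residues)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
})

test_that("site protection keeps every annotated site exact", {
  sc <- scaffold_fixture()
  fam <- evolve_family(sc, evolution_params(n_leaves = 6, subst_prob = 0.05,
                                            indel_rate = 0.5, seed = 13))
  reports <- scan_dataset(fam$records, sc$annotation)
  for (r in reports) {
    expect_true(all(r$calls$state == "EXACT"), label = r$sequence_id)
    expect_equal(r$tryptophan_at_ref_positions, 14)
  }
})

test_that("knockout directives edit their target and are recorded", {
  sc <- scaffold_fixture()
  fam <- evolve_family(sc, evolution_params(
    n_leaves = 4, subst_prob = 0, seed = 21,
    knockouts = list(list(leaf = "t2", site = "VP_core", edit = "delete"),
                     list(leaf = "t3", site = "blade6_GWRHT",
                          edit = "conservative_swap"))))
  reports <- scan_dataset(fam$records, sc$annotation)
  expect_false(report_state(reports[["t2"]], "VP_core") == "EXACT")
  expect_equal(fam$truth$knockout_sites[fam$truth$id == "t2"], "VP_core")

  b6 <- reports[["t3"]]$calls[reports[["t3"]]$calls$site == "blade6_GWRHT", ]
  expect_equal(b6$state, "CONSERVATIVE")
  expect_true(b6$observed %in% c("GWRHS", "GWKHT"))

  expect_error(evolve_family(sc, evolution_params(
    n_leaves = 4, knockouts = list(list(leaf = "t9", site = "VP_core",
                                        edit = "delete")))),
    "unknown knockout leaf")
  expect_error(evolve_family(sc, evolution_params(
    n_leaves = 4, knockouts = list(list(leaf = "t1", site = "bogus",
                                        edit = "delete")))),
    "unknown site")
})

test_that("dataset generation writes regenerable files with copy design", {
  cfg <- list(
    scaffold = list(length = 440, seed = 1),
    evolution = list(subst_prob = 0.02, seed = 3),
    species_design = list(
      list(species = "Physcomitrella patens", copies = 2, clade = "bryophyte"),
      list(species = "Arabidopsis thaliana", copies = 1, clade = "dicot"),
      list(species = "Oryza sativa", copies = 1, clade = "monocot")))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(cfg, d1)
  ds2 <- generate_dataset(cfg, d2)
  expect_identical(readLines(ds1$paths$fasta), readLines(ds2$paths$fasta))
  expect_identical(readLines(ds1$paths$truth), readLines(ds2$paths$truth))

  expect_equal(nrow(ds1$records), 4)
  expect_equal(sort(table(ds1$records$species), decreasing = TRUE)[[1]], 2)

  sc <- make_scaffold()
  reports <- scan_dataset(ds1$records, sc$annotation)
  cls <- classify_reports(reports)
  cls$species <- ds1$records$species
  cn <- copy_number_summary(cls, ds1$metadata)
  expect_equal(cn$per_species$copies[cn$per_species$species ==
                                       "Physcomitrella patens"], 2)
  expect_true(all(cls$tier == "STRICT_HOMOLOG"))

  expect_error(generate_dataset(list(scaffold = list()), d1),
               "required field")
  expect_error(generate_dataset(list(scaffold = list(), evolution = list(),
                                     species_design = list(list(copies = 1))),
                                d1), "species")
})

test_that("NJ recovers the generating topology for clean families", {
  sc <- scaffold_fixture()
  hits <- 0
  for (seed in 1:8) {
    fam <- evolve_family(sc, evolution_params(n_leaves = 6,
                                              subst_prob = 0.05,
                                              seed = 500 + seed))
    msa <- build_pseudo_msa(fam$records, sc$record)
    keep <- rownames(msa) != sc$record$id
    D <- p_distance_matrix(msa[keep, , drop = FALSE])
    nj_tree <- neighbor_joining(D)
    if (ape::dist.topo(ape::unroot(fam$tree), nj_tree) == 0) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
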