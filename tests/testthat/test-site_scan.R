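# Most tests scan edited copies of the scaffold against its own annotation;
# edits are made directly at reference coordinates so the expected call is
# known by construction.

scan_edited <- function(pos, chars, site) {
  sc <- scaffold_fixture()
  q <- one_record("edited", edit_at(sc$record$residues, pos, chars))
  rep <- scan_sequence(q, sc$annotation)
  rep$calls[rep$calls$site == site, , drop = FALSE]
}

test_that("motif calls walk the exact/conservative/degraded/absent ladder", {
  # blade6 GWRHT occupies 284-288: T288S and R286K are the conservative
  # substitutions, R286S matches the degraded oomycete form GWSHT,
  # S286+S288 the diatom form GWSHS
  expect_equal(scan_edited(288, "S", "blade6_GWRHT")$state, "CONSERVATIVE")
  expect_equal(scan_edited(288, "S", "blade6_GWRHT")$observed, "GWRHS")
  expect_equal(scan_edited(286, "K", "blade6_GWRHT")$state, "CONSERVATIVE")
  expect_equal(scan_edited(286, "S", "blade6_GWRHT")$state, "DEGRADED")
  expect_equal(scan_edited(286, "S", "blade6_GWRHT")$observed, "GWSHT")
  expect_equal(scan_edited(c(286, 288), c("S", "S"), "blade6_GWRHT")$state,
               "DEGRADED")
  # the W is invariant: replacing it can never be conservative
  expect_equal(scan_edited(285, "F", "blade6_GWRHT")$state, "DEGRADED")
  # three non-conservative mismatches kill the motif
  absent <- scan_edited(284:288, c("A", "A", "A", "H", "T"), "blade6_GWRHT")
  expect_equal(absent$state, "ABSENT")
  expect_equal(absent$observed, "")
})

test_that("an X never satisfies a motif or residue check", {
  expect_equal(scan_edited(288, "X", "blade6_GWRHT")$state, "DEGRADED")
  expect_equal(scan_edited(286, "X", "R286")$state, "DEGRADED")
})

test_that("residue calls honour projection, identity and the flag", {
  sc <- scaffold_fixture()
  self <- scan_sequence(sc$record, sc$annotation)
  expect_equal(report_state(self, "R286"), "EXACT")

  expect_equal(scan_edited(286, "K", "R286")$state, "DEGRADED")
  q <- one_record("k286", edit_at(sc$record$residues, 286, "K"))
  rep_flag <- scan_sequence(q, sc$annotation, accept_conservative = TRUE)
  expect_equal(report_state(rep_flag, "R286"), "CONSERVATIVE")

  # C-terminal truncation before the C27 region: VP unaligned, not absent
  trunc <- one_record("trunc", substr(sc$record$residues, 1, 380))
  rep <- scan_sequence(trunc, sc$annotation)
  expect_equal(report_state(rep, "VP_core"), "UNALIGNED")
})

test_that("tryptophan census counts totals and reference positions", {
  sc <- scaffold_fixture()
  p <- alignment_params()
  self_map <- build_coordinate_map(
    global_align(sc$record$residues, sc$record$residues, p))
  expect_equal(unname(tryptophan_census(sc$record$residues, self_map,
                                        sc$annotation)), c(14, 14))

  w_out <- edit_at(sc$record$residues, 285, "A")
  map <- build_coordinate_map(global_align(w_out, sc$record$residues, p))
  expect_equal(unname(tryptophan_census(w_out, map, sc$annotation)), c(13, 13))

  no_w <- gsub("W", "A", sc$record$residues)
  map <- build_coordinate_map(global_align(no_w, sc$record$residues, p))
  expect_equal(unname(tryptophan_census(no_w, map, sc$annotation)), c(0, 0))
})

test_that("self-scan of the scaffold is all-EXACT with identity 100", {
  sc <- scaffold_fixture()
  rep <- scan_sequence(sc$record, sc$annotation)
  expect_true(all(rep$calls$state == "EXACT"))
  expect_equal(rep$identity_percent, 100)
  expect_equal(rep$tryptophan_total, 14)
  expect_equal(rep$tryptophan_at_ref_positions, 14)
})

test_that("deleting the VP core leaves every other site EXACT", {
  sc <- scaffold_fixture()
  q <- one_record("novp", delete_at(sc$record$residues, 410:411))
  rep <- scan_sequence(q, sc$annotation)
  vp <- rep$calls[rep$calls$site == "VP_core", ]
  expect_true(vp$state %in% c("ABSENT", "UNALIGNED"))
  others <- rep$calls[rep$calls$site != "VP_core", ]
  expect_true(all(others$state == "EXACT"))
})

test_that("targeted edits flag exactly the overlapping annotated sites", {
  sc <- scaffold_fixture()
  # each annotated site with the reference positions its edit touches;
  # expected flags are the sites sharing those positions
  sites <- list(
    blade5_GWRHT = 232:236, blade6_GWRHT = 284:288, blade7_GWRHT = 336:340,
    VP_core = 410:411, E43 = 43, D44 = 44, D96 = 96, D107 = 107,
    W233 = 233, W285 = 285, R286 = 286, W337 = 337, R338 = 338)
  for (target in names(sites)) {
    pos <- sites[[target]]
    q <- one_record(target, edit_at(sc$record$residues, pos, "A"))
    rep <- scan_sequence(q, sc$annotation)
    flagged <- rep$calls$site[rep$calls$state != "EXACT"]
    expected <- names(sites)[vapply(sites, function(p)
      length(intersect(p, pos)) > 0, logical(1))]
    expect_setequal(flagged, expected)
  }
})

test_that("scan_motif agrees with the exhaustive window-scan oracle", {
  sc <- scaffold_fixture()
  p <- alignment_params()
  set.seed(23)
  blade6 <- sc$annotation$motifs[[2]]
  for (k in 1:25) {
    q <- edit_at(sc$record$residues,
                 sample(270:300, sample(1:4, 1)),
                 sample(AA20_TEST, 4, replace = TRUE)[1])
    map <- build_coordinate_map(global_align(q, sc$record$residues, p))
    expect_equal(scan_motif(q, map, blade6, slack = 5)$state,
                 oracle_scan_state(q, map, blade6, slack = 5))
  }
})

test_that("random unrelated sequences fall below the 40% identity screen", {
  sc <- scaffold_fixture()
  set.seed(31)
  below <- vapply(1:5, function(k) {
    q <- one_record(paste0("r", k), rand_protein(440))
    scan_sequence(q, sc$annotation)$identity_percent
  }, numeric(1))
  expect_true(all(below < 40))
})

test_that("site report tables serialise one row per sequence-site pair", {
  sc <- scaffold_fixture()
  reports <- scan_dataset(rbind(sc$record,
                                one_record("b", sc$record$residues)),
                          sc$annotation)
  tab <- site_report_table(reports)
  expect_equal(nrow(tab), 2 * 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_reports(reports, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 26)
  expect_true(all(back$state == "EXACT"))
})
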