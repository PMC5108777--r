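test_that("pseudo-MSA stacks pairwise alignments on reference columns", {
  sc <- scaffold_fixture()
  ref <- sc$record
  L <- nchar(ref$residues)

  # reference alone: one gap-free row
  solo <- build_pseudo_msa(ref[0, ], ref)
  expect_equal(dim(solo), c(1L, L))
  expect_false(any(solo == "-"))

  # one internal deletion: exactly those columns gapped
  del <- one_record("del", delete_at(ref$residues, 150:154))
  msa <- build_pseudo_msa(del, ref)
  expect_equal(dim(msa), c(2L, L))
  expect_equal(sum(msa["del", ] == "-"), 5)
  expect_true(all(msa["del", 150:154] == "-"))

  # an insertion is invisible: row length stays L, no gaps introduced
  v <- strsplit(ref$residues, "")[[1]]
  ins <- one_record("ins", paste(c(v[1:200], "A", "A", "A", v[201:length(v)]),
                                 collapse = ""))
  msa2 <- build_pseudo_msa(ins, ref)
  expect_equal(ncol(msa2), L)
  expect_false(any(msa2["ins", ] == "-"))
  expect_equal(paste(msa2["ins", ], collapse = ""), ref$residues)
})

test_that("column filter applies gap-fraction and entropy thresholds", {
  # 20 rows: column 1 all identical (entropy 0, kept); column 2 twenty
  # distinct residues (normalized entropy 1, dropped); column 3 60% gaps
  # (dropped); column 4 half-and-half residues (entropy ~0.23, kept)
  msa <- cbind(rep("A", 20), AA20_TEST, c(rep("-", 12), rep("A", 8)),
               rep(c("A", "C"), 10))
  rownames(msa) <- paste0("r", 1:20)
  mask <- filter_columns(msa)
  expect_equal(unname(mask), c(TRUE, FALSE, FALSE, TRUE))
  # check the derived entropy values directly
  expect_equal(-sum(rep(1 / 20, 20) * log(1 / 20)) / log(20), 1)
  expect_lt(-sum(rep(0.5, 2) * log(0.5)) / log(20), 0.5)
})

test_that("column filter depends only on column contents", {
  set.seed(17)
  msa <- matrix(sample(c(AA20_TEST, "-"), 10 * 30, replace = TRUE), 10, 30)
  rownames(msa) <- paste0("r", 1:10)
  m1 <- filter_columns(msa)
  perm <- sample(10)
  m2 <- filter_columns(msa[perm, ])
  expect_equal(unname(m1), unname(m2))
})

test_that("p-distances count mismatches over comparable kept columns", {
  msa <- rbind(a = strsplit("GWRHT", "")[[1]], b = strsplit("GWRHS", "")[[1]])
  expect_equal(p_distance_matrix(msa)["a", "b"], 0.2)
  msa2 <- rbind(a = strsplit("GWRHT", "")[[1]], b = strsplit("AYDEC", "")[[1]])
  expect_equal(p_distance_matrix(msa2)["a", "b"], 1)
  same <- rbind(a = strsplit("GWRHT", "")[[1]], b = strsplit("GWRHT", "")[[1]])
  expect_equal(p_distance_matrix(same)["a", "b"], 0)
  gappy <- rbind(a = c("G", "-", "R"), b = c("-", "W", "R"))
  expect_error(p_distance_matrix(gappy, mask = c(TRUE, TRUE, FALSE)),
               "no comparable columns")
})

test_that("NJ solves the 3-taxon star in closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.5)  # (2 + 3 - 4) / 2
  expect_equal(len[["B"]], 1.5)
  expect_equal(len[["C"]], 2.5)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  asym <- D; asym[1, 2] <- 9
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("NJ exactly recovers additive trees up to 8 taxa", {
  set.seed(19)
  for (k in 1:15) {
    case <- random_additive_case(sample(4:8, 1))
    nj_tree <- neighbor_joining(case$D)
    # path-length metric of the reconstruction equals the input distances,
    # which for additive input pins both topology and branch lengths
    D2 <- ape::cophenetic.phylo(nj_tree)
    ids <- rownames(case$D)
    expect_lt(max(abs(D2[ids, ids] - case$D)), 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), nj_tree), 0,
                 ignore_attr = TRUE)
  }
})

test_that("4-taxon additive quartet recovers topology and internal branch", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);")
  D <- ape::cophenetic.phylo(tr)
  nj_tree <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj_tree), 0,
               ignore_attr = TRUE)
  internal <- nj_tree$edge.length[nj_tree$edge[, 2] > ape::Ntip(nj_tree)]
  expect_equal(internal, 2)
})

test_that("negative NJ branch estimates are clamped with a warning", {
  D <- matrix(c(0, 1, 10, 11, 1, 0, 10.5, 10, 10, 10.5, 0, 0.2,
                11, 10, 0.2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(tr <- neighbor_joining(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and saturate on clean data", {
  set.seed(29)
  case <- random_additive_case(6)
  # translate the tree into a clean alignment: evolve the scaffold along
  # it with a moderate substitution rate and no indels
  sc <- scaffold_fixture()
  fam <- evolve_family(sc, evolution_params(tree = case$tree,
                                            subst_prob = 0.05, seed = 3))
  msa <- build_pseudo_msa(fam$records, sc$record)
  mask <- filter_columns(msa, max_entropy = 1)  # keep variable columns
  t1 <- bootstrap_support(msa, mask, n_reps = 30, seed = 77)
  t2 <- bootstrap_support(msa, mask, n_reps = 30, seed = 77)
  expect_identical(t1$node.label, t2$node.label)

  one <- bootstrap_support(msa, mask, n_reps = 1, seed = 5)
  sup <- one$node.label[!is.na(one$node.label)]
  expect_true(all(sup %in% c(0, 100)))
})

test_that("newick output round-trips topology and renders supports", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  txt <- readLines(f)
  expect_match(txt, "A:0.5")
  expect_match(txt, "C:2.5")
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)

  set.seed(41)
  case <- random_additive_case(5)
  sc <- scaffold_fixture()
  fam <- evolve_family(sc, evolution_params(tree = case$tree,
                                            subst_prob = 0.05, seed = 9))
  msa <- build_pseudo_msa(fam$records, sc$record)
  boot <- bootstrap_support(msa, n_reps = 10, seed = 1)
  write_newick(boot, f)
  expect_match(readLines(f), "\\)[0-9]")  # support labels on internal nodes
  back2 <- ape::read.tree(f)
  expect_equal(ape::dist.topo(back2, boot), 0, ignore_attr = TRUE)
})
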