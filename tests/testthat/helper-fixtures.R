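# Shared fixtures, built in code at test time.

# Default synthetic scaffold + annotation, built once per session.
scaffold_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_scaffold()
    cache
  }
})

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n, letters = AA20_TEST) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Replaces reference positions `pos` of a residue string with `chars`.
edit_at <- function(residues, pos, chars) {
  v <- strsplit(residues, "")[[1]]
  v[pos] <- chars
  paste(v, collapse = "")
}

# Deletes reference positions `pos` from a residue string.
delete_at <- function(residues, pos) {
  v <- strsplit(residues, "")[[1]]
  paste(v[-pos], collapse = "")
}

one_record <- function(id, residues, species = "", source_tag = "synthetic") {
  seq_records(id = id, residues = residues, species = species,
              source_tag = source_tag)
}

# Exhaustive global-alignment oracle: enumerates every global alignment
# (three moves, affine gap state carried explicitly) and returns the
# optimal score. Independent of the package's alignment engine.
oracle_align_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= na) {
      cost <- if (identical(prev, "D")) gap_extend else gap_open
      best <- max(best, -cost + rec(i + 1, j, "D"))
    }
    if (j <= nb) {
      cost <- if (identical(prev, "I")) gap_extend else gap_open
      best <- max(best, -cost + rec(i, j + 1, "I"))
    }
    best
  }
  rec(1, 1, "M")
}

# Exhaustive motif window-scan oracle: enumerates every placement of the
# pattern inside the projected window and scores mismatches directly.
oracle_scan_state <- function(query, map, motif, slack) {
  win <- project_window(map, motif$ref_anchor[1], motif$ref_anchor[2], slack)
  plen <- nchar(motif$canonical)
  if (is.null(win)) return("UNALIGNED")
  canon <- strsplit(motif$canonical, "")[[1]]
  best <- c(Inf, Inf)
  for (s in seq.int(win[1], max(win[1], win[2] - plen + 1))) {
    if (s + plen - 1 > nchar(query)) next
    obs <- strsplit(substr(query, s, s + plen - 1), "")[[1]]
    total <- 0; noncons <- 0
    for (i in seq_len(plen)) {
      if (obs[i] == canon[i]) next
      total <- total + 1
      cons <- motif$conservative[[as.character(i)]]
      if (i %in% motif$invariant || is.null(cons) || !(obs[i] %in% cons)) {
        noncons <- noncons + 1
      }
    }
    if (noncons < best[1] || (noncons == best[1] && total < best[2])) {
      best <- c(noncons, total)
    }
  }
  if (!is.finite(best[1])) return("UNALIGNED")
  if (best[2] == 0) "EXACT"
  else if (best[1] == 0) "CONSERVATIVE"
  else if (best[1] <= 2 && 2 * best[1] < plen) "DEGRADED"
  else "ABSENT"
}

# Random additive distance matrix realised on a random binary tree;
# returns the generating tree and its path-length (cophenetic) matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = TRUE,
                   br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# State of one site's call inside a report.
report_state <- function(report, site) {
  report$calls$state[report$calls$site == site]
}

# Builds a minimal synthetic site_report for classifier unit tests.
fake_report <- function(states, identity = 90, id = "fake") {
  sites <- c("blade5_GWRHT", "blade6_GWRHT", "blade7_GWRHT", "VP_core",
             "E43", "D44", "D96", "D107", "W233", "W285", "R286", "W337",
             "R338")
  st <- rep("EXACT", length(sites))
  names(st) <- sites
  st[names(states)] <- unlist(states)
  structure(list(sequence_id = id, species = "",
                 identity_percent = identity,
                 calls = data.frame(site = sites, state = unname(st),
                                    observed = "", query_pos = NA_integer_,
                                    mismatches = 0L, nonconservative = 0L,
                                    stringsAsFactors = FALSE),
                 tryptophan_total = 14, tryptophan_at_ref_positions = 14),
            class = "site_report")
}
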