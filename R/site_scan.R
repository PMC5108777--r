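SITE_STATES <- c("EXACT", "CONSERVATIVE", "DEGRADED", "ABSENT", "UNALIGNED")

site_call <- function(site_name, state, observed = "", query_pos = NA_integer_,
                      mismatch_count = 0L, n_nonconservative = 0L) {
  state <- match.arg(state, SITE_STATES)
  data.frame(site = site_name, state = state, observed = observed,
             query_pos = as.integer(query_pos),
             mismatches = as.integer(mismatch_count),
             nonconservative = as.integer(n_nonconservative),
             stringsAsFactors = FALSE)
}

# Scores one placement of a motif pattern on the query. Returns total
# mismatches vs the canonical pattern and the non-conservative subset
# (deviations at invariant positions, or to residues outside the
# position's conservative set; X never matches anything).
score_placement <- function(obs_chars, motif) {
  canon <- strsplit(motif$canonical, "")[[1]]
  diff <- obs_chars != canon
  noncons <- vapply(seq_along(canon), function(i) {
    if (!diff[i]) return(FALSE)
    if (i %in% motif$invariant) return(TRUE)
    cons <- motif$conservative[[as.character(i)]]
    is.null(cons) || !(obs_chars[i] %in% cons)
  }, logical(1))
  c(total = sum(diff), noncons = sum(noncons))
}

#' Call a motif on a query sequence
#'
#' Projects the motif's reference anchor through the coordinate map,
#' widens it by `slack`, and evaluates every placement of the pattern
#' inside the projected window. The placement with fewest non-conservative
#' mismatches (ties: fewest total mismatches, then leftmost) determines
#' the call: `EXACT` (canonical), `CONSERVATIVE` (all deviations inside
#' per-position conservative sets at non-invariant positions), `DEGRADED`
#' (at most 2 non-conservative mismatches, and strictly fewer than half
#' the pattern positions — for the 5-mer GWRHT that is 1-2, keeping
#' oomycete-style GWSHT visible as degraded; for the VP dipeptide any
#' mismatch is already `ABSENT`), `ABSENT` (worse at every placement), or
#' `UNALIGNED` (the anchor does not project onto the query at all).
#'
#' @param query residue string of the candidate protein.
#' @param map `coordinate_map` of the query against the motif's reference.
#' @param motif a [motif_definition].
#' @param slack non-negative window widening in residues (default 5).
#' @return A one-row site-call `data.frame`.
#' @export
scan_motif <- function(query, map, motif, slack = 5) {
  win <- project_window(map, motif$ref_anchor[1], motif$ref_anchor[2], slack)
  plen <- nchar(motif$canonical)
  if (is.null(win)) return(site_call(motif$name, "UNALIGNED"))
  starts <- seq.int(win[1], max(win[1], win[2] - plen + 1))
  starts <- starts[starts + plen - 1 <= nchar(query)]
  if (!length(starts)) return(site_call(motif$name, "UNALIGNED"))
  qchars <- strsplit(query, "")[[1]]
  scores <- vapply(starts, function(s) {
    score_placement(qchars[s:(s + plen - 1)], motif)
  }, numeric(2))
  best <- order(scores["noncons", ], scores["total", ], starts)[1]
  total <- scores["total", best]
  noncons <- scores["noncons", best]
  obs <- substr(query, starts[best], starts[best] + plen - 1)
  if (total == 0) {
    site_call(motif$name, "EXACT", obs, starts[best], 0L, 0L)
  } else if (noncons == 0) {
    site_call(motif$name, "CONSERVATIVE", obs, starts[best], total, 0L)
  } else if (noncons <= 2 && 2 * noncons < plen) {
    site_call(motif$name, "DEGRADED", obs, starts[best], total, noncons)
  } else {
    site_call(motif$name, "ABSENT", "", NA_integer_, total, noncons)
  }
}

#' Call a single functional residue on a query sequence
#'
#' @param query residue string of the candidate protein.
#' @param map `coordinate_map` of the query against the reference.
#' @param residue a [residue_definition].
#' @param accept_conservative when `TRUE`, residues in the definition's
#'   conservative set are called `CONSERVATIVE`; by default any deviation
#'   from the canonical residue is `DEGRADED` (identity calling, the
#'   convention used for presence/absence tallies).
#' @return A one-row site-call `data.frame`.
#' @export
check_residue <- function(query, map, residue, accept_conservative = FALSE) {
  q <- project_position(map, residue$ref_pos)
  if (is.na(q)) return(site_call(residue$name, "UNALIGNED"))
  obs <- substr(query, q, q)
  if (obs == residue$canonical) {
    site_call(residue$name, "EXACT", obs, q, 0L, 0L)
  } else if (accept_conservative && obs %in% residue$conservative) {
    site_call(residue$name, "CONSERVATIVE", obs, q, 1L, 0L)
  } else {
    site_call(residue$name, "DEGRADED", obs, q, 1L, 1L)
  }
}

#' Tryptophan census of a query sequence
#'
#' @param query residue string.
#' @param map `coordinate_map` of the query against the reference.
#' @param annotation a `reference_annotation` (supplies the reference
#'   tryptophan positions).
#' @return `c(total, at_ref_positions)`: the number of W residues in the
#'   query, and how many of the reference's annotated tryptophan positions
#'   project onto a W in the query.
#' @export
tryptophan_census <- function(query, map, annotation) {
  qchars <- strsplit(query, "")[[1]]
  total <- sum(qchars == "W")
  at_ref <- sum(vapply(annotation$tryptophan_positions, function(p) {
    q <- project_position(map, p)
    !is.na(q) && qchars[q] == "W"
  }, logical(1)))
  c(total = total, at_ref_positions = at_ref)
}

#' Scan one candidate sequence against a reference annotation
#'
#' Aligns the candidate globally to the annotation's reference, builds the
#' coordinate map, and emits one call per annotated motif and residue plus
#' the tryptophan census and alignment identity.
#'
#' @param record a single-row [seq_records] table (the candidate).
#' @param annotation a `reference_annotation`.
#' @param params [alignment_params].
#' @param slack motif window slack in residues (default 5).
#' @param accept_conservative passed to [check_residue].
#' @return A list of class `site_report`: `sequence_id`, `species`,
#'   `identity_percent`, `calls` (one row per site), `tryptophan_total`,
#'   `tryptophan_at_ref_positions`, and the coordinate `map`.
#' @export
scan_sequence <- function(record, annotation, params = alignment_params(),
                          slack = 5, accept_conservative = FALSE) {
  stopifnot(nrow(record) == 1)
  query <- record$residues[1]
  aln <- global_align(query, annotation$reference$residues[1], params)
  map <- build_coordinate_map(aln)
  calls <- do.call(rbind, c(
    lapply(annotation$motifs, function(m) scan_motif(query, map, m, slack)),
    lapply(annotation$residues, function(r)
      check_residue(query, map, r, accept_conservative))
  ))
  census <- tryptophan_census(query, map, annotation)
  structure(list(sequence_id = record$id[1], species = record$species[1],
                 identity_percent = map$identity_percent, calls = calls,
                 tryptophan_total = unname(census["total"]),
                 tryptophan_at_ref_positions = unname(census["at_ref_positions"]),
                 map = map),
            class = "site_report")
}

#' Scan a set of candidate sequences
#'
#' @param records a [seq_records] table.
#' @param annotation,params,slack,accept_conservative see [scan_sequence].
#' @return A named list of `site_report`s, one per record.
#' @export
scan_dataset <- function(records, annotation, params = alignment_params(),
                         slack = 5, accept_conservative = FALSE) {
  reports <- lapply(seq_len(nrow(records)), function(k) {
    scan_sequence(records[k, , drop = FALSE], annotation, params, slack,
                  accept_conservative)
  })
  names(reports) <- records$id
  reports
}

# Looks up the call row for one site in a report; errors on unknown sites.
report_call <- function(report, site_name) {
  row <- report$calls[report$calls$site == site_name, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown site name: ", site_name)
  row
}

#' Flatten site reports to a per-site table
#'
#' @param reports a list of `site_report`s.
#' @return A `data.frame` with one row per (sequence, site):
#'   `sequence_id`, `species`, `site`, `state`, `observed`, `query_pos`,
#'   `mismatches`, `identity_percent`, `tryptophan_total`,
#'   `tryptophan_at_ref_positions`.
#' @export
site_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(sequence_id = r$sequence_id, species = r$species,
               site = r$calls$site, state = r$calls$state,
               observed = r$calls$observed, query_pos = r$calls$query_pos,
               mismatches = r$calls$mismatches,
               identity_percent = r$identity_percent,
               tryptophan_total = r$tryptophan_total,
               tryptophan_at_ref_positions = r$tryptophan_at_ref_positions,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write site reports as TSV
#'
#' @param reports a list of `site_report`s.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_site_reports <- function(reports, path) {
  write.table(site_report_table(reports), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
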