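#' Tally presence of one site across reports
#'
#' @param reports a list of `site_report`s (non-empty).
#' @param site_name an annotated site name.
#' @param present_states site states counted as "present"
#'   (default `EXACT` and `CONSERVATIVE`, matching how conservatively
#'   substituted motifs are tallied among conserved homologs; pass
#'   `"EXACT"` alone for strict counting).
#' @return `c(n_present, n_total)`.
#' @export
tally_site <- function(reports, site_name,
                       present_states = c("EXACT", "CONSERVATIVE")) {
  if (length(reports) == 0) stop("no reports to tally")
  states <- vapply(reports, function(r) report_call(r, site_name)$state, "")
  c(n_present = sum(states %in% present_states), n_total = length(reports))
}

#' Integer conservation percentage (round half up)
#'
#' @param n_present,n_total counts with `0 <= n_present <= n_total`,
#'   `n_total > 0`.
#' @return `100 * n_present / n_total` rounded half-up to an integer,
#'   e.g. 97 of 102 gives 95.
#' @export
percent_present <- function(n_present, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_present < 0 || n_present > n_total) {
    stop("n_present must lie in [0, n_total]")
  }
  as.integer(floor(100 * n_present / n_total + 0.5))
}

#' Conservation table over all annotated sites
#'
#' One row per site (optionally per clade x site) with present/total
#' counts and the rounded percentage.
#'
#' @param reports a list of `site_report`s.
#' @param present_states see [tally_site].
#' @param metadata optional species metadata `data.frame` (from
#'   [read_species_metadata]); when supplied, per-clade rows are appended
#'   after the overall rows.
#' @return A `data.frame` with columns `scope`, `site`, `n_present`,
#'   `n_total`, `percent`, `present_states`.
#' @export
conservation_table <- function(reports,
                               present_states = c("EXACT", "CONSERVATIVE"),
                               metadata = NULL) {
  sites <- reports[[1]]$calls$site
  one_scope <- function(scope, reps) {
    do.call(rbind, lapply(sites, function(s) {
      t <- tally_site(reps, s, present_states)
      data.frame(scope = scope, site = s, n_present = t[["n_present"]],
                 n_total = t[["n_total"]],
                 percent = percent_present(t[["n_present"]], t[["n_total"]]),
                 present_states = paste(present_states, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one_scope("overall", reports)
  if (!is.null(metadata)) {
    clade_of <- stats::setNames(metadata$clade, metadata$species)
    clades <- vapply(reports, function(r) {
      c <- clade_of[r$species]
      if (is.na(c)) "other" else c
    }, "")
    for (cl in sort(unique(clades))) {
      out <- rbind(out, one_scope(cl, reports[clades == cl]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-species copy-number summary of homolog sequences
#'
#' Counts homolog-tier sequences per species and summarises the copy-count
#' distribution: the share of species carrying more than one copy, and the
#' distribution over copy counts among those multi-copy species.
#'
#' @param classification a `data.frame` from [classify_reports].
#' @param metadata optional species metadata; species absent from it are
#'   counted under their raw species string with a warning.
#' @param tiers tiers counted as homologs (default strict + putative).
#' @return A list of class `copy_number_summary`: `per_species`
#'   (`species`, `copies`), `n_species`, `percent_multi_copy`, and
#'   `multi_copy_distribution` (`copies`, `n_species`, `percent` among
#'   multi-copy species).
#' @export
copy_number_summary <- function(classification, metadata = NULL,
                                tiers = c("STRICT_HOMOLOG", "PUTATIVE_HOMOLOG")) {
  hom <- classification[classification$tier %in% tiers, , drop = FALSE]
  if (nrow(hom) == 0) stop("no homolog-tier sequences to summarise")
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(hom$species), metadata$species)
    if (length(unknown)) {
      warning("species not in metadata, counted under their raw label: ",
              paste(unknown, collapse = ", "))
    }
  }
  counts <- table(hom$species)
  per_species <- data.frame(species = names(counts),
                            copies = as.integer(counts),
                            stringsAsFactors = FALSE)
  per_species <- per_species[order(per_species$species), , drop = FALSE]
  rownames(per_species) <- NULL
  multi <- per_species$copies > 1
  dist <- if (any(multi)) {
    tab <- table(per_species$copies[multi])
    data.frame(copies = as.integer(names(tab)),
               n_species = as.integer(tab),
               percent = round(100 * as.integer(tab) / sum(multi), 1),
               stringsAsFactors = FALSE)
  } else {
    data.frame(copies = integer(), n_species = integer(), percent = numeric())
  }
  structure(list(per_species = per_species,
                 n_species = nrow(per_species),
                 percent_multi_copy = percent_present(sum(multi),
                                                      nrow(per_species)),
                 multi_copy_distribution = dist),
            class = "copy_number_summary")
}

#' Write a conservation summary to TSV
#'
#' Output is deterministic: identical inputs render byte-identical files.
#'
#' @param table a `data.frame` from [conservation_table].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
render_summary <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
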