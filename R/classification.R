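HOMOLOG_TIERS <- c("STRICT_HOMOLOG", "PUTATIVE_HOMOLOG", "REMOTE_RCC1_LIKE",
                   "NON_HOMOLOG")

DIMER_SITES <- c("E43", "D44", "D96", "D107", "R286", "R338")

present_state <- function(state) state %in% c("EXACT", "CONSERVATIVE")

#' Classify a scanned sequence into a homology tier
#'
#' Tiers, from strongest to weakest evidence:
#' `STRICT_HOMOLOG` - blade-6 GWRHT present (exact or conservative) and the
#' VP core exactly conserved; `PUTATIVE_HOMOLOG` - blade-6 GWRHT present
#' but VP not exact (degraded, absent or unaligned, as in several green
#' algae); `REMOTE_RCC1_LIKE` - blade-6 motif not present and overall
#' identity below the threshold (RCC1-style beta-propellers and the
#' degraded oomycete/diatom sequences); `NON_HOMOLOG` otherwise. The rule
#' is monotone: improving any single site call never demotes the tier.
#'
#' @param report a `site_report`.
#' @param identity_threshold percent identity separating remote
#'   beta-propeller relatives from non-homologs (default 40).
#' @return One of the tier labels.
#' @export
classify_homolog <- function(report, identity_threshold = 40) {
  blade6 <- report_call(report, "blade6_GWRHT")$state
  vp <- report_call(report, "VP_core")$state
  if (present_state(blade6)) {
    if (vp == "EXACT") "STRICT_HOMOLOG" else "PUTATIVE_HOMOLOG"
  } else if (report$identity_percent < identity_threshold) {
    "REMOTE_RCC1_LIKE"
  } else {
    "NON_HOMOLOG"
  }
}

#' Assess UV-B photoreception competence
#'
#' True when both W233 and W285 — the two tryptophans most important for
#' UV-B perception, W285 being the main sensor — are exactly conserved.
#' W337, which plays an auxiliary role, is not required.
#'
#' @param report a `site_report`.
#' @return Logical flag.
#' @export
assess_photoreception <- function(report) {
  report_call(report, "W233")$state == "EXACT" &&
    report_call(report, "W285")$state == "EXACT"
}

#' Assess homodimerization competence
#'
#' The UVR8 dimer is held by salt bridges between R286/R338 of one monomer
#' and D96/D107 (blade 2) and D44/E43 (blade 1) of the other; loss of any
#' of the six predicts a constitutive monomer.
#'
#' @param report a `site_report`.
#' @return A list: `dimer_competent` (all six interface residues present),
#'   `monomer_predicted` (an arginine or acidic partner is missing) and
#'   `missing` (names of the non-present interface residues).
#' @export
assess_dimerization <- function(report) {
  states <- vapply(DIMER_SITES, function(s) report_call(report, s)$state, "")
  missing <- DIMER_SITES[!present_state(states)]
  arg_lost <- any(c("R286", "R338") %in% missing)
  acidic_lost <- any(setdiff(DIMER_SITES, c("R286", "R338")) %in% missing)
  list(dimer_competent = length(missing) == 0,
       monomer_predicted = arg_lost || acidic_lost,
       missing = missing)
}

#' Full homolog call for one report
#'
#' @param report a `site_report`.
#' @param identity_threshold see [classify_homolog].
#' @return A list of class `homolog_call`: `sequence_id`, `tier`,
#'   `photoreception_competent`, `dimer_competent`, `monomer_predicted`,
#'   `missing_sites`, `identity_percent`, `rationale`.
#' @export
classify_report <- function(report, identity_threshold = 40) {
  tier <- classify_homolog(report, identity_threshold)
  dim <- assess_dimerization(report)
  photo <- assess_photoreception(report)
  rationale <- c(
    sprintf("blade6_GWRHT=%s", report_call(report, "blade6_GWRHT")$state),
    sprintf("VP_core=%s", report_call(report, "VP_core")$state),
    sprintf("identity=%.1f%%", report$identity_percent),
    if (length(dim$missing))
      paste("missing interface residues:", paste(dim$missing, collapse = ","))
  )
  structure(list(sequence_id = report$sequence_id, tier = tier,
                 photoreception_competent = photo,
                 dimer_competent = dim$dimer_competent,
                 monomer_predicted = dim$monomer_predicted,
                 missing_sites = dim$missing,
                 identity_percent = report$identity_percent,
                 rationale = rationale),
            class = "homolog_call")
}

#' Classify a list of reports into a table
#'
#' @param reports a list of `site_report`s.
#' @param identity_threshold see [classify_homolog].
#' @return A `data.frame` with one row per sequence: `sequence_id`,
#'   `species`, `tier`, `photoreception`, `dimer_competent`,
#'   `monomer_predicted`, `missing_sites`, `identity_percent`.
#' @export
classify_reports <- function(reports, identity_threshold = 40) {
  do.call(rbind, lapply(reports, function(r) {
    cl <- classify_report(r, identity_threshold)
    data.frame(sequence_id = cl$sequence_id, species = r$species,
               tier = cl$tier,
               photoreception = cl$photoreception_competent,
               dimer_competent = cl$dimer_competent,
               monomer_predicted = cl$monomer_predicted,
               missing_sites = paste(cl$missing_sites, collapse = ","),
               identity_percent = cl$identity_percent,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
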