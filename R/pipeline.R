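# Stage orchestration: each run_* function reads its inputs, runs one
# pipeline stage, writes deterministic outputs plus a JSON manifest
# recording inputs, parameters and seeds, and returns its results
# invisibly. Identical inputs and seeds produce byte-identical outputs.

write_manifest <- function(out_dir, stage, inputs, parameters, outputs) {
  manifest <- list(stage = stage, inputs = inputs, parameters = parameters,
                   outputs = outputs,
                   package = "uvr8scan",
                   version = as.character(utils::packageVersion("uvr8scan")))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

# Resolves the annotation: a JSON path + reference FASTA, a reference
# FASTA alone (default UVR8 layout), or NULL (built-in synthetic scaffold).
resolve_annotation <- function(annotation_json = NULL, reference_fasta = NULL) {
  if (is.null(reference_fasta)) {
    return(make_scaffold()$annotation)
  }
  ref <- read_fasta(reference_fasta)[1, , drop = FALSE]
  if (is.null(annotation_json)) default_uvr8_annotation(ref)
  else load_annotation(annotation_json, ref)
}

#' Run the site-scanning stage
#'
#' @param input_fasta path to the candidate FASTA file.
#' @param out_dir output directory.
#' @param reference_fasta optional reference FASTA (default: the built-in
#'   synthetic scaffold).
#' @param annotation_json optional annotation JSON for the reference.
#' @param slack,accept_conservative see [scan_sequence].
#' @param params [alignment_params].
#' @param species_from_description when `TRUE` (default), a record whose
#'   species field is empty takes its FASTA description as its species
#'   label (the convention used by [generate_dataset]).
#' @return Invisibly, the list of `site_report`s. Writes
#'   `site_reports.tsv` and `scan_manifest.json`.
#' @export
run_scan <- function(input_fasta, out_dir, reference_fasta = NULL,
                     annotation_json = NULL, slack = 5,
                     accept_conservative = FALSE,
                     params = alignment_params(),
                     species_from_description = TRUE) {
  if (!file.exists(input_fasta)) stop("input FASTA not found: ", input_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- resolve_annotation(annotation_json, reference_fasta)
  records <- read_fasta(input_fasta)
  if (species_from_description) {
    fill <- !nzchar(records$species) & nzchar(records$description)
    records$species[fill] <- records$description[fill]
  }
  reports <- scan_dataset(records, annotation, params, slack,
                          accept_conservative)
  tsv <- file.path(out_dir, "site_reports.tsv")
  write_site_reports(reports, tsv)
  write_manifest(out_dir, "scan",
                 inputs = list(input_fasta = input_fasta,
                               reference_fasta = reference_fasta,
                               annotation_json = annotation_json),
                 parameters = list(slack = slack,
                                   accept_conservative = accept_conservative,
                                   gap_open = params$gap_open,
                                   gap_extend = params$gap_extend),
                 outputs = list(site_reports = tsv))
  invisible(reports)
}

#' Run the classification stage
#'
#' @param reports list of `site_report`s (from [run_scan] or
#'   [scan_dataset]).
#' @param out_dir output directory.
#' @param identity_threshold see [classify_homolog].
#' @return Invisibly, the classification `data.frame`. Writes
#'   `classification.tsv` and `classify_manifest.json`.
#' @export
run_classify <- function(reports, out_dir, identity_threshold = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classify_reports(reports, identity_threshold)
  tsv <- file.path(out_dir, "classification.tsv")
  write.table(cls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "classify",
                 inputs = list(n_reports = length(reports)),
                 parameters = list(identity_threshold = identity_threshold),
                 outputs = list(classification = tsv))
  invisible(cls)
}

#' Run the conservation-summary stage
#'
#' @param reports list of `site_report`s.
#' @param classification `data.frame` from [run_classify].
#' @param out_dir output directory.
#' @param metadata optional species metadata `data.frame`.
#' @param present_states see [tally_site].
#' @return Invisibly, a list with `conservation` and `copy_numbers`.
#'   Writes `conservation.tsv`, `copy_numbers.tsv` and
#'   `summarize_manifest.json`.
#' @export
run_summarize <- function(reports, classification, out_dir, metadata = NULL,
                          present_states = c("EXACT", "CONSERVATIVE")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cons <- conservation_table(reports, present_states, metadata)
  cons_tsv <- file.path(out_dir, "conservation.tsv")
  render_summary(cons, cons_tsv)
  cn <- copy_number_summary(classification, metadata)
  cn_tsv <- file.path(out_dir, "copy_numbers.tsv")
  write.table(cn$per_species, cn_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(out_dir, "summarize",
                 inputs = list(n_reports = length(reports)),
                 parameters = list(present_states = present_states),
                 outputs = list(conservation = cons_tsv,
                                copy_numbers = cn_tsv,
                                percent_multi_copy = cn$percent_multi_copy))
  invisible(list(conservation = cons, copy_numbers = cn))
}

#' Run the phylogeny stage
#'
#' Builds the reference-anchored pseudo-alignment, filters columns,
#' computes p-distances, the NJ tree and bootstrap supports, and writes
#' the Newick tree.
#'
#' @param records a [seq_records] table of candidates.
#' @param out_dir output directory.
#' @param reference single-row [seq_records] (default: built-in scaffold).
#' @param params [alignment_params].
#' @param max_gap_fraction,max_entropy see [filter_columns].
#' @param n_boot bootstrap replicates (0 disables supports).
#' @param seed RNG seed for the bootstrap.
#' @return Invisibly, a list with `tree`, `distances`, `mask`. Writes
#'   `tree.nwk`, `distances.phylip` and `tree_manifest.json`.
#' @export
run_tree <- function(records, out_dir, reference = NULL,
                     params = alignment_params(), max_gap_fraction = 0.5,
                     max_entropy = 0.5, n_boot = 100, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reference)) reference <- make_scaffold()$record
  msa <- build_pseudo_msa(records, reference, params)
  mask <- filter_columns(msa, max_gap_fraction, max_entropy)
  D <- p_distance_matrix(msa, mask)
  tree <- if (n_boot > 0) bootstrap_support(msa, mask, n_boot, seed)
          else neighbor_joining(D)
  nwk <- file.path(out_dir, "tree.nwk")
  write_newick(tree, nwk)
  phy <- file.path(out_dir, "distances.phylip")
  write_phylip_distances(D, phy)
  write_manifest(out_dir, "tree",
                 inputs = list(n_sequences = nrow(records),
                               reference_id = reference$id[1]),
                 parameters = list(max_gap_fraction = max_gap_fraction,
                                   max_entropy = max_entropy,
                                   n_boot = n_boot, seed = seed),
                 outputs = list(newick = nwk, distances = phy))
  invisible(list(tree = tree, distances = D, mask = mask))
}

#' Run the simulation stage
#'
#' Thin wrapper over [generate_dataset] that also writes a manifest.
#'
#' @param config list or JSON path (see [generate_dataset]).
#' @param out_dir output directory.
#' @return Invisibly, the [generate_dataset] result.
#' @export
run_simulate <- function(config, out_dir) {
  ds <- generate_dataset(config, out_dir)
  write_manifest(out_dir, "simulate",
                 inputs = list(config = if (is.character(config)) config
                               else "inline"),
                 parameters = if (is.character(config)) jsonlite::read_json(config)
                              else config,
                 outputs = ds$paths)
  invisible(ds)
}

#' Run the full pipeline on a FASTA input
#'
#' scan -> classify -> summarize -> tree, chaining outputs under one
#' directory.
#'
#' @param input_fasta candidate FASTA path.
#' @param out_dir output directory.
#' @param metadata_tsv optional species metadata TSV.
#' @param reference_fasta,annotation_json see [run_scan].
#' @param identity_threshold,slack,n_boot,seed stage parameters.
#' @return Invisibly, a list with `reports`, `classification`, `summary`,
#'   `phylogeny`.
#' @export
run_pipeline <- function(input_fasta, out_dir, metadata_tsv = NULL,
                         reference_fasta = NULL, annotation_json = NULL,
                         identity_threshold = 40, slack = 5, n_boot = 100,
                         seed = 1) {
  reports <- run_scan(input_fasta, out_dir, reference_fasta, annotation_json,
                      slack)
  cls <- run_classify(reports, out_dir, identity_threshold)
  metadata <- if (!is.null(metadata_tsv)) read_species_metadata(metadata_tsv)
  summ <- run_summarize(reports, cls, out_dir, metadata)
  reference <- if (is.null(reference_fasta)) make_scaffold()$record
               else read_fasta(reference_fasta)[1, , drop = FALSE]
  records <- read_fasta(input_fasta)
  phylo <- run_tree(records, out_dir, reference, n_boot = n_boot, seed = seed)
  invisible(list(reports = reports, classification = cls, summary = summ,
                 phylogeny = phylo))
}
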