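#' @importFrom utils read.delim write.table head tail
NULL

# Protein alphabet accepted throughout: the 20 standard residues plus X
# (unknown). X never satisfies a motif or residue check.
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Construct a set of protein sequence records
#'
#' The record table is the container shared by every stage of the pipeline:
#' one row per protein with its identifier, free-text description, species
#' label (may be empty) and residue string.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of upper-case residue strings over the
#'   20-letter amino-acid alphabet plus `X`.
#' @param description free-text description (default empty).
#' @param species species label (default empty).
#' @param source_tag `"real"` or `"synthetic"`.
#' @return A `data.frame` of class `seq_records` with columns `id`,
#'   `description`, `species`, `residues`, `source_tag`.
#' @export
seq_records <- function(id, residues, description = "", species = "",
                        source_tag = "real") {
  stopifnot(length(id) == length(residues))
  source_tag <- match.arg(source_tag, c("real", "synthetic"))
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  for (k in seq_along(residues)) {
    check_residue_string(residues[k], id[k])
  }
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    species = rep_len(as.character(species), length(id)),
    residues = residues,
    source_tag = rep_len(source_tag, length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

# Validates one residue string; errors name the offending id and 1-based
# position. A single terminal '*' (stop) must already have been stripped.
check_residue_string <- function(residues, id) {
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad)) {
    stop("sequence '", id, "': illegal residue character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace: the first token becomes the
#' record id, the remainder the description. Lowercase residues are
#' upper-cased and a single terminal `*` (translated stop) is stripped;
#' an internal `*` is an error because it signals a mis-annotated ORF.
#'
#' @param path path to a FASTA file.
#' @param source_tag tag recorded on every record, `"real"` by default.
#' @return A [seq_records] table, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path, source_tag = "real") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  residues <- sub("\\*$", "", residues)
  star <- regexpr("\\*", residues)
  if (any(star > 0)) {
    k <- which(star > 0)[1]
    stop("sequence '", id[k], "': internal stop symbol '*' at position ",
         star[k], " (terminal stops only)")
  }
  seq_records(id = id, residues = residues, description = description,
              source_tag = source_tag)
}

#' Write protein sequences to a FASTA file
#'
#' @param records a [seq_records] table.
#' @param path output path.
#' @param width line width for wrapping residues (default 60).
#' @return Invisibly, `path`. Round-trips through [read_fasta] exactly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(nrow(records) >= 1, width >= 1)
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

VALID_CLADES <- c("chlorophyte", "bryophyte", "lycophyte", "monocot",
                  "dicot", "outgroup", "other")

#' Read species metadata from a TSV file
#'
#' Expected columns: `species`, `clade`, `chromosome` (optional). Clade
#' strings outside the recognised vocabulary (chlorophyte, bryophyte,
#' lycophyte, monocot, dicot, outgroup, other) are mapped to `other` with
#' a warning.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A `data.frame` with columns `species`, `clade`, `chromosome`.
#' @export
read_species_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"species" %in% names(tab)) {
    stop("metadata file lacks a 'species' column: ", path)
  }
  if (nrow(tab) == 0) {
    return(data.frame(species = character(), clade = character(),
                      chromosome = character(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(tab$species))) stop("metadata rows must name a species")
  clade <- if ("clade" %in% names(tab)) tab$clade else rep("other", nrow(tab))
  unknown <- !clade %in% VALID_CLADES
  if (any(unknown)) {
    warning("unrecognised clade value(s) mapped to 'other': ",
            paste(unique(clade[unknown]), collapse = ", "))
    clade[unknown] <- "other"
  }
  chromosome <- if ("chromosome" %in% names(tab)) tab$chromosome
                else rep(NA_character_, nrow(tab))
  data.frame(species = tab$species, clade = clade, chromosome = chromosome,
             stringsAsFactors = FALSE)
}
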