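#' Define a sequence motif in reference coordinates
#'
#' A motif is a short canonical peptide plus, per position, the set of
#' residues accepted as conservative replacements, and the positions whose
#' canonical residue is invariant (no substitution, conservative or not,
#' preserves function there).
#'
#' @param name motif name, e.g. `"blade6_GWRHT"`.
#' @param canonical canonical residue string (length >= 2).
#' @param ref_anchor `c(start, end)`, 1-based inclusive reference interval
#'   marking the canonical location (for region motifs such as the VP core
#'   the anchor may be much wider than the pattern).
#' @param conservative named list mapping pattern positions (as character
#'   keys) to character vectors of accepted conservative residues.
#' @param invariant integer vector of pattern positions where only the
#'   canonical residue counts.
#' @return A list of class `motif_definition`.
#' @export
motif_definition <- function(name, canonical, ref_anchor,
                             conservative = list(), invariant = integer()) {
  n <- nchar(canonical)
  if (n < 2) stop("motif pattern must have length >= 2")
  if (length(invariant) && any(invariant < 1 | invariant > n)) {
    stop("invariant positions outside pattern for motif ", name)
  }
  if (length(conservative)) {
    pos <- as.integer(names(conservative))
    if (any(is.na(pos)) || any(pos < 1 | pos > n)) {
      stop("conservative map keys must be pattern positions for motif ", name)
    }
  }
  structure(list(name = name, canonical = toupper(canonical),
                 ref_anchor = as.integer(ref_anchor),
                 conservative = conservative,
                 invariant = as.integer(invariant)),
            class = "motif_definition")
}

#' Define a single functional residue in reference coordinates
#'
#' @param name site name, e.g. `"R286"`.
#' @param ref_pos 1-based reference position.
#' @param canonical the canonical residue (one letter).
#' @param conservative character vector of residues accepted as conservative
#'   replacements (must not contain the canonical residue).
#' @param functional_class one of `"photoreception"`,
#'   `"dimer_interface_basic"`, `"dimer_interface_acidic"`, `"census"`.
#' @return A list of class `residue_definition`.
#' @export
residue_definition <- function(name, ref_pos, canonical,
                               conservative = character(),
                               functional_class = "census") {
  functional_class <- match.arg(functional_class,
    c("photoreception", "dimer_interface_basic", "dimer_interface_acidic",
      "census"))
  canonical <- toupper(canonical)
  if (canonical %in% toupper(conservative)) {
    stop("canonical residue must not appear in its conservative set (", name, ")")
  }
  structure(list(name = name, ref_pos = as.integer(ref_pos),
                 canonical = canonical,
                 conservative = toupper(conservative),
                 functional_class = functional_class),
            class = "residue_definition")
}

#' Assemble a reference annotation
#'
#' Validates every definition against the reference sequence: each residue
#' definition's canonical residue must equal the reference residue at its
#' position, each motif's canonical pattern must occur inside its anchor,
#' and the tryptophan census positions are recomputed from the reference.
#'
#' @param reference a single-row [seq_records] table (the reference protein).
#' @param motifs list of [motif_definition]s.
#' @param residues list of [residue_definition]s.
#' @param c27_region `c(start, end)` of the C-terminal C27 region
#'   (reference coordinates; default 397-423).
#' @return A list of class `reference_annotation` with the validated
#'   components plus `tryptophan_positions`.
#' @export
reference_annotation <- function(reference, motifs, residues,
                                 c27_region = c(397L, 423L)) {
  stopifnot(nrow(reference) == 1)
  seqstr <- reference$residues[1]
  chars <- strsplit(seqstr, "")[[1]]
  bad <- character()
  for (r in residues) {
    if (r$ref_pos > length(chars) || chars[r$ref_pos] != r$canonical) {
      bad <- c(bad, sprintf("%s (expected %s at reference position %d)",
                            r$name, r$canonical, r$ref_pos))
    }
  }
  for (m in motifs) {
    a <- m$ref_anchor
    if (a[2] > length(chars)) {
      bad <- c(bad, sprintf("%s (anchor %d-%d beyond reference length %d)",
                            m$name, a[1], a[2], length(chars)))
      next
    }
    region <- substr(seqstr, a[1], a[2])
    if (!grepl(m$canonical, region, fixed = TRUE)) {
      bad <- c(bad, sprintf("%s (pattern %s not found in anchor %d-%d)",
                            m$name, m$canonical, a[1], a[2]))
    }
  }
  if (length(bad)) {
    stop("annotation does not match reference: ", paste(bad, collapse = "; "))
  }
  structure(list(reference = reference, motifs = motifs, residues = residues,
                 c27_region = as.integer(c27_region),
                 tryptophan_positions = which(chars == "W")),
            class = "reference_annotation")
}

#' Built-in UVR8 annotation for a reference sequence
#'
#' Encodes the functional sites of Arabidopsis UVR8: GWRHT pentapeptides in
#' beta-propeller blades 5, 6 and 7 (anchors 232-236, 284-288, 336-340,
#' placing the chromophore tryptophans at 233, 285 and 337), the VP core
#' anywhere in the C27 region (397-423), and the key residues E43, D44,
#' D96, D107, W233, W285, R286, W337, R338. Motifs tolerate the
#' conservative substitutions R<->K (position 3) and T<->S (position 5);
#' the W (position 2) is invariant. Key residues carry D<->E / R<->K
#' conservative sets that are only honoured when scanning with
#' `accept_conservative = TRUE`; by default they are called by identity.
#'
#' @param reference a single-row [seq_records] table, at least 423 residues
#'   long, carrying the canonical residues at all annotated positions.
#' @return A validated `reference_annotation`.
#' @export
default_uvr8_annotation <- function(reference) {
  stopifnot(nrow(reference) == 1)
  if (nchar(reference$residues[1]) < 423) {
    stop("reference is shorter than 423 residues; the C27 region (397-423) ",
         "must be present")
  }
  gwrht <- function(name, w_pos) {
    motif_definition(name, "GWRHT", ref_anchor = c(w_pos - 1L, w_pos + 3L),
                     conservative = list(`3` = "K", `5` = "S"),
                     invariant = 2L)
  }
  motifs <- list(
    gwrht("blade5_GWRHT", 233L),
    gwrht("blade6_GWRHT", 285L),
    gwrht("blade7_GWRHT", 337L),
    motif_definition("VP_core", "VP", ref_anchor = c(397L, 423L),
                     conservative = list(), invariant = integer())
  )
  residues <- list(
    residue_definition("E43", 43L, "E", "D", "dimer_interface_acidic"),
    residue_definition("D44", 44L, "D", "E", "dimer_interface_acidic"),
    residue_definition("D96", 96L, "D", "E", "dimer_interface_acidic"),
    residue_definition("D107", 107L, "D", "E", "dimer_interface_acidic"),
    residue_definition("W233", 233L, "W", character(), "photoreception"),
    residue_definition("W285", 285L, "W", character(), "photoreception"),
    residue_definition("R286", 286L, "R", "K", "dimer_interface_basic"),
    residue_definition("W337", 337L, "W", character(), "photoreception"),
    residue_definition("R338", 338L, "R", "K", "dimer_interface_basic")
  )
  reference_annotation(reference, motifs, residues, c(397L, 423L))
}

#' Serialize a reference annotation to JSON
#'
#' Pattern positions are written as strings whose first character is the
#' canonical residue and whose remaining characters are the conservative
#' set for that position.
#'
#' @param annotation a `reference_annotation`.
#' @param path output path for the JSON document.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  enc_motif <- function(m) {
    chars <- strsplit(m$canonical, "")[[1]]
    pattern <- vapply(seq_along(chars), function(i) {
      cons <- m$conservative[[as.character(i)]]
      paste0(chars[i], paste(cons, collapse = ""))
    }, "")
    list(name = m$name, pattern = pattern,
         anchor = m$ref_anchor, invariant = m$invariant)
  }
  enc_res <- function(r) {
    list(name = r$name, pos = r$ref_pos, canonical = r$canonical,
         conservative = r$conservative, class = r$functional_class)
  }
  doc <- list(
    reference_id = annotation$reference$id[1],
    motifs = lapply(annotation$motifs, enc_motif),
    residues = lapply(annotation$residues, enc_res),
    c27 = annotation$c27_region
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a reference annotation from JSON plus a reference sequence
#'
#' All annotation invariants are re-validated on load; a residue definition
#' whose canonical residue disagrees with the reference, or a motif whose
#' pattern is missing from its anchor, is an error naming the site.
#'
#' @param path path to an annotation JSON document (see [write_annotation]
#'   for the schema).
#' @param reference a single-row [seq_records] table.
#' @return A validated `reference_annotation`.
#' @export
load_annotation <- function(path, reference) {
  doc <- jsonlite::read_json(path)
  motifs <- lapply(doc$motifs, function(m) {
    pattern <- unlist(m$pattern)
    canonical <- paste(substr(pattern, 1, 1), collapse = "")
    cons <- list()
    for (i in seq_along(pattern)) {
      extra <- substring(pattern[i], 2)
      if (nzchar(extra)) cons[[as.character(i)]] <- strsplit(extra, "")[[1]]
    }
    motif_definition(m$name, canonical, unlist(m$anchor), cons,
                     unlist(m$invariant))
  })
  residues <- lapply(doc$residues, function(r) {
    residue_definition(r$name, r$pos, r$canonical,
                       unlist(r$conservative) %||% character(),
                       r$class)
  })
  reference_annotation(reference, motifs, residues, unlist(doc$c27))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
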