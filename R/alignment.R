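#' Alignment parameters
#'
#' Scoring scheme for global (Needleman-Wunsch) protein alignment with
#' affine gaps. A gap of length L costs `gap_open + gap_extend * (L - 1)`;
#' terminal gaps are penalised (true global alignment).
#'
#' @param substitution_matrix a symmetric named integer matrix, or the name
#'   of a matrix shipped with Biostrings (default `"BLOSUM62"`).
#' @param gap_open non-negative cost of the first residue of a gap
#'   (default 10).
#' @param gap_extend non-negative cost of each further gap residue
#'   (default 0.5); must not exceed `gap_open`.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5) {
  if (is.character(substitution_matrix)) {
    env <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = env)
    substitution_matrix <- get(substitution_matrix, envir = env)
  }
  common <- intersect(rownames(substitution_matrix),
                      colnames(substitution_matrix))
  m <- substitution_matrix[common, common]
  if (!isSymmetric(unname(m))) stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by NCBI BLAST
#' (`#` comment lines, a header row of residue letters, one labelled row
#' per residue).
#'
#' @param path path to the matrix file.
#' @return A symmetric named numeric matrix.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, "", 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(lab, header)
  if (!isSymmetric(unname(vals[header, header]))) {
    stop("matrix in ", path, " is not symmetric")
  }
  vals
}

#' Globally align a query protein against a reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (engine:
#' [Biostrings::pairwiseAlignment]). The score is the maximum over all
#' global alignments under the scheme in `params`.
#'
#' @param query,reference residue strings (non-empty).
#' @param params an [alignment_params] object.
#' @return A list of class `pairwise_alignment` with fields `ref_aligned`,
#'   `query_aligned` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(query, reference, params = alignment_params()) {
  if (!nzchar(query)) stop("query sequence is empty")
  if (!nzchar(reference)) stop("reference sequence is empty")
  # Biostrings charges gapOpening + L * gapExtension for a length-L gap;
  # shifting the opening cost by one extension reproduces
  # gap_open + (L - 1) * gap_extend.
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(reference),
    type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend
  )
  out <- list(
    ref_aligned = as.character(Biostrings::alignedSubject(pa)),
    query_aligned = as.character(Biostrings::alignedPattern(pa)),
    score = as.numeric(Biostrings::score(pa))
  )
  stopifnot(nchar(out$ref_aligned) == nchar(out$query_aligned))
  class(out) <- "pairwise_alignment"
  out
}

#' Build a reference-to-query coordinate map from an alignment
#'
#' The map pairs every residue-residue column of the alignment:
#' `(ref_pos, query_pos)` in 1-based coordinates, strictly increasing in
#' both. Identity is the percentage of matched residues among
#' residue-residue columns.
#'
#' @param alignment a `pairwise_alignment`.
#' @return A list of class `coordinate_map` with fields `pairs` (two-column
#'   integer matrix `ref_pos`, `query_pos`), `identity_percent`, `ref_length`,
#'   `query_length`.
#' @export
build_coordinate_map <- function(alignment) {
  rc <- strsplit(alignment$ref_aligned, "")[[1]]
  qc <- strsplit(alignment$query_aligned, "")[[1]]
  stopifnot(length(rc) == length(qc))
  rpos <- cumsum(rc != "-")
  qpos <- cumsum(qc != "-")
  both <- rc != "-" & qc != "-"
  pairs <- cbind(ref_pos = rpos[both], query_pos = qpos[both])
  n_aln <- sum(both)
  identity <- if (n_aln > 0) 100 * sum(rc[both] == qc[both]) / n_aln else 0
  structure(list(pairs = pairs, identity_percent = identity,
                 ref_length = sum(rc != "-"),
                 query_length = sum(qc != "-")),
            class = "coordinate_map")
}

#' Project a single reference position onto the query
#'
#' @param map a `coordinate_map`.
#' @param ref_pos 1-based reference position.
#' @return The paired 1-based query position, or `NA_integer_` when the
#'   position is deleted or unaligned in the query.
#' @export
project_position <- function(map, ref_pos) {
  stopifnot(ref_pos >= 1)
  hit <- map$pairs[map$pairs[, "ref_pos"] == ref_pos, "query_pos"]
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

#' Project a reference window onto the query
#'
#' Returns the smallest query interval containing every projected position
#' of `[ref_start, ref_end]`, widened by `slack` on each side and clipped
#' to the query.
#'
#' @param map a `coordinate_map`.
#' @param ref_start,ref_end 1-based inclusive reference interval.
#' @param slack non-negative widening in residues.
#' @return `c(start, end)` on the query, or `NULL` when no position of the
#'   window is aligned.
#' @export
project_window <- function(map, ref_start, ref_end, slack = 0) {
  stopifnot(ref_start <= ref_end, slack >= 0)
  in_win <- map$pairs[, "ref_pos"] >= ref_start & map$pairs[, "ref_pos"] <= ref_end
  if (!any(in_win)) return(NULL)
  q <- range(map$pairs[in_win, "query_pos"])
  c(max(1L, q[1] - slack), min(map$query_length, q[2] + slack))
}
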