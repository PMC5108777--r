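#' Reference-anchored pseudo-alignment
#'
#' Stacks the pairwise reference alignments of all candidates into a
#' rectangular matrix whose columns are the reference positions 1..L.
#' Row r holds the query residue paired with each reference position, or
#' `-` where the position is deleted/unaligned; insertions relative to the
#' reference are dropped. The reference itself is the (gap-free) first row.
#'
#' @param records a [seq_records] table of candidates.
#' @param reference a single-row [seq_records] table.
#' @param params [alignment_params] used for each pairwise alignment.
#' @return A character matrix of class `pseudo_msa`, rows named by
#'   sequence id (reference first).
#' @export
build_pseudo_msa <- function(records, reference, params = alignment_params()) {
  refseq <- reference$residues[1]
  L <- nchar(refseq)
  ids <- c(reference$id[1], records$id)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in pseudo-MSA")
  msa <- matrix("-", nrow = nrow(records) + 1, ncol = L,
                dimnames = list(ids, NULL))
  msa[1, ] <- strsplit(refseq, "")[[1]]
  for (k in seq_len(nrow(records))) {
    q <- records$residues[k]
    map <- build_coordinate_map(global_align(q, refseq, params))
    qchars <- strsplit(q, "")[[1]]
    msa[k + 1, map$pairs[, "ref_pos"]] <- qchars[map$pairs[, "query_pos"]]
  }
  class(msa) <- c("pseudo_msa", class(msa))
  msa
}

#' Select informative alignment columns
#'
#' A column is kept when its gap fraction does not exceed
#' `max_gap_fraction` and its normalized Shannon entropy (natural log over
#' residue frequencies, gaps excluded, divided by log 20) does not exceed
#' `max_entropy`. This is a deliberately simple gap/entropy trim in the
#' spirit of alignment-masking tools such as BMGE, with no claim of
#' equivalence to any of them.
#'
#' @param msa a `pseudo_msa` (>= 2 rows).
#' @param max_gap_fraction maximum tolerated fraction of gaps per column
#'   (default 0.5).
#' @param max_entropy maximum normalized entropy per column (default 0.5).
#' @return A logical mask over columns (TRUE = keep).
#' @export
filter_columns <- function(msa, max_gap_fraction = 0.5, max_entropy = 0.5) {
  stopifnot(nrow(msa) >= 2)
  apply(msa, 2, function(col) {
    gap_frac <- mean(col == "-")
    if (gap_frac > max_gap_fraction) return(FALSE)
    res <- col[col != "-"]
    if (length(res) == 0) return(FALSE)
    p <- table(res) / length(res)
    entropy <- -sum(p * log(p)) / log(20)
    entropy <= max_entropy
  })
}

#' p-distance matrix from a pseudo-alignment
#'
#' `d(a, b)` is the fraction of mismatching residues over columns that are
#' kept by the mask and ungapped in both rows.
#'
#' @param msa a `pseudo_msa`.
#' @param mask logical column mask (default: keep all columns).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(msa, mask = NULL) {
  stopifnot(nrow(msa) >= 2)
  if (is.null(mask)) mask <- rep(TRUE, ncol(msa))
  sub <- msa[, mask, drop = FALSE]
  n <- nrow(sub)
  ids <- rownames(sub)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- sub[i, ] != "-" & sub[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", ids[i], "' and '", ids[j], "'")
      }
      D[i, j] <- D[j, i] <- mean(sub[i, ok] != sub[j, ok])
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (via [ape::nj]); exactly recovers topology
#' and branch lengths for additive distances. Negative branch-length
#' estimates, which NJ can produce on non-additive input, are clamped to
#' zero with a warning.
#'
#' @param D a symmetric non-negative distance matrix over >= 3 taxa with
#'   zero diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples kept alignment columns with replacement `n_reps` times,
#' rebuilds the NJ tree per replicate, and labels each internal node of
#' the full-data tree with the percentage of replicate trees containing
#' its bipartition.
#'
#' @param msa a `pseudo_msa`.
#' @param mask logical column mask (default: keep all).
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed optional RNG seed; given a seed the supports are
#'   deterministic.
#' @return The full-data NJ tree with numeric `node.label` supports in
#'   `[0, 100]` (the root label is `NA`).
#' @export
bootstrap_support <- function(msa, mask = NULL, n_reps = 100, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(mask)) mask <- rep(TRUE, ncol(msa))
  kept <- which(mask)
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(p_distance_matrix(msa, mask))
  boot <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample(kept, length(kept), replace = TRUE)
    boot[[r]] <- suppressWarnings(
      neighbor_joining(p_distance_matrix(msa[, cols, drop = FALSE]))
    )
  }
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  support[1] <- NA  # root of the unrooted representation carries no split
  main$node.label <- support
  main
}

#' Write a tree in Newick format
#'
#' Branch lengths are included; bootstrap supports, when present, are
#' rendered as internal node labels.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.label)) {
    lab <- as.character(tree$node.label)
    lab[is.na(lab)] <- ""
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP format
#'
#' @param D a square distance matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phylip_distances <- function(D, path) {
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste0(formatC(rownames(D)[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
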