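# Standard 20-residue alphabet used by the simulator (no X).
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fixed scaffold layout: GWRHT pentapeptides placing the chromophore
# tryptophans at 233/285/337, the charged interface residues, a VP core at
# 410-411 inside the C27 region (397-423), and 11 further tryptophans so
# the scaffold carries 14 in total.
SCAFFOLD_MOTIFS <- list(blade5 = 232:236, blade6 = 284:288, blade7 = 336:340)
SCAFFOLD_RESIDUES <- c(E43 = 43L, D44 = 44L, D96 = 96L, D107 = 107L)
SCAFFOLD_VP <- 410:411
SCAFFOLD_EXTRA_W <- c(25L, 70L, 130L, 160L, 198L, 255L, 310L, 355L, 380L,
                      400L, 435L)

#' Specification of the synthetic UVR8-like scaffold
#'
#' @param length total scaffold length (default 440; must accommodate the
#'   C27 region ending at 423 and every fixed tryptophan position).
#' @param seed RNG seed for the background residues.
#' @param background named probability vector over the 19 non-tryptophan
#'   residues used to fill unconstrained positions (default uniform);
#'   tryptophan is excluded so the scaffold carries exactly 14 W.
#' @return A list of class `scaffold_spec`.
#' @export
scaffold_spec <- function(length = 440, seed = 1, background = NULL) {
  bg_letters <- setdiff(AA20, "W")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 19, 19), bg_letters)
  }
  if (!setequal(names(background), bg_letters)) {
    stop("background frequencies must cover exactly the 19 non-W residues")
  }
  structure(list(length = as.integer(length), seed = as.integer(seed),
                 background = background),
            class = "scaffold_spec")
}

#' Build the synthetic scaffold and its annotation
#'
#' Deterministic given `spec$seed`: background positions are drawn
#' from the background frequency table, then every annotated site is
#' overwritten with its canonical residues. The result validates under
#' [default_uvr8_annotation] and carries exactly 14 tryptophans.
#'
#' @param spec a [scaffold_spec].
#' @return A list with `record` (a synthetic-tagged [seq_records] row named
#'   `UVR8_scaffold`) and `annotation` (the validated
#'   `reference_annotation`).
#' @export
make_scaffold <- function(spec = scaffold_spec()) {
  min_len <- max(423L, max(SCAFFOLD_EXTRA_W))
  if (spec$length < min_len) {
    stop("scaffold length ", spec$length, " too short: annotated positions ",
         "extend to ", min_len, " (C27 region ends at 423)")
  }
  withr_seed <- function(code) {  # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  chars <- withr_seed(sample(names(spec$background), spec$length,
                             replace = TRUE, prob = spec$background))
  for (rng in SCAFFOLD_MOTIFS) chars[rng] <- strsplit("GWRHT", "")[[1]]
  for (nm in names(SCAFFOLD_RESIDUES)) {
    chars[SCAFFOLD_RESIDUES[[nm]]] <- substr(nm, 1, 1)
  }
  chars[SCAFFOLD_VP] <- c("V", "P")
  chars[SCAFFOLD_EXTRA_W] <- "W"
  stopifnot(sum(chars == "W") == 14)
  record <- seq_records(id = "UVR8_scaffold",
                        residues = paste(chars, collapse = ""),
                        description = "synthetic UVR8-like scaffold",
                        species = "synthetic scaffold",
                        source_tag = "synthetic")
  list(record = record, annotation = default_uvr8_annotation(record))
}

# Reference positions occupied by one annotated site (motif anchor span,
# the VP occurrence, or a single residue position).
site_positions <- function(annotation, site_name) {
  for (m in annotation$motifs) {
    if (m$name == site_name) {
      if (m$name == "VP_core") {
        region <- substr(annotation$reference$residues[1],
                         m$ref_anchor[1], m$ref_anchor[2])
        off <- regexpr(m$canonical, region, fixed = TRUE)
        start <- m$ref_anchor[1] + off - 1L
        return(seq.int(start, start + nchar(m$canonical) - 1L))
      }
      return(seq.int(m$ref_anchor[1], m$ref_anchor[2]))
    }
  }
  for (r in annotation$residues) {
    if (r$name == site_name) return(r$ref_pos)
  }
  stop("unknown site name: ", site_name)
}

# All reference positions shielded from background mutation when
# invariant-site protection is on.
protected_positions <- function(annotation) {
  site_names <- c(vapply(annotation$motifs, `[[`, "", "name"),
                  vapply(annotation$residues, `[[`, "", "name"))
  sort(unique(c(unlist(lapply(site_names, site_positions,
                              annotation = annotation)),
                annotation$tryptophan_positions)))
}

#' Evolution parameters for family simulation
#'
#' @param n_leaves number of leaves when no tree is supplied.
#' @param tree optional `ape::phylo` tree whose tip labels name the
#'   sequences; default: a random rooted binary tree on `n_leaves` tips.
#' @param subst_prob per-site substitution probability applied on every
#'   branch (uniform replacement among the 19 alternatives).
#' @param indel_rate expected number of indel events per branch
#'   (Poisson; default 0).
#' @param indel_length_p geometric success parameter for indel lengths
#'   (length = 1 + Geom(p); default 0.5).
#' @param knockouts list of directives, each
#'   `list(leaf = <tip label>, site = <annotated site>,
#'   edit = "delete" | "to_alanine" | "conservative_swap")`.
#' @param protect_sites when `TRUE` (default) annotated positions never
#'   receive background substitutions or indels, so the ground truth is
#'   exactly the directive list.
#' @param seed RNG seed; simulation is deterministic given the seed.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(n_leaves = 8, tree = NULL, subst_prob = 0.02,
                             indel_rate = 0, indel_length_p = 0.5,
                             knockouts = list(), protect_sites = TRUE,
                             seed = 1) {
  stopifnot(subst_prob >= 0, subst_prob <= 1, indel_rate >= 0,
            indel_length_p > 0, indel_length_p <= 1)
  structure(list(n_leaves = as.integer(n_leaves), tree = tree,
                 subst_prob = subst_prob, indel_rate = indel_rate,
                 indel_length_p = indel_length_p, knockouts = knockouts,
                 protect_sites = protect_sites, seed = as.integer(seed)),
            class = "evolution_params")
}

#' Simulate a UVR8-like protein family along a tree
#'
#' The scaffold evolves from root to leaves: on each branch every eligible
#' site substitutes with probability `subst_prob` (uniformly to one of the
#' 19 alternative residues) and `Poisson(indel_rate)` indel events of
#' geometric length are applied at unprotected positions (insertions draw
#' residues from the 19 non-W letters so the tryptophan census stays
#' interpretable). Knockout directives are applied at the named leaves
#' and recorded in the truth table.
#'
#' @param scaffold output of [make_scaffold] (or a compatible
#'   `record`/`annotation` list).
#' @param params an [evolution_params].
#' @return A list: `records` (leaf sequences, ids = tip labels), `truth`
#'   (`data.frame`: `id`, `species`, `knockout_sites`, `knockout_edits`,
#'   `branch_path`), and `tree` (the generating `ape::phylo`).
#' @export
evolve_family <- function(scaffold, params = evolution_params()) {
  annotation <- scaffold$annotation
  set.seed(params$seed)
  tree <- params$tree
  if (is.null(tree)) tree <- ape::rtree(params$n_leaves)
  n_tip <- length(tree$tip.label)
  for (ko in params$knockouts) {
    if (!ko$leaf %in% tree$tip.label) stop("unknown knockout leaf: ", ko$leaf)
    site_positions(annotation, ko$site)  # errors on unknown sites
    match.arg(ko$edit, c("delete", "to_alanine", "conservative_swap"))
  }
  protected <- if (params$protect_sites) protected_positions(annotation)
               else integer()
  bg <- setdiff(AA20, "W")

  root_chars <- strsplit(scaffold$record$residues[1], "")[[1]]
  root_state <- list(chars = root_chars, refpos = seq_along(root_chars))

  mutate_branch <- function(state) {
    eligible <- which(is.na(state$refpos) | !(state$refpos %in% protected))
    hit <- eligible[stats::runif(length(eligible)) < params$subst_prob]
    for (i in hit) {
      state$chars[i] <- sample(setdiff(AA20, state$chars[i]), 1)
    }
    n_indel <- stats::rpois(1, params$indel_rate)
    for (e in seq_len(n_indel)) {
      len <- 1 + stats::rgeom(1, params$indel_length_p)
      if (stats::runif(1) < 0.5) {  # insertion, not between two protected sites
        prot <- !is.na(state$refpos) & state$refpos %in% protected
        pts <- which(!(c(prot, FALSE) & c(FALSE, prot))) - 1L  # insert after pts
        if (!length(pts)) next
        at <- sample(pts, 1)
        ins <- sample(bg, len, replace = TRUE)
        state$chars <- append(state$chars, ins, after = at)
        state$refpos <- append(state$refpos, rep(NA_integer_, len), after = at)
      } else {  # deletion of a fully unprotected run
        n <- length(state$chars)
        if (len >= n) next
        prot <- !is.na(state$refpos) & state$refpos %in% protected
        ok <- which(vapply(seq_len(n - len + 1), function(s)
          !any(prot[s:(s + len - 1)]), logical(1)))
        if (!length(ok)) next
        s <- sample(ok, 1)
        keep <- setdiff(seq_len(n), s:(s + len - 1))
        state$chars <- state$chars[keep]
        state$refpos <- state$refpos[keep]
      }
    }
    state
  }

  apply_knockout <- function(state, ko) {
    pos <- site_positions(annotation, ko$site)
    idx <- which(state$refpos %in% pos)
    if (!length(idx)) return(state)
    if (ko$edit == "delete") {
      keep <- setdiff(seq_along(state$chars), idx)
      state$chars <- state$chars[keep]
      state$refpos <- state$refpos[keep]
    } else if (ko$edit == "to_alanine") {
      state$chars[idx] <- "A"
    } else {  # conservative_swap
      swapped <- FALSE
      for (m in annotation$motifs) {
        if (m$name == ko$site && length(m$conservative)) {
          ppos <- as.integer(sample(names(m$conservative), 1))
          target <- pos[1] + ppos - 1L
          i <- which(state$refpos == target)
          if (length(i)) {
            state$chars[i] <- sample(m$conservative[[as.character(ppos)]], 1)
            swapped <- TRUE
          }
        }
      }
      for (r in annotation$residues) {
        if (r$name == ko$site) {
          if (!length(r$conservative)) {
            stop("site ", ko$site, " has no conservative alternative")
          }
          i <- which(state$refpos == r$ref_pos)
          if (length(i)) {
            state$chars[i] <- sample(r$conservative, 1)
            swapped <- TRUE
          }
        }
      }
      if (!swapped) warning("conservative_swap had no effect at ", ko$site)
    }
    state
  }

  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  states <- vector("list", max(tree$edge))
  paths <- character(max(tree$edge))
  root <- n_tip + 1L
  states[[root]] <- root_state
  paths[root] <- "root"
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    states[[child]] <- mutate_branch(states[[parent]])
    paths[child] <- paste0(paths[parent], ">", child)
  }

  ids <- tree$tip.label
  rows <- lapply(seq_len(n_tip), function(tip) {
    state <- states[[tip]]
    kos <- Filter(function(ko) ko$leaf == ids[tip], params$knockouts)
    for (ko in kos) state <- apply_knockout(state, ko)
    list(residues = paste(state$chars, collapse = ""),
         knockout_sites = paste(vapply(kos, `[[`, "", "site"), collapse = ";"),
         knockout_edits = paste(vapply(kos, `[[`, "", "edit"), collapse = ";"),
         branch_path = paths[tip])
  })
  records <- seq_records(id = ids,
                         residues = vapply(rows, `[[`, "", "residues"),
                         source_tag = "synthetic")
  truth <- data.frame(
    id = ids, species = "",
    knockout_sites = vapply(rows, `[[`, "", "knockout_sites"),
    knockout_edits = vapply(rows, `[[`, "", "knockout_edits"),
    branch_path = vapply(rows, `[[`, "", "branch_path"),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth, tree = tree)
}

#' Generate a full synthetic dataset on disk
#'
#' Drives [make_scaffold] and [evolve_family] from a single configuration
#' (an R list or a path to a JSON document) and writes the family FASTA,
#' a species metadata TSV and the ground-truth TSV. Species and copy
#' numbers come from `species_design`: leaves are assigned to species in
#' tip-label order, a species with `copies = 2` receiving two leaves
#' (recorded as chromosomes 1 and 2).
#'
#' Config fields: `scaffold` (`length`, `seed`), `evolution`
#' (`subst_prob`, `indel_rate`, `indel_length_p`, `knockouts`, `seed`,
#' `protect_sites`), `species_design` (list of
#' `list(species=, copies=, clade=)`).
#'
#' @param config list or JSON path.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list: `records`, `truth`, `metadata`, `scaffold`,
#'   `tree`, and the written `paths`. Re-running the same config writes
#'   byte-identical files.
#' @export
generate_dataset <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  for (field in c("scaffold", "evolution", "species_design")) {
    if (is.null(config[[field]])) stop("config lacks required field: ", field)
  }
  design <- do.call(rbind, lapply(config$species_design, function(d) {
    if (is.null(d$species) || is.null(d$copies)) {
      stop("species_design entries need 'species' and 'copies'")
    }
    data.frame(species = d$species, copies = as.integer(d$copies),
               clade = d$clade %||% "other", stringsAsFactors = FALSE)
  }))
  n_leaves <- sum(design$copies)
  sc <- config$scaffold
  scaffold <- make_scaffold(scaffold_spec(length = sc$length %||% 440,
                                          seed = sc$seed %||% 1))
  ev <- config$evolution
  kos <- lapply(ev$knockouts %||% list(), function(k)
    list(leaf = k$leaf, site = k$site, edit = k$edit))
  params <- evolution_params(
    n_leaves = n_leaves,
    subst_prob = ev$subst_prob %||% 0.02,
    indel_rate = ev$indel_rate %||% 0,
    indel_length_p = ev$indel_length_p %||% 0.5,
    knockouts = kos,
    protect_sites = ev$protect_sites %||% TRUE,
    seed = ev$seed %||% 1)
  fam <- evolve_family(scaffold, params)

  species <- rep(design$species, design$copies)
  chrom <- unlist(lapply(design$copies, seq_len))
  fam$records$species <- species
  fam$records$description <- species  # survives the FASTA round-trip
  fam$truth$species <- species
  metadata <- data.frame(species = design$species, clade = design$clade,
                         chromosome = NA_character_, stringsAsFactors = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(out_dir, "family.fasta"),
                metadata = file.path(out_dir, "metadata.tsv"),
                truth = file.path(out_dir, "truth.tsv"))
  write_fasta(fam$records, paths$fasta)
  write.table(metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_out <- cbind(fam$truth, chromosome = chrom)
  write.table(truth_out, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(records = fam$records, truth = truth_out,
                 metadata = metadata, scaffold = scaffold, tree = fam$tree,
                 paths = paths))
}
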