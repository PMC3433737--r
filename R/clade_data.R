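#' Read and validate an ultrametric timetree
#'
#' Reads a Newick tree with branch lengths in millions of years whose tips are
#' named higher taxa. The tree must be rooted, have non-negative branch
#' lengths, and be ultrametric within a relative tolerance of the root height.
#' Square-bracket comments (e.g. NHX annotations) are stripped with a warning.
#' Polytomies are rejected by default because the downstream covariance and
#' likelihood machinery assumes binary trees; \code{resolve_polytomies = TRUE}
#' resolves them arbitrarily with zero-length branches.
#'
#' @param path Path to a Newick file (or a Newick string containing ";").
#' @param ultrametric_tol Relative tolerance on root-to-tip depth spread.
#' @param allow_nonultrametric Skip the ultrametricity check?
#' @param resolve_polytomies Resolve multifurcations with zero-length edges?
#' @return An \code{ape} \code{phylo} object passing \code{\link{validate_timetree}}.
#' @export
read_timetree <- function(path, ultrametric_tol = 1e-6,
                          allow_nonultrametric = FALSE,
                          resolve_polytomies = FALSE) {
  txt <- if (grepl(";", path, fixed = TRUE)) path
         else paste(readLines(path, warn = FALSE), collapse = "")
  if (grepl("\\[", txt)) {
    warning("square-bracket comments stripped from Newick input")
    txt <- gsub("\\[[^]]*\\]", "", txt)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) warning("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies (or an unrooted basal trifurcation); set resolve_polytomies = TRUE to resolve with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  validate_timetree(tree, ultrametric_tol = ultrametric_tol,
                    allow_nonultrametric = allow_nonultrametric)
  tree
}

#' Validate timetree invariants
#'
#' Checks that a \code{phylo} object is rooted, binary, carries non-negative
#' branch lengths, and is ultrametric within a relative tolerance of its root
#' height.
#'
#' @inheritParams read_timetree
#' @param tree A \code{phylo} object.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_timetree <- function(tree, ultrametric_tol = 1e-6,
                              allow_nonultrametric = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths present")
  if (!allow_nonultrametric) {
    depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
    h <- max(depths)
    if (h <= 0) stop("tree has zero height")
    if ((max(depths) - min(depths)) / h > ultrametric_tol)
      stop(sprintf("tree is not ultrametric within relative tolerance %g (depth spread %g of height %g); set allow_nonultrametric = TRUE to override",
                   ultrametric_tol, max(depths) - min(depths), h))
  }
  invisible(tree)
}

#' Write a timetree to Newick
#'
#' @param tree A \code{phylo} object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @export
write_timetree <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

## ages of all nodes (time before present), tips first; tips of an ultrametric
## tree get age 0 exactly
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(ape::Ntip(tree))]) - depths
}

#' Stem ages of the tips of an ultrametric timetree
#'
#' The stem age of a tip is the age of its parent node, equivalently its
#' pendant branch length on an ultrametric tree; for a child of the root it
#' equals the root age.
#'
#' @param tree A valid timetree (\code{phylo}).
#' @return Named numeric vector of stem ages (My), one per tip.
#' @export
stem_ages <- function(tree) {
  validate_timetree(tree, allow_nonultrametric = TRUE)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  parent <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
  stats::setNames(ages[parent], tree$tip.label)
}

#' Load a clade richness table
#'
#' Reads a tab-separated table with header columns \code{name},
#' \code{richness} and optionally \code{source}. Richness values must be
#' integers >= 1 (extant clades only); duplicate names are rejected.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns \code{name}, \code{richness},
#'   \code{source}.
#' @export
load_richness <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("name", "richness") %in% names(tab)))
    stop("richness table must have header columns 'name' and 'richness'")
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$richness))) |
               as.numeric(tab$richness) < 1 |
               as.numeric(tab$richness) != floor(as.numeric(tab$richness)))
  if (length(bad))
    stop("invalid richness (must be integer >= 1) in rows: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate clade names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  data.frame(name = as.character(tab$name),
             richness = as.numeric(tab$richness),
             source = if ("source" %in% names(tab)) as.character(tab$source)
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Construct a clade dataset
#'
#' Binds a timetree to a richness table with a one-to-one correspondence
#' between tips and records, deriving stem ages from the tree.
#'
#' @param tree A valid timetree.
#' @param records Data frame with columns \code{name} and \code{richness}
#'   (and optionally \code{source}) covering every tip exactly once.
#' @return An object of class \code{"clade_dataset"}: list with \code{tree}
#'   and \code{records} (name, stem_age, richness, source).
#' @export
clade_dataset <- function(tree, records) {
  validate_timetree(tree, allow_nonultrametric = TRUE)
  if (!setequal(tree$tip.label, records$name) ||
      length(tree$tip.label) != nrow(records))
    stop("tips and records must be in bijection; offending names: ",
         paste(union(setdiff(tree$tip.label, records$name),
                     setdiff(records$name, tree$tip.label)), collapse = ", "))
  if (any(records$richness < 1)) stop("richness must be >= 1")
  sa <- stem_ages(tree)
  recs <- data.frame(name = tree$tip.label,
                     stem_age = as.numeric(sa[tree$tip.label]),
                     richness = records$richness[match(tree$tip.label, records$name)],
                     source = if ("source" %in% names(records))
                       records$source[match(tree$tip.label, records$name)]
                     else NA_character_,
                     stringsAsFactors = FALSE)
  structure(list(tree = tree, records = recs), class = "clade_dataset")
}

#' @export
print.clade_dataset <- function(x, ...) {
  s <- summarize_clades(x)
  cat(sprintf("clade dataset: %d clades, %s species, stem ages %.3g-%.3g My\n",
              s$n_clades, format(s$total_species, big.mark = ","),
              s$age_range[1], s$age_range[2]))
  invisible(x)
}

## nearest recorded sister tip: walk rootward from `tip`, at each ancestor look
## in the newly added sister subtree for tips with records; choose the one at
## minimal patristic distance
closest_recorded_sister <- function(tree, tip_idx, has_record, tie_break = "error") {
  ntip <- ape::Ntip(tree)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  node <- tip_idx
  repeat {
    up <- parent[match(node, child)]
    if (is.na(up)) return(NA_integer_)
    sibs <- child[parent == up & child != node]
    cand <- integer(0)
    for (s in sibs) {
      tips_s <- if (s <= ntip) s else {
        ex <- ape::extract.clade(tree, s)
        match(ex$tip.label, tree$tip.label)
      }
      cand <- c(cand, tips_s[has_record[tips_s]])
    }
    if (length(cand)) {
      if (length(cand) == 1L) return(cand)
      ## all candidates meet the focal tip at `up`, so on an ultrametric tree
      ## their patristic distances tie structurally: apply the tie-break policy
      if (tie_break == "error")
        stop("ambiguous sister assignment for tip '", tree$tip.label[tip_idx],
             "' (", length(cand), " equally close recorded tips); ",
             "set tie_break = 'first' for deterministic resolution")
      return(cand[order(tree$tip.label[cand])][1])
    }
    node <- up
  }
}

#' Reconcile a timetree with a richness table
#'
#' Aligns tips and richness records. Tips without a record are pruned; if a
#' richness value is supplied for such a tip (via \code{missing}), that
#' richness is added to the closest sister tip that has a record, so the total
#' species count is conserved. Pruning a member of a cherry merges the cherry
#' into one tip whose richness is the sum and whose stem age is the merged
#' clade's stem age. Names in \code{missing} that are absent from both the
#' tree and the records, or that lack an attachment, are flagged in the
#' report rather than guessed.
#'
#' @param tree A valid timetree.
#' @param records Richness data frame (\code{name}, \code{richness}).
#' @param missing Optional data frame (\code{name}, \code{richness},
#'   optional \code{attach_to}) of lineages without their own record/tip whose
#'   species must be reassigned.
#' @param tie_break Policy when several recorded sister tips are equally
#'   close: \code{"error"} (default) or \code{"first"} (alphabetical).
#' @return List with \code{dataset} (a \code{\link{clade_dataset}}) and
#'   \code{report} (merges, pruned tips, flagged names).
#' @export
reconcile <- function(tree, records, missing = NULL, tie_break = "error") {
  validate_timetree(tree, allow_nonultrametric = TRUE)
  tips <- tree$tip.label
  if (!length(intersect(tips, records$name)))
    stop("no overlap between tree tips and record names")
  rich <- stats::setNames(records$richness, records$name)
  has_record <- tips %in% records$name
  merges <- data.frame(from = character(0), to = character(0),
                       richness_moved = numeric(0), stringsAsFactors = FALSE)
  flagged <- character(0)

  ## external richness for unrecorded lineages (tips or off-tree names)
  if (!is.null(missing)) {
    for (i in seq_len(nrow(missing))) {
      nm <- missing$name[i]; nr <- missing$richness[i]
      att <- if ("attach_to" %in% names(missing)) missing$attach_to[i] else NA
      if (!is.na(att) && att %in% tips && has_record[match(att, tips)]) {
        rich[att] <- rich[att] + nr
        merges <- rbind(merges, data.frame(from = nm, to = att,
                                           richness_moved = nr))
      } else if (nm %in% tips) {
        sis <- closest_recorded_sister(tree, match(nm, tips),
                                       stats::setNames(has_record, NULL),
                                       tie_break)
        if (is.na(sis)) { flagged <- c(flagged, nm); next }
        to <- tips[sis]
        rich[to] <- rich[to] + nr
        merges <- rbind(merges, data.frame(from = nm, to = to,
                                           richness_moved = nr))
      } else {
        flagged <- c(flagged, nm)
      }
    }
  }

  pruned <- tips[!has_record]
  if (length(pruned) == length(tips)) stop("no tip has a richness record")
  newtree <- if (length(pruned)) ape::drop.tip(tree, pruned) else tree
  keep <- newtree$tip.label
  src <- if ("source" %in% names(records))
    records$source[match(keep, records$name)] else NA_character_
  ds <- clade_dataset(newtree,
                      data.frame(name = keep,
                                 richness = as.numeric(rich[keep]),
                                 source = src, stringsAsFactors = FALSE))
  list(dataset = ds,
       report = list(merges = merges, pruned = pruned, flagged = flagged,
                     off_tree_records = setdiff(records$name, tips)))
}

#' Dataset totals
#'
#' Exact bookkeeping totals of a reconciled dataset: number of clades, total
#' species count, and the range of stem ages.
#'
#' @param dataset A \code{\link{clade_dataset}}.
#' @return List with \code{n_clades}, \code{total_species},
#'   \code{age_range}.
#' @export
summarize_clades <- function(dataset) {
  stopifnot(inherits(dataset, "clade_dataset"))
  list(n_clades = nrow(dataset$records),
       total_species = sum(dataset$records$richness),
       age_range = range(dataset$records$stem_age))
}
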