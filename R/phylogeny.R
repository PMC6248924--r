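#' Pairwise distance matrix from a trimmed core alignment
#'
#' p-distance (or its Poisson correction `-ln(1 - p)`) over the columns
#' where both rows carry residues. The correction is capped by clamping p
#' at `p_max` so saturated pairs stay finite.
#'
#' @param msa a [flg_msa] with >= 3 rows.
#' @param model `"p_distance"` or `"poisson_corrected"`.
#' @param p_max clamp for the Poisson correction (default 0.95).
#' @return symmetric numeric matrix with zero diagonal, labelled by row id.
#' @export
core_distance_matrix <- function(msa, model = c("p_distance",
                                                "poisson_corrected"),
                                 p_max = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 3) stop("need >= 3 rows for a distance matrix")
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(shared))
      stop("no shared columns between '", msa$ids[i], "' and '",
           msa$ids[j], "'")
    p <- mean(m[i, shared] != m[j, shared])
    d <- if (model == "p_distance") p else -log(1 - min(p, p_max))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via [ape::nj()]) with two determinism and
#' sanity post-passes: labels are sorted before agglomeration so ties
#' break by label order, and negative branch lengths are clamped to zero
#' with the deficit moved onto a sibling branch (leaf path lengths through
#' the pair are preserved).
#'
#' @param dm symmetric distance matrix with labels (>= 3).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (nrow(dm) < 3) stop("need >= 3 labels")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    if (len >= 0) next
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    tr$edge.length[e] <- 0
    if (length(sibs) > 0)
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + len
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Annotate tree leaves with measured insert sizes
#'
#' @param tree an [ape::phylo] whose tips are sequence ids.
#' @param architectures data.frame with at least id, insert_len, n_de,
#'   size_class (one row per tip).
#' @return object of class `annotated_tree`: the tree, a legend
#'   data.frame (one row per leaf), and Newick text whose labels carry
#'   `|ins<len>|de<k>` suffixes for external viewers.
#' @export
annotate_inserts <- function(tree, architectures) {
  missing <- setdiff(tree$tip.label, architectures$id)
  if (length(missing) > 0)
    stop("no architecture for leaves: ", paste(missing, collapse = ", "))
  idx <- match(tree$tip.label, architectures$id)
  legend <- data.frame(id = tree$tip.label,
                       insert_len = architectures$insert_len[idx],
                       n_de = architectures$n_de[idx],
                       size_class = architectures$size_class[idx])
  tagged <- tree
  tagged$tip.label <- paste0(legend$id, "|ins", legend$insert_len,
                             "|de", legend$n_de)
  structure(list(tree = tree, legend = legend,
                 newick = ape::write.tree(tagged)),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree:", length(x$tree$tip.label), "leaves\n")
  invisible(x)
}

# non-trivial bipartitions of an unrooted tree as canonical label-set keys
tree_bipartitions <- function(tree) {
  tr <- ape::unroot(tree)
  labs <- tr$tip.label
  ref <- sort(labs)[1] # label-based reference so keys are tree-independent
  pp <- ape::prop.part(tr)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) <= 1 || length(side) >= length(labs) - 1) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds congruence of two trees
#'
#' Counts bipartitions present in exactly one tree; `rf = 0` means
#' topological congruence. Both trees must carry the same leaf set
#' (collapse DE-copy labels to their parent sequence first, e.g. via
#' [de_congruence()]).
#'
#' @param tree_a,tree_b [ape::phylo] trees on identical leaf sets.
#' @return list: `rf_distance`, `max_rf`, `normalised` in [0, 1].
#' @export
rf_congruence <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label); lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    diff <- union(setdiff(la, lb), setdiff(lb, la))
    stop("leaf sets differ: ", paste(diff, collapse = ", "))
  }
  ba <- tree_bipartitions(tree_a)
  bb <- tree_bipartitions(tree_b)
  rf <- length(setdiff(ba, bb)) + length(setdiff(bb, ba))
  max_rf <- length(ba) + length(bb)
  n <- length(la)
  if (max_rf == 0) max_rf <- max(2L * (n - 3L), 1L)
  list(rf_distance = rf, max_rf = max_rf, normalised = rf / max_rf)
}

#' Congruence of a DE-copy tree with the species tree
#'
#' DE-copy leaves are labelled `seqid/<origin>`; the post-duplication
#' copies are compared separately: for each origin present on >= 4
#' sequences the copy subtree is extracted, relabelled to the parent
#' sequence id, and compared by Robinson-Foulds to the species tree
#' restricted to the same leaves.
#'
#' @param de_tree tree over DE copy instances (`seqid/origin` labels).
#' @param species_tree tree over sequence ids.
#' @return data.frame: origin, n_leaves, rf_distance, max_rf, normalised.
#' @export
de_congruence <- function(de_tree, species_tree) {
  parts <- strsplit(de_tree$tip.label, "/", fixed = TRUE)
  sid <- vapply(parts, `[`, character(1), 1)
  origin <- vapply(parts, function(p)
    if (length(p) > 1) sub("\\..*$", "", p[2]) else "copy", character(1))
  out <- list()
  for (o in unique(origin)) {
    tips <- de_tree$tip.label[origin == o]
    ids <- sid[origin == o]
    if (length(tips) < 4 || anyDuplicated(ids)) next
    sub <- ape::keep.tip(de_tree, tips)
    sub$tip.label <- sid[match(sub$tip.label, de_tree$tip.label)]
    sp <- ape::keep.tip(species_tree,
                        intersect(species_tree$tip.label, sub$tip.label))
    if (length(sp$tip.label) < 4) next
    sub <- ape::keep.tip(sub, sp$tip.label)
    cmp <- rf_congruence(sub, sp)
    out[[length(out) + 1]] <- data.frame(
      origin = o, n_leaves = length(sp$tip.label),
      rf_distance = cmp$rf_distance, max_rf = cmp$max_rf,
      normalised = cmp$normalised)
  }
  if (length(out) == 0)
    return(data.frame(origin = character(0), n_leaves = integer(0),
                      rf_distance = integer(0), max_rf = integer(0),
                      normalised = numeric(0)))
  do.call(rbind, out)
}
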