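# Gene-tree plumbing: outgroup rerooting with deterministic root placement,
# bipartition-based monophyly, and per-clade abundance / branch-length
# summaries for annotated HgcA trees.

#' Reroot a gene tree on an outgroup
#'
#' Places the root on the branch separating the outgroup's most recent
#' common ancestor from the ingroup, at the midpoint of that branch (the
#' two root-child edges share its length equally), so that leaf set, total
#' tree length and all unrooted pairwise leaf path lengths are preserved.
#' If the outgroup is not monophyletic in the unrooted topology, a warning
#' is issued and the tree is rooted on the MRCA edge anyway; the result
#' carries the attribute `outgroup_monophyletic`.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param outgroup_leaves Non-empty character vector of tip labels.
#' @return A rooted `phylo`.
#' @export
reroot_on_outgroup <- function(tree, outgroup_leaves) {
  abort_if(length(outgroup_leaves) == 0, "empty outgroup")
  abort_if(!all(outgroup_leaves %in% tree$tip.label),
           "outgroup leaves missing from tree: %s",
           paste(setdiff(outgroup_leaves, tree$tip.label), collapse = ", "))
  abort_if(length(outgroup_leaves) >= length(tree$tip.label),
           "outgroup cannot contain every leaf")
  tr <- ape::unroot(tree)
  mono <- is_monophyletic(tr, outgroup_leaves)
  if (!mono)
    warning("outgroup is not monophyletic; rooting on its MRCA edge")
  if (length(outgroup_leaves) == 1 || mono) {
    res <- ape::root(tr, outgroup = outgroup_leaves, resolve.root = TRUE,
                     edgelabel = TRUE)
  } else {
    anchor <- setdiff(tr$tip.label, outgroup_leaves)[1]
    tmp <- ape::root(tr, outgroup = anchor, resolve.root = TRUE,
                     edgelabel = TRUE)
    m <- ape::getMRCA(tmp, outgroup_leaves)
    res <- ape::root(tmp, node = m, resolve.root = TRUE, edgelabel = TRUE)
  }
  # split the attachment branch evenly across the two root-child edges
  rootnode <- length(res$tip.label) + 1L
  ce <- which(res$edge[, 1] == rootnode)
  if (length(ce) == 2 && !is.null(res$edge.length)) {
    tot <- sum(res$edge.length[ce])
    res$edge.length[ce] <- tot / 2
  }
  attr(res, "outgroup_monophyletic") <- mono
  res
}

#' Bipartition monophyly test
#'
#' TRUE iff some edge of the unrooted topology bipartitions exactly
#' `leaf_set` from the remaining leaves (pendant edges included, so a
#' single leaf and its complement count as monophyletic).
#'
#' @param tree An [ape::phylo].
#' @param leaf_set Non-empty character vector of tip labels.
#' @export
is_monophyletic <- function(tree, leaf_set) {
  abort_if(length(leaf_set) == 0, "empty leaf set")
  abort_if(!all(leaf_set %in% tree$tip.label), "leaf_set not a subset of tips")
  n <- length(tree$tip.label)
  k <- length(unique(leaf_set))
  if (k == 1 || k == n - 1) return(TRUE)
  if (k == n) return(TRUE)
  target <- sort(unique(leaf_set))
  comp <- sort(setdiff(tree$tip.label, target))
  pp <- ape::prop.part(tree)   # tip sets descending from each internal node
  labs <- attr(pp, "labels")
  for (s in pp) {
    tips <- sort(labs[s])
    if (identical(tips, target) || identical(tips, comp)) return(TRUE)
  }
  FALSE
}

#' Per-clade abundance and branch-length summary
#'
#' For each named clade: the summed relative abundance of its member
#' leaves per sample, the mean root-to-tip path length of its members, and
#' a rank by that mean (longest first). Members missing from the abundance
#' table contribute zero abundance, with a warning.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param clades Named list of character vectors of tip labels.
#' @param abundance Long data frame `gene_id`, `sample_id`,
#'   `rel_abundance_pct`; gene ids match tip labels. May be `NULL`.
#' @return List: `abundance` (clade x sample sums, long) and `branch`
#'   (`clade`, `n_leaves`, `mean_root_to_tip`, `length_rank`).
#' @export
clade_summary <- function(tree, clades, abundance = NULL) {
  abort_if(is.null(names(clades)) || any(!nzchar(names(clades))),
           "clades must be a named list")
  all_members <- unlist(clades)
  abort_if(!all(all_members %in% tree$tip.label),
           "clade members missing from tree: %s",
           paste(setdiff(all_members, tree$tip.label), collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)
  tipd <- stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
  branch <- data.frame(
    clade = names(clades),
    n_leaves = vapply(clades, length, integer(1)),
    mean_root_to_tip = vapply(clades, function(m) mean(tipd[m]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  branch$length_rank <- rank(-branch$mean_root_to_tip, ties.method = "min")
  ab <- NULL
  if (!is.null(abundance) && nrow(abundance)) {
    missing <- setdiff(all_members, unique(abundance$gene_id))
    if (length(missing))
      warning(sprintf("%d clade member(s) absent from abundance table; counted as 0",
                      length(missing)))
    rows <- list()
    for (cl in names(clades)) {
      sub <- abundance[abundance$gene_id %in% clades[[cl]], , drop = FALSE]
      for (s in sort(unique(abundance$sample_id))) {
        rows[[length(rows) + 1]] <- data.frame(
          clade = cl, sample_id = s,
          rel_abundance_pct = sum(sub$rel_abundance_pct[sub$sample_id == s]),
          stringsAsFactors = FALSE)
      }
    }
    ab <- do.call(rbind, rows)
  }
  list(abundance = ab, branch = branch)
}
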