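#' Attach branch partition tags to a rooted tree
#'
#' Branches are partitioned into three classes reflecting the history of the
#' catalytic residue: `SEC` (selenocysteine retained), `EXCHANGE` (the branch
#' on which Sec was exchanged for Cys) and `INHERITED` (descendant branches
#' that inherited Cys). Each branch is identified by the label of its child
#' node (a tip label, or an internal node label).
#'
#' @param tree A rooted `phylo` object. Internal nodes without labels are
#'   labelled `N<k>`.
#' @param tags Named character vector or two-column data frame
#'   (`branch`, `tag`) mapping child-node labels to tags. Branches not
#'   mentioned default to `SEC`.
#' @return A `tagged_phylo`: the tree with a `tag` vector aligned to the
#'   rows of `tree$edge`.
#' @export
tag_tree <- function(tree, tags) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree <- label_nodes(tree)
  if (is.data.frame(tags)) tags <- setNames(tags$tag, tags$branch)
  tags <- toupper(tags)
  bad <- setdiff(unique(tags), c("SEC", "EXCHANGE", "INHERITED"))
  if (length(bad)) stop("unknown branch tag(s): ", paste(bad, collapse = ", "))
  ids <- branch_ids(tree)
  missing <- setdiff(names(tags), ids)
  if (length(missing)) {
    stop("tag error: no branch with child label ", paste(missing, collapse = ", "))
  }
  tag <- rep("SEC", nrow(tree$edge))
  tag[match(names(tags), ids)] <- unname(tags)
  tree$tag <- tag
  class(tree) <- c("tagged_phylo", "phylo")
  validate_tagged_tree(tree)
  tree
}

label_nodes <- function(tree) {
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    lab <- tree$node.label
    need <- if (is.null(lab)) rep(TRUE, tree$Nnode) else lab == ""
    if (is.null(lab)) lab <- character(tree$Nnode)
    lab[need] <- paste0("N", which(need))
    tree$node.label <- lab
  }
  tree
}

#' Branch identifiers (child-node labels) in edge order
#' @param tree A `phylo` with node labels.
#' @return Character vector, one entry per row of `tree$edge`.
#' @export
branch_ids <- function(tree) {
  labs <- c(tree$tip.label, tree$node.label)
  labs[tree$edge[, 2]]
}

#' Branch tags in edge order
#' @param tree A `tagged_phylo`.
#' @return Character vector of tags aligned to `tree$edge`.
#' @export
branch_tags <- function(tree) {
  if (is.null(tree$tag)) stop("tree has no branch tags; see tag_tree()")
  tree$tag
}

validate_tagged_tree <- function(tree) {
  if (length(tree$tag) != nrow(tree$edge)) stop("one tag per branch required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  # Once Sec is exchanged for Cys it cannot be regained: no SEC branch may
  # descend from an EXCHANGE (or INHERITED) branch.
  ntip <- length(tree$tip.label)
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2]) # NA at root children
  for (e in seq_len(nrow(tree$edge))) {
    if (tree$tag[e] != "SEC") next
    a <- parent_edge[e]
    while (!is.na(a)) {
      if (tree$tag[a] %in% c("EXCHANGE", "INHERITED")) {
        stop(
          "invalid tagging: SEC branch ", branch_ids(tree)[e],
          " descends from ", tree$tag[a], " branch ", branch_ids(tree)[a]
        )
      }
      a <- parent_edge[a]
    }
  }
  invisible(tree)
}

#' @export
print.tagged_phylo <- function(x, ...) {
  cat("<tagged_phylo> ", length(x$tip.label), " tips; tags: ", sep = "")
  print(table(x$tag))
  invisible(x)
}

#' Consistency check: taxa whose catalytic residue is Cys
#'
#' Flags the taxa carrying Cys (TGT/TGC) at the catalytic site of the
#' alignment and compares them with the taxa descending from branches tagged
#' `EXCHANGE`/`INHERITED`. Tags are always user-supplied; this helper only
#' reports disagreements, it never modifies tags.
#'
#' @param aln A `codon_alignment` with a catalytic site.
#' @param tree A `tagged_phylo`.
#' @return Tibble with columns `taxon`, `catalytic_codon`, `has_cys`,
#'   `tagged_cys`, `consistent`.
#' @export
check_catalytic_tags <- function(aln, tree) {
  cs <- attr(aln, "catalytic_site")
  if (is.na(cs)) stop("alignment has no catalytic site")
  cod <- aln[, cs + 1L]
  has_cys <- cod %in% c("TGT", "TGC")
  cys_taxa <- unlist(lapply(which(tree$tag != "SEC"), function(e) {
    descendant_tips(tree, tree$edge[e, 2])
  }))
  tibble::tibble(
    taxon = rownames(aln),
    catalytic_codon = unname(cod),
    has_cys = unname(has_cys),
    tagged_cys = rownames(aln) %in% cys_taxa,
    consistent = unname(has_cys == (rownames(aln) %in% cys_taxa))
  )
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# edge index whose child is the given node id
edge_of_node <- function(tree, node) match(node, tree$edge[, 2])

# resolve branch id (child label) -> edge index
edge_of_branch <- function(tree, branch) {
  idx <- match(branch, branch_ids(tree))
  if (anyNA(idx)) {
    stop("branch not in tree: ", paste(branch[is.na(idx)], collapse = ", "))
  }
  idx
}

# is edge a ancestral to edge b?
edge_is_ancestral <- function(tree, a, b) {
  parent_edge <- match(tree$edge[, 1], tree$edge[, 2])
  e <- parent_edge[b]
  while (!is.na(e)) {
    if (e == a) return(TRUE)
    e <- parent_edge[e]
  }
  FALSE
}
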