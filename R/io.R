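#' Load and cross-validate the analysis inputs
#'
#' Reads an in-frame codon alignment (FASTA), a rooted species tree (Newick,
#' internal node labels allowed), a branch-tag table and a domain partition
#' table, and returns validated, cross-linked objects. The taxon sets of the
#' alignment and tree must agree exactly.
#'
#' @param alignment_file FASTA file of in-frame coding sequences.
#' @param tree_file Newick file of the rooted species tree.
#' @param tags Path to a TSV with columns `branch` (child-node label) and
#'   `tag`, or a data frame of the same shape.
#' @param domains Path to a TSV with columns `name`, `start`, `end`
#'   (0-based, half-open amino-acid coordinates), or a data frame; `NULL`
#'   for no domain partition.
#' @param catalytic_site 0-based codon coordinate of the catalytic site
#'   (`NA` for none).
#' @return List with elements `alignment` (`codon_alignment`), `tree`
#'   (`tagged_phylo`) and `domains` (tibble).
#' @export
load_inputs <- function(alignment_file, tree_file, tags, domains = NULL,
                        catalytic_site = NA_integer_) {
  seqs <- read_fasta(alignment_file)
  tree <- ape::read.tree(tree_file)
  if (is.null(tree)) stop("could not parse tree file ", tree_file)
  if (is.character(tags)) tags <- read.delim(tags, stringsAsFactors = FALSE)
  if (is.character(domains)) domains <- read.delim(domains, stringsAsFactors = FALSE)
  miss_aln <- setdiff(tree$tip.label, names(seqs))
  miss_tree <- setdiff(names(seqs), tree$tip.label)
  if (length(miss_aln) || length(miss_tree)) {
    stop(
      "taxon mismatch between alignment and tree",
      if (length(miss_aln)) paste0("; missing from alignment: ",
                                   paste(miss_aln, collapse = ", ")),
      if (length(miss_tree)) paste0("; missing from tree: ",
                                    paste(miss_tree, collapse = ", "))
    )
  }
  aln <- codon_alignment(seqs, catalytic_site = catalytic_site,
                         domains = domains)
  tree <- tag_tree(tree, tags)
  list(alignment = aln, tree = tree, domains = attr(aln, "domains"))
}

read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' Write alignments and trees back to disk
#'
#' @param aln A `codon_alignment` or `protein_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste0, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = path)
  invisible(path)
}

#' Read a per-column confidence track
#'
#' One posterior probability in `[0,1]` per amino-acid alignment column,
#' e.g. average column posteriors exported from an HMM alignment; this
#' package consumes the track, it does not compute it.
#'
#' @param path TSV with a `posterior` column (optionally a `site` column,
#'   0-based, used only for ordering), or a numeric vector.
#' @return Numeric vector of posteriors.
#' @export
read_confidence <- function(path) {
  if (is.numeric(path)) return(validate_confidence(path))
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"posterior" %in% names(x)) stop("confidence file needs a 'posterior' column")
  if ("site" %in% names(x)) x <- x[order(x$site), ]
  validate_confidence(x$posterior)
}

validate_confidence <- function(conf) {
  if (any(!is.finite(conf)) || any(conf < 0 | conf > 1)) {
    stop("confidence values must lie in [0, 1]")
  }
  conf
}

#' Mask low-confidence alignment columns
#'
#' Drops every codon column whose column confidence falls below `threshold`
#' (masking is per codon column: one amino-acid confidence value governs the
#' whole codon). Domain coordinates and the catalytic site are remapped onto
#' the retained columns; the old-to-new column mapping is recorded in the
#' `column_map` attribute.
#'
#' @param aln A `codon_alignment`.
#' @param conf Numeric vector of per-column posteriors (length
#'   `n_codons(aln)`), or a path readable by [read_confidence()].
#' @param threshold Columns with confidence `< threshold` are removed.
#' @return The masked `codon_alignment`.
#' @export
apply_column_mask <- function(aln, conf, threshold = 0.95) {
  conf <- read_confidence(conf)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (length(conf) != ncol(aln)) {
    stop(
      "confidence track length (", length(conf),
      ") does not match alignment length (", ncol(aln), ")"
    )
  }
  keep <- which(conf >= threshold)
  if (!length(keep)) warning("all columns masked; alignment is empty")
  subset_columns(aln, keep)
}

# Keep the given (1-based) codon columns, remapping catalytic site and
# domains; columns removed from the middle shift later domains left.
subset_columns <- function(aln, keep) {
  new_of_old <- match(seq_len(ncol(aln)), keep) # NA if dropped
  cs <- attr(aln, "catalytic_site")
  new_cs <- if (!is.na(cs)) {
    v <- new_of_old[cs + 1L]
    if (is.na(v)) NA_integer_ else v - 1L
  } else NA_integer_
  dom <- attr(aln, "domains")
  if (nrow(dom)) {
    dom <- dplyr::mutate(dom,
      start = vapply(.data$start, function(s) sum(keep <= s), integer(1)),
      end = vapply(.data$end, function(e) sum(keep <= e), integer(1))
    )
    dom <- dplyr::filter(dom, .data$end > .data$start)
  }
  out <- codon_alignment(unclass(aln)[, keep, drop = FALSE],
    catalytic_site = new_cs, domains = dom, validate = FALSE
  )
  attr(out, "column_map") <- tibble::tibble(
    old = seq_along(new_of_old) - 1L,
    new = new_of_old - 1L
  )
  out
}

#' Extract a domain region from an alignment
#'
#' @param aln A `codon_alignment` with a domain partition.
#' @param region A domain name, or `"full"` for the whole alignment.
#' @param exclude_catalytic Drop the catalytic-site column if it lies inside
#'   the region. The Sec/Cys site is the conditioning event of the analysis,
#'   not data, so rate estimation and convergence counting exclude it.
#' @return The sub-`codon_alignment` with remapped coordinates.
#' @export
extract_region <- function(aln, region = "full", exclude_catalytic = FALSE) {
  dom <- attr(aln, "domains")
  if (identical(region, "full")) {
    keep <- seq_len(ncol(aln))
  } else {
    r <- dom[dom$name == region, ]
    if (!nrow(r)) stop("unknown region: ", region)
    keep <- seq.int(r$start + 1L, r$end)
  }
  cs <- attr(aln, "catalytic_site")
  if (exclude_catalytic && !is.na(cs)) keep <- setdiff(keep, cs + 1L)
  subset_columns(aln, keep)
}

#' Read a domain partition table
#' @param path TSV with columns `name`, `start`, `end` (0-based half-open).
#' @return Tibble.
#' @export
read_domains <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Write the branch-tag table for a tagged tree
#' @param tree A `tagged_phylo`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_branch_tags <- function(tree, path) {
  write.table(
    data.frame(branch = branch_ids(tree), tag = tree$tag),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
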