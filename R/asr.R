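#' Empirical amino-acid replacement models
#'
#' An amino-acid model is a symmetric 20x20 exchangeability matrix plus
#' stationary frequencies; the rate matrix is `ex[i,j] * pi[j]`, scaled to
#' one expected replacement per site per unit time. [jtt_model()] returns
#' the Jones-Taylor-Thornton model (exchangeabilities and frequencies taken
#' from phangorn), reordered to the package's alphabetical amino-acid order.
#'
#' @param exchangeabilities Symmetric non-negative 20x20 matrix with zero
#'   diagonal, rows/cols named by [AA20] order.
#' @param frequencies Stationary frequencies summing to 1.
#' @param name Model label.
#' @return An `amino_acid_model` with elements `ex`, `pi`, `Q` (scaled rate
#'   matrix) and `eig` (its eigen-decomposition).
#' @export
amino_acid_model <- function(exchangeabilities, frequencies, name = "custom") {
  ex <- as.matrix(exchangeabilities)
  pi <- as.numeric(frequencies)
  if (!isTRUE(all.equal(ex, t(ex)))) stop("exchangeabilities must be symmetric")
  if (any(ex < 0)) stop("exchangeabilities must be non-negative")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6) stop("frequencies must sum to 1")
  pi <- pi / sum(pi)
  Q <- ex * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  dimnames(Q) <- list(AA20, AA20)
  structure(
    list(name = name, ex = ex, pi = setNames(pi, AA20), Q = Q,
         eig = eigen_reversible(Q, pi)),
    class = "amino_acid_model"
  )
}

#' @rdname amino_acid_model
#' @export
jtt_model <- function() {
  if (!is.null(.selconv$jtt)) return(.selconv$jtt)
  paml_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  env <- new.env()
  local({
    Q <- NULL; bf <- NULL
    getModelAA <- get("getModelAA", envir = asNamespace("phangorn"))
    getModelAA("JTT", bf = TRUE, Q = TRUE)
    assign("Q", Q, envir = env); assign("bf", bf, envir = env)
  })
  ex <- matrix(0, 20, 20, dimnames = list(paml_order, paml_order))
  ex[lower.tri(ex)] <- env$Q
  ex <- ex + t(ex)
  pi <- setNames(env$bf, paml_order)
  ord <- match(AA20, paml_order)
  .selconv$jtt <- amino_acid_model(ex[ord, ord], pi[ord], name = "JTT")
  .selconv$jtt
}

#' @export
print.amino_acid_model <- function(x, ...) {
  cat("<amino_acid_model> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Marginal empirical-Bayes ancestral sequence reconstruction
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over the 20 amino acids given the tip sequences, the tree
#' and an empirical replacement model, by combining inside (subtree) and
#' outside (rest-of-tree) partial likelihoods. The MAP state breaks ties
#' toward the alphabetically earlier amino acid. The selenocysteine column
#' (catalytic site), gaps and ambiguous residues contribute no information;
#' the catalytic column is excluded from reconstruction and handled
#' separately by [sec_parsimony()].
#'
#' @param prot A `protein_alignment` (or `codon_alignment`, translated
#'   internally).
#' @param tree A rooted `phylo`/`tagged_phylo` matching the alignment.
#' @param model An `amino_acid_model` (default [jtt_model()]).
#' @param optimize_lengths Refit branch lengths by maximum likelihood under
#'   the amino-acid model before reconstructing (recommended when the input
#'   lengths are not on an amino-acid scale).
#' @return An `asr` object: posterior array (`nodes x 20 x sites`), MAP
#'   matrix, per-node labels, the tree with the lengths used, and the
#'   0-based original site coordinates retained.
#' @export
marginal_asr <- function(prot, tree, model = jtt_model(),
                         optimize_lengths = TRUE) {
  if (inherits(prot, "codon_alignment")) prot <- translate_alignment(prot)
  if (!setequal(rownames(prot), tree$tip.label)) {
    stop("alignment taxa and tree tips differ")
  }
  cs <- attr(prot, "catalytic_site")
  sites0 <- seq_len(ncol(prot)) - 1L
  keep <- if (!is.null(cs) && !is.na(cs)) which(sites0 != cs) else seq_along(sites0)
  states <- protein_states(unclass(prot)[, keep, drop = FALSE])
  rownames(states) <- rownames(prot)
  allgap <- which(colSums(!is.na(states)) == 0)
  if (length(allgap)) {
    warning(length(allgap), " all-gap column(s); posterior left uniform there")
  }
  tree <- label_nodes(tree)
  pt <- prune_tree(tree)
  tvec <- pt$tree$edge.length
  if (is.null(tvec)) tvec <- rep(0.1, pt$nedge)
  tvec <- pmax(tvec, 1e-8)
  cp <- compress_patterns(states)
  tipp <- tip_partials(pt, cp$states, 20)
  egs <- list(model$eig)
  ecl <- rep(1L, pt$nedge)
  if (optimize_lengths) {
    opt <- optimize_edge_lengths(pt, tipp, egs, ecl, tvec, model$pi,
                                 weights = cp$weights, sweeps = 5)
    tvec <- opt$t
  }
  # posteriors on the full (uncompressed) site set
  tipp_full <- tip_partials(pt, states, 20)
  P_list <- lapply(tvec, function(t) pmat_from_eigen(model$eig, t))
  insr <- inside_partials(pt, tipp_full, P_list)
  outs <- outside_partials(pt, insr$ins, P_list, model$pi)
  ntip <- pt$ntip
  nodes <- seq.int(ntip + 1L, ntip + pt$tree$Nnode)
  labs <- c(pt$tree$tip.label, pt$tree$node.label)
  nsites <- ncol(states)
  post <- array(NA_real_, dim = c(length(nodes), 20, nsites),
                dimnames = list(labs[nodes], AA20, NULL))
  for (i in seq_along(nodes)) {
    m <- insr$ins[[nodes[i]]] * outs[[nodes[i]]]
    tot <- colSums(m)
    tot[tot <= 0] <- 1
    m <- sweep(m, 2, tot, "/")
    post[i, , ] <- m
  }
  if (length(allgap)) post[, , allgap] <- 1 / 20
  map <- apply(post, c(1, 3), function(v) AA20[which.max(v)])
  fitted_tree <- pt$tree
  fitted_tree$edge.length <- tvec
  structure(
    list(
      posterior = post, map = map, nodes = labs[nodes],
      tree = fitted_tree, model = model,
      sites = sites0[keep], # 0-based original coordinates
      tip_states = states, catalytic_site = if (is.null(cs)) NA_integer_ else cs
    ),
    class = "asr"
  )
}

#' @export
print.asr <- function(x, ...) {
  cat("<asr> ", length(x$nodes), " internal nodes x ", length(x$sites),
      " sites (", x$model$name, ")\n", sep = "")
  invisible(x)
}

#' Per-node reconstruction accuracy
#'
#' The accuracy of a node's reconstruction is the mean, over sites, of the
#' posterior probability of the MAP state -- the expected fraction of
#' correctly inferred residues under the model.
#'
#' @param rec An `asr` object.
#' @return Tibble with `node` and `accuracy` (in `[0, 1]`).
#' @export
node_accuracy <- function(rec) {
  acc <- vapply(seq_along(rec$nodes), function(i) {
    p <- matrix(rec$posterior[i, , ], nrow = 20)
    mean(apply(p, 2, max))
  }, numeric(1))
  tibble::tibble(node = rec$nodes, accuracy = acc)
}

#' MAP ancestral sequences as a character matrix
#' @param rec An `asr` object.
#' @return Character matrix, internal nodes x sites.
#' @export
map_sequences <- function(rec) rec$map

#' Parsimony reconstruction of the Sec/Cys catalytic character
#'
#' Fitch parsimony on the binary selenocysteine/cysteine state of the
#' catalytic site, used to place and count the independent Sec losses.
#' Ambiguous assignments (Fitch ties) are reported as both states, never
#' resolved silently.
#'
#' @param aln A `codon_alignment` with a catalytic site.
#' @param tree A rooted `phylo` matching the alignment.
#' @return List with `states` (tibble: node, state, ambiguous), `n_losses`
#'   (minimum number of Sec-to-Cys transitions) and `loss_branches`
#'   (branch ids where a loss is unambiguously placed).
#' @export
sec_parsimony <- function(aln, tree) {
  cs <- attr(aln, "catalytic_site")
  if (is.na(cs)) stop("alignment has no catalytic site")
  cod <- aln[, cs + 1L]
  tipstate <- unname(ifelse(cod == "TGA", "U",
                            ifelse(cod %in% c("TGT", "TGC"), "C", NA)))
  tree <- label_nodes(tree)
  pt <- prune_tree(tree)
  tr <- pt$tree
  labs <- c(tr$tip.label, tr$node.label)
  n <- pt$ntip + tr$Nnode
  sets <- vector("list", n)
  ord <- match(tr$tip.label, rownames(aln))
  for (i in seq_len(pt$ntip)) {
    s <- tipstate[ord[i]]
    sets[[i]] <- if (is.na(s)) c("U", "C") else s
  }
  changes <- 0
  for (e in seq_len(pt$nedge)) { # postorder: combine children into parent
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- intersect(sets[[p]], sets[[ch]])
      if (length(inter)) sets[[p]] <- inter
      else { sets[[p]] <- union(sets[[p]], sets[[ch]]); changes <- changes + 1 }
    }
  }
  # top-down final states (prefer parent state on ties)
  final <- vector("list", n)
  final[[pt$root]] <- sets[[pt$root]]
  for (e in rev(seq_len(pt$nedge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    inter <- intersect(sets[[ch]], final[[p]])
    final[[ch]] <- if (length(inter)) inter else sets[[ch]]
  }
  loss <- character(0)
  for (e in seq_len(pt$nedge)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (identical(final[[p]], "U") && identical(final[[ch]], "C")) {
      loss <- c(loss, labs[ch])
    }
  }
  list(
    states = tibble::tibble(
      node = labs,
      state = vapply(final, paste0, character(1), collapse = "/"),
      ambiguous = lengths(final) > 1
    ),
    n_losses = changes,
    loss_branches = loss
  )
}
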