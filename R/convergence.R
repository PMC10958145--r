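#' Extract amino-acid substitution events from a reconstruction
#'
#' One event is emitted for every (branch, site) where the MAP states at the
#' two ends of the branch differ. Tip branches use the observed tip residue;
#' sites where either endpoint is a gap or ambiguous are skipped. Masked
#' columns and the catalytic column never appear (they are absent from the
#' reconstruction).
#'
#' @param rec An `asr` object.
#' @param branches Branch ids (child-node labels) to scan; default all.
#' @return Tibble of `SubstitutionEvent`s: `branch`, `site` (0-based
#'   original coordinate), `from`, `to`.
#' @export
extract_substitutions <- function(rec, branches = NULL) {
  tr <- rec$tree
  ids <- branch_ids(tr)
  if (is.null(branches)) branches <- ids
  edges <- edge_of_branch(tr, branches)
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label, tr$node.label)
  state_of <- function(node) {
    if (node <= ntip) {
      s <- rec$tip_states[tr$tip.label[node], ]
      ifelse(is.na(s), NA_character_, AA20[s])
    } else {
      rec$map[match(labs[node], rec$nodes), ]
    }
  }
  purrr::map_dfr(edges, function(e) {
    from <- state_of(tr$edge[e, 1])
    to <- state_of(tr$edge[e, 2])
    hit <- which(!is.na(from) & !is.na(to) & from != to)
    tibble::tibble(
      branch = ids[e], site = rec$sites[hit],
      from = from[hit], to = to[hit]
    )
  })
}

#' Classify convergent and parallel substitutions between branch pairs
#'
#' For each (phylogenetically independent) pair of branches, sites carrying
#' an event on both branches with the same derived residue are classified as
#' *parallel* (same ancestral residue on both) or *convergent* (different
#' ancestral residues). Following the umbrella usage of the field's
#' convergence counts, reported "convergent sites" are the union of the two
#' classes; the classes stay distinguishable in the output. Events toward
#' merely *similar* residues (same physicochemical group) are reported in a
#' separate `similar` class and never merged into the headline counts.
#'
#' @param events Tibble from [extract_substitutions()].
#' @param pairs Two-column data frame / matrix of branch ids, or `NULL` to
#'   take all unordered pairs of the branches present in `events`.
#' @param tree Optional `phylo` used to verify that no branch of a pair is
#'   ancestral to the other.
#' @param similarity Named list of amino-acid groups used for the `similar`
#'   class (default standard physicochemical classes).
#' @return List with `pairs` (tibble: branch1, branch2, n_parallel,
#'   n_convergent, n_similar, sites list-column) and `sites` (tibble of
#'   per-site classifications); `convergent_sites(x)` gives the union.
#' @export
detect_pairwise_convergence <- function(events, pairs = NULL, tree = NULL,
                                        similarity = aa_groups()) {
  brs <- sort(unique(events$branch))
  if (is.null(pairs)) {
    if (length(brs) < 2) {
      pairs <- matrix(character(0), ncol = 2)
    } else {
      pairs <- t(utils::combn(brs, 2))
    }
  }
  pairs <- as.matrix(pairs)
  if (!is.null(tree)) {
    for (r in seq_len(nrow(pairs))) {
      e1 <- edge_of_branch(tree, pairs[r, 1])
      e2 <- edge_of_branch(tree, pairs[r, 2])
      if (edge_is_ancestral(tree, e1, e2) || edge_is_ancestral(tree, e2, e1)) {
        stop(
          "branch pair not independent: ", pairs[r, 1], " / ", pairs[r, 2],
          " (one is ancestral to the other)"
        )
      }
    }
  }
  group_of <- function(a) {
    g <- vapply(similarity, function(set) a %in% set, logical(1))
    if (any(g)) names(similarity)[which(g)[1]] else a
  }
  site_rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    b1 <- pairs[r, 1]; b2 <- pairs[r, 2]
    e1 <- events[events$branch == b1, ]
    e2 <- events[events$branch == b2, ]
    shared <- intersect(e1$site, e2$site)
    if (!length(shared)) return(tibble::tibble())
    i1 <- match(shared, e1$site); i2 <- match(shared, e2$site)
    same_to <- e1$to[i1] == e2$to[i2]
    same_from <- e1$from[i1] == e2$from[i2]
    sim <- !same_to & mapply(
      function(a, b) group_of(a) == group_of(b), e1$to[i1], e2$to[i2]
    )
    cls <- dplyr::case_when(
      same_to & same_from ~ "parallel",
      same_to & !same_from ~ "convergent",
      sim ~ "similar",
      TRUE ~ "none"
    )
    tibble::tibble(
      branch1 = b1, branch2 = b2, site = shared,
      from1 = e1$from[i1], from2 = e2$from[i2],
      to1 = e1$to[i1], to2 = e2$to[i2], class = cls
    )
  })
  if (!nrow(site_rows)) {
    site_rows <- tibble::tibble(
      branch1 = character(), branch2 = character(), site = integer(),
      from1 = character(), from2 = character(), to1 = character(),
      to2 = character(), class = character()
    )
  }
  pair_tab <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    b1 <- pairs[r, 1]; b2 <- pairs[r, 2]
    s <- site_rows[site_rows$branch1 == b1 & site_rows$branch2 == b2, ]
    tibble::tibble(
      branch1 = b1, branch2 = b2,
      n_parallel = sum(s$class == "parallel"),
      n_convergent = sum(s$class == "convergent"),
      n_similar = sum(s$class == "similar"),
      sites = list(sort(s$site[s$class %in% c("parallel", "convergent")]))
    )
  })
  structure(list(pairs = pair_tab, sites = site_rows),
            class = "convergence_scan")
}

#' @export
print.convergence_scan <- function(x, ...) {
  cat("<convergence_scan> ", nrow(x$pairs), " branch pairs; ",
      length(convergent_sites(x)), " convergent sites (union)\n", sep = "")
  invisible(x)
}

#' Union of convergent + parallel sites across all scanned pairs
#' @param scan A `convergence_scan`.
#' @return Sorted integer vector of 0-based site coordinates.
#' @export
convergent_sites <- function(scan) {
  sort(unique(unlist(scan$pairs$sites)))
}

#' Standard physicochemical amino-acid groups
#' @return Named list of character vectors.
#' @export
aa_groups <- function() {
  list(
    aliphatic = c("A", "G", "I", "L", "P", "V"),
    aromatic = c("F", "W", "Y"),
    acidic = c("D", "E"),
    basic = c("H", "K", "R"),
    hydroxyl = c("S", "T"),
    sulfur = c("C", "M"),
    amide = c("N", "Q")
  )
}

#' Model-based expected convergence counts for a branch pair
#'
#' For each site the probability that both branches substitute and end in
#' the same residue is computed by summing the marginal ancestral posteriors
#' at the two parent nodes against the replacement model's transition
#' probabilities over each branch; the sum over sites gives the expected
#' parallel (same ancestral state) and convergent (different ancestral
#' states) counts. A Poisson tail `P(X >= observed)` with mean equal to the
#' expectation gives the per-pair p-value.
#'
#' @param rec An `asr` object (provides posteriors and branch lengths on the
#'   amino-acid scale).
#' @param pair Character vector of two branch ids.
#' @param observed Optional observed counts (list or tibble row with
#'   `n_parallel`, `n_convergent`); when supplied, Poisson p-values are
#'   attached.
#' @param model Replacement model (defaults to the one in `rec`).
#' @return Tibble with expected counts and, when `observed` is given,
#'   Poisson tail probabilities.
#' @export
expected_convergence_counts <- function(rec, pair, observed = NULL,
                                        model = rec$model) {
  tr <- rec$tree
  e1 <- edge_of_branch(tr, pair[1]); e2 <- edge_of_branch(tr, pair[2])
  t1 <- tr$edge.length[e1]; t2 <- tr$edge.length[e2]
  P1 <- pmat_from_eigen(model$eig, t1)
  P2 <- pmat_from_eigen(model$eig, t2)
  labs <- c(tr$tip.label, tr$node.label)
  post_at <- function(node) {
    i <- match(labs[node], rec$nodes)
    if (is.na(i)) stop("no posterior available at node ", labs[node])
    matrix(rec$posterior[i, , ], nrow = 20)
  }
  q1 <- post_at(tr$edge[e1, 1])
  q2 <- post_at(tr$edge[e2, 1])
  nsites <- ncol(q1)
  # per ancestral pair (x1, x2): prob both branches change and meet at y
  # meet[x1, x2] = sum_y P1[x1,y] P2[x2,y] [y != x1] [y != x2]
  meet <- P1 %*% t(P2)
  # subtract the y = x1 and y = x2 terms
  sub1 <- outer(seq_len(20), seq_len(20),
                function(i, j) P1[cbind(i, i)] * P2[cbind(j, i)])
  sub2 <- outer(seq_len(20), seq_len(20),
                function(i, j) P1[cbind(i, j)] * P2[cbind(j, j)])
  both <- outer(seq_len(20), seq_len(20),
                function(i, j) ifelse(i == j, P1[cbind(i, i)] * P2[cbind(j, j)], 0))
  meet_chg <- meet - sub1 - sub2 + both # double-subtraction fixed on diagonal
  ep <- 0; ec <- 0
  for (s in seq_len(nsites)) {
    W <- q1[, s] %o% q2[, s]
    ep <- ep + sum(diag(W) * diag(meet_chg))
    ec <- ec + sum(W * meet_chg) - sum(diag(W) * diag(meet_chg))
  }
  out <- tibble::tibble(
    branch1 = pair[1], branch2 = pair[2], t1 = t1, t2 = t2,
    expected_parallel = ep, expected_convergent = ec,
    expected_total = ep + ec
  )
  if (!is.null(observed)) {
    obs_p <- observed$n_parallel; obs_c <- observed$n_convergent
    pois_tail <- function(obs, lambda) {
      if (lambda <= 0) return(as.numeric(obs == 0) * 1 + as.numeric(obs > 0) * 0)
      ppois(obs - 1, lambda, lower.tail = FALSE)
    }
    out$observed_parallel <- obs_p
    out$observed_convergent <- obs_c
    out$p_parallel <- pois_tail(obs_p, ep)
    out$p_convergent <- pois_tail(obs_c, ec)
    out$p_total <- pois_tail(obs_p + obs_c, ep + ec)
  }
  out
}

#' Summarise convergence on a focal branch by protein domain
#'
#' Lists the sites substituting on one focal (Sec-loss) branch, flags those
#' belonging to the convergent-site set, counts them per protein domain
#' (with exact percentages), and, when branch-site selection posteriors are
#' supplied, flags sites whose posterior lies in the upper tail percentile.
#'
#' @param events Tibble from [extract_substitutions()].
#' @param conv_sites Integer vector of convergent sites (0-based), e.g. from
#'   [convergent_sites()].
#' @param focal Focal branch id (should be tagged EXCHANGE).
#' @param domains Domain partition tibble (`name`, `start`, `end`).
#' @param posteriors Optional tibble (`site`, `posterior`) from
#'   [site_posteriors()].
#' @param percentile Upper-percentile threshold used for the selection flag.
#' @param percentile_domain Restrict the percentile reference distribution
#'   to this domain (`NULL` = all supplied sites).
#' @return A `convergence_report`: list with `sites` (per-site tibble) and
#'   `domains` (per-domain counts and percentages).
#' @export
focal_branch_summary <- function(events, conv_sites, focal, domains,
                                 posteriors = NULL, percentile = 90,
                                 percentile_domain = NULL) {
  ev <- events[events$branch == focal, ]
  domain_of <- function(site) {
    hit <- domains$name[site >= domains$start & site < domains$end]
    if (length(hit)) hit[1] else NA_character_
  }
  sites <- tibble::tibble(
    site = ev$site, from = ev$from, to = ev$to,
    domain = vapply(ev$site, domain_of, character(1)),
    convergent = ev$site %in% conv_sites
  )
  if (!is.null(posteriors)) {
    ref <- posteriors
    if (!is.null(percentile_domain)) {
      d <- domains[domains$name == percentile_domain, ]
      ref <- ref[ref$site >= d$start & ref$site < d$end, ]
    }
    thr <- stats::quantile(ref$posterior, percentile / 100, type = 5,
                           names = FALSE)
    sites$posterior <- posteriors$posterior[match(sites$site, posteriors$site)]
    sites$selected <- !is.na(sites$posterior) & sites$posterior > thr
  }
  conv <- sites[sites$convergent, ]
  dom_tab <- dplyr::bind_rows(
    purrr::map_dfr(domains$name, function(nm) {
      tibble::tibble(
        domain = nm,
        n_changes = sum(sites$domain == nm, na.rm = TRUE),
        n_convergent = sum(conv$domain == nm, na.rm = TRUE)
      )
    })
  )
  dom_tab$pct_convergent <- if (sum(dom_tab$n_convergent) > 0) {
    100 * dom_tab$n_convergent / sum(dom_tab$n_convergent)
  } else 0
  structure(
    list(focal = focal, sites = sites, domains = dom_tab,
         n_changes = nrow(sites), n_convergent = nrow(conv)),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> focal branch ", x$focal, ": ", x$n_changes,
      " changes, ", x$n_convergent, " convergent\n", sep = "")
  print(x$domains)
  invisible(x)
}

#' Tree built from a subset of (convergent) sites
#'
#' Builds a midpoint-rooted neighbour-joining tree from maximum-likelihood
#' pairwise distances under an empirical amino-acid model, using only the
#' given alignment columns; convergence strong enough to mimic shared
#' ancestry pulls the converging lineages together in this tree.
#'
#' @param prot A `protein_alignment`.
#' @param sites 0-based site coordinates to keep (`NULL` = all).
#' @param taxa_of_interest Optional taxon set for the clade-membership
#'   report (e.g. the Cys-bearing taxa).
#' @param model Distance model name passed to [phangorn::dist.ml()]
#'   (default `"JTT"`).
#' @return List with `tree` (rooted `phylo`) and, when `taxa_of_interest`
#'   is given, `n_clades` -- the minimum number of clades of the tree whose
#'   union is exactly that taxon set.
#' @export
convergence_tree <- function(prot, sites = NULL, taxa_of_interest = NULL,
                             model = "JTT") {
  m <- unclass(prot)
  if (!is.null(sites)) m <- m[, sites + 1L, drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 taxa")
  if (ncol(m) < 1) stop("need at least 1 site")
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    warning("all selected columns are invariant; tree is star-like")
  }
  pd <- phangorn::phyDat(m, type = "AA")
  d <- phangorn::dist.ml(pd, model = model)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  out <- list(tree = tr)
  if (!is.null(taxa_of_interest)) {
    out$n_clades <- count_covering_clades(tr, taxa_of_interest)
  }
  out
}

# Minimum number of clades of a rooted tree whose tip sets are contained in
# `taxa` and together cover it: maximal monophyletic blocks of the set.
count_covering_clades <- function(tree, taxa) {
  tree <- label_nodes(tree)
  pt <- prune_tree(tree)
  tr <- pt$tree
  ntip <- pt$ntip
  n <- ntip + tr$Nnode
  pure <- logical(n)
  for (i in seq_len(ntip)) pure[i] <- tr$tip.label[i] %in% taxa
  for (e in seq_len(pt$nedge)) {
    p <- tr$edge[e, 1]
    kids <- tr$edge[tr$edge[, 1] == p, 2]
    pure[p] <- all(pure[kids])
  }
  parent_of <- rep(NA_integer_, n)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  maximal <- vapply(seq_len(n), function(v) {
    pure[v] && (is.na(parent_of[v]) || !pure[parent_of[v]])
  }, logical(1))
  sum(maximal)
}
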