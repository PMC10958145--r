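# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct enumerations / closed forms, never via the package's pruning or
# posterior code paths.

# small rooted tagged tree with given tip count (deterministic shape)
fixture_tree <- function(ntip = 6, seed = 1, tags = NULL) {
  set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.25)
  if (is.null(tags)) tags <- c(t1 = "EXCHANGE", t2 = "EXCHANGE")
  tag_tree(tr, tags)
}

# random in-frame sequences (no stops) as a codon_alignment
fixture_alignment <- function(taxa, n_codons, seed = 1, domains = NULL,
                              catalytic_site = NA_integer_) {
  set.seed(seed)
  ct <- selconv:::codon_table()
  m <- matrix(sample(ct$codons, length(taxa) * n_codons, replace = TRUE),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  codon_alignment(m, catalytic_site = catalytic_site, domains = domains)
}

# brute-force codon-site likelihood for a 2-taxon rooted tree
#   L = sum_i pi_i P[i,a](t1) P[i,b](t2)
oracle_2taxon_site_lik <- function(P1, P2, pi, a, b) {
  sum(pi * P1[, a] * P2[, b])
}

# brute-force likelihood for tree ((A:t1,B:t2)I:t3, C:t4)R by enumerating
# the two internal states
oracle_3taxon_site_lik <- function(P1, P2, P3, P4, pi, a, b, c) {
  tot <- 0
  k <- length(pi)
  for (r in seq_len(k)) {
    inner <- sum(P3[r, ] * (P1[, a] * P2[, b]))
    tot <- tot + pi[r] * inner * P4[r, c]
  }
  tot
}

# direct Bayes posterior for the root of a 3-taxon star tree, single site
oracle_star_posterior <- function(model, t, states) {
  P <- selconv:::pmat_from_eigen(model$eig, t)
  idx <- match(states, selconv::AA20)
  w <- model$pi
  for (i in idx) w <- w * P[, i]
  w / sum(w)
}

# brute-force expected parallel/convergent probability for one site with
# ancestral posteriors q1, q2 (20-vectors): full 20x20x20 enumeration
oracle_expected_one_site <- function(P1, P2, q1, q2) {
  ep <- 0; ec <- 0
  for (x1 in 1:20) for (x2 in 1:20) {
    w <- q1[x1] * q2[x2]
    if (w == 0) next
    for (y in 1:20) {
      if (y == x1 || y == x2) next
      pr <- w * P1[x1, y] * P2[x2, y]
      if (x1 == x2) ep <- ep + pr else ec <- ec + pr
    }
  }
  c(parallel = ep, convergent = ec)
}

# events tibble shortcut
ev <- function(branch, site, from, to) {
  tibble::tibble(branch = branch, site = site, from = from, to = to)
}

# recompute protein-level substitution events from a dataset's true node
# sequences, independently of the generator's bookkeeping
recount_true_events <- function(ds) {
  aln <- ds$alignment
  cs <- attr(aln, "catalytic_site")
  tr <- ds$tree
  labs <- c(tr$tip.label, tr$node.label)
  seq_of <- function(lab) {
    if (lab %in% rownames(aln)) unclass(aln)[lab, ]
    else ds$truth$node_codons[lab, ]
  }
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- seq_of(labs[tr$edge[e, 1]]); ch <- seq_of(labs[tr$edge[e, 2]])
    aa_p <- gc[p]; aa_c <- gc[ch]
    hit <- which(aa_p != aa_c & seq_along(p) != cs + 1L)
    if (length(hit)) {
      out[[length(out) + 1]] <- tibble::tibble(
        branch = labs[tr$edge[e, 2]], site = hit - 1L,
        from = unname(aa_p[hit]), to = unname(aa_c[hit])
      )
    }
  }
  dplyr::bind_rows(out)
}
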