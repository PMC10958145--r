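# The pruning engine is checked against direct enumeration oracles on tiny
# trees, then for its structural invariances.

test_that("single-taxon, single-codon likelihood equals log pi", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1)r;") # minimal rooted tree
  aln <- codon_alignment(c(a = "AAA", b = "AAA"), validate = FALSE)
  pi <- setNames(rep(1 / 61, 61), selconv:::codon_table()$codons)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(2, 0.5, pi), pi)
  pt <- selconv:::prune_tree(tr)
  tipp <- selconv:::tip_partials(pt, selconv:::codon_states(aln), 61)
  # with both branch lengths ~0 this is just log pi(AAA)
  ll <- selconv:::tree_loglik(pt, tipp, list(eg), c(1L, 1L), c(1e-9, 1e-9), pi)
  expect_equal(ll, log(pi[["AAA"]]), tolerance = 1e-6)
})

test_that("pruning equals the direct sum on a 2-taxon tree", {
  aln <- fixture_alignment(c("a", "b"), 40, seed = 9)
  pi <- f3x4_frequencies(aln)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(1.8, 0.3, pi), pi)
  t1 <- 0.12; t2 <- 0.31
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f)r;", t1, t2))
  pt <- selconv:::prune_tree(tr)
  st <- selconv:::codon_states(aln)
  tipp <- selconv:::tip_partials(pt, st, 61)
  sl <- selconv:::site_loglik(
    pt, tipp,
    lapply(pt$tree$edge.length, function(t) selconv:::pmat_from_eigen(eg, t)),
    pi
  )
  P1 <- selconv:::pmat_from_eigen(eg, t1)
  P2 <- selconv:::pmat_from_eigen(eg, t2)
  for (s in 1:5) {
    expect_equal(
      sl[s],
      log(oracle_2taxon_site_lik(P1, P2, pi, st["a", s], st["b", s])),
      tolerance = 1e-10
    )
  }
})

test_that("pruning equals brute-force enumeration over internal states on a
           3-taxon tree", {
  aln <- fixture_alignment(c("a", "b", "c"), 60, seed = 10)
  pi <- f3x4_frequencies(aln)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(2.2, 0.6, pi), pi)
  ts <- c(a = 0.08, b = 0.2, i = 0.15, c = 0.3)
  tr <- ape::read.tree(
    text = sprintf("((a:%f,b:%f)i:%f,c:%f)r;", ts["a"], ts["b"], ts["i"], ts["c"])
  )
  pt <- selconv:::prune_tree(tr)
  st <- selconv:::codon_states(aln)
  tipp <- selconv:::tip_partials(pt, st, 61)
  P <- lapply(ts, function(t) selconv:::pmat_from_eigen(eg, t))
  sl <- selconv:::site_loglik(
    pt, tipp,
    lapply(seq_len(pt$nedge), function(e) {
      selconv:::pmat_from_eigen(eg, pt$tree$edge.length[e])
    }),
    pi
  )
  for (s in 1:5) {
    expect_equal(
      sl[s],
      log(oracle_3taxon_site_lik(P$a, P$b, P$i, P$c, pi,
                                 st["a", s], st["b", s], st["c", s])),
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("gaps and ambiguities contribute all-ones partials", {
  aln <- codon_alignment(c(a = "AAATTT", b = "AAA---"), validate = FALSE)
  pi <- rep(1 / 61, 61)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(2, 0.5, pi), pi)
  tr <- ape::read.tree(text = "(a:0.1,b:0.2)r;")
  pt <- selconv:::prune_tree(tr)
  tipp <- selconv:::tip_partials(pt, selconv:::codon_states(aln), 61)
  sl <- selconv:::site_loglik(
    pt, tipp,
    lapply(pt$tree$edge.length, function(t) selconv:::pmat_from_eigen(eg, t)),
    pi
  )
  # the gapped site reduces to the single-taxon marginal
  P1 <- selconv:::pmat_from_eigen(eg, 0.1)
  i <- selconv:::codon_index("TTT")
  expect_equal(sl[2], log(sum(pi * P1[, i])), tolerance = 1e-10)
})

test_that("likelihood is invariant to leaf order and to re-rooting", {
  aln <- fixture_alignment(paste0("t", 1:6), 40, seed = 11)
  pi <- f3x4_frequencies(aln)
  tr <- fixture_tree(6, seed = 11)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(2, 0.4, pi), pi)
  ll_of <- function(tree, a) {
    pt <- selconv:::prune_tree(tree)
    tipp <- selconv:::tip_partials(pt, selconv:::codon_states(a), 61)
    selconv:::tree_loglik(pt, tipp, list(eg), rep(1L, pt$nedge),
                          pt$tree$edge.length, pi)
  }
  base <- ll_of(tr, aln)
  perm <- aln[rev(rownames(aln)), ]
  perm <- codon_alignment(perm, validate = FALSE)
  expect_equal(ll_of(tr, perm), base, tolerance = 1e-8)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "t3", resolve.root = TRUE)
  expect_equal(ll_of(rerooted, aln), base, tolerance = 1e-6)
})

test_that("edge-length optimisation is monotone and matches joint
           quasi-Newton optimisation", {
  aln <- fixture_alignment(paste0("t", 1:5), 60, seed = 12)
  pi <- f3x4_frequencies(aln)
  tr <- fixture_tree(5, seed = 12)
  eg <- selconv:::eigen_reversible(build_gy94_matrix(2, 0.4, pi), pi)
  pt <- selconv:::prune_tree(tr)
  st <- selconv:::codon_states(aln)
  cp <- selconv:::compress_patterns(st)
  tipp <- selconv:::tip_partials(pt, cp$states, 61)
  ecl <- rep(1L, pt$nedge)
  t0 <- pt$tree$edge.length
  ll0 <- selconv:::tree_loglik(pt, tipp, list(eg), ecl, t0, pi, cp$weights)
  sw <- selconv:::optimize_edge_lengths(pt, tipp, list(eg), ecl, t0, pi,
                                        weights = cp$weights, sweeps = 6)
  expect_gte(sw$loglik, ll0)
  # local optimality: joint quasi-Newton started at the sweep solution
  # cannot improve it appreciably
  ref <- optim(
    log(sw$t),
    function(lt) -selconv:::tree_loglik(pt, tipp, list(eg), ecl, exp(lt),
                                        pi, cp$weights),
    method = "L-BFGS-B", lower = log(1e-8), upper = log(5),
    control = list(maxit = 500, factr = 1e4)
  )
  expect_lte(-ref$value - sw$loglik, 1e-3)
})
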