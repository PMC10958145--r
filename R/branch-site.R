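#' Branch-site positive-selection test (model A)
#'
#' Fits the branch-site mixture model on a designated foreground branch set:
#' four site classes with proportions `p0`, `p1`, `p2a`, `p2b` where
#' `p2a = (1-p0-p1) p0/(p0+p1)` and `p2b = (1-p0-p1) p1/(p0+p1)`. Class 0
#' evolves at `omega0 < 1` everywhere, class 1 neutrally, and classes 2a/2b
#' at `omega2` on the foreground (with class-0/1 background behaviour). The
#' null fixes `omega2 = 1`; the alternative leaves `omega2 >= 1` free. The
#' likelihood-ratio test uses a chi-squared reference with one degree of
#' freedom (the conservative convention, no boundary mixture).
#'
#' Branch lengths and codon frequencies are estimated once under the
#' one-ratio model and held fixed in both mixture fits.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `tagged_phylo`.
#' @param foreground Branch ids forming the foreground, or a tag name
#'   (e.g. `"EXCHANGE"`).
#' @param exclude_catalytic Drop the catalytic column before fitting.
#' @param restarts Deterministic optimisation restarts per model.
#' @return List with `alt` and `null` (`branch_site_fit` objects) and
#'   `lrt` (tibble from [lrt()]).
#' @export
fit_branch_site_pair <- function(aln, tree, foreground = "EXCHANGE",
                                 exclude_catalytic = TRUE, restarts = 2) {
  cs <- attr(aln, "catalytic_site")
  orig_sites <- seq_len(ncol(aln)) - 1L
  if (exclude_catalytic && !is.na(cs)) {
    keep <- setdiff(seq_len(ncol(aln)), cs + 1L)
    orig_sites <- orig_sites[keep]
    aln <- subset_columns(aln, keep)
  }
  base <- fit_branch_model(aln, tree, "one-ratio",
                           exclude_catalytic = FALSE, restarts = 1)
  pi <- base$pi
  tvec <- base$tree$edge.length
  pt <- prune_tree(tree)
  post_tag <- pt$tree$tag
  fg <- if (length(foreground) == 1 &&
            foreground %in% c("SEC", "EXCHANGE", "INHERITED")) {
    which(post_tag == foreground)
  } else {
    edge_of_branch(pt$tree, foreground)
  }
  if (!length(fg)) stop("empty foreground branch set")
  states <- codon_states(aln)
  cp <- compress_patterns(states)
  tipp <- tip_partials(pt, cp$states, 61)

  # null first, then the alternative warm-started from the null over a grid
  # of omega2 values (and one cold start); this makes the null reachable
  # from every alternative start, so logL_alt >= logL_null by construction
  fit0 <- fit_branch_site_one(pt, tipp, cp, pi, tvec, fg, fix_w2 = TRUE,
                              kappa0 = base$kappa, restarts = restarts)
  alt_starts <- lapply(c(1, 6), function(dw2) {
    c(fit0$par_init, log(dw2))
  })
  fit1 <- fit_branch_site_one(pt, tipp, cp, pi, tvec, fg, fix_w2 = FALSE,
                              kappa0 = base$kappa, restarts = restarts,
                              extra_starts = alt_starts)
  fit1$sites <- orig_sites
  fit0$sites <- orig_sites
  test <- lrt(fit0, fit1)
  list(alt = fit1, null = fit0, lrt = test)
}

# per-site class log-likelihoods: classes 0, 1, 2a, 2b
branch_site_class_logliks <- function(pt, tipp, pi, tvec, fg, kappa,
                                      w0, w2) {
  egs <- lapply(c(w0, 1, w2), function(om) {
    eigen_reversible(build_gy94_matrix(kappa, om, pi), pi)
  })
  nE <- pt$nedge
  # one transition matrix per (omega value, edge); classes share them
  P <- lapply(1:3, function(i) {
    lapply(tvec, function(t) pmat_from_eigen(egs[[i]], t))
  })
  cls_map <- list(
    rep(1L, nE),                                   # class 0: w0 everywhere
    rep(2L, nE),                                   # class 1: neutral
    {m <- rep(1L, nE); m[fg] <- 3L; m},            # class 2a
    {m <- rep(2L, nE); m[fg] <- 3L; m}             # class 2b
  )
  do.call(rbind, lapply(cls_map, function(m) {
    site_loglik(pt, tipp, lapply(seq_len(nE), function(e) P[[m[e]]][[e]]), pi)
  }))
}

mix_loglik <- function(class_ll, props, weights) {
  lp <- log(pmax(props, 1e-12))
  m <- class_ll + lp
  mx <- apply(m, 2, max)
  sl <- mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
  sum(weights * sl)
}

bs_props <- function(p0, p1) {
  rest <- max(1 - p0 - p1, 0)
  c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
}

fit_branch_site_one <- function(pt, tipp, cp, pi, tvec, fg, fix_w2,
                                kappa0, restarts = 2, extra_starts = NULL) {
  w <- cp$weights
  # parameters: log kappa, a, b (softmax for p0, p1), logit w0, log(w2 - 1)
  unpack <- function(par) {
    par <- pmin(pmax(par, -30), 30)
    kappa <- exp(pmin(pmax(par[1], log(0.05)), log(50)))
    ea <- exp(par[2]); eb <- exp(par[3])
    p0 <- ea / (1 + ea + eb); p1 <- eb / (1 + ea + eb)
    w0 <- 1 / (1 + exp(-par[4]))
    w2 <- if (fix_w2) 1 else 1 + exp(min(par[5], log(99))) # omega2 <= 100
    list(kappa = kappa, p0 = p0, p1 = p1, w0 = w0, w2 = w2)
  }
  obj <- function(par) {
    q <- unpack(par)
    cl <- branch_site_class_logliks(pt, tipp, pi, tvec, fg,
                                    q$kappa, q$w0, q$w2)
    -mix_loglik(cl, bs_props(q$p0, q$p1), w)
  }
  starts <- list(
    c(log(kappa0), log(0.7 / 0.2), log(0.2 / 0.2), stats::qlogis(0.2), log(1)),
    c(log(kappa0), log(0.45 / 0.1), log(0.45 / 0.1), stats::qlogis(0.05), log(3))
  )
  if (is.null(extra_starts)) {
    starts <- starts[seq_len(min(length(starts), max(restarts, 1)))]
  } else {
    # warm starts dominate; keep at most restarts - 1 cold ones
    starts <- c(extra_starts,
                starts[seq_len(min(length(starts), max(restarts - 1, 0)))])
  }
  best <- NULL
  for (s in starts) {
    p0 <- if (fix_w2) s[1:4] else s
    op <- optim(p0, function(p) obj(if (fix_w2) c(p, 0) else p),
                method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  par <- if (fix_w2) c(best$par, 0) else best$par
  q <- unpack(par)
  cl <- branch_site_class_logliks(pt, tipp, pi, tvec, fg, q$kappa, q$w0, q$w2)
  props <- bs_props(q$p0, q$p1)
  boundary <- q$p0 + q$p1 > 1 - 1e-4
  structure(
    list(
      loglik = -best$value, kappa = q$kappa,
      p = setNames(props, c("p0", "p1", "p2a", "p2b")),
      omega0 = q$w0, omega2 = q$w2, fixed_w2 = fix_w2,
      foreground = branch_ids(pt$tree)[fg],
      class_loglik = cl, pattern_index = cp$index,
      np = (if (fix_w2) 4L else 5L) + pt$nedge,
      boundary = boundary, par_init = best$par[1:4],
      posterior_kind = "NEB"
    ),
    class = "branch_site_fit"
  )
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat("<branch_site_fit> ", if (x$fixed_w2) "null (omega2 = 1)" else "alternative",
      " logL=", format(x$loglik, digits = 10),
      " omega2=", round(x$omega2, 3), "\n", sep = "")
  if (x$boundary) cat("note: boundary convergence (p0 + p1 ~ 1)\n")
  invisible(x)
}

#' @export
glance.branch_site_fit <- function(x, ...) {
  tibble::tibble(
    model = if (x$fixed_w2) "null" else "alternative",
    logLik = x$loglik, np = x$np, kappa = x$kappa,
    p0 = x$p[["p0"]], p1 = x$p[["p1"]],
    omega0 = x$omega0, omega2 = x$omega2, boundary = x$boundary
  )
}

#' Per-site posterior probability of positive selection
#'
#' Naive empirical-Bayes posteriors of the positively selected classes
#' (2a + 2b) at the maximum-likelihood estimates of the alternative
#' branch-site fit. (PAML reports Bayes empirical Bayes posteriors, which
#' additionally integrate over parameter uncertainty; the `kind` column
#' records which was computed.)
#'
#' @param fit The alternative `branch_site_fit`.
#' @return Tibble with `site` (0-based), `posterior`, `kind`.
#' @export
site_posteriors <- function(fit) {
  lp <- log(pmax(fit$p, 1e-12))
  m <- fit$class_loglik + lp
  mx <- apply(m, 2, max)
  w <- exp(sweep(m, 2, mx, "-"))
  post_pat <- colSums(w[3:4, , drop = FALSE]) / colSums(w)
  post <- post_pat[fit$pattern_index]
  sites <- if (!is.null(fit$sites)) fit$sites else seq_along(post) - 1L
  tibble::tibble(site = sites, posterior = post, kind = fit$posterior_kind)
}

#' Flag sites in the upper percentile of selection posteriors
#'
#' @param posteriors Tibble from [site_posteriors()].
#' @param percentile Upper-percentile cutoff (default 90).
#' @param reference_sites 0-based site set over which the percentile is
#'   computed (`NULL` = all); the flag is still evaluated for every site.
#' @return Input tibble with a logical `selected` column and the threshold
#'   as attribute `threshold`.
#' @export
flag_selected_sites <- function(posteriors, percentile = 90,
                                reference_sites = NULL) {
  ref <- if (is.null(reference_sites)) posteriors else {
    posteriors[posteriors$site %in% reference_sites, ]
  }
  thr <- stats::quantile(ref$posterior, percentile / 100, type = 5,
                         names = FALSE)
  out <- posteriors
  out$selected <- out$posterior > thr
  attr(out, "threshold") <- thr
  out
}

#' Mann-Whitney enrichment test between two site sets
#'
#' Compares selection posteriors (or any per-site scores) between two
#' disjoint site sets with a Mann-Whitney U test: exact enumeration when the
#' smaller set has at most 8 sites and there are no ties, the
#' tie-corrected normal approximation otherwise.
#'
#' @param posteriors Tibble with `site` and `posterior` columns, or a named
#'   numeric vector indexed by 0-based site.
#' @param set_a,set_b Disjoint, non-empty 0-based site sets; the default
#'   alternative tests whether `set_a` scores are greater.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return Tibble with `u`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
enrichment_test <- function(posteriors, set_a, set_b,
                            alternative = "greater") {
  if (!length(set_a) || !length(set_b)) stop("site sets must be non-empty")
  if (length(intersect(set_a, set_b))) stop("site sets must be disjoint")
  score <- function(s) {
    if (is.data.frame(posteriors)) {
      v <- posteriors$posterior[match(s, posteriors$site)]
    } else {
      v <- unname(posteriors[as.character(s)])
    }
    if (anyNA(v)) stop("no score for site(s) ", paste(s[is.na(v)], collapse = ", "))
    v
  }
  a <- score(set_a); b <- score(set_b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact)
  )
  tibble::tibble(
    u = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation",
    n_a = length(a), n_b = length(b)
  )
}
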