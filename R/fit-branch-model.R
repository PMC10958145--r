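#' Fit a codon model with branch-partitioned dN/dS
#'
#' Maximum-likelihood fit of the GY94 codon model with F3x4 frequencies and a
#' single transition/transversion ratio, under one of three branch schemes:
#' `"one-ratio"` (a single dN/dS for the whole tree), `"partition"` (one
#' dN/dS per branch tag: SEC / EXCHANGE / INHERITED) or `"free-ratio"` (an
#' independent dN/dS per branch). Branch lengths are re-estimated by
#' default. Codon frequencies are fixed at their F3x4 estimates from the
#' analysed region, never re-optimised.
#'
#' Optimisation alternates Nelder-Mead moves on the log of the global
#' parameters with monotone coordinate ascent on branch lengths (Brent steps
#' against cached partial likelihoods), from `restarts` deterministic
#' perturbed starts; the best solution is returned.
#'
#' @param aln A `codon_alignment` (the analysed region).
#' @param tree A `tagged_phylo` whose tips match the alignment.
#' @param scheme `"one-ratio"`, `"partition"` or `"free-ratio"`.
#' @param exclude_catalytic Drop the catalytic-site column before fitting
#'   (default; the Sec/Cys site is the conditioning event, not data).
#' @param restarts Number of optimisation starts (>= 1).
#' @param max_rounds Maximum alternation rounds per start.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param optimize_lengths Re-estimate branch lengths (default). With
#'   `FALSE` the input tree's lengths are held fixed (e.g. to share
#'   full-gene lengths across domain-level fits).
#' @param init Optional `codon_fit` used as warm start (e.g. the nested
#'   fit of an LRT pair); when given, a single start is run from it.
#' @return A `codon_fit` object; see [tidy.codon_fit()] and
#'   [glance.codon_fit()].
#' @export
fit_branch_model <- function(aln, tree,
                             scheme = c("one-ratio", "partition", "free-ratio"),
                             exclude_catalytic = TRUE,
                             restarts = 3, max_rounds = 8, tol = 1e-6,
                             optimize_lengths = TRUE, init = NULL) {
  scheme <- match.arg(scheme)
  if (!setequal(rownames(aln), tree$tip.label)) {
    stop("alignment taxa and tree tips differ")
  }
  cs <- attr(aln, "catalytic_site")
  if (exclude_catalytic && !is.na(cs)) {
    aln <- subset_columns(aln, setdiff(seq_len(ncol(aln)), cs + 1L))
  }
  pi <- f3x4_frequencies(aln)
  states <- codon_states(aln)
  cp <- compress_patterns(states)
  pt <- prune_tree(tree)
  tipp <- tip_partials(pt, cp$states, 61)
  post_tag <- pt$tree$tag
  if (is.null(post_tag) && scheme == "partition") {
    stop("partition scheme requires branch tags; see tag_tree()")
  }

  if (scheme == "one-ratio") {
    eclass <- rep(1L, pt$nedge)
    class_names <- "all"
  } else if (scheme == "partition") {
    lev <- intersect(c("SEC", "EXCHANGE", "INHERITED"), unique(post_tag))
    eclass <- match(post_tag, lev)
    class_names <- lev
  } else {
    eclass <- seq_len(pt$nedge)
    class_names <- branch_ids(pt$tree)
  }
  n_class <- length(unique(eclass))

  t_in <- pt$tree$edge.length
  if (is.null(t_in) || any(!is.finite(t_in))) t_in <- rep(0.1, pt$nedge)
  t_in <- pmax(t_in, 1e-4)

  starts <- list(
    list(kappa = 2, omega = 0.3, tmul = 1),
    list(kappa = 4, omega = 0.1, tmul = 0.5),
    list(kappa = 1, omega = 0.8, tmul = 2)
  )
  starts <- starts[seq_len(min(max(restarts, 1), length(starts)))]
  warm <- !is.null(init)
  if (warm) {
    om0 <- rep_len(unname(init$omega), n_class)
    starts <- list(list(kappa = init$kappa, omega_vec = om0, tmul = 1))
    t_init <- init$tree$edge.length
    if (length(t_init) == pt$nedge) t_in <- pmax(t_init, 1e-6)
  }

  best <- NULL
  for (st in starts) {
    fit <- fit_codon_core(
      pt, tipp, cp$weights, pi, eclass, n_class,
      kappa0 = st$kappa,
      omega0 = if (is.null(st$omega_vec)) rep(st$omega, n_class) else st$omega_vec,
      tvec0 = if (optimize_lengths) t_in * st$tmul else t_in,
      scheme = scheme,
      max_rounds = max_rounds, tol = tol, optimize_lengths = optimize_lengths,
      warm = warm
    )
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  fitted_tree <- pt$tree
  fitted_tree$edge.length <- best$t
  structure(
    list(
      scheme = scheme, loglik = best$loglik,
      kappa = best$kappa,
      omega = setNames(best$omega, class_names),
      eclass = eclass, class_names = class_names,
      tree = fitted_tree, pi = pi,
      n_sites = ncol(aln), n_taxa = nrow(aln),
      np = 1L + n_class + pt$nedge,
      converged = best$converged, rounds = best$rounds
    ),
    class = "codon_fit"
  )
}

# Alternating optimisation core. Returns kappa, omega vector, edge lengths,
# loglik.
fit_codon_core <- function(pt, tipp, weights, pi, eclass, n_class,
                           kappa0, omega0, tvec0, scheme,
                           max_rounds, tol, optimize_lengths = TRUE,
                           warm = FALSE) {
  kappa <- kappa0; omega <- omega0; tvec <- tvec0
  eig_all <- function() {
    lapply(seq_len(n_class), function(c) {
      eigen_reversible(build_gy94_matrix(kappa, omega[c], pi), pi)
    })
  }
  ll <- function(egs) tree_loglik(pt, tipp, egs, eclass, tvec, pi, weights)
  last <- ll(eig_all())
  converged <- FALSE; r <- 0
  for (r in seq_len(max_rounds)) {
    if (scheme == "free-ratio") {
      # per-edge omega by Brent on the full likelihood (only that edge's
      # eigensystem is rebuilt per candidate), then global kappa
      egs <- eig_all()
      cur_ll <- ll(egs)
      for (e in seq_len(pt$nedge)) {
        cl <- eclass[e]
        f <- function(lo) {
          egs2 <- egs
          egs2[[cl]] <- eigen_reversible(build_gy94_matrix(kappa, exp(lo), pi), pi)
          -tree_loglik(pt, tipp, egs2, eclass, tvec, pi, weights)
        }
        op <- optimize(f, c(log(1e-4), log(20)), tol = 1e-3)
        if (-op$objective > cur_ll) {
          omega[cl] <- exp(op$minimum)
          egs[[cl]] <- eigen_reversible(build_gy94_matrix(kappa, omega[cl], pi), pi)
          cur_ll <- -op$objective
        }
      }
      fk <- function(lk) {
        -tree_loglik(pt, tipp, eig_all_cached(exp(lk), omega, pi, eclass),
                     eclass, tvec, pi, weights)
      }
      opk <- optimize(fk, c(log(0.05), log(50)), tol = 1e-4)
      if (-opk$objective > cur_ll) kappa <- exp(opk$minimum)
    } else {
      par <- c(log(kappa), log(omega))
      obj <- function(p) {
        p <- pmin(pmax(p, log(1e-6)), log(50))
        k <- exp(p[1]); om <- exp(p[-1])
        egs <- lapply(seq_len(n_class), function(c) {
          eigen_reversible(build_gy94_matrix(k, om[c], pi), pi)
        })
        -tree_loglik(pt, tipp, egs, eclass, tvec, pi, weights)
      }
      op <- optim(par, obj, method = "Nelder-Mead",
                  control = list(maxit = if (r == 1 && !warm) 200 else 80,
                                 reltol = 1e-9))
      if (-op$value >= last - 1e-9) {
        par <- pmin(pmax(op$par, log(1e-6)), log(50))
        kappa <- exp(par[1]); omega <- exp(par[-1])
      }
    }
    if (optimize_lengths) {
      egs <- eig_all()
      sw <- optimize_edge_lengths(pt, tipp, egs, eclass, tvec, pi,
                                  weights = weights, sweeps = 2, tol = tol)
      tvec <- sw$t
      cur <- sw$loglik
    } else {
      cur <- ll(eig_all())
    }
    if (abs(cur - last) < tol) { last <- cur; converged <- TRUE; break }
    last <- cur
  }
  list(kappa = kappa, omega = omega, t = tvec, loglik = last,
       converged = converged, rounds = r)
}

# eigen systems for the distinct omega values actually used (free-ratio
# shares identical omegas across edges only by value)
eig_all_cached <- function(kappa, omega, pi, eclass) {
  lapply(seq_along(omega), function(c) {
    eigen_reversible(build_gy94_matrix(kappa, omega[c], pi), pi)
  })
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> scheme=", x$scheme, " logL=", format(x$loglik, digits = 10),
      " kappa=", round(x$kappa, 3), "\n", sep = "")
  if (length(x$omega) <= 6) {
    cat("omega:", paste0(names(x$omega), "=", round(x$omega, 4),
                         collapse = " "), "\n")
  } else {
    cat("omega: free-ratio over", length(x$omega), "branches\n")
  }
  invisible(x)
}

#' Per-branch parameter table for a codon fit
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble with one row per branch: `branch`, `tag`, `class`, `t`
#'   (substitutions per codon), `omega`, `dN`, `dS`.
#' @export
tidy.codon_fit <- function(x, ...) {
  tr <- x$tree
  tag <- if (!is.null(tr$tag)) tr$tag else rep(NA_character_, nrow(tr$edge))
  purrr::map_dfr(seq_len(nrow(tr$edge)), function(e) {
    om <- x$omega[[x$eclass[e]]]
    dd <- branch_dnds(tr$edge.length[e], x$kappa, om, x$pi)
    tibble::tibble(
      branch = branch_ids(tr)[e], tag = tag[e],
      class = x$class_names[x$eclass[e]],
      t = tr$edge.length[e], omega = om, dN = dd$dN, dS = dd$dS
    )
  })
}

#' One-row summary of a codon fit
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble with `scheme`, `logLik`, `np`, `kappa`, `n_sites`,
#'   `n_taxa`, `converged`.
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, logLik = x$loglik, np = x$np, kappa = x$kappa,
    n_sites = x$n_sites, n_taxa = x$n_taxa, converged = x$converged
  )
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$loglik, df = object$np, class = "logLik")
}

#' Likelihood-ratio test between nested codon fits
#'
#' The statistic is `LR = 2 (logL_alt - logL_null)`, clipped at zero, with a
#' chi-squared reference whose degrees of freedom equal the difference in
#' free-parameter counts (df = 2 for the three-ratio partition model against
#' the one-ratio null).
#'
#' @param null_fit,alt_fit Nested `codon_fit` (or `branch_site_fit`)
#'   objects, the null inside the alternative.
#' @return Tibble with `lr`, `df`, `p_value`, and the two log-likelihoods.
#' @export
lrt <- function(null_fit, alt_fit) {
  l0 <- null_fit$loglik; l1 <- alt_fit$loglik
  df <- alt_fit$np - null_fit$np
  if (df < 0) stop("null model must be nested in the alternative")
  if (l1 < l0 - 1e-3) {
    warning(
      "alternative log-likelihood below null (", format(l1 - l0, digits = 4),
      "); refit with more restarts"
    )
  }
  lr <- max(2 * (l1 - l0), 0)
  p <- if (df == 0) as.numeric(lr <= 0) else pchisq(lr, df, lower.tail = FALSE)
  tibble::tibble(
    lr = lr, df = df, p_value = p, logLik_null = l0, logLik_alt = l1
  )
}
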