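# Felsenstein pruning machinery, dimension-agnostic (61 codon states or 20
# amino-acid states). Trees are ape phylo objects reordered to postorder;
# tip data are integer state matrices (taxa x sites) with NA for gaps and
# ambiguities (all-ones partial likelihood). Per-site scaling guards against
# underflow.

# postorder copy with edge bookkeeping; per-edge attributes (tags) are
# permuted together with the edge matrix
prune_tree <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  if (!is.null(tree$tag)) {
    tr$tag <- tree$tag[match(tr$edge[, 2], tree$edge[, 2])]
  }
  list(
    tree = tr,
    nedge = nrow(tr$edge),
    ntip = length(tr$tip.label),
    root = length(tr$tip.label) + 1L,
    kids = split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  )
}

tip_partials <- function(pt, states, k) {
  n <- pt$ntip + pt$tree$Nnode
  nsites <- ncol(states)
  part <- vector("list", n)
  ord <- match(pt$tree$tip.label, rownames(states))
  if (anyNA(ord)) stop("tip labels missing from state matrix")
  for (i in seq_len(pt$ntip)) {
    m <- matrix(0, k, nsites)
    s <- states[ord[i], ]
    obs <- !is.na(s)
    m[cbind(s[obs], which(obs))] <- 1
    m[, !obs] <- 1
    part[[i]] <- m
  }
  part
}

# Per-site log-likelihood given per-edge transition matrices.
# P_list: list over postorder edges of k x k matrices.
site_loglik <- function(pt, part, P_list, pi) {
  tr <- pt$tree
  nsites <- ncol(part[[1]])
  scaler <- numeric(nsites)
  for (e in seq_len(pt$nedge)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    contrib <- P_list[[e]] %*% part[[ch]]
    part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
    if (e == max(pt$kids[[as.character(p)]])) {
      mx <- colSums(part[[p]])
      mx[mx <= 0] <- 1
      part[[p]] <- part[[p]] / rep(mx, each = nrow(part[[p]]))
      scaler <- scaler + log(mx)
    }
  }
  lik <- colSums(pi * part[[pt$root]])
  log(pmax(lik, 1e-300)) + scaler
}

# Full log-likelihood under per-edge eigensystems.
# egs: list of eigensystems; eclass: integer per edge into egs; tvec: lengths.
tree_loglik <- function(pt, part, egs, eclass, tvec, pi, weights = NULL) {
  P_list <- lapply(seq_len(pt$nedge), function(e) {
    pmat_from_eigen(egs[[eclass[e]]], tvec[e])
  })
  sl <- site_loglik(pt, part, P_list, pi)
  if (is.null(weights)) sum(sl) else sum(weights * sl)
}

# Inside (upward) partials at every node, with per-node scaling factors kept
# per site; used by ASR and by the expected-convergence computation.
inside_partials <- function(pt, part, P_list) {
  tr <- pt$tree
  nsites <- ncol(part[[1]])
  n <- pt$ntip + tr$Nnode
  scaler <- matrix(0, n, nsites)
  for (e in seq_len(pt$nedge)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    contrib <- P_list[[e]] %*% part[[ch]]
    part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
    scaler[p, ] <- scaler[p, ] + scaler[ch, ]
    if (e == max(pt$kids[[as.character(p)]])) {
      mx <- colSums(part[[p]]); mx[mx <= 0] <- 1
      part[[p]] <- part[[p]] / rep(mx, each = nrow(part[[p]]))
      scaler[p, ] <- scaler[p, ] + log(mx)
    }
  }
  list(ins = part, scaler = scaler)
}

# Outside (downward) partials at every node: the likelihood of all data
# outside the node's subtree, as a function of the node's state, with the
# root prior folded in. Scaled per site; scale factors are irrelevant for
# the posteriors these feed.
outside_partials <- function(pt, ins, P_list, pi) {
  tr <- pt$tree
  nsites <- ncol(ins[[1]])
  k <- nrow(ins[[1]])
  n <- pt$ntip + tr$Nnode
  out <- vector("list", n)
  out[[pt$root]] <- matrix(pi, k, nsites)
  contrib <- lapply(seq_len(pt$nedge), function(e) {
    P_list[[e]] %*% ins[[tr$edge[e, 2]]]
  })
  for (e in rev(seq_len(pt$nedge))) { # pre-order
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    O <- out[[p]]
    for (s in setdiff(pt$kids[[as.character(p)]], e)) O <- O * contrib[[s]]
    O <- crossprod(P_list[[e]], O)
    mx <- colSums(O); mx[mx <= 0] <- 1
    out[[ch]] <- O / rep(mx, each = nrow(O))
  }
  out
}

# Coordinate-ascent optimisation of branch lengths: depth-first walk that
# Brent-optimises each edge against cached inside/outside partials, then
# refreshes the partials on the way back up (Gauss-Seidel, monotone in the
# joint likelihood). egs/eclass as in tree_loglik.
optimize_edge_lengths <- function(pt, tipp, egs, eclass, tvec, pi,
                                  weights = NULL, sweeps = 4,
                                  t_max = 20, tol = 1e-6) {
  tr <- pt$tree
  nsites <- ncol(tipp[[1]])
  k <- nrow(tipp[[1]])
  w <- if (is.null(weights)) rep(1, nsites) else weights
  kids <- pt$kids
  n <- pt$ntip + tr$Nnode
  lo <- log(1e-8); hi <- log(t_max)

  ll_now <- function() tree_loglik(pt, tipp, egs, eclass, tvec, pi, weights)
  last <- ll_now()
  for (sw in seq_len(sweeps)) {
    ins <- tipp
    contrib <- vector("list", pt$nedge)
    for (e in seq_len(pt$nedge)) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      contrib[[e]] <- pmat_from_eigen(egs[[eclass[e]]], tvec[e]) %*% ins[[ch]]
      ins[[p]] <- if (is.null(ins[[p]])) contrib[[e]] else ins[[p]] * contrib[[e]]
    }
    for (nd in seq.int(pt$ntip + 1L, n)) { # rescale internal partials
      mx <- colSums(ins[[nd]]); mx[mx <= 0] <- 1
      ins[[nd]] <- ins[[nd]] / rep(mx, each = k)
    }
    visit <- function(node, node_out) {
      for (e in kids[[as.character(node)]]) {
        ch <- tr$edge[e, 2]
        O <- node_out
        for (s in setdiff(kids[[as.character(node)]], e)) O <- O * contrib[[s]]
        mx <- colSums(O); mx[mx <= 0] <- 1
        O <- O / rep(mx, each = k)
        inc <- ins[[ch]]
        eg <- egs[[eclass[e]]]
        # spectral form of the edge profile: sum_x O_x (P(t) inc)_x
        #   = sum_k e^{d_k t} (V' O)_k (Vi inc)_k per site
        C <- crossprod(eg$V, O) * (eg$Vi %*% inc)
        f <- function(lt) {
          -sum(w * log(pmax(colSums(exp(eg$d * exp(lt)) * C), 1e-300)))
        }
        op <- optimize(f, c(lo, hi), tol = 1e-4)
        if (op$objective < f(log(tvec[e]))) tvec[e] <<- exp(op$minimum)
        P <- pmat_from_eigen(eg, tvec[e])
        contrib[[e]] <<- P %*% inc
        if (ch > pt$ntip) {
          visit(ch, crossprod(P, O))
          m <- NULL
          for (s in kids[[as.character(ch)]]) {
            m <- if (is.null(m)) contrib[[s]] else m * contrib[[s]]
          }
          mx <- colSums(m); mx[mx <= 0] <- 1
          ins[[ch]] <<- m / rep(mx, each = k)
          contrib[[e]] <<- pmat_from_eigen(eg, tvec[e]) %*% ins[[ch]]
        }
      }
    }
    visit(pt$root, matrix(pi, k, nsites))
    cur <- ll_now()
    if (cur - last < tol) { last <- cur; break }
    last <- cur
  }
  list(t = tvec, loglik = last)
}

# collapse identical site columns into patterns with weights
compress_patterns <- function(states) {
  key <- apply(states, 2, paste0, collapse = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(
    states = states[, first, drop = FALSE],
    weights = as.numeric(tabulate(idx, nbins = sum(first))),
    index = idx
  )
}
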