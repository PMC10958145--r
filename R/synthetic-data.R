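#' Scenario configuration for synthetic codon datasets
#'
#' Describes a simulated dataset with the statistical structure the analysis
#' assumes: a tagged tree, tag-specific dN/dS, a domain partition, a
#' catalytic (Sec/Cys) column, and optionally a burst of substitutions on a
#' focal Sec-loss branch of which a chosen number are forced to be
#' convergent across all Sec-loss branches.
#'
#' @param tree A `tagged_phylo` with branch lengths in expected
#'   substitutions per codon.
#' @param omega Named vector of dN/dS per tag, e.g.
#'   `c(SEC = 0.217, EXCHANGE = 0.370, INHERITED = 0.279)`.
#' @param kappa Transition/transversion ratio.
#' @param domain_lengths Named integer vector of amino-acid lengths; their
#'   sum is the total protein length (catalytic column included).
#' @param catalytic_site 0-based amino-acid coordinate of the Sec/Cys site.
#' @param n_focal_changes Target number of amino-acid changes on the focal
#'   branch (0 = leave as simulated).
#' @param n_convergent Number of sites forced to converge across all
#'   EXCHANGE branches (must be `<= n_focal_changes` when both are set).
#' @param focal_branch Branch id of the focal EXCHANGE branch.
#' @param pos_freq 3x4 matrix of nucleotide frequencies per codon position
#'   (columns in T, C, A, G order) defining the F3x4 root/stationary
#'   distribution.
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(tree, omega, kappa = 2.5,
                            domain_lengths = c("N-terminus" = 39L,
                                               "GPX" = 113L,
                                               "C-terminus" = 65L),
                            catalytic_site = 73L,
                            n_focal_changes = 0L, n_convergent = 0L,
                            focal_branch = NULL,
                            pos_freq = default_pos_freq(),
                            seed = 1L) {
  if (n_convergent > 0 && n_focal_changes > 0 &&
      n_convergent > n_focal_changes) {
    stop("injected convergent sites cannot exceed focal changes")
  }
  L <- sum(domain_lengths)
  if (catalytic_site < 0 || catalytic_site >= L) {
    stop("catalytic site outside the protein")
  }
  structure(
    list(tree = tree, omega = omega, kappa = kappa,
         domain_lengths = domain_lengths, catalytic_site = as.integer(catalytic_site),
         n_focal_changes = as.integer(n_focal_changes),
         n_convergent = as.integer(n_convergent),
         focal_branch = focal_branch, pos_freq = pos_freq,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Slightly AT/GC-skewed position-specific nucleotide frequencies typical of
#' mammalian coding sequence (rows = codon positions; columns T, C, A, G).
#' @return 3x4 numeric matrix.
#' @export
default_pos_freq <- function() {
  rbind(
    c(0.22, 0.24, 0.26, 0.28),
    c(0.28, 0.24, 0.28, 0.20),
    c(0.22, 0.28, 0.22, 0.28)
  )
}

#' The 22-mammal GPX6-like preset
#'
#' A packaged scenario emulating the mammalian GPX6 study design: 22 taxa on
#' a mammal-like topology, five independent Sec-loss (EXCHANGE) branches --
#' the stem of a four-species Eumuroida-like rodent clade (the focal
#' branch), rabbit, guinea pig, a New-World-monkey pair, and a bat -- nine
#' Cys-bearing species in total, tag-specific dN/dS of 0.217 (SEC), 0.370
#' (EXCHANGE) and 0.279 (INHERITED), domains of 39/113/65 amino acids with
#' the catalytic site inside the central GPX domain, and a burst of 25
#' changes on the focal branch of which 14 are convergent across the
#' Sec-loss branches. Taxon names are generic common names; all sequence
#' content is synthetic.
#'
#' @param seed Integer seed stored in the config.
#' @return A `scenario_config`.
#' @export
gpx6_scenario <- function(seed = 1L) {
  scenario_config(
    tree = gpx6_tree(),
    omega = c(SEC = 0.217, EXCHANGE = 0.370, INHERITED = 0.279),
    kappa = 2.5,
    n_focal_changes = 25L, n_convergent = 14L,
    focal_branch = "EUM",
    seed = seed
  )
}

#' @rdname gpx6_scenario
#' @export
gpx6_tree <- function() {
  EUM <- "((mouse:0.08,rat:0.08)MR:0.05,(gerbil:0.09,hamster:0.09)GH:0.05)EUM:0.06"
  MUR <- paste0("(jerboa:0.12,", EUM, ")MUR:0.04")
  SCI <- "(squirrel:0.10,guinea_pig:0.14)SCI:0.03"
  ROD <- paste0("(", SCI, ",", MUR, ")ROD:0.03")
  LAG <- "(rabbit:0.12,pika:0.12)LAG:0.04"
  GLI <- paste0("(", LAG, ",", ROD, ")GLI:0.03")
  HC <- "(human:0.03,chimp:0.03)HC:0.02"
  CAT1 <- paste0("(", HC, ",macaque:0.05)CAT1:0.03")
  ANTH <- "(marmoset:0.06,squirrel_monkey:0.06)ANTH:0.05"
  SIM <- paste0("(", CAT1, ",", ANTH, ")SIM:0.04")
  EUA <- paste0("(treeshrew:0.12,", SIM, ")EUA:0.02")
  EGL <- paste0("(", GLI, ",", EUA, ")EGL:0.03")
  CP <- "(cow:0.08,pig:0.08)CP:0.03"
  CD <- "(cat:0.06,dog:0.06)CD:0.03"
  HCD <- paste0("(horse:0.08,", CD, ")HCD:0.02")
  UNG <- paste0("(", CP, ",", HCD, ")UNG:0.02")
  LAU <- paste0("(megabat:0.12,", UNG, ")LAU:0.03")
  BOR <- paste0("(", EGL, ",", LAU, ")BOR:0.02")
  nwk <- paste0("(elephant:0.15,", BOR, ")ROOT;")
  tree <- ape::read.tree(text = nwk)
  tags <- c(
    EUM = "EXCHANGE", rabbit = "EXCHANGE", guinea_pig = "EXCHANGE",
    ANTH = "EXCHANGE", megabat = "EXCHANGE",
    mouse = "INHERITED", rat = "INHERITED", gerbil = "INHERITED",
    hamster = "INHERITED", MR = "INHERITED", GH = "INHERITED",
    marmoset = "INHERITED", squirrel_monkey = "INHERITED"
  )
  tag_tree(tree, tags)
}

#' Simulate a codon dataset with ground truth
#'
#' Evolves codon states down the tagged tree under the GY94 model with the
#' tag-specific dN/dS of the scenario (stop codons cannot arise: the state
#' space is the 61 sense codons), synthesises the catalytic column (TGA for
#' Sec lineages, TGT/TGC below EXCHANGE branches), then applies the
#' scenario's convergence injection and focal-branch change top-up, if any.
#' True ancestral sequences and true substitution events are returned.
#'
#' @param cfg A [scenario_config()].
#' @return List with `alignment` (`codon_alignment`), `tree`
#'   (`tagged_phylo`) and `truth` (list: `node_codons`, `events`,
#'   `convergent_sites`, `focal_sites`, `omega`).
#' @export
simulate_codon_dataset <- function(cfg) {
  tree <- label_nodes(cfg$tree)
  pt <- prune_tree(tree)
  tr <- pt$tree
  pi <- f3x4_from_positions(cfg$pos_freq)
  tags <- tr$tag
  lev <- unique(tags)
  egs <- lapply(lev, function(tg) {
    eigen_reversible(build_gy94_matrix(cfg$kappa, cfg$omega[[tg]], pi), pi)
  })
  eclass <- match(tags, lev)
  L <- sum(cfg$domain_lengths)
  cs <- cfg$catalytic_site
  sim_sites <- setdiff(seq_len(L) - 1L, cs) # original 0-based coords
  nsim <- length(sim_sites)
  n <- pt$ntip + tr$Nnode
  labs <- c(tr$tip.label, tr$node.label)

  ds <- with_seed(cfg$seed, {
    P_list <- lapply(seq_len(pt$nedge), function(e) {
      P <- pmat_from_eigen(egs[[eclass[e]]], tr$edge.length[e])
      P / rowSums(P)
    })
    st <- matrix(NA_integer_, n, nsim)
    st[pt$root, ] <- sample.int(61, nsim, replace = TRUE, prob = pi)
    for (e in rev(seq_len(pt$nedge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      st[ch, ] <- sample_children(st[p, ], P_list[[e]])
    }
    # catalytic column: Sec (TGA) ancestrally, Cys below EXCHANGE branches
    cat_codon <- rep("TGA", n)
    for (e in rev(seq_len(pt$nedge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (tags[e] == "EXCHANGE") {
        cat_codon[ch] <- sample(c("TGT", "TGC"), 1)
      } else {
        cat_codon[ch] <- cat_codon[p]
      }
    }
    ds <- list(states = st, cat_codon = cat_codon, P_list = P_list)
    # convergence injection and focal top-up inside the same seed scope
    injected <- integer(0)
    if (cfg$n_convergent > 0) {
      ex_edges <- which(tags == "EXCHANGE")
      inj <- inject_convergence_states(
        ds$states, pt, ds$P_list, ex_edges, cfg$n_convergent
      )
      ds$states <- inj$states
      injected <- sim_sites[inj$sites]
      ds$multi_step <- inj$multi_step
    }
    focal_added <- integer(0)
    if (cfg$n_focal_changes > 0) {
      if (is.null(cfg$focal_branch)) stop("focal_branch required")
      fe <- edge_of_branch(tr, cfg$focal_branch)
      top <- topup_focal_changes(ds$states, pt, ds$P_list, fe,
                                 cfg$n_focal_changes,
                                 protect = match(injected, sim_sites))
      ds$states <- top$states
      focal_added <- sim_sites[top$sites]
    }
    ds$injected <- injected
    ds$focal_added <- focal_added
    ds
  })

  # assemble alignment with catalytic column inserted
  ct <- codon_table()
  full <- matrix("", n, L)
  full[, sim_sites + 1L] <- ct$codons[ds$states]
  full[, cs + 1L] <- ds$cat_codon
  rownames(full) <- labs
  dom <- domain_tibble(cfg$domain_lengths)
  aln <- codon_alignment(full[seq_len(pt$ntip), , drop = FALSE],
                         catalytic_site = cs, domains = dom)
  events <- true_events(pt, ds$states, sim_sites)
  truth <- list(
    node_codons = full[seq.int(pt$ntip + 1L, n), , drop = FALSE],
    events = events,
    convergent_sites = sort(ds$injected),
    focal_sites = sort(unique(c(ds$injected, ds$focal_added))),
    omega = setNames(cfg$omega[tags], branch_ids(tr))
  )
  list(alignment = aln, tree = tr, truth = truth)
}

domain_tibble <- function(domain_lengths) {
  ends <- cumsum(domain_lengths)
  tibble::tibble(
    name = names(domain_lengths),
    start = as.integer(ends - domain_lengths),
    end = as.integer(ends)
  )
}

sample_children <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

# true protein-level substitution events from true codon states
true_events <- function(pt, states, sim_sites) {
  ct <- codon_table()
  tr <- pt$tree
  ids <- branch_ids(tr)
  purrr::map_dfr(seq_len(pt$nedge), function(e) {
    fa <- ct$aa[states[tr$edge[e, 1], ]]
    ta <- ct$aa[states[tr$edge[e, 2], ]]
    hit <- which(fa != ta)
    tibble::tibble(branch = ids[e], site = sim_sites[hit],
                   from = fa[hit], to = ta[hit])
  })
}

# Force `n_sites` sites to the same derived amino acid on all `edges`,
# re-evolving each modified subtree so descendants stay coherent.
# Operates on simulation-column indices; returns updated states + chosen
# columns. Assumes an RNG scope is already established by the caller.
inject_convergence_states <- function(states, pt, P_list, edges, n_sites) {
  ct <- codon_table()
  tr <- pt$tree
  nsim <- ncol(states)
  chosen <- integer(0)
  multi_step <- list()
  candidates <- sample.int(nsim) # random visiting order
  nb <- codon_neighbors()
  for (sc in candidates) {
    if (length(chosen) >= n_sites) break
    par_states <- states[tr$edge[edges, 1], sc]
    par_aa <- ct$aa[par_states]
    onestep <- lapply(par_states, function(s) {
      unique(ct$aa[nb[[s]]][ct$aa[nb[[s]]] != ct$aa[s]])
    })
    target_pool <- Reduce(intersect, onestep)
    target_pool <- setdiff(target_pool, par_aa)
    multi <- character(0)
    if (!length(target_pool)) {
      all_aa <- setdiff(unique(unlist(onestep)), par_aa)
      if (!length(all_aa)) next
      target <- sample(all_aa, 1)
      multi <- branch_ids(tr)[edges][vapply(onestep, function(x) !(target %in% x),
                                            logical(1))]
    } else {
      target <- sample(target_pool, 1)
    }
    for (i in seq_along(edges)) {
      e <- edges[i]
      s <- par_states[i]
      cand <- nb[[s]][ct$aa[nb[[s]]] == target]
      new_codon <- if (length(cand)) resample(cand, 1) else {
        resample(which(ct$aa == target), 1)
      }
      states <- set_and_reevolve(states, pt, P_list, e, sc, new_codon)
    }
    chosen <- c(chosen, sc)
    if (length(multi)) multi_step[[as.character(sc)]] <- multi
  }
  if (length(chosen) < n_sites) {
    warning("could only inject ", length(chosen), " of ", n_sites, " sites")
  }
  list(states = states, sites = chosen, multi_step = multi_step)
}

# adjust substitutions on one focal edge until it carries exactly n_total
# amino-acid changes: add forced changes at unchanged sites, or revert
# surplus (unprotected) changes by copying the parent state down
topup_focal_changes <- function(states, pt, P_list, fe, n_total,
                                protect = integer(0)) {
  ct <- codon_table()
  tr <- pt$tree
  nb <- codon_neighbors()
  p <- tr$edge[fe, 1]; ch <- tr$edge[fe, 2]
  added <- integer(0)
  changed <- function() which(ct$aa[states[p, ]] != ct$aa[states[ch, ]])
  current <- length(changed())
  if (current > n_total) {
    surplus <- sample(setdiff(changed(), protect))
    for (sc in surplus) {
      if (current <= n_total) break
      states <- set_and_reevolve(states, pt, P_list, fe, sc, states[p, sc])
      current <- current - 1
    }
  }
  pool <- sample(which(ct$aa[states[p, ]] == ct$aa[states[ch, ]]))
  for (sc in pool) {
    if (current >= n_total) break
    s <- states[p, sc]
    cand <- nb[[s]][ct$aa[nb[[s]]] != ct$aa[s]]
    if (!length(cand)) next
    states <- set_and_reevolve(states, pt, P_list, fe, sc, resample(cand, 1))
    added <- c(added, sc)
    current <- current + 1
  }
  list(states = states, sites = added)
}

# set the child state of edge e at column sc and re-simulate the subtree
set_and_reevolve <- function(states, pt, P_list, e, sc, new_state) {
  tr <- pt$tree
  states[tr$edge[e, 2], sc] <- new_state
  below <- subtree_edges(pt, tr$edge[e, 2])
  for (e2 in below) { # pre-order within the subtree
    p <- tr$edge[e2, 1]; ch <- tr$edge[e2, 2]
    states[ch, sc] <- sample.int(ncol(P_list[[e2]]), 1,
                                 prob = P_list[[e2]][states[p, sc], ])
  }
  states
}

# edges below a node, parents before children
subtree_edges <- function(pt, node) {
  tr <- pt$tree
  out <- integer(0)
  stack <- which(tr$edge[, 1] == node)
  while (length(stack)) {
    e <- stack[1]; stack <- stack[-1]
    out <- c(out, e)
    stack <- c(stack, which(tr$edge[, 1] == tr$edge[e, 2]))
  }
  out
}

resample <- function(x, n) x[sample.int(length(x), n)]

# single-nucleotide sense-codon neighbours, cached
codon_neighbors <- function() {
  if (!is.null(.selconv$nb)) return(.selconv$nb)
  ct <- codon_table()
  nb <- split(ct$pairs$j, factor(ct$pairs$i, levels = seq_len(ct$n)))
  .selconv$nb <- unname(lapply(nb, as.integer))
  .selconv$nb
}
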