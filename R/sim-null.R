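#' Configuration for protein-evolution simulation
#'
#' The null model of the convergence analysis: sequences evolve along the
#' fixed tree under an empirical replacement model, with branch lengths set
#' to the per-branch amino-acid substitution rate (the dN values of a
#' free-ratio codon fit), starting from the inferred ancestral sequence (or
#' a stationary draw). Any convergence produced this way is chance
#' convergence under the rate pattern of the data.
#'
#' @param tree Rooted `phylo` whose edge lengths are replacements per site
#'   (e.g. dN); zero lengths are floored at 1e-8.
#' @param model An `amino_acid_model` (default [jtt_model()]).
#' @param root_seq Character vector of amino acids for the root, or `NULL`
#'   to draw each site from the stationary frequencies.
#' @param n_sites Number of sites when `root_seq` is `NULL`.
#' @param n_rep Number of replicates (>= 1; the full-scale analysis uses
#'   1000).
#' @param seed Integer seed; every replicate is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(tree, model = jtt_model(), root_seq = NULL,
                              n_sites = NULL, n_rep = 1000, seed = 1L) {
  if (n_rep < 1) stop("replicate count must be >= 1")
  if (is.null(root_seq) && is.null(n_sites)) {
    stop("give either root_seq or n_sites")
  }
  tree <- label_nodes(tree)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  structure(
    list(tree = tree, model = model, root_seq = root_seq,
         n_sites = if (is.null(root_seq)) n_sites else length(root_seq),
         n_rep = n_rep, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# run code with a local RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate protein evolution along a tree
#'
#' States are drawn at the root and propagated down each branch by sampling
#' from the replacement model's transition matrices. True internal states
#' are returned with every replicate so reconstruction error can be
#' quantified against the truth.
#'
#' @param cfg A [simulation_config()].
#' @return List of replicates; each has `tips` (a `protein_alignment`) and
#'   `nodes` (character matrix of true internal states).
#' @export
simulate_protein_evolution <- function(cfg) {
  pt <- prune_tree(cfg$tree)
  tr <- pt$tree
  k <- 20
  P_list <- lapply(tr$edge.length, function(t) {
    P <- pmat_from_eigen(cfg$model$eig, t)
    P / rowSums(P)
  })
  root_states <- if (!is.null(cfg$root_seq)) {
    match(cfg$root_seq, AA20)
  } else NULL
  nsites <- cfg$n_sites
  labs <- c(tr$tip.label, tr$node.label)
  n <- pt$ntip + tr$Nnode
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_rep), function(rep) {
      st <- matrix(NA_integer_, n, nsites)
      st[pt$root, ] <- if (is.null(root_states)) {
        sample.int(k, nsites, replace = TRUE, prob = cfg$model$pi)
      } else root_states
      for (e in rev(seq_len(pt$nedge))) { # pre-order
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        par <- st[p, ]
        out <- integer(nsites)
        for (s in unique(par)) {
          idx <- which(par == s)
          out[idx] <- sample.int(k, length(idx), replace = TRUE,
                                 prob = P_list[[e]][s, ])
        }
        st[ch, ] <- out
      }
      tips <- matrix(AA20[st[seq_len(pt$ntip), ]], pt$ntip,
                     dimnames = list(tr$tip.label, NULL))
      nodes <- matrix(AA20[st[seq.int(pt$ntip + 1L, n), ]], tr$Nnode,
                      dimnames = list(tr$node.label, NULL))
      list(
        tips = structure(tips, class = c("protein_alignment", "matrix", "array"),
                         catalytic_site = NA_integer_),
        nodes = nodes
      )
    })
  })
}

#' Simulation null distribution of convergence counts
#'
#' Re-runs the full observed-data procedure -- ancestral reconstruction with
#' the same settings, substitution extraction on the same branch set and
#' pairwise convergence classification over the same pairs -- on every
#' simulated replicate, and compares the observed convergent-site count with
#' the resulting null distribution. The empirical p-value is
#' `(1 + #{replicates >= observed}) / (R + 1)`.
#'
#' @param cfg A [simulation_config()].
#' @param branches Branch ids scanned for substitutions (the Sec-loss
#'   branches in the motivating analysis).
#' @param pairs Branch pairs passed to [detect_pairwise_convergence()]
#'   (`NULL` = all pairs of `branches`).
#' @param observed Observed convergent-site count (union over pairs), e.g.
#'   `length(convergent_sites(scan))`.
#' @param optimize_lengths Refit branch lengths in each replicate's
#'   reconstruction (the observed-data pipeline does; keeping it in the null
#'   keeps reconstruction error in the null).
#' @return A `null_distribution`: tibble of per-replicate counts with the
#'   observed count and empirical p as attributes; see
#'   [autoplot.null_distribution()].
#' @export
convergence_null_test <- function(cfg, branches, pairs = NULL, observed,
                                  optimize_lengths = TRUE) {
  reps <- simulate_protein_evolution(cfg)
  fail <- 0
  counts <- purrr::map_dfr(seq_along(reps), function(i) {
    res <- tryCatch({
      rec <- marginal_asr(reps[[i]]$tips, cfg$tree, model = cfg$model,
                          optimize_lengths = optimize_lengths)
      ev <- extract_substitutions(rec, branches)
      scan <- detect_pairwise_convergence(ev, pairs = pairs)
      tibble::tibble(
        rep = i,
        n_convergent_sites = length(convergent_sites(scan)),
        n_pair_events = sum(scan$pairs$n_parallel + scan$pairs$n_convergent)
      )
    }, error = function(e) NULL)
    if (is.null(res)) fail <<- fail + 1
    res
  })
  if (fail > 0.05 * length(reps)) {
    stop(fail, " of ", length(reps), " replicates failed (> 5%)")
  }
  r <- nrow(counts)
  p <- (1 + sum(counts$n_convergent_sites >= observed)) / (r + 1)
  structure(counts,
    observed = observed, empirical_p = p, n_rep = r, dropped = fail,
    class = c("null_distribution", class(counts))
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> R=", attr(x, "n_rep"),
      " observed=", attr(x, "observed"),
      " empirical p=", format(attr(x, "empirical_p"), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Empirical p-value of a null distribution
#' @param x A `null_distribution`.
#' @return Numeric p-value in `[1/(R+1), 1]`.
#' @export
empirical_p <- function(x) attr(x, "empirical_p")
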