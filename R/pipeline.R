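#' Default pipeline configuration
#'
#' @param threshold Column-masking confidence threshold.
#' @param regions Regions analysed with branch-model LRTs (`"full"` plus
#'   domain names found in the data).
#' @param n_rep Simulation-null replicate count (the full-scale analysis
#'   uses 1000).
#' @param percentile Upper-percentile cutoff for selection flags.
#' @param branch_site_region Region on which the branch-site test is run.
#' @param share_lengths Reuse the full-length branch lengths for
#'   domain-level fits instead of re-estimating them per domain.
#' @param restarts Optimisation restarts for codon fits.
#' @param focal_branch Branch id for the focal-branch report (`NULL` =
#'   the EXCHANGE branch carrying most substitution events).
#' @param max_rounds,tol Optimisation budget per codon fit.
#' @param null_optimize_lengths Refit branch lengths in each null
#'   replicate's reconstruction. The default keeps them fixed at the dN
#'   lengths the replicate was simulated under; reconstruction itself (and
#'   hence its error) is always part of the null.
#' @param seed Master seed; each stochastic stage derives its own seed from
#'   it.
#' @return Named list of settings.
#' @export
pipeline_config <- function(threshold = 0.95, regions = NULL, n_rep = 1000,
                            percentile = 90, branch_site_region = "GPX",
                            share_lengths = FALSE, restarts = 2,
                            focal_branch = NULL, max_rounds = 8,
                            tol = 1e-6, null_optimize_lengths = FALSE,
                            seed = 1L) {
  list(
    threshold = threshold, regions = regions, n_rep = n_rep,
    percentile = percentile, branch_site_region = branch_site_region,
    share_lengths = share_lengths, restarts = restarts,
    focal_branch = focal_branch, max_rounds = max_rounds, tol = tol,
    null_optimize_lengths = null_optimize_lengths, seed = as.integer(seed)
  )
}

#' Run the full convergence-analysis pipeline
#'
#' Orchestrates the complete analysis on one dataset: optional column
#' masking; one-ratio vs. tag-partition branch-model LRTs for the full
#' protein and each domain; a free-ratio fit (whose per-branch dN values
#' scale the simulation null); protein-level ancestral reconstruction;
#' convergent/parallel substitution detection over the Sec-loss branch
#' pairs with model-based expectations; the simulation null of convergence
#' counts; a branch-site positive-selection test with site posteriors; and
#' enrichment of selection signal at convergent sites. Results are returned
#' as tibbles and, when `out_dir` is given, written as TSV/JSON.
#'
#' @param data List with `alignment` (`codon_alignment`) and `tree`
#'   (`tagged_phylo`), e.g. from [load_inputs()] or
#'   [simulate_codon_dataset()].
#' @param config List from [pipeline_config()].
#' @param confidence Optional per-column confidence track for masking.
#' @param out_dir Optional output directory.
#' @return List with `region_summary` (per-region dN/dS, LRT p and convergent-site
#'   counts), `focal` (focal-branch site report), `pairs`, `expected`,
#'   `null`, `branch_site`, `enrichment`, `asr_accuracy`, `convergent_tree` and
#'   `manifest`.
#' @export
run_pipeline <- function(data, config = pipeline_config(),
                         confidence = NULL, out_dir = NULL) {
  aln <- data$alignment
  tree <- data$tree
  seed <- config$seed
  if (!is.null(confidence)) {
    aln <- apply_column_mask(aln, confidence, config$threshold)
  }
  dom <- attr(aln, "domains")
  regions <- config$regions
  if (is.null(regions)) regions <- c("full", dom$name)

  # --- branch-model LRTs per region -----------------------------------
  full_fit_alt <- NULL
  region_summary <- purrr::map_dfr(regions, function(rg) {
    sub <- extract_region(aln, rg, exclude_catalytic = TRUE)
    tr_in <- tree
    opt_len <- TRUE
    if (config$share_lengths && rg != "full" && !is.null(full_fit_alt)) {
      tr_in <- full_fit_alt$tree
      opt_len <- FALSE
    }
    f0 <- fit_branch_model(sub, tr_in, "one-ratio",
                           exclude_catalytic = FALSE,
                           restarts = config$restarts,
                           max_rounds = config$max_rounds, tol = config$tol,
                           optimize_lengths = opt_len)
    f1 <- fit_branch_model(sub, tr_in, "partition",
                           exclude_catalytic = FALSE,
                           restarts = 1, init = f0,
                           max_rounds = config$max_rounds, tol = config$tol,
                           optimize_lengths = opt_len)
    if (rg == "full") full_fit_alt <<- f1
    tt <- lrt(f0, f1)
    tibble::tibble(
      region = rg, n_codons = ncol(sub),
      omega_sec = unname(f1$omega["SEC"]),
      omega_exchange = unname(f1$omega["EXCHANGE"]),
      omega_inherited = unname(f1$omega["INHERITED"]),
      omega_all = unname(f0$omega[1]),
      lr = tt$lr, df = tt$df, p_value = tt$p_value
    )
  })

  # --- free-ratio fit: per-branch dN for the simulation null ----------
  free_fit <- fit_branch_model(aln, tree, "free-ratio", restarts = 1,
                               max_rounds = min(config$max_rounds, 4),
                               tol = config$tol)
  branch_table <- tidy(free_fit)

  # --- ancestral reconstruction --------------------------------------
  prot <- translate_alignment(aln)
  rec <- marginal_asr(prot, tree, optimize_lengths = TRUE)
  acc <- node_accuracy(rec)

  # --- convergence scan over EXCHANGE pairs --------------------------
  ex_branches <- branch_ids(rec$tree)[branch_tags(rec$tree) == "EXCHANGE"]
  events <- extract_substitutions(rec, ex_branches)
  scan <- detect_pairwise_convergence(events, tree = rec$tree)
  conv <- convergent_sites(scan)
  expected <- purrr::map_dfr(seq_len(nrow(scan$pairs)), function(r) {
    expected_convergence_counts(
      rec, c(scan$pairs$branch1[r], scan$pairs$branch2[r]),
      observed = scan$pairs[r, ]
    )
  })
  region_summary$n_convergent <- unname(vapply(regions, function(rg) {
    if (rg == "full") return(length(conv))
    d <- dom[dom$name == rg, ]
    sum(conv >= d$start & conv < d$end)
  }, integer(1)))

  # --- simulation null ------------------------------------------------
  sim_tree <- free_fit$tree
  dn <- branch_table$dN[match(branch_ids(sim_tree), branch_table$branch)]
  sim_tree$edge.length <- pmax(dn, 1e-8)
  root_seq <- rec$map[1, ] # first internal node is the root
  cfg_null <- simulation_config(
    sim_tree, root_seq = root_seq, n_rep = config$n_rep, seed = seed + 1L
  )
  null <- convergence_null_test(cfg_null, ex_branches,
                                observed = length(conv),
                                optimize_lengths = config$null_optimize_lengths)

  # --- branch-site test and enrichment -------------------------------
  bs_region <- config$branch_site_region
  bs_aln <- extract_region(aln, bs_region, exclude_catalytic = TRUE)
  bs <- fit_branch_site_pair(bs_aln, tree, foreground = "EXCHANGE",
                             restarts = config$restarts)
  post <- site_posteriors(bs$alt)
  # lift posteriors back to original protein coordinates
  cmap <- attr(bs_aln, "column_map")
  post$site <- cmap$old[match(post$site, cmap$new)]
  conv_in_region <- intersect(conv, post$site)
  other <- setdiff(post$site, conv_in_region)
  enrich <- if (length(conv_in_region) && length(other)) {
    enrichment_test(post, conv_in_region, other)
  } else NULL

  # --- focal-branch report -------------------------------------------
  focal <- NULL
  ftag <- which(branch_tags(rec$tree) == "EXCHANGE")
  if (length(ftag)) {
    fb <- config$focal_branch
    if (is.null(fb)) { # default: the EXCHANGE branch with most events
      tabs <- table(events$branch)
      fb <- names(which.max(tabs))
    }
    focal <- focal_branch_summary(events, conv, fb, dom,
                                  posteriors = post,
                                  percentile = config$percentile,
                                  percentile_domain = NULL)
  }

  # --- tree from convergent sites ------------------------------------
  convergent_tree <- if (length(conv) >= 1 && nrow(prot) >= 4) {
    cys_taxa <- unique(unlist(lapply(
      which(branch_tags(tree) != "SEC"),
      function(e) descendant_tips(tree, tree$edge[e, 2])
    )))
    convergence_tree(prot, sites = conv, taxa_of_interest = cys_taxa)
  } else NULL

  manifest <- list(
    seed = seed, config = config[c("threshold", "n_rep", "percentile",
                                   "branch_site_region", "share_lengths",
                                   "restarts")],
    n_taxa = nrow(aln), n_codons = ncol(aln),
    alignment_hash = rlang::hash(unclass(aln)[, ]),
    tree_hash = rlang::hash(list(tree$edge, tree$edge.length, tree$tag,
                                 tree$tip.label)),
    package_version = as.character(utils::packageVersion("selconv"))
  )
  out <- list(
    region_summary = region_summary, branch_table = branch_table, focal = focal,
    pairs = scan$pairs, site_classes = scan$sites, expected = expected,
    convergent_sites = conv, null = null, branch_site = bs,
    posteriors = post, enrichment = enrich, asr_accuracy = acc,
    convergent_tree = convergent_tree, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) {
    write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(out$region_summary, "region_summary.tsv")
  tsv(out$branch_table, "branch_rates.tsv")
  tsv(out$expected, "pair_expectations.tsv")
  tsv(out$site_classes, "site_classes.tsv")
  tsv(as.data.frame(out$null), "null_distribution.tsv")
  tsv(out$posteriors, "site_posteriors.tsv")
  tsv(out$asr_accuracy, "asr_accuracy.tsv")
  if (!is.null(out$focal)) tsv(out$focal$sites, "focal_sites.tsv")
  if (!is.null(out$convergent_tree)) {
    ape::write.tree(out$convergent_tree$tree, file.path(out_dir, "convergent_sites_tree.nwk"))
  }
  summ <- list(
    convergent_sites = out$convergent_sites,
    null_empirical_p = empirical_p(out$null),
    branch_site = list(
      lr = out$branch_site$lrt$lr, p = out$branch_site$lrt$p_value,
      omega2 = out$branch_site$alt$omega2
    ),
    enrichment = if (!is.null(out$enrichment)) {
      list(u = out$enrichment$u, p = out$enrichment$p_value)
    },
    manifest = out$manifest
  )
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
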