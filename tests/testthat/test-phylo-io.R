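test_that("load_inputs round-trips alignment, tree and tags through disk", {
  cfg <- gpx6_scenario(seed = 5)
  ds <- simulate_codon_dataset(cfg)
  td <- withr::local_tempdir()
  fa <- file.path(td, "aln.fasta"); nw <- file.path(td, "tree.nwk")
  tg <- file.path(td, "tags.tsv"); dm <- file.path(td, "domains.tsv")
  write_fasta(ds$alignment, fa)
  ape::write.tree(ds$tree, nw)
  write_branch_tags(ds$tree, tg)
  write.table(attr(ds$alignment, "domains"), dm, sep = "\t",
              quote = FALSE, row.names = FALSE)
  inp <- load_inputs(fa, nw, tg, dm, catalytic_site = 73)
  expect_equal(sort(rownames(inp$alignment)), sort(rownames(ds$alignment)))
  expect_equal(n_taxa(inp$alignment), 22)
  expect_equal(n_codons(inp$alignment), 217)
  expect_identical(unclass(inp$alignment)[rownames(ds$alignment), ],
                   unclass(ds$alignment)[, ])
  # tags land on the same branches
  reload <- setNames(inp$tree$tag, branch_ids(inp$tree))
  orig <- setNames(ds$tree$tag, branch_ids(ds$tree))
  expect_identical(reload[names(orig)], orig)
  # branch lengths survive to printed precision
  expect_equal(sort(inp$tree$edge.length), sort(ds$tree$edge.length),
               tolerance = 1e-8)
  # domain structure: 39/113/65
  d <- inp$domains
  expect_equal(d$end - d$start, c(39, 113, 65))
})

test_that("taxon mismatches are reported by name", {
  cfg <- gpx6_scenario(seed = 5)
  ds <- simulate_codon_dataset(cfg)
  td <- withr::local_tempdir()
  fa <- file.path(td, "aln.fasta"); nw <- file.path(td, "tree.nwk")
  tg <- file.path(td, "tags.tsv")
  aln2 <- ds$alignment[rownames(ds$alignment) != "mouse", ]
  aln2 <- codon_alignment(aln2, catalytic_site = 73, validate = FALSE)
  write_fasta(aln2, fa)
  ape::write.tree(ds$tree, nw)
  write_branch_tags(ds$tree, tg)
  expect_error(load_inputs(fa, nw, tg), "mouse")
})

test_that("frame and stop-codon violations are rejected", {
  expect_error(codon_alignment(c(a = "ATGAA", b = "ATGAA")), "frame")
  # internal TAA stop away from the catalytic site
  expect_error(
    codon_alignment(c(a = "ATGTAAATG", b = "ATGAAAATG")),
    "stop codon"
  )
  # TGA tolerated only at the catalytic site
  expect_silent(codon_alignment(c(a = "ATGTGAATG", b = "ATGTGTATG"),
                                catalytic_site = 1L))
  expect_error(codon_alignment(c(a = "ATGTGAATG", b = "ATGAAAATG")),
               "stop codon")
})

test_that("column masking drops codon columns below threshold and remaps", {
  dom <- tibble::tibble(name = c("A", "B"), start = c(0L, 4L), end = c(4L, 10L))
  aln <- fixture_alignment(c("x", "y"), 10, seed = 2, domains = dom,
                           catalytic_site = 5L)
  strip <- function(a) {
    m <- unclass(a)
    attributes(m) <- list(dim = dim(a), dimnames = dimnames(a))
    list(m = m, cs = attr(a, "catalytic_site"))
  }
  conf <- rep(1, 10)
  expect_identical(strip(apply_column_mask(aln, conf, 0.95)), strip(aln))
  conf2 <- rep(1, 10); conf2[c(2, 4, 7)] <- 0.90
  masked <- apply_column_mask(aln, conf2, 0.95)
  expect_equal(n_codons(masked), 7)
  # catalytic site (old 5) shifts left past two dropped columns before it
  expect_equal(attr(masked, "catalytic_site"), 3L)
  # domain lengths shrink accordingly and still partition the alignment
  d <- attr(masked, "domains")
  expect_equal(sum(d$end - d$start), 7)
  # degenerate: everything masked
  expect_warning(out <- apply_column_mask(aln, rep(0, 10), 0.95), "empty")
  expect_equal(n_codons(out), 0)
  # idempotent at a fixed threshold
  twice <- apply_column_mask(masked, conf2[conf2 >= 0.95], 0.95)
  expect_identical(strip(twice), strip(masked))
  # length mismatch
  expect_error(apply_column_mask(aln, rep(1, 9), 0.95), "length")
})

test_that("extract_region partitions the alignment and can drop the
           catalytic column", {
  cfg <- gpx6_scenario(seed = 5)
  aln <- simulate_codon_dataset(cfg)$alignment
  expect_equal(n_codons(extract_region(aln, "full", TRUE)), 216)
  expect_equal(n_codons(extract_region(aln, "GPX")), 113)
  # catalytic site in GPX, so the N-terminus is untouched by the flag
  expect_equal(n_codons(extract_region(aln, "N-terminus", TRUE)), 39)
  dom <- attr(aln, "domains")
  total <- sum(vapply(dom$name, function(r) n_codons(extract_region(aln, r)),
                      integer(1)))
  expect_equal(total, n_codons(aln))
  expect_error(extract_region(aln, "nope"), "unknown region")
})

test_that("tagging validation enforces the Sec-loss partial order", {
  tr <- ape::read.tree(text = "((a:1,b:1)ab:1,(c:1,d:1)cd:1)r;")
  expect_error(
    tag_tree(tr, c(ab = "EXCHANGE", a = "SEC")),
    "descends from"
  )
  tg <- tag_tree(tr, c(ab = "EXCHANGE", a = "INHERITED", b = "INHERITED"))
  expect_setequal(unique(tg$tag), c("SEC", "EXCHANGE", "INHERITED"))
  expect_error(tag_tree(tr, c(zz = "EXCHANGE")), "zz")
  expect_error(tag_tree(tr, c(a = "WEIRD")), "unknown branch tag")
})

test_that("catalytic-tag consistency helper flags disagreements only", {
  cfg <- gpx6_scenario(seed = 5)
  ds <- simulate_codon_dataset(cfg)
  chk <- check_catalytic_tags(ds$alignment, ds$tree)
  expect_true(all(chk$consistent))
  # flip one taxon's catalytic codon
  m <- unclass(ds$alignment)
  m["elephant" == rownames(m), 74] <- "TGT"
  aln2 <- codon_alignment(m, catalytic_site = 73,
                          domains = attr(ds$alignment, "domains"))
  chk2 <- check_catalytic_tags(aln2, ds$tree)
  expect_false(chk2$consistent[chk2$taxon == "elephant"])
})
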