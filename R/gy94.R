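#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are tabulated from the alignment
#' and multiplied across the three codon positions; the product is restricted
#' to the 61 sense codons and renormalised. This is the standard empirical
#' frequency model of codon-based selection analyses.
#'
#' @param aln A `codon_alignment` (gap and ambiguous codons are ignored).
#' @return Numeric vector of 61 codon frequencies summing to 1, named by
#'   codon.
#' @export
f3x4_frequencies <- function(aln) {
  ct <- codon_table()
  cods <- aln[aln %in% ct$codons]
  if (!length(cods)) stop("no unambiguous codons in alignment")
  m <- do.call(rbind, strsplit(cods, ""))
  posfreq <- vapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = NUCS))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  f3x4_from_positions(t(posfreq))
}

# pos_freq: 3 x 4 matrix (rows = codon positions, cols = T,C,A,G order NUCS)
f3x4_from_positions <- function(pos_freq) {
  ct <- codon_table()
  if (any(pos_freq <= 0)) {
    stop("zero nucleotide frequency would give zero frequency for an observed codon")
  }
  pi <- vapply(seq_len(ct$n), function(i) {
    prod(pos_freq[cbind(1:3, match(ct$cmat[i, ], NUCS))])
  }, numeric(1))
  setNames(pi / sum(pi), ct$codons)
}

#' Build a GY94 codon rate matrix
#'
#' Off-diagonal rates are zero for multi-nucleotide changes and otherwise
#' proportional to the target codon's equilibrium frequency, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous changes. The
#' matrix is scaled so that the expected number of substitutions per codon
#' per unit time at equilibrium is one.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Codon equilibrium frequencies over the 61 sense codons.
#' @return A 61x61 rate matrix with zero row sums.
#' @export
build_gy94_matrix <- function(kappa, omega, pi) {
  ct <- codon_table()
  if (length(pi) != ct$n) stop("pi must have 61 entries")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be a distribution")
  if (kappa <= 0 || omega < 0) stop("kappa must be > 0 and omega >= 0")
  Q <- matrix(0, ct$n, ct$n, dimnames = list(ct$codons, ct$codons))
  p <- ct$pairs
  rate <- pi[p$j] * ifelse(p$ts, kappa, 1) * ifelse(p$ns, omega, 1)
  Q[cbind(p$i, p$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (all rates zero)")
  Q / scale
}

# Eigen-decomposition of a reversible rate matrix via its symmetrised form.
# Returns V, Vi (V^{-1}) and eigenvalues d so that expm(Q t) = V exp(d t) Vi.
eigen_reversible <- function(Q, pi) {
  s <- sqrt(pi)
  S <- sweep(sweep(Q, 1, s, "*"), 2, s, "/") # diag(s) Q diag(1/s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(
    V = e$vectors / s,              # diag(1/s) %*% vectors
    Vi = t(e$vectors) * rep(s, each = nrow(Q)), # t(vectors) %*% diag(s)
    d = e$values
  )
}

pmat_from_eigen <- function(eg, t) {
  P <- eg$V %*% (exp(eg$d * t) * eg$Vi)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix
#'
#' @param Q Rate matrix (as from [build_gy94_matrix()]).
#' @param t Branch length (expected substitutions per codon, >= 0).
#' @param pi Equilibrium frequencies; when supplied and `Q` is reversible
#'   with respect to them, a fast eigen route is used.
#' @return Probability matrix `expm(Q t)` with unit row sums.
#' @export
transition_matrix <- function(Q, t, pi = NULL) {
  if (t < 0) stop("branch length must be non-negative")
  if (!is.null(pi)) {
    P <- pmat_from_eigen(eigen_reversible(Q, pi), t)
  } else {
    e <- eigen(Q)
    P <- Re(e$vectors %*% (exp(e$values * t) * solve(e$vectors)))
    P[P < 0] <- 0
  }
  dimnames(P) <- dimnames(Q)
  P
}

# Expected proportions of nonsynonymous / synonymous flux of a scaled GY94
# matrix; used to convert branch lengths (subs/codon) into dN and dS
# (subs per nonsyn/syn site), with "sites" counted at omega = 1 as in
# standard codon-model practice.
substitution_proportions <- function(kappa, omega, pi) {
  ct <- codon_table()
  p <- ct$pairs
  base <- pi[p$j] * ifelse(p$ts, kappa, 1)
  rate <- base * ifelse(p$ns, omega, 1)
  flux <- pi[p$i] * rate
  tot <- sum(flux)
  # mutational opportunity at omega = 1 (same kappa, pi)
  flux1 <- pi[p$i] * base
  list(
    rho_n = sum(flux[p$ns]) / tot,
    rho_s = sum(flux[!p$ns]) / tot,
    prop_n_sites = sum(flux1[p$ns]) / sum(flux1),
    prop_s_sites = sum(flux1[!p$ns]) / sum(flux1)
  )
}

#' Per-branch dN and dS from fitted parameters
#'
#' Converts a branch length in expected substitutions per codon into dN
#' (nonsynonymous substitutions per nonsynonymous site) and dS, using the
#' expected substitution flux under the fitted matrix and site proportions
#' counted at `omega = 1`.
#'
#' @param t Branch length (substitutions per codon).
#' @param kappa,omega,pi Model parameters for the branch.
#' @return Named list with `dN`, `dS`, `en` (expected nonsynonymous
#'   substitutions per codon) and `es`.
#' @export
branch_dnds <- function(t, kappa, omega, pi) {
  pr <- substitution_proportions(kappa, omega, pi)
  en <- t * pr$rho_n
  es <- t * pr$rho_s
  list(
    dN = en / (3 * pr$prop_n_sites),
    dS = es / (3 * pr$prop_s_sites),
    en = en, es = es
  )
}
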