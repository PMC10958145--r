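#' Construct a codon alignment
#'
#' A codon alignment holds in-frame coding sequences as a taxa-by-codon
#' character matrix, together with the optional catalytic-site coordinate
#' (the Sec/Cys site of a selenoprotein, where the stop codon TGA is read as
#' selenocysteine) and a named partition of the protein into domains.
#' Coordinates are 0-based and intervals half-open, and one codon column
#' corresponds to one amino-acid position.
#'
#' @param sequences Named character vector of in-frame nucleotide sequences
#'   (all the same length, divisible by 3), or a taxa-by-codon character
#'   matrix of 3-letter codon strings with row names.
#' @param catalytic_site 0-based codon coordinate of the catalytic site, or
#'   `NA` if there is none. TGA is only tolerated in this column.
#' @param domains Optional tibble/data frame with columns `name`, `start`,
#'   `end` (0-based, half-open, amino-acid coordinates).
#' @param validate Check frame, internal stops and domain consistency.
#'
#' @return An object of class `codon_alignment`: a codon matrix with
#'   attributes `catalytic_site` and `domains`.
#' @export
codon_alignment <- function(sequences, catalytic_site = NA_integer_,
                            domains = NULL, validate = TRUE) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences))) {
      stop("sequences must be named by taxon")
    }
    nc <- unique(nchar(sequences))
    if (length(nc) != 1L) {
      stop("all sequences must have equal length")
    }
    if (nc %% 3L != 0L) {
      stop("frame error: sequence length ", nc, " is not divisible by 3")
    }
    mat <- t(vapply(
      toupper(sequences),
      function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
      character(nc / 3)
    ))
    if (nc / 3 == 1) mat <- matrix(mat, ncol = 1, dimnames = list(names(sequences), NULL))
  }
  if (is.null(rownames(mat))) stop("codon matrix must have taxon row names")
  domains <- if (is.null(domains)) {
    tibble::tibble(name = character(), start = integer(), end = integer())
  } else {
    tibble::as_tibble(domains)
  }
  obj <- structure(mat,
    catalytic_site = as.integer(catalytic_site),
    domains = domains,
    class = c("codon_alignment", "matrix", "array")
  )
  if (validate) validate_codon_alignment(obj)
  obj
}

validate_codon_alignment <- function(aln) {
  ct <- codon_table()
  taxa <- rownames(aln)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  cs <- attr(aln, "catalytic_site")
  cols <- seq_len(ncol(aln))
  check <- if (!is.na(cs)) cols[cols != cs + 1L] else cols
  stop_hits <- which(matrix(aln[, check, drop = FALSE] %in% ct$stops,
                            nrow = nrow(aln)), arr.ind = TRUE)
  if (nrow(stop_hits)) {
    stop(
      "internal stop codon in taxon ", taxa[stop_hits[1, 1]],
      " at codon ", check[stop_hits[1, 2]] - 1L, " (0-based)"
    )
  }
  dom <- attr(aln, "domains")
  if (nrow(dom)) {
    if (anyDuplicated(dom$name)) stop("duplicate domain names")
    o <- order(dom$start)
    d <- dom[o, ]
    if (any(d$end <= d$start)) stop("empty or inverted domain interval")
    if (any(d$start[-1] < d$end[-nrow(d)])) stop("overlapping domains")
    if (max(d$end) > ncol(aln)) stop("domain interval exceeds alignment length")
  }
  invisible(aln)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(
    "<codon_alignment> ", nrow(x), " taxa x ", ncol(x), " codons",
    if (!is.na(attr(x, "catalytic_site"))) {
      paste0("; catalytic site at ", attr(x, "catalytic_site"))
    } else "",
    "\n", sep = ""
  )
  dom <- attr(x, "domains")
  if (nrow(dom)) {
    cat("domains:", paste0(dom$name, "[", dom$start, ",", dom$end, ")",
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of codons / taxa in an alignment
#' @param aln A `codon_alignment`.
#' @return Integer count.
#' @export
n_codons <- function(aln) ncol(aln)

#' @rdname n_codons
#' @export
n_taxa <- function(aln) nrow(aln)

#' Translate a codon alignment to protein
#'
#' TGA at the catalytic site is translated as the 21st amino acid "U"
#' (selenocysteine); any other untranslatable or gap codon becomes "-".
#'
#' @param aln A `codon_alignment`.
#' @return Character matrix (taxa x sites) of one-letter amino acids, with
#'   the `catalytic_site` and `domains` attributes carried over.
#' @export
translate_alignment <- function(aln) {
  cs <- attr(aln, "catalytic_site")
  cat_col <- if (!is.na(cs)) cs + 1L else integer(0)
  prot <- t(apply(aln, 1, function(row) {
    aa <- translate_codons(row, catalytic = cat_col)
    aa[is.na(aa)] <- "-"
    aa
  }))
  if (ncol(aln) == 1) prot <- matrix(prot, ncol = 1, dimnames = list(rownames(aln), NULL))
  structure(prot,
    catalytic_site = cs, domains = attr(aln, "domains"),
    class = c("protein_alignment", "matrix", "array")
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> ", nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  invisible(x)
}

# integer codon states 1..61 (NA for gaps/ambiguity), taxa x sites
codon_states <- function(aln) {
  ct <- codon_table()
  m <- matrix(match(aln, ct$codons), nrow = nrow(aln),
              dimnames = list(rownames(aln), NULL))
  m
}

# integer amino-acid states 1..20 (NA for gap/X/U)
protein_states <- function(prot) {
  matrix(match(prot, AA20), nrow = nrow(prot),
         dimnames = list(rownames(prot), NULL))
}
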