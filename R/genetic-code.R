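# Universal genetic code machinery for the 61 sense codons.
#
# All codon-model code works on integer codon states 1..61 in the fixed order
# returned by codon_table(). TGA is a stop in the standard code; at the
# catalytic site of a selenoprotein it encodes Sec ("U"), which is handled at
# the alignment level (the column is excluded from codon-model fits).

NUCS <- c("T", "C", "A", "G")

codon_table <- function() {
  if (!is.null(.selconv$codon)) {
    return(.selconv$codon)
  }
  all64 <- as.vector(t(outer(
    as.vector(t(outer(NUCS, NUCS, paste0))), NUCS, paste0
  )))
  aa64 <- vapply(
    all64,
    function(x) seqinr::translate(strsplit(x, "")[[1]]),
    character(1)
  )
  sense <- aa64 != "*"
  codons <- all64[sense]
  aa <- unname(aa64[sense])
  n <- length(codons) # 61
  cmat <- do.call(rbind, strsplit(codons, ""))

  # single-nucleotide-difference structure
  purine <- c("A", "G")
  ii <- integer(0); jj <- integer(0)
  is_ts <- logical(0); is_ns <- logical(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(cmat[i, ] != cmat[j, ])
      if (length(d) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      a <- cmat[i, d]; b <- cmat[j, d]
      is_ts <- c(is_ts, (a %in% purine) == (b %in% purine))
      is_ns <- c(is_ns, aa[i] != aa[j])
    }
  }
  .selconv$codon <- list(
    codons = codons, aa = aa, n = n, cmat = cmat,
    pairs = list(i = ii, j = jj, ts = is_ts, ns = is_ns),
    stops = all64[!sense]
  )
  .selconv$codon
}

codon_index <- function(codon) {
  ct <- codon_table()
  match(codon, ct$codons)
}

# Translate a vector of codon strings; TGA at the catalytic position becomes
# "U", other stops and unresolvable codons become NA.
translate_codons <- function(codons, catalytic = integer(0)) {
  ct <- codon_table()
  aa <- ct$aa[match(codons, ct$codons)]
  if (length(catalytic)) {
    sec <- codons[catalytic] == "TGA" & !is.na(codons[catalytic])
    aa[catalytic][sec] <- "U"
  }
  aa
}

#' The 20 standard amino acids in lexicographic order
#'
#' The fixed state order used by every amino-acid-level computation in the
#' package; MAP-state ties break toward the earlier letter.
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
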