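#' @keywords internal
"_PACKAGE"

#' @importFrom stats binom.test coef dbinom median pbinom quantile
#'   rgamma rmultinom rnorm runif setNames cor lm vcov residuals
#'   complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' The 20-letter amino-acid alphabet
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue positions of the variable region (numbering of the unprocessed
# precursor: Met1 is fixed, positions 2-5 are randomized).
NT_POSITIONS <- 2:5

# Allowed phosphoacceptor residues at position 3.
PHOSPHOACCEPTORS <- c("S", "T")

#' Enumerate the cofilin N-terminal variant design space
#'
#' The library randomizes residues 2, 4 and 5 of cofilin-1 over all twenty
#' canonical amino acids while position 3 (the phosphoacceptor) is either
#' serine or threonine, giving 20^3 x 2 = 16,000 unique four-residue
#' sequences.
#'
#' @return Character vector of 16,000 four-letter variant strings
#'   (positions 2-5), sorted lexicographically. The wild-type human sequence
#'   is "ASGV".
#' @export
#' @examples
#' length(nterm_variants())  # 16000
nterm_variants <- function() {
  grid <- expand.grid(p5 = AA_ALPHABET, p4 = AA_ALPHABET,
                      p3 = PHOSPHOACCEPTORS, p2 = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$p2, grid$p3, grid$p4, grid$p5))
}

#' Validate variant strings against the library design
#'
#' @param x Character vector of candidate four-residue sequences.
#' @return Logical vector: `TRUE` where `x` is a member of the design space
#'   (length 4, canonical residues, position 3 Ser/Thr).
#' @export
is_design_variant <- function(x) {
  ok <- !is.na(x) & nchar(x) == 4L
  ok[ok] <- vapply(strsplit(x[ok], ""), function(r) {
    all(r %in% AA_ALPHABET) && r[2] %in% PHOSPHOACCEPTORS
  }, logical(1))
  ok
}

#' Residue at a library position
#'
#' @param variants Character vector of four-residue variant strings.
#' @param position Integer position in 2..5.
#' @return Character vector of single residues.
#' @export
residue_at <- function(variants, position) {
  stopifnot(position %in% NT_POSITIONS)
  substr(variants, position - 1L, position - 1L)
}

# Position 3 is overridden to the ACC/AGC pair actually used in the
# synthesized oligo mixture; the remaining codons are a documented stand-in
# since trimer-phosphoramidite codon compositions are rarely disclosed.

#' Default residue-to-codon map for read emission (common yeast codons)
#' @export
DEFAULT_CODON_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
  G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "TTG",
  M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
  S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# Position-3 codons: ACC encodes Thr, AGC encodes Ser.
POS3_CODON <- c(S = "AGC", T = "ACC")

#' Amplicon anchors flanking the 12-nt variable region
#'
#' The 5' anchor ends in the initiator ATG (preceded by the His-tag
#' Gly-Ala linker); the 3' anchor encodes the invariant downstream
#' residues Ala6-Val7-Ser8 of cofilin-1.
#' @export
DEFAULT_ANCHORS <- c(five = "GGTGCTGGAGCTATG", three = "GCTGTTTCTGAT")

#' Encode variants as 12-nt variable-region DNA
#'
#' Uses one fixed codon per residue at positions 2, 4 and 5 and the ACC/AGC
#' pair at position 3 (ACC = Thr, AGC = Ser), mirroring the codon scheme of
#' the synthesized library.
#'
#' @param variants Character vector of design variants.
#' @param codon_table Named character vector mapping all 20 residues to
#'   codons (positions 2/4/5 only; position 3 always uses ACC/AGC).
#' @return Character vector of 12-nt DNA inserts.
#' @export
#' @examples
#' encode_variant("ASGV")  # "GCTAGCGGTGTT"
encode_variant <- function(variants, codon_table = DEFAULT_CODON_TABLE) {
  if (!all(AA_ALPHABET %in% names(codon_table)))
    stop("codon_table must cover all 20 residues")
  if (!all(is_design_variant(variants)))
    stop("variants outside the library design space")
  paste0(codon_table[residue_at(variants, 2)],
         POS3_CODON[residue_at(variants, 3)],
         codon_table[residue_at(variants, 4)],
         codon_table[residue_at(variants, 5)])
}

#' Decode a 12-nt variable-region insert to a library variant
#'
#' Translates the four codons by the standard genetic code. Reads carrying a
#' stop codon or a non-ACGT base fail as `codon_fail`; reads whose
#' position-3 codon is not one of the two design codons (ACC/AGC) decode to
#' a valid protein but are flagged `off_design`.
#'
#' @param inserts Character vector of 12-nt DNA strings.
#' @return Data frame with columns `insert`, `outcome` (one of `variant`,
#'   `codon_fail`, `off_design`) and `variant` (NA unless outcome is
#'   `variant`).
#' @export
#' @examples
#' decode_variant("GCTAGCGGTGTT")  # ASGV
decode_variant <- function(inserts) {
  n <- length(inserts)
  outcome <- rep("codon_fail", n)
  variant <- rep(NA_character_, n)
  ok_len <- !is.na(inserts) & nchar(inserts) == 12L &
    !grepl("[^ACGT]", inserts)
  if (any(ok_len)) {
    gc <- Biostrings::GENETIC_CODE
    idx <- which(ok_len)
    codons <- matrix(substring(rep(inserts[idx], each = 4L),
                               rep(c(1L, 4L, 7L, 10L), length(idx)),
                               rep(c(3L, 6L, 9L, 12L), length(idx))),
                     nrow = 4L)
    aa <- matrix(gc[codons], nrow = 4L)
    has_stop <- colSums(aa == "*") > 0L
    pos3_codon <- codons[2L, ]
    on_design <- !has_stop & pos3_codon %in% POS3_CODON
    off <- !has_stop & !on_design
    outcome[idx[off]] <- "off_design"
    outcome[idx[on_design]] <- "variant"
    variant[idx[on_design]] <-
      apply(aa[, on_design, drop = FALSE], 2L, paste0, collapse = "")
  }
  data.frame(insert = inserts, outcome = outcome, variant = variant,
             stringsAsFactors = FALSE)
}
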