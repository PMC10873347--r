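#' Emit amplicon FASTQ reads from a count matrix
#'
#' Writes one read per counted molecule: 5' anchor + 12-nt variable region +
#' 3' anchor, with independent per-base substitution errors at `error_rate`
#' and constant Phred quality "I". At `error_rate = 0` the files round-trip
#' exactly through [tally_counts()].
#'
#' @param counts A `count_matrix` (or plain integer matrix with variant
#'   rownames and sample colnames).
#' @param dir Output directory.
#' @param anchors Length-2 character vector `c(five, three)` of anchor
#'   sequences.
#' @param codon_table Residue-to-codon map for positions 2/4/5.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for error injection and read shuffling.
#' @param gzip Write `.fastq.gz` (default) or plain `.fastq`.
#' @return Named character vector of file paths (names = sample ids).
#' @export
emit_amplicon_fastq <- function(counts, dir, anchors = DEFAULT_ANCHORS,
                                codon_table = DEFAULT_CODON_TABLE,
                                error_rate = 0, seed = 1, gzip = TRUE) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (any(nchar(anchors) == 0)) stop("anchors must be non-empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- rownames(counts)
  inserts <- encode_variant(variants, codon_table)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- setNames(file.path(dir, paste0(colnames(counts), ext)),
                    colnames(counts))
  for (j in seq_len(ncol(counts))) {
    n <- counts[, j]
    reads <- paste0(anchors[1], rep(inserts, n), anchors[2])
    if (length(reads) > 0) {
      reads <- sample(reads)
      if (error_rate > 0) reads <- inject_substitutions(reads, error_rate)
    }
    seqs <- Biostrings::DNAStringSet(reads)
    names(seqs) <- if (length(reads)) paste0("read", seq_along(reads)) else
      character(0)
    Biostrings::writeXStringSet(
      seqs, paths[j], format = "fastq", compress = gzip,
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(seqs))))
  }
  paths
}

# Uniform substitution errors: each base independently replaced by one of
# the three alternatives with probability `rate`. No indels (amplicon reads
# of a fixed-length core; indels would fail anchor framing regardless).
inject_substitutions <- function(reads, rate) {
  widths <- nchar(reads)
  stopifnot(length(unique(widths)) <= 1L)
  w <- widths[1]
  mat <- matrix(unlist(strsplit(reads, "")), nrow = w)
  hit <- which(runif(length(mat)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- mat[hit]
    repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                   character(1))
    mat[hit] <- repl
  }
  apply(mat, 2, paste0, collapse = "")
}
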