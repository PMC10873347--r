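#' Extract the 12-nt variable region from amplicon reads
#'
#' Locates the exact 5' and 3' anchor sequences (first occurrences, no
#' mismatches) and returns the insert between them. Reads missing either
#' anchor are `anchor_fail`; reads whose anchors frame an insert of the
#' wrong length are `frame_fail`. Rejections are data, not errors.
#'
#' @param reads Character vector of read sequences.
#' @param anchors Length-2 character vector `c(five, three)`.
#' @param insert_length Expected insert length (12 nt for four codons).
#' @return Data frame with columns `outcome` (`insert`, `anchor_fail`,
#'   `frame_fail`) and `insert` (NA unless extracted).
#' @export
extract_variable_region <- function(reads, anchors = DEFAULT_ANCHORS,
                                    insert_length = 12L) {
  if (any(nchar(anchors) == 0)) stop("anchors must be non-empty")
  n <- length(reads)
  outcome <- rep("anchor_fail", n)
  insert <- rep(NA_character_, n)
  p5 <- regexpr(anchors[1], reads, fixed = TRUE)
  has5 <- p5 > 0
  start <- p5 + nchar(anchors[1])
  # search the 3' anchor only downstream of the 5' anchor
  tail3 <- substr(reads, start, nchar(reads))
  p3 <- rep(-1L, n)
  p3[has5] <- regexpr(anchors[2], tail3[has5], fixed = TRUE)
  framed <- has5 & p3 > 0
  len <- p3 - 1L
  good <- framed & len == insert_length
  outcome[framed & !good] <- "frame_fail"
  outcome[good] <- "insert"
  insert[good] <- substr(reads[good], start[good],
                         start[good] + insert_length - 1L)
  data.frame(outcome = outcome, insert = insert, stringsAsFactors = FALSE)
}

#' Decode reads end-to-end
#'
#' Applies anchor extraction then codon decoding, yielding exactly one
#' outcome per read: `variant`, `anchor_fail`, `frame_fail`, `codon_fail`
#' or `off_design`.
#'
#' @inheritParams extract_variable_region
#' @return Data frame with columns `outcome` and `variant`.
#' @export
decode_reads <- function(reads, anchors = DEFAULT_ANCHORS) {
  ext <- extract_variable_region(reads, anchors)
  outcome <- ext$outcome
  variant <- rep(NA_character_, length(reads))
  hit <- outcome == "insert"
  if (any(hit)) {
    dec <- decode_variant(ext$insert[hit])
    outcome[hit] <- dec$outcome
    variant[hit] <- dec$variant
  }
  data.frame(outcome = outcome, variant = variant, stringsAsFactors = FALSE)
}

#' Tally amplicon FASTQ files into a variant count matrix
#'
#' Counts decoded on-design reads per sample over the complete
#' 16,000-variant design space (zero-count variants included) and records a
#' QC breakdown that partitions every read: valid + anchor_fail +
#' frame_fail + codon_fail + off_design = total.
#'
#' @param files Named character vector of FASTQ paths (plain or gzipped);
#'   names are the sample ids. Unnamed paths use the file base name.
#' @param anchors Length-2 anchor vector.
#' @param samples Optional sample metadata data frame with a `sample_id`
#'   column matching `names(files)` (e.g. `screen_design()$samples`).
#' @return A `count_matrix` over the full design space with per-sample QC.
#' @export
tally_counts <- function(files, anchors = DEFAULT_ANCHORS, samples = NULL) {
  ids <- names(files)
  if (is.null(ids)) ids <- sub("\\.fastq(\\.gz)?$", "", basename(files))
  variants <- nterm_variants()
  counts <- matrix(0L, nrow = length(variants), ncol = length(files),
                   dimnames = list(variants, ids))
  qc <- data.frame(sample_id = ids, total = 0L, valid = 0L,
                   anchor_fail = 0L, frame_fail = 0L, codon_fail = 0L,
                   off_design = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(files)) {
    if (!file.exists(files[j])) stop("missing FASTQ: ", files[j])
    reads <- as.character(Biostrings::readDNAStringSet(files[j],
                                                       format = "fastq"))
    dec <- decode_reads(unname(reads), anchors)
    qc$total[j] <- nrow(dec)
    for (o in c("anchor_fail", "frame_fail", "codon_fail", "off_design"))
      qc[[o]][j] <- sum(dec$outcome == o)
    hit <- dec$outcome == "variant"
    qc$valid[j] <- sum(hit)
    if (any(hit)) {
      tab <- table(factor(dec$variant[hit], levels = variants))
      counts[, j] <- as.integer(tab)
    }
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  new_count_matrix(counts, samples, qc)
}

#' Write / read a count matrix as TSV
#'
#' Plain-text interchange: a `variant` column followed by one integer
#' column per sample.
#'
#' @param x A `count_matrix`.
#' @param path Output TSV path.
#' @return `write_count_tsv` returns `path` invisibly; `read_count_tsv`
#'   returns a `count_matrix`.
#' @export
write_count_tsv <- function(x, path) {
  df <- data.frame(variant = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$variant
  new_count_matrix(counts,
                   data.frame(sample_id = colnames(counts),
                              stringsAsFactors = FALSE))
}
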