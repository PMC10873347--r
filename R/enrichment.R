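# The three contrasts scored by the screen. "function" compares the start
# of selection to ~6-7 doublings of growth without kinase; the two kinase
# axes compare T1 to T3 (after the induction lag) in each sugar.
CONTRASTS <- list(
  function_ = list(label = "func", start = c("shared", "T0"),
                   end = c("glucose", "T2")),
  limk_glu  = list(label = "limk_glu", start = c("glucose", "T1"),
                   end = c("glucose", "T3")),
  limk_gal  = list(label = "limk_gal", start = c("galactose", "T1"),
                   end = c("galactose", "T3")))

#' Per-sample variant frequencies (relative representation)
#'
#' A variant's relative representation in a sample is its read count divided
#' by the sample's total valid read count. A pseudocount added to every
#' variant keeps log-ratios finite for unobserved variants.
#'
#' @param counts A `count_matrix` or integer matrix.
#' @param pseudocount Added to every variant in every sample (default 0.5).
#' @return Numeric matrix of frequencies; every column sums to 1.
#' @export
sample_frequencies <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(pseudocount >= 0)
  tot <- colSums(counts) + pseudocount * nrow(counts)
  if (any(tot == 0)) stop("all-zero sample with zero pseudocount")
  sweep(counts + pseudocount, 2, tot, "/")
}

#' Log2 enrichment between two frequency vectors
#'
#' @param freq_end,freq_start Positive frequency vectors (same variants).
#' @return `log2(freq_end / freq_start)`; antisymmetric under swapping the
#'   arguments. Non-positive frequencies yield `NA` (flag for exclusion).
#' @export
log2_enrichment <- function(freq_end, freq_start) {
  out <- log2(freq_end / freq_start)
  out[freq_end <= 0 | freq_start <= 0] <- NA_real_
  out
}

#' Score a screen: per-replicate and mean log2 fold changes, ranks
#'
#' Computes, for every variant, the log2 change in relative representation
#' over each contrast in each replicate, the unweighted mean across valid
#' replicates, the descending rank on the mean function score (ties broken
#' lexicographically by variant), and the enriched flag (mean function
#' score strictly > 0).
#'
#' @param counts A `count_matrix` whose samples carry `replicate`,
#'   `condition`, `timepoint` columns (as produced by the simulator or by
#'   [tally_counts()] with design metadata).
#' @param pseudocount Passed to [sample_frequencies()].
#' @return Data frame of class `enrichment_records`: `variant`, per-contrast
#'   replicate columns (`func_rep1` ...), per-contrast means (`func_mean`,
#'   `limk_glu_mean`, `limk_gal_mean`), `rank`, `enriched`.
#' @export
score_screen <- function(counts, pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  smp <- counts$samples
  need <- c("replicate", "condition", "timepoint")
  if (!all(need %in% names(smp)))
    stop("sample metadata must carry replicate/condition/timepoint")
  freq <- sample_frequencies(counts, pseudocount)
  variants <- rownames(counts$counts)
  reps <- sort(unique(smp$replicate))
  out <- data.frame(variant = variants, stringsAsFactors = FALSE)
  find_sample <- function(r, cond, tp) {
    i <- which(smp$replicate == r & smp$condition == cond &
                 smp$timepoint == tp)
    if (length(i) != 1)
      stop("expected exactly one sample for replicate ", r, " ", cond,
           " ", tp)
    smp$sample_id[i]
  }
  for (ct in CONTRASTS) {
    vals <- sapply(reps, function(r) {
      s0 <- find_sample(r, ct$start[1], ct$start[2])
      s1 <- find_sample(r, ct$end[1], ct$end[2])
      log2_enrichment(freq[, s1], freq[, s0])
    })
    colnames(vals) <- paste0(ct$label, "_rep", reps)
    out <- cbind(out, vals)
    out[[paste0(ct$label, "_mean")]] <- rowMeans(vals, na.rm = TRUE)
    out[[paste0(ct$label, "_mean")]][rowSums(!is.na(vals)) == 0] <- NA_real_
  }
  rk <- rank_records(out$func_mean, out$variant)
  out$rank <- rk
  out$enriched <- !is.na(out$func_mean) & out$func_mean > 0
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Replicate mean and deterministic rank
#'
#' Unweighted mean of per-replicate log2 fold changes over valid (non-NA)
#' replicates, with descending rank on the mean; ties are broken
#' lexicographically by the variant string so repeated runs give identical
#' ranks. Variants invalid in every replicate are unranked (`NA`).
#'
#' @param values Numeric matrix (variants x replicates) of per-replicate
#'   log2 fold changes, possibly containing `NA`.
#' @param variants Character vector of variant ids (tie-break key).
#' @return Data frame `variant`, `mean`, `n_valid`, `rank`.
#' @export
replicate_mean_and_rank <- function(values, variants) {
  values <- as.matrix(values)
  m <- rowMeans(values, na.rm = TRUE)
  nv <- rowSums(!is.na(values))
  m[nv == 0] <- NA_real_
  data.frame(variant = variants, mean = m, n_valid = nv,
             rank = rank_records(m, variants), stringsAsFactors = FALSE)
}

rank_records <- function(means, variants) {
  rk <- rep(NA_integer_, length(means))
  ok <- !is.na(means)
  ord <- order(-means[ok], variants[ok])
  rk[which(ok)[ord]] <- seq_len(sum(ok))
  rk
}

#' Select the enriched variant set
#'
#' Variants whose mean function-contrast log2 fold change is strictly
#' greater than `threshold` (default 0, matching the screen's definition of
#' enrichment across three replicates).
#'
#' @param records An `enrichment_records` data frame.
#' @param threshold Strict lower bound on the mean function score.
#' @return Character vector of enriched variants.
#' @export
select_enriched <- function(records, threshold = 0) {
  records$variant[!is.na(records$func_mean) & records$func_mean > threshold]
}

#' Top-ranked variants
#'
#' @param records An `enrichment_records` data frame.
#' @param n Number of variants (by mean-function rank) to return.
#' @return Character vector of the `n` most enriched variants.
#' @export
top_enriched <- function(records, n = 400) {
  records$variant[!is.na(records$rank) & records$rank <= n]
}
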