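#' Mean score per residue at each library position
#'
#' Heat-map summaries: for each position and residue, the mean log2 fold
#' change over exactly the library sequences carrying that residue there.
#' On the complete design space each cell at positions 2/4/5 averages 800
#' sequences and each position-3 cell averages 8000.
#'
#' @param records An `enrichment_records` data frame (or any data frame
#'   with `variant` plus a numeric score column).
#' @param score_col Name of the score column (default `"func_mean"`).
#' @return Data frame `position`, `residue`, `mean`, `n`.
#' @export
residue_position_means <- function(records, score_col = "func_mean") {
  stopifnot(score_col %in% names(records))
  out <- do.call(rbind, lapply(NT_POSITIONS, function(pos) {
    res <- residue_at(records$variant, pos)
    levs <- if (pos == 3) PHOSPHOACCEPTORS else AA_ALPHABET
    f <- factor(res, levels = levs)
    data.frame(position = pos, residue = levs,
               mean = as.numeric(tapply(records[[score_col]], f, mean,
                                        na.rm = TRUE)),
               n = as.integer(table(f)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Box-plot statistics of scores grouped by residue at a position
#'
#' Median, quartiles (box) and 10th/90th percentiles (whiskers) of the
#' score distribution for each residue at the given position. Percentiles
#' use linear interpolation between order statistics.
#'
#' @inheritParams residue_position_means
#' @param position Library position (2-5).
#' @return Data frame `position`, `residue`, `p10`, `p25`, `median`, `p75`,
#'   `p90`, `n`.
#' @export
score_distribution_summary <- function(records, position,
                                       score_col = "func_mean") {
  stopifnot(position %in% NT_POSITIONS)
  res <- residue_at(records$variant, position)
  levs <- if (position == 3) PHOSPHOACCEPTORS else AA_ALPHABET
  out <- do.call(rbind, lapply(levs, function(r) {
    x <- records[[score_col]][res == r]
    x <- x[!is.na(x)]
    q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
    data.frame(position = position, residue = r, p10 = q[1], p25 = q[2],
               median = q[3], p75 = q[4], p90 = q[5], n = length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Exact binomial tail probabilities. Upper tail P(X >= k); lower tail
# P(X <= k). p is floored at the smallest positive double so -log10 heights
# stay finite.
binom_tail_upper <- function(k, n, p) {
  pbinom(k - 1, n, p, lower.tail = FALSE)
}
binom_tail_lower <- function(k, n, p) pbinom(k, n, p)

#' Binomial probability logo of a foreground variant set
#'
#' For each position and residue, compares the residue's count in the
#' foreground set against the library background composition (uniform 1/20
#' at positions 2/4/5, 1/2 at position 3) with exact binomial tail sums (no
#' normal approximation). Letter height is the signed -log10 tail
#' probability: positive, `-log10 P(X >= k)`, for overrepresented residues;
#' negative, `-(-log10 P(X <= k))`, for underrepresented ones. The
#' significance threshold is `-log10(alpha / m)` with a Bonferroni divisor
#' `m` defaulting to the 62 tested residue-position cells (20 + 2 + 20 +
#' 20).
#'
#' @param foreground Character vector of design variants.
#' @param background Optional data frame `position`, `residue`, `p_bg`
#'   giving the background composition; defaults to the exact design
#'   composition. (An observed-T0 composition can be supplied here.)
#' @param alpha Significance level before correction.
#' @param bonferroni_m Bonferroni divisor.
#' @return Data frame of class `logo_matrix`: `position`, `residue`, `k`,
#'   `n`, `p_bg`, `height`, `threshold`, `significant`.
#' @export
binomial_logo <- function(foreground, background = NULL, alpha = 0.05,
                          bonferroni_m = 62L) {
  if (length(foreground) == 0) stop("empty foreground set")
  n <- length(foreground)
  if (is.null(background)) background <- design_background()
  threshold <- -log10(alpha / bonferroni_m)
  k <- mapply(function(pos, r) sum(residue_at(foreground, pos) == r),
              background$position, background$residue)
  p <- background$p_bg
  over <- k / n > p
  pmin_dbl <- .Machine$double.xmin
  tail_p <- ifelse(over, binom_tail_upper(k, n, p),
                   binom_tail_lower(k, n, p))
  tail_p <- pmax(tail_p, pmin_dbl)
  height <- ifelse(over, -log10(tail_p), log10(tail_p))
  height[k / n == p] <- 0
  out <- data.frame(position = background$position,
                    residue = background$residue, k = k, n = n, p_bg = p,
                    height = height, threshold = threshold,
                    significant = abs(height) >= threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("logo_matrix", "data.frame")
  out
}

#' Exact design-space background composition
#'
#' @return Data frame `position`, `residue`, `p_bg`: 1/20 per residue at
#'   positions 2, 4, 5 and 1/2 per phosphoacceptor at position 3.
#' @export
design_background <- function() {
  out <- do.call(rbind, lapply(NT_POSITIONS, function(pos) {
    levs <- if (pos == 3) PHOSPHOACCEPTORS else AA_ALPHABET
    data.frame(position = pos, residue = levs, p_bg = 1 / length(levs),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise residue covariation within a selected set
#'
#' Tests, for each residue pair (a at position i, b at position j), whether
#' the pair occurs in the selected set more or less often than expected
#' under positional independence. The expected count is `N * p_i(a) *
#' p_j(b)` with marginals taken from the selected set itself, the p-value
#' is the exact two-sided binomial test of the observed joint count against
#' `p_i(a) * p_j(b)`, and significance is Bonferroni-corrected over all
#' tested cells (those with both marginals positive) across all requested
#' position pairs.
#'
#' @param selected Character vector of design variants (the selected set).
#' @param position_pairs List of integer pairs from \{2,3,4,5\}; default all
#'   six unordered pairs.
#' @param alpha Family-wise significance level.
#' @param expected_floor Cells with expected count below this are reported
#'   with `log2_obs_exp = NA` (ratio unstable) but still tested.
#' @return Data frame of class `covariation_result`: `pos_i`, `pos_j`,
#'   `res_i`, `res_j`, `observed`, `expected`, `log2_obs_exp`, `p_value`,
#'   `significant`, plus attribute `m` (number of tested cells).
#' @export
pairwise_covariation <- function(selected, position_pairs = NULL,
                                 alpha = 0.05, expected_floor = 1) {
  if (length(selected) == 0) stop("empty selected set")
  if (is.null(position_pairs))
    position_pairs <- utils::combn(NT_POSITIONS, 2, simplify = FALSE)
  for (pp in position_pairs)
    if (!all(pp %in% NT_POSITIONS)) stop("position pair outside 2..5")
  N <- length(selected)
  rows <- list()
  for (pp in position_pairs) {
    i <- pp[1]; j <- pp[2]
    ri <- residue_at(selected, i); rj <- residue_at(selected, j)
    levi <- sort(unique(ri)); levj <- sort(unique(rj))
    pi <- table(factor(ri, levels = levi)) / N
    pj <- table(factor(rj, levels = levj)) / N
    joint <- table(factor(ri, levels = levi), factor(rj, levels = levj))
    for (a in levi) for (b in levj) {
      pe <- as.numeric(pi[a] * pj[b])
      if (pe <= 0) next
      obs <- as.integer(joint[a, b])
      expd <- N * pe
      rows[[length(rows) + 1L]] <- data.frame(
        pos_i = i, pos_j = j, res_i = a, res_j = b, observed = obs,
        expected = expd,
        log2_obs_exp = if (expd >= expected_floor && obs > 0)
          log2(obs / expd) else NA_real_,
        p_value = binom.test(obs, N, pe)$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$significant <- out$p_value < alpha / m
  rownames(out) <- NULL
  attr(out, "m") <- m
  class(out) <- c("covariation_result", "data.frame")
  out
}
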