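#' Classify variants by kinase-sensitivity quadrant
#'
#' Plots of mean enrichment with (galactose) versus without (glucose) kinase
#' induction partition variants about the origin: variants enriched on the
#' glucose axis are functional; among these, strict depletion on the
#' galactose axis marks phospho-sensitivity. A galactose score of exactly 0
#' is called resistant, so "sensitive" always means strict depletion.
#'
#' @param records An `enrichment_records` data frame carrying
#'   `limk_glu_mean` and `limk_gal_mean`.
#' @param margin Non-negative half-width of a dead zone about 0 on both
#'   axes for noise-robust calling (default 0: plain quadrants).
#' @param functional_axis Which glucose contrast gates "functional":
#'   `"limk_glu"` (the T1-T3 glucose axis, as plotted) or `"func"` (the
#'   T0-T2 contrast). The other axis' enrichment flag is reported alongside.
#' @return Data frame of class `quadrant_calls`: `variant`, `glu_score`,
#'   `gal_score`, `call` in functional_sensitive / functional_resistant /
#'   nonfunctional_depleted / nonfunctional_other, or `unclassified` when a
#'   score is missing; plus `enriched_func` (T0-T2 flag).
#' @export
classify_quadrants <- function(records, margin = 0,
                               functional_axis = c("limk_glu", "func")) {
  functional_axis <- match.arg(functional_axis)
  stopifnot(margin >= 0)
  glu <- if (functional_axis == "limk_glu") records$limk_glu_mean else
    records$func_mean
  gal <- records$limk_gal_mean
  call <- rep("unclassified", nrow(records))
  ok <- !is.na(glu) & !is.na(gal)
  functional <- ok & glu > margin
  call[functional & gal < -margin] <- "functional_sensitive"
  call[functional & gal >= -margin] <- "functional_resistant"
  call[ok & !functional & gal < -margin] <- "nonfunctional_depleted"
  call[ok & !functional & gal >= -margin] <- "nonfunctional_other"
  out <- data.frame(variant = records$variant, glu_score = glu,
                    gal_score = gal, call = call,
                    enriched_func = !is.na(records$func_mean) &
                      records$func_mean > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("quadrant_calls", "data.frame")
  out
}

#' Summarize kinase sensitivity among functional variants
#'
#' @param calls A `quadrant_calls` data frame.
#' @param stratify_by Optional position (2-5) to stratify by the residue at
#'   that position (e.g. 3 splits by Ser/Thr phosphoacceptor).
#' @return Data frame with `n_functional`, `n_sensitive` and
#'   `fraction_sensitive`, one row overall or per residue stratum.
#' @export
sensitivity_summary <- function(calls, stratify_by = NULL) {
  fun <- calls[calls$call %in% c("functional_sensitive",
                                 "functional_resistant"), ]
  if (nrow(fun) == 0) stop("no functional variants to summarize")
  tally <- function(df, label) {
    data.frame(stratum = label, n_functional = nrow(df),
               n_sensitive = sum(df$call == "functional_sensitive"),
               fraction_sensitive =
                 sum(df$call == "functional_sensitive") / nrow(df),
               stringsAsFactors = FALSE)
  }
  if (is.null(stratify_by)) return(tally(fun, "all"))
  res <- residue_at(fun$variant, stratify_by)
  out <- do.call(rbind, lapply(sort(unique(res)), function(r)
    tally(fun[res == r, ], r)))
  rownames(out) <- NULL
  out
}
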