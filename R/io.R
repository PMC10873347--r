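#' Write / read ground-truth fitness tables
#'
#' Plain-text interchange for fitness maps: columns `variant`, `w_glu`,
#' `w_gal`.
#'
#' @param fitness A `fitness_map` data frame.
#' @param path TSV path.
#' @return `write_fitness_tsv` returns `path` invisibly; `read_fitness_tsv`
#'   returns a `fitness_map` built through the `user-table` preset (which
#'   validates design-space coverage).
#' @export
write_fitness_tsv <- function(fitness, path) {
  write.table(fitness[, c("variant", "w_glu", "w_gal")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_tsv <- function(path) {
  build_fitness_map("user-table",
                    table = read.delim(path, stringsAsFactors = FALSE))
}

#' Write enrichment records to TSV
#'
#' @param records An `enrichment_records` data frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a screen design as YAML
#'
#' @param design A `screen_design`.
#' @param path YAML path.
#' @return `design_from_yaml` returns a `screen_design`.
#' @export
design_to_yaml <- function(design, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML design files")
  fields <- design[c("replicates", "cycles", "doublings_per_cycle",
                     "depth", "bottleneck_size", "induction_lag_cycles")]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML design files")
  f <- yaml::read_yaml(path)
  do.call(screen_design, f[!vapply(f, is.null, logical(1))])
}
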