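#' Describe the competitive-growth screen layout
#'
#' The screen starts from a shared T0 sample (taken just before the culture
#' is split), then propagates each replicate through serial growth-dilution
#' cycles in glucose (kinase repressed) and galactose (kinase induced),
#' sampling T1-T3 after each cycle. Cultures grow from OD600 0.1 to 1-2 per
#' cycle, about 3.5 doublings, so three cycles span roughly 10 pooled
#' doublings.
#'
#' @param replicates Number of independent replicate screens.
#' @param cycles Number of growth-dilution cycles (timepoints T1..Tcycles).
#' @param doublings_per_cycle Pooled population doublings per cycle.
#' @param depth Sequencing depth (reads) per sample.
#' @param bottleneck_size Optional integer: number of cells surviving each
#'   dilution, applied as binomial subsampling. `NULL` (default) disables the
#'   bottleneck and the simulation is deterministic given the start.
#' @param induction_lag_cycles Cycles of the galactose arm grown with
#'   glucose fitness before kinase inhibition takes effect. The default 1
#'   encodes the observed lag of 1-2 doublings between induction and
#'   depletion, which is why the kinase contrast runs T1 to T3.
#' @return List of class `screen_design`, including a `samples` data frame
#'   with one row per (replicate, condition, timepoint) sample.
#' @export
screen_design <- function(replicates = 3, cycles = 3,
                          doublings_per_cycle = 3.5, depth = 1e6,
                          bottleneck_size = NULL, induction_lag_cycles = 1) {
  stopifnot(replicates >= 1, cycles >= 1, doublings_per_cycle > 0,
            depth >= 0)
  tps <- paste0("T", 0:cycles)
  samples <- rbind(
    data.frame(replicate = seq_len(replicates), condition = "shared",
               timepoint = "T0", stringsAsFactors = FALSE),
    expand.grid(replicate = seq_len(replicates),
                condition = c("glucose", "galactose"),
                timepoint = tps[-1],
                stringsAsFactors = FALSE))
  samples$sample_id <- with(samples, paste0(
    "rep", replicate, "_",
    ifelse(condition == "shared", "", paste0(substr(condition, 1, 3), "_")),
    timepoint))
  samples <- samples[order(samples$replicate, samples$condition,
                           samples$timepoint), ]
  rownames(samples) <- NULL
  structure(list(replicates = replicates, cycles = cycles,
                 timepoints = tps,
                 doublings_per_cycle = doublings_per_cycle,
                 depth = depth, bottleneck_size = bottleneck_size,
                 induction_lag_cycles = induction_lag_cycles,
                 samples = samples),
            class = "screen_design")
}

#' Simulate serial-dilution competitive growth
#'
#' Deterministic exponential competition: after `d` pooled doublings a
#' variant's abundance is proportional to `initial * 2^(w * d)`,
#' renormalized to frequencies. Each growth-dilution cycle advances the
#' population by `design$doublings_per_cycle`; an optional binomial
#' bottleneck subsamples cells at each dilution. The galactose arm grows
#' with glucose fitness for the first `induction_lag_cycles` cycles before
#' the induced kinase becomes effective.
#'
#' @param fitness A `fitness_map` (columns `variant`, `w_glu`, `w_gal`).
#' @param design A `screen_design`.
#' @param initial Optional numeric matrix (variants x replicates) of
#'   starting frequencies; default draws each replicate's start from a
#'   gamma-perturbed uniform pool emulating a transformation bottleneck of
#'   about 1000 clones per variant.
#' @param seed Integer seed (used for the default initial pool and any
#'   bottleneck).
#' @return List of class `abundance_trajectory`: `freq` (variants x
#'   samples frequency matrix, columns summing to 1), `samples` metadata,
#'   `variants`.
#' @export
simulate_serial_growth <- function(fitness, design = screen_design(),
                                   initial = NULL, seed = 1) {
  stopifnot(inherits(design, "screen_design"))
  variants <- fitness$variant
  nv <- length(variants)
  if (any(fitness$w_glu < 0) || any(fitness$w_gal < 0))
    stop("negative fitness")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  if (is.null(initial)) {
    initial <- matrix(rgamma(nv * design$replicates, shape = 1000, rate = 1),
                      nrow = nv)
    initial <- sweep(initial, 2, colSums(initial), "/")
  } else {
    initial <- as.matrix(initial)
    if (nrow(initial) != nv) stop("initial must have one row per variant")
    if (ncol(initial) == 1L)
      initial <- initial[, rep(1L, design$replicates), drop = FALSE]
    sums <- colSums(initial)
    if (any(abs(sums - 1) > 1e-6)) stop("initial frequencies must sum to 1")
    initial <- sweep(initial, 2, sums, "/")
  }

  d <- design$doublings_per_cycle
  samples <- design$samples
  freq <- matrix(0, nrow = nv, ncol = nrow(samples),
                 dimnames = list(variants, samples$sample_id))
  for (r in seq_len(design$replicates)) {
    freq[, samples$condition == "shared" & samples$replicate == r] <-
      initial[, r]
    for (cond in c("glucose", "galactose")) {
      f <- initial[, r]
      for (k in seq_len(design$cycles)) {
        w <- if (cond == "glucose" || k <= design$induction_lag_cycles)
          fitness$w_glu else fitness$w_gal
        f <- f * 2^(w * d)
        f <- f / sum(f)
        if (!is.null(design$bottleneck_size)) {
          cells <- rmultinom(1, size = design$bottleneck_size, prob = f)[, 1]
          if (sum(cells) == 0) stop("zero total population after bottleneck")
          f <- cells / sum(cells)
        }
        sel <- samples$replicate == r & samples$condition == cond &
          samples$timepoint == paste0("T", k)
        freq[, sel] <- f
      }
    }
  }
  structure(list(freq = freq, samples = samples, variants = variants),
            class = "abundance_trajectory")
}

#' Sample sequencing reads from an abundance trajectory
#'
#' Draws each sample's per-variant read counts from a multinomial with the
#' trajectory frequencies as probabilities, modeling finite sequencing
#' depth.
#'
#' @param trajectory An `abundance_trajectory`.
#' @param depth Reads per sample (scalar or per-sample vector).
#' @param seed Integer seed.
#' @return A `count_matrix`: list with `counts` (variants x samples integer
#'   matrix), `samples` metadata and `qc` (all reads valid by construction).
#' @export
sample_sequencing_reads <- function(trajectory, depth = 1e6, seed = 1) {
  stopifnot(inherits(trajectory, "abundance_trajectory"))
  freq <- trajectory$freq
  if (any(abs(colSums(freq) - 1) > 1e-6))
    stop("trajectory frequencies are not normalized")
  depth <- rep_len(as.integer(round(depth)), ncol(freq))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  counts <- matrix(0L, nrow = nrow(freq), ncol = ncol(freq),
                   dimnames = dimnames(freq))
  for (j in seq_len(ncol(freq))) {
    if (depth[j] > 0)
      counts[, j] <- rmultinom(1, size = depth[j], prob = freq[, j])[, 1]
  }
  new_count_matrix(counts, trajectory$samples)
}

new_count_matrix <- function(counts, samples, qc = NULL) {
  if (is.null(qc)) {
    qc <- data.frame(sample_id = colnames(counts),
                     total = colSums(counts), valid = colSums(counts),
                     anchor_fail = 0L, frame_fail = 0L, codon_fail = 0L,
                     off_design = 0L, stringsAsFactors = FALSE)
    rownames(qc) <- NULL
  }
  structure(list(counts = counts, samples = samples, qc = qc),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "variants x", ncol(x$counts),
      "samples; total reads", sum(x$counts), "\n")
  invisible(x)
}

#' Simulate a complete screen in one call
#'
#' Convenience wrapper: builds the trajectory under `fitness` and `design`,
#' then samples sequencing counts at `design$depth`.
#'
#' @inheritParams simulate_serial_growth
#' @param seed Integer seed covering both stages.
#' @return List with `trajectory` and `counts`.
#' @export
simulate_screen <- function(fitness, design = screen_design(), seed = 1) {
  traj <- simulate_serial_growth(fitness, design, seed = seed)
  counts <- sample_sequencing_reads(traj, depth = design$depth,
                                    seed = seed + 1L)
  list(trajectory = traj, counts = counts)
}
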