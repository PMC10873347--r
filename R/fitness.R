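# Residue classes used by the empirical fitness preset. Position 5 demands
# aliphatic or beta-branched side chains for actin severing; charged residues
# and proline are strongly deleterious at positions 4 and 5; bulky
# hydrophobics at position 4 shield the phosphoacceptor from inactivation.
P5_STRONG <- c("I", "L", "V", "M", "T")          # aliphatic / beta-branched
P5_WEAK   <- c("A", "C", "F", "Y", "W")          # partially tolerated
P4_BAD    <- c("D", "E", "K", "R", "P")          # charged / proline
P4_BULKY  <- c("L", "F", "W")                    # confer LIMK resistance
P2_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
P2_CHARGED     <- c("D", "E", "K", "R")

#' Build a ground-truth fitness landscape for the variant library
#'
#' Assigns every one of the 16,000 design variants a relative growth rate in
#' glucose (`w_glu`, no kinase) and in galactose (`w_gal`, LIM kinase
#' induced), in units of doublings per wild-type doubling. Presets:
#'
#' \describe{
#'   \item{uniform}{all variants neutral, `w_glu = w_gal = 1` (no selection).}
#'   \item{empirical}{fitness keyed to the residue preferences found in the
#'     screen: position 5 requires aliphatic/beta-branched residues, charged
#'     residues and Pro at positions 4/5 abolish function, position 2 is
#'     nearly indiscriminate, the Gly4-Val5 pair carries a small synergy, and
#'     only Ser3 variants lacking a bulky position-4 residue are
#'     phospho-inhibitable (`w_gal < w_glu`); Thr3 variants and bulky-4 Ser3
#'     variants are kinase-resistant (`w_gal = w_glu`). A small seeded jitter
#'     makes fitness values distinct across variants.}
#'   \item{user-table}{takes `w_glu`/`w_gal` from a supplied data frame.}
#' }
#'
#' @param preset One of `"uniform"`, `"empirical"`, `"user-table"`.
#' @param seed Integer seed (required for `empirical`).
#' @param table For `user-table`: data frame with columns `variant`,
#'   `w_glu`, `w_gal` covering the full design space.
#' @param jitter_sd Standard deviation of the per-variant fitness jitter in
#'   the empirical preset (doublings per WT doubling).
#' @return Data frame of class `fitness_map` with columns `variant`,
#'   `w_glu`, `w_gal` over all 16,000 variants; attributes `preset`, `seed`.
#' @export
#' @examples
#' fm <- build_fitness_map("empirical", seed = 1)
#' subset(fm, variant %in% c("ASGV", "ATGV"))
build_fitness_map <- function(preset = c("empirical", "uniform", "user-table"),
                              seed = NULL, table = NULL, jitter_sd = 0.08) {
  preset <- match.arg(preset)
  variants <- nterm_variants()
  if (preset == "uniform") {
    fm <- data.frame(variant = variants, w_glu = 1, w_gal = 1,
                     stringsAsFactors = FALSE)
  } else if (preset == "user-table") {
    if (is.null(table)) stop("user-table preset requires `table`")
    stopifnot(all(c("variant", "w_glu", "w_gal") %in% names(table)))
    if (!setequal(table$variant, variants))
      stop("user table must cover the full 16,000-variant design space")
    fm <- table[match(variants, table$variant),
                c("variant", "w_glu", "w_gal")]
    rownames(fm) <- NULL
  } else {
    if (is.null(seed)) stop("empirical preset requires a seed")
    p2 <- residue_at(variants, 2); p3 <- residue_at(variants, 3)
    p4 <- residue_at(variants, 4); p5 <- residue_at(variants, 5)

    w <- ifelse(p5 %in% P5_STRONG, 1.0, ifelse(p5 %in% P5_WEAK, 0.55, 0.15))
    w <- w * ifelse(p4 %in% P4_BAD, 0.3, 1.0)
    w <- w + ifelse(p2 %in% P2_HYDROPHOBIC, 0.03,
                    ifelse(p2 %in% P2_CHARGED, -0.03, 0))
    w <- w + ifelse(p4 == "G" & p5 == "V", 0.10, 0)  # co-selected pair
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    w <- pmax(w + rnorm(length(w), 0, jitter_sd), 0.01)

    # Phospho-inhibition: Ser3 without a bulky residue at position 4 is
    # phosphorylated and inactivated once the kinase is induced.
    sensitive <- p3 == "S" & !(p4 %in% P4_BULKY)
    w_gal <- ifelse(sensitive, 0.1 * w, w)
    fm <- data.frame(variant = variants, w_glu = w, w_gal = w_gal,
                     stringsAsFactors = FALSE)
  }
  structure(fm, preset = preset, seed = seed, class = c("fitness_map",
                                                        "data.frame"))
}

# Seed handling: run a block under a fixed seed without clobbering the
# caller's RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
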