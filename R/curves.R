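#' Actin-binding affinities of individually characterized variants
#'
#' Pyrene-quench assay results: K_0.5 in uM with 95% CI bounds where
#' measured. Used as generator presets for synthetic binding curves.
#' @export
K05_TABLE <- data.frame(
  variant_label = c("WT", "A2L", "A2L,V5M", "A2D", "S3D", "S3D,G4F",
                    "S3D,G4L", "G4A", "G4L", "G4F", "G4K", "V5M"),
  K05 = c(0.61, 0.53, 0.85, 1.5, 4.7, 1.06, 0.39, 3.2, 0.59, 1.0, 3.5,
          0.48),
  ci_lo = c(0.54, 0.48, NA, 1.4, 4.4, 1.02, 0.37, 3.0, 0.55, 0.9, 3.3,
            0.45),
  ci_hi = c(0.67, 0.57, 0.93, 1.6, 4.9, 1.09, 0.41, 3.3, 0.62, 1.1, 3.7,
            0.52),
  stringsAsFactors = FALSE)

#' LIM-kinase Michaelis-Menten parameters of characterized substrates
#'
#' Radiolabel assay estimates (2 nM kinase, 30 C) with standard errors.
#' Used as generator presets for synthetic kinase time courses.
#' @export
KINETICS_TABLE <- data.frame(
  variant_label = c("WT", "G4F"),
  kcat = c(0.20, 0.55), kcat_se = c(0.03, 0.05),
  KM = c(9, 12), KM_se = c(3, 3),
  stringsAsFactors = FALSE)

#' Specify a binding dose-response curve
#'
#' True parameters and sampling scheme for a synthetic pyrene-quench actin
#' binding curve. Presets take K_0.5 from the characterized variants
#' (`"WT"` 0.61 uM, `"S3D"` 4.7 uM, ...); the concentration grid is a
#' two-fold serial dilution bracketing K_0.5 (plus a zero-dose point), as
#' in titrations against 1 uM polymerized actin.
#'
#' @param preset Variant label from the binding table, or `NULL` to set
#'   `K05` directly.
#' @param K05 Half-maximal binding concentration (uM).
#' @param h Hill slope (dimensionless, > 0).
#' @param top,bottom Signal plateaus (unquenched pyrene-actin alone = top;
#'   saturated cofilactin = bottom).
#' @param concentrations Dose grid in uM; default `K05 * 2^(-4..4)` plus 0.
#' @param replicates Measurements per concentration.
#' @param cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return List of class `curve_spec` (kind "binding").
#' @export
binding_curve_spec <- function(preset = NULL, K05 = 0.61, h = 2, top = 1,
                               bottom = 0, concentrations = NULL,
                               replicates = 3, cv = 0.05, seed = 1) {
  if (!is.null(preset)) {
    row <- K05_TABLE[K05_TABLE$variant_label == preset, ]
    if (nrow(row) != 1) stop("unknown binding preset: ", preset)
    K05 <- row$K05
  }
  if (K05 <= 0 || h <= 0) stop("K05 and h must be positive")
  if (cv < 0) stop("noise CV must be >= 0")
  if (is.null(concentrations)) concentrations <- c(0, K05 * 2^seq(-4, 4))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  structure(list(kind = "binding", preset = preset, K05 = K05, h = h,
                 top = top, bottom = bottom,
                 concentrations = sort(concentrations),
                 replicates = replicates, cv = cv, seed = seed),
            class = "curve_spec")
}

#' Simulate a pyrene-quench binding curve
#'
#' Expected signal follows the variable-slope sigmoid
#' `S(C) = top + (bottom - top) * C^h / (K05^h + C^h)` (signal decreases
#' with dose as filaments saturate with cofilin; the zero-dose signal
#' equals the top plateau), with multiplicative lognormal-free Gaussian
#' noise of the given CV.
#'
#' @param spec A binding `curve_spec`.
#' @return Data frame `concentration`, `replicate`, `signal`.
#' @export
simulate_binding_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"), spec$kind == "binding")
  conc <- rep(spec$concentrations, each = spec$replicates)
  mu <- hill_signal(conc, spec$K05, spec$h, spec$top, spec$bottom)
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))
  noise <- if (spec$cv > 0) 1 + rnorm(length(mu), 0, spec$cv) else 1
  data.frame(concentration = conc,
             replicate = rep(seq_len(spec$replicates),
                             length(spec$concentrations)),
             signal = mu * noise)
}

hill_signal <- function(conc, K05, h, top, bottom) {
  frac <- ifelse(conc == 0, 0, conc^h / (K05^h + conc^h))
  top + (bottom - top) * frac
}

#' Specify a kinase kinetics experiment
#'
#' True Michaelis-Menten parameters and design of a radiolabel kinase
#' time course: seven substrate concentrations spanning 50 to 0.5 uM, 2 nM
#' kinase, sampling at 5 and 10 min, with optional ATP standards at
#' 2.5, 5 and 10 nCi.
#'
#' @param preset Substrate label from the kinetics table (`"WT"`: kcat
#'   0.20 1/s, KM 9 uM; `"G4F"`: kcat 0.55 1/s, KM 12 uM), or `NULL`.
#' @param kcat Turnover number (1/s).
#' @param KM Michaelis constant (uM).
#' @param enzyme_nM Kinase concentration (nM).
#' @param substrate_uM Substrate grid (uM).
#' @param timepoints_min Sampling times (min).
#' @param cv Multiplicative noise CV on product amounts.
#' @param standards_nCi Radiolabel standards to emit (set `NULL` to omit).
#' @param standard_gain Signal units per nCi for the emitted standards.
#' @param seed Integer seed.
#' @return List of class `curve_spec` (kind "kinetics").
#' @export
kinase_curve_spec <- function(preset = NULL, kcat = 0.20, KM = 9,
                              enzyme_nM = 2,
                              substrate_uM = exp(seq(log(50), log(0.5),
                                                     length.out = 7)),
                              timepoints_min = c(5, 10), cv = 0.05,
                              standards_nCi = c(2.5, 5, 10),
                              standard_gain = 10, seed = 1) {
  if (!is.null(preset)) {
    row <- KINETICS_TABLE[KINETICS_TABLE$variant_label == preset, ]
    if (nrow(row) != 1) stop("unknown kinetics preset: ", preset)
    kcat <- row$kcat; KM <- row$KM
  }
  if (kcat <= 0 || KM <= 0 || enzyme_nM <= 0)
    stop("kcat, KM and enzyme concentration must be positive")
  if (cv < 0) stop("noise CV must be >= 0")
  structure(list(kind = "kinetics", preset = preset, kcat = kcat, KM = KM,
                 enzyme_nM = enzyme_nM, substrate_uM = substrate_uM,
                 timepoints_min = timepoints_min, cv = cv,
                 standards_nCi = standards_nCi,
                 standard_gain = standard_gain, seed = seed),
            class = "curve_spec")
}

#' Simulate a radiolabel kinase time course
#'
#' Initial-rate product formation: `product(t) = kcat * E * S / (KM + S) *
#' t`, with multiplicative noise. The specification is rejected if any
#' noiseless product would exceed 10% of its substrate (initial-rate
#' validity bound). Standards, when requested, are emitted as (nCi, signal)
#' pairs with the spec's gain.
#'
#' @param spec A kinetics `curve_spec`.
#' @return List of class `kinetics_dataset`: `timecourse` (data frame
#'   `substrate_uM`, `time_min`, `product_uM`), `standards` (data frame
#'   `nCi`, `signal`, or NULL), `enzyme_nM`.
#' @export
simulate_kinase_timecourse <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"), spec$kind == "kinetics")
  E <- spec$enzyme_nM / 1000  # uM
  S <- spec$substrate_uM
  grid <- expand.grid(substrate_uM = S, time_min = spec$timepoints_min)
  v <- spec$kcat * E * grid$substrate_uM / (spec$KM + grid$substrate_uM)
  mu <- v * grid$time_min * 60  # uM product
  if (any(mu > 0.1 * grid$substrate_uM))
    stop("timepoints violate the initial-rate bound (product > 10% of S)")
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))
  noise <- if (spec$cv > 0) 1 + rnorm(length(mu), 0, spec$cv) else 1
  grid$product_uM <- mu * noise
  standards <- NULL
  if (!is.null(spec$standards_nCi)) {
    snoise <- if (spec$cv > 0)
      1 + rnorm(length(spec$standards_nCi), 0, spec$cv) else 1
    standards <- data.frame(nCi = spec$standards_nCi,
                            signal = spec$standards_nCi *
                              spec$standard_gain * snoise)
  }
  structure(list(timecourse = grid, standards = standards,
                 enzyme_nM = spec$enzyme_nM, spec = spec),
            class = "kinetics_dataset")
}
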