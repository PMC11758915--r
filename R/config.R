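#' Configuration for the synthetic mother-infant cohort generator
#'
#' Collects every knob of the generative model in one validated list. The
#' defaults describe a small breastfed-majority cohort of vaginally born,
#' antibiotic-free infants sampled at one and six months, with their mothers
#' sampled prenatally: \emph{B. longum} subsp. \emph{longum} dominant at one
#' month and replaced by subsp. \emph{infantis} at six months, species-specific
#' vertical-transmission rates (29\% for BLlongum; none detected for
#' BLinfantis and \emph{B. breve} at one month), and three HMG-utilization
#' archetypes among \emph{B. longum} genomes.
#'
#' Abundances are percentages of the total community (0-100 scale). Infant
#' abundances are generated on the log scale around a taxon-by-timepoint
#' baseline — multiplied by \code{exp(maternal_effect * maternal abundance)}
#' and log-normal noise — then shifted additively (percentage points) by the
#' feeding effect of the pair's feeding type and by \code{sharing_bonus} when
#' the maternal strain was transmitted, truncated at zero, and closed to 100\%
#' with an \code{other_bacteria} remainder.
#'
#' @param n_pairs number of mother-infant pairs (>= 1).
#' @param taxa character vector of bifidobacterial taxa; must contain
#'   \code{BLlongum}, \code{BLinfantis}, \code{B.breve}, \code{B.bifidum},
#'   \code{B.adolescentis}, \code{B.pseudocatenulatum} and \code{other}
#'   (the non-focal bifidobacteria catch-all).
#' @param baselines named list (\code{mother}, \code{1m}, \code{6m}) of named
#'   numeric vectors: median relative abundance (\%) per taxon when carried.
#' @param carriage_prob named list (same keys) of per-taxon probabilities that
#'   the taxon colonizes at all in that sample.
#' @param transmission_prob named per-taxon probability of mother-to-infant
#'   strain transmission (detected sharing at one month, given maternal
#'   carriage).
#' @param persistence_prob probability that a strain shared at one month is
#'   still detected as shared at six months.
#' @param maternal_effect additive shift in infant log-abundance per
#'   percentage point of maternal abundance of the same taxon.
#' @param sharing_bonus additive shift (percentage points) in infant abundance
#'   of a taxon whose maternal strain was transmitted.
#' @param feeding_probs named probabilities for \code{breast}, \code{formula},
#'   \code{mixed} feeding types.
#' @param feeding_effects named list (feeding type -> named per-taxon additive
#'   effect in percentage points).
#' @param feeding_frequency_mean Poisson mean of daily milk feeds.
#' @param archetype_defs named list of three mean copy-number vectors over gene
#'   families (see [default_archetypes()]).
#' @param archetype_probs mixing proportions of the three archetypes among
#'   simulated MAGs (normalized internally).
#' @param noise_sd log-scale abundance noise SD (also the copy-number noise SD
#'   of the MAG generator); >= 0.
#' @param seed integer RNG seed.
#'
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_pairs = 24,
                              taxa = c("BLlongum", "BLinfantis", "B.breve",
                                       "B.bifidum", "B.adolescentis",
                                       "B.pseudocatenulatum", "other"),
                              baselines = NULL,
                              carriage_prob = NULL,
                              transmission_prob = NULL,
                              persistence_prob = 0.7,
                              maternal_effect = 0.15,
                              sharing_bonus = 10,
                              feeding_probs = c(breast = 0.5, formula = 0.25,
                                                mixed = 0.25),
                              feeding_effects = NULL,
                              feeding_frequency_mean = 8,
                              archetype_defs = default_archetypes(),
                              archetype_probs = c(`BLinfantis-HMG` = 14,
                                                  `BLlongum-HMGcomplex` = 25,
                                                  `BLlongum-HMGsimple` = 24),
                              noise_sd = 0.5,
                              seed = 1L) {
  tx <- function(...) {
    v <- c(...)
    stopifnot(length(v) == length(taxa))
    setNames(v, taxa)
  }
  required <- c("BLlongum", "BLinfantis", "B.breve", "B.bifidum",
                "B.adolescentis", "B.pseudocatenulatum", "other")
  if (!all(required %in% taxa))
    stop("`taxa` must include: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (is.null(baselines) || is.null(carriage_prob) ||
      is.null(transmission_prob) || is.null(feeding_effects)) {
    if (!identical(sort(taxa), sort(required)))
      stop("defaults for baselines/carriage/transmission/feeding are only ",
           "defined for the standard seven taxa; supply them explicitly for ",
           "a custom taxa set", call. = FALSE)
  }
  d <- function(BLlongum, BLinfantis, B.breve, B.bifidum, B.adolescentis,
                B.pseudocatenulatum, other) {
    setNames(c(BLlongum, BLinfantis, B.breve, B.bifidum, B.adolescentis,
               B.pseudocatenulatum, other)[match(taxa, required)], taxa)
  }
  baselines <- baselines %||% list(
    mother = d(1.5, 0.02, 0.05, 0.3, 1.0, 0.4, 0.5),
    `1m`   = d(35, 1.5, 15, 8, 1.0, 1.0, 1.0),
    `6m`   = d(8, 40, 10, 6, 1.5, 1.0, 1.5))
  carriage_prob <- carriage_prob %||% list(
    mother = d(0.90, 0.10, 0.30, 0.60, 0.80, 0.70, 0.90),
    `1m`   = d(0.85, 0.08, 0.31, 0.38, 0.50, 0.50, 0.90),
    `6m`   = d(0.67, 0.71, 0.71, 0.52, 0.55, 0.50, 0.90))
  transmission_prob <- transmission_prob %||%
    d(0.29, 0, 0, 0.60, 0.80, 0.80, 0.10)
  feeding_effects <- feeding_effects %||% list(
    breast  = d(8, 4, 0, 0, 0, 0, 0),
    formula = d(-8, -4, 0, 0, 0, 0, 0),
    mixed   = d(0, 0, 0, 0, 0, 0, 0))

  config <- list(
    n_pairs = as.integer(n_pairs), taxa = taxa, baselines = baselines,
    carriage_prob = carriage_prob, transmission_prob = transmission_prob,
    persistence_prob = persistence_prob, maternal_effect = maternal_effect,
    sharing_bonus = sharing_bonus, feeding_probs = feeding_probs,
    feeding_effects = feeding_effects,
    feeding_frequency_mean = feeding_frequency_mean,
    archetype_defs = archetype_defs, archetype_probs = archetype_probs,
    noise_sd = noise_sd, seed = as.integer(seed))
  class(config) <- "simulation_config"
  validate_simulation_config(config)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the generator configuration: probabilities in
#' [0, 1], nonnegative noise, finite effect sizes, archetypes sharing one gene
#' key set with nonnegative means.
#'
#' @param config a \code{"simulation_config"} list.
#' @return \code{config}, invisibly unchanged, or an error.
#' @export
validate_simulation_config <- function(config) {
  stopifnot(is.list(config))
  if (config$n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  if (!is.finite(config$noise_sd) || config$noise_sd < 0)
    stop("noise_sd must be a nonnegative finite number", call. = FALSE)
  probs <- c(unlist(config$carriage_prob), config$transmission_prob,
             config$persistence_prob, config$feeding_probs)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  eff <- c(config$maternal_effect, config$sharing_bonus,
           unlist(config$feeding_effects))
  if (any(!is.finite(eff)))
    stop("effect sizes must be finite", call. = FALSE)
  if (any(unlist(config$baselines) < 0))
    stop("baseline abundances must be >= 0", call. = FALSE)
  keys <- lapply(config$archetype_defs, names)
  if (length(config$archetype_defs) < 1L ||
      !all(vapply(keys, identical, logical(1), keys[[1]])))
    stop("archetype_defs must share an identical set of gene-family keys",
         call. = FALSE)
  if (any(unlist(config$archetype_defs) < 0))
    stop("archetype means must be >= 0", call. = FALSE)
  for (tp in names(config$baselines)) {
    if (!all(config$taxa %in% names(config$baselines[[tp]])))
      stop("baselines must name every taxon at timepoint ", tp, call. = FALSE)
  }
  invisible(config)
}
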