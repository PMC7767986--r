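#' Simulation configuration for the two-breed + crossbred population
#'
#' Bundles every parameter of the synthetic population: marker and QTL
#' counts, breed divergence, group sizes, the trait's variance-component
#' parameters, and the record/daughter-count ranges that drive DRP
#' reliabilities. Defaults emulate the structure of a Holstein-dominated
#' dairy population with a Jersey minority and three crossbred cow groups
#' (75:25, 50:50, 25:75 Holstein:Jersey), at desk scale (about 3,000
#' animals, 5,000 markers, 300 QTL).
#'
#' @param seed integer seed governing every random draw downstream.
#' @param n_snp number of biallelic SNPs.
#' @param n_qtl number of causal loci (a subset of the SNPs).
#' @param fst Wright's fixation index between the two pure breeds;
#'   allele frequencies diverge under the Balding-Nichols model.
#' @param ancestral_freq_range range of ancestral allele frequencies
#'   (uniform draw).
#' @param group_sizes named integer vector with elements `H_bull`,
#'   `J_bull`, `H_cow`, `J_cow`, `X75_cow`, `X50_cow`, `X25_cow`.
#' @param h2 narrow-sense heritability of the trait (default 0.33).
#' @param t repeatability (default 0.56); must satisfy `t >= h2`.
#' @param c proportion of genetic variance not explained by markers
#'   (default 0.2), entering the DRP weighting formulas.
#' @param sigma2_g additive genetic variance; trait effects are rescaled so
#'   the true-breeding-value variance in pure Holsteins equals this.
#' @param records_range integer range for cow lactation-record counts n.
#' @param daughters_range integer range for bull daughter counts p.
#' @param breed_effect_J non-genetic mean shift applied in proportion to
#'   Jersey fraction, making the breed-group fixed effect identifiable.
#' @param sex_effect non-genetic mean shift for bulls, making the sex
#'   fixed effect identifiable.
#' @param traits character vector of trait names to simulate (each trait
#'   gets its own QTL effect draw and DRP noise; genotypes are shared).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_snp = 5000L,
                       n_qtl = 300L,
                       fst = 0.10,
                       ancestral_freq_range = c(0.05, 0.95),
                       group_sizes = c(H_bull = 400L, J_bull = 110L,
                                       H_cow = 700L, J_cow = 300L,
                                       X75_cow = 700L, X50_cow = 600L,
                                       X25_cow = 150L),
                       h2 = 0.33, t = 0.56, c = 0.2,
                       sigma2_g = 1,
                       records_range = c(1L, 10L),
                       daughters_range = c(20L, 300L),
                       breed_effect_J = 0.5,
                       sex_effect = 0.2,
                       traits = c("milk", "fat", "protein")) {
  cfg <- list(seed = as.integer(seed), n_snp = as.integer(n_snp),
              n_qtl = as.integer(n_qtl), fst = fst,
              ancestral_freq_range = ancestral_freq_range,
              group_sizes = group_sizes, h2 = h2, t = t, c = c,
              sigma2_g = sigma2_g,
              records_range = as.integer(records_range),
              daughters_range = as.integer(daughters_range),
              breed_effect_J = breed_effect_J, sex_effect = sex_effect,
              traits = traits)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  req <- c("H_bull", "J_bull", "H_cow", "J_cow",
           "X75_cow", "X50_cow", "X25_cow")
  if (!all(req %in% names(cfg$group_sizes)))
    stop("group_sizes must name all of: ", paste(req, collapse = ", "))
  if (any(cfg$group_sizes < 0)) stop("group sizes must be >= 0")
  if (cfg$n_qtl > cfg$n_snp) stop("n_qtl must not exceed n_snp")
  if (!is.finite(cfg$fst) || cfg$fst < 0 || cfg$fst > 0.5)
    stop("fst must lie in [0, 0.5]")
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must lie in (0, 1)")
  if (cfg$t < cfg$h2 || cfg$t >= 1)
    stop("repeatability t must satisfy h2 <= t < 1")
  if (cfg$c < 0 || cfg$c >= 1) stop("c must lie in [0, 1)")
  if (cfg$sigma2_g <= 0) stop("sigma2_g must be positive")
  fr <- cfg$ancestral_freq_range
  if (length(fr) != 2 || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    stop("ancestral_freq_range must be an increasing interval inside (0, 1)")
  if (any(cfg$records_range < 1) || any(cfg$daughters_range < 1))
    stop("record and daughter counts must be >= 1")
  invisible(cfg)
}

#' Four-component mixture prior on SNP effects
#'
#' The BayesR-style prior: each SNP effect comes from one of four normal
#' components with variances expressed as fractions of the additive genetic
#' variance; the first component is a point mass at zero. Defaults follow
#' the standard dairy calibration: proportions 0.94, 0.049, 0.01, 0.001
#' with variance fractions 0, 1e-4, 1e-3, 1e-2, i.e. a 94% prior chance of
#' zero contribution.
#'
#' @param proportions length-4 vector of mixing proportions (sums to 1).
#' @param variance_fractions length-4 non-decreasing vector of per-SNP
#'   variance as a fraction of `sigma2_g`; first element must be 0.
#' @return object of class `mixture_prior`.
#' @export
mixture_prior <- function(proportions = c(0.94, 0.049, 0.01, 0.001),
                          variance_fractions = c(0, 1e-4, 1e-3, 1e-2)) {
  if (length(proportions) != 4L || length(variance_fractions) != 4L)
    stop("mixture prior has exactly four components")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("mixture proportions must sum to 1")
  if (any(proportions < 0)) stop("mixture proportions must be non-negative")
  if (variance_fractions[1] != 0)
    stop("first component must be the null (variance fraction 0)")
  if (is.unsorted(variance_fractions))
    stop("variance fractions must be non-decreasing")
  structure(list(proportions = proportions,
                 variance_fractions = variance_fractions),
            class = "mixture_prior")
}

#' Variance-ratio parameters for DRP weighting
#'
#' Houses the heritability, repeatability and unexplained-variance fraction
#' used by [cow_weight()] and [bull_weight()] and by the GBLUP shrinkage
#' default.
#'
#' @param h2 heritability in (0, 1); default 0.33.
#' @param t repeatability in `[h2, 1)`; default 0.56.
#' @param c proportion of genetic variance not captured by markers, in
#'   (0, 1); default 0.2.
#' @return object of class `weight_params`.
#' @export
weight_params <- function(h2 = 0.33, t = 0.56, c = 0.2) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (t < h2 || t >= 1) stop("t must satisfy h2 <= t < 1")
  if (c <= 0 || c >= 1) stop("c must lie in (0, 1)")
  structure(list(h2 = h2, t = t, c = c), class = "weight_params")
}
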