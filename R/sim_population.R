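#' Breed allele frequencies under the Balding-Nichols model
#'
#' Given ancestral frequencies p and a divergence level FST, draws each
#' breed's frequency independently from Beta(p (1-FST)/FST,
#' (1-p)(1-FST)/FST), which has mean p and variance FST p (1-p). At
#' FST = 0 both breeds get the ancestral frequencies exactly.
#'
#' @param p_ancestral vector of ancestral frequencies, each in (0, 1).
#' @param fst divergence in `[0, 0.5]`.
#' @param seed integer seed.
#' @return list with components `H` and `J`, frequency vectors clipped to
#'   `[0.001, 0.999]`.
#' @export
draw_breed_allele_freqs <- function(p_ancestral, fst, seed = 1L) {
  bad <- which(!is.finite(p_ancestral) | p_ancestral <= 0 | p_ancestral >= 1)
  if (length(bad))
    stop("ancestral frequencies out of (0,1) at index ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.finite(fst) || fst < 0 || fst > 0.5)
    stop("fst must be finite and in [0, 0.5], got ", fst)
  if (fst == 0) return(list(H = p_ancestral, J = p_ancestral))
  shape_scale <- (1 - fst) / fst
  clip <- function(x) pmin(pmax(x, 0.001), 0.999)
  set.seed(seed)
  f_H <- stats::rbeta(length(p_ancestral), p_ancestral * shape_scale,
                      (1 - p_ancestral) * shape_scale)
  f_J <- stats::rbeta(length(p_ancestral), p_ancestral * shape_scale,
                      (1 - p_ancestral) * shape_scale)
  list(H = clip(f_H), J = clip(f_J))
}

# One gamete per animal per locus from breed frequency vector p: matrix of
# 0/1 allele counts, n animals x m loci.
.gamete_from_freq <- function(n, p) {
  matrix(rbinom(n * length(p), 1L, rep(p, each = n)), nrow = n)
}

# Gamete transmitted by a simulated F1 parent: the parent carries one
# H-derived and one J-derived allele per locus and transmits one of the two
# at random (loci independent; no recombination map).
.gamete_from_f1_parent <- function(n, p_H, p_J) {
  aH <- .gamete_from_freq(n, p_H)
  aJ <- .gamete_from_freq(n, p_J)
  pick_H <- matrix(runif(n * length(p_H)) < 0.5, nrow = n)
  ifelse(pick_H, aH, aJ)
}

# Gametes transmitted by recorded sires: row i is one gamete from the
# sire genotype in dosage row sire_rows[i]. For an unphased HWE genotype
# the transmitted allele at a heterozygous locus is a fair coin.
.gamete_from_sires <- function(sire_dosages, sire_rows) {
  d <- sire_dosages[sire_rows, , drop = FALSE]
  het <- d == 1L
  out <- (d == 2L) * 1L
  out[het] <- rbinom(sum(het), 1L, 0.5)
  out
}

#' Simulate genotypes for purebred and crossbred groups
#'
#' Bulls get Hardy-Weinberg dosages Binomial(2, p_breed). Cows receive
#' one gamete from a recorded sire drawn from the simulated bull pool of
#' the appropriate breed and one maternal gamete: from the breed's
#' frequencies for purebred cows; from the other breed for F1 (50:50)
#' cows (Holstein sire, Jersey-population dam); from a simulated,
#' unrecorded F1 dam for the 75:25 (Holstein sire) and 25:75 (Jersey
#' sire) backcrosses. Recorded sires create the paternal half-sib family
#' structure the reference/validation split rules operate on; dams are
#' never shared, so no full sibs or maternal half sibs arise. When a
#' required bull pool is empty the maternal-style gamete is drawn from
#' population frequencies instead and the sire is unrecorded.
#'
#' @param freqs_by_breed list with `H` and `J` frequency vectors (as from
#'   [draw_breed_allele_freqs()]).
#' @param group_sizes named counts (see [sim_config()]).
#' @param seed integer seed.
#' @return a `geno_matrix` plus attributes consumed by
#'   [simulate_population()] (`animals` with `sire_id`).
#' @export
simulate_genotypes <- function(freqs_by_breed, group_sizes, seed = 1L) {
  if (length(group_sizes) == 0) stop("group_sizes must not be empty")
  p_H <- freqs_by_breed$H; p_J <- freqs_by_breed$J
  stopifnot(length(p_H) == length(p_J), all(p_H >= 0 & p_H <= 1),
            all(p_J >= 0 & p_J <= 1))
  gs <- function(nm) if (nm %in% names(group_sizes))
    as.integer(group_sizes[[nm]]) else 0L
  set.seed(seed)
  blocks <- list()
  meta <- list()
  add <- function(n, group, sex, prefix, maker) {
    if (n <= 0) return(invisible())
    made <- maker(n)
    d <- if (is.list(made)) made$dosages else made
    sire <- if (is.list(made)) made$sire_id else rep(NA_character_, n)
    rownames(d) <- sprintf("%s_%04d", prefix, seq_len(n))
    blocks[[length(blocks) + 1L]] <<- d
    meta[[length(meta) + 1L]] <<- data.frame(
      animal_id = rownames(d), breed_group = group, sex = sex,
      sire_id = sire, stringsAsFactors = FALSE)
  }
  pure <- function(p) function(n) .gamete_from_freq(n, p) +
    .gamete_from_freq(n, p)
  # bulls first: they are the sire pool for every cow group
  add(gs("H_bull"), "H", "M", "H_bull", pure(p_H))
  add(gs("J_bull"), "J", "M", "J_bull", pure(p_J))
  bull_pool <- function(breed) {
    ix <- which(vapply(meta, function(m)
      m$breed_group[1] == breed && m$sex[1] == "M", logical(1)))
    if (!length(ix)) return(NULL)
    list(dosages = blocks[[ix]], ids = meta[[ix]]$animal_id)
  }
  sired <- function(sire_breed, dam_gamete) function(n) {
    pool <- bull_pool(sire_breed)
    if (is.null(pool)) {
      p_sire <- if (sire_breed == "H") p_H else p_J
      return(.gamete_from_freq(n, p_sire) + dam_gamete(n))
    }
    rows <- sample.int(length(pool$ids), n, replace = TRUE)
    list(dosages = .gamete_from_sires(pool$dosages, rows) + dam_gamete(n),
         sire_id = pool$ids[rows])
  }
  add(gs("H_cow"), "H", "F", "H_cow",
      sired("H", function(n) .gamete_from_freq(n, p_H)))
  add(gs("J_cow"), "J", "F", "J_cow",
      sired("J", function(n) .gamete_from_freq(n, p_J)))
  add(gs("X75_cow"), "75H25J", "F", "X75_cow",
      sired("H", function(n) .gamete_from_f1_parent(n, p_H, p_J)))
  add(gs("X50_cow"), "50H50J", "F", "X50_cow",
      sired("H", function(n) .gamete_from_freq(n, p_J)))
  add(gs("X25_cow"), "25H75J", "F", "X25_cow",
      sired("J", function(n) .gamete_from_f1_parent(n, p_H, p_J)))
  if (!length(blocks)) stop("all group sizes are zero")
  d <- do.call(rbind, blocks)
  colnames(d) <- sprintf("snp_%05d", seq_len(ncol(d)))
  map <- data.frame(snp_id = colnames(d), chrom = "1",
                    pos = seq_len(ncol(d)), stringsAsFactors = FALSE)
  g <- geno_matrix(d, map = map, freq_source = "simulated")
  attr(g, "animals") <- do.call(rbind, meta)
  g
}

#' Draw sparse QTL effects from the mixture prior
#'
#' Chooses `n_qtl` SNP indices uniformly without replacement, draws each
#' QTL effect from the non-null mixture components (proportions
#' renormalized over components 2-4, variances = fraction x `sigma2_g`),
#' and sets every other SNP to exactly zero. When reference dosages are
#' supplied the effects are rescaled so the realized true-breeding-value
#' variance in that set equals `sigma2_g` exactly.
#'
#' @param n_snp total SNP count.
#' @param n_qtl causal SNP count.
#' @param prior a [mixture_prior()].
#' @param sigma2_g target additive genetic variance (> 0).
#' @param seed integer seed.
#' @param ref_dosages optional dosage matrix (e.g. pure-Holstein animals)
#'   used to rescale; with fewer than 2 rows no rescaling occurs.
#' @return numeric effect vector of length `n_snp`.
#' @export
assign_qtl_effects <- function(n_snp, n_qtl, prior, sigma2_g, seed = 1L,
                               ref_dosages = NULL) {
  if (sigma2_g <= 0) stop("sigma2_g must be positive")
  if (n_qtl > n_snp) stop("n_qtl must not exceed n_snp")
  effects <- numeric(n_snp)
  if (n_qtl == 0) return(effects)
  set.seed(seed)
  qtl <- sample.int(n_snp, n_qtl)
  pi_nn <- prior$proportions[-1]
  if (sum(pi_nn) <= 0) stop("prior places no mass on non-null components")
  pi_nn <- pi_nn / sum(pi_nn)
  comp <- sample(2:4, n_qtl, replace = TRUE, prob = pi_nn)
  sds <- sqrt(prior$variance_fractions * sigma2_g)
  effects[qtl] <- rnorm(n_qtl, 0, sds[comp])
  if (!is.null(ref_dosages) && nrow(ref_dosages) >= 2) {
    tbv <- as.vector(ref_dosages %*% effects)
    v <- var(tbv)
    if (v > 0) effects <- effects * sqrt(sigma2_g / v)
  }
  effects
}

#' Simulate DRP-like phenotypes with reliabilities and weights
#'
#' Each animal's deregressed proof is its true breeding value plus noise
#' calibrated to the reliability implied by its information content:
#' `r2 = n h2 / (1 + (n-1) t)` for a cow with n lactation records and
#' `r2 = p / (p + (4 - h2)/h2)` for a bull with p daughters, with noise
#' variance `sigma2_g (1 - r2) / r2`. Non-genetic fixed effects (sex and a
#' Jersey-fraction-proportional breed shift) are added so the model's
#' fixed effects are identifiable. The matching DRP weight is attached
#' via [cow_weight()] / [bull_weight()].
#'
#' @param population a `population` (see [simulate_population()]).
#' @param cfg the `sim_config` used to build it.
#' @param seed integer seed.
#' @return a DRP table: data.frame with one row per animal per trait and
#'   columns `animal_id`, `trait`, `drp`, `sex`, `breed_group`, `n_eff`,
#'   `reliability`, `weight`, `tbv`.
#' @export
simulate_drp <- function(population, cfg, seed = 1L) {
  an <- population$animals
  n_anim <- nrow(an)
  wp <- weight_params(cfg$h2, cfg$t, cfg$c)
  set.seed(seed)
  n_eff <- integer(n_anim)
  cows <- an$sex == "F"
  n_eff[cows] <- sample(cfg$records_range[1]:cfg$records_range[2],
                        sum(cows), replace = TRUE)
  n_eff[!cows] <- sample(cfg$daughters_range[1]:cfg$daughters_range[2],
                         sum(!cows), replace = TRUE)
  r2 <- ifelse(cows,
               n_eff * cfg$h2 / (1 + (n_eff - 1) * cfg$t),
               n_eff / (n_eff + (4 - cfg$h2) / cfg$h2))
  if (any(r2 <= 0)) stop("zero reliability: every animal needs information")
  w <- ifelse(cows, cow_weight(wp, n_eff), bull_weight(wp, n_eff))
  fixed <- cfg$sex_effect * (an$sex == "M") +
    cfg$breed_effect_J * population$breed_fractions_true[, "fJ"]
  out <- lapply(names(population$traits), function(tr) {
    tbv <- population$traits[[tr]]$tbv
    noise <- rnorm(n_anim, 0, sqrt(cfg$sigma2_g * (1 - r2) / r2))
    data.frame(animal_id = an$animal_id, trait = tr,
               drp = fixed + tbv + noise,
               sex = an$sex, breed_group = an$breed_group,
               n_eff = n_eff, reliability = r2, weight = w, tbv = tbv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate the full two-breed + crossbred population
#'
#' Orchestrates [draw_breed_allele_freqs()], [simulate_genotypes()],
#' [assign_qtl_effects()] (per trait) and [simulate_drp()], and assigns
#' the abstract marker panels: `tag` (all non-QTL markers, emulating an
#' array panel near but not at causal variants), `causal_enriched` (same
#' size, containing every QTL, emulating a variant-selected panel), with
#' the full SNP set available for a pruned dense panel.
#'
#' @param cfg a [sim_config()].
#' @return object of class `population`: list with `genotypes`
#'   (`geno_matrix` incl. panel flags in the map), `animals` (data.frame
#'   with sex/breed group), `breed_fractions_true` (n x 2 matrix),
#'   `traits` (per trait: `qtl_effects`, `tbv`), `drp` (DRP table over
#'   all traits), `true_breeding_values` and `qtl_effects` (first trait,
#'   for convenience), `freqs_by_breed`, `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  p_anc <- runif(cfg$n_snp, cfg$ancestral_freq_range[1],
                 cfg$ancestral_freq_range[2])
  freqs <- draw_breed_allele_freqs(p_anc, cfg$fst, seed = cfg$seed + 1L)
  g <- simulate_genotypes(freqs, cfg$group_sizes, seed = cfg$seed + 2L)
  an <- attr(g, "animals")
  attr(g, "animals") <- NULL
  fr <- GROUP_FRACTIONS[an$breed_group, , drop = FALSE]
  rownames(fr) <- an$animal_id
  h_ids <- an$animal_id[an$breed_group == "H"]
  prior <- mixture_prior()
  traits <- list()
  qtl_union <- logical(cfg$n_snp)
  for (i in seq_along(cfg$traits)) {
    eff <- assign_qtl_effects(cfg$n_snp, cfg$n_qtl, prior, cfg$sigma2_g,
                              seed = cfg$seed + 10L + i,
                              ref_dosages = g$dosages[h_ids, , drop = FALSE])
    traits[[cfg$traits[i]]] <- list(qtl_effects = eff,
                                    tbv = as.vector(g$dosages %*% eff))
    qtl_union <- qtl_union | eff != 0
  }
  # panels: tag excludes QTL; causal_enriched keeps all QTL and fills with
  # random non-QTL markers up to the tag panel's size
  set.seed(cfg$seed + 5L)
  non_qtl <- which(!qtl_union)
  tag <- !qtl_union
  n_fill <- max(0L, sum(tag) - sum(qtl_union))
  fill <- sample(non_qtl, min(n_fill, length(non_qtl)))
  causal <- qtl_union
  causal[fill] <- TRUE
  g$map$qtl <- qtl_union
  g$map$tag <- tag
  g$map$causal_enriched <- causal
  g$map$custom <- FALSE
  pop <- structure(list(genotypes = g, animals = an,
                        breed_fractions_true = fr, traits = traits,
                        true_breeding_values = traits[[1]]$tbv,
                        qtl_effects = traits[[1]]$qtl_effects,
                        freqs_by_breed = freqs, config = cfg),
                   class = "population")
  pop$drp <- simulate_drp(pop, cfg, seed = cfg$seed + 3L)
  pop
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d animals x %d SNPs; groups: %s\n",
              nrow(x$animals), ncol(x$genotypes$dosages),
              paste(sprintf("%s=%d", names(table(x$animals$breed_group)),
                            table(x$animals$breed_group)), collapse = " ")))
  invisible(x)
}
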