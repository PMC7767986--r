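#' Breed-proportion weighted-average GEBV for crossbreds
#'
#' Combines predictions from two purebred reference populations:
#' `GEBV_i = fH_i * gebv_H_i + fJ_i * gebv_J_i`, the weighted-average
#' approach used for crossbred cows when crossbreds cannot contribute to
#' the reference.
#'
#' @param gebv_H,gebv_J named GEBV vectors from the Holstein-only and
#'   Jersey-only reference fits; must cover every target animal.
#' @param fractions breed-composition data.frame (`animal_id`, `fH`,
#'   `fJ`) defining the per-animal proportions.
#' @return named vector of combined GEBV for `fractions$animal_id`.
#' @export
wa_gebv <- function(gebv_H, gebv_J, fractions) {
  ids <- fractions$animal_id
  missH <- setdiff(ids, names(gebv_H))
  missJ <- setdiff(ids, names(gebv_J))
  if (length(missH) || length(missJ))
    stop("missing component GEBV for animal(s): ",
         paste(head(c(missH, missJ), 5), collapse = ", "))
  if (any(abs(fractions$fH + fractions$fJ - 1) > 1e-8))
    stop("breed fractions must lie on the 2-simplex")
  out <- fractions$fH * gebv_H[ids] + fractions$fJ * gebv_J[ids]
  names(out) <- ids
  out
}

#' Prediction accuracy: Pearson correlation of GEBV with DRP
#'
#' @param gebv,drp numeric vectors over the same animals (>= 2).
#' @return Pearson correlation; `NA` with a warning if either vector has
#'   zero variance.
#' @export
accuracy <- function(gebv, drp) {
  stopifnot(length(gebv) == length(drp), length(gebv) >= 2,
            all(is.finite(gebv)), all(is.finite(drp)))
  if (sd(gebv) == 0 || sd(drp) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  cor(gebv, drp)
}

#' Prediction bias: slope of DRP regressed on GEBV
#'
#' `cov(drp, gebv) / var(gebv)`; predictions are least biased when the
#' slope is closest to one (slopes below one indicate inflated GEBV
#' spread).
#'
#' @inheritParams accuracy
#' @return regression slope; `NA` with a warning for zero GEBV variance.
#' @export
bias <- function(gebv, drp) {
  stopifnot(length(gebv) == length(drp), length(gebv) >= 2)
  if (var(gebv) == 0) {
    warning("zero GEBV variance: bias undefined")
    return(NA_real_)
  }
  cov(drp, gebv) / var(gebv)
}

#' SNP mask for an abstract marker panel
#'
#' Panels abstract the marker sets of dairy genotyping practice: `tag`
#' (markers excluding causal loci, like a standard array), `
#' causal_enriched` (a same-size set containing the causal loci, like a
#' sequence-selected custom panel), and `pruned_dense` (the full SNP set
#' LD-pruned at r-squared 0.95).
#'
#' @param population a `population`.
#' @param panel one of `"tag"`, `"causal_enriched"`, `"pruned_dense"`.
#' @return logical SNP mask over the population's markers.
#' @export
panel_snps <- function(population,
                       panel = c("tag", "causal_enriched",
                                 "pruned_dense")) {
  panel <- match.arg(panel)
  map <- population$genotypes$map
  switch(panel,
         tag = map$tag,
         causal_enriched = map$causal_enriched,
         pruned_dense = {
           pruned <- ld_prune(population$genotypes, r2_threshold = 0.95)
           map$snp_id %in% pruned$map$snp_id
         })
}

# GEBV for one (design, method, panel, trait) cell, given the design's
# panel genotypes and precomputed GRM.
.fit_cell <- function(population, design, method, panel_geno, grm, trait,
                      params, prior, model_opts, seed) {
  ids <- c(design$reference_ids, design$validation_ids)
  gsub <- subset_geno(panel_geno, animals = ids)
  drp_tr <- population$drp[population$drp$trait == trait, ]
  drp_ref <- drp_tr[drp_tr$animal_id %in% design$reference_ids, ]
  if (method == "gblup") {
    fit <- fit_wgblup(drp_ref, grm, params,
                      variance_mode = model_opts$variance_mode %||% "fixed",
                      sigma2_g = model_opts$sigma2_g,
                      sigma2_e = model_opts$sigma2_e)
    fit$gebv
  } else if (method == "embayesr") {
    p <- allele_freqs(gsub)
    gsub <- subset_geno(gsub, snps = p > 0 & p < 1)
    W <- standardize_genotypes(gsub)
    Wref <- W[drp_ref$animal_id, , drop = FALSE]
    X <- .design_matrix(drp_ref)
    s2g <- model_opts$sigma2_g %||% (params$h2 * var(drp_ref$drp))
    s2e <- model_opts$sigma2_e %||% (s2g * (1 - params$h2) / params$h2)
    fit <- run_embayesr(drp_ref$drp, Wref, X, prior,
                        weights = drp_ref$weight, sigma2_g = s2g,
                        sigma2_e = s2e,
                        iters = model_opts$gibbs_iters %||% 3000L,
                        burnin = model_opts$burnin %||% 600L,
                        n_chains = model_opts$n_chains %||% 5L,
                        base_seed = seed,
                        em_max_iter = model_opts$em_max_iter %||% 200L)
    gebv <- as.vector(W %*% fit$snp_effects)
    names(gebv) <- rownames(W)
    gebv
  } else stop("unknown method: ", method)
}

# Breed fractions for WA designs, per the design's stated source.
.design_fractions <- function(population, design, val_ids, seed) {
  src <- design$breed_fraction_source
  an <- population$animals
  if (src == "truth") {
    fr <- population$breed_fractions_true[val_ids, , drop = FALSE]
    return(data.frame(animal_id = val_ids, fH = fr[, "fH"],
                      fJ = fr[, "fJ"], stringsAsFactors = FALSE))
  }
  g <- population$genotypes
  ids <- c(design$reference_ids, val_ids)
  if (src == "pca") {
    gsub <- subset_geno(g, animals = ids)
    grm <- build_grm(gsub)
    h_ids <- intersect(ids, an$animal_id[an$breed_group == "H"])
    pcs <- pca_of_grm(grm, 1, positive_ids = h_ids)
    ped <- setNames(an$breed_group, an$animal_id)[ids]
    comp <- allocate_groups(pcs[, 1], ped)
    comp[match(val_ids, comp$animal_id), c("animal_id", "fH", "fJ")]
  } else if (src == "admixture") {
    # estimated on a marker subset for speed, as practice does with a
    # low-density core set
    set.seed(seed)
    snps <- sort(sample.int(ncol(g$dosages), min(1000L, ncol(g$dosages))))
    gsub <- subset_geno(g, animals = ids, snps = snps)
    h_ids <- intersect(ids, an$animal_id[an$breed_group == "H"])
    j_ids <- intersect(ids, an$animal_id[an$breed_group == "J"])
    adm <- estimate_admixture(gsub, seed = seed, max_iter = 1500L,
                              h_ids = h_ids, j_ids = j_ids)
    comp <- adm$composition
    comp[match(val_ids, comp$animal_id), c("animal_id", "fH", "fJ")]
  } else stop("unknown breed fraction source: ", src)
}

#' Run the reference-design x method x panel experiment grid
#'
#' For each cell, rebuilds the panel genotypes and a design-specific GRM
#' (centering frequencies from that design's reference plus validation
#' animals), fits the model on the reference animals, predicts the shared
#' validation cows, and scores accuracy and bias per validation breed
#' group. Weighted-average designs (combine rule `weighted_average`)
#' reuse their two purebred component fits and combine them with
#' [wa_gebv()] using the design's breed-fraction source. Per-trait rows
#' are emitted along with across-trait averages (`trait = "avg"`). Cell
#' failures are recorded and the grid continues.
#'
#' @param population a `population`.
#' @param designs named list from [build_reference_designs()].
#' @param methods subset of `c("gblup", "embayesr")`.
#' @param panels subset of `c("tag", "causal_enriched", "pruned_dense")`.
#' @param traits trait names (default: all simulated traits).
#' @param params a [weight_params()].
#' @param prior a [mixture_prior()] (for `embayesr`).
#' @param model_opts list of model options (`variance_mode`, `sigma2_g`,
#'   `sigma2_e`, `gibbs_iters`, `burnin`, `n_chains`, `em_max_iter`).
#' @param base_seed seed from which every cell's seed is derived
#'   deterministically.
#' @return an evaluation table (data.frame: `design`, `method`, `panel`,
#'   `trait`, `validation_group`, `accuracy`, `bias`, `n_validation`)
#'   with attribute `failures` (character vector of failed cells).
#' @export
run_experiment <- function(population, designs,
                           methods = "gblup", panels = "tag",
                           traits = names(population$traits),
                           params = weight_params(),
                           prior = mixture_prior(),
                           model_opts = list(), base_seed = 1L) {
  rows <- list()
  failures <- character(0)
  gebv_cache <- new.env(parent = emptyenv())
  cell_i <- 0L
  # direct designs first so weighted-average cells can reuse their
  # component fits
  ord <- order(vapply(designs, function(d)
    d$combine_rule == "weighted_average", logical(1)))
  for (panel in panels) {
    mask <- panel_snps(population, panel)
    pg <- subset_geno(population$genotypes, snps = mask)
    xp <- tcrossprod(pg$dosages)
    dimnames(xp) <- list(rownames(pg$dosages), rownames(pg$dosages))
    for (design in designs[ord]) {
      # the design-specific GRM is shared by every method and trait
      grm <- NULL
      if (design$combine_rule != "weighted_average") {
        grm <- tryCatch({
          ids <- c(design$reference_ids, design$validation_ids)
          build_grm(subset_geno(pg, animals = ids), xp = xp[ids, ids])
        }, error = function(e) e)
      }
      for (method in methods) for (trait in traits) {
        cell_i <- cell_i + 1L
        seed <- base_seed + 1000L * cell_i
        key <- paste(design$name, method, panel, trait, sep = "|")
        res <- tryCatch({
          val_ids <- design$validation_ids
          if (design$combine_rule == "weighted_average") {
            comp_keys <- paste(design$component_designs, method, panel,
                               trait, sep = "|")
            if (!all(vapply(comp_keys, exists, logical(1),
                            envir = gebv_cache)))
              stop("component design fits unavailable for ", design$name)
            gH <- get(comp_keys[1], envir = gebv_cache)
            gJ <- get(comp_keys[2], envir = gebv_cache)
            fr <- .design_fractions(population, design, val_ids, seed)
            gebv <- wa_gebv(gH, gJ, fr)
          } else {
            if (inherits(grm, "error")) stop(conditionMessage(grm))
            gebv <- .fit_cell(population, design, method, pg, grm, trait,
                              params, prior, model_opts, seed)
            assign(key, gebv, envir = gebv_cache)
          }
          drp_tr <- population$drp[population$drp$trait == trait, ]
          vd <- drp_tr[match(val_ids, drp_tr$animal_id), ]
          out <- lapply(split(seq_len(nrow(vd)), vd$breed_group),
                        function(ix) {
            data.frame(design = design$name, method = method,
                       panel = panel, trait = trait,
                       validation_group = vd$breed_group[ix[1]],
                       accuracy = accuracy(gebv[vd$animal_id[ix]],
                                           vd$drp[ix]),
                       bias = bias(gebv[vd$animal_id[ix]], vd$drp[ix]),
                       n_validation = length(ix),
                       stringsAsFactors = FALSE)
          })
          do.call(rbind, out)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures,
                        paste0(key, ": ", conditionMessage(res)))
        } else rows[[length(rows) + 1L]] <- res
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(design = character(0), method = character(0),
                      panel = character(0), trait = character(0),
                      validation_group = character(0),
                      accuracy = numeric(0), bias = numeric(0),
                      n_validation = integer(0))
  rownames(tab) <- NULL
  if (length(traits) > 1 && nrow(tab) > 0) {
    ag <- stats::aggregate(cbind(accuracy, bias) ~ design + method +
                             panel + validation_group, data = tab, FUN = mean)
    ag$trait <- "avg"
    nv <- tab$n_validation[match(ag$validation_group,
                                 tab$validation_group)]
    ag$n_validation <- nv
    tab <- rbind(tab, ag[, names(tab)])
  }
  if (length(failures))
    warning(length(failures), " experiment cell(s) failed; ",
            "see attr(, 'failures')")
  attr(tab, "failures") <- failures
  tab
}
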