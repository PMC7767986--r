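#' Genotype matrix container
#'
#' Thin container for an animal-by-SNP dosage matrix (counts of the
#' alternate allele, in 0/1/2) with a marker map and optional panel flags.
#'
#' @param dosages integer matrix, animals in rows, SNPs in columns; must
#'   carry animal ids as rownames and SNP ids as colnames.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based)
#'   and optionally logical panel-flag columns (`tag`, `custom`,
#'   `causal_enriched`).
#' @param freq_source label for the animal set over which `allele_freq`
#'   was computed.
#' @return object of class `geno_matrix` with fields `dosages`, `map`,
#'   `allele_freq`, `freq_source`.
#' @export
geno_matrix <- function(dosages, map = NULL, freq_source = "all") {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("animal_", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp_", seq_len(ncol(dosages)))
  if (anyNA(dosages)) stop("dosages must not contain missing values; ",
                           "impute at load (see read_genotypes)")
  if (anyDuplicated(rownames(dosages))) stop("animal ids must be unique")
  if (anyDuplicated(colnames(dosages))) stop("snp ids must be unique")
  if (is.null(map)) {
    map <- data.frame(snp_id = colnames(dosages), chrom = "1",
                      pos = seq_len(ncol(dosages)),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(dosages),
            identical(as.character(map$snp_id), colnames(dosages)))
  g <- structure(list(dosages = dosages, map = map,
                      allele_freq = colMeans(dosages) / 2,
                      freq_source = freq_source),
                 class = "geno_matrix")
  g
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d SNPs (freq source: %s)\n",
              nrow(x$dosages), ncol(x$dosages), x$freq_source))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by animals and/or SNPs
#'
#' @param g a `geno_matrix`.
#' @param animals animal ids or indices (default: all).
#' @param snps SNP ids, indices or a logical mask (default: all).
#' @return the subset `geno_matrix`; allele frequencies are recomputed
#'   over the retained animals.
#' @export
subset_geno <- function(g, animals = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ai <- if (is.null(animals)) seq_len(nrow(g$dosages)) else animals
  si <- if (is.null(snps)) seq_len(ncol(g$dosages)) else snps
  d <- g$dosages[ai, si, drop = FALSE]
  if (is.character(si)) si <- match(si, g$map$snp_id)
  if (is.logical(si)) si <- which(si)
  geno_matrix(d, map = g$map[si, , drop = FALSE], freq_source = g$freq_source)
}

#' Alternate-allele frequencies over a stated animal set
#'
#' @param g a `geno_matrix`.
#' @param ids animal ids defining the frequency source (default: all
#'   animals in `g`).
#' @return numeric vector of per-SNP alternate-allele frequencies.
#' @export
allele_freqs <- function(g, ids = NULL) {
  d <- g$dosages
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(d))
    if (length(miss)) stop("unknown animal ids in frequency source: ",
                           paste(head(miss, 5), collapse = ", "))
    d <- d[ids, , drop = FALSE]
  }
  colMeans(d) / 2
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' SNPs whose minor allele frequency is strictly below the threshold are
#' removed (a SNP at exactly the threshold is retained); survivor order is
#' preserved.
#'
#' @param g a `geno_matrix`.
#' @param threshold MAF threshold in `[0, 0.5]`; the default 0.002 matches
#'   routine dairy-genotype QC.
#' @return filtered `geno_matrix`; the number of removed SNPs is reported
#'   via `message()`.
#' @export
filter_maf <- function(g, threshold = 0.002) {
  stopifnot(inherits(g, "geno_matrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must lie in [0, 0.5]")
  p <- allele_freqs(g)
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  if (!any(keep)) stop("MAF filter at ", threshold, " removed every SNP")
  message(sum(!keep), " SNP removed at MAF < ", threshold)
  subset_geno(g, snps = keep)
}

#' Greedy sliding-window LD pruning
#'
#' Scans SNPs in position order with a sliding window; whenever two SNPs
#' in the window have squared Pearson correlation of dosages above the
#' threshold, the lower-priority SNP is dropped (ties drop the later SNP).
#' Monomorphic SNPs have undefined correlation and are always retained.
#'
#' @param g a `geno_matrix`.
#' @param r2_threshold prune pairs with r-squared above this (default
#'   0.95, the conventional strong-LD cut).
#' @param priority per-SNP numeric rank, higher = preferentially kept
#'   (e.g. rank custom/array SNPs above fill-in sequence SNPs). Default:
#'   equal priority.
#' @param window,step window size and step in SNP count.
#' @return pruned `geno_matrix`.
#' @export
ld_prune <- function(g, r2_threshold = 0.95, priority = NULL,
                     window = 100L, step = 50L) {
  stopifnot(inherits(g, "geno_matrix"))
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  m <- ncol(g$dosages)
  if (is.null(priority)) priority <- rep(0, m)
  if (length(priority) != m) stop("priority must be defined for every SNP")
  ord <- order(g$map$chrom, g$map$pos)
  d <- g$dosages[, ord, drop = FALSE]
  prio <- priority[ord]
  sds <- apply(d, 2, sd)
  poly <- sds > 0
  alive <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - window + 1L), by = step),
                     max(1L, m - window + 1L)))
  for (s in starts) {
    idx <- s:min(m, s + window - 1L)
    idx <- idx[alive[idx] & poly[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(d[, idx, drop = FALSE]))^2
    for (a in seq_len(length(idx) - 1L)) {
      if (!alive[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (!alive[idx[b]]) next
        if (is.finite(r2[a, b]) && r2[a, b] > r2_threshold) {
          # keep the higher priority SNP; tie keeps the earlier position
          if (prio[idx[b]] > prio[idx[a]]) alive[idx[a]] <- FALSE
          else alive[idx[b]] <- FALSE
          if (!alive[idx[a]]) break
        }
      }
    }
  }
  keep_ids <- g$map$snp_id[ord][alive]
  subset_geno(g, snps = match(keep_ids, g$map$snp_id))
}

#' Standardize dosages to unit variance under Hardy-Weinberg
#'
#' Column j becomes `(dosage - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j`
#' computed over the stated frequency-source animals, giving each SNP
#' variance 1 under HWE — the design-matrix convention of the Bayesian
#' SNP-effect model.
#'
#' @param g a `geno_matrix`.
#' @param freq_source_ids animal ids over which allele frequencies are
#'   computed (default: all animals in `g`).
#' @return numeric matrix of standardized dosages (same dimnames).
#' @export
standardize_genotypes <- function(g, freq_source_ids = NULL) {
  p <- allele_freqs(g, freq_source_ids)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNPs in frequency source; apply filter_maf first")
  sweep(sweep(g$dosages, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: `G = M M' / (2 sum p_j (1 - p_j))` with `M` the dosage
#' matrix centered by twice the allele frequency. Frequencies come from a
#' stated animal set (by default all animals in `g`); in the experiment
#' harness they are recomputed per design from the union of that design's
#' reference and validation animals, because genomic relationships between
#' breeds depend visibly on the base frequencies used.
#'
#' @param g a `geno_matrix` (at least 2 animals and 2 SNPs).
#' @param freq_source_ids animal ids defining the centering frequencies.
#' @param xp optional precomputed raw cross-product `D D'` over all
#'   animals of `g` (an internal cache used when many designs share one
#'   panel); results are identical with or without it.
#' @return object of class `grm`: list with `matrix` (dense symmetric,
#'   dimnames = animal ids) and `freq_source`.
#' @export
build_grm <- function(g, freq_source_ids = NULL, xp = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$dosages) < 2 || ncol(g$dosages) < 2)
    stop("GRM needs at least 2 animals and 2 SNPs")
  p <- allele_freqs(g, freq_source_ids)
  # SNPs monomorphic in the frequency source contribute zero to both the
  # centered cross-product and the denominator under method 1, so they are
  # tolerated (a design-specific frequency source routinely fixes alleles
  # that segregate in the full data)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic in frequency source; apply filter_maf first")
  if (is.null(xp)) {
    M <- sweep(g$dosages, 2, 2 * p, "-")
    G <- tcrossprod(M) / denom
  } else {
    # D D' - a 1' - 1 a' + (4 p'p) 11', with a = D (2p): algebraically the
    # centered cross-product, without rebuilding M per frequency source
    a <- as.vector(g$dosages %*% (2 * p))
    G <- (xp - outer(a, rep(1, length(a))) - outer(rep(1, length(a)), a) +
            4 * sum(p^2)) / denom
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(g$dosages), rownames(g$dosages))
  structure(list(matrix = G,
                 freq_source = if (is.null(freq_source_ids)) "all"
                               else "custom"),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d (freq source: %s), mean diagonal %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$freq_source,
              mean(diag(x$matrix))))
  invisible(x)
}
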