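#' Read genotypes from PLINK text or VCF
#'
#' PLINK text: `.ped` (FID IID PAT MAT SEX PHENO + two alleles per SNP,
#' coded A/B) with a matching `.map` (chrom, snp id, cM, 1-based bp).
#' Dosages count the alternate allele ("B"). VCF: diploid GT field only;
#' multi-allelic records are skipped with a reported count. Missing calls
#' (`0` alleles in ped, `./.` in VCF) are imputed to the rounded SNP mean
#' with a reported count.
#'
#' @param path file path: the `.ped` (or its prefix) for `plink_text`,
#'   the `.vcf` for `vcf`.
#' @param format `"plink_text"` or `"vcf"`.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_text") .read_plink_text(path) else .read_vcf(path)
}

.read_plink_text <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f) || !file.exists(map_f))
    stop("need both ", ped_f, " and ", map_f)
  map <- read.table(map_f, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- read.table(ped_f, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped/map mismatch: ", ncol(ped) - 6, " allele columns for ",
         m, " SNPs in the map")
  ids <- as.character(ped[[2]])
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  dos <- (a1 == "B") + (a2 == "B")
  miss <- a1 == "0" | a2 == "0"
  dos[miss] <- NA_real_
  dimnames(dos) <- list(ids, map$snp_id)
  dos <- .impute_dosages(dos)
  map_out <- data.frame(snp_id = as.character(map$snp_id),
                        chrom = as.character(map$chrom), pos = map$pos,
                        stringsAsFactors = FALSE)
  .with_sorted_positions(dos, map_out)
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multi-allelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(al) {
      if (any(al == ".") || length(al) != 2) NA_real_
      else sum(al == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, count_alt))
  dimnames(dos) <- list(fix[, "ID"], colnames(gt))
  dos <- t(dos)
  dos <- .impute_dosages(dos)
  map <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  .with_sorted_positions(dos, map)
}

.impute_dosages <- function(dos) {
  n_miss <- sum(is.na(dos))
  if (n_miss > 0) {
    message(n_miss, " missing genotype call(s) imputed to the SNP mean")
    for (j in which(colSums(is.na(dos)) > 0)) {
      mj <- round(mean(dos[, j], na.rm = TRUE))
      dos[is.na(dos[, j]), j] <- if (is.finite(mj)) mj else 0
    }
  }
  dos
}

.with_sorted_positions <- function(dos, map) {
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    warning("positions not sorted; applying a stable sort")
    map <- map[ord, , drop = FALSE]
    dos <- dos[, ord, drop = FALSE]
  }
  geno_matrix(dos, map = map)
}

#' Write genotypes as PLINK text or VCF
#'
#' PLINK text uses allele coding A (reference) / B (alternate); VCF
#' writes unphased diploid GT on a single-sample-per-column layout with
#' one contig.
#'
#' @param g a `geno_matrix`.
#' @param prefix output path prefix (`.ped`/`.map` or `.vcf` appended).
#' @param format `"plink_text"` or `"vcf"`.
#' @param sex optional per-animal sex labels ("M"/"F") for the ped file.
#' @return the written file path(s), invisibly.
#' @export
write_genotypes <- function(g, prefix, format = c("plink_text", "vcf"),
                            sex = NULL) {
  format <- match.arg(format)
  d <- g$dosages
  if (format == "plink_text") {
    ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
    al <- matrix("A", nrow(d), 2 * ncol(d))
    al[, seq(1, 2 * ncol(d), 2)][d >= 1] <- "B"
    al[, seq(2, 2 * ncol(d), 2)][d == 2] <- "B"
    sx <- if (is.null(sex)) rep(0L, nrow(d)) else ifelse(sex == "M", 1L, 2L)
    ped <- cbind(rownames(d), rownames(d), "0", "0", sx, "-9", al)
    write.table(ped, ped_f, quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(g$map$chrom, g$map$snp_id, 0, g$map$pos),
                map_f, quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(c(ped_f, map_f))
  } else {
    vcf_f <- paste0(prefix, ".vcf")
    gt <- matrix("0/0", ncol(d), nrow(d))
    gt[t(d) == 1] <- "0/1"
    gt[t(d) == 2] <- "1/1"
    header <- c("##fileformat=VCFv4.2",
                "##contig=<ID=1>",
                paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                       "Description=\"Genotype\">"),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", rownames(d)),
                      collapse = "\t"))
    body <- cbind(g$map$chrom, g$map$pos, g$map$snp_id, "A", "C", ".",
                  "PASS", ".", "GT", gt)
    con <- file(vcf_f, "w")
    writeLines(header, con)
    write.table(body, con, quote = FALSE, row.names = FALSE,
                col.names = FALSE, sep = "\t")
    close(con)
    invisible(vcf_f)
  }
}

#' Write a GRM as square TSV and lower-triangle text
#'
#' @param grm a `grm`.
#' @param prefix output prefix; writes `<prefix>.grm.tsv` (square, with
#'   ids) and `<prefix>.grm.lowtri` (`id1 id2 value` rows).
#' @return written paths, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  sq <- paste0(prefix, ".grm.tsv"); lt <- paste0(prefix, ".grm.lowtri")
  G <- grm$matrix
  df <- data.frame(animal_id = rownames(G),
                   format(G, digits = 12, trim = TRUE),
                   check.names = FALSE)
  write.table(df, sq, quote = FALSE, row.names = FALSE, sep = "\t")
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  write.table(data.frame(rownames(G)[idx[, 1]], colnames(G)[idx[, 2]],
                         format(G[idx], digits = 12, trim = TRUE)),
              lt, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(c(sq, lt))
}

#' Read a square-TSV GRM written by [write_grm()]
#' @param path the `.grm.tsv` file.
#' @return a `grm`.
#' @export
read_grm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1])
  storage.mode(G) <- "double"
  dimnames(G) <- list(df$animal_id, colnames(df)[-1])
  structure(list(matrix = G, freq_source = "file"), class = "grm")
}

#' Write analysis tables plus a manifest
#'
#' Writes each named data.frame as a TSV with header and stable column
#' order, then a `MANIFEST.txt` listing every artifact with the config
#' hash and seed.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param config object whose serialized MD5 stamps the manifest.
#' @param seed the run seed recorded in the manifest.
#' @param overwrite allow clobbering existing files (default `FALSE`).
#' @return written file paths, invisibly.
#' @export
write_outputs <- function(tables, dir, config = NULL, seed = NA,
                          overwrite = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  clash <- paths[file.exists(paths)]
  if (length(clash) && !overwrite)
    stop("output file(s) exist (set overwrite = TRUE): ",
         paste(basename(clash), collapse = ", "))
  for (i in seq_along(tables))
    write.table(tables[[i]], paths[i], quote = FALSE, row.names = FALSE,
                sep = "\t")
  manifest <- file.path(dir, "MANIFEST.txt")
  lines <- c(paste0("config_hash: ", config_hash(config)),
             paste0("seed: ", seed),
             paste0("file: ", basename(paths)))
  writeLines(lines, manifest)
  invisible(c(paths, manifest))
}

#' MD5 hash of a configuration object
#'
#' Any change to any parameter changes the hash; used to stamp output
#' manifests.
#'
#' @param config any serializable R object.
#' @return hex MD5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_run_config`, the config list (with `sim` rebuilt as
#'   a `sim_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    raw$sim <- lapply(raw$sim, unlist)
    raw$sim <- do.call(sim_config, raw$sim)
  }
  if (!is.null(raw$weights)) raw$weights <- do.call(weight_params,
                                                    raw$weights)
  if (!is.null(raw$prior)) raw$prior <- do.call(mixture_prior, raw$prior)
  raw
}

#' @rdname read_run_config
#' @param config a config list (elements `sim`, `weights`, `prior`,
#'   `model`, ... as plain lists or their constructed classes).
#' @export
write_run_config <- function(config, path) {
  # yaml serializes only lists as maps, so named atomic vectors (e.g.
  # group_sizes) are converted to keep their names
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Deterministic micro-dataset fixtures for tests and examples
#'
#' Writes a tiny, seeded dataset (genotypes as PLINK text and VCF, the
#' DRP table and true breed fractions as TSV) into `dir`; regeneration
#' is bit-identical.
#'
#' @param name fixture name; currently `"two_breeds_small"` (60 animals:
#'   20 H, 20 J, 20 F1; 300 SNPs) and `"three_group_micro"` (24 animals,
#'   120 SNPs).
#' @param dir output directory.
#' @return list with the `population` and written `paths`.
#' @export
make_fixture <- function(name = "two_breeds_small", dir = tempdir()) {
  fixtures <- list(
    two_breeds_small = sim_config(
      seed = 424L, n_snp = 300L, n_qtl = 30L,
      group_sizes = c(H_bull = 5L, J_bull = 5L, H_cow = 15L, J_cow = 15L,
                      X75_cow = 0L, X50_cow = 20L, X25_cow = 0L)),
    three_group_micro = sim_config(
      seed = 77L, n_snp = 120L, n_qtl = 12L,
      group_sizes = c(H_bull = 2L, J_bull = 2L, H_cow = 8L, J_cow = 6L,
                      X75_cow = 0L, X50_cow = 6L, X25_cow = 0L)))
  if (!name %in% names(fixtures))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "))
  cfg <- fixtures[[name]]
  pop <- simulate_population(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, name)
  p1 <- write_genotypes(pop$genotypes, prefix, "plink_text",
                        sex = pop$animals$sex)
  p2 <- write_genotypes(pop$genotypes, prefix, "vcf")
  drp_f <- paste0(prefix, "_drp.tsv")
  write.table(pop$drp, drp_f, quote = FALSE, row.names = FALSE,
              sep = "\t")
  fr_f <- paste0(prefix, "_fractions.tsv")
  write.table(data.frame(animal_id = rownames(pop$breed_fractions_true),
                         pop$breed_fractions_true,
                         group = pop$animals$breed_group),
              fr_f, quote = FALSE, row.names = FALSE, sep = "\t")
  list(population = pop, paths = c(p1, p2, drp_f, fr_f))
}
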