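make_geno <- function(dos) geno_matrix(as.matrix(dos))

test_that("MAF filtering removes strictly below the threshold", {
  # 500 animals = 1000 alleles: 2 alt copies gives MAF exactly 0.002,
  # 1 copy gives 0.001 (below threshold, removed)
  d <- matrix(0L, 500, 3,
              dimnames = list(NULL, c("at_thr", "below", "common")))
  d[1, "at_thr"] <- 2L
  d[1, "below"] <- 1L
  d[, "common"] <- rbinom(500, 2, 0.3)
  g <- make_geno(d)
  f <- suppressMessages(filter_maf(g, 0.002))
  expect_identical(colnames(f$dosages), c("at_thr", "common"))
  # threshold 0 is the identity
  f0 <- suppressMessages(filter_maf(g, 0))
  expect_identical(f0$dosages, g$dosages)
  # counting on a constructed fixture, and idempotence
  d2 <- sapply(c(rep(0.001, 3), rep(0.3, 7)),
               function(p) rbinom(2000, 2, p))
  colnames(d2) <- paste0("s", 1:10)
  g2 <- make_geno(d2)
  f2 <- suppressMessages(filter_maf(g2, 0.05))
  expect_equal(ncol(f2$dosages), 7)
  expect_identical(suppressMessages(filter_maf(f2, 0.05))$dosages,
                   f2$dosages)
  expect_error(suppressMessages(filter_maf(g2, 0.49)), "every SNP")
})

test_that("LD pruning drops one of each high-r2 pair by priority", {
  set.seed(5)
  base <- rbinom(300, 2, 0.4)
  d <- cbind(dup1 = base, mid = rbinom(300, 2, 0.5), dup2 = base)
  g <- make_geno(d)
  # equal priority: the earlier duplicate survives
  pr <- ld_prune(g, 0.95)
  expect_true("dup1" %in% colnames(pr$dosages))
  expect_false("dup2" %in% colnames(pr$dosages))
  # higher priority on the later duplicate flips the outcome
  pr2 <- ld_prune(g, 0.95, priority = c(0, 0, 1))
  expect_false("dup1" %in% colnames(pr2$dosages))
  expect_true("dup2" %in% colnames(pr2$dosages))
  # monomorphic SNPs are always retained
  d3 <- cbind(d, mono = rep(1L, 300))
  pr3 <- ld_prune(make_geno(d3), 0.95)
  expect_true("mono" %in% colnames(pr3$dosages))
  # independent SNPs are essentially untouched at n = 1000
  set.seed(6)
  d4 <- sapply(runif(200, 0.1, 0.9), function(p) rbinom(1000, 2, p))
  colnames(d4) <- paste0("s", 1:200)
  pr4 <- ld_prune(make_geno(d4), 0.95)
  expect_gte(ncol(pr4$dosages), 198)
  # idempotence
  expect_identical(ld_prune(pr4, 0.95)$dosages, pr4$dosages)
})

test_that("standardization matches the 2p-centered unit-variance formula", {
  d <- matrix(c(0L, 1L, 2L, 1L), 4, 1, dimnames = list(letters[1:4], "s1"))
  W <- standardize_genotypes(make_geno(d))
  # p = 0.5: heterozygote 0, homozygote alt +1/sqrt(0.5)
  expect_equal(W["b", 1], 0)
  expect_equal(W["c", 1], 1 / sqrt(0.5), tolerance = 1e-12)
  # an HWE column standardized at its own sample frequency has variance ~1
  set.seed(7)
  d2 <- matrix(rbinom(5000, 2, 0.3), ncol = 1,
               dimnames = list(NULL, "s1"))
  W2 <- standardize_genotypes(make_geno(d2))
  expect_equal(var(W2[, 1]), 1, tolerance = 0.05)
  mono <- make_geno(matrix(2L, 10, 1, dimnames = list(NULL, "m")))
  expect_error(standardize_genotypes(mono), "filter_maf")
})

test_that("VanRaden GRM has the expected algebraic structure", {
  set.seed(8)
  p <- runif(500, 0.1, 0.9)
  d <- t(sapply(1:80, function(i) rbinom(500, 2, p)))
  d <- rbind(d, d[1, ])  # animal 81 is a genotype copy of animal 1
  rownames(d) <- paste0("a", 1:81)
  colnames(d) <- paste0("s", 1:500)
  g <- make_geno(d)
  G <- build_grm(g)$matrix
  expect_lt(max(abs(G - t(G))), 1e-10)
  # identical genotypes: off-diagonal equals the mean of the diagonals
  expect_equal(G["a1", "a81"], (G["a1", "a1"] + G["a81", "a81"]) / 2,
               tolerance = 1e-12)
  # HWE at (close to) its own frequencies: mean diagonal near 1
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  # independent oracle: explicit centered cross-product
  pj <- colMeans(d) / 2
  M <- sweep(d, 2, 2 * pj)
  G2 <- tcrossprod(M) / (2 * sum(pj * (1 - pj)))
  expect_equal(unname(G), unname(G2), tolerance = 1e-10)
  # permuting animals permutes G identically
  perm <- sample(81)
  Gp <- build_grm(subset_geno(g, animals = perm))$matrix
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12)
  # the cached cross-product path is exact
  xp <- tcrossprod(d)
  dimnames(xp) <- list(rownames(d), rownames(d))
  expect_equal(build_grm(g, xp = xp)$matrix, G, tolerance = 1e-8)
})

test_that("between-breed relationships depend on the frequency source", {
  pop <- breeds_pop()
  an <- pop$animals
  h_ids <- an$animal_id[an$breed_group == "H"]
  j_ids <- an$animal_id[an$breed_group == "J"]
  g <- pop$genotypes
  # H-dominated source vs balanced source
  G_h <- build_grm(g, freq_source_ids = c(h_ids, j_ids[1:6]))$matrix
  G_bal <- build_grm(g, freq_source_ids = c(h_ids, j_ids))$matrix
  m_h <- mean(G_h[j_ids, h_ids])
  m_bal <- mean(G_bal[j_ids, h_ids])
  expect_false(isTRUE(all.equal(m_h, m_bal, tolerance = 1e-3)))
})
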