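test_that("Balding-Nichols frequency draws have the stated moments", {
  p <- rep(0.5, 10000)
  # zero divergence: both breeds inherit the ancestral frequencies exactly
  f0 <- draw_breed_allele_freqs(p, fst = 0, seed = 1)
  expect_identical(f0$H, p)
  expect_identical(f0$J, p)
  # variance fst * p * (1 - p) around mean p
  f <- draw_breed_allele_freqs(p, fst = 0.1, seed = 2)
  expect_equal(var(f$H), 0.1 * 0.25, tolerance = 0.2)
  expect_equal(mean(f$H), 0.5, tolerance = 0.02)
  # determinism
  expect_identical(draw_breed_allele_freqs(p[1:50], 0.1, seed = 7),
                   draw_breed_allele_freqs(p[1:50], 0.1, seed = 7))
  expect_error(draw_breed_allele_freqs(c(0.5, 1.2), 0.1),
               "index 2")
  expect_error(draw_breed_allele_freqs(p[1:5], fst = 0.7), "fst")
})

test_that("purebred genotypes follow Hardy-Weinberg moments", {
  p <- runif(200, 0.1, 0.9)
  g <- simulate_genotypes(list(H = p, J = p),
                          c(H_cow = 400L), seed = 3)
  expect_equal(dim(g$dosages), c(400L, 200L))
  mean_dos <- colMeans(g$dosages)
  sd3 <- 3 * sqrt(2 * p * (1 - p) / 400)
  expect_true(all(abs(mean_dos - 2 * p) < pmax(sd3, 0.15)))
})

test_that("crossbred gamete sampling respects breed origin", {
  # fixed-difference locus: F1 dosage exactly 1, 75:25 has mean 1.5
  pH <- c(1, 0.5); pJ <- c(0, 0.5)
  g <- simulate_genotypes(list(H = pH, J = pJ),
                          c(X50_cow = 200L, X75_cow = 400L), seed = 4)
  an <- attr(g, "animals")
  f1 <- g$dosages[an$breed_group == "50H50J", 1]
  expect_true(all(f1 == 1))
  bc <- g$dosages[an$breed_group == "75H25J", 1]
  expect_equal(mean(bc), 1.5, tolerance = 0.08)
  expect_error(simulate_genotypes(list(H = pH, J = pJ), integer(0)),
               "empty")
})

test_that("QTL effects are sparse, mixture-drawn and rescaled exactly", {
  prior <- mixture_prior()
  expect_identical(assign_qtl_effects(100, 0, prior, 1, seed = 1),
                   numeric(100))
  # degenerate mixture: all mass on the largest component, every SNP causal
  deg <- mixture_prior(c(0, 0, 0, 1), c(0, 1e-4, 1e-3, 1e-2))
  eff <- assign_qtl_effects(50, 50, deg, 1, seed = 2)
  expect_true(all(eff != 0))
  # rescaling pins the realized TBV variance in the reference dosages
  pop <- small_pop()
  h_dos <- pop$genotypes$dosages[pop$animals$breed_group == "H", ]
  eff <- assign_qtl_effects(400, 40, prior, 2.5, seed = 3,
                            ref_dosages = h_dos)
  expect_equal(var(as.vector(h_dos %*% eff)), 2.5, tolerance = 1e-9)
  expect_equal(sum(eff != 0), 40)
  expect_error(assign_qtl_effects(100, 10, prior, sigma2_g = -1),
               "positive")
})

test_that("DRP reliabilities and noise follow the stated formulas", {
  # cow with one record: r2 = h2; bull with huge p: DRP ~ TBV
  cfg <- sim_config(seed = 31L, n_snp = 200L, n_qtl = 30L,
                    group_sizes = c(H_bull = 500L, J_bull = 0L,
                                    H_cow = 1000L, J_cow = 0L,
                                    X75_cow = 0L, X50_cow = 0L,
                                    X25_cow = 0L),
                    records_range = c(1L, 1L),
                    daughters_range = c(1000000L, 1000000L))
  pop <- simulate_population(cfg)
  drp <- pop$drp
  cows <- drp[drp$sex == "F", ]
  bulls <- drp[drp$sex == "M", ]
  expect_equal(unique(cows$reliability), cfg$h2)
  # noise variance sigma2_g (1 - r2)/r2 within 10% (single stratum)
  expect_equal(var(cows$drp - cows$tbv - mean(cows$drp - cows$tbv)),
               cfg$sigma2_g * (1 - cfg$h2) / cfg$h2, tolerance = 0.1)
  # near-perfect bull reliability: noise SD < 1% of genetic SD
  expect_lt(sd(bulls$drp - bulls$tbv - mean(bulls$drp - bulls$tbv)),
            0.01 * sqrt(cfg$sigma2_g))
  # additive noise leaves DRP unbiased for TBV
  cfg2 <- small_cfg(seed = 33L, group_sizes = c(
    H_bull = 500L, J_bull = 0L, H_cow = 4500L, J_cow = 0L,
    X75_cow = 0L, X50_cow = 0L, X25_cow = 0L), n_snp = 200L, n_qtl = 30L)
  pop2 <- simulate_population(cfg2)
  sl <- coef(lm(drp ~ tbv, data = pop2$drp))["tbv"]
  expect_equal(unname(sl), 1, tolerance = 0.05)
})

test_that("population simulation is deterministic and bookkeeps breeds", {
  p1 <- simulate_population(small_cfg())
  p2 <- simulate_population(small_cfg())
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_identical(p1$drp, p2$drp)
  fr <- p1$breed_fractions_true
  expect_true(all(rowSums(fr) == 1))
  expect_true(all(fr[, "fH"] %in% c(1, 0.75, 0.5, 0.25, 0)))
  # per-locus FST between simulated purebreds near the configured value
  pop <- breeds_pop()
  an <- pop$animals
  pH <- colMeans(pop$genotypes$dosages[an$breed_group == "H", ]) / 2
  pJ <- colMeans(pop$genotypes$dosages[an$breed_group == "J", ]) / 2
  nH <- sum(an$breed_group == "H"); nJ <- sum(an$breed_group == "J")
  num <- (pH - pJ)^2 - pH * (1 - pH) / (2 * nH) - pJ * (1 - pJ) / (2 * nJ)
  pbar <- (pH + pJ) / 2
  fst_hat <- mean(num) / mean(2 * pbar * (1 - pbar))
  expect_equal(fst_hat, pop$config$fst, tolerance = 0.2)
})

test_that("reference designs mirror the study's composition logic", {
  pop <- small_pop()
  des <- build_reference_designs(pop, seed = 9L,
                                 validation_sizes = c(H = 8, `75H25J` = 5,
                                                      `50H50J` = 6,
                                                      `25H75J` = 5, J = 8))
  expect_setequal(sort(des$Ref3$reference_ids),
                  sort(union(des$Ref1$reference_ids,
                             des$Ref2$reference_ids)))
  expect_identical(length(des$Ref6$reference_ids),
                   length(des$Ref7$reference_ids))
  # Ref8 is the union of Ref6 and Ref7
  expect_setequal(des$Ref8$reference_ids,
                  union(des$Ref6$reference_ids, des$Ref7$reference_ids))
  # one shared validation set, disjoint from every reference
  for (d in des) {
    expect_identical(d$validation_ids, des$Ref1$validation_ids)
    expect_length(intersect(d$reference_ids, d$validation_ids), 0)
  }
  # weighted-average designs reference their two purebred components
  expect_identical(des$Ref4$component_designs, c("Ref1", "Ref2"))
  expect_identical(des$Ref4$breed_fraction_source, "pca")
  expect_identical(des$Ref4p$breed_fraction_source, "admixture")
  expect_error(build_reference_designs(pop, scheme = "nope"), "scheme")
})
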