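# small standardized design shared by several blocks
std_design <- function(n, m, seed) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- t(sapply(seq_len(n), function(i) rbinom(m, 2, p)))
  dimnames(d) <- list(paste0("a", seq_len(n)), paste0("s", seq_len(m)))
  standardize_genotypes(geno_matrix(d))
}

test_that("EM warm start shrinks null traits and flags large effects", {
  W <- std_design(300, 200, seed = 41)
  prior <- mixture_prior()
  # pure-noise trait: every initial effect shrunk far below the
  # noise-implied marginal SD of a single-SNP association
  set.seed(42)
  y <- rnorm(300)
  em <- em_warm_start(y, W, sigma2_g = 1, sigma2_e = 1)
  marginal_sd <- 1 / sqrt(300)
  expect_lt(max(abs(em$effects)), 0.1 * marginal_sd * 3)
  expect_true(em$converged)
  # a single SNP explaining half the variance dominates the top component
  set.seed(43)
  b <- sqrt(1)          # Var(W v) = 1 for standardized W
  y2 <- W[, 77] * b + rnorm(300, 0, 1)
  em2 <- em_warm_start(y2, W, prior = prior, sigma2_g = 2, sigma2_e = 1)
  expect_gt(em2$responsibilities[77, 4], 0.9)
  # tol = Inf returns after exactly one sweep
  em3 <- em_warm_start(y, W, tol = Inf)
  expect_equal(em3$iterations, 1L)
})

test_that("Gibbs chains are seed-deterministic and average correctly", {
  W <- std_design(100, 60, seed = 44)
  set.seed(45)
  y <- as.vector(W[, 5] * 0.5) + rnorm(100)
  c1 <- run_gibbs_chain(y, W, iters = 500, burnin = 100, seed = 9)
  c2 <- run_gibbs_chain(y, W, iters = 500, burnin = 100, seed = 9)
  expect_identical(c1$snp_effects, c2$snp_effects)
  expect_identical(c1$component_post, c2$component_post)
  # component posterior rows are probability vectors
  expect_equal(rowSums(c1$component_post), rep(1, 60), tolerance = 1e-8)
  expect_error(run_gibbs_chain(y, W, iters = 100, burnin = 100),
               "burnin")
})

test_that("single-component prior degenerates to ridge regression", {
  W <- std_design(200, 80, seed = 46)
  set.seed(47)
  v_true <- rnorm(80, 0, sqrt(0.01))
  y <- as.vector(W %*% v_true) + rnorm(200, 0, 1)
  prior <- mixture_prior(c(0, 0, 0, 1), c(0, 0.01, 0.01, 0.01))
  fit <- run_gibbs_chain(y, W, prior = prior, sigma2_g = 1, sigma2_e = 1,
                         iters = 4000, burnin = 1000, seed = 10)
  # ridge oracle with matching shrinkage sigma2_e / (0.01 sigma2_g)
  lam <- 1 / 0.01
  Wc <- cbind(1, W)
  C <- crossprod(Wc) + diag(c(0, rep(lam, 80)))
  v_ridge <- solve(C, crossprod(Wc, y))[-1]
  expect_gte(cor(fit$snp_effects, v_ridge), 0.99)
})

test_that("posterior effects shrink as residual variance grows", {
  W <- std_design(150, 50, seed = 48)
  set.seed(49)
  y <- as.vector(W[, 1:5] %*% rep(0.4, 5)) + rnorm(150)
  norms <- sapply(c(0.5, 2, 8), function(s2e)
    sum(abs(run_gibbs_chain(y, W, sigma2_g = 1, sigma2_e = s2e,
                            iters = 1500, burnin = 300,
                            seed = 11)$snp_effects)))
  expect_true(all(diff(norms) < 0))
})

test_that("chain averaging and null-trait component mass behave", {
  W <- std_design(120, 40, seed = 50)
  set.seed(51)
  y <- rnorm(120)
  # averaging five chains with one seed equals the single chain
  f1 <- run_embayesr(y, W, iters = 400, burnin = 100, n_chains = 1,
                     base_seed = 3)
  f5 <- run_embayesr(y, W, iters = 400, burnin = 100, n_chains = 5,
                     base_seed = 3)
  expect_equal(f1$snp_effects,
               rowMeans(cbind(f1$snp_effects)), tolerance = 1e-12)
  # with distinct seeds the average differs from any single chain only
  # by Monte Carlo error, and the default prior's proportions are intact
  expect_equal(sum(mixture_prior()$proportions), 1, tolerance = 1e-12)
  # an all-null trait keeps most posterior mass in the null component
  expect_gte(mean(f5$component_post[, 1]), 0.5)
  # chain-to-chain GEBV stability: sd across chains well below GEBV sd
  gebv_chain <- W %*% f5$chain_effects
  chain_sd <- mean(apply(gebv_chain, 1, sd))
  expect_lt(chain_sd, 0.25 * max(sd(rowMeans(gebv_chain)), 0.05))
})

test_that("mixture prior beats GBLUP when few QTL carry half the variance", {
  wins <- 0L
  for (r in 1:10) {
    set.seed(900 + r)
    n <- 400; n_val <- 100; m <- 600
    p <- runif(m, 0.1, 0.9)
    d <- t(sapply(seq_len(n + n_val), function(i) rbinom(m, 2, p)))
    dimnames(d) <- list(paste0("a", seq_len(n + n_val)),
                        paste0("s", 1:m))
    ids <- rownames(d)[1:n]; val <- rownames(d)[(n + 1):(n + n_val)]
    W <- standardize_genotypes(geno_matrix(d), freq_source_ids = ids)
    # 10 large QTL carry half the genetic variance, a polygenic tail the
    # rest; h2 = 0.33
    big <- sample(m, 10); small <- sample(setdiff(seq_len(m), big), 200)
    v <- numeric(m)
    v[big] <- rnorm(10, 0, sqrt(0.5 / 10))
    v[small] <- rnorm(200, 0, sqrt(0.5 / 200))
    tbv <- as.vector(W %*% v)
    tbv <- tbv / sd(tbv)
    y <- tbv[1:n] + rnorm(n, 0, sqrt(0.67 / 0.33))
    drp <- data.frame(animal_id = ids, drp = y, sex = "F",
                      breed_group = "H", weight = 1)
    grm <- structure(list(matrix = tcrossprod(W) / m, freq_source = "s"),
                     class = "grm")
    gb <- fit_wgblup(drp, grm, weight_params(), sigma2_g = 1,
                     sigma2_e = 0.67 / 0.33, ridge = 1e-8)
    eb <- run_embayesr(y, W[ids, ], prior = mixture_prior(),
                       sigma2_g = 1, sigma2_e = 0.67 / 0.33,
                       iters = 1200, burnin = 300, n_chains = 2,
                       base_seed = 910 + r, em_max_iter = 300)
    gebv_eb <- as.vector(W[val, ] %*% eb$snp_effects)
    acc_gb <- cor(gb$gebv[val], tbv[(n + 1):(n + n_val)])
    acc_eb <- cor(gebv_eb, tbv[(n + 1):(n + n_val)])
    if (acc_eb >= acc_gb) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
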