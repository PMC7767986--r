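wp <- weight_params(h2 = 0.33, t = 0.56, c = 0.2)

test_that("cow and bull DRP weights match the closed formulas", {
  # n = 1: (1 - h2) / (c h2 + 1 - h2) = 0.67 / 0.736
  expect_equal(cow_weight(wp, 1), 0.67 / 0.736, tolerance = 1e-12)
  # many-record limit: denominator c h2 + t - h2
  expect_equal(cow_weight(wp, Inf), 0.67 / 0.296, tolerance = 1e-12)
  expect_equal(bull_weight(wp, 100), 0.67 / (0.066 + 0.0367),
               tolerance = 1e-3)
  # progeny-test limit (1 - h2) / (c h2)
  expect_equal(bull_weight(wp, Inf), 0.67 / 0.066, tolerance = 1e-12)
  # strict monotonicity in information content
  expect_true(all(diff(cow_weight(wp, 1:50)) > 0))
  expect_true(all(diff(bull_weight(wp, 1:500)) > 0))
  expect_error(cow_weight(wp, 0), ">= 1")
})

ident_grm <- function(ids) {
  structure(list(matrix = diag(length(ids)) |>
                   `dimnames<-`(list(ids, ids)),
                 freq_source = "identity"), class = "grm")
}

test_that("independence case shrinks each record by 1/(1+lambda)", {
  set.seed(10)
  ids <- paste0("a", 1:40)
  drp <- data.frame(animal_id = ids, drp = rnorm(40), sex = "F",
                    breed_group = "H", weight = 1)
  fit <- fit_wgblup(drp, ident_grm(ids), wp, sigma2_g = 1, sigma2_e = 3,
                    ridge = 0)
  lambda <- 3
  expect_equal(unname(fit$gebv[ids]),
               (drp$drp - fit$fixed_effects[1]) / (1 + lambda),
               tolerance = 1e-8)
})

test_that("weighted GBLUP equals SNP ridge regression when G = WW'/m", {
  set.seed(11)
  n <- 120; m <- 300
  p <- runif(m, 0.1, 0.9)
  d <- t(sapply(seq_len(n + 30), function(i) rbinom(m, 2, p)))
  dimnames(d) <- list(paste0("a", seq_len(n + 30)), paste0("s", 1:m))
  g <- geno_matrix(d)
  # frequencies from the phenotyped subset so W columns are not exactly
  # centered over all animals (G = WW'/m stays positive definite)
  W <- standardize_genotypes(g, freq_source_ids = rownames(d)[1:n])
  G <- tcrossprod(W) / m
  grm <- structure(list(matrix = G, freq_source = "sample"),
                   class = "grm")
  ids <- rownames(d)[1:n]
  eff <- rnorm(m, 0, sqrt(1 / m))
  y <- as.vector(W[ids, ] %*% eff) + rnorm(n, 0, 0.7)
  drp <- data.frame(animal_id = ids, drp = y,
                    sex = sample(c("M", "F"), n, TRUE),
                    breed_group = "H",
                    weight = runif(n, 0.5, 3))
  s2g <- 1; s2e <- 0.5
  # sample-frequency centering leaves G with one null direction; a
  # negligible ridge (1e-10) makes the factorization well defined without
  # moving the solution at the 1e-6 scale under test
  fit <- fit_wgblup(drp, grm, wp, sigma2_g = s2g, sigma2_e = s2e,
                    ridge = 1e-10)
  # independent oracle: weighted ridge regression on SNP effects with
  # lambda_snp = m * lambda_G, predictions W v_hat
  X <- cbind(1, as.numeric(drp$sex == "M"))
  Wr <- W[ids, ]
  R <- drp$weight
  lam <- m * s2e / s2g
  C <- rbind(cbind(crossprod(X * R, X), crossprod(X * R, Wr)),
             cbind(crossprod(Wr * R, X),
                   crossprod(Wr * R, Wr) + diag(lam, m)))
  rhs <- c(crossprod(X * R, y), crossprod(Wr * R, y))
  sol <- solve(C, rhs)
  v <- sol[-(1:2)]
  pred <- as.vector(W %*% v)
  expect_lt(max(abs(fit$gebv[rownames(W)] - pred)), 1e-6)
})

test_that("rescaling weights and residual variance together is neutral", {
  set.seed(12)
  ids <- paste0("a", 1:50)
  d <- matrix(rbinom(50 * 100, 2, 0.4), 50, 100,
              dimnames = list(ids, paste0("s", 1:100)))
  grm <- build_grm(geno_matrix(d))
  drp <- data.frame(animal_id = ids[1:40], drp = rnorm(40),
                    sex = "F", breed_group = "H",
                    weight = runif(40, 0.5, 2))
  f1 <- fit_wgblup(drp, grm, wp, sigma2_g = 1, sigma2_e = 2)
  drp2 <- drp; drp2$weight <- drp$weight * 2
  f2 <- fit_wgblup(drp2, grm, wp, sigma2_g = 1, sigma2_e = 4)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-9)
  # solver residual against the assembled equations
  q <- length(f1$gebv); X <- matrix(1, 40, 1)
  Gi <- chol2inv(chol(grm$matrix + diag(1e-6, q)))
  Zi <- match(drp$animal_id, ids)
  Z <- matrix(0, 40, q); Z[cbind(1:40, Zi)] <- 1
  R <- diag(drp$weight)
  lam <- f1$lambda
  C <- rbind(cbind(t(X) %*% R %*% X, t(X) %*% R %*% Z),
             cbind(t(Z) %*% R %*% X, t(Z) %*% R %*% Z + Gi * lam))
  rhs <- c(t(X) %*% R %*% drp$drp, t(Z) %*% R %*% drp$drp)
  resid <- C %*% c(f1$fixed_effects, f1$gebv) - rhs
  expect_lt(max(abs(resid)), 1e-8 * max(abs(rhs)))
})

test_that("an unphenotyped clone inherits the phenotyped animal's GEBV", {
  set.seed(13)
  ids <- c(paste0("a", 1:30), "clone")
  d <- matrix(rbinom(30 * 200, 2, 0.4), 30, 200)
  d <- rbind(d, d[1, ])
  dimnames(d) <- list(ids, paste0("s", 1:200))
  grm <- build_grm(geno_matrix(d))
  drp <- data.frame(animal_id = ids[1:30], drp = rnorm(30), sex = "F",
                    breed_group = "H", weight = 1)
  fit <- fit_wgblup(drp, grm, wp, sigma2_g = 1, sigma2_e = 1,
                    ridge = 1e-8)
  expect_equal(unname(fit$gebv["clone"]), unname(fit$gebv["a1"]),
               tolerance = 1e-6)
})

test_that("EM-REML mode converges to sensible variance components", {
  set.seed(14)
  pop <- small_pop()
  drp <- pop$drp[pop$drp$trait == "milk", ]
  grm <- build_grm(pop$genotypes)
  fit <- fit_wgblup(drp, grm, wp, variance_mode = "em_reml",
                    max_iter = 50, tol = 1e-5)
  expect_true(fit$sigma2_g > 0 && fit$sigma2_e > 0)
  expect_true(is.finite(fit$lambda))
})

test_that("validation accuracy grows with reference size", {
  wins <- 0L
  for (r in 1:10) {
    cfg <- sim_config(seed = 500L + r, n_snp = 300L, n_qtl = 60L,
                      group_sizes = c(H_bull = 0L, J_bull = 0L,
                                      H_cow = 640L, J_cow = 0L,
                                      X75_cow = 0L, X50_cow = 0L,
                                      X25_cow = 0L))
    pop <- simulate_population(cfg)
    drp <- pop$drp
    val <- drp$animal_id[601:640]
    grm <- build_grm(pop$genotypes)
    acc <- sapply(c(150, 600), function(nref) {
      ref <- drp[seq_len(nref), ]
      fit <- fit_wgblup(ref, grm, wp, sigma2_g = 1,
                        sigma2_e = 2 * mean(ref$weight))
      cor(fit$gebv[val], pop$true_breeding_values[match(
        val, pop$animals$animal_id)])
    })
    if (acc[2] > acc[1]) wins <- wins + 1L
    if (r == 1) expect_gt(acc[2], 0)
  }
  # one-sided sign test at the 5% level for 10 replicates
  expect_gte(wins, 9L)
})
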