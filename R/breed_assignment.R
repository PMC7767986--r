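#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of the GRM; scores are eigenvectors scaled by the
#' square root of their eigenvalues, ordered by decreasing eigenvalue.
#' With two diverged breeds the first component separates them. The sign
#' of each component is fixed so that the mean score of `positive_ids`
#' (typically the pure-Holstein animals) is positive, when supplied.
#'
#' @param grm a `grm`.
#' @param n_components number of leading components (>= 1).
#' @param positive_ids optional animal ids anchoring the sign convention.
#' @return matrix of scores, animals x components, columns `PC1`, ...
#' @export
pca_of_grm <- function(grm, n_components = 2L, positive_ids = NULL) {
  stopifnot(inherits(grm, "grm"), n_components >= 1)
  G <- grm$matrix
  if (any(!is.finite(G))) stop("GRM contains non-finite entries")
  eg <- eigen(G, symmetric = TRUE)
  k <- min(n_components, ncol(G))
  ev <- pmax(eg$values[seq_len(k)], 0)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  if (!is.null(positive_ids)) {
    for (j in seq_len(k)) {
      m <- mean(scores[positive_ids, j])
      if (is.finite(m) && m < 0) scores[, j] <- -scores[, j]
    }
  }
  scores
}

#' Allocate animals to breed groups from PC1 anchored by pedigree codes
#'
#' Pedigree-labeled animals define each claimed group's mean PC1 score;
#' boundaries are placed midway between adjacent group means, and every
#' animal — including unlabeled or mislabeled ones — is assigned to the
#' group whose PC1 interval contains it. Nominal group ancestry fractions
#' are attached.
#'
#' @param pc1_scores named numeric vector of first-component scores.
#' @param pedigree_groups named character vector (animal id -> breed
#'   group) for the pedigree-trusted subset; at least one animal per
#'   claimed group.
#' @return a breed-composition data.frame (`animal_id`, `fH`, `fJ`,
#'   `group`, `source = "pca"`).
#' @export
allocate_groups <- function(pc1_scores, pedigree_groups) {
  stopifnot(!is.null(names(pc1_scores)), !is.null(names(pedigree_groups)))
  groups <- intersect(BREED_GROUPS, unique(pedigree_groups))
  if (!length(groups)) stop("no recognized breed groups among anchors")
  anchors <- pedigree_groups[names(pedigree_groups) %in% names(pc1_scores)]
  mu <- vapply(groups, function(g)
    mean(pc1_scores[names(anchors)[anchors == g]]), numeric(1))
  if (anyNA(mu)) stop("every claimed group needs >= 1 anchored animal ",
                      "with a PC1 score")
  # groups are listed by decreasing Holstein fraction; their PC1 means
  # must decrease accordingly for the anchoring to be coherent
  if (is.unsorted(rev(mu), strictly = TRUE))
    stop("group PC1 means are not monotone along PC1; ",
         "inconsistent pedigree anchoring")
  cuts <- (mu[-1] + mu[-length(mu)]) / 2
  idx <- findInterval(-pc1_scores, -cuts) + 1L  # descending boundaries
  grp <- groups[idx]
  data.frame(animal_id = names(pc1_scores),
             fH = GROUP_FRACTIONS[grp, "fH"],
             fJ = GROUP_FRACTIONS[grp, "fJ"],
             group = grp, source = "pca",
             pc1 = unname(pc1_scores), stringsAsFactors = FALSE,
             row.names = NULL)
}

# log-likelihood of the binomial admixture model
.admix_loglik <- function(x, Q, F) {
  Gp <- Q %*% F
  Gp <- pmin(pmax(Gp, 1e-12), 1 - 1e-12)
  sum(x * log(Gp) + (2 - x) * log(1 - Gp))
}

#' Two-population admixture estimation by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' `sum_ij [x_ij log(g_ij) + (2 - x_ij) log(1 - g_ij)]`,
#' `g_ij = sum_k q_ik f_kj`, over per-animal ancestry fractions Q (on the
#' simplex) and per-population allele frequencies F (boxed to
#' `[0.001, 0.999]`) by alternating EM updates; both constrained M-steps
#' are exact maximizers of the EM minorizer, so the log-likelihood is
#' non-decreasing at every iteration. Population labels are mapped to
#' H/J by correlating each frequency row with purebred sample
#' frequencies when purebred ids are supplied, otherwise with the
#' frequency spread along PC1 of the dosage matrix.
#'
#' @param g a `geno_matrix` (MAF-filtered).
#' @param k number of ancestral populations; only 2 is supported.
#' @param max_iter,tol iteration cap and log-likelihood gain tolerance.
#' @param seed integer seed (initialization noise).
#' @param h_ids,j_ids optional purebred animal ids used to label the two
#'   estimated populations.
#' @return list with `composition` (data.frame `animal_id`, `fH`, `fJ`,
#'   `group`, `source = "admixture"`), `F` (2 x SNP frequency matrix),
#'   `loglik` (per-iteration trace), `converged`, `warning_flag`.
#' @export
estimate_admixture <- function(g, k = 2L, max_iter = 2000L, tol = 1e-6,
                               seed = 1L, h_ids = NULL, j_ids = NULL) {
  if (k != 2L) stop("only k = 2 ancestral populations supported")
  x <- g$dosages
  n <- nrow(x); m <- ncol(x)
  set.seed(seed)
  p0 <- colMeans(x) / 2
  F <- rbind(pmin(pmax(p0 + runif(m, -0.05, 0.05), 0.001), 0.999),
             pmin(pmax(p0 - runif(m, -0.05, 0.05), 0.001), 0.999))
  # Q init: first PC of centered dosages rescaled to [0.05, 0.95]
  xc <- sweep(x, 2, 2 * p0)
  pc1 <- tryCatch(svd(xc, nu = 1, nv = 0)$u[, 1], error = function(e)
    runif(n, -1, 1))
  q1 <- (rank(pc1) - 0.5) / n * 0.9 + 0.05
  Q <- cbind(q1, 1 - q1)
  em_step <- function(Q, F) {
    Gp <- pmin(pmax(Q %*% F, 1e-12), 1 - 1e-12)
    # E-step responsibilities folded into the multiplicative updates;
    # all reductions are matrix-vector products (the expected allele
    # counts factorize as q_ik f_kj x_ij / g_ij and analogously for the
    # reference allele)
    A1 <- x / Gp; B1 <- (2 - x) / (1 - Gp)
    Qnew <- matrix(0, n, 2); Fnew <- matrix(0, 2, m)
    for (kk in 1:2) {
      rowA <- as.vector(A1 %*% F[kk, ]) * Q[, kk]       # sum_j x a_ijk
      rowB <- as.vector(B1 %*% (1 - F[kk, ])) * Q[, kk]
      colA <- as.vector(crossprod(A1, Q[, kk])) * F[kk, ]
      colB <- as.vector(crossprod(B1, Q[, kk])) * (1 - F[kk, ])
      Qnew[, kk] <- (rowA + rowB) / (2 * m)
      Fnew[kk, ] <- colA / (colA + colB)
    }
    Qnew <- Qnew / rowSums(Qnew)
    Fnew <- pmin(pmax(Fnew, 0.001), 0.999)
    list(Q = Qnew, F = Fnew)
  }
  project <- function(th) {
    th$Q <- pmin(pmax(th$Q, 1e-6), 1 - 1e-6)
    th$Q <- th$Q / rowSums(th$Q)
    th$F <- pmin(pmax(th$F, 0.001), 0.999)
    th
  }
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    # one SQUAREM acceleration round = two EM maps plus an extrapolated
    # step, kept monotone by falling back to the plain EM iterate
    th0 <- list(Q = Q, F = F)
    th1 <- em_step(th0$Q, th0$F)
    th2 <- em_step(th1$Q, th1$F)
    r <- c(th1$Q - th0$Q, th1$F - th0$F)
    v <- c(th2$Q - th1$Q, th2$F - th1$F) - r
    alpha <- if (sum(v^2) > 0) max(1, sqrt(sum(r^2) / sum(v^2))) else 1
    prop <- project(list(
      Q = th0$Q + 2 * alpha * (th1$Q - th0$Q) +
        alpha^2 * (th2$Q - th1$Q - (th1$Q - th0$Q)),
      F = th0$F + 2 * alpha * (th1$F - th0$F) +
        alpha^2 * (th2$F - th1$F - (th1$F - th0$F))))
    prop <- em_step(prop$Q, prop$F)   # stabilizing EM map
    ll_prop <- .admix_loglik(x, prop$Q, prop$F)
    ll_em <- .admix_loglik(x, th2$Q, th2$F)
    if (is.finite(ll_prop) && ll_prop >= ll_em) {
      Q <- prop$Q; F <- prop$F
      ll <- c(ll, ll_prop)
      it <- it + 3L
    } else {
      Q <- th2$Q; F <- th2$F
      ll <- c(ll, ll_em)
      it <- it + 2L
    }
    k <- length(ll)
    if (k > 1 && ll[k] - ll[k - 1] < tol) { converged <- TRUE; break }
  }
  # two indistinguishable ancestral frequency vectors mean the membership
  # fractions are unidentifiable (e.g. data from a single population)
  unidentifiable <- sd(F[1, ] - F[2, ]) < 0.01 ||
    suppressWarnings(cor(F[1, ], F[2, ])) > 0.999
  warning_flag <- !converged || isTRUE(unidentifiable)
  if (!converged)
    warning("admixture EM did not reach the log-likelihood tolerance in ",
            max_iter, " iterations")
  else if (isTRUE(unidentifiable))
    warning("estimated ancestral populations are nearly identical; ",
            "membership fractions are not identifiable")
  # label populations: which estimated frequency row is Holstein?
  if (!is.null(h_ids) && !is.null(j_ids)) {
    pH <- colMeans(x[h_ids, , drop = FALSE]) / 2
    pJ <- colMeans(x[j_ids, , drop = FALSE]) / 2
    hol_row <- if (cor(F[1, ], pH) + cor(F[2, ], pJ) >=
                   cor(F[2, ], pH) + cor(F[1, ], pJ)) 1L else 2L
  } else {
    # fall back: population whose mean membership correlates positively
    # with PC1 of the dosages is called H (matching pca_of_grm's sign
    # convention only up to sign; caller should supply purebred ids)
    hol_row <- if (cor(Q[, 1], pc1) >= 0) 1L else 2L
  }
  fH <- Q[, hol_row]
  fr <- cbind(fH = fH, fJ = 1 - fH)
  grp <- BREED_GROUPS[apply(abs(outer(fH, GROUP_FRACTIONS[, "fH"], "-")),
                            1, which.min)]
  comp <- data.frame(animal_id = rownames(x), fH = fr[, "fH"],
                     fJ = fr[, "fJ"], group = grp, source = "admixture",
                     stringsAsFactors = FALSE, row.names = NULL)
  list(composition = comp, F = F, loglik = ll, converged = converged,
       warning_flag = warning_flag)
}
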