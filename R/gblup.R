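#' DRP weighting coefficient for a cow
#'
#' `w = (1 - h2) / (c h2 + (1 + (n - 1) t) / n - h2)` for a cow with `n`
#' repeated records: the inverse of the residual-variance ratio of her
#' deregressed proof given heritability, repeatability and the fraction
#' of genetic variance not captured by markers. Vectorized over `n`.
#'
#' @param params a [weight_params()].
#' @param n number of records (>= 1); `Inf` gives the many-record limit.
#' @return weight(s) `w > 0`.
#' @export
cow_weight <- function(params, n) {
  stopifnot(inherits(params, "weight_params"))
  if (any(n < 1)) stop("record count n must be >= 1")
  avg <- ifelse(is.infinite(n), params$t, (1 + (n - 1) * params$t) / n)
  denom <- params$c * params$h2 + avg - params$h2
  if (any(denom <= 0)) stop("non-positive weight denominator: ",
                            "inconsistent (h2, t, c)")
  (1 - params$h2) / denom
}

#' DRP weighting coefficient for a bull
#'
#' `w = (1 - h2) / (c h2 + (4 - h2) / p)` for a bull with `p` daughters.
#' Vectorized over `p`; `Inf` gives the progeny-test limit
#' `(1 - h2) / (c h2)`.
#'
#' @inheritParams cow_weight
#' @param p number of daughters (>= 1).
#' @return weight(s) `w > 0`.
#' @export
bull_weight <- function(params, p) {
  stopifnot(inherits(params, "weight_params"))
  if (any(p < 1)) stop("daughter count p must be >= 1")
  term <- ifelse(is.infinite(p), 0, (4 - params$h2) / p)
  (1 - params$h2) / (params$c * params$h2 + term)
}

# Fixed-effect design matrix: intercept + sex + breed group (first level
# reference); aliased columns dropped from the end with a warning.
.design_matrix <- function(drp) {
  X <- matrix(1, nrow(drp), 1, dimnames = list(NULL, "(Intercept)"))
  for (f in c("sex", "breed_group")) {
    lev <- unique(drp[[f]])
    if (length(lev) > 1)
      for (l in lev[-1])
        X <- cbind(X, as.numeric(drp[[f]] == l))
    if (length(lev) > 1)
      colnames(X)[(ncol(X) - length(lev) + 2):ncol(X)] <-
        paste0(f, lev[-1])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    # drop aliased columns, preferring to keep earlier ones
    drop_idx <- setdiff(seq_len(ncol(X)), keep)
    warning("dropping aliased fixed-effect column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Weighted GBLUP via the mixed-model equations
#'
#' Fits `y = X b + Z u + e` with `Var(u) = G sigma2_g`,
#' `Var(e) = E sigma2_e`, `diag(E)_i = 1/w_i`: DRP observations with
#' per-animal weights, fixed effects (intercept, sex, breed group), and
#' animal effects covarying through the genomic relationship matrix. The
#' equations
#' `[X'RX, X'RZ; Z'RX, Z'RZ + inv(G) lambda] [b; u] = [X'Ry; Z'Ry]` with
#' `R = diag(w)` are solved dense; every animal in the GRM gets a GEBV,
#' so validation animals (present in G, absent from `drp`) are predicted
#' through the relationship coupling.
#'
#' @param drp single-trait DRP table (columns `animal_id`, `drp`, `sex`,
#'   `breed_group`, `weight`); one row per animal.
#' @param grm a `grm` containing every phenotyped and every prediction
#'   animal.
#' @param params a [weight_params()] (used by `"fixed"` variance mode).
#' @param variance_mode `"fixed"` derives `sigma2_e` from `h2` and the
#'   mean weight (unless both variances are supplied); `"em_reml"`
#'   iterates EM-REML updates of both components.
#' @param sigma2_g,sigma2_e optional variance components; `sigma2_g`
#'   defaults to `h2 * var(y)` when not given.
#' @param ridge diagonal ridge added to G before inversion.
#' @param max_iter,tol EM-REML iteration controls.
#' @return object of class `gblup_fit`: `fixed_effects`, `gebv` (named,
#'   for every GRM animal), `sigma2_g`, `sigma2_e`, `lambda`,
#'   `converged`.
#' @export
fit_wgblup <- function(drp, grm, params = weight_params(),
                       variance_mode = c("fixed", "em_reml"),
                       sigma2_g = NULL, sigma2_e = NULL, ridge = 1e-6,
                       max_iter = 200L, tol = 1e-6) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(grm, "grm"))
  ids <- rownames(grm$matrix)
  if (anyDuplicated(drp$animal_id))
    stop("one record per animal per trait expected")
  miss <- setdiff(drp$animal_id, ids)
  if (length(miss)) stop("phenotyped animals missing from GRM: ",
                         paste(head(miss, 5), collapse = ", "))
  if (any(drp$weight <= 0)) stop("weights must be positive")
  y <- drp$drp
  w <- drp$weight
  n <- length(y); q <- length(ids)
  X <- .design_matrix(drp)
  p <- ncol(X)
  Zi <- match(drp$animal_id, ids)   # row i of Z has a 1 in column Zi[i]
  G <- grm$matrix + diag(ridge, q)
  Gi <- tryCatch(chol2inv(chol(G)),
                 error = function(e) stop("GRM not invertible after ridge: ",
                                          conditionMessage(e)))
  if (is.null(sigma2_g)) sigma2_g <- params$h2 * var(y)
  # the weights are scaled so a single-record cow has w near 1; the
  # matching residual variance is the phenotypic residual sigma2_g (1-h2)/h2
  if (variance_mode == "fixed" && is.null(sigma2_e))
    sigma2_e <- sigma2_g * (1 - params$h2) / params$h2
  if (is.null(sigma2_e)) sigma2_e <- sigma2_g  # em_reml start
  XtR <- t(X * w)                    # X' R  (R = diag(w))
  XtRX <- XtR %*% X
  XtRy <- XtR %*% y
  # Z'RZ is diagonal with per-animal summed weights; Z'Ry likewise
  ztrz <- numeric(q); ztry <- numeric(q)
  for (i in seq_len(n)) {
    ztrz[Zi[i]] <- ztrz[Zi[i]] + w[i]
    ztry[Zi[i]] <- ztry[Zi[i]] + w[i] * y[i]
  }
  XtRZ <- matrix(0, p, q)
  for (i in seq_len(n)) XtRZ[, Zi[i]] <- XtRZ[, Zi[i]] + XtR[, i]
  rhs <- c(XtRy, ztry)
  rankX <- qr(X)$rank
  solve_mme <- function(lambda) {
    C <- rbind(cbind(XtRX, XtRZ),
               cbind(t(XtRZ), diag(ztrz, q) + Gi * lambda))
    ch <- tryCatch(chol(C), error = function(e)
      stop("singular mixed-model coefficient matrix: ",
           conditionMessage(e)))
    Cinv <- chol2inv(ch)
    list(sol = as.vector(Cinv %*% rhs), Cinv = Cinv)
  }
  iters <- 1L
  converged <- TRUE
  if (variance_mode == "fixed") {
    lambda <- sigma2_e / sigma2_g
    s <- solve_mme(lambda)
  } else {
    converged <- FALSE
    for (iters in seq_len(max_iter)) {
      lambda <- sigma2_e / sigma2_g
      s <- solve_mme(lambda)
      u <- s$sol[(p + 1):(p + q)]
      Cuu <- s$Cinv[(p + 1):(p + q), (p + 1):(p + q)]
      sg_new <- as.numeric(t(u) %*% Gi %*% u +
                             sigma2_e * sum(Gi * Cuu)) / q
      se_new <- as.numeric(sum(rhs * s$sol) * -1 + sum(w * y^2)) /
        (n - rankX)
      rel <- max(abs(sg_new - sigma2_g), abs(se_new - sigma2_e)) /
        max(sigma2_g, sigma2_e)
      sigma2_g <- sg_new; sigma2_e <- se_new
      if (rel < tol) { converged <- TRUE; break }
    }
    lambda <- sigma2_e / sigma2_g
    s <- solve_mme(lambda)
  }
  sol <- s$sol
  b <- sol[seq_len(p)]
  names(b) <- colnames(X)
  u <- sol[(p + 1):(p + q)]
  names(u) <- ids
  structure(list(fixed_effects = b, gebv = u, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, lambda = lambda,
                 converged = converged, iterations = iters,
                 variance_mode = variance_mode),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(paste0("gblup_fit: %d animals, lambda = %.4g ",
                     "(sigma2_g = %.4g, sigma2_e = %.4g, mode = %s)\n"),
              length(x$gebv), x$lambda, x$sigma2_g, x$sigma2_e,
              x$variance_mode))
  invisible(x)
}
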