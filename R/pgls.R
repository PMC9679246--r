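#' Phylogenetic covariance matrix under Brownian motion
#'
#' `V[i, j]` is the root-to-MRCA path length shared by taxa i and j;
#' the diagonal holds root-to-leaf depths. Under time-scaled Brownian
#' motion this is the trait covariance up to the rate constant sigma^2.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric matrix with taxa as dimnames.
#' @export
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
phylo_vcv <- function(tree) {
  dec <- tree_decomp(tree)
  V <- vcv_from_decomp(dec, kappa = 1)
  if (all(diag(V) == 0))
    stop("tree has zero depth; covariance matrix is degenerate")
  V
}

## edge decomposition: Z (tips x edges, 0/1 descendant indicators) and
## edge lengths b; V(kappa) = Z diag(b^kappa) Z^T.
tree_decomp <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 leaves")
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  E <- nrow(tree$edge)
  nn <- n + tree$Nnode
  tipsets <- vector("list", nn)
  for (i in seq_len(n)) tipsets[[i]] <- i
  po <- ape::postorder(tree)  # child edges before parent edges
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  Z <- matrix(0, n, E)
  for (e in seq_len(E)) Z[tipsets[[tree$edge[e, 2]]], e] <- 1
  list(Z = Z, b = el, tips = tree$tip.label)
}

vcv_from_decomp <- function(dec, kappa = 1) {
  w <- dec$b^kappa  # 0^0 = 1 in R, matching the kappa -> 0 limit convention
  V <- dec$Z %*% (w * t(dec$Z))
  V <- (V + t(V)) / 2
  dimnames(V) <- list(dec$tips, dec$tips)
  V
}

#' Pagel's kappa: raise branch lengths to a power
#'
#' `kappa = 1` leaves the tree unchanged; `kappa = 0` sets every
#' positive branch to 1 (punctuated, "speciational" change);
#' `0 < kappa < 1` compresses long branches. `0^0` is defined as 1, so
#' zero-length branches (e.g. polytomies resolved with zero branches)
#' become 1 at `kappa = 0` as well.
#'
#' @param tree a `phylo` object.
#' @param kappa nonnegative exponent.
#' @return the transformed tree.
#' @export
apply_kappa <- function(tree, kappa) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("kappa must be a single nonnegative number")
  tree$edge.length <- tree$edge.length^kappa
  tree
}

#' Pagel's delta: raise node depths to a power
#'
#' Every node's root-to-node depth `d` becomes `d^delta`; branch
#' lengths are recomputed as child depth minus parent depth.
#' `delta > 1` concentrates change late in the tree, `delta < 1` early.
#' Requires an ultrametric tree (within the tolerance of
#' [is_ultrametric_tree()]); `0^x` is 0 for `x > 0`.
#'
#' @param tree an ultrametric `phylo` object.
#' @param delta positive exponent.
#' @return the transformed tree.
#' @export
apply_delta <- function(tree, delta) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  if (!is_ultrametric_tree(tree))
    stop("delta transform requires an ultrametric tree; ",
         "rescale the tree to a time calibration first")
  d <- node_depths(tree)^delta
  tree$edge.length <- d[tree$edge[, 2]] - d[tree$edge[, 1]]
  tree
}

#' Pagel's lambda: shrink off-diagonal covariances
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance
#' matrix by `lambda` in `[0, 1]`, leaving the diagonal unchanged.
#' `lambda = 1` keeps the Brownian expectation; `lambda = 0` is a star
#' phylogeny (phylogenetically independent residuals).
#'
#' @param V covariance matrix from [phylo_vcv()].
#' @param lambda value in `[0, 1]`.
#' @return the transformed matrix.
#' @export
apply_lambda <- function(V, lambda) {
  stopifnot(is.matrix(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]")
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

#' Covariance matrix under composed kappa, delta, lambda transforms
#'
#' Fixed composition order: kappa on branch lengths, then delta on
#' (MRCA) depths, then lambda on the covariance. Delta acts elementwise
#' on the MRCA depths of the kappa-transformed tree, which on an
#' ultrametric tree with `kappa = 1` coincides with [apply_delta()]
#' followed by [phylo_vcv()].
#'
#' @param tree a `phylo` object (or a precomputed decomposition via the
#'   `decomp` argument, for repeated evaluation).
#' @param kappa,delta,lambda transform parameters.
#' @param decomp optional internal edge decomposition.
#' @return covariance matrix.
#' @export
transform_vcv <- function(tree, kappa = 1, lambda = 1, delta = 1,
                          decomp = NULL) {
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  dec <- decomp %||% tree_decomp(tree)
  V <- vcv_from_decomp(dec, kappa = kappa)
  if (delta != 1) V <- V^delta  # entries are MRCA depths, all >= 0
  if (lambda != 1) V <- apply_lambda(V, lambda)
  V
}

#' Generalized least squares with a phylogenetic covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V)` by GLS:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`. Standard errors come from
#' `sigma2 * (X' V^-1 X)^-1` with `sigma2 = RSS_V / (n - k)`; p-values
#' are two-sided t with `n - k` df. R-squared is defined against the
#' GLS intercept-only fit under the same `V`, so fixed- and
#' optimized-transform fits are comparable. The log-likelihood profiles
#' sigma^2 at its ML value `RSS_V / n`.
#'
#' If `V` is not numerically positive definite, a ridge of
#' `1e-10 * mean(diag(V))` is added once, with a warning.
#'
#' @param X design matrix (n x k), including the intercept column.
#' @param y response vector.
#' @param V covariance matrix (n x n), e.g. from [transform_vcv()].
#' @param transforms optional list recording kappa/lambda/delta and the
#'   mode ("fixed" or "optimized") for reporting.
#' @return object of class `pgls_fit`.
#' @export
pgls_fit <- function(X, y, V, transforms = list(kappa = 1, lambda = 1,
                                                delta = 1, mode = "fixed")) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(X)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  if (n <= k) stop("need more observations than coefficients (n > k)")
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1L)))[seq_len(k)]

  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    warning("V not positive definite; adding ridge 1e-10 * mean(diag(V))")
    V <- V + diag(1e-10 * mean(diag(V)), n)
    U <- chol(V)
  }
  ## whiten: solve t(U) z = v  (V = U'U)
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  colnames(wX) <- colnames(X)  # backsolve drops dimnames
  qrX <- qr(wX)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("collinear design: X'V^-1X is singular; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, wy)
  resid <- wy - wX %*% beta
  rss <- sum(resid^2)
  df_res <- n - k
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qrX)[seq_len(k), seq_len(k), drop = FALSE])
  ## qr.R columns follow qrX$pivot; map back to original column order
  se <- sqrt(sigma2 * diag(XtX_inv))[order(qrX$pivot)]
  names(se) <- colnames(X)
  beta <- beta[colnames(X)]
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)

  ## intercept-only GLS null for R^2
  w1 <- backsolve(U, rep(1, n), transpose = TRUE)
  b0 <- sum(w1 * wy) / sum(w1^2)
  rss0 <- sum((wy - w1 * b0)^2)
  r2 <- 1 - rss / rss0

  logdet <- 2 * sum(log(diag(U)))
  sigma2_ml <- rss / n
  ll <- -(n / 2) * log(2 * pi * sigma2_ml) - logdet / 2 - n / 2

  structure(list(
    coefficients = beta, se = se, t_values = tval, p_values = pval,
    r_squared = r2, log_likelihood = ll, sigma2 = sigma2, rss = rss,
    transforms = transforms, n = n, df_residual = df_res
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic generalized least squares fit\n")
  tab <- cbind(Estimate = x$coefficients, SE = x$se,
               t = x$t_values, p = x$p_values)
  print(round(tab, digits))
  tr <- x$transforms
  cat(sprintf("kappa = %.3g  lambda = %.3g  delta = %.3g  (%s)\n",
              tr$kappa, tr$lambda, tr$delta, tr$mode))
  cat(sprintf("n = %d  R2 = %.4f  logLik = %.4f  sigma2 = %.4g\n",
              x$n, x$r_squared, x$log_likelihood, x$sigma2))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' Profile log-likelihood of a transformed PGLS model
#'
#' Applies kappa to branch lengths, delta to depths, lambda to the
#' covariance (in that order), fits the GLS, and returns
#' `-(n/2) log(2 pi sigma2_ML) - log|V|/2 - n/2` with
#' `sigma2_ML = RSS_V / n`.
#'
#' @inheritParams pgls_fit
#' @param tree a `phylo` object over the rows of `X`/`y` (same order as
#'   the tip labels unless `decomp` is supplied with a known ordering).
#' @param kappa,lambda,delta transform values.
#' @param decomp optional precomputed decomposition for speed.
#' @return scalar log-likelihood.
#' @export
pgls_profile_loglik <- function(tree, X, y, kappa = 1, lambda = 1, delta = 1,
                                decomp = NULL) {
  dec <- decomp %||% tree_decomp(tree)
  V <- transform_vcv(NULL, kappa = kappa, lambda = lambda, delta = delta,
                     decomp = dec)
  fit <- pgls_fit(X, y, V, transforms = list(kappa = kappa, lambda = lambda,
                                             delta = delta, mode = "fixed"))
  fit$log_likelihood
}

#' Maximum-likelihood optimization of branch-length transforms
#'
#' Maximizes the profile log-likelihood over the requested subset of
#' Pagel's transforms, the others held at 1. A deterministic coarse
#' lattice of starting points (about 8) seeds bounded local
#' optimizations (`L-BFGS-B`); the best optimum is returned together
#' with its fit. Estimates landing on a bound are flagged in
#' `hit_bounds` -- with the default upper bound of 3 on kappa and
#' delta, an estimate printed exactly at the bound should be read as a
#' bound artifact.
#'
#' @inheritParams pgls_profile_loglik
#' @param which character subset of `c("kappa", "lambda", "delta")` to
#'   optimize (default all three, jointly).
#' @param bounds named list of `c(lower, upper)` bounds; defaults
#'   kappa in `[1e-6, 3]`, lambda in `[0, 1]`, delta in `[1e-6, 3]`.
#' @return list with `transforms` (kappa, lambda, delta, mode =
#'   "optimized"), `fit` (a `pgls_fit` at the optimum), `log_likelihood`
#'   and `hit_bounds` (character vector of parameters at a bound).
#' @export
optimize_transforms <- function(tree, X, y,
                                which = c("kappa", "lambda", "delta"),
                                bounds = list(kappa = c(1e-6, 3),
                                              lambda = c(0, 1),
                                              delta = c(1e-6, 3))) {
  which <- match.arg(which, c("kappa", "lambda", "delta"),
                     several.ok = TRUE)
  dec <- tree_decomp(tree)
  full <- c(kappa = 1, lambda = 1, delta = 1)
  lo <- vapply(which, function(p) bounds[[p]][1], 0)
  hi <- vapply(which, function(p) bounds[[p]][2], 0)

  obj <- function(par) {
    pp <- full
    pp[which] <- par
    ll <- tryCatch(
      pgls_profile_loglik(NULL, X, y, kappa = pp["kappa"],
                          lambda = pp["lambda"], delta = pp["delta"],
                          decomp = dec),
      error = function(e) NA_real_, warning = function(w) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ## deterministic coarse lattice, about 8 starts
  d <- length(which)
  pts_per_dim <- c(8L, 3L, 2L)[d]
  grid1 <- function(l, h) l + (h - l) * (seq_len(pts_per_dim) - 0.5) / pts_per_dim
  starts <- as.matrix(expand.grid(lapply(seq_len(d), function(i)
    grid1(lo[i], hi[i]))))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    op <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value) || op$value >= 1e10) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("non-finite likelihood at all starting points")

  pp <- full
  pp[which] <- best$par
  tol <- 1e-6 * pmax(1, abs(hi))
  at_bound <- which[(best$par - lo) <= tol[seq_len(d)] |
                    (hi - best$par) <= tol[seq_len(d)]]
  V <- transform_vcv(NULL, kappa = pp["kappa"], lambda = pp["lambda"],
                     delta = pp["delta"], decomp = dec)
  transforms <- list(kappa = unname(pp["kappa"]), lambda = unname(pp["lambda"]),
                     delta = unname(pp["delta"]), mode = "optimized")
  fit <- pgls_fit(X, y, V, transforms = transforms)
  list(transforms = transforms, fit = fit,
       log_likelihood = fit$log_likelihood, hit_bounds = at_bound)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 39)  # 0.00128
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1)
    stop("m must be a positive integer")
  alpha / m
}

#' Formula interface for PGLS
#'
#' Convenience wrapper around [pgls_fit()] / [optimize_transforms()]:
#' aligns a data frame (rows named by species) with a tree, prunes the
#' tree to the modelled species, and fits the model either with fixed
#' transform values or with maximum-likelihood optimization.
#'
#' @param formula model formula over columns of `data`.
#' @param data data frame with species row names.
#' @param tree a `phylo` object containing at least the modelled species.
#' @param method `"fixed"` (default) or `"ML"`.
#' @param kappa,lambda,delta fixed transform values (used when
#'   `method = "fixed"`).
#' @param which transforms to optimize when `method = "ML"`.
#' @return a `pgls_fit` (for `method = "ML"`, with the optimized
#'   transform values recorded in `$transforms` and bound hits in
#'   `$hit_bounds`).
#' @export
pgls <- function(formula, data, tree, method = c("fixed", "ML"),
                 kappa = 1, lambda = 1, delta = 1,
                 which = c("kappa", "lambda", "delta")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), inherits(tree, "phylo"))
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  species <- rownames(data)
  if (is.null(species)) stop("data must have species row names")
  tree <- prune_to_taxa(tree, species)
  data <- data[tree$tip.label, , drop = FALSE]  # tree tip order
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  if (method == "fixed") {
    V <- transform_vcv(tree, kappa = kappa, lambda = lambda, delta = delta)
    fit <- pgls_fit(X, y, V, transforms = list(kappa = kappa, lambda = lambda,
                                               delta = delta, mode = "fixed"))
  } else {
    op <- optimize_transforms(tree, X, y, which = which)
    fit <- op$fit
    fit$hit_bounds <- op$hit_bounds
  }
  fit$species <- tree$tip.label
  fit$formula <- formula
  fit
}
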