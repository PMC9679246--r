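test_that("phylo_vcv matches brute-force shared-path enumeration and ape::vcv", {
  for (i in 1:20) {
    tr <- random_tree(sample(4:12, 1), seed = 200 + i)
    V <- phylo_vcv(tr)
    B <- brute_force_vcv(tr)
    expect_equal(V[rownames(B), colnames(B)], B, tolerance = 1e-12)
    A <- ape::vcv(tr)
    expect_equal(V[rownames(A), colnames(A)], A, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("worked three-taxon covariance example", {
  V <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(V["a", "b"], 1)
  expect_equal(V["a", "c"], 0)
  expect_equal(diag(V), c(a = 2, b = 2, c = 2))
})

test_that("kappa = 1, lambda = 1, delta = 1 are exact identities", {
  for (i in 1:10) {
    tr <- random_tree(8, seed = 300 + i)
    V <- phylo_vcv(tr)
    expect_identical(apply_kappa(tr, 1)$edge.length, tr$edge.length)
    expect_equal(apply_lambda(V, 1), V)
    expect_equal(transform_vcv(tr, kappa = 1, lambda = 1, delta = 1), V)
  }
  # delta identity needs an ultrametric tree
  ut <- simulate_yule_tree(sim_config(seed = 5, n_taxa = 10))
  expect_equal(apply_delta(ut, 1)$edge.length, ut$edge.length,
               tolerance = 1e-12)
  expect_equal(transform_vcv(ut, delta = 1), phylo_vcv(ut))
})

test_that("kappa = 0 gives unit branches with 0^0 = 1; lambda = 0 gives a star", {
  tr <- random_tree(6, seed = 11)
  tr$edge.length[1] <- 0
  k0 <- apply_kappa(tr, 0)
  expect_true(all(k0$edge.length == 1))  # includes the zero-length branch
  V <- phylo_vcv(tr)
  V0 <- apply_lambda(V, 0)
  expect_equal(V0, diag(diag(V)), ignore_attr = TRUE)
  expect_equal(diag(V0), diag(V))
})

test_that("delta transforms powers node depths; composed path matches tree path", {
  ut <- simulate_yule_tree(sim_config(seed = 7, n_taxa = 12))
  for (delta in c(0.5, 1.5, 2)) {
    d <- node_depths(apply_delta(ut, delta))
    expect_equal(sort(unname(d)), sort(unname(node_depths(ut)^delta)),
                 tolerance = 1e-10)
    # covariance path: V^delta elementwise equals vcv of the
    # depth-transformed tree (ultrametric, kappa = 1)
    expect_equal(transform_vcv(ut, delta = delta),
                 phylo_vcv(apply_delta(ut, delta)), tolerance = 1e-10)
  }
  expect_error(apply_delta(random_tree(6, seed = 2), 2), "ultrametric")
})

test_that("transform composition order is kappa then delta then lambda", {
  ut <- simulate_yule_tree(sim_config(seed = 9, n_taxa = 10))
  kappa <- 0.6; delta <- 1.4; lambda <- 0.7
  V <- transform_vcv(ut, kappa = kappa, lambda = lambda, delta = delta)
  # manual composition
  Vk <- phylo_vcv(apply_kappa(ut, kappa))
  Vkd <- Vk^delta
  Vman <- apply_lambda(Vkd, lambda)
  expect_equal(V, Vman, tolerance = 1e-10)
})

test_that("GLS with V = I reproduces lm exactly", {
  set.seed(42)
  n <- 40
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  colnames(X)[1] <- "(Intercept)"
  y <- 1 + 0.5 * X[, 2] - 0.2 * X[, 3] + rnorm(n)
  fit <- pgls_fit(X, y, diag(n))
  ref <- lm(y ~ X[, 2] + X[, 3])
  sref <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-12)
  expect_equal(unname(fit$se), unname(sref$coefficients[, 2]), tolerance = 1e-12)
  expect_equal(unname(fit$p_values), unname(sref$coefficients[, 4]),
               tolerance = 1e-12)
  expect_equal(fit$r_squared, sref$r.squared, tolerance = 1e-12)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(fit$sigma2, sref$sigma^2, tolerance = 1e-12)
})

test_that("GLS with general V reproduces lm on pre-whitened data", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- random_tree(25, seed = 500 + rep)
    V <- phylo_vcv(tr)
    n <- nrow(V)
    X <- cbind("(Intercept)" = 1, x = rnorm(n))
    y <- 0.3 + 0.8 * X[, 2] + t(chol(V)) %*% rnorm(n)
    fit <- pgls_fit(X, y, V)
    U <- chol(V)
    wy <- backsolve(U, y, transpose = TRUE)
    wX <- backsolve(U, X, transpose = TRUE)
    ref <- lm(wy ~ wX - 1)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(unname(fit$se),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
  }
})

test_that("collinear designs fail loudly with the offending column named", {
  set.seed(1)
  n <- 20
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x, x_copy = 2 * x)
  expect_error(pgls_fit(X, rnorm(n), diag(n)), "x_copy")
})

test_that("profile likelihood is maximized near the generating lambda", {
  cfg <- sim_config(seed = 31, n_taxa = 50)
  tr <- simulate_yule_tree(cfg)
  y <- simulate_bm_traits(tr, cfg, sigma = 1, n_traits = 1, seed_offset = 9)[, 1]
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  dec <- tree_decomp(tr)
  ll1 <- pgls_profile_loglik(NULL, X, y, lambda = 1, decomp = dec)
  ll0 <- pgls_profile_loglik(NULL, X, y, lambda = 0, decomp = dec)
  expect_gt(ll1, ll0)  # data generated with lambda = 1
  op <- optimize_transforms(tr, X, y, which = "lambda")
  expect_gt(op$transforms$lambda, 0.8)
  expect_gte(op$log_likelihood, ll1 - 1e-6)
})

test_that("optimizer reports bound hits", {
  cfg <- sim_config(seed = 33, n_taxa = 40)
  tr <- simulate_yule_tree(cfg)
  set.seed(99)
  y <- rnorm(ape::Ntip(tr))  # star-like data: lambda should hit 0
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  op <- optimize_transforms(tr, X, y, which = "lambda")
  expect_lt(op$transforms$lambda, 0.05)
  if (op$transforms$lambda == 0)
    expect_true("lambda" %in% op$hit_bounds)
})

test_that("non-positive-definite V gets a ridge with a warning", {
  n <- 5
  V <- matrix(1, n, n)  # rank 1, not PD
  diag(V) <- 1
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  expect_warning(fit <- pgls_fit(X, rnorm(n), V), "ridge")
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("bonferroni_threshold matches the 39-test study threshold", {
  expect_equal(bonferroni_threshold(0.05, 39), 0.05 / 39)
  expect_lt(abs(bonferroni_threshold(0.05, 39) - 0.00128), 5e-6)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("pgls formula wrapper aligns data to the tree and drops incomplete rows", {
  b <- small_bundle()
  norm <- b$normalized
  df <- data.frame(z_tsg = norm$z_tsg, z_og = norm$z_og,
                   row.names = norm$species)
  df$z_og[1] <- NA  # one incomplete row must be dropped
  fit <- pgls(z_tsg ~ z_og, df, b$tree)
  expect_s3_class(fit, "pgls_fit")
  expect_equal(fit$n, nrow(df) - 1L)
  expect_false(norm$species[1] %in% fit$species)

  # permuting data rows must not change the fit (alignment by name)
  df2 <- df[sample(nrow(df)), ]
  fit2 <- pgls(z_tsg ~ z_og, df2, b$tree)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
})
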