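# independent dense restricted log-likelihood used as an oracle
dense_reml_ll <- function(sg, se, y, K, X = matrix(1, length(y), 1)) {
  V <- sg * K + se * diag(length(y))
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  Vi <- chol2inv(cV)
  T_ <- t(X) %*% Vi %*% X
  b <- solve(T_, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
             2 * sum(log(diag(cV))) + determinant(T_)$modulus +
             t(r) %*% Vi %*% r))
}

test_that("AIC follows 2P - 2 logL", {
  expect_equal(aic(-100, 2), 204)
  expect_equal(aic(0, 3), 6)
  expect_error(aic(-1, 0), "P must")
})

test_that("AI-REML attains the optimum of a brute-force likelihood grid", {
  set.seed(41)
  n <- 40
  gm <- random_genotypes(n, 200, seed = 41)
  K <- unclass(compute_grm(gm, alpha = -0.5))
  ev <- eigen(K, symmetric = TRUE)
  g <- ev$vectors %*% (sqrt(pmax(ev$values, 0) * 1.5) * rnorm(n))
  y <- drop(2 + g + rnorm(n, 0, 1))
  names(y) <- rownames(K)
  fit <- suppressWarnings(fit_hreml(y, K))
  expect_equal(fit$logL, dense_reml_ll(fit$sigma_g2, fit$sigma_e2, y, K),
               tolerance = 1e-8)
  grid <- expand.grid(sg = seq(0.01, 5, length.out = 200),
                      se = seq(0.01, 5, length.out = 200))
  lls <- mapply(function(a, b) dense_reml_ll(a, b, y, K), grid$sg, grid$se)
  expect_gte(fit$logL, max(lls) - 1e-4)
  expect_equal(fit$AIC, 2 * 2 - 2 * fit$logL)
})

test_that("restricted likelihood is invariant to phenotype translation", {
  set.seed(42)
  n <- 60
  K <- unclass(compute_grm(random_genotypes(n, 100, seed = 42)))
  y <- drop(eigen(K, symmetric = TRUE)$vectors %*% rnorm(n)) + rnorm(n)
  names(y) <- rownames(K)
  f1 <- suppressWarnings(fit_hreml(y, K))
  f2 <- suppressWarnings(fit_hreml(y + 1000, K))
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-5)
  expect_equal(f1$blup, f2$blup, tolerance = 1e-4)
})

test_that("accepted iterations never decrease the log-likelihood", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 50
    K <- unclass(compute_grm(random_genotypes(n, 80, seed = 43 + rep)))
    ev <- eigen(K, symmetric = TRUE)
    y <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n))) +
      rnorm(n, 0, sqrt(runif(1, 0.2, 2)))
    names(y) <- rownames(K)
    fit <- suppressWarnings(fit_hreml(y, K))
    expect_true(all(diff(fit$trajectory) > -1e-6))
    expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  }
})

test_that("a zero-heritability trait is estimated at the boundary", {
  # sigma_g2 = 0 truth, n = 500: h2-hat near 0 in nearly all replicates
  pop <- small_pop()
  gm <- sim_genotypes(pop, generations = 1:5)   # the 500 offspring
  K <- suppressMessages(compute_grm(gm, alpha = -0.5))
  eig <- reml_eigen(K)
  set.seed(44)
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    y <- stats::setNames(rnorm(length(gm$ids)), gm$ids)
    fit <- suppressWarnings(fit_hreml(y, eig))
    if (fit$h2 < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("heritability is recovered from a simulated half-sib population", {
  pop <- small_pop()
  phen <- simulate_phenotypes(pop, h2 = 0.8, alpha_true = -0.5,
                              n_causal = 150, seed = 45)
  y <- stats::setNames(phen$y, phen$id)
  gm <- sim_genotypes(pop)
  K <- suppressMessages(compute_grm(gm, alpha = -0.5))
  fit <- suppressWarnings(fit_hreml(y, unclass(K)))
  expect_lt(abs(fit$h2 - 0.8), 0.1)
})

test_that("BLUP equals hand-built mixed-model equations on a worked pedigree", {
  # 5 individuals: founders 1,2; 3 = (1,2); 4 = (1,3); 5 = (3,2);
  # phenotypes on 1,2,3; predict 4,5 at fixed variance components
  ped <- pedigree(c("1", "2", "3", "4", "5"), c("0", "0", "1", "1", "3"),
                  c("0", "0", "2", "3", "2"))
  A <- build_nrm(ped)
  obs <- c("1", "2", "3"); targ <- c("4", "5")
  y <- c("1" = 1.2, "2" = -0.6, "3" = 0.9)
  sg <- 0.7; se <- 0.5
  # Henderson's MME with Z mapping records to the 5 genetic effects
  X <- matrix(1, 3, 1)
  Z <- matrix(0, 3, 5); Z[cbind(1:3, 1:3)] <- 1
  Ainv <- solve(unclass(A))
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + Ainv * se / sg))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  g_mme <- sol[-1]
  names(g_mme) <- ped$id
  # package route: REML evaluation at fixed components, then kinship BLUP
  fit <- fit_hreml(y, unclass(A)[obs, obs], start = c(sg, se), max_iter = 0)
  expect_equal(unname(fit$blup), unname(g_mme[obs]), tolerance = 1e-8)
  ghat <- predict_blup(fit, A, obs, targ)
  expect_equal(unname(ghat), unname(g_mme[targ]), tolerance = 1e-8)
})

test_that("BLUP limits: zero genetic variance and near-interpolation", {
  A <- build_nrm(pedigree(c("1", "2", "3"), c("0", "0", "1"),
                          c("0", "0", "2")))
  y <- c("1" = 0.3, "2" = -0.2)
  fit0 <- fit_hreml(y, unclass(A)[1:2, 1:2], start = c(1e-10, 1),
                    max_iter = 0)
  expect_equal(max(abs(predict_blup(fit0, A, c("1", "2"), "3"))), 0,
               tolerance = 1e-8)
  # duplicate relationship row + tiny residual variance: prediction
  # approaches the observed individual's centered phenotype
  K <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3,
              dimnames = list(c("a", "b", "t"), c("a", "b", "t")))
  yk <- c(a = 2, b = -2)
  fitk <- fit_hreml(yk, K[1:2, 1:2], start = c(1, 1e-9), max_iter = 0)
  pk <- predict_blup(fitk, K, c("a", "b"), "t")
  expect_equal(unname(pk), 2 - mean(yk), tolerance = 1e-4)
})

test_that("missing phenotypes are dropped and rank-deficient X rejected", {
  set.seed(46)
  n <- 30
  K <- unclass(compute_grm(random_genotypes(n, 60, seed = 46)))
  y <- rnorm(n); y[c(3, 7)] <- NA
  names(y) <- rownames(K)
  fit <- suppressWarnings(fit_hreml(y, K))
  expect_setequal(fit$ids, names(y)[-c(3, 7)])
  Xbad <- cbind(1, 1)[rep(1, n), ]
  expect_error(fit_hreml(stats::setNames(rnorm(n), rownames(K)), K,
                         X = Xbad), "rank deficient")
})
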