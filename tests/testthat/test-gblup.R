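# Independent oracles used here:
#  * closed-form balanced one-way ANOVA-REML estimators,
#  * a brute-force likelihood grid,
#  * an independently coded EM-REML for the single-kernel model,
#  * the conditional mean of the partitioned joint Gaussian.

naive_reml_loglik <- function(y, kernels, vc, s2) {
  n <- length(y); X <- matrix(1, n, 1)
  V <- diag(s2, n)
  for (k in seq_along(kernels)) V <- V + vc[k] * kernels[[k]]
  ch <- chol(V); Vi <- chol2inv(ch)
  A <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(A) %*% t(X) %*% Vi
  -0.5 * (2 * sum(log(diag(ch))) + log(det(A)) +
            drop(crossprod(y, P %*% y)))
}

em_reml_single <- function(y, K, tol = 1e-10, maxit = 5000) {
  n <- length(y); X <- matrix(1, n, 1)
  vc <- s2 <- var(y) / 2
  for (it in seq_len(maxit)) {
    V <- vc * K + diag(s2, n)
    Vi <- chol2inv(chol(V))
    A <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(A) %*% t(X) %*% Vi
    Py <- P %*% y
    vc_new <- vc + vc^2 * drop(crossprod(Py, K %*% Py) - sum(P * K)) / n
    s2_new <- s2 + s2^2 * drop(crossprod(Py) - sum(diag(P))) / n
    if (abs(vc_new - vc) + abs(s2_new - s2) < tol * (vc + s2)) break
    vc <- max(vc_new, 1e-12); s2 <- max(s2_new, 1e-12)
  }
  c(vc = vc, s2 = s2)
}

test_that("build_kernel scales cross-products and stays PSD", {
  expect_equal(build_kernel(diag(3)), diag(3) / 3)
  w <- matrix(c(1, 2, -1), 3, 1)
  expect_equal(build_kernel(w), tcrossprod(w))
  set.seed(1)
  K <- build_kernel(matrix(rnorm(500), 10, 50))
  expect_true(min(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
  expect_error(build_kernel(matrix(numeric(0), 3, 0)), "one column")
})

test_that("kernel_set validates symmetry, PSD and dimensions", {
  K <- build_kernel(matrix(rnorm(40), 8, 5))
  expect_s3_class(kernel_set(list(G = K)), "KernelSet")
  bad <- K; bad[1, 2] <- bad[1, 2] + 1
  expect_error(kernel_set(list(G = bad)), "not symmetric")
  expect_error(kernel_set(list(G = K, H = K[1:4, 1:4])), "dimensions")
  expect_error(kernel_set(list(K)), "named")
  neg <- diag(8); neg[1, 1] <- -1
  expect_error(kernel_set(list(G = neg)), "positive semidefinite")
})

test_that("zero-residual responses drive all components to the boundary", {
  set.seed(2)
  K <- build_kernel(matrix(rnorm(200), 20, 10))
  y <- rep(3, 20)  # y = X * 3 exactly
  fit <- reml_fit(y, kernels = list(G = K))
  expect_true(all(fit$variance_components == 0))
  expect_true(all(fit$boundary))
})

test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(42)
  g <- 10; r <- 6; n <- g * r
  grp <- rep(seq_len(g), each = r)
  Z <- outer(grp, seq_len(g), "==") * 1
  y <- drop(Z %*% rnorm(g, sd = 2)) + rnorm(n)
  fit <- reml_fit(y, kernels = list(grp = build_kernel(Z, divisor = 1)))
  MSE <- sum((y - ave(y, grp))^2) / (n - g)
  MSB <- r * sum((tapply(y, grp, mean) - mean(y))^2) / (g - 1)
  expect_equal(unname(fit$variance_components["grp"]), (MSB - MSE) / r,
               tolerance = 1e-5)
  expect_equal(unname(fit$variance_components["residual"]), MSE,
               tolerance = 1e-5)
})

test_that("the optimum beats a brute-force grid", {
  for (s in 1:3) {
    set.seed(s)
    n <- 20
    K <- build_kernel(matrix(rnorm(n * 30), n, 30))
    y <- drop(crossprod(chol(0.8 * K + diag(0.5, n)), rnorm(n)))
    fit <- reml_fit(y, kernels = list(K = K))
    vy <- var(y)
    grid <- exp(seq(log(1e-4 * vy), log(5 * vy), length.out = 50))
    gridmax <- max(outer(grid, grid, Vectorize(function(a, b)
      naive_reml_loglik(y, list(K), a, b))))
    expect_gte(fit$loglik, gridmax - 1e-6)
  }
})

test_that("single-kernel REML agrees with an independent EM-REML", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 40
    # low-rank kernel, clearly distinguishable from the residual identity,
    # keeps both components interior where EM-REML converges cleanly
    K <- build_kernel(matrix(rnorm(n * 15), n, 15))
    y <- drop(crossprod(chol(1.2 * K + diag(0.8, n)), rnorm(n))) + 2
    fit <- reml_fit(y, kernels = list(K = K))
    em <- em_reml_single(y, K)
    expect_equal(unname(fit$variance_components["K"]), unname(em["vc"]),
                 tolerance = 1e-4)
    expect_equal(unname(fit$variance_components["residual"]),
                 unname(em["s2"]), tolerance = 1e-4)
  }
})

test_that("spectral and general likelihood paths agree", {
  set.seed(7)
  n <- 30
  K <- build_kernel(matrix(rnorm(n * 20), n, 20))
  K2 <- build_kernel(matrix(rnorm(n * 15), n, 15))
  y <- drop(crossprod(chol(K + 0.5 * K2 + diag(0.7, n)), rnorm(n)))
  # two identical kernels halve the component; compare against single fit
  f1 <- reml_fit(y, kernels = list(K = K))            # spectral path
  ll <- naive_reml_loglik(y, list(K),
                          f1$variance_components["K"],
                          f1$variance_components["residual"])
  expect_equal(f1$loglik, ll, tolerance = 1e-8)
  f2 <- reml_fit(y, kernels = list(K = K, K2 = K2))   # general path
  ll2 <- naive_reml_loglik(y, list(K, K2),
                           f2$variance_components[c("K", "K2")],
                           f2$variance_components["residual"])
  expect_equal(f2$loglik, ll2, tolerance = 1e-8)
})

test_that("BLUP equals the joint-Gaussian conditional mean", {
  for (s in 1:3) {
    set.seed(10 + s)
    n <- 12; n1 <- 10
    KG <- build_kernel(matrix(rnorm(n * 25), n, 25))
    KM <- build_kernel(matrix(rnorm(n * 10), n, 10))
    vc <- c(G = 1.3, M = 0.6); s2 <- 0.4; beta <- 1.7
    V <- vc["G"] * KG + vc["M"] * KM + diag(s2, n)
    y <- beta + drop(crossprod(chol(V), rnorm(n)))
    tr <- seq_len(n1); te <- (n1 + 1):n
    split <- train_test_split(list(G = KG, M = KM), tr, te)
    fit <- reml_fit(y[tr], kernels = split$K11)
    yhat <- predict_blup(fit, split)
    # brute-force conditional mean with the fitted parameters
    vch <- fit$variance_components
    Vfit <- vch["G"] * KG + vch["M"] * KM + diag(vch["residual"], n)
    mu <- rep(fit$beta, n)
    oracle <- mu[te] + Vfit[te, tr] %*%
      solve(Vfit[tr, tr], y[tr] - mu[tr])
    expect_equal(yhat, drop(oracle), tolerance = 1e-8)
    # recomputing the training solve gives the same answer
    yhat2 <- predict_blup(fit, split, y1 = y[tr],
                          X1 = matrix(1, n1, 1))
    expect_equal(yhat2, yhat, tolerance = 1e-10)
  }
})

test_that("zero covariance to training collapses prediction to X2 beta", {
  set.seed(30)
  n1 <- 15
  K11 <- build_kernel(matrix(rnorm(n1 * 20), n1, 20))
  y1 <- drop(crossprod(chol(K11 + diag(0.5, n1)), rnorm(n1))) + 4
  fit <- reml_fit(y1, kernels = list(K = K11))
  K21 <- matrix(0, 2, n1)
  pred <- predict_blup(fit, list(K = K21))
  expect_equal(pred, rep(unname(fit$beta), 2), tolerance = 1e-10)
})

test_that("a duplicated training individual is recovered in the noiseless limit", {
  set.seed(31)
  n <- 30
  W <- matrix(rnorm(n * 40), n, 40)
  K <- build_kernel(W)
  u <- drop(crossprod(chol(K + 1e-8 * diag(n)), rnorm(n)))
  y <- 2 + u  # no residual noise
  split <- train_test_split(list(K = rbind(cbind(K, K[, n]),
                                           c(K[n, ], K[n, n]))),
                            seq_len(n), n + 1)
  fit <- reml_fit(y, kernels = list(K = K))
  pred <- predict_blup(fit, split)
  expect_equal(pred, y[n], tolerance = 1e-3)
})

test_that("rescaling the response rescales components and predictions", {
  set.seed(33)
  n <- 30; n1 <- 24
  K <- build_kernel(matrix(rnorm(n * 50), n, 50))
  y <- drop(crossprod(chol(0.9 * K + diag(0.6, n)), rnorm(n))) + 1
  tr <- seq_len(n1); te <- (n1 + 1):n
  split <- train_test_split(list(K = K), tr, te)
  f1 <- reml_fit(y[tr], kernels = split$K11)
  f2 <- reml_fit(10 * y[tr], kernels = split$K11)
  expect_equal(f2$variance_components, 100 * f1$variance_components,
               tolerance = 1e-6)
  expect_equal(predict_blup(f2, split), 10 * predict_blup(f1, split),
               tolerance = 1e-6)
})

test_that("prediction is invariant to permuting the training individuals", {
  set.seed(34)
  n <- 25; n1 <- 20
  K <- build_kernel(matrix(rnorm(n * 40), n, 40))
  y <- drop(crossprod(chol(K + diag(0.5, n)), rnorm(n)))
  tr <- seq_len(n1); te <- (n1 + 1):n
  split <- train_test_split(list(K = K), tr, te)
  fit <- reml_fit(y[tr], kernels = split$K11)
  p1 <- predict_blup(fit, split)
  perm <- sample(n1)
  split2 <- train_test_split(list(K = K), tr[perm], te)
  fit2 <- reml_fit(y[tr][perm], kernels = split2$K11)
  p2 <- predict_blup(fit2, split2)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("fits serialize to JSON", {
  set.seed(35)
  K <- build_kernel(matrix(rnorm(150), 15, 10))
  y <- rnorm(15)
  fit <- reml_fit(y, kernels = list(K = K))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$variance_components$K,
               unname(fit$variance_components["K"]), tolerance = 1e-10)
})
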