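## Multi-kernel linear mixed model:
##   y = X beta + sum_k u_k + e,  u_k ~ N(0, phi_k^2 K_k),  e ~ N(0, s2 I)
## with kinships K built as scaled cross-products of hybrid feature
## matrices (K = W W' / ncol(W)). Variance components by REML; prediction
## of untested individuals by the conditional mean of the joint Gaussian
## with the kinships partitioned into training/testing blocks.

#' Build a kinship kernel from a feature matrix
#' @param W numeric matrix (individuals x features).
#' @param divisor scaling divisor; defaults to the number of features.
#' @return symmetric PSD matrix W W' / divisor.
#' @export
build_kernel <- function(W, divisor = ncol(W)) {
  if (is.null(ncol(W)) || ncol(W) < 1) stop("W needs at least one column")
  K <- tcrossprod(W) / divisor
  (K + t(K)) / 2
}

#' Validate and bundle named kernels
#'
#' Checks symmetry (within 1e-8 relative), positive semidefiniteness
#' (smallest eigenvalue >= -1e-8 * trace/n) and consistent dimensions.
#'
#' @param kernels named list of n x n matrices.
#' @return the list, classed \code{KernelSet}.
#' @export
kernel_set <- function(kernels) {
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    stop("kernels must be named")
  n <- nrow(kernels[[1]])
  for (nm in names(kernels)) {
    K <- kernels[[nm]]
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      stop("kernel ", nm, " has inconsistent dimensions")
    sc <- max(abs(K), 1e-12)
    if (max(abs(K - t(K))) > 1e-8 * sc) stop("kernel ", nm, " not symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(sum(diag(K)) / n, 1e-12))
      stop("kernel ", nm, " not positive semidefinite")
  }
  structure(kernels, class = "KernelSet")
}

## Restricted log-likelihood and its gradient at variance components `vc`
## (kernels) and `s2` (residual). Returns -2 being avoided; loglik is the
## standard REML criterion up to an additive constant.
reml_eval <- function(vc, s2, y, X, kernels) {
  n <- length(y)
  V <- diag(s2, n)
  for (k in seq_along(kernels)) V <- V + vc[k] * kernels[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  jitter <- FALSE
  if (is.null(ch)) {
    V <- V + diag(1e-8 * mean(diag(V)), n)
    ch <- chol(V)
    jitter <- TRUE
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chA <- chol(XtVinvX)
  logdetA <- 2 * sum(log(diag(chA)))
  beta <- backsolve(chA, forwardsolve(t(chA), crossprod(VinvX, y)))
  P <- Vinv - VinvX %*% chol2inv(chA) %*% t(VinvX)
  Py <- P %*% y
  quad <- drop(crossprod(y, Py))
  ll <- -0.5 * (logdetV + logdetA + quad)
  grad <- numeric(length(kernels) + 1)
  for (k in seq_along(kernels)) {
    KPy <- kernels[[k]] %*% Py
    grad[k] <- -0.5 * (sum(P * kernels[[k]]) - drop(crossprod(Py, KPy)))
  }
  grad[length(grad)] <- -0.5 * (sum(diag(P)) - sum(Py^2))
  list(loglik = ll, grad = grad, beta = drop(beta), Py = drop(Py),
       w = drop(Vinv %*% (y - X %*% beta)), jitter = jitter)
}

## Single-kernel fast path: work in the kernel eigenbasis so each
## evaluation is O(n p^2) instead of O(n^3).
reml_eval_spectral <- function(vc, s2, z, W, d, y_norm2_unused = NULL) {
  v <- vc * d + s2
  A <- crossprod(W, W / v)
  chA <- chol(A)
  logdetA <- 2 * sum(log(diag(chA)))
  bz <- crossprod(W, z / v)
  beta <- backsolve(chA, forwardsolve(t(chA), bz))
  Ainv <- chol2inv(chA)
  pz <- z / v - (W / v) %*% (Ainv %*% bz)
  quad <- sum(z * pz)
  ll <- -0.5 * (sum(log(v)) + logdetA + quad)
  # tr(P K) and tr(P) with K = diag(d) in this basis
  Wv <- W / v
  trPK <- sum(d / v) - sum(Ainv * crossprod(Wv, Wv * d))
  trP <- sum(1 / v) - sum(Ainv * crossprod(Wv, Wv))
  gK <- -0.5 * (trPK - sum(d * pz^2))
  gE <- -0.5 * (trP - sum(pz^2))
  list(loglik = ll, grad = c(gK, gE), beta = drop(beta), pz = drop(pz))
}

#' REML fit of a multi-kernel mixed model
#'
#' Maximizes the restricted log-likelihood over non-negative variance
#' components with a bounded quasi-Newton search (L-BFGS-B) on the log
#' scale, using analytic gradients; a spectral reparameterization is used
#' for single-kernel models. Convergence: relative restricted-log-likelihood
#' change below 1e-8, at most 500 iterations. Components at the lower bound
#' (1e-10 of the phenotypic variance) are reported as 0 and flagged.
#'
#' @param y numeric response (no missing values).
#' @param kernels named list of kinship matrices (or a \code{KernelSet}).
#' @param X fixed-effect design matrix; default intercept-only.
#' @param init optional numeric vector of starting values, one per kernel
#'   plus residual (raw variance scale).
#' @param validate check the kernels with \code{\link{kernel_set}}.
#' @return an object of class \code{MixedModelFit}: fixed effects
#'   \code{beta}, \code{variance_components} (named, incl. "residual"),
#'   \code{loglik}, \code{convergence}, \code{boundary} flags, and the
#'   training-side vector \code{w} = V^{-1}(y - X beta) used for block
#'   prediction.
#' @export
reml_fit <- function(y, kernels, X = NULL, init = NULL, validate = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("need at least 10 observations")
  if (anyNA(y)) stop("missing phenotypes must be removed upstream")
  if (validate) kernels <- kernel_set(kernels)
  if (is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  vy <- stats::var(y)
  if (vy == 0) vy <- 1
  nk <- length(kernels)
  lower_vc <- 1e-10 * vy
  lb <- log(lower_vc)
  ub <- log(1e6 * vy)
  if (is.null(init)) init <- rep(vy / (nk + 1), nk + 1)
  par0 <- pmin(pmax(log(pmax(init, lower_vc * 2)), lb + 1), ub - 1)

  spectral <- nk == 1
  if (spectral) {
    eg <- eigen(kernels[[1]], symmetric = TRUE)
    U <- eg$vectors
    d <- pmax(eg$values, 0)
    z <- drop(crossprod(U, y))
    W <- crossprod(U, X)
  }

  cache <- new.env(parent = emptyenv())
  evalfn <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    vc <- exp(par[seq_len(nk)]); s2 <- exp(par[nk + 1])
    ev <- if (spectral) reml_eval_spectral(vc, s2, z, W, d)
          else reml_eval(vc, s2, y, X, kernels)
    ev$par <- par
    cache$key <- key; cache$val <- ev
    ev
  }
  fn <- function(par) -evalfn(par)$loglik
  gr <- function(par) {
    ev <- evalfn(par)
    -(ev$grad * exp(par))  # chain rule for log-scale parameters
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(maxit = 500, factr = 4.5e7))
  ev <- evalfn(opt$par)
  vc <- exp(opt$par[seq_len(nk)]); s2 <- exp(opt$par[nk + 1])
  boundary <- c(vc, s2) <= 2 * lower_vc
  vc_rep <- ifelse(boundary[seq_len(nk)], 0, vc)
  s2_rep <- if (boundary[nk + 1]) 0 else s2
  comps <- c(vc_rep, s2_rep)
  names(comps) <- c(names(kernels), "residual")
  names(boundary) <- names(comps)
  # w on the original scale (spectral path works in the eigenbasis)
  w <- if (spectral) drop(U %*% ev$pz) else ev$w
  fit <- list(beta = ev$beta,
              variance_components = comps,
              loglik = ev$loglik,
              convergence = list(converged = opt$convergence == 0,
                                 code = opt$convergence,
                                 message = opt$message,
                                 iterations = opt$counts[["function"]],
                                 grad_norm = sqrt(sum(gr(opt$par)^2))),
              boundary = boundary,
              kernel_labels = names(kernels),
              n = n, w = w, X = X)
  class(fit) <- "MixedModelFit"
  fit
}

#' @exportS3Method base::print
print.MixedModelFit <- function(x, ...) {
  cat("Multi-kernel REML fit\n")
  cat("  variance components:\n")
  for (nm in names(x$variance_components))
    cat(sprintf("    %-10s %.6g%s\n", nm, x$variance_components[nm],
                if (x$boundary[nm]) " (boundary)" else ""))
  cat(sprintf("  restricted loglik: %.4f  (converged: %s)\n", x$loglik,
              x$convergence$converged))
  invisible(x)
}

#' Partition kernels into training/testing blocks
#' @param kernels named list of full n x n kernels.
#' @param train_idx,test_idx disjoint row indices.
#' @return list of class \code{TrainTestSplit} with per-kernel K11, K21,
#'   K22 blocks.
#' @export
train_test_split <- function(kernels, train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)))
    stop("training and testing ids overlap")
  out <- list(train_idx = train_idx, test_idx = test_idx,
              K11 = lapply(kernels, function(K)
                K[train_idx, train_idx, drop = FALSE]),
              K21 = lapply(kernels, function(K)
                K[test_idx, train_idx, drop = FALSE]),
              K22 = lapply(kernels, function(K)
                K[test_idx, test_idx, drop = FALSE]))
  class(out) <- "TrainTestSplit"
  out
}

#' BLUP prediction of testing individuals from a fitted model
#'
#' Computes yhat2 = X2 beta + (sum_k phi_k^2 K21_k) V11^{-1} (y1 - X1 beta).
#' When \code{y1} is omitted the training-side solve stored in \code{fit}
#' (from the same training data) is reused.
#'
#' @param fit a \code{MixedModelFit} trained on the training block.
#' @param split a \code{TrainTestSplit} (or a named list of K21 matrices).
#' @param y1,X1 training response / design, only needed to recompute the
#'   training-side solve.
#' @param X2 testing design matrix; defaults to intercept-only.
#' @return numeric vector of predictions.
#' @export
predict_blup <- function(fit, split, y1 = NULL, X1 = NULL, X2 = NULL) {
  K21 <- if (inherits(split, "TrainTestSplit")) split$K21 else split
  labels <- fit$kernel_labels
  if (!all(labels %in% names(K21)))
    stop("split lacks kernels: ",
         paste(setdiff(labels, names(K21)), collapse = ", "))
  n2 <- nrow(K21[[labels[1]]])
  if (is.null(X2)) X2 <- matrix(1, n2, ncol(fit$X))
  vc <- fit$variance_components
  if (is.null(y1)) {
    w <- fit$w
  } else {
    if (!inherits(split, "TrainTestSplit"))
      stop("recomputing the training solve requires a TrainTestSplit")
    n1 <- length(y1)
    if (is.null(X1)) X1 <- matrix(1, n1, ncol(fit$X))
    V11 <- diag(vc["residual"], n1)
    for (nm in labels) V11 <- V11 + vc[nm] * split$K11[[nm]]
    ch <- tryCatch(chol(V11), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(V11 + diag(1e-8 * mean(diag(V11)), n1))
    w <- drop(chol2inv(ch) %*% (y1 - X1 %*% fit$beta))
  }
  cov21w <- numeric(n2)
  for (nm in labels)
    cov21w <- cov21w + unname(vc[nm]) * drop(K21[[nm]] %*% w)
  unname(drop(X2 %*% fit$beta)) + cov21w
}

#' Serialize a mixed-model fit to JSON
#' @param fit a \code{MixedModelFit}.
#' @param path output file.
#' @export
write_fit <- function(fit, path) {
  obj <- list(beta = unname(fit$beta),
              variance_components = as.list(fit$variance_components),
              loglik = fit$loglik,
              convergence = fit$convergence,
              boundary = as.list(fit$boundary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
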