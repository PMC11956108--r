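make_mwas_data <- function(n, m, seed = 1, causal = 0, r = 0.9) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(paste0("L", seq_len(n)),
                              paste0("met", seq_len(m))))
  y <- rnorm(n)
  if (causal > 0)
    for (j in seq_len(causal))
      y <- y + X[, j] * r / sqrt(1 - r^2) / sqrt(causal)
  mx <- metabolome_matrix(X, normalized = TRUE)
  ph <- phenotype_table(matrix(y, ncol = 1,
                               dimnames = list(rownames(X), "tr")))
  list(mx = mx, ph = ph)
}

test_that("constant metabolites never enter the path and get p = 1", {
  d <- make_mwas_data(50, 10, seed = 2)
  d$mx$values[, 4] <- 7
  res <- lasso_entry_pvalues(d$mx, d$ph, "tr")
  expect_equal(res$p_value[4], 1)
  expect_false(res$significant[4])
  expect_equal(res$lambda_entry[4], 0)
})

test_that("a strong planted metabolite gets a tiny p-value", {
  d <- make_mwas_data(100, 200, seed = 3, causal = 1, r = 0.9)
  res <- lasso_entry_pvalues(d$mx, d$ph, "tr")
  expect_lt(res$p_value[1], 1e-6)
  expect_true(res$significant[1])
  expect_true("met1" %in% select_markers(res))
})

test_that("p-values are monotone in the entry lambda", {
  d <- make_mwas_data(80, 60, seed = 5, causal = 3, r = 0.5)
  res <- lasso_entry_pvalues(d$mx, d$ph, "tr")
  ord <- order(-res$lambda_entry)
  expect_true(all(diff(res$p_value[ord]) >= -1e-12))
})

test_that("permutation backend is seeded and deterministic", {
  d <- make_mwas_data(40, 15, seed = 6, causal = 1, r = 0.6)
  p1 <- lasso_entry_pvalues(d$mx, d$ph, "tr", method = "permutation",
                            B = 50, seed = 9)
  p2 <- lasso_entry_pvalues(d$mx, d$ph, "tr", method = "permutation",
                            B = 50, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  expect_true(all(p1$p_value >= 1 / 51))
})

test_that("input contracts are enforced", {
  d <- make_mwas_data(8, 5)
  expect_error(lasso_entry_pvalues(d$mx, d$ph, "tr"), "fewer than 10")
  d2 <- make_mwas_data(20, 5)
  d2$ph$values[, 1] <- 3
  expect_error(lasso_entry_pvalues(d2$mx, d2$ph, "tr"), "constant trait")
  expect_error(lasso_entry_pvalues(d2$mx, d2$ph, "nope"), "unknown trait")
})

test_that("select_markers uses a strict threshold and orders by p", {
  res <- structure(
    data.frame(metabolite_id = c("a", "b", "c", "d"),
               lambda_entry = c(0.3, 0.4, 0.2, 0.1),
               p_value = c(0.049, 0.01, 0.05, 0.2),
               r2 = 0.1, significant = c(TRUE, TRUE, FALSE, FALSE)),
    class = c("MWASResult", "data.frame"))
  expect_identical(select_markers(res), c("b", "a"))
  res$p_value[] <- 1
  expect_length(select_markers(res), 0)
})

test_that("planted markers are recovered among the selections", {
  d <- make_mwas_data(150, 100, seed = 8, causal = 5, r = 0.8)
  res <- lasso_entry_pvalues(d$mx, d$ph, "tr")
  sel <- select_markers(res)
  expect_true(all(paste0("met", 1:5) %in% sel))
})

test_that("shared_markers intersects per-trait selections", {
  mk <- function(ids_sig, all_ids = paste0("m", 1:6)) {
    structure(data.frame(metabolite_id = all_ids,
                         lambda_entry = 0.1,
                         p_value = ifelse(all_ids %in% ids_sig, 0.01, 0.5),
                         r2 = 0.1,
                         significant = all_ids %in% ids_sig),
              class = c("MWASResult", "data.frame"))
  }
  results <- list(mk(c("m1", "m2")), mk(c("m1", "m3")),
                  mk(c("m1", "m2")), mk(c("m1")))
  expect_identical(shared_markers(results, 4), "m1")
  expect_identical(sort(shared_markers(results, 2)),
                   c("m1", "m2"))
  expect_setequal(shared_markers(results, 1), c("m1", "m2", "m3"))
  expect_error(shared_markers(results, 0), ">= 1")
})

test_that("marker correlations match Pearson and flag constants", {
  set.seed(10)
  n <- 200
  x <- rnorm(n)
  v <- cbind(a = x, b = -x,
             c = 0.5 * x + sqrt(1 - 0.25) * rnorm(n),
             d = rep(2, n))
  rownames(v) <- paste0("L", 1:n)
  mx <- metabolome_matrix(v, normalized = TRUE)
  cc <- marker_correlations(mx, c("a", "b", "c", "d"))
  expect_equal(cc$r["a", "a"], 1)
  expect_equal(cc$r["a", "b"], -1)
  expect_gt(cc$r["a", "c"], 0.36)   # Fisher-z 99% band for rho = 0.5
  expect_lt(cc$r["a", "c"], 0.62)
  expect_true(all(is.na(cc$r["d", ])))
  expect_error(marker_correlations(mx, "a"), "two markers")
})

test_that("metabolite genomic variance separates signal from noise", {
  set.seed(12)
  n <- 200; g <- 300
  codes <- matrix(sample(c(-1, 1), n * g, TRUE), n, g,
                  dimnames = list(paste0("L", 1:n), paste0("s", 1:g)))
  G <- genotype_matrix(codes)
  eff <- rnorm(10)
  v <- cbind(genetic = drop(codes[, 1:10] %*% eff),
             noise = rnorm(n),
             const = rep(1, n))
  rownames(v) <- rownames(codes)
  mx <- metabolome_matrix(v, normalized = TRUE)
  expect_gt(metabolite_genomic_variance(G, mx, "genetic"), 0.9)
  expect_lt(metabolite_genomic_variance(G, mx, "noise"), 0.15)
  expect_warning(out <- metabolite_genomic_variance(G, mx, "const"),
                 "constant")
  expect_true(is.na(out))
})

test_that("MWAS results serialize with their trait", {
  d <- make_mwas_data(30, 8, seed = 13)
  res <- lasso_entry_pvalues(d$mx, d$ph, "tr")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mwas(res, f)
  back <- read.delim(f)
  expect_equal(back$trait[1], "tr")
  expect_equal(nrow(back), 8)
})
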