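## Repeated k-fold cross-validation of the five model configurations with
## the kernel (GBLUP) and boosting engines, predictive-ability computation,
## model comparison, and the random-metabolite control.
##
## Protocol notes. Folds are drawn fresh per repeat from (seed, repeat).
## Within every fold, anything data-driven — metabolic-marker selection in
## "per_fold" mode, boosting hyperparameter tuning when enabled — sees only
## the training portion; test-fold phenotypes influence nothing but the
## final score. Per-repeat predictive ability is computed on the pooled
## out-of-fold predictions (the full sample is predicted exactly once per
## repeat), matching the repeated-CV procedure the models are evaluated
## with; fold-level abilities are kept for diagnostics.

#' Bundle the aligned inputs of a hybrid-prediction analysis
#'
#' @param genotypes parental \code{GenotypeMatrix} (filtered and imputed).
#' @param metabolome line-level, normalized \code{MetabolomeMatrix}.
#' @param parent_phenotypes \code{PhenotypeTable} for the parental lines
#'   (used by the MWAS).
#' @param hybrid_phenotypes \code{PhenotypeTable} for the hybrids.
#' @param crosses \code{CrossTable} mapping hybrids to parents.
#' @return an object of class \code{mmgp_data}.
#' @export
mmgp_data <- function(genotypes, metabolome, parent_phenotypes,
                      hybrid_phenotypes, crosses) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            inherits(metabolome, "MetabolomeMatrix"),
            inherits(parent_phenotypes, "PhenotypeTable"),
            inherits(hybrid_phenotypes, "PhenotypeTable"),
            inherits(crosses, "CrossTable"))
  if (!is.null(metabolome$replicate))
    stop("metabolome must be replicate-averaged (line-level)")
  parents <- unique(c(crosses$parent_female, crosses$parent_male))
  if (!all(parents %in% line_ids(genotypes)))
    stop("cross parents missing from genotypes")
  if (!all(parents %in% metabolome$lines))
    stop("cross parents missing from metabolome")
  if (!all(crosses$hybrid_id %in% rownames(hybrid_phenotypes$values)))
    stop("hybrids missing from hybrid phenotypes")
  structure(list(genotypes = genotypes, metabolome = metabolome,
                 parent_phenotypes = parent_phenotypes,
                 hybrid_phenotypes = hybrid_phenotypes, crosses = crosses),
            class = "mmgp_data")
}

#' @exportS3Method base::print
print.mmgp_data <- function(x, ...) {
  cat(sprintf(
    "mmgp_data: %d parents x %d markers, %d metabolites, %d hybrids, traits: %s\n",
    nrow(x$genotypes$codes), ncol(x$genotypes$codes),
    ncol(x$metabolome$values), nrow(x$crosses),
    paste(colnames(x$hybrid_phenotypes$values), collapse = ", ")))
  invisible(x)
}

#' Predictive ability of a set of predictions
#'
#' The determination coefficient: the squared Pearson correlation between
#' observed and predicted values (the standard genomic-selection usage).
#' \code{method = "R2"} selects 1 - SSE/SST instead; outputs flag which
#' definition produced them via the \code{"method"} attribute.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @param method \code{"cor2"} (default) or \code{"R2"}.
#' @return scalar ability; 0 with a warning if either vector is constant.
#' @export
predictive_ability <- function(observed, predicted,
                               method = c("cor2", "R2")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant vector; predictive ability set to 0")
    out <- 0
  } else out <- switch(method,
    cor2 = stats::cor(observed, predicted)^2,
    R2 = 1 - sum((observed - predicted)^2) /
      sum((observed - mean(observed))^2))
  attr(out, "method") <- method
  out
}

#' Reproducible fold assignment
#' @param n sample size.
#' @param k folds.
#' @param seed base seed.
#' @param rep repeat index; the partition depends only on (seed, rep).
#' @return integer vector of fold labels 1..k.
#' @export
cv_folds <- function(n, k, seed, rep = 1) {
  if (k < 2) stop("k must be >= 2")
  if (n < 3 * k) stop("need at least 3 observations per fold")
  set.seed(seed * 10000L + rep)
  sample(rep(seq_len(k), length.out = n))
}

## Build the kernel list a model configuration uses, from feature blocks on
## all hybrids (training + testing rows together; phenotypes untouched).
model_kernels <- function(model_tag, Z_full, Mline, crosses, marker_ids) {
  ker <- list()
  if (model_uses_genome(model_tag))
    ker$G <- build_kernel(Z_full)
  if (model_uses_metabolome(model_tag)) {
    ids <- if (model_uses_markers(model_tag)) marker_ids else
      metabolite_ids(Mline)
    keep <- match(ids, metabolite_ids(Mline))
    Msub <- metabolome_matrix(Mline$values[, keep, drop = FALSE],
                              lines = Mline$lines, normalized = TRUE)
    ad <- code_metabolites(Msub, crosses)
    ker$Ma <- build_kernel(ad$A)
    ker$Md <- build_kernel(ad$D)
  }
  ker
}

select_markers_for_lines <- function(data, trait, lines, alpha,
                                     mwas_method) {
  Msub <- metabolome_matrix(
    data$metabolome$values[match(lines, data$metabolome$lines), ,
                           drop = FALSE],
    lines = lines, normalized = TRUE)
  res <- lasso_entry_pvalues(Msub, data$parent_phenotypes, trait,
                             alpha = alpha, method = mwas_method)
  select_markers(res, alpha = alpha)
}

#' Repeated k-fold cross-validation of a model configuration
#'
#' @param data an \code{\link{mmgp_data}} bundle.
#' @param trait trait name (column of the hybrid phenotypes).
#' @param model_tag one of GP, MP, MMP, M_GP, MM_GP.
#' @param engine \code{"kernel"} (GBLUP) or \code{"boosting"}.
#' @param k folds (default 10).
#' @param repeats repeats (default 20).
#' @param seed base seed for the fold partitions.
#' @param alpha MWAS significance threshold for marker selection.
#' @param marker_mode \code{"per_fold"} re-selects markers inside each
#'   training fold using only parents of training hybrids (strict
#'   protocol; default); \code{"global"} selects once from all parental
#'   lines; \code{"fixed"} uses \code{marker_ids} as given.
#' @param marker_ids metabolite ids for \code{marker_mode = "fixed"}.
#' @param mwas_method p-value backend for marker selection.
#' @param boost_params boosting hyperparameters (list); ignored by the
#'   kernel engine.
#' @param tune logical: tune boosting hyperparameters inside each training
#'   fold (slow); when FALSE, \code{boost_params} (or defaults) are used.
#' @param n_trials,inner_folds TPE budget when \code{tune = TRUE}.
#' @return an object of class \code{CVResult}.
#' @export
cross_validate <- function(data, trait, model_tag,
                           engine = c("kernel", "boosting"),
                           k = 10, repeats = 20, seed = 1, alpha = 0.05,
                           marker_mode = c("per_fold", "global", "fixed"),
                           marker_ids = NULL,
                           mwas_method = "analytic",
                           boost_params = NULL, tune = FALSE,
                           n_trials = 20, inner_folds = 5) {
  engine <- match.arg(engine)
  marker_mode <- match.arg(marker_mode)
  model_tag <- match.arg(model_tag, model_tags)
  if (!trait %in% colnames(data$hybrid_phenotypes$values))
    stop("unknown trait: ", trait)
  yall <- data$hybrid_phenotypes$values[data$crosses$hybrid_id, trait]
  keep <- !is.na(yall)
  crosses <- data$crosses[keep, , drop = FALSE]
  class(crosses) <- c("CrossTable", "data.frame")
  y <- yall[keep]
  n <- length(y)

  needs_markers <- model_uses_markers(model_tag)
  global_markers <- NULL
  if (needs_markers) {
    if (marker_mode == "fixed") {
      if (is.null(marker_ids) || !length(marker_ids))
        stop("marker_mode='fixed' requires marker_ids")
      global_markers <- marker_ids
    } else if (marker_mode == "global") {
      global_markers <- select_markers_for_lines(
        data, trait, data$metabolome$lines, alpha, mwas_method)
      if (!length(global_markers))
        stop("MWAS selected no markers; ", model_tag,
             " cannot run (consider MP/M_GP or a larger alpha)")
    }
  }

  Z_full <- if (model_uses_genome(model_tag))
    infer_hybrid_genotypes(data$genotypes, crosses) else NULL

  # kernels reusable across folds unless markers are re-selected per fold
  static_model <- !(needs_markers && marker_mode == "per_fold")
  kernels_full <- NULL
  features_full <- NULL
  if (static_model) {
    if (engine == "kernel") {
      kernels_full <- model_kernels(model_tag, Z_full, data$metabolome,
                                    crosses, global_markers)
    } else {
      features_full <- feature_matrix(assemble_features(
        model_tag, data$genotypes, data$metabolome, crosses,
        marker_ids = global_markers))
    }
  }

  fold_tab <- list()
  repeat_ability <- numeric(repeats)
  fold_assignments <- vector("list", repeats)
  predictions <- matrix(NA_real_, n, repeats,
                        dimnames = list(crosses$hybrid_id, NULL))
  warm <- NULL
  for (r in seq_len(repeats)) {
    fold <- cv_folds(n, k, seed, r)
    fold_assignments[[r]] <- fold
    pred <- rep(NA_real_, n)
    fab <- numeric(k)
    for (f in seq_len(k)) {
      te <- which(fold == f); tr <- which(fold != f)
      markers_f <- global_markers
      if (needs_markers && marker_mode == "per_fold") {
        train_parents <- unique(c(crosses$parent_female[tr],
                                  crosses$parent_male[tr]))
        markers_f <- select_markers_for_lines(data, trait, train_parents,
                                              alpha, mwas_method)
        if (!length(markers_f))
          stop("MWAS selected no markers in a training fold; ", model_tag,
               " cannot run (consider marker_mode='global' or larger alpha)")
      }
      if (engine == "kernel") {
        ker <- if (static_model) kernels_full else
          model_kernels(model_tag, Z_full, data$metabolome, crosses,
                        markers_f)
        split <- train_test_split(ker, tr, te)
        fit <- reml_fit(y[tr], kernels = split$K11, init = warm)
        warm <- fit$variance_components
        warm[warm == 0] <- 1e-8 * stats::var(y[tr])
        pred[te] <- predict_blup(fit, split)
      } else {
        Xf <- if (static_model) features_full else
          feature_matrix(assemble_features(
            model_tag, data$genotypes, data$metabolome, crosses,
            marker_ids = markers_f))
        params <- boost_params
        if (tune) {
          params <- tune_boosting(Xf[tr, , drop = FALSE], y[tr],
                                  n_trials = n_trials,
                                  inner_folds = inner_folds,
                                  seed = seed * 1000L + r * 10L + f)$params
        }
        m <- fit_boosting(Xf[tr, , drop = FALSE], y[tr],
                          params = if (is.null(params)) list() else params,
                          seed = seed * 1000L + r * 10L + f)
        pred[te] <- predict_boosting(m, Xf[te, , drop = FALSE])
      }
      fab[f] <- suppressWarnings(
        as.numeric(predictive_ability(y[te], pred[te])))
    }
    repeat_ability[r] <- suppressWarnings(
      as.numeric(predictive_ability(y, pred)))
    predictions[, r] <- pred
    fold_tab[[r]] <- data.frame(rep = r, fold = seq_len(k), ability = fab)
  }
  out <- list(model_tag = model_tag, engine = engine, trait = trait,
              k = k, repeats = repeats, seed = seed,
              marker_mode = if (needs_markers) marker_mode else NA,
              fold_table = do.call(rbind, fold_tab),
              fold_assignments = fold_assignments,
              predictions = predictions,
              repeat_ability = repeat_ability,
              mean_ability = mean(repeat_ability),
              sd_ability = stats::sd(repeat_ability),
              n = n)
  class(out) <- "CVResult"
  out
}

#' @exportS3Method base::print
print.CVResult <- function(x, ...) {
  cat(sprintf(
    "CVResult[%s/%s, %s]: mean ability %.3f (SD %.3f) over %d x %d-fold\n",
    x$model_tag, x$engine, x$trait, x$mean_ability, x$sd_ability,
    x$repeats, x$k))
  invisible(x)
}

#' Write a CV result as a long-format delimited table
#' @param cv a \code{CVResult}.
#' @param path output file.
#' @export
write_cv_result <- function(cv, path) {
  df <- data.frame(model = cv$model_tag, engine = cv$engine,
                   trait = cv$trait, cv$fold_table)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pairwise comparison of cross-validated models
#'
#' Paired two-sided t-tests on the repeat-level mean abilities (folds
#' within a repeat are dependent, repeats are the exchangeable unit) and a
#' compact letter display at the given alpha: models sharing a letter are
#' not significantly different.
#'
#' @param results list of \code{CVResult}s sharing trait, fold structure
#'   and seed.
#' @param alpha significance level for the letters.
#' @return list with \code{table} (model, engine, mean, sd, letters) and
#'   \code{p_matrix}.
#' @export
compare_models <- function(results, alpha = 0.05) {
  if (length(results) < 2) stop("need at least two results")
  r0 <- results[[1]]
  for (r in results[-1]) {
    if (r$trait != r0$trait || r$k != r0$k || r$repeats != r0$repeats ||
        r$seed != r0$seed)
      stop("results do not share trait / fold structure / seed")
  }
  labs <- vapply(results, function(r)
    paste(r$model_tag, r$engine, sep = "/"), character(1))
  M <- length(results)
  P <- matrix(1, M, M, dimnames = list(labs, labs))
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    a <- results[[i]]$repeat_ability; b <- results[[j]]$repeat_ability
    dd <- a - b
    p <- if (stats::sd(dd) < 1e-12 * max(abs(dd), 1)) {
      if (mean(abs(dd)) < 1e-12) 1 else 0  # (near-)constant differences
    } else tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
                    error = function(e) if (mean(abs(dd)) < 1e-12) 1 else 0)
    if (is.na(p)) p <- 1
    P[i, j] <- P[j, i] <- p
  }
  means <- vapply(results, function(r) r$mean_ability, numeric(1))
  ord <- order(means, decreasing = TRUE)
  # contiguous-range compact letters over the mean ordering
  ranges <- list()
  for (i in seq_len(M)) {
    j <- i
    while (j < M && all(P[ord[i], ord[(i + 1):(j + 1)]] >= alpha)) j <- j + 1
    ranges[[i]] <- c(i, j)
  }
  keepr <- rep(TRUE, length(ranges))
  for (i in seq_along(ranges)) for (j in seq_along(ranges))
    if (i != j && ranges[[j]][1] <= ranges[[i]][1] &&
        ranges[[j]][2] >= ranges[[i]][2] &&
        !identical(ranges[[i]], ranges[[j]])) keepr[i] <- FALSE
  ranges <- unique(ranges[keepr])
  letters_out <- rep("", M)
  for (g in seq_along(ranges)) {
    rg <- ranges[[g]]
    for (pos in rg[1]:rg[2])
      letters_out[ord[pos]] <- paste0(letters_out[ord[pos]], letters[g])
  }
  tab <- data.frame(model = labs, mean = means,
                    sd = vapply(results, function(r) r$sd_ability,
                                numeric(1)),
                    letters = letters_out, stringsAsFactors = FALSE)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(table = tab, p_matrix = P, alpha = alpha)
}

#' Random-metabolite control for the marker-assisted model
#'
#' Re-runs the MM_GP configuration with randomly drawn metabolites in
#' place of the MWAS-selected markers, one CV per draw, to check that the
#' markers' contribution is not explained by their number alone.
#'
#' @param data an \code{mmgp_data} bundle.
#' @param trait trait name.
#' @param n_markers number of metabolites per draw (the number of selected
#'   markers).
#' @param n_draws number of random draws (default 10).
#' @param seed base seed; draw d uses seed*100+d, and every CV re-uses the
#'   same fold seed so draws are comparable.
#' @param engine,k,repeats passed to \code{\link{cross_validate}}.
#' @return list with \code{draws} (id lists), \code{results}
#'   (\code{CVResult} per draw) and \code{mean_abilities}.
#' @export
random_metabolite_control <- function(data, trait, n_markers, n_draws = 10,
                                      seed = 1, engine = "kernel", k = 10,
                                      repeats = 20) {
  m <- ncol(data$metabolome$values)
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (n_markers > m) stop("n_markers exceeds metabolome size")
  ids <- metabolite_ids(data$metabolome)
  draws <- vector("list", n_draws)
  res <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(seed * 100L + d)
    draws[[d]] <- sort(sample(ids, n_markers))
    res[[d]] <- cross_validate(data, trait, "MM_GP", engine = engine,
                               k = k, repeats = repeats, seed = seed,
                               marker_mode = "fixed",
                               marker_ids = draws[[d]])
  }
  list(draws = draws, results = res,
       mean_abilities = vapply(res, function(r) r$mean_ability, numeric(1)))
}
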