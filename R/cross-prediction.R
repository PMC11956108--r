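## Exhaustive prediction of untested crosses: enumerate the diallel
## (unordered pairs, no selfs, reciprocals collapsed), build features for
## every cross from parental data, predict with a model trained on the
## observed hybrids, rank, and summarize selection gains.

#' Enumerate all unordered crosses among a set of parents
#'
#' @param parent_ids unique parent ids (>= 2).
#' @return a \code{CrossTable} with n(n-1)/2 rows, canonically ordered
#'   lexicographically by parent pair; hybrid ids are "female_x_male".
#' @export
enumerate_crosses <- function(parent_ids) {
  parent_ids <- as.character(parent_ids)
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  if (length(parent_ids) < 2) stop("need at least two parents")
  ids <- sort(parent_ids)
  n <- length(ids)
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cross_table(paste(ids[i], ids[j], sep = "_x_"), ids[i], ids[j])
}

#' Predict every enumerated cross from a trained model
#'
#' Trains the requested engine on all observed hybrids of the bundle, then
#' predicts each enumerated cross from features inferred from its parents.
#' Kernel predictions reuse the training-block factorization once and
#' stream the cross features in chunks, so tens of thousands of crosses
#' run in seconds. Crosses with a parent lacking metabolome data are
#' excluded with a message.
#'
#' @param data an \code{mmgp_data} bundle.
#' @param trait trait name.
#' @param model_tag model configuration (default "MM_GP").
#' @param engine \code{"kernel"} or \code{"boosting"}.
#' @param marker_ids metabolic markers for MMP/MM_GP; when NULL they are
#'   selected by a global MWAS on all parental lines.
#' @param alpha MWAS threshold used when selecting markers.
#' @param crosses optional \code{CrossTable} of crosses to predict;
#'   defaults to the full diallel of genotyped parents.
#' @param boost_params,seed boosting engine controls.
#' @param chunk rows of features built per batch.
#' @return a data.frame of class \code{CrossPredictionTable}, sorted by
#'   descending prediction, with columns parent_female, parent_male,
#'   predicted, rank, observed.
#' @export
predict_all_crosses <- function(data, trait, model_tag = "MM_GP",
                                engine = c("kernel", "boosting"),
                                marker_ids = NULL, alpha = 0.05,
                                crosses = NULL, boost_params = NULL,
                                seed = 1, chunk = 5000) {
  engine <- match.arg(engine)
  model_tag <- match.arg(model_tag, model_tags)
  yall <- data$hybrid_phenotypes$values[data$crosses$hybrid_id, trait]
  keep <- !is.na(yall)
  obs_crosses <- data$crosses[keep, , drop = FALSE]
  class(obs_crosses) <- c("CrossTable", "data.frame")
  y <- yall[keep]

  if (model_uses_markers(model_tag) && is.null(marker_ids)) {
    marker_ids <- select_markers_for_lines(
      data, trait, data$metabolome$lines, alpha, "analytic")
    if (!length(marker_ids))
      stop("MWAS selected no markers for ", model_tag)
  }
  if (is.null(crosses))
    crosses <- enumerate_crosses(line_ids(data$genotypes))

  # exclude crosses with parents lacking metabolome coverage
  if (model_uses_metabolome(model_tag)) {
    ok <- crosses$parent_female %in% data$metabolome$lines &
      crosses$parent_male %in% data$metabolome$lines
    if (any(!ok)) {
      message(sprintf("excluded %d cross(es) with missing parent metabolome",
                      sum(!ok)))
      crosses <- crosses[ok, , drop = FALSE]
      class(crosses) <- c("CrossTable", "data.frame")
    }
  }

  ids_sub <- function(ids) {
    Msub <- data$metabolome
    if (!is.null(ids)) {
      keep <- match(ids, metabolite_ids(Msub))
      Msub <- metabolome_matrix(Msub$values[, keep, drop = FALSE],
                                lines = Msub$lines, normalized = TRUE)
    }
    Msub
  }

  if (engine == "kernel") {
    # training features and kernels
    Ztr <- if (model_uses_genome(model_tag))
      infer_hybrid_genotypes(data$genotypes, obs_crosses) else NULL
    Mmk <- if (model_uses_metabolome(model_tag))
      ids_sub(if (model_uses_markers(model_tag)) marker_ids else NULL)
      else NULL
    adtr <- if (!is.null(Mmk)) code_metabolites(Mmk, obs_crosses) else NULL
    ker <- list()
    div <- list()
    if (!is.null(Ztr)) { ker$G <- build_kernel(Ztr); div$G <- ncol(Ztr) }
    if (!is.null(adtr)) {
      ker$Ma <- build_kernel(adtr$A); div$Ma <- ncol(adtr$A)
      ker$Md <- build_kernel(adtr$D); div$Md <- ncol(adtr$D)
    }
    fit <- reml_fit(y, kernels = ker)
    vc <- fit$variance_components
    pred <- numeric(nrow(crosses))
    for (start in seq(1, nrow(crosses), by = chunk)) {
      idx <- start:min(start + chunk - 1, nrow(crosses))
      cc <- crosses[idx, , drop = FALSE]
      class(cc) <- c("CrossTable", "data.frame")
      cov21w <- numeric(length(idx))
      if (!is.null(Ztr)) {
        Znew <- infer_hybrid_genotypes(data$genotypes, cc)
        cov21w <- cov21w + vc["G"] *
          drop(Znew %*% crossprod(Ztr, fit$w)) / div$G
      }
      if (!is.null(adtr)) {
        adn <- code_metabolites(Mmk, cc)
        cov21w <- cov21w + vc["Ma"] *
          drop(adn$A %*% crossprod(adtr$A, fit$w)) / div$Ma
        cov21w <- cov21w + vc["Md"] *
          drop(adn$D %*% crossprod(adtr$D, fit$w)) / div$Md
      }
      pred[idx] <- fit$beta[1] + cov21w
    }
  } else {
    fs_tr <- assemble_features(model_tag, data$genotypes, data$metabolome,
                               obs_crosses, marker_ids = marker_ids)
    Xtr <- feature_matrix(fs_tr)
    model <- fit_boosting(Xtr, y,
                          params = if (is.null(boost_params)) list()
                                   else boost_params, seed = seed)
    pred <- numeric(nrow(crosses))
    for (start in seq(1, nrow(crosses), by = chunk)) {
      idx <- start:min(start + chunk - 1, nrow(crosses))
      cc <- crosses[idx, , drop = FALSE]
      class(cc) <- c("CrossTable", "data.frame")
      Xn <- feature_matrix(assemble_features(
        model_tag, data$genotypes, data$metabolome, cc,
        marker_ids = marker_ids))
      pred[idx] <- predict_boosting(model, Xn)
    }
  }

  okey <- paste(pmin(obs_crosses$parent_female, obs_crosses$parent_male),
                pmax(obs_crosses$parent_female, obs_crosses$parent_male))
  ckey <- paste(pmin(crosses$parent_female, crosses$parent_male),
                pmax(crosses$parent_female, crosses$parent_male))
  out <- data.frame(parent_female = crosses$parent_female,
                    parent_male = crosses$parent_male,
                    predicted = pred,
                    observed = ckey %in% okey,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted, out$parent_female, out$parent_male), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("CrossPredictionTable", "data.frame")
  attr(out, "trait") <- trait
  attr(out, "model_tag") <- model_tag
  attr(out, "engine") <- engine
  out
}

#' Top-k / bottom-k summary of a cross prediction table
#'
#' @param table a \code{CrossPredictionTable} (or numeric predictions).
#' @param k selection size (default 100).
#' @return list with mean and SD of the top-k, bottom-k and full
#'   population of predicted values, and the percent difference of top vs
#'   bottom mean: 100 (mean_top - mean_bottom) / mean_bottom.
#' @export
top_bottom_summary <- function(table, k = 100) {
  pred <- if (is.numeric(table)) table else table$predicted
  if (k < 1) stop("k must be >= 1")
  if (k > length(pred)) stop("k exceeds number of crosses")
  s <- sort(pred, decreasing = TRUE)
  top <- s[seq_len(k)]; bot <- rev(s)[seq_len(k)]
  list(k = k,
       top_mean = mean(top), top_sd = stats::sd(top),
       bottom_mean = mean(bot), bottom_sd = stats::sd(bot),
       population_mean = mean(pred), population_sd = stats::sd(pred),
       percent_diff_top_bottom = 100 * (mean(top) - mean(bot)) / mean(bot))
}

#' Selection gain of a selected set over a baseline
#'
#' @param top_mean mean predicted value of the selected crosses.
#' @param baseline_mean baseline mean (population mean of all predicted
#'   crosses, or a bottom-k mean; both are reported by
#'   \code{\link{top_bottom_summary}}).
#' @return list with \code{absolute} (top_mean - baseline_mean) and
#'   \code{percent} (100 * absolute / baseline_mean).
#' @export
selection_gain <- function(top_mean, baseline_mean) {
  if (baseline_mean == 0) stop("zero baseline mean")
  abs_gain <- top_mean - baseline_mean
  list(absolute = abs_gain, percent = 100 * abs_gain / baseline_mean)
}

#' Write a ranked cross prediction table
#' @param table a \code{CrossPredictionTable}.
#' @param path output file.
#' @export
write_cross_predictions <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}
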