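## Metabolome preprocessing: replicate-concordance filtering, normalization,
## replicate averaging, and variability profiling.

#' Filter metabolites on replicate concordance
#'
#' For each metabolite, a paired two-sided t-test compares replicate-1 and
#' replicate-2 intensities across lines; metabolites whose replicates differ
#' significantly (p below \code{alpha}) are removed. Degenerate cases where
#' all paired differences are identical yield p = 1 when the common
#' difference is zero (identical replicates) and p = 0 when it is not (a
#' pure systematic offset).
#'
#' @param Mx a replicated \code{MetabolomeMatrix} with exactly two replicates
#'   per line.
#' @param alpha significance threshold for exclusion (default 0.01).
#' @return list with \code{metabolome} (filtered, still replicated) and
#'   \code{report}, a data.frame of class \code{MetaboliteQCReport} with
#'   columns metabolite_id, p_value, kept, cv, mean.
#' @export
replicate_concordance_filter <- function(Mx, alpha = 0.01) {
  if (is.null(Mx$replicate))
    stop("metabolome carries no replicate structure")
  tab <- table(Mx$lines)
  bad <- names(tab)[tab != 2]
  if (length(bad))
    stop("lines without exactly two replicates: ",
         paste(utils::head(bad, 5), collapse = ", "))
  ord <- order(Mx$lines, Mx$replicate)
  v <- Mx$values[ord, , drop = FALSE]
  r1 <- v[seq(1, nrow(v), by = 2), , drop = FALSE]
  r2 <- v[seq(2, nrow(v), by = 2), , drop = FALSE]
  d <- r2 - r1
  nl <- nrow(d)
  dbar <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  tstat <- ifelse(sdd > 0, dbar / (sdd / sqrt(nl)), ifelse(dbar == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df = nl - 1)
  p[is.nan(p)] <- 1
  avg <- (r1 + r2) / 2
  mu <- colMeans(avg)
  cv <- ifelse(mu != 0, apply(avg, 2, stats::sd) / mu, NA_real_)
  kept <- p >= alpha
  report <- data.frame(metabolite_id = metabolite_ids(Mx), p_value = p,
                       kept = kept, cv = cv, mean = mu,
                       stringsAsFactors = FALSE, row.names = NULL)
  class(report) <- c("MetaboliteQCReport", "data.frame")
  filt <- metabolome_matrix(Mx$values[, kept, drop = FALSE],
                            lines = Mx$lines, replicate = Mx$replicate,
                            meta = if (is.null(Mx$meta)) NULL else
                              Mx$meta[kept, , drop = FALSE],
                            normalized = Mx$normalized)
  list(metabolome = filt, report = report)
}

#' Write a metabolite QC report as a delimited table
#' @param report a \code{MetaboliteQCReport}.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Average replicate rows to one row per line
#' @param Mx a \code{MetabolomeMatrix}; lines with a single replicate pass
#'   through unchanged.
#' @return a line-level \code{MetabolomeMatrix}.
#' @export
average_replicates <- function(Mx) {
  if (is.null(Mx$replicate)) return(Mx)
  lines <- unique(Mx$lines)
  idx <- split(seq_along(Mx$lines), factor(Mx$lines, levels = lines))
  avg <- t(vapply(idx, function(i)
    colMeans(Mx$values[i, , drop = FALSE]), numeric(ncol(Mx$values))))
  colnames(avg) <- metabolite_ids(Mx)
  metabolome_matrix(avg, lines = lines, meta = Mx$meta,
                    normalized = Mx$normalized)
}

#' Normalize metabolite intensities
#'
#' \code{"zscore"} centers each metabolite to mean 0 and scales to unit
#' variance; \code{"log-zscore"} applies \code{log1p} first. Variances use
#' the population (n-denominator) convention. Constant metabolites map to
#' all-zero columns with a warning.
#'
#' @param Mx a \code{MetabolomeMatrix} without missing values.
#' @param method \code{"zscore"} or \code{"log-zscore"}.
#' @return a normalized \code{MetabolomeMatrix}.
#' @export
normalize_metabolome <- function(Mx, method = c("zscore", "log-zscore")) {
  method <- match.arg(method)
  v <- Mx$values
  if (method == "log-zscore") v <- log1p(v)
  mu <- colMeans(v)
  sdv <- sqrt(colMeans(sweep(v, 2, mu)^2))
  const <- sdv == 0
  if (any(const))
    warning(sprintf("%d constant metabolite(s) normalized to zero",
                    sum(const)))
  sdv[const] <- 1
  z <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  metabolome_matrix(z, lines = Mx$lines, replicate = Mx$replicate,
                    meta = Mx$meta, normalized = TRUE)
}

#' Per-metabolite coefficient of variation
#'
#' CV = sample standard deviation (n-1 denominator) divided by the mean,
#' computed on raw (pre-normalization) intensities. Undefined (NA, with a
#' warning) when the mean is zero.
#'
#' @param Mx a line-level raw-intensity \code{MetabolomeMatrix}.
#' @return named numeric vector of CVs (fractions).
#' @export
metabolite_cv <- function(Mx) {
  if (isTRUE(Mx$normalized))
    stop("CV must be computed on raw intensities, before normalization")
  if (any(Mx$values < 0)) stop("negative intensities")
  mu <- colMeans(Mx$values)
  sdv <- apply(Mx$values, 2, stats::sd)
  cv <- ifelse(mu != 0, sdv / mu, NA_real_)
  if (anyNA(cv)) warning("CV undefined for zero-mean metabolite(s)")
  names(cv) <- metabolite_ids(Mx)
  cv
}
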