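## Input containers and readers/writers for the four data layers:
## parental genotypes, parental metabolome, phenotypes, and the cross table.
##
## Delimited dialect used throughout: UTF-8, tab-separated, first row holds
## marker/metabolite/trait ids, first column holds the line/entry id, "NA"
## marks missing values.

#' Construct a parental genotype matrix
#'
#' Lines-by-markers numeric matrix of inbred genotype codes. Homozygotes are
#' coded \code{-1} and \code{+1}; \code{0} is permitted for heterozygous
#' calls or after mean imputation; \code{NA} marks missing calls.
#'
#' @param codes numeric matrix, lines in rows, markers in columns; dimnames
#'   provide line and marker ids unless given explicitly.
#' @param line_ids,marker_ids optional character vectors overriding dimnames.
#' @param marker_meta optional data.frame with one row per marker
#'   (e.g. chromosome, position); must carry a \code{marker_id} column.
#' @return an object of class \code{GenotypeMatrix}.
#' @export
genotype_matrix <- function(codes, line_ids = rownames(codes),
                            marker_ids = colnames(codes), marker_meta = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(line_ids) || is.null(marker_ids))
    stop("line and marker ids are required (dimnames or arguments)")
  line_ids <- as.character(line_ids); marker_ids <- as.character(marker_ids)
  if (nrow(codes) != length(line_ids) || ncol(codes) != length(marker_ids))
    stop("code matrix dimensions do not match id lengths")
  if (anyDuplicated(line_ids)) stop("duplicated line ids")
  if (anyDuplicated(marker_ids)) stop("duplicated marker ids")
  rng <- range(codes, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1 || rng[2] > 1))
    stop("genotype codes must lie in [-1, 1]")
  dimnames(codes) <- list(line_ids, marker_ids)
  if (!is.null(marker_meta)) {
    marker_meta <- as.data.frame(marker_meta)
    if (!"marker_id" %in% names(marker_meta))
      stop("marker_meta needs a marker_id column")
    marker_meta <- marker_meta[match(marker_ids, marker_meta$marker_id), ,
                               drop = FALSE]
  }
  structure(list(codes = codes, meta = marker_meta), class = "GenotypeMatrix")
}

#' @exportS3Method base::print
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d lines x %d markers, %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$codes)

line_ids <- function(G) rownames(G$codes)
marker_ids <- function(G) colnames(G$codes)

#' Construct a metabolome matrix
#'
#' Rows are line-replicate observations (or line-level means), columns are
#' metabolites. Raw intensities must be non-negative; normalized values may
#' be any finite real.
#'
#' @param values numeric matrix of intensities.
#' @param lines character vector, one line id per row.
#' @param replicate optional integer vector of replicate labels per row;
#'   \code{NULL} means one (averaged) row per line.
#' @param meta optional data.frame of per-metabolite metadata with a
#'   \code{metabolite_id} column (annotation, category, tissue, ...).
#' @param normalized logical; normalized values may be negative.
#' @return an object of class \code{MetabolomeMatrix}.
#' @export
metabolome_matrix <- function(values, lines = rownames(values),
                              replicate = NULL, meta = NULL,
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(lines)) stop("line ids required")
  lines <- as.character(lines)
  if (length(lines) != nrow(values)) stop("one line id per row required")
  if (is.null(colnames(values))) stop("metabolite ids (colnames) required")
  if (anyDuplicated(colnames(values))) stop("duplicated metabolite ids")
  if (!is.null(replicate)) {
    replicate <- as.integer(replicate)
    if (length(replicate) != nrow(values)) stop("one replicate label per row")
    if (anyDuplicated(paste(lines, replicate)))
      stop("(line, replicate) pairs must be unique")
  } else if (anyDuplicated(lines)) {
    stop("duplicated line ids (supply replicate labels for replicated data)")
  }
  if (!all(is.finite(values))) stop("metabolite values must be finite")
  if (!normalized && any(values < 0))
    stop("raw intensities must be non-negative")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"metabolite_id" %in% names(meta))
      stop("meta needs a metabolite_id column")
    meta <- meta[match(colnames(values), meta$metabolite_id), , drop = FALSE]
  }
  rownames(values) <- if (is.null(replicate)) lines else
    paste(lines, replicate, sep = ".")
  structure(list(values = values, lines = lines, replicate = replicate,
                 meta = meta, normalized = normalized),
            class = "MetabolomeMatrix")
}

#' @exportS3Method base::print
print.MetabolomeMatrix <- function(x, ...) {
  cat(sprintf("MetabolomeMatrix: %d rows (%d lines%s) x %d metabolites%s\n",
              nrow(x$values), length(unique(x$lines)),
              if (is.null(x$replicate)) "" else ", replicated",
              ncol(x$values),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

metabolite_ids <- function(x) colnames(x$values)

#' Construct a phenotype table
#'
#' @param values numeric matrix, entries (parental lines or hybrids) in rows,
#'   traits in columns; missing values allowed.
#' @param entry_ids optional character vector overriding rownames.
#' @return an object of class \code{PhenotypeTable}.
#' @export
phenotype_table <- function(values, entry_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(entry_ids)) stop("entry ids required")
  entry_ids <- as.character(entry_ids)
  if (anyDuplicated(entry_ids)) stop("duplicated entry ids")
  if (is.null(colnames(values))) stop("trait names (colnames) required")
  if (any(is.infinite(values))) stop("phenotypes must be finite or NA")
  rownames(values) <- entry_ids
  structure(list(values = values), class = "PhenotypeTable")
}

#' @exportS3Method base::print
print.PhenotypeTable <- function(x, ...) {
  cat(sprintf("PhenotypeTable: %d entries x %d traits (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' Construct a cross table
#'
#' Maps each hybrid to its female and male parent. Reciprocal crosses are
#' treated as the same unordered pair and must not be duplicated.
#'
#' @param hybrid_id,parent_female,parent_male character vectors.
#' @param genotypes optional \code{GenotypeMatrix}; when given, both parents
#'   of every cross must be present among its lines.
#' @return a data.frame of class \code{CrossTable}.
#' @export
cross_table <- function(hybrid_id, parent_female, parent_male,
                        genotypes = NULL) {
  ct <- data.frame(hybrid_id = as.character(hybrid_id),
                   parent_female = as.character(parent_female),
                   parent_male = as.character(parent_male),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ct$hybrid_id)) stop("duplicated hybrid ids")
  key <- paste(pmin(ct$parent_female, ct$parent_male),
               pmax(ct$parent_female, ct$parent_male))
  if (anyDuplicated(key)) stop("duplicated unordered parent pair")
  if (!is.null(genotypes)) {
    miss <- setdiff(unique(c(ct$parent_female, ct$parent_male)),
                    line_ids(genotypes))
    if (length(miss))
      stop("parents absent from genotype matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  class(ct) <- c("CrossTable", "data.frame")
  ct
}

## ---------------------------------------------------------------- readers

read_delim_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2) stop("expected id column plus at least one data column")
  ids <- as.character(dt[[1]])
  rest <- dt[, -1, drop = FALSE]
  list(ids = ids, data = rest)
}

#' Read a parental genotype matrix
#'
#' Supported formats: \code{"delimited"} (the package dialect; cells either
#' numeric codes in \{-1,0,1\} or two-letter genotypes like \code{AA}/
#' \code{aa}), \code{"vcf"} (biallelic records, GT field; requires the
#' VariantAnnotation package), and \code{"hapmap"}.
#'
#' For letter-coded input the homozygote for the alphabetically first allele
#' at each marker is mapped to \code{+1}, the other homozygote to \code{-1},
#' heterozygotes to \code{0}. For VCF the REF homozygote is \code{+1} and
#' the ALT homozygote \code{-1}. Multi-allelic VCF records are skipped with
#' a warning; the number skipped is recorded in the \code{skipped} attribute.
#'
#' @param path file path.
#' @param format one of \code{"delimited"}, \code{"vcf"}, \code{"hapmap"}.
#' @return a \code{GenotypeMatrix}.
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         delimited = read_genotypes_delim(path),
         vcf = read_genotypes_vcf(path),
         hapmap = read_genotypes_hapmap(path))
}

read_genotypes_delim <- function(path) {
  parsed <- read_delim_matrix(path)
  dat <- parsed$data
  if (all(vapply(dat, is.numeric, logical(1)))) {
    codes <- as.matrix(dat)
  } else {
    codes <- vapply(dat, function(col) {
      col <- as.character(col)
      out <- rep(NA_real_, length(col))
      ok <- !is.na(col) & col != "NA" & col != ""
      gl <- col[ok]
      alleles <- sort(unique(unlist(strsplit(gl, ""))))
      if (length(alleles) > 2)
        stop("more than two alleles in a letter-coded marker column")
      a <- alleles[1]
      first <- substr(gl, 1, 1); second <- substr(gl, 2, 2)
      val <- (first == a) + (second == a) - 1  # 2 copies -> +1, 0 -> -1
      out[ok] <- val
      out
    }, numeric(nrow(dat)))
    colnames(codes) <- names(dat)
  }
  rownames(codes) <- parsed$ids
  genotype_matrix(codes)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- nalt != 1
  nskip <- sum(multi)
  if (nskip > 0) {
    warning(sprintf("skipped %d non-biallelic VCF record(s)", nskip))
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks a GT genotype field")
  map <- c("0/0" = 1, "0|0" = 1, "1/1" = -1, "1|1" = -1,
           "0/1" = 0, "1/0" = 0, "0|1" = 0, "1|0" = 0)
  codes <- matrix(unname(map[gt]), nrow = nrow(gt), ncol = ncol(gt))
  codes <- t(codes)  # lines x markers
  rownames(codes) <- colnames(gt)
  colnames(codes) <- rownames(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  meta <- data.frame(marker_id = rownames(gt),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(codes, marker_meta = meta)
  attr(out, "skipped") <- nskip
  out
}

read_genotypes_hapmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  need <- c("rs#", "alleles", "chrom", "pos")
  if (!all(need %in% names(dt)[1:4]))
    stop("not a HapMap file (expected rs#, alleles, chrom, pos columns)")
  gcols <- dt[, -(1:11), drop = FALSE]
  codes <- t(vapply(seq_len(nrow(dt)), function(i) {
    al <- strsplit(dt$alleles[i], "/")[[1]]
    g <- as.character(unlist(gcols[i, ]))
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !(g %in% c("NN", "N"))
    first <- substr(g[ok], 1, 1); second <- substr(g[ok], 2, 2)
    out[ok] <- (first == al[1]) + (second == al[1]) - 1
    out
  }, numeric(ncol(gcols))))
  codes <- t(codes)
  rownames(codes) <- names(gcols)
  colnames(codes) <- dt[["rs#"]]
  meta <- data.frame(marker_id = dt[["rs#"]], chrom = dt$chrom, pos = dt$pos,
                     stringsAsFactors = FALSE)
  genotype_matrix(codes, marker_meta = meta)
}

#' Write a genotype matrix in the delimited dialect
#' @param G a \code{GenotypeMatrix}.
#' @param path output file.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(line_id = rownames(G$codes), G$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a metabolome matrix in the delimited dialect
#'
#' A column named \code{replicate} directly after the id column is taken as
#' the replicate label; all remaining columns are metabolites.
#'
#' @param path intensity table path.
#' @param meta_path optional path to a per-metabolite metadata table
#'   (columns \code{metabolite_id}, and e.g. annotation, category, tissue).
#' @param normalized logical, passed to \code{\link{metabolome_matrix}}.
#' @return a \code{MetabolomeMatrix}.
#' @export
read_metabolome <- function(path, meta_path = NULL, normalized = FALSE) {
  parsed <- read_delim_matrix(path)
  dat <- parsed$data
  replicate <- NULL
  if (names(dat)[1] == "replicate") {
    replicate <- as.integer(dat[[1]])
    dat <- dat[, -1, drop = FALSE]
  }
  meta <- if (!is.null(meta_path))
    data.table::fread(meta_path, sep = "\t", data.table = FALSE) else NULL
  metabolome_matrix(as.matrix(dat), lines = parsed$ids,
                    replicate = replicate, meta = meta,
                    normalized = normalized)
}

#' Write a metabolome matrix in the delimited dialect
#' @param Mx a \code{MetabolomeMatrix}.
#' @param path output file.
#' @export
write_metabolome <- function(Mx, path) {
  df <- data.frame(line_id = Mx$lines, stringsAsFactors = FALSE)
  if (!is.null(Mx$replicate)) df$replicate <- Mx$replicate
  df <- cbind(df, as.data.frame(Mx$values, check.names = FALSE))
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table (entries x traits, delimited dialect)
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  parsed <- read_delim_matrix(path)
  phenotype_table(as.matrix(parsed$data), entry_ids = parsed$ids)
}

#' Write a phenotype table
#' @param ph a \code{PhenotypeTable}.
#' @param path output file.
#' @export
write_phenotypes <- function(ph, path) {
  df <- data.frame(entry_id = rownames(ph$values), ph$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a cross table (hybrid_id, parent_female, parent_male)
#' @param path file path.
#' @param genotypes optional \code{GenotypeMatrix} for parent validation.
#' @export
read_crosses <- function(path, genotypes = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 3) stop("cross table needs 3 columns")
  cross_table(dt[[1]], dt[[2]], dt[[3]], genotypes = genotypes)
}

#' Write a cross table
#' @param crosses a \code{CrossTable}.
#' @param path output file.
#' @export
write_crosses <- function(crosses, path) {
  data.table::fwrite(as.data.frame(crosses), path, sep = "\t", quote = FALSE)
  invisible(path)
}

## ----------------------------------------------------------------- QC ops

marker_freq <- function(G) {
  # frequency of the +1 allele from dosages (code+1)/2, missing excluded
  colMeans((G$codes + 1) / 2, na.rm = TRUE)
}

#' Marker minor-allele frequencies
#' @param G a \code{GenotypeMatrix}.
#' @return named numeric vector of MAFs.
#' @export
marker_maf <- function(G) {
  f <- marker_freq(G)
  pmin(f, 1 - f)
}

#' Marker missing rates
#' @param G a \code{GenotypeMatrix}.
#' @export
marker_missing_rate <- function(G) colMeans(is.na(G$codes))

#' Filter markers on minor-allele frequency and missing rate
#'
#' Removes markers with MAF strictly below \code{maf_min} or missing rate
#' strictly above \code{missing_max}; markers exactly at either threshold
#' are kept.
#'
#' @param G a \code{GenotypeMatrix}.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param missing_max maximum missing rate (default 0.1).
#' @return the filtered \code{GenotypeMatrix}; the number of markers removed
#'   is reported via \code{message()}.
#' @export
filter_snps <- function(G, maf_min = 0.05, missing_max = 0.1) {
  maf <- marker_maf(G)
  miss <- marker_missing_rate(G)
  maf[is.nan(maf)] <- 0  # all-missing marker: no allele information
  keep <- (maf >= maf_min) & (miss <= missing_max)
  if (!any(keep)) stop("all markers removed by QC filtering")
  message(sprintf("filter_snps: retained %d of %d markers", sum(keep),
                  length(keep)))
  out <- genotype_matrix(G$codes[, keep, drop = FALSE],
                         marker_meta = if (is.null(G$meta)) NULL else
                           G$meta[keep, , drop = FALSE])
  out
}

#' Mean-impute missing genotype codes
#'
#' Missing codes are replaced by the per-marker mean of the non-missing
#' codes, preserving per-marker means exactly.
#'
#' @param G a \code{GenotypeMatrix}.
#' @return a \code{GenotypeMatrix} without missing values.
#' @export
impute_missing <- function(G) {
  codes <- G$codes
  nmiss <- colSums(is.na(codes))
  if (!any(nmiss > 0)) return(G)
  if (any(nmiss == nrow(codes)))
    stop("marker(s) with no observed genotypes; run filter_snps first")
  mu <- colMeans(codes, na.rm = TRUE)
  idx <- which(is.na(codes), arr.ind = TRUE)
  codes[idx] <- mu[idx[, 2]]
  genotype_matrix(codes, marker_meta = G$meta)
}

#' Subset a metabolome by tissue
#'
#' Retains metabolites whose \code{tissue} metadata matches, preserving
#' column order.
#'
#' @param Mx a \code{MetabolomeMatrix} with a \code{tissue} metadata column.
#' @param tissue tissue label.
#' @export
subset_metabolome <- function(Mx, tissue) {
  if (is.null(Mx$meta) || !"tissue" %in% names(Mx$meta))
    stop("metabolome has no tissue metadata")
  if (!tissue %in% Mx$meta$tissue)
    stop("unknown tissue label: ", tissue)
  keep <- which(Mx$meta$tissue == tissue)
  metabolome_matrix(Mx$values[, keep, drop = FALSE], lines = Mx$lines,
                    replicate = Mx$replicate,
                    meta = Mx$meta[keep, , drop = FALSE],
                    normalized = Mx$normalized)
}
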