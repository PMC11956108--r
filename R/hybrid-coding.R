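## Hybrid-level design matrices from parental data.
##
## Genotypes: a hybrid's marker code is the mean of its parents' codes, so
## with inbred parents coded {-1,+1} a heterozygous hybrid lands on 0.
## Metabolites: additive coding A = (M + F)/2 and dominance coding
## D = |M - F|/2 from the female (M) and male (F) parental metabolite
## levels; both are symmetric in the parents, so reciprocal crosses share
## one feature row.

#' Infer hybrid genotypes from parental genotypes
#'
#' @param G parental \code{GenotypeMatrix} (imputed; non-inbred codes are
#'   tolerated with a warning and propagate through the midpoint formula).
#' @param crosses a \code{CrossTable}.
#' @return numeric matrix, hybrids x markers.
#' @export
infer_hybrid_genotypes <- function(G, crosses) {
  miss <- setdiff(unique(c(crosses$parent_female, crosses$parent_male)),
                  line_ids(G))
  if (length(miss))
    stop("parents absent from genotypes: ", paste(miss, collapse = ", "))
  if (anyNA(G$codes)) stop("impute missing genotypes first")
  if (any(abs(G$codes) != 1))
    warning("non-inbred parental codes present; midpoint coding applied")
  Zf <- G$codes[crosses$parent_female, , drop = FALSE]
  Zm <- G$codes[crosses$parent_male, , drop = FALSE]
  Z <- (Zf + Zm) / 2
  rownames(Z) <- crosses$hybrid_id
  Z
}

#' Additive and dominance metabolite coding of hybrids
#'
#' @param Mline line-level \code{MetabolomeMatrix} (replicate-averaged,
#'   normalized).
#' @param crosses a \code{CrossTable}.
#' @return list with matrices \code{A} = (M+F)/2 and \code{D} = |M-F|/2,
#'   hybrids x metabolites.
#' @export
code_metabolites <- function(Mline, crosses) {
  if (!is.null(Mline$replicate))
    stop("average replicates before metabolite coding")
  miss <- setdiff(unique(c(crosses$parent_female, crosses$parent_male)),
                  Mline$lines)
  if (length(miss))
    stop("parents missing from metabolome: ", paste(miss, collapse = ", "))
  M <- Mline$values[match(crosses$parent_female, Mline$lines), , drop = FALSE]
  F_ <- Mline$values[match(crosses$parent_male, Mline$lines), , drop = FALSE]
  A <- (M + F_) / 2
  D <- abs(M - F_) / 2
  rownames(A) <- rownames(D) <- crosses$hybrid_id
  list(A = A, D = D)
}

model_tags <- c("GP", "MP", "MMP", "M_GP", "MM_GP")

model_uses_genome <- function(tag) tag %in% c("GP", "M_GP", "MM_GP")
model_uses_metabolome <- function(tag) tag %in% c("MP", "MMP", "M_GP", "MM_GP")
model_uses_markers <- function(tag) tag %in% c("MMP", "MM_GP")

#' Assemble hybrid feature matrices for a model configuration
#'
#' Model configurations: \code{GP} genome only; \code{MP} full metabolome;
#' \code{MMP} selected metabolic markers only; \code{M_GP} genome plus full
#' metabolome; \code{MM_GP} genome plus selected metabolic markers.
#'
#' @param model_tag one of GP, MP, MMP, M_GP, MM_GP.
#' @param G parental \code{GenotypeMatrix} (required unless MP/MMP).
#' @param Mline line-level \code{MetabolomeMatrix} (required unless GP).
#' @param crosses a \code{CrossTable}.
#' @param marker_ids metabolite ids from \code{\link{select_markers}};
#'   required for MMP and MM_GP.
#' @return an object of class \code{FeatureSet}: list with hybrid_ids,
#'   model_tag, and the matrices Z_G, A_M, D_M that the configuration uses.
#' @export
assemble_features <- function(model_tag, G = NULL, Mline = NULL, crosses,
                              marker_ids = NULL) {
  model_tag <- match.arg(model_tag, model_tags)
  fs <- list(hybrid_ids = crosses$hybrid_id, model_tag = model_tag,
             Z_G = NULL, A_M = NULL, D_M = NULL, marker_ids = NULL)
  if (model_uses_genome(model_tag)) {
    if (is.null(G)) stop(model_tag, " requires genotypes")
    fs$Z_G <- infer_hybrid_genotypes(G, crosses)
  }
  if (model_uses_metabolome(model_tag)) {
    if (is.null(Mline)) stop(model_tag, " requires a metabolome")
    if (model_uses_markers(model_tag)) {
      if (is.null(marker_ids) || length(marker_ids) == 0)
        stop(model_tag, " requires selected metabolic markers; run the ",
             "MWAS and select_markers(), or use MP/M_GP for the full ",
             "metabolome")
      keep <- match(marker_ids, metabolite_ids(Mline))
      if (anyNA(keep)) stop("marker ids absent from metabolome")
      Msub <- metabolome_matrix(Mline$values[, keep, drop = FALSE],
                                lines = Mline$lines, normalized = TRUE)
      fs$marker_ids <- marker_ids
      ad <- code_metabolites(Msub, crosses)
    } else {
      ad <- code_metabolites(Mline, crosses)
    }
    fs$A_M <- ad$A
    fs$D_M <- ad$D
  }
  class(fs) <- "FeatureSet"
  fs
}

#' @exportS3Method base::print
print.FeatureSet <- function(x, ...) {
  blk <- function(m) if (is.null(m)) "-" else paste(dim(m), collapse = "x")
  cat(sprintf("FeatureSet[%s]: %d hybrids; Z_G %s, A_M %s, D_M %s\n",
              x$model_tag, length(x$hybrid_ids), blk(x$Z_G), blk(x$A_M),
              blk(x$D_M)))
  invisible(x)
}

#' Concatenated feature matrix for tree-based learners
#' @param fs a \code{FeatureSet}.
#' @return numeric matrix [Z_G | A_M | D_M] with prefixed column names.
#' @export
feature_matrix <- function(fs) {
  parts <- list()
  if (!is.null(fs$Z_G)) {
    Z <- fs$Z_G; colnames(Z) <- paste0("G:", colnames(Z)); parts$Z <- Z
  }
  if (!is.null(fs$A_M)) {
    A <- fs$A_M; colnames(A) <- paste0("A:", colnames(A)); parts$A <- A
    D <- fs$D_M; colnames(D) <- paste0("D:", colnames(D)); parts$D <- D
  }
  out <- do.call(cbind, unname(parts))
  rownames(out) <- fs$hybrid_ids
  out
}

#' Persist a feature set as delimited matrices plus a JSON manifest
#' @param fs a \code{FeatureSet}.
#' @param dir output directory (created if needed).
#' @export
write_feature_set <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in c("Z_G", "A_M", "D_M")) {
    if (!is.null(fs[[nm]])) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      df <- data.frame(hybrid_id = rownames(fs[[nm]]), fs[[nm]],
                       check.names = FALSE, stringsAsFactors = FALSE)
      data.table::fwrite(df, f, sep = "\t", quote = FALSE)
      written <- c(written, basename(f))
    }
  }
  manifest <- list(model_tag = fs$model_tag,
                   n_hybrids = length(fs$hybrid_ids),
                   matrices = written,
                   marker_ids = fs$marker_ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
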