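## Synthetic data with the statistical structure the method assumes:
## fully inbred parents, replicated metabolite intensities partially under
## genetic control, a sparse partial diallel of hybrids, and traits with
## additive + dominance architecture plus metabolite-mediated signal that
## is in part independent of the SNP panel (so that metabolic markers can
## carry information the genome-wide kernel does not).

#' Simulation configuration
#'
#' Defaults describe the desk-scale analogue of a maize-style hybrid
#' panel: 150 inbred parents (the parent-to-hybrid proportion of a sparse
#' partial diallel with 300 hybrids), 1000 SNPs, 200 metabolites measured
#' in two replicates, and a trait with heritability 0.6 split among
#' additive SNP effects, dominance, and metabolite-mediated signal.
#'
#' @param n_parents number of inbred parental lines.
#' @param g number of SNPs.
#' @param m number of metabolites.
#' @param n_replicates metabolite replicates per line.
#' @param n_hybrids hybrids sampled (without replacement) from the diallel.
#' @param n_qtl causal SNPs per trait.
#' @param met_genetic_fraction fraction of metabolites under genetic
#'   control.
#' @param met_h2 line-level heritability of genetically controlled
#'   metabolites.
#' @param met_qtl SNPs controlling each genetic metabolite.
#' @param n_causal_met metabolites with direct trait effects.
#' @param causal_met_nongenetic_fraction fraction of causal metabolites
#'   drawn from the non-genetic pool (signal invisible to the SNP kernel).
#' @param h2 trait heritability (hybrid level).
#' @param dominance_fraction share of the genetic trait variance from
#'   dominance.
#' @param metabolite_fraction share of the genetic trait variance mediated
#'   by causal metabolites.
#' @param replicate_noise_sd replicate (technical) noise SD relative to a
#'   unit-variance line-level metabolite signal.
#' @param intensity_base baseline raw intensity (keeps intensities
#'   positive).
#' @param seed RNG seed (mandatory; all generators derive from it).
#' @return list of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_parents = 150, g = 1000, m = 200,
                       n_replicates = 2, n_hybrids = 300, n_qtl = 50,
                       met_genetic_fraction = 0.5, met_h2 = 0.6,
                       met_qtl = 5, n_causal_met = 10,
                       causal_met_nongenetic_fraction = 0.5,
                       h2 = 0.6, dominance_fraction = 0.15,
                       metabolite_fraction = 0.35,
                       replicate_noise_sd = 0.3, intensity_base = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(met_genetic_fraction, met_h2, h2, dominance_fraction,
          metabolite_fraction, causal_met_nongenetic_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (dominance_fraction + metabolite_fraction > 1)
    stop("dominance and metabolite fractions exceed the variance budget")
  if (n_hybrids > n_parents * (n_parents - 1) / 2)
    stop("n_hybrids exceeds the diallel size")
  if (g < n_qtl) stop("fewer SNPs than QTL")
  if (is.null(seed)) stop("seed is mandatory")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate inbred parental genotypes
#'
#' Codes are drawn in \{-1, +1\} with per-marker allele frequencies
#' Uniform(0.1, 0.9).
#'
#' @param config a \code{SimulationConfig}.
#' @return a \code{GenotypeMatrix}.
#' @export
simulate_parents <- function(config) {
  set.seed(config$seed)
  p <- stats::runif(config$g, 0.1, 0.9)
  codes <- matrix(0, config$n_parents, config$g)
  for (j in seq_len(config$g))
    codes[, j] <- ifelse(stats::runif(config$n_parents) < p[j], 1, -1)
  dimnames(codes) <- list(sprintf("L%03d", seq_len(config$n_parents)),
                          sprintf("snp%04d", seq_len(config$g)))
  genotype_matrix(codes)
}

#' Simulate a replicated parental metabolome
#'
#' Genetically controlled metabolites are linear in a few SNPs plus
#' line-level noise scaled to the target metabolite heritability;
#' the rest are pure line-level noise. Replicates add technical noise.
#' Raw intensities are the line values shifted by a positive baseline.
#'
#' @param G parental \code{GenotypeMatrix} from
#'   \code{\link{simulate_parents}}.
#' @param config a \code{SimulationConfig}.
#' @return list with \code{metabolome} (replicated raw-intensity
#'   \code{MetabolomeMatrix}), \code{line_values} (true line-level values,
#'   unit scale), and \code{truth} (per-metabolite control information).
#' @export
simulate_metabolome <- function(G, config) {
  set.seed(config$seed + 1L)
  n <- nrow(G$codes); m <- config$m
  n_gen <- round(config$met_genetic_fraction * m)
  met_ids <- sprintf("met%03d", seq_len(m))
  genetic <- seq_len(m) <= n_gen
  line_vals <- matrix(stats::rnorm(n * m), n, m)
  qtl <- vector("list", m)
  for (j in which(genetic)) {
    qtl[[j]] <- sample(colnames(G$codes), config$met_qtl)
    eff <- stats::rnorm(config$met_qtl)
    gv <- drop(G$codes[, qtl[[j]], drop = FALSE] %*% eff)
    sgv <- stats::sd(gv)
    gv <- if (sgv > 0) (gv - mean(gv)) / sgv else gv * 0
    line_vals[, j] <- sqrt(config$met_h2) * gv +
      sqrt(1 - config$met_h2) * line_vals[, j]
  }
  colnames(line_vals) <- met_ids
  rownames(line_vals) <- rownames(G$codes)
  reps <- config$n_replicates
  values <- matrix(0, n * reps, m)
  lines <- rep(rownames(G$codes), each = reps)
  replicate <- rep(seq_len(reps), times = n)
  for (r in seq_len(reps)) {
    noise <- matrix(stats::rnorm(n * m, sd = config$replicate_noise_sd),
                    n, m)
    values[replicate == r, ] <- config$intensity_base + line_vals + noise
  }
  values <- pmax(values, 0)
  colnames(values) <- met_ids
  mx <- metabolome_matrix(values, lines = lines, replicate = replicate)
  truth <- list(genetic_metabolites = met_ids[genetic],
                metabolite_qtl = stats::setNames(qtl, met_ids),
                met_h2 = config$met_h2)
  list(metabolome = mx, line_values = line_vals, truth = truth)
}

#' Simulate hybrids, their trait, and the parental trait
#'
#' Hybrids are sampled uniformly without replacement from the diallel.
#' The hybrid trait sums an additive SNP term (midparent codes), a
#' dominance term (heterozygosity-coded), and a causal-metabolite term
#' through the additive/dominance metabolite codings, each standardized
#' and weighted so the genetic variance splits per the configured
#' fractions; Gaussian noise scales the total to the target heritability.
#' The parental trait applies the same effects to parental features (for
#' inbreds the dominance and metabolite-dominance terms vanish).
#'
#' @param G parental \code{GenotypeMatrix}.
#' @param sim_met result of \code{\link{simulate_metabolome}}.
#' @param config a \code{SimulationConfig}.
#' @return list with \code{crosses}, \code{hybrid_phenotypes},
#'   \code{parent_phenotypes} (trait column "trait"), and \code{truth}.
#' @export
simulate_hybrids_and_trait <- function(G, sim_met, config) {
  set.seed(config$seed + 2L)
  full <- enumerate_crosses(line_ids(G))
  pick <- sort(sample(nrow(full), config$n_hybrids))
  crosses <- full[pick, , drop = FALSE]
  class(crosses) <- c("CrossTable", "data.frame")

  qtl_ids <- sample(colnames(G$codes), config$n_qtl)
  a_eff <- stats::rnorm(config$n_qtl)
  d_eff <- stats::rnorm(config$n_qtl)
  mvals <- sim_met$line_values
  met_ids <- colnames(mvals)
  n_gen <- length(sim_met$truth$genetic_metabolites)
  n_ng <- round(config$causal_met_nongenetic_fraction * config$n_causal_met)
  n_gn <- config$n_causal_met - n_ng
  nongen_pool <- setdiff(met_ids, sim_met$truth$genetic_metabolites)
  causal_met <- c(sample(sim_met$truth$genetic_metabolites,
                         min(n_gn, n_gen)),
                  sample(nongen_pool, min(n_ng, length(nongen_pool))))
  ma_eff <- stats::rnorm(length(causal_met))
  md_eff <- stats::rnorm(length(causal_met), sd = 0.5)

  Z <- infer_hybrid_genotypes(G, crosses)[, qtl_ids, drop = FALSE]
  H <- 1 - abs(Z)
  Mline <- metabolome_matrix(mvals, lines = rownames(mvals),
                             normalized = TRUE)
  Msub <- metabolome_matrix(mvals[, causal_met, drop = FALSE],
                            lines = rownames(mvals), normalized = TRUE)
  ad <- code_metabolites(Msub, crosses)

  stdz <- function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  }
  add_h <- stdz(drop(Z %*% a_eff))
  dom_h <- stdz(drop(H %*% d_eff))
  met_h <- stdz(drop(ad$A %*% ma_eff + ad$D %*% md_eff))
  wa <- sqrt(1 - config$dominance_fraction - config$metabolite_fraction)
  wd <- sqrt(config$dominance_fraction)
  wm <- sqrt(config$metabolite_fraction)
  signal_h <- wa * add_h + wd * dom_h + wm * met_h

  n_h <- nrow(crosses)
  if (config$h2 == 0) {
    y_h <- stats::rnorm(n_h)
    signal_h <- signal_h * 0
  } else {
    svar <- stats::var(signal_h)
    esd <- sqrt(svar * (1 - config$h2) / config$h2)
    y_h <- signal_h + stats::rnorm(n_h, sd = esd)
  }

  # parental trait from the same effect vectors on parental features
  Zp <- G$codes[, qtl_ids, drop = FALSE]
  add_p <- stdz(drop(Zp %*% a_eff))
  met_p <- stdz(drop(mvals[, causal_met, drop = FALSE] %*% ma_eff))
  signal_p <- wa * add_p + wm * met_p
  n_p <- nrow(G$codes)
  if (config$h2 == 0) {
    y_p <- stats::rnorm(n_p)
  } else {
    esd_p <- sqrt(stats::var(signal_p) * (1 - config$h2) / config$h2)
    y_p <- signal_p + stats::rnorm(n_p, sd = esd_p)
  }

  hp <- matrix(y_h, ncol = 1, dimnames = list(crosses$hybrid_id, "trait"))
  pp <- matrix(y_p, ncol = 1, dimnames = list(rownames(G$codes), "trait"))
  truth <- list(causal_snps = qtl_ids, additive_effects = a_eff,
                dominance_effects = d_eff,
                causal_metabolites = causal_met,
                met_additive_effects = ma_eff,
                met_dominance_effects = md_eff,
                weights = c(additive = wa, dominance = wd,
                            metabolite = wm),
                realized_h2 = if (config$h2 == 0) 0 else
                  stats::var(signal_h) / stats::var(y_h),
                target_h2 = config$h2)
  list(crosses = crosses,
       hybrid_phenotypes = phenotype_table(hp),
       parent_phenotypes = phenotype_table(pp),
       truth = truth)
}

#' Generate a complete ready-to-run synthetic dataset
#'
#' Runs the three generators, applies the standard preprocessing
#' (replicate concordance filter, averaging, z-score normalization) and
#' returns an \code{\link{mmgp_data}} bundle plus ground truth. When
#' \code{dir} is given, the raw inputs are also written in the delimited
#' dialect together with a \code{truth.json}.
#'
#' @param config a \code{SimulationConfig}.
#' @param dir optional output directory.
#' @return list with \code{data} (an \code{mmgp_data}), \code{raw}
#'   (replicated raw metabolome), \code{qc_report}, and \code{truth}.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  G <- simulate_parents(config)
  sm <- simulate_metabolome(G, config)
  ht <- simulate_hybrids_and_trait(G, sm, config)
  qc <- replicate_concordance_filter(sm$metabolome)
  Ml <- normalize_metabolome(average_replicates(qc$metabolome))
  data <- mmgp_data(G, Ml, ht$parent_phenotypes, ht$hybrid_phenotypes,
                    ht$crosses)
  truth <- c(ht$truth, sm$truth["genetic_metabolites"],
             list(met_h2 = config$met_h2))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(G, file.path(dir, "genotypes.tsv"))
    write_metabolome(sm$metabolome, file.path(dir, "metabolome.tsv"))
    write_phenotypes(ht$parent_phenotypes,
                     file.path(dir, "parent_phenotypes.tsv"))
    write_phenotypes(ht$hybrid_phenotypes,
                     file.path(dir, "hybrid_phenotypes.tsv"))
    write_crosses(ht$crosses, file.path(dir, "crosses.tsv"))
    tr <- truth
    tr$metabolite_qtl <- NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(data = data, raw = sm$metabolome, qc_report = qc$report,
       truth = truth)
}
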