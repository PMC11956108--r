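# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except files the tests write first.

tiny_genotypes <- function(n = 6, g = 8, seed = 1) {
  set.seed(seed)
  codes <- matrix(sample(c(-1, 1), n * g, replace = TRUE), n, g,
                  dimnames = list(paste0("L", seq_len(n)),
                                  paste0("s", seq_len(g))))
  genotype_matrix(codes)
}

tiny_metabolome <- function(n = 6, m = 5, seed = 1, reps = NULL,
                            normalized = FALSE) {
  set.seed(seed)
  if (is.null(reps)) {
    v <- matrix(abs(rnorm(n * m, mean = 10)), n, m,
                dimnames = list(paste0("L", seq_len(n)),
                                paste0("met", seq_len(m))))
    metabolome_matrix(v, normalized = normalized)
  } else {
    v <- matrix(abs(rnorm(n * reps * m, mean = 10)), n * reps, m)
    colnames(v) <- paste0("met", seq_len(m))
    metabolome_matrix(v, lines = rep(paste0("L", seq_len(n)), each = reps),
                      replicate = rep(seq_len(reps), n))
  }
}

tiny_crosses <- function(parents, n_cross = NULL, seed = 1) {
  full <- enumerate_crosses(parents)
  if (is.null(n_cross) || n_cross >= nrow(full)) return(full)
  set.seed(seed)
  out <- full[sort(sample(nrow(full), n_cross)), , drop = FALSE]
  class(out) <- c("CrossTable", "data.frame")
  out
}

# moderately sized simulated bundle reused by several test files
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(
        n_parents = 60, g = 300, m = 80, n_hybrids = 150, seed = 3))
    cache
  }
})
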