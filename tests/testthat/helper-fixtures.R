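# Shared fixture builders: everything is generated in code at test time.

# A random valid summary-statistics record table.
random_records <- function(n, seed = 1L, palindromic_frac = 0) {
  set.seed(seed)
  pairs_ok <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                   c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  pairs_pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pal <- runif(n) < palindromic_frac
  pick <- function(is_pal) {
    src <- if (is_pal) pairs_pal else pairs_ok
    src[[sample.int(length(src), 1L)]]
  }
  al <- t(vapply(pal, pick, character(2)))
  data.frame(
    snp_id = sprintf("rs%04d", sample.int(9999L, n)),
    chrom = as.character(sample.int(22L, n, replace = TRUE)),
    pos = sample.int(1e6L, n),
    effect_allele = al[, 1L], other_allele = al[, 2L],
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.005, 0.05),
    pval = runif(n),
    n = sample(1000:50000, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_dataset <- function(n, seed = 1L, trait_kind = "metabolite", ...) {
  summary_dataset(random_records(n, seed, ...), trait_name = "trait",
                  trait_kind = trait_kind)
}

# A random valid LD matrix with block-exchangeable structure.
random_ld <- function(snp_ids, block_size = 3L, r2 = 0.6, seed = 1L) {
  set.seed(seed)
  J <- length(snp_ids)
  block <- rep(seq_len(ceiling(J / block_size)), each = block_size)[1:J]
  m <- outer(block, block, function(a, b) ifelse(a == b, r2, 0))
  diag(m) <- 1
  ld_matrix(m, snp_ids)
}

# A random harmonized set (already aligned).
random_hset <- function(J, seed = 1L, theta = 0.3) {
  set.seed(seed)
  bx <- rnorm(J, 0.1, 0.04)
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.01, 0.05)
  by <- theta * bx + rnorm(J, 0, sy)
  harmonized_set(bx, sx, by, sy)
}

# Fast analytic-mode simulation config used across simulation tests.
fast_sim_cfg <- function(seed, ...) {
  defaults <- list(seed = seed, n_snps = 50L, n_metabolites = 1L,
                   n_exposure_gwas = 50000L, n_outcome_gwas = 50000L,
                   instrument_effects = 0.1, theta = 0.5,
                   palindromic_frac = 0, ld_block_size = 1L,
                   gwas_mode = "analytic")
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# One analytic-mode IVW replicate pooled over k outcome datasets; returns
# estimate, pooled SE, CI, and the generating standardized truth.
ivw_replicate <- function(seed, k = 4L, ...) {
  cfg <- fast_sim_cfg(seed, ...)
  sim <- simulate_two_sample_gwas(cfg, n_outcome_datasets = k)
  ests <- lapply(sim$outcome_datasets, function(d) {
    mr_ivw(harmonize(sim$exposure, d[[1L]]))
  })
  pooled <- meta_mr_datasets(ests)
  list(theta = pooled$pooled_theta, se = pooled$se,
       ci_low = pooled$ci_low, ci_high = pooled$ci_high,
       pval = pooled$pval, truth = sim$truth$theta[1L],
       total_f = instrument_strength(sim$exposure)$total_f)
}
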