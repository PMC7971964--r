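#' Configuration for the synthetic two-sample MR / cohort study generator
#'
#' Bundles every knob of the generator into one validated record. The
#' defaults emulate the study design the pipeline targets: a binary sleep
#' exposure arising from a liability-threshold model, 113 metabolite
#' outcomes in SD units of log concentration whose correlation is carried
#' by 17 latent factors accounting for 95% of variance, two non-overlapping
#' GWAS samples, block-structured LD, and age/sex/BMI plus a shared latent
#' confounder acting on both exposure and metabolites.
#'
#' @param seed integer; together with the config it fully determines all
#'   output. Each component (genotypes, phenotypes, cohorts, ...) draws from
#'   its own named sub-stream derived from this seed, so adding one
#'   component never perturbs another's draws.
#' @param n_snps number of candidate instrument SNPs.
#' @param n_exposure_gwas,n_outcome_gwas sample sizes of the two
#'   non-overlapping GWAS samples (exposure sample A, metabolite sample B).
#' @param n_cohorts,n_per_cohort number and size of the cohort tables for
#'   the adjusted-multivariable-regression (AMV) arm.
#' @param n_metabolites number of metabolite outcomes.
#' @param exposure_kind `"binary_liability"` (e.g. insomnia
#'   usually-vs-less-often, evening-vs-morning chronotype, short/long
#'   vs. normal duration) or `"continuous_hours"` (sleep duration in
#'   hours).
#' @param exposure_prevalence case fraction for binary exposures.
#' @param duration_mean,duration_sd mean and SD in hours for
#'   `"continuous_hours"` exposures.
#' @param instrument_effects per-SNP effects of the allele count on the
#'   exposure liability/value; recycled, or `NULL` to draw them once from
#'   `instrument_effect_sd`.
#' @param instrument_effect_sd SD of drawn instrument effects when
#'   `instrument_effects` is `NULL`.
#' @param theta true causal effect(s) of the exposure on each metabolite,
#'   on the metabolite's pre-standardization log scale (recycled across
#'   metabolites). The truth record reports the equivalent effect in final
#'   SD units, which is what estimators are scored against.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct SNP-to-metabolite
#'   effects with mean zero) or `"directional"` (mean `pleiotropy_scale`).
#' @param pleiotropy_scale scale of pleiotropic effects: SD for balanced,
#'   mean (with SD of half the mean) for directional.
#' @param pleiotropy_frac fraction of SNPs given pleiotropic paths.
#' @param n_factors latent metabolite factors.
#' @param factor_variance_target fraction of each metabolite's baseline
#'   variance carried by its factor; matches the convention that 17
#'   principal components explain 95% of metabolomic panel variance.
#' @param confounder_exposure,confounder_metabolite loadings of a shared
#'   standard-normal confounder U on the exposure liability and on every
#'   metabolite.
#' @param age_exposure,sex_exposure,bmi_exposure covariate effects on the
#'   exposure liability/value (age and BMI enter standardized; sex is 0/1).
#' @param age_metabolite,sex_metabolite,bmi_metabolite covariate effects on
#'   every metabolite.
#' @param maf_range range of minor-allele frequencies to draw from.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_r2_within exchangeable r-squared within a block.
#' @param palindromic_frac fraction of SNPs assigned strand-ambiguous (A/T
#'   or C/G) allele pairs, to exercise the palindrome filter.
#' @param gwas_mode `"regression"` computes summary statistics by actually
#'   regressing simulated phenotypes on simulated genotypes, so standard
#'   errors, heterogeneity, and weak-instrument behaviour emerge naturally;
#'   `"analytic"` draws beta-hat from its asymptotic normal law (fast path
#'   for large-n property tests).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_snps = 60L,
                       n_exposure_gwas = 20000L,
                       n_outcome_gwas = 20000L,
                       n_cohorts = 10L,
                       n_per_cohort = 2000L,
                       n_metabolites = 113L,
                       exposure_kind = c("binary_liability", "continuous_hours"),
                       exposure_prevalence = 0.3,
                       duration_mean = 7.2,
                       duration_sd = 1.1,
                       instrument_effects = NULL,
                       instrument_effect_sd = 0.08,
                       theta = 0.05,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_scale = 0.05,
                       pleiotropy_frac = 0.3,
                       n_factors = min(17L, n_metabolites),
                       factor_variance_target = 0.95,
                       confounder_exposure = 0.3,
                       confounder_metabolite = 0.2,
                       age_exposure = 0.1, sex_exposure = 0.1,
                       bmi_exposure = 0.2,
                       age_metabolite = 0.1, sex_metabolite = 0.1,
                       bmi_metabolite = 0.2,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1L,
                       ld_r2_within = 0.5,
                       palindromic_frac = 0.1,
                       gwas_mode = c("regression", "analytic")) {
  cfg <- list(
    seed = as.integer(seed), n_snps = as.integer(n_snps),
    n_exposure_gwas = as.integer(n_exposure_gwas),
    n_outcome_gwas = as.integer(n_outcome_gwas),
    n_cohorts = as.integer(n_cohorts),
    n_per_cohort = as.integer(n_per_cohort),
    n_metabolites = as.integer(n_metabolites),
    exposure_kind = match.arg(exposure_kind),
    exposure_prevalence = exposure_prevalence,
    duration_mean = duration_mean, duration_sd = duration_sd,
    instrument_effects = instrument_effects,
    instrument_effect_sd = instrument_effect_sd,
    theta = theta,
    pleiotropy_mode = match.arg(pleiotropy_mode),
    pleiotropy_scale = pleiotropy_scale,
    pleiotropy_frac = pleiotropy_frac,
    n_factors = as.integer(n_factors),
    factor_variance_target = factor_variance_target,
    confounder_exposure = confounder_exposure,
    confounder_metabolite = confounder_metabolite,
    age_exposure = age_exposure, sex_exposure = sex_exposure,
    bmi_exposure = bmi_exposure,
    age_metabolite = age_metabolite, sex_metabolite = sex_metabolite,
    bmi_metabolite = bmi_metabolite,
    maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size),
    ld_r2_within = ld_r2_within,
    palindromic_frac = palindromic_frac,
    gwas_mode = match.arg(gwas_mode))

  with(cfg, {
    if (n_snps < 1L || n_exposure_gwas < 1L || n_outcome_gwas < 1L ||
        n_cohorts < 1L || n_per_cohort < 1L || n_metabolites < 1L) {
      stop("all sample/feature counts must be positive", call. = FALSE)
    }
    if (exposure_prevalence <= 0 || exposure_prevalence >= 1) {
      stop("exposure_prevalence must lie in (0,1)", call. = FALSE)
    }
    if (factor_variance_target >= 1 || factor_variance_target < 0) {
      stop("factor_variance_target must lie in [0,1)", call. = FALSE)
    }
    if (n_factors < 1L || n_factors > n_metabolites) {
      stop("n_factors must lie in [1, n_metabolites]", call. = FALSE)
    }
    if (ld_r2_within < 0 || ld_r2_within > 1 || ld_block_size < 1L) {
      stop("invalid LD block parameters", call. = FALSE)
    }
    if (any(c(instrument_effect_sd, pleiotropy_scale) < 0)) {
      stop("variance/scale parameters must be non-negative", call. = FALSE)
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-component sub-stream: seeds R's RNG from the base seed
# and a component label via a small string hash, keeping the result in
# [0, 2^31). Adding a component never shifts another component's draws.
.seed_substream <- function(seed, component) {
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 1789569706
  set.seed((as.numeric(seed) %% 1789569706) + h)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Model moments implied by the generating equations (used both to calibrate
# the analytic fast path and to express the causal truth in final SD units).

# Allele-count covariance matrix under block-exchangeable LD.
.geno_cov <- function(truth, cfg) {
  vg <- 2 * truth$maf * (1 - truth$maf)
  R <- outer(truth$block_of, truth$block_of,
             function(a, b) ifelse(a == b, sqrt(cfg$ld_r2_within), 0))
  diag(R) <- 1
  R * outer(sqrt(vg), sqrt(vg))
}

.model_moments <- function(truth, cfg) {
  Cg <- .geno_cov(truth, cfg)
  var_L_geno <- as.numeric(crossprod(truth$gamma, Cg %*% truth$gamma))
  sd_L <- sqrt(var_L_geno + cfg$confounder_exposure^2 + cfg$age_exposure^2 +
                 0.25 * cfg$sex_exposure^2 + cfg$bmi_exposure^2 + 1)
  if (cfg$exposure_kind == "binary_liability") {
    p <- cfg$exposure_prevalence
    k <- stats::dnorm(qnorm(1 - p)) / sd_L  # d E[x] / d liability shift
    var_x <- p * (1 - p)
  } else {
    k <- cfg$duration_sd / sd_L
    var_x <- cfg$duration_sd^2
  }
  # cov(x, .) = k * cov(L, .) for liability components
  Cg_gamma <- Cg %*% truth$gamma
  cov_x_g <- k * as.numeric(Cg_gamma)            # per SNP
  cov_x_U <- k * cfg$confounder_exposure
  cov_x_age <- k * cfg$age_exposure
  cov_x_sex <- k * 0.25 * cfg$sex_exposure
  cov_x_bmi <- k * cfg$bmi_exposure

  CgA <- Cg %*% truth$alpha                       # J x M
  var_Galpha <- colSums(truth$alpha * CgA)        # per metabolite
  cov_x_Galpha <- k * as.numeric(crossprod(truth$gamma, CgA))

  th <- truth$theta_raw
  # baseline metabolite variance is 1 by construction (factor + shared
  # paths scaled to factor_variance_target, residual the complement)
  s <- truth$loading / sqrt(1 + .shared_var(cfg))
  cov_x_shared <- s * (cfg$confounder_metabolite * cov_x_U +
                         cfg$age_metabolite * cov_x_age +
                         cfg$sex_metabolite * cov_x_sex +
                         cfg$bmi_metabolite * cov_x_bmi)
  pop_var <- 1 + th^2 * var_x + var_Galpha +
    2 * th * (cov_x_Galpha + cov_x_shared)
  list(Cg = Cg, sd_L = sd_L, k = k, var_x = var_x,
       cov_x_g = cov_x_g, pop_sd = sqrt(pop_var))
}

# Realized simulation truth: everything needed to score an estimator.
.sim_truth <- function(cfg) {
  J <- cfg$n_snps; M <- cfg$n_metabolites

  .seed_substream(cfg$seed, "truth")
  maf <- runif(J, cfg$maf_range[1L], cfg$maf_range[2L])
  gamma <- cfg$instrument_effects
  if (is.null(gamma)) gamma <- rnorm(J, 0, cfg$instrument_effect_sd)
  gamma <- rep_len(as.numeric(gamma), J)
  theta_raw <- rep_len(as.numeric(cfg$theta), M)

  alpha <- matrix(0, J, M)
  pleio_snps <- logical(J)
  if (cfg$pleiotropy_mode != "none" && cfg$pleiotropy_frac > 0) {
    n_pleio <- max(1L, round(cfg$pleiotropy_frac * J))
    pleio_snps[sample.int(J, n_pleio)] <- TRUE
    mu <- if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_scale else 0
    sdev <- if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_scale / 2
            else cfg$pleiotropy_scale
    alpha[pleio_snps, ] <- rnorm(sum(pleio_snps) * M, mu, sdev)
  }

  # allele pairs; a configurable fraction is strand-ambiguous
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  all_pairs <- expand.grid(e = .ALLELES, o = .ALLELES, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$e != all_pairs$o, ]
  is_pal <- paste(all_pairs$e, all_pairs$o) %in% paste(pal_pairs[, 1L],
                                                       pal_pairs[, 2L])
  pal <- runif(J) < cfg$palindromic_frac
  pi <- sample.int(4L, J, replace = TRUE)
  npi <- sample(which(!is_pal), J, replace = TRUE)
  effect_allele <- ifelse(pal, pal_pairs[pi, 1L], all_pairs$e[npi])
  other_allele <- ifelse(pal, pal_pairs[pi, 2L], all_pairs$o[npi])

  # factor model: each metabolite loads on one of n_factors latent factors
  factor_of <- rep_len(seq_len(cfg$n_factors), M)
  loading <- sqrt(cfg$factor_variance_target)

  n_blocks <- ceiling(J / cfg$ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(J)]

  truth <- list(snp_id = sprintf("rs%05d", seq_len(J)),
                chrom = as.character(block_of %% 22L + 1L),
                pos = seq_len(J) * 50000L,
                effect_allele = effect_allele, other_allele = other_allele,
                maf = maf, gamma = gamma, theta_raw = theta_raw,
                alpha = alpha,
                valid_instrument = !pleio_snps & abs(gamma) > 0,
                factor_of = factor_of, loading = loading,
                block_of = block_of)
  mom <- .model_moments(truth, cfg)
  # the scoreable causal effect: per exposure unit, in final SD units of
  # the (standardized) log metabolite
  truth$pop_sd <- mom$pop_sd
  truth$theta <- theta_raw / mom$pop_sd
  truth$alpha_std <- sweep(alpha, 2L, mom$pop_sd, "/")
  truth
}

# Draw a genotype matrix (allele counts 0/1/2) with exchangeable
# within-block haplotype correlation via a Gaussian copula.
.sim_genotypes <- function(n, truth, cfg) {
  J <- length(truth$maf)
  rho <- sqrt(cfg$ld_r2_within)  # target allele-level correlation
  thresh <- qnorm(truth$maf)
  G <- matrix(0L, n, J)
  for (hap in 1:2) {
    z_block <- matrix(rnorm(n * max(truth$block_of)), n)
    z <- sqrt(rho) * z_block[, truth$block_of, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * J), n)
    G <- G + (z < rep(thresh, each = n))
  }
  colnames(G) <- truth$snp_id
  G
}

# Per-SNP simple linear regression of y on each genotype column, vectorized.
.gwas_scan <- function(G, y) {
  n <- length(y)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  if (any(sxx == 0)) stop("monomorphic SNP in simulated sample", call. = FALSE)
  beta <- as.numeric(crossprod(Gc, yc)) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  se[se == 0] <- .Machine$double.xmin
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, se = se, pval = p, eaf = colMeans(G) / 2)
}

# Exposure phenotype from genotypes + covariates + confounder.
.sim_exposure <- function(G, truth, cfg, covars) {
  liab <- as.numeric(G %*% truth$gamma) +
    cfg$confounder_exposure * covars$U +
    cfg$age_exposure * covars$age + cfg$sex_exposure * covars$sex +
    cfg$bmi_exposure * covars$bmi +
    rnorm(nrow(G))
  if (cfg$exposure_kind == "binary_liability") {
    as.numeric(liab > stats::quantile(liab, 1 - cfg$exposure_prevalence))
  } else {
    cfg$duration_mean + cfg$duration_sd * scale(liab)[, 1L]
  }
}

# Shared (confounder + covariate) variance added to each factor score.
.shared_var <- function(cfg) {
  cfg$confounder_metabolite^2 + cfg$age_metabolite^2 +
    0.25 * cfg$sex_metabolite^2 + cfg$bmi_metabolite^2
}

# Metabolite panel on the log scale. The confounder and covariate paths
# enter through the latent factor scores, so the systematic part of the
# panel covariance stays rank-n_factors: the configured number of
# principal components carries the configured variance fraction even with
# confounding switched on. Each column is standardized to unit variance
# (SD units of log concentration).
.sim_metabolites <- function(G, exposure, truth, cfg, covars) {
  n <- nrow(G); M <- cfg$n_metabolites
  shared <- cfg$confounder_metabolite * covars$U +
    cfg$age_metabolite * covars$age + cfg$sex_metabolite * covars$sex +
    cfg$bmi_metabolite * covars$bmi
  Fmat <- matrix(rnorm(n * cfg$n_factors), n) + shared
  s <- truth$loading / sqrt(1 + .shared_var(cfg))
  resid_sd <- sqrt(1 - cfg$factor_variance_target)
  base <- s * Fmat[, truth$factor_of, drop = FALSE] +
    matrix(rnorm(n * M, 0, resid_sd), n)
  expo_c <- if (cfg$exposure_kind == "continuous_hours")
    (exposure - cfg$duration_mean) else exposure
  Y <- base +
    outer(expo_c, truth$theta_raw) +
    G %*% truth$alpha
  Y <- scale(Y, center = TRUE, scale = TRUE)
  colnames(Y) <- sprintf("metabolite_%03d", seq_len(M))
  Y
}

.sim_covars <- function(n) {
  list(U = rnorm(n), age = rnorm(n), sex = rbinom(n, 1L, 0.5),
       bmi = rnorm(n))
}

# Population (block-exchangeable) LD matrix implied by the config.
.sim_ld <- function(truth, cfg) {
  r2 <- outer(truth$block_of, truth$block_of,
              function(a, b) ifelse(a == b, cfg$ld_r2_within, 0))
  diag(r2) <- 1
  ld_matrix(r2, truth$snp_id)
}

.records_from_scan <- function(truth, scan, n) {
  data.frame(snp_id = truth$snp_id, chrom = truth$chrom, pos = truth$pos,
             effect_allele = truth$effect_allele,
             other_allele = truth$other_allele,
             eaf = pmin(pmax(scan$eaf, 1e-6), 1 - 1e-6),
             beta = scan$beta, se = scan$se, pval = scan$pval,
             n = n, stringsAsFactors = FALSE)
}

# Analytic fast path: draw beta-hat from Normal(beta_true, se) with the
# asymptotic standard error for a phenotype of the given variance.
.analytic_scan <- function(truth, beta_true, n, pheno_var) {
  vg <- 2 * truth$maf * (1 - truth$maf)
  se <- sqrt(pheno_var / (n * vg))
  beta <- rnorm(length(beta_true), beta_true, se)
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, se = se, pval = p, eaf = truth$maf)
}

#' Simulate non-overlapping two-sample GWAS summary statistics
#'
#' Draws sample A for the exposure GWAS and, independently, one sample B
#' per outcome dataset for the metabolite GWAS, then computes per-SNP
#' summary statistics in each. Binary exposures are analysed on the
#' observed 0/1 scale by linear regression, mirroring the biobank GWAS
#' convention; metabolites are standardized within sample so betas are in
#' SD units of log concentration. With `gwas_mode = "analytic"` the
#' per-SNP estimates are drawn from their asymptotic normal law instead of
#' fitted, which is orders of magnitude faster for property tests.
#'
#' @param cfg a [sim_config()].
#' @param n_outcome_datasets number of independent metabolite GWAS samples
#'   (the study design this emulates pooled four).
#' @return a list with elements `exposure` (a `summary_dataset`),
#'   `outcome_datasets` (a named list, one element per dataset, each a
#'   named list of per-metabolite `summary_dataset`s), `metabolites` (the
#'   first dataset, for the common single-dataset case), `ld` (an
#'   `ld_matrix`), and `truth` (realized effects: `gamma`, `alpha`,
#'   `theta` in final SD units, allele frequencies, valid-instrument
#'   flags).
#' @export
simulate_two_sample_gwas <- function(cfg, n_outcome_datasets = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_outcome_datasets >= 1L)
  truth <- .sim_truth(cfg)
  M <- cfg$n_metabolites
  mom <- .model_moments(truth, cfg)

  if (cfg$gwas_mode == "regression") {
    .seed_substream(cfg$seed, "gwas_exposure")
    GA <- .sim_genotypes(cfg$n_exposure_gwas, truth, cfg)
    covA <- .sim_covars(cfg$n_exposure_gwas)
    xA <- .sim_exposure(GA, truth, cfg, covA)
    scanA <- .gwas_scan(GA, xA)
    make_outcome <- function(d) {
      .seed_substream(cfg$seed, paste0("gwas_outcome_", d))
      GB <- .sim_genotypes(cfg$n_outcome_gwas, truth, cfg)
      covB <- .sim_covars(cfg$n_outcome_gwas)
      xB <- .sim_exposure(GB, truth, cfg, covB)
      YB <- .sim_metabolites(GB, xB, truth, cfg, covB)
      GBc <- scale(GB, center = TRUE, scale = FALSE)
      sxx <- colSums(GBc^2)
      if (any(sxx == 0)) stop("monomorphic SNP in simulated sample", call. = FALSE)
      betas <- crossprod(GBc, YB) / sxx   # YB already centred by scale()
      eaf <- colMeans(GB) / 2
      lapply(seq_len(M), function(t) {
        b <- betas[, t]
        rss <- (cfg$n_outcome_gwas - 1) - b^2 * sxx  # unit-variance outcome
        se <- sqrt(pmax(rss, 0) / (cfg$n_outcome_gwas - 2) / sxx)
        se[se == 0] <- .Machine$double.xmin
        p <- pmin(pmax(2 * pnorm(-abs(b / se)), .Machine$double.xmin), 1)
        list(beta = b, se = se, pval = p, eaf = eaf)
      })
    }
  } else {
    # analytic path: marginal per-SNP slopes implied by the model
    gobs <- mom$cov_x_g / (2 * truth$maf * (1 - truth$maf))
    Cg <- mom$Cg
    vg <- diag(Cg)
    make_outcome <- function(d) {
      .seed_substream(cfg$seed, paste0("gwas_outcome_", d))
      # marginal SNP-metabolite slope: causal path + pleiotropic path,
      # including LD leakage from block neighbours, on the SD scale
      direct <- sweep(truth$alpha, 2L, mom$pop_sd, "/")  # J x M
      causal <- outer(mom$cov_x_g, truth$theta_raw / mom$pop_sd) # J x M
      ld_leak <- Cg %*% direct
      bmar <- sweep(causal + ld_leak, 1L, vg, "/")
      lapply(seq_len(M), function(t) {
        .analytic_scan(truth, bmar[, t], cfg$n_outcome_gwas, 1)
      })
    }
    .seed_substream(cfg$seed, "gwas_exposure")
    scanA <- .analytic_scan(truth, gobs, cfg$n_exposure_gwas, mom$var_x)
  }

  exposure <- summary_dataset(
    .records_from_scan(truth, scanA, cfg$n_exposure_gwas),
    trait_name = "exposure",
    trait_kind = if (cfg$exposure_kind == "binary_liability")
      "binary_exposure" else "continuous_exposure")
  met_names <- sprintf("metabolite_%03d", seq_len(M))
  outcome_datasets <- lapply(seq_len(n_outcome_datasets), function(d) {
    scans <- make_outcome(d)
    mets <- lapply(seq_len(M), function(t) {
      summary_dataset(.records_from_scan(truth, scans[[t]],
                                         cfg$n_outcome_gwas),
                      trait_name = met_names[t], trait_kind = "metabolite")
    })
    names(mets) <- met_names
    mets
  })
  names(outcome_datasets) <- sprintf("dataset_%d", seq_len(n_outcome_datasets))

  list(exposure = exposure, outcome_datasets = outcome_datasets,
       metabolites = outcome_datasets[[1L]],
       ld = .sim_ld(truth, cfg), truth = truth)
}

#' Simulate per-cohort tables for the observational (AMV) arm
#'
#' Each cohort table holds one row per participant with the exposure, the
#' standardized log-scale metabolite panel, and age, sex, and BMI. The
#' shared confounder and the covariate paths induce a confounded crude
#' exposure-metabolite association; conditioning on age/sex/BMI leaves the
#' causal effect plus only the residual confounder-induced bias.
#' Participants are simulated free of exclusions (e.g. diabetes), so the
#' regression stage can assume clean input.
#'
#' @param cfg a [sim_config()].
#' @return a list of `n_cohorts` data frames with columns `exposure`,
#'   `metabolite_001`..., `age`, `sex`, `bmi`; independent noise across
#'   cohorts, shared truth.
#' @export
simulate_amv_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- .sim_truth(cfg)
  out <- lapply(seq_len(cfg$n_cohorts), function(k) {
    .seed_substream(cfg$seed, paste0("cohort_", k))
    n <- cfg$n_per_cohort
    covars <- .sim_covars(n)
    G <- .sim_genotypes(n, truth, cfg)
    exposure <- .sim_exposure(G, truth, cfg, covars)
    Y <- .sim_metabolites(G, exposure, truth, cfg, covars)
    tab <- data.frame(exposure = as.numeric(exposure), Y, check.names = FALSE)
    tab$age <- covars$age
    tab$sex <- covars$sex
    tab$bmi <- covars$bmi
    tab
  })
  names(out) <- sprintf("cohort_%02d", seq_len(cfg$n_cohorts))
  attr(out, "truth") <- truth
  out
}

#' Write every artifact of a simulated two-sample study to disk
#'
#' Emits the exposure and per-dataset, per-metabolite summary-statistics
#' TSVs, the LD matrix TSV, truth TSVs (per-SNP gamma and validity flags;
#' per-metabolite causal effect in SD units), and the full configuration
#' echoed as YAML.
#'
#' @param sim result of [simulate_two_sample_gwas()].
#' @param cfg the [sim_config()] that produced it.
#' @param dir output directory (created if absent).
#' @return named character vector of the top-level paths written,
#'   invisibly.
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             ld = file.path(dir, "ld_matrix.tsv"),
             truth_snps = file.path(dir, "truth_snps.tsv"),
             truth_metabolites = file.path(dir, "truth_metabolites.tsv"),
             config = file.path(dir, "sim_config.yaml"))
  write_summary_stats(sim$exposure, paths[["exposure"]])
  write_ld_matrix(sim$ld, paths[["ld"]])
  tr <- sim$truth
  data.table::fwrite(
    data.frame(snp_id = tr$snp_id, maf = tr$maf, gamma = tr$gamma,
               valid_instrument = tr$valid_instrument,
               mean_alpha = rowMeans(tr$alpha)),
    paths[["truth_snps"]], sep = "\t")
  data.table::fwrite(
    data.frame(metabolite = names(sim$metabolites), theta = tr$theta),
    paths[["truth_metabolites"]], sep = "\t")
  for (d in names(sim$outcome_datasets)) {
    met_dir <- file.path(dir, d)
    dir.create(met_dir, showWarnings = FALSE)
    for (nm in names(sim$outcome_datasets[[d]])) {
      write_summary_stats(sim$outcome_datasets[[d]][[nm]],
                          file.path(met_dir, paste0(nm, ".tsv")))
    }
  }
  cfg_out <- cfg
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, paths[["config"]])
  invisible(paths)
}
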