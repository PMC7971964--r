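#' Keep genome-wide significant associations
#'
#' Retains exactly the records with `pval` strictly below the threshold
#' (the conventional genome-wide significance level by default), in their
#' original order.
#'
#' @param ds a `summary_dataset`.
#' @param threshold significance level; strict inequality is applied.
#' @return a `summary_dataset` with the surviving records.
#' @export
filter_significant <- function(ds, threshold = 5e-8) {
  stopifnot(inherits(ds, "summary_dataset"))
  keep <- ds$records$pval < threshold
  ds$records <- ds$records[keep, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}

#' Drop strand-ambiguous (palindromic) SNPs
#'
#' Removes records whose allele pair is A/T or C/G. Such variants cannot be
#' oriented across datasets without frequency-based strand inference, so
#' the pipeline excludes them outright before harmonization.
#'
#' @param ds a `summary_dataset`.
#' @param verbose log one message per removed SNP.
#' @return a `summary_dataset` without palindromic records.
#' @export
drop_palindromic <- function(ds, verbose = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  pal <- is_palindromic(ds$records$effect_allele, ds$records$other_allele)
  if (verbose && any(pal)) {
    for (id in ds$records$snp_id[pal]) {
      message("dropping palindromic SNP: ", id)
    }
  }
  ds$records <- ds$records[!pal, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}

#' Is an allele pair strand-ambiguous?
#' @param a1,a2 character vectors of alleles (A/C/G/T).
#' @return logical vector: `TRUE` where the unordered pair is \{A,T\} or
#'   \{C,G\}.
#' @export
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Greedy LD clumping of a summary dataset
#'
#' Repeatedly keeps the remaining record with the smallest p-value and
#' discards every remaining record in linkage disequilibrium with it above
#' the r-squared threshold, until no record remains. P-value ties break by
#' the lexicographically smaller `snp_id`, for determinism. Clumping is
#' all-pairs against the supplied LD matrix; no physical-distance window is
#' applied.
#'
#' @param ds a `summary_dataset` whose SNPs all appear in `ld`.
#' @param ld an [ld_matrix()].
#' @param r2_threshold discard threshold: records with r-squared strictly
#'   greater than this to any kept record are removed.
#' @return a `summary_dataset` of the kept records, in selection order
#'   (ascending p-value).
#' @export
ld_clump <- function(ds, ld, r2_threshold = 0.001) {
  stopifnot(inherits(ds, "summary_dataset"), inherits(ld, "ld_matrix"))
  rec <- ds$records
  missing <- setdiff(rec$snp_id, rownames(ld))
  if (length(missing) > 0L) {
    stop("SNP(s) absent from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  remaining <- order(rec$pval, rec$snp_id)
  kept <- integer(0)
  r2 <- unclass(ld)
  while (length(remaining) > 0L) {
    top <- remaining[1L]
    kept <- c(kept, top)
    remaining <- remaining[-1L]
    if (length(remaining) > 0L) {
      linked <- r2[rec$snp_id[remaining], rec$snp_id[top]] > r2_threshold
      remaining <- remaining[!linked]
    }
  }
  ds$records <- rec[kept, , drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}

#' Reorient records to the trait-increasing allele
#'
#' Re-expresses every record on the allele associated with a higher trait
#' value (e.g. evening rather than morning chronotype preference): where
#' `beta < 0`, the effect and other alleles are swapped, the beta is
#' negated, and the effect-allele frequency complemented. Idempotent.
#'
#' @param ds a `summary_dataset`.
#' @return a `summary_dataset` with all betas non-negative.
#' @export
reorient_to_risk_allele <- function(ds) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  flip <- rec$beta < 0
  if (any(flip)) {
    ea <- rec$effect_allele[flip]
    rec$effect_allele[flip] <- rec$other_allele[flip]
    rec$other_allele[flip] <- ea
    rec$beta[flip] <- -rec$beta[flip]
    rec$eaf[flip] <- 1 - rec$eaf[flip]
  }
  ds$records <- rec
  ds
}

#' Instrument strength F-statistics
#'
#' Per-SNP F is the squared z-score `(beta/se)^2`; the total F is their
#' sum over the instrument set.
#'
#' @param ds a nonempty `summary_dataset`.
#' @return a list with `per_snp_f` (named numeric vector keyed by
#'   `snp_id`) and `total_f`.
#' @export
instrument_strength <- function(ds) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (nrow(ds$records) == 0L) {
    stop("cannot compute instrument strength of an empty dataset",
         call. = FALSE)
  }
  f <- (ds$records$beta / ds$records$se)^2
  names(f) <- ds$records$snp_id
  list(per_snp_f = f, total_f = sum(f))
}

#' Select instruments for an exposure
#'
#' Runs the fixed selection pipeline — significance filter, palindromic-SNP
#' exclusion, greedy LD clumping, and (optionally) reorientation to the
#' trait-increasing allele — and attaches F-statistics.
#'
#' @param ds the exposure `summary_dataset`.
#' @param ld an [ld_matrix()] covering the dataset's SNPs.
#' @param threshold significance threshold, see [filter_significant()].
#' @param r2_threshold clumping threshold, see [ld_clump()].
#' @param reorient re-express on the trait-increasing allele (used for
#'   chronotype-style exposures).
#' @return an object of class `instrument_set`: list with
#'   `exposure_name`, `dataset` (the surviving `summary_dataset`),
#'   `per_snp_f`, `total_f`, and per-stage `counts`.
#' @export
select_instruments <- function(ds, ld, threshold = 5e-8,
                               r2_threshold = 0.001, reorient = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  sig <- filter_significant(ds, threshold)
  nopal <- drop_palindromic(sig)
  clumped <- ld_clump(nopal, ld, r2_threshold)
  if (reorient) clumped <- reorient_to_risk_allele(clumped)
  if (nrow(clumped$records) == 0L) {
    stop("no instruments survive selection for '", ds$trait_name, "'",
         call. = FALSE)
  }
  strength <- instrument_strength(clumped)
  structure(list(exposure_name = ds$trait_name, dataset = clumped,
                 per_snp_f = strength$per_snp_f,
                 total_f = strength$total_f,
                 counts = c(input = nrow(ds$records),
                            significant = nrow(sig$records),
                            non_palindromic = nrow(nopal$records),
                            clumped = nrow(clumped$records))),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> exposure '%s': %d instruments (of %d input SNPs), total F = %.1f\n",
    x$exposure_name, length(x$per_snp_f), x$counts[["input"]], x$total_f))
  invisible(x)
}

#' Write an instrument set to disk
#'
#' Emits the surviving records as a summary-statistics TSV plus a
#' two-column F-statistic TSV (`snp_id`, `f`).
#'
#' @param iset an `instrument_set`.
#' @param stats_path,f_path output paths.
#' @return `stats_path`, invisibly.
#' @export
write_instrument_set <- function(iset, stats_path, f_path) {
  stopifnot(inherits(iset, "instrument_set"))
  write_summary_stats(iset$dataset, stats_path)
  data.table::fwrite(
    data.frame(snp_id = names(iset$per_snp_f),
               f = sprintf("%.17g", iset$per_snp_f)),
    f_path, sep = "\t", quote = FALSE)
  invisible(stats_path)
}
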