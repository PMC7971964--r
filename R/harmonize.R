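.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align exposure instruments and outcome summary statistics
#'
#' For each instrument SNP found in the outcome dataset, re-expresses the
#' outcome association on the instrument's effect allele so both betas are
#' coded in the same direction:
#'
#' * alleles identical: kept as-is;
#' * outcome alleles are the swap of the exposure alleles: outcome beta
#'   negated, outcome eaf complemented;
#' * outcome alleles are the strand complement (or complement-swap) of the
#'   exposure alleles: resolved as above after complementing — unambiguous
#'   here because palindromic SNPs are excluded upstream;
#' * anything else: dropped with reason `"allele_mismatch"`.
#'
#' Instrument SNPs absent from the outcome are dropped with reason
#' `"missing_in_outcome"`. Matching is by `snp_id`; with `strict = TRUE`,
#' chromosome/position are additionally required to agree where present.
#'
#' @param instruments an `instrument_set` (or a `summary_dataset` of
#'   selected instruments).
#' @param outcome the outcome `summary_dataset`.
#' @param strict also cross-check chrom/pos when both sides carry them.
#' @return an object of class `harmonized_set`: list with
#'   `exposure_name`, `outcome_name`, `rows` (data frame: `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`) and `dropped` (data frame: `snp_id`,
#'   `reason`).
#' @export
harmonize <- function(instruments, outcome, strict = FALSE) {
  if (inherits(instruments, "instrument_set")) {
    exp_name <- instruments$exposure_name
    exp_rec <- instruments$dataset$records
  } else {
    stopifnot(inherits(instruments, "summary_dataset"))
    exp_name <- instruments$trait_name
    exp_rec <- instruments$records
  }
  stopifnot(inherits(outcome, "summary_dataset"))
  if (nrow(exp_rec) == 0L) stop("no instruments to harmonize", call. = FALSE)
  if (any(is_palindromic(exp_rec$effect_allele, exp_rec$other_allele))) {
    stop("palindromic instrument(s) present; run drop_palindromic() first",
         call. = FALSE)
  }
  out_rec <- outcome$records
  idx <- match(exp_rec$snp_id, out_rec$snp_id)

  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    j <- idx[i]
    if (is.na(j)) {
      dropped[[length(dropped) + 1L]] <- c(e$snp_id, "missing_in_outcome")
      next
    }
    o <- out_rec[j, ]
    if (strict && !is.na(e$chrom) && !is.na(o$chrom) &&
        (e$chrom != o$chrom ||
         (!is.na(e$pos) && !is.na(o$pos) && e$pos != o$pos))) {
      dropped[[length(dropped) + 1L]] <- c(e$snp_id, "position_mismatch")
      next
    }
    oe <- o$effect_allele; oo <- o$other_allele
    action <- if (oe == e$effect_allele && oo == e$other_allele) {
      "keep"
    } else if (oe == e$other_allele && oo == e$effect_allele) {
      "flip"
    } else if (.COMPLEMENT[[oe]] == e$effect_allele &&
               .COMPLEMENT[[oo]] == e$other_allele) {
      "keep"   # opposite strand, same orientation
    } else if (.COMPLEMENT[[oe]] == e$other_allele &&
               .COMPLEMENT[[oo]] == e$effect_allele) {
      "flip"   # opposite strand, swapped
    } else {
      "drop"
    }
    if (action == "drop") {
      dropped[[length(dropped) + 1L]] <- c(e$snp_id, "allele_mismatch")
      next
    }
    beta_out <- if (action == "flip") -o$beta else o$beta
    eaf_out <- if (action == "flip") {
      if (is.na(o$eaf)) NA_real_ else 1 - o$eaf
    } else o$eaf
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = e$snp_id, effect_allele = e$effect_allele,
      other_allele = e$other_allele,
      beta_exp = e$beta, se_exp = e$se,
      beta_out = beta_out, se_out = o$se,
      eaf_exp = e$eaf, eaf_out = eaf_out,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no usable instruments: every SNP was dropped during harmonization",
         call. = FALSE)
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  dropped <- if (length(dropped) > 0L) {
    d <- do.call(rbind, dropped)
    data.frame(snp_id = d[, 1L], reason = d[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(exposure_name = exp_name,
                 outcome_name = outcome$trait_name,
                 rows = rows, dropped = dropped),
            class = "harmonized_set")
}

#' Construct a harmonized set directly from aligned vectors
#'
#' Convenience constructor for already-aligned effect estimates (used by
#' the estimators' tests and by callers with pre-harmonized data).
#'
#' @param beta_exp,se_exp SNP-exposure effects and standard errors.
#' @param beta_out,se_out SNP-outcome effects and standard errors, coded on
#'   the same effect allele as the exposure.
#' @param snp_id optional SNP identifiers.
#' @param exposure_name,outcome_name trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = sprintf("snp_%d", seq_along(beta_exp)),
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  stopifnot(length(beta_exp) == length(se_exp),
            length(beta_exp) == length(beta_out),
            length(beta_exp) == length(se_out),
            all(se_exp > 0), all(se_out > 0))
  rows <- data.frame(snp_id = snp_id, effect_allele = NA_character_,
                     other_allele = NA_character_,
                     beta_exp = as.numeric(beta_exp),
                     se_exp = as.numeric(se_exp),
                     beta_out = as.numeric(beta_out),
                     se_out = as.numeric(se_out),
                     eaf_exp = NA_real_, eaf_out = NA_real_,
                     stringsAsFactors = FALSE)
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 rows = rows,
                 dropped = data.frame(snp_id = character(0),
                                      reason = character(0))),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d SNP(s), %d dropped\n",
              x$exposure_name, x$outcome_name, nrow(x$rows),
              nrow(x$dropped)))
  invisible(x)
}

#' Write a harmonized set (and its dropped-SNP companion) to TSV
#' @param hset a `harmonized_set`.
#' @param rows_path path for the harmonized rows.
#' @param dropped_path optional path for the dropped-SNP table.
#' @return `rows_path`, invisibly.
#' @export
write_harmonized_set <- function(hset, rows_path, dropped_path = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  data.table::fwrite(hset$rows, rows_path, sep = "\t", quote = FALSE)
  if (!is.null(dropped_path)) {
    data.table::fwrite(hset$dropped, dropped_path, sep = "\t", quote = FALSE)
  }
  invisible(rows_path)
}
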