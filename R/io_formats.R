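#' @importFrom stats approx coef cor cov lm median pchisq pnorm prcomp pt
#'   qnorm qt rbinom rnorm runif sd setNames var complete.cases
#' @importFrom utils modifyList head
NULL

# Canonical column order for summary-statistics TSVs.
.SUMMARY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
.REQUIRED_COLS <- c("snp_id", "effect_allele", "other_allele", "eaf",
                    "beta", "se", "pval", "n")
.TRAIT_KINDS <- c("binary_exposure", "continuous_exposure", "metabolite")
.ALLELES <- c("A", "C", "G", "T")

#' Construct a summary dataset of GWAS associations
#'
#' A `summary_dataset` holds one trait's per-SNP association records
#' (effect/other allele, effect-allele frequency, beta, SE, p-value, sample
#' size) in a validated data frame. Betas for metabolite traits are in SD
#' units of the log-transformed concentration per effect allele.
#'
#' @param records data frame with at least the canonical columns
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n` (optionally `chrom`, `pos`).
#' @param trait_name character scalar naming the trait.
#' @param trait_kind one of `"binary_exposure"`, `"continuous_exposure"`,
#'   `"metabolite"`.
#' @param allow_missing_eaf permit `NA` effect-allele frequencies. Only
#'   sensible when palindromic SNPs are excluded outright (the pipeline's
#'   default), since eaf is then never needed for strand inference.
#' @return An object of class `summary_dataset`: a list with elements
#'   `trait_name`, `trait_kind`, and `records` (a data frame keyed uniquely
#'   by `snp_id`, original row order preserved).
#' @export
summary_dataset <- function(records, trait_name, trait_kind,
                            allow_missing_eaf = TRUE) {
  trait_kind <- match.arg(trait_kind, .TRAIT_KINDS)
  stopifnot(is.character(trait_name), length(trait_name) == 1L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(.REQUIRED_COLS, names(records))
  if (length(missing) > 0L) {
    stop("summary dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  records$snp_id <- as.character(records$snp_id)
  for (col in c("eaf", "beta", "se", "pval")) records[[col]] <- as.numeric(records[[col]])
  records$n <- as.integer(records$n)
  if (!"chrom" %in% names(records)) records$chrom <- NA_character_
  if (!"pos" %in% names(records)) records$pos <- NA_integer_
  records <- records[, .SUMMARY_COLS]

  bad <- .validate_gwas_rows(records, allow_missing_eaf)
  if (length(bad) > 0L) {
    stop("invalid GWAS record(s):\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup) > 0L) {
    stop("duplicate snp_id in dataset: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(trait_name = trait_name, trait_kind = trait_kind,
                 records = records),
            class = "summary_dataset")
}

# Per-row invariant checks; returns character vector of messages labelled by
# data row number (1-based, excluding the header).
.validate_gwas_rows <- function(rec, allow_missing_eaf) {
  msgs <- character(0)
  add <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      msgs <<- c(msgs, sprintf("row %d: %s", which(rows), what))
    }
    invisible(NULL)
  }
  add(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  add(!rec$effect_allele %in% .ALLELES, "effect_allele not one of A/C/G/T")
  add(!rec$other_allele %in% .ALLELES, "other_allele not one of A/C/G/T")
  add(rec$effect_allele == rec$other_allele, "effect_allele equals other_allele")
  if (allow_missing_eaf) {
    add(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1), "eaf outside (0,1)")
  } else {
    add(is.na(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1, "eaf outside (0,1)")
  }
  add(is.na(rec$beta), "missing beta")
  add(is.na(rec$se) | rec$se <= 0, "se not positive")
  add(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1, "pval outside (0,1]")
  add(is.na(rec$n) | rec$n <= 0L, "n not positive")
  add(!is.na(rec$pos) & rec$pos < 0L, "negative position")
  msgs
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> trait '%s' (%s), %d SNP record(s)\n",
              x$trait_name, x$trait_kind, nrow(x$records)))
  print(head(x$records, 6L))
  if (nrow(x$records) > 6L) cat("...\n")
  invisible(x)
}

#' Number of SNP records in a summary dataset
#' @param ds a `summary_dataset`.
#' @return integer count.
#' @export
n_records <- function(ds) {
  stopifnot(inherits(ds, "summary_dataset"))
  nrow(ds$records)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a header with at least the canonical columns `snp_id`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#' (UTF-8, '.' decimal separator, scientific notation accepted). Foreign
#' headers can be renamed on the fly via `col_map`. Alleles are upper-cased;
#' positions are 1-based. Rows violating the record invariants abort the
#' read with their line numbers.
#'
#' @param path file path to a TSV.
#' @param trait_kind trait class of the file, see [summary_dataset()].
#' @param trait_name trait label; defaults to the file name without
#'   extension.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(snp_id = "rsid", pval = "P")`.
#' @param allow_missing_eaf see [summary_dataset()].
#' @return a validated `summary_dataset`, file row order preserved.
#' @export
read_summary_stats <- function(path, trait_kind,
                               trait_name = sub("\\.[^.]*$", "", basename(path)),
                               col_map = NULL, allow_missing_eaf = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      foreign <- col_map[[canon]]
      if (!foreign %in% names(dt)) {
        stop("column mapping names absent column '", foreign, "'", call. = FALSE)
      }
      names(dt)[names(dt) == foreign] <- canon
    }
  }
  missing <- setdiff(.REQUIRED_COLS, names(dt))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tryCatch(
    summary_dataset(dt, trait_name = trait_name, trait_kind = trait_kind,
                    allow_missing_eaf = allow_missing_eaf),
    error = function(e) {
      stop("while reading ", path, " (row numbers exclude the header): ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Numeric fields are written with full `%.17g` precision so a
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param ds a `summary_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  rec <- ds$records
  out <- data.frame(
    snp_id = rec$snp_id, chrom = rec$chrom, pos = rec$pos,
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    eaf = sprintf("%.17g", rec$eaf), beta = sprintf("%.17g", rec$beta),
    se = sprintf("%.17g", rec$se), pval = sprintf("%.17g", rec$pval),
    n = rec$n, stringsAsFactors = FALSE)
  out$eaf[is.na(rec$eaf)] <- NA_character_
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a linkage-disequilibrium r-squared matrix
#'
#' @param r2 square numeric matrix of pairwise r-squared values.
#' @param snp_ids SNP identifiers; defaults to `rownames(r2)`.
#' @param tol tolerance for symmetry violations.
#' @return an object of class `ld_matrix`: the validated symmetric matrix
#'   with `snp_ids` as dimnames, unit diagonal, entries in \[0, 1\].
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2), tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(snp_ids) || length(snp_ids) != nrow(r2)) {
    stop("LD matrix needs one SNP id per row", call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in LD matrix", call. = FALSE)
  bad <- which(is.na(r2) | r2 < 0 | r2 > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("LD entry outside [0,1] at (%s, %s)",
                 snp_ids[bad[1L, 1L]], snp_ids[bad[1L, 2L]]), call. = FALSE)
  }
  asym <- abs(r2 - t(r2))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf("LD matrix asymmetric beyond tolerance at (%s, %s)",
                 snp_ids[ij[1L]], snp_ids[ij[2L]]), call. = FALSE)
  }
  if (max(abs(diag(r2) - 1)) > tol) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  class(r2) <- c("ld_matrix", "matrix")
  r2
}

#' Read an LD r-squared matrix from a tab-separated file
#'
#' The file carries SNP ids as both the first row and the first column;
#' row and column labels must match.
#'
#' @param path file path.
#' @param tol symmetry tolerance, see [ld_matrix()].
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop("LD matrix row labels do not match column labels", call. = FALSE)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ld_matrix(m, ids, tol = tol)
}

#' Write an LD r-squared matrix to a tab-separated file
#' @param ld an `ld_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  ids <- rownames(ld)
  body <- apply(unclass(ld), 2L, function(x) sprintf("%.17g", x))
  out <- data.frame(snp_id = ids, body, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("snp_id", ids)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
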