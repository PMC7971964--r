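#' Bonferroni threshold over effective independent tests
#'
#' Divides the nominal two-sided level by the effective number of
#' independent tests. With the conventional 17 effective metabolomic
#' dimensions (the number of principal components explaining 95% of
#' variance in this class of NMR panel), 0.05 becomes 0.0029.
#'
#' @param alpha nominal two-sided level in (0,1).
#' @param effective_tests effective number of independent tests (>= 1).
#' @return `alpha / effective_tests`.
#' @export
corrected_threshold <- function(alpha = 0.05, effective_tests = 17L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0,1)", call. = FALSE)
  }
  if (effective_tests < 1L) stop("effective_tests must be >= 1", call. = FALSE)
  alpha / effective_tests
}

#' Effective number of tests from a metabolite panel
#'
#' The smallest number of principal components of the panel's correlation
#' matrix whose cumulative explained-variance fraction reaches the target.
#' Useful for synthetic panels; for the real NMR panel the literature
#' value (17 components for 95%) is used directly via
#' [corrected_threshold()].
#'
#' @param panel numeric matrix or data frame, rows = samples, columns =
#'   metabolites (at least 2 columns and at least as many rows as
#'   columns).
#' @param variance_target cumulative variance fraction to reach.
#' @return integer number of components.
#' @export
effective_tests_from_panel <- function(panel, variance_target = 0.95) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 2L) stop("panel needs at least 2 metabolites", call. = FALSE)
  if (nrow(panel) < ncol(panel)) {
    stop("panel needs at least as many rows as metabolites", call. = FALSE)
  }
  sds <- apply(panel, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance metabolite column(s): ",
         paste(colnames(panel)[sds == 0], collapse = ", "), call. = FALSE)
  }
  ev <- eigen(cor(panel), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumfrac <- cumsum(ev) / sum(ev)
  as.integer(which(cumfrac >= variance_target)[1L])
}

#' Classify cross-method consistency for one metabolite
#'
#' Applies the selection-then-replication rule: an association is selected
#' when either arm (observational AMV or genetic MR) passes the corrected
#' threshold; the verdict is `"consistent"` when the other arm's point
#' estimate has the same sign and its p-value is below `replication_alpha`
#' (a hypothesized effect in one design, replicated in the other). A zero
#' point estimate in either arm never counts as sign agreement. When both
#' arms pass the corrected threshold, the rule is applied symmetrically;
#' opposite signs then yield `"not_consistent"`.
#'
#' @param metabolite metabolite label.
#' @param amv_theta,amv_se,amv_pval pooled AMV estimate, SE, p-value.
#' @param mr_theta,mr_se,mr_pval pooled (IVW) MR estimate, SE, p-value.
#' @param threshold corrected selection threshold, see
#'   [corrected_threshold()].
#' @param replication_alpha p-value bar for the non-selecting arm.
#' @return a one-row data frame (a triangulation row): the inputs plus
#'   `amv_passes`, `mr_passes`, and
#'   `verdict` in `consistent`/`not_consistent`/`not_selected`.
#' @export
classify_consistency <- function(metabolite, amv_theta, amv_se, amv_pval,
                                 mr_theta, mr_se, mr_pval,
                                 threshold, replication_alpha = 0.05) {
  stopifnot(is.finite(amv_theta), is.finite(mr_theta),
            is.finite(amv_pval), is.finite(mr_pval))
  amv_passes <- amv_pval < threshold
  mr_passes <- mr_pval < threshold
  same_sign <- sign(amv_theta) == sign(mr_theta) &&
    amv_theta != 0 && mr_theta != 0
  verdict <- if (!amv_passes && !mr_passes) {
    "not_selected"
  } else if (amv_passes && mr_passes) {
    if (same_sign) "consistent" else "not_consistent"
  } else if (amv_passes) {
    if (same_sign && mr_pval < replication_alpha) "consistent"
    else "not_consistent"
  } else {
    if (same_sign && amv_pval < replication_alpha) "consistent"
    else "not_consistent"
  }
  data.frame(metabolite = metabolite,
             amv_theta = amv_theta, amv_se = amv_se, amv_pval = amv_pval,
             mr_theta = mr_theta, mr_se = mr_se, mr_pval = mr_pval,
             amv_passes = amv_passes, mr_passes = mr_passes,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Triangulate AMV and MR results across a metabolite panel
#'
#' Joins the pooled observational and genetic estimates by metabolite and
#' classifies every row with [classify_consistency()].
#'
#' @param amv data frame with columns `metabolite`, `theta_fixed`,
#'   `se_fixed`, `pval_fixed` (as from [run_amv()]).
#' @param mr data frame with columns `metabolite`, `theta`, `se`, `pval`
#'   (pooled IVW estimates, one row per metabolite).
#' @param threshold corrected selection threshold.
#' @param replication_alpha see [classify_consistency()].
#' @return data frame of triangulation rows, one per metabolite.
#' @export
triangulate <- function(amv, mr, threshold = corrected_threshold(),
                        replication_alpha = 0.05) {
  stopifnot(all(c("metabolite", "theta_fixed", "se_fixed", "pval_fixed")
                %in% names(amv)),
            all(c("metabolite", "theta", "se", "pval") %in% names(mr)))
  common <- intersect(amv$metabolite, mr$metabolite)
  if (length(common) == 0L) stop("no shared metabolites", call. = FALSE)
  ai <- match(common, amv$metabolite)
  mi <- match(common, mr$metabolite)
  out <- do.call(rbind, lapply(seq_along(common), function(i) {
    classify_consistency(common[i],
                         amv$theta_fixed[ai[i]], amv$se_fixed[ai[i]],
                         amv$pval_fixed[ai[i]],
                         mr$theta[mi[i]], mr$se[mi[i]], mr$pval[mi[i]],
                         threshold = threshold,
                         replication_alpha = replication_alpha)
  }))
  rownames(out) <- NULL
  out
}

#' Concordance between MR and AMV estimates across metabolites
#'
#' Ordinary least squares of the MR estimates (response) on the AMV
#' estimates (regressor) with intercept, summarizing agreement between the
#' two designs; a slope of 1 with intercept 0 is perfect concordance, and
#' R-squared measures goodness of fit across the panel.
#'
#' @param amv_thetas,mr_thetas equal-length numeric vectors (length >= 3).
#' @return list with `slope`, `intercept`, `r2`.
#' @export
concordance <- function(amv_thetas, mr_thetas) {
  stopifnot(length(amv_thetas) == length(mr_thetas))
  if (length(amv_thetas) < 3L) {
    stop("concordance needs at least 3 paired estimates", call. = FALSE)
  }
  if (var(amv_thetas) == 0) {
    stop("AMV estimates have zero variance; slope undefined", call. = FALSE)
  }
  slope <- cov(amv_thetas, mr_thetas) / var(amv_thetas)
  intercept <- mean(mr_thetas) - slope * mean(amv_thetas)
  r2 <- if (var(mr_thetas) == 0) 1 else cor(amv_thetas, mr_thetas)^2
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Write triangulation tables and concordance scatter plots
#'
#' Emits the full triangulation TSV, a selected-associations TSV (rows
#' passing the corrected threshold in either arm, with all four methods'
#' estimates where supplied), and one concordance scatter per exposure:
#' MR on the vertical axis, AMV on the horizontal, per-point 95% CI bars,
#' the identity line of perfect concordance, the fitted line, and the
#' R-squared annotation.
#'
#' @param rows triangulation rows from [triangulate()], optionally with a
#'   `exposure` column (one scatter per exposure).
#' @param summary a [concordance()] result for annotation (computed per
#'   exposure when absent).
#' @param outdir output directory (created if needed; must be writable).
#' @param sensitivity optional data frame of per-metabolite sensitivity
#'   estimates (e.g. Egger, weighted median) merged into the selected
#'   table by `metabolite`.
#' @return named character vector of files written, invisibly.
#' @export
render_outputs <- function(rows, summary = NULL, outdir = ".",
                           sensitivity = NULL) {
  if (nrow(rows) == 0L) stop("no triangulation rows to render", call. = FALSE)
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  if (file.access(outdir, mode = 2L) != 0L) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  if (!"exposure" %in% names(rows)) rows$exposure <- "exposure"
  files <- c(triangulation = file.path(outdir, "triangulation.tsv"),
             selected = file.path(outdir, "selected_associations.tsv"))
  data.table::fwrite(rows, files[["triangulation"]], sep = "\t", quote = FALSE)
  sel <- rows[rows$amv_passes | rows$mr_passes, , drop = FALSE]
  if (!is.null(sensitivity) && nrow(sel) > 0L) {
    sel <- merge(sel, sensitivity, by = intersect(
      c("exposure", "metabolite"), names(sensitivity)), all.x = TRUE,
      sort = FALSE)
  }
  data.table::fwrite(sel, files[["selected"]], sep = "\t", quote = FALSE)

  for (expo in unique(rows$exposure)) {
    sub <- rows[rows$exposure == expo, , drop = FALSE]
    conc <- if (!is.null(summary) && length(unique(rows$exposure)) == 1L) {
      summary
    } else if (nrow(sub) >= 3L && var(sub$amv_theta) > 0) {
      concordance(sub$amv_theta, sub$mr_theta)
    } else NULL
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = amv_theta, y = mr_theta)) +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = mr_theta - .Z95 * mr_se, ymax = mr_theta + .Z95 * mr_se),
        linewidth = 0.2, colour = "grey60") +
      ggplot2::geom_errorbarh(ggplot2::aes(
        xmin = amv_theta - .Z95 * amv_se, xmax = amv_theta + .Z95 * amv_se),
        linewidth = 0.2, colour = "grey60") +
      ggplot2::geom_point(size = 1.2) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      ggplot2::labs(
        x = "AMV estimate (SD per exposure unit)",
        y = "MR (IVW) estimate (SD per exposure unit)",
        title = sprintf("Concordance: %s", expo)) +
      ggplot2::theme_minimal()
    if (!is.null(conc)) {
      p <- p + ggplot2::geom_abline(slope = conc$slope,
                                    intercept = conc$intercept,
                                    colour = "red", linetype = "dashed") +
        ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1,
                          vjust = 1.5,
                          label = sprintf("R² = %.2f", conc$r2))
    }
    plot_file <- file.path(outdir, sprintf("concordance_%s.png", expo))
    ggplot2::ggsave(plot_file, p, width = 5, height = 5, dpi = 150)
    files[paste0("plot_", expo)] <- plot_file
  }
  invisible(files)
}
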