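# The central fitting surface: one call running the whole analysis and
# returning a classed object with the usual accessor methods.

#' Fit the cis/trans regulatory divergence analysis to a cross
#'
#' End-to-end analysis of replicated SNP-site allele counts for a parental
#' pair and their F1 hybrid: dual-mapping merge (if present), SNP quality
#' filters, aggregation to genes, TMM normalization with replicate QC,
#' hybrid-versus-parent differential expression with inheritance
#' classification, per-gene cis/trans decomposition with the three exact
#' tests and regulatory categories, and the cross-level summary.
#'
#' @param sites SNP-site count table (data frame as from
#'   [simulate_cross()]/[read_snp_counts()], or a TSV path).
#' @param label cross label used in printing.
#' @param female which parent is the female (`"parent1"` or `"parent2"`).
#' @param min_minor,min_total SNP-site filter thresholds (defaults 2, 20).
#' @param fc minimum linear fold change for DEG calls (default 1.25).
#' @param fdr FDR threshold for all test families (default 0.05).
#' @param pseudocount log-ratio pseudocount (default 0.5).
#' @param qc_threshold minimum median within-class replicate R-squared.
#' @param drop_failed_qc exclude libraries that fall outside a coherent
#'   within-class core (at least two classmates whose pairwise R-squared
#'   reaches `qc_threshold`) and refit normalization without them.
#' @param dispersion common NB dispersion for the DE test; estimated when
#'   `NULL`.
#' @param bin_edges fold-change bin edges for the percent-cis profile.
#' @return object of class `cistrans_fit`; see [summary.cistrans_fit()],
#'   [coef.cistrans_fit()], [plot.cistrans_fit()].
#' @examples
#' fit <- cistrans_fit(simulate_cross(sim_config(300, seed = 1))$sites)
#' fit
#' coef(fit)[1:3, ]
#' @export
cistrans_fit <- function(sites, label = "cross", female = "parent1",
                         min_minor = 2, min_total = 20,
                         fc = 1.25, fdr = 0.05, pseudocount = 0.5,
                         qc_threshold = 0.90, drop_failed_qc = TRUE,
                         dispersion = NULL, bin_edges = c(1.25, 2, 4)) {
  if (is.character(sites)) sites <- read_snp_counts(sites)
  validate_snp_counts(sites)
  all_genes <- unique(sites$gene_id)
  merged <- merge_dual_mappings(sites)
  flt <- filter_snp_sites(merged, min_minor = min_minor,
                          min_total = min_total)
  if (!nrow(flt$retained)) stop("no SNP sites pass the quality filters")
  gene_tab <- aggregate_to_genes(flt$retained, all_genes = all_genes)

  totals <- gene_totals_matrix(gene_tab)
  factors <- tmm_factors(totals)
  qc <- replicate_qc(cpm_normalize(totals, factors),
                     threshold = qc_threshold)
  dropped_libs <- character(0)
  if (drop_failed_qc && any(!qc$pass)) {
    # a library is excluded only when its class retains a coherent core:
    # at least two classmates whose pairwise R-squared reaches the
    # threshold. A class that is incoherent wholesale gives QC no outlier
    # to point at, so nothing is dropped there.
    r2 <- attr(qc, "r2")
    droppable <- character(0)
    not_droppable <- character(0)
    for (cl in unique(qc$class)) {
      members <- qc$library[qc$class == cl]
      fails <- qc$library[qc$class == cl & !qc$pass]
      if (!length(fails)) next
      sub <- r2[members, members, drop = FALSE]
      diag(sub) <- NA
      coherent <- members[apply(sub >= qc_threshold, 1, any, na.rm = TRUE)]
      out <- setdiff(members, coherent)
      if (length(coherent) >= 2 && length(out)) {
        droppable <- c(droppable, out)
      }
      # failures inside the coherent core are collateral damage from the
      # outlier's presence in their median, not outliers themselves
      not_droppable <- c(not_droppable, setdiff(fails, c(out, coherent)))
    }
    if (length(not_droppable)) {
      message("replicate QC flagged but not dropped (no coherent ",
              "within-class core to compare against): ",
              paste(not_droppable, collapse = ", "))
    }
    if (length(droppable)) {
      info <- parse_count_columns(count_columns(gene_tab))
      info$lib <- lib_id(info$class, info$rep)
      gene_tab <- gene_tab[, !(names(gene_tab) %in%
                                 info$column[info$lib %in% droppable])]
      totals <- gene_totals_matrix(gene_tab)
      factors <- tmm_factors(totals)
      dropped_libs <- droppable
    }
  }

  contrasts <- de_contrasts(gene_tab, factors, fc = fc, fdr = fdr,
                            dispersion = dispersion)
  inh <- classify_inheritance(contrasts, female = female)
  reg <- regulatory_calls(gene_tab, factors, fdr = fdr,
                          pseudocount = pseudocount)
  # the summary compares call sets on the shared analyzed gene universe
  inh_shared <- inh[inh$gene_id %in% reg$gene_id, , drop = FALSE]
  summ <- cross_summary(reg, inh_shared, label = label,
                        bin_edges = bin_edges)
  structure(list(
    label = label,
    sites = merged,
    rejected_sites = flt$rejected,
    gene_table = gene_tab,
    factors = factors,
    qc = qc,
    dropped_libraries = dropped_libs,
    dispersion = attr(contrasts, "dispersion"),
    contrasts = contrasts,
    inheritance = inh,
    regulatory = reg,
    summary = summ,
    params = list(female = female, min_minor = min_minor,
                  min_total = min_total, fc = fc, fdr = fdr,
                  pseudocount = pseudocount, qc_threshold = qc_threshold,
                  bin_edges = bin_edges)
  ), class = "cistrans_fit")
}

#' @export
print.cistrans_fit <- function(x, ...) {
  cat("cis/trans regulatory divergence fit:", x$label, "\n")
  cat(sprintf("  %d SNP sites retained (%d rejected), %d genes analyzed\n",
              nrow(x$sites) - nrow(x$rejected_sites),
              nrow(x$rejected_sites), nrow(x$regulatory)))
  if (length(x$dropped_libraries)) {
    cat("  libraries dropped by replicate QC:",
        paste(x$dropped_libraries, collapse = ", "), "\n")
  }
  cat(sprintf("  DE dispersion: %.4g; thresholds: fold >= %.2f, FDR < %.2f\n",
              x$dispersion, x$params$fc, x$params$fdr))
  cat("  regulatory categories:\n")
  print(x$summary$category_counts)
  invisible(x)
}

#' Summarize a fitted cross
#'
#' @param object a `cistrans_fit`.
#' @param ... unused.
#' @return the [cross_summary()] of the fit.
#' @export
summary.cistrans_fit <- function(object, ...) object$summary

#' Per-gene cis/trans estimates
#'
#' @param object a `cistrans_fit`.
#' @param ... unused.
#' @return numeric matrix (genes x `cis`, `trans`, `parental_div`,
#'   `pct_cis`).
#' @export
coef.cistrans_fit <- function(object, ...) {
  r <- object$regulatory
  m <- as.matrix(r[, c("cis", "trans", "parental_div", "pct_cis")])
  rownames(m) <- r$gene_id
  m
}

#' Plot allelic versus parental divergence
#'
#' The classic cis/trans scatter: parental log2 ratio on x, hybrid allelic
#' log2 ratio (cis estimate) on y, coloured by regulatory category.
#' Cis-only genes fall on the diagonal, trans-only genes on the
#' horizontal axis, compensatory genes on the vertical axis.
#'
#' @param x a `cistrans_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cistrans_fit <- function(x, ...) {
  r <- x$regulatory
  pal <- c(cis_only = "#D55E00", trans_only = "#0072B2",
           cis_plus_trans = "#009E73", cis_by_trans = "#CC79A7",
           compensatory = "#E69F00", conserved = "grey70",
           ambiguous = "grey40")
  graphics::plot(r$parental_div, r$cis, col = pal[r$category], pch = 16,
                 cex = 0.6, xlab = "parental divergence, log2(P1/P2)",
                 ylab = "hybrid allelic ratio, log2(F1A1/F1A2)",
                 main = x$label, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}
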