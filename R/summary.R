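# Comparative statistics across genes and crosses.

#' Compare magnitudes of significant cis and trans divergence
#'
#' Median `|cis|` over genes with a significant allelic test, median
#' `|trans|` over genes with a significant trans test, and a two-sided
#' Wilcoxon rank-sum test between the two sets (exact for small samples
#' without ties, tie-corrected normal approximation otherwise). Medians
#' are also reported as linear fold changes.
#'
#' @param reg output of [regulatory_calls()].
#' @return list `median_abs_cis`, `median_abs_trans` (log2),
#'   `median_fold_cis`, `median_fold_trans`, `p_value`, `n_cis`, `n_trans`.
#' @export
compare_magnitudes <- function(reg) {
  x <- abs(reg$cis[reg$sig_allelic])
  y <- abs(reg$trans[reg$sig_trans])
  if (!length(x) || !length(y)) {
    stop("need at least one significant cis and one significant trans gene")
  }
  # ties force the normal approximation; the fallback is expected
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = (length(x) <= 25 && length(y) <= 25)))
  list(median_abs_cis = stats::median(x),
       median_abs_trans = stats::median(y),
       median_fold_cis = 2^stats::median(x),
       median_fold_trans = 2^stats::median(y),
       p_value = p$p.value, n_cis = length(x), n_trans = length(y))
}

#' Kendall correlation of parental divergence with cis and trans
#'
#' Tau-b (tie-handling) correlations of `parental_div` with the cis and
#' trans components, quantifying their relative contribution to
#' between-species expression divergence.
#'
#' @param reg output of [regulatory_calls()].
#' @return data frame with rows `cis` and `trans`: `tau`, `p_value`, `n`.
#' @export
correlate_divergence <- function(reg) {
  if (nrow(reg) < 10) stop("need >= 10 genes")
  one <- function(y) {
    ct <- suppressWarnings(
      stats::cor.test(reg$parental_div, y, method = "kendall"))
    c(tau = unname(ct$estimate), p_value = ct$p.value)
  }
  res <- rbind(cis = one(reg$cis), trans = one(reg$trans))
  data.frame(component = rownames(res), tau = res[, "tau"],
             p_value = res[, "p_value"], n = nrow(reg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median percent-cis by magnitude of parental divergence
#'
#' Genes are binned on `|parental_div|` expressed as a linear fold change,
#' into half-open bins defined by `edges` (a final open bin above the last
#' edge is implied; the first bin starts at fold change 1).
#'
#' @param reg output of [regulatory_calls()].
#' @param edges increasing fold-change bin edges (default 1.25, 2, 4).
#' @return data frame `bin`, `n`, `median_pct_cis`.
#' @export
pct_cis_by_bin <- function(reg, edges = c(1.25, 2, 4)) {
  if (!nrow(reg)) stop("empty call set")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 1)) {
    stop("edges must be increasing fold changes > 1")
  }
  fold <- 2^abs(reg$parental_div)
  brk <- c(1, edges, Inf)
  bin <- cut(fold, breaks = brk, right = FALSE, include.lowest = TRUE)
  med <- tapply(reg$pct_cis, bin, stats::median, na.rm = TRUE)
  data.frame(bin = levels(bin), n = as.integer(table(bin)),
             median_pct_cis = as.numeric(med),
             stringsAsFactors = FALSE)
}

#' @noRd
.is_additive <- function(cluster) {
  cluster %in% c("additivity_f_gt_m", "additivity_f_lt_m")
}

#' Percent-cis for additively versus non-additively inherited DEGs
#'
#' Strata follow the inheritance calls on the shared gene universe:
#' additive is the two additivity subtypes, non-additive pools dominance
#' and transgressive clusters; `no_change` genes are outside both. Strata
#' medians and a two-sided Wilcoxon rank-sum p-value are reported (`NA`
#' when a stratum is empty).
#'
#' @param reg output of [regulatory_calls()].
#' @param inh output of [classify_inheritance()].
#' @return list `median_additive`, `median_non_additive`, `n_additive`,
#'   `n_non_additive`, `p_value`.
#' @export
pct_cis_by_inheritance <- function(reg, inh) {
  m <- merge(reg[, c("gene_id", "pct_cis")], inh, by = "gene_id")
  add <- m$pct_cis[.is_additive(m$cluster)]
  non <- m$pct_cis[!.is_additive(m$cluster) & m$cluster != "no_change"]
  add <- add[!is.na(add)]
  non <- non[!is.na(non)]
  p <- if (length(add) && length(non)) {
    suppressWarnings(stats::wilcox.test(
      add, non, exact = (length(add) <= 25 && length(non) <= 25))$p.value)
  } else NA_real_
  list(median_additive = if (length(add)) stats::median(add) else NA_real_,
       median_non_additive = if (length(non)) stats::median(non) else NA_real_,
       n_additive = length(add), n_non_additive = length(non),
       p_value = p)
}

#' Regulatory category by inheritance pattern contingency table
#'
#' Cross-tabulates the seven regulatory categories against the merged
#' inheritance patterns (additivity; female and male dominance with up/down
#' pooled; transgressivity = over- plus underdominance) over DEGs on the
#' shared gene universe.
#'
#' @param reg output of [regulatory_calls()].
#' @param inh output of [classify_inheritance()].
#' @return list `counts` (7 x 4 matrix) and `col_pct` (column
#'   percentages, each column summing to 100 where nonempty).
#' @export
category_by_cluster_table <- function(reg, inh) {
  m <- merge(reg[, c("gene_id", "category")], inh, by = "gene_id")
  m <- m[m$cluster != "no_change", ]
  pattern <- ifelse(.is_additive(m$cluster), "additivity",
             ifelse(grepl("^female_dominance", m$cluster), "female_dominance",
             ifelse(grepl("^male_dominance", m$cluster), "male_dominance",
                    "transgressivity")))
  counts <- table(
    factor(m$category, levels = .REG_CATEGORIES),
    factor(pattern, levels = c("additivity", "female_dominance",
                               "male_dominance", "transgressivity"))
  )
  counts <- unclass(counts)
  cs <- colSums(counts)
  col_pct <- sweep(counts, 2, ifelse(cs > 0, cs, 1), "/") * 100
  list(counts = counts, col_pct = col_pct)
}

#' Per-cross summary of a fitted analysis
#'
#' Collects the quantities compared between crosses: DEG fraction and
#' inheritance proportions, regulatory category counts, medians of
#' significant `|cis|`/`|trans|`, Kendall correlations, percent-cis by
#' divergence bin and by inheritance, and the category-by-pattern table.
#'
#' @param reg output of [regulatory_calls()].
#' @param inh output of [classify_inheritance()].
#' @param label cross label.
#' @param bin_edges passed to [pct_cis_by_bin()].
#' @return object of class `cross_summary`.
#' @export
cross_summary <- function(reg, inh, label = "cross",
                          bin_edges = c(1.25, 2, 4)) {
  inh_sum <- summarize_inheritance(inh)
  counts <- inh_sum$counts
  diverged <- reg$sig_parental | reg$sig_allelic | reg$sig_trans
  structure(list(
    label = label,
    n_genes = nrow(reg),
    n_deg = sum(counts) - counts[["no_change"]],
    deg_fraction = inh_sum$deg_fraction,
    inheritance_counts = counts,
    inheritance_proportions = inh_sum$proportions,
    n_non_additive = sum(counts[c("female_dominance_up",
                                  "female_dominance_down",
                                  "male_dominance_up", "male_dominance_down",
                                  "overdominance", "underdominance")]),
    n_transgressive = sum(counts[c("overdominance", "underdominance")]),
    category_counts = stats::setNames(
      as.integer(table(factor(reg$category, levels = .REG_CATEGORIES))),
      .REG_CATEGORIES),
    n_cis_sig = sum(reg$sig_allelic),
    n_trans_sig = sum(reg$sig_trans),
    median_pct_cis_diverged = stats::median(reg$pct_cis[diverged],
                                            na.rm = TRUE),
    pct_cis_diverged = reg$pct_cis[diverged],
    magnitudes = tryCatch(compare_magnitudes(reg), error = function(e) NULL),
    divergence_correlation = tryCatch(correlate_divergence(reg),
                                      error = function(e) NULL),
    pct_cis_bins = pct_cis_by_bin(reg, edges = bin_edges),
    pct_cis_inheritance = pct_cis_by_inheritance(reg, inh),
    category_by_cluster = category_by_cluster_table(reg, inh)
  ), class = "cross_summary")
}

#' @export
print.cross_summary <- function(x, ...) {
  cat("Cross summary:", x$label, "\n")
  cat(sprintf("  genes analyzed: %d; DEGs: %d (%.1f%%)\n",
              x$n_genes, x$n_deg, 100 * x$deg_fraction))
  cat(sprintf("  cis-significant: %d (%.2f%%); trans-significant: %d (%.2f%%)\n",
              x$n_cis_sig, 100 * x$n_cis_sig / x$n_genes,
              x$n_trans_sig, 100 * x$n_trans_sig / x$n_genes))
  cat("  regulatory categories:\n")
  print(x$category_counts)
  cat("  inheritance clusters:\n")
  print(x$inheritance_counts)
  if (!is.null(x$magnitudes)) {
    cat(sprintf(
      "  median |cis| %.2f-fold vs |trans| %.2f-fold (Wilcoxon p = %.3g)\n",
      x$magnitudes$median_fold_cis, x$magnitudes$median_fold_trans,
      x$magnitudes$p_value))
  }
  cat(sprintf("  median %%cis among diverged genes: %.1f\n",
              x$median_pct_cis_diverged))
  invisible(x)
}

#' @noRd
.fisher_2x2 <- function(in_a, n_a, in_b, n_b) {
  fisher_test_p(in_a, n_a - in_a, in_b, n_b - in_b)
}

#' Compare two crosses
#'
#' Fisher exact tests on proportion differences between two cross
#' summaries: non-additive among DEGs, transgressive among DEGs,
#' cis-significant among analyzed genes, and `cis_only` among analyzed
#' genes; plus a Wilcoxon rank-sum comparison of percent-cis among
#' diverged genes.
#'
#' @param a,b `cross_summary` objects.
#' @return data frame with one row per comparison: the two proportions and
#'   the p-value.
#' @export
compare_crosses <- function(a, b) {
  stopifnot(inherits(a, "cross_summary"), inherits(b, "cross_summary"))
  rows <- list(
    c("non_additive_among_degs", a$n_non_additive, a$n_deg,
      b$n_non_additive, b$n_deg),
    c("transgressive_among_degs", a$n_transgressive, a$n_deg,
      b$n_transgressive, b$n_deg),
    c("cis_significant_among_genes", a$n_cis_sig, a$n_genes,
      b$n_cis_sig, b$n_genes),
    c("cis_only_among_genes", a$category_counts[["cis_only"]], a$n_genes,
      b$category_counts[["cis_only"]], b$n_genes)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    k <- as.numeric(r[-1])
    data.frame(comparison = r[1],
               prop_a = k[1] / k[2], prop_b = k[3] / k[4],
               p_value = .fisher_2x2(k[1], k[2], k[3], k[4]),
               stringsAsFactors = FALSE)
  }))
  xa <- a$pct_cis_diverged[!is.na(a$pct_cis_diverged)]
  xb <- b$pct_cis_diverged[!is.na(b$pct_cis_diverged)]
  pw <- if (length(xa) && length(xb)) {
    tryCatch(stats::wilcox.test(xa, xb, exact = FALSE)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  rbind(out, data.frame(comparison = "median_pct_cis_diverged",
                        prop_a = a$median_pct_cis_diverged / 100,
                        prop_b = b$median_pct_cis_diverged / 100,
                        p_value = pw, stringsAsFactors = FALSE))
}
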