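# Cis/trans decomposition, the three exact tests with FDR control, and the
# seven regulatory categories.

.REG_CATEGORIES <- c("cis_only", "trans_only", "cis_plus_trans",
                     "cis_by_trans", "compensatory", "conserved", "ambiguous")

#' Pooled pseudo-counts for the regulatory tests
#'
#' For each gene, the mean across replicates of normalized counts rescaled
#' to the mean effective library size, rounded half-to-even to an integer
#' pseudo-count: parental quantities (P1, P2) from the parental libraries,
#' allelic quantities (F1A1, F1A2) from the hybrid libraries. Genes with
#' all four quantities zero are excluded (ids in attribute `excluded`).
#'
#' @param gene_tab output of [aggregate_to_genes()].
#' @param factors output of [tmm_factors()] on [gene_totals_matrix()].
#' @return data frame `gene_id`, `P1`, `P2`, `F1A1`, `F1A2`.
#' @export
allelic_inputs <- function(gene_tab, factors) {
  cc <- count_columns(gene_tab)
  info <- parse_count_columns(cc)
  if (any(info$mapping != "")) stop("merge dual mappings first")
  info$lib <- lib_id(info$class, info$rep)
  eff <- stats::setNames(factors$eff_size, factors$library)
  if (!all(info$lib %in% names(eff))) {
    stop("normalization factors missing for some libraries")
  }
  target <- mean(eff)
  pooled <- function(class, allele) {
    cols <- info$column[info$class == class & info$allele == allele]
    m <- vapply(cols, function(col) {
      gene_tab[[col]] / eff[[info$lib[info$column == col]]] * target
    }, numeric(nrow(gene_tab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gene_tab))
    round(rowMeans(m))
  }
  out <- data.frame(
    gene_id = gene_tab$gene_id,
    P1 = pooled("parent1", "a1"),
    P2 = pooled("parent2", "a2"),
    F1A1 = pooled("F1", "a1"),
    F1A2 = pooled("F1", "a2"),
    stringsAsFactors = FALSE
  )
  zero <- out$P1 + out$P2 + out$F1A1 + out$F1A2 == 0
  excluded <- out$gene_id[zero]
  out <- out[!zero, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Cis/trans decomposition of expression divergence
#'
#' Parental divergence is `log2((P1 + pc) / (P2 + pc))`; the cis component
#' is the hybrid allelic log ratio `log2((F1A1 + pc) / (F1A2 + pc))` (both
#' alleles share the hybrid's trans environment, so allelic imbalance reads
#' out cis divergence); the trans component is their difference. The
#' identity `cis + trans = parental_div` holds exactly.
#'
#' @param P1,P2,F1A1,F1A2 nonnegative pooled counts (vectors).
#' @param pseudocount added inside the log ratios only (default 0.5),
#'   guarding zeros without touching any test statistic.
#' @return data frame `cis`, `trans`, `parental_div` (log2 units).
#' @examples
#' cis_trans_decompose(400, 100, 300, 100, pseudocount = 0)
#' @export
cis_trans_decompose <- function(P1, P2, F1A1, F1A2, pseudocount = 0.5) {
  if (any(c(P1, P2, F1A1, F1A2) < 0)) stop("counts must be nonnegative")
  parental_div <- log2((P1 + pseudocount) / (P2 + pseudocount))
  cis <- log2((F1A1 + pseudocount) / (F1A2 + pseudocount))
  data.frame(cis = cis, trans = parental_div - cis,
             parental_div = parental_div)
}

#' Percent of regulatory divergence attributable to cis
#'
#' `|cis| / (|cis| + |trans|) * 100`; undefined (NA) when both components
#' are zero.
#'
#' @param cis,trans log2-scale components.
#' @return percentages in `[0, 100]`.
#' @export
pct_cis <- function(cis, trans) {
  tot <- abs(cis) + abs(trans)
  ifelse(tot > 0, abs(cis) / tot * 100, NA_real_)
}

#' Exact binomial test of hybrid allelic imbalance
#'
#' Null: the two parental alleles are equally expressed in the hybrid
#' (`F1A1 = F1A2`); significance indicates cis-regulatory divergence.
#'
#' @param F1A1,F1A2 integer pooled pseudo-counts.
#' @return two-sided p-values.
#' @export
binomial_allelic_test <- function(F1A1, F1A2) {
  binom_test_p(F1A1, F1A1 + F1A2)
}

#' Exact binomial test of parental expression difference
#'
#' Null: the two parents express the gene equally (`P1 = P2`).
#'
#' @param P1,P2 integer pooled pseudo-counts.
#' @return two-sided p-values.
#' @export
binomial_parental_test <- function(P1, P2) {
  binom_test_p(P1, P1 + P2)
}

#' Fisher exact test for trans-regulatory divergence
#'
#' Null: the parental expression ratio equals the hybrid allelic ratio
#' (`P1/P2 = F1A1/F1A2`) — any parental difference is fully explained by
#' cis divergence. Tests the 2x2 table `[[P1, P2], [F1A1, F1A2]]`.
#'
#' @param P1,P2,F1A1,F1A2 integer pooled pseudo-counts.
#' @return two-sided p-values.
#' @export
fisher_trans_test <- function(P1, P2, F1A1, F1A2) {
  fisher_test_p(P1, P2, F1A1, F1A2)
}

#' Assign the seven regulatory categories
#'
#' Total mapping from the three significance flags (A = parental
#' difference, B = allelic imbalance, C = trans effect) and the signs of
#' the estimates: conserved (none), cis only (A, B), trans only (A, C),
#' compensatory (B, C), cis + trans / cis x trans (all three, split by the
#' sign of `cis * trans`; an exactly-zero product is direction-undefined
#' and falls to ambiguous), and ambiguous for the remaining single-flag
#' combinations.
#'
#' @param sig_parental,sig_allelic,sig_trans logical vectors.
#' @param cis,trans log2 estimates (used only inside the all-significant
#'   cell).
#' @return character vector of categories.
#' @export
classify_regulatory <- function(sig_parental, sig_allelic, sig_trans,
                                cis, trans) {
  n <- length(sig_parental)
  out <- rep("ambiguous", n)
  A <- sig_parental; B <- sig_allelic; C <- sig_trans
  out[!A & !B & !C] <- "conserved"
  out[A & B & !C] <- "cis_only"
  out[A & !B & C] <- "trans_only"
  out[!A & B & C] <- "compensatory"
  abc <- A & B & C
  out[abc & cis * trans > 0] <- "cis_plus_trans"
  out[abc & cis * trans < 0] <- "cis_by_trans"
  out
}

#' Per-gene regulatory divergence calls
#'
#' Runs the full regulatory analysis on a gene allele table: pooled
#' pseudo-counts, cis/trans decomposition, the three exact tests with BH
#' FDR control applied separately per test family, and category
#' assignment.
#'
#' @param gene_tab output of [aggregate_to_genes()].
#' @param factors output of [tmm_factors()].
#' @param fdr FDR threshold per family (default 0.05).
#' @param pseudocount log-ratio pseudocount (default 0.5); never enters
#'   the test counts.
#' @return data frame with one row per analyzed gene: pooled counts,
#'   `cis`, `trans`, `parental_div`, `pct_cis`, the three p-values and
#'   FDRs, significance flags and `category`. Excluded (all-zero) genes
#'   are listed in attribute `excluded`.
#' @export
regulatory_calls <- function(gene_tab, factors, fdr = 0.05,
                             pseudocount = 0.5) {
  inp <- allelic_inputs(gene_tab, factors)
  dec <- cis_trans_decompose(inp$P1, inp$P2, inp$F1A1, inp$F1A2,
                             pseudocount = pseudocount)
  p_par <- binomial_parental_test(inp$P1, inp$P2)
  p_all <- binomial_allelic_test(inp$F1A1, inp$F1A2)
  p_trn <- fisher_trans_test(inp$P1, inp$P2, inp$F1A1, inp$F1A2)
  q_par <- bh_adjust(p_par)
  q_all <- bh_adjust(p_all)
  q_trn <- bh_adjust(p_trn)
  sig_par <- q_par < fdr
  sig_all <- q_all < fdr
  sig_trn <- q_trn < fdr
  out <- data.frame(
    gene_id = inp$gene_id,
    P1 = inp$P1, P2 = inp$P2, F1A1 = inp$F1A1, F1A2 = inp$F1A2,
    cis = dec$cis, trans = dec$trans, parental_div = dec$parental_div,
    pct_cis = pct_cis(dec$cis, dec$trans),
    p_parental = p_par, p_allelic = p_all, p_trans = p_trn,
    fdr_parental = q_par, fdr_allelic = q_all, fdr_trans = q_trn,
    sig_parental = sig_par, sig_allelic = sig_all, sig_trans = sig_trn,
    category = classify_regulatory(sig_par, sig_all, sig_trn,
                                   dec$cis, dec$trans),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- attr(inp, "excluded")
  out
}
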