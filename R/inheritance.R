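# Hybrid-versus-parent differential expression and the eight
# expression-inheritance clusters.

.INHERITANCE_CLUSTERS <- c(
  "additivity_f_gt_m", "additivity_f_lt_m",
  "female_dominance_up", "female_dominance_down",
  "male_dominance_up", "male_dominance_down",
  "overdominance", "underdominance", "no_change"
)

# Per-class count matrices on a common effective-library scale, rounded to
# integers (the exact DE test needs integer counts on equal footing).
#' @noRd
scaled_class_matrices <- function(gene_tab, factors) {
  cc <- count_columns(gene_tab)
  info <- parse_count_columns(cc)
  info$lib <- lib_id(info$class, info$rep)
  if (!all(info$lib %in% factors$library)) {
    stop("normalization factors missing for some libraries")
  }
  eff <- stats::setNames(factors$eff_size, factors$library)
  target <- mean(eff)
  mats <- list()
  for (cl in c("parent1", "parent2", "F1")) {
    sub <- info[info$class == cl, ]
    reps <- sort(unique(sub$rep))
    m <- vapply(reps, function(j) {
      cols <- sub$column[sub$rep == j]
      tot <- rowSums(gene_tab[, cols, drop = FALSE])
      round(tot / eff[lib_id(cl, j)] * target)
    }, numeric(nrow(gene_tab)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gene_tab))
    dimnames(m) <- list(gene_tab$gene_id, lib_id(cl, reps))
    mats[[cl]] <- m
  }
  mats
}

#' Method-of-moments common dispersion
#'
#' Pooled ratio estimator `max(0, sum(v - m) / sum(m^2))` over all
#' (gene, group) cells of the supplied scaled count matrices, where `m`
#' and `v` are the within-group replicate mean and variance. The ratio
#' form avoids the downward bias of per-gene moment estimates at small
#' replicate numbers.
#'
#' @param mats list of genes x replicates count matrices on a common scale.
#' @return a single nonnegative dispersion estimate.
#' @export
estimate_common_dispersion <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  num <- 0
  den <- 0
  for (m in mats) {
    if (ncol(m) < 2) next
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ok <- mu > 0
    num <- num + sum(v[ok] - mu[ok])
    den <- den + sum(mu[ok]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Differential expression contrasts for inheritance classification
#'
#' Runs the conditional negative-binomial exact test ([nb_exact_test()])
#' on effective-library-scaled counts for the three contrasts
#' `F1_vs_parent1`, `F1_vs_parent2` and `parent1_vs_parent2` (fold change
#' is first over second). BH adjustment is applied across genes within
#' each contrast; a gene is significant when FDR < `fdr` and the linear
#' fold change is at least `fc`.
#'
#' @param gene_tab output of [aggregate_to_genes()].
#' @param factors output of [tmm_factors()] on [gene_totals_matrix()].
#' @param fc minimum linear fold change (default 1.25).
#' @param fdr FDR threshold (default 0.05).
#' @param dispersion common NB dispersion; estimated by
#'   [estimate_common_dispersion()] when `NULL`.
#' @return data frame `gene_id`, `contrast`, `log2fc`, `pvalue`, `fdr`,
#'   `significant`, with the dispersion used in attribute `dispersion`.
#' @export
de_contrasts <- function(gene_tab, factors, fc = 1.25, fdr = 0.05,
                         dispersion = NULL) {
  mats <- scaled_class_matrices(gene_tab, factors)
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(mats)
  pairs <- list(
    F1_vs_parent1 = c("F1", "parent1"),
    F1_vs_parent2 = c("F1", "parent2"),
    parent1_vs_parent2 = c("parent1", "parent2")
  )
  out <- do.call(rbind, lapply(names(pairs), function(nm) {
    res <- nb_exact_test(mats[[pairs[[nm]][1]]], mats[[pairs[[nm]][2]]],
                         dispersion = dispersion)
    q <- bh_adjust(res$pvalue)
    data.frame(gene_id = gene_tab$gene_id, contrast = nm,
               log2fc = res$log2fc, pvalue = res$pvalue, fdr = q,
               significant = q < fdr & abs(res$log2fc) >= log2(fc),
               stringsAsFactors = FALSE)
  }))
  attr(out, "dispersion") <- dispersion
  out
}

#' Classify expression inheritance in the hybrid
#'
#' Maps the two hybrid-versus-parent contrasts onto the eight inheritance
#' clusters: neither significant is `no_change`; both significant with
#' opposite signs is additivity (subtype by whether the female parent
#' out-expresses the male); exactly one significant is expression-level
#' dominance toward the parent the hybrid matches, with direction from the
#' sign of the significant contrast; both significant in the same
#' direction is over-/underdominance (transgressivity).
#'
#' @param contrasts output of [de_contrasts()].
#' @param female which parent is the female (`"parent1"` or `"parent2"`).
#' @return data frame `gene_id`, `cluster`.
#' @export
classify_inheritance <- function(contrasts, female = "parent1") {
  female <- match.arg(female, c("parent1", "parent2"))
  wide <- function(nm, col) {
    sub <- contrasts[contrasts$contrast == nm, ]
    stats::setNames(sub[[col]], sub$gene_id)
  }
  genes <- unique(contrasts$gene_id)
  s1 <- wide("F1_vs_parent1", "significant")[genes]
  s2 <- wide("F1_vs_parent2", "significant")[genes]
  l1 <- wide("F1_vs_parent1", "log2fc")[genes]
  l2 <- wide("F1_vs_parent2", "log2fc")[genes]
  lp <- wide("parent1_vs_parent2", "log2fc")[genes]
  if (anyNA(s1) || anyNA(s2)) stop("contrasts incomplete for some genes")
  female_minus_male <- if (female == "parent1") lp else -lp

  cluster <- character(length(genes))
  for (i in seq_along(genes)) {
    if (!s1[i] && !s2[i]) {
      cluster[i] <- "no_change"
    } else if (s1[i] && s2[i]) {
      if (sign(l1[i]) == sign(l2[i])) {
        cluster[i] <- if (l1[i] > 0) "overdominance" else "underdominance"
      } else {
        cluster[i] <- if (female_minus_male[i] > 0) "additivity_f_gt_m"
                      else "additivity_f_lt_m"
      }
    } else {
      # one contrast NS: the hybrid matches that parent
      matched_p1 <- !s1[i]
      matched_female <- (matched_p1 && female == "parent1") ||
                        (!matched_p1 && female == "parent2")
      dir_up <- if (matched_p1) l2[i] > 0 else l1[i] > 0
      cluster[i] <- paste0(if (matched_female) "female" else "male",
                           "_dominance_", if (dir_up) "up" else "down")
    }
  }
  data.frame(gene_id = genes, cluster = cluster, stringsAsFactors = FALSE)
}

#' Summarize inheritance calls
#'
#' @param calls output of [classify_inheritance()].
#' @return list with `counts` (named vector over the nine outcomes),
#'   `deg_fraction` (DEGs / analyzed genes), and `proportions` among DEGs
#'   (`NULL` when there are no DEGs).
#' @export
summarize_inheritance <- function(calls) {
  if (!nrow(calls)) stop("empty call set")
  counts <- table(factor(calls$cluster, levels = .INHERITANCE_CLUSTERS))
  counts <- stats::setNames(as.integer(counts), names(counts))
  deg <- sum(counts) - counts[["no_change"]]
  props <- if (deg > 0) {
    k <- counts[setdiff(names(counts), "no_change")]
    k / deg
  } else NULL
  list(counts = counts,
       deg_fraction = deg / sum(counts),
       proportions = props)
}
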