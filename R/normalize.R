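# TMM normalization of per-library totals and replicate quality control.

#' Per-library gene-total matrix from a gene allele table
#'
#' Parent libraries contribute their own-allele counts; each F1 library
#' contributes the sum of its two allele counts. Column names are library
#' ids (`parent1_rep1`, ..., `F1_rep3`).
#'
#' @param gene_tab output of [aggregate_to_genes()].
#' @return integer matrix, genes x libraries, rownames = gene ids.
#' @export
gene_totals_matrix <- function(gene_tab) {
  cc <- count_columns(gene_tab)
  info <- parse_count_columns(cc)
  libs <- unique(info[, c("class", "rep")])
  libs <- libs[order(match(libs$class, c("parent1", "parent2", "F1")),
                     libs$rep), ]
  mat <- vapply(seq_len(nrow(libs)), function(i) {
    cols <- info$column[info$class == libs$class[i] & info$rep == libs$rep[i]]
    rowSums(gene_tab[, cols, drop = FALSE])
  }, numeric(nrow(gene_tab)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(gene_tab))
  dimnames(mat) <- list(gene_tab$gene_id, lib_id(libs$class, libs$rep))
  mat
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors across libraries: the
#' per-library factor is the inverse-asymptotic-variance-weighted mean of
#' gene-wise log ratios (M) against a reference library, after doubly
#' trimming the M (default 30%) and A (log abundance, default 5%)
#' distributions; factors are rescaled to geometric mean 1. The reference
#' is the library whose upper-quartile count fraction is closest to the
#' mean, unless given. Delegates to the edgeR implementation of the
#' published TMM definition.
#'
#' @param mat nonnegative integer matrix, genes x libraries.
#' @param trim_M trim fraction on log ratios.
#' @param trim_A trim fraction on log abundances.
#' @param reference reference library (column index), or `NULL` for the
#'   automatic upper-quartile rule.
#' @return data frame with one row per library: `library`, `lib_size`
#'   (column sum), `tmm_factor`, `eff_size` (`lib_size * tmm_factor`).
#' @examples
#' m <- matrix(rpois(600, 50), ncol = 3,
#'             dimnames = list(NULL, c("a", "b", "c")))
#' tmm_factors(m)
#' @export
tmm_factors <- function(mat, trim_M = 0.30, trim_A = 0.05, reference = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two libraries")
  if (any(mat < 0)) stop("counts must be nonnegative")
  lib_size <- colSums(mat)
  if (any(lib_size == 0)) {
    stop("all-zero library: ", paste(colnames(mat)[lib_size == 0],
                                     collapse = ", "))
  }
  if (nrow(mat) < 2) {
    warning("single gene: TMM factors set to 1")
    f <- rep(1, ncol(mat))
  } else {
    f <- edgeR::calcNormFactors(mat, method = "TMM",
                                refColumn = reference,
                                logratioTrim = trim_M, sumTrim = trim_A)
  }
  f <- f / exp(mean(log(f)))
  data.frame(
    library = if (is.null(colnames(mat))) paste0("lib", seq_along(f))
              else colnames(mat),
    lib_size = as.numeric(lib_size),
    tmm_factor = as.numeric(f),
    eff_size = as.numeric(lib_size * f),
    stringsAsFactors = FALSE
  )
}

#' Counts-per-million on effective library sizes
#'
#' @param mat counts, genes x libraries.
#' @param factors output of [tmm_factors()] for the same columns.
#' @return normalized matrix: `count / eff_size * 1e6`.
#' @export
cpm_normalize <- function(mat, factors) {
  mat <- as.matrix(mat)
  if (ncol(mat) != nrow(factors)) stop("dimension mismatch")
  if (!is.null(colnames(mat)) &&
      !identical(colnames(mat), factors$library)) {
    stop("library names disagree with factors")
  }
  sweep(mat, 2, factors$eff_size, "/") * 1e6
}

#' Replicate quality control by within-class correlation
#'
#' For each library, the squared Pearson correlation of `log2(x + 1)`
#' normalized values with every other replicate of the same sample class
#' is computed; a library fails when its median within-class R-squared
#' drops below `threshold`, mirroring the removal of outlying replicates
#' before downstream analysis.
#'
#' @param norm_mat normalized matrix, genes x libraries, with library-id
#'   column names (`parent1_rep1`, ...).
#' @param threshold minimum median within-class R-squared (pass is `>=`).
#' @return data frame `library`, `class`, `median_r2`, `pass`, with the
#'   full pairwise R-squared matrix in attribute `r2`.
#' @export
replicate_qc <- function(norm_mat, threshold = 0.90) {
  libs <- colnames(norm_mat)
  cls <- sub("_rep[0-9]+$", "", libs)
  lx <- log2(norm_mat + 1)
  r2 <- stats::cor(lx)^2
  med <- vapply(seq_along(libs), function(i) {
    peers <- which(cls == cls[i] & seq_along(libs) != i)
    if (!length(peers)) return(NA_real_)
    stats::median(r2[i, peers])
  }, numeric(1))
  if (anyNA(med)) {
    warning("class with a single replicate: QC skipped for ",
            paste(libs[is.na(med)], collapse = ", "))
  }
  out <- data.frame(library = libs, class = cls, median_r2 = med,
                    pass = is.na(med) | med >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "r2") <- r2
  out
}
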