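# SNP-site allele count IO: validation, dual-mapping merge, quality
# filters, and aggregation to the per-gene allele table.

#' Read a SNP-site allele count table
#'
#' TSV with columns `site_id`, `gene_id` and one nonnegative integer count
#' column per library-allele combination (`parent1_rep1_a1`,
#' `F1_rep2_a2`, ..., optionally with `_m1`/`_m2` dual-mapping suffixes for
#' F1 alleles). Parental libraries carry only their own allele; every F1
#' library carries exactly the two parental alleles — the structural form
#' of the parental-homozygosity and F1-biallelism quality filters.
#'
#' @param file path to the TSV.
#' @return validated data frame of SNP-site counts.
#' @export
read_snp_counts <- function(file) {
  x <- read_tsv(file)
  validate_snp_counts(x)
}

#' Validate a SNP-site count table's structure
#'
#' @param x data frame as produced by [read_snp_counts()] or
#'   [simulate_cross()].
#' @return `x`, invisibly, after checks.
#' @export
validate_snp_counts <- function(x) {
  if (!all(c("site_id", "gene_id") %in% names(x))) {
    stop("count table needs site_id and gene_id columns")
  }
  if (anyDuplicated(x$site_id)) stop("duplicated site_id values")
  info <- parse_count_columns(count_columns(x))
  check_counts_integral(x)
  f1 <- info[info$class == "F1", ]
  if (nrow(f1) == 0) stop("no F1 libraries in the table")
  for (j in unique(f1$rep)) {
    if (!setequal(unique(f1$allele[f1$rep == j]), c("a1", "a2"))) {
      stop("F1 replicate ", j, " must carry exactly alleles a1 and a2")
    }
  }
  invisible(x)
}

#' Merge dual pseudo-genome mappings of F1 alleles
#'
#' Each F1 allele mapped against the two parental pseudo-genomes yields two
#' counts per site; the merged count is their maximum (the rule that
#' counteracts allele-mapping bias), and a site's F1 total is the sum of
#' the two merged allele counts. Tables without `_m1`/`_m2` columns pass
#' through unchanged, so the operation is idempotent.
#'
#' @param x SNP-site count table, possibly with `_m1`/`_m2` columns.
#' @return table with one merged column per F1 library-allele.
#' @export
merge_dual_mappings <- function(x) {
  info <- parse_count_columns(count_columns(x))
  dual <- info[info$mapping != "", ]
  if (nrow(dual) == 0) return(x)
  keys <- unique(dual[, c("class", "rep", "allele")])
  for (i in seq_len(nrow(keys))) {
    base <- paste0(keys$class[i], "_rep", keys$rep[i], "_", keys$allele[i])
    m1 <- paste0(base, "_m1")
    m2 <- paste0(base, "_m2")
    if (!all(c(m1, m2) %in% names(x))) {
      stop("dual-mapping columns incomplete for ", base)
    }
    x[[base]] <- pmax(x[[m1]], x[[m2]])
    x[[m1]] <- NULL
    x[[m2]] <- NULL
  }
  x
}

#' Filter SNP sites on hybrid allele counts
#'
#' Retains a site iff the minor parental allele count in the hybrid is at
#' least `min_minor` and the site's total hybrid count is at least
#' `min_total`. By default both thresholds apply to counts pooled across F1
#' replicates (the downstream allelic tests also pool replicates);
#' `per_replicate = TRUE` requires every F1 replicate to pass instead.
#'
#' @param x merged SNP-site count table (no dual-mapping columns).
#' @param min_minor minimum hybrid minor-allele count (default 2).
#' @param min_total minimum hybrid total count per site (default 20).
#' @param per_replicate apply thresholds within each F1 replicate.
#' @return list with `retained` (filtered table) and `rejected`
#'   (data frame `site_id`, `reason`; reasons `min_minor`, `min_total`,
#'   or both semicolon-joined).
#' @examples
#' cross <- simulate_cross(sim_config(n_genes = 10, seed = 1))
#' flt <- filter_snp_sites(cross$sites)
#' nrow(flt$rejected)
#' @export
filter_snp_sites <- function(x, min_minor = 2, min_total = 20,
                             per_replicate = FALSE) {
  validate_snp_counts(x)
  info <- parse_count_columns(count_columns(x))
  if (any(info$mapping != "")) {
    stop("merge dual mappings before filtering (see merge_dual_mappings)")
  }
  f1 <- info[info$class == "F1", ]
  a1_cols <- f1$column[f1$allele == "a1"]
  a2_cols <- f1$column[f1$allele == "a2"]
  a1 <- as.matrix(x[, a1_cols, drop = FALSE])
  a2 <- as.matrix(x[, a2_cols, drop = FALSE])
  if (per_replicate) {
    minor_ok <- apply(pmin(a1, a2) >= min_minor, 1, all)
    total_ok <- apply(a1 + a2 >= min_total, 1, all)
  } else {
    s1 <- rowSums(a1)
    s2 <- rowSums(a2)
    minor_ok <- pmin(s1, s2) >= min_minor
    total_ok <- s1 + s2 >= min_total
  }
  keep <- minor_ok & total_ok
  reason <- character(sum(!keep))
  fails <- cbind(min_minor = !minor_ok[!keep], min_total = !total_ok[!keep])
  reason <- apply(fails, 1, function(r) {
    paste(colnames(fails)[r], collapse = ";")
  })
  list(
    retained = x[keep, , drop = FALSE],
    rejected = data.frame(site_id = x$site_id[!keep],
                          reason = as.character(reason),
                          stringsAsFactors = FALSE)
  )
}

#' Aggregate retained SNP sites to a per-gene allele table
#'
#' Sums counts over a gene's retained sites, per library-allele column.
#' Genes left with zero retained sites are absent from the result (their
#' ids are recorded in the `dropped_genes` attribute).
#'
#' @param x filtered, merged SNP-site count table.
#' @param all_genes optional character vector of the full gene universe,
#'   used to report dropped genes.
#' @return data frame `gene_id`, `n_sites`, then one summed count column
#'   per library-allele.
#' @export
aggregate_to_genes <- function(x, all_genes = NULL) {
  validate_snp_counts(x)
  cc <- count_columns(x)
  info <- parse_count_columns(cc)
  if (any(info$mapping != "")) stop("merge dual mappings before aggregating")
  g <- factor(x$gene_id, levels = unique(x$gene_id))
  out <- data.frame(gene_id = levels(g),
                    n_sites = as.integer(table(g)),
                    stringsAsFactors = FALSE)
  for (col in cc) {
    out[[col]] <- as.vector(rowsum(x[[col]], g, reorder = FALSE))
  }
  dropped <- if (is.null(all_genes)) character(0) else {
    setdiff(all_genes, out$gene_id)
  }
  attr(out, "dropped_genes") <- dropped
  out
}
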