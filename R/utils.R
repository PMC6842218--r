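# Internal helpers: column grammar of count tables, TSV IO, seed handling.

# Count columns are named <class>_rep<j>_<allele>[_<mapping>], e.g.
# "parent1_rep2_a1", "F1_rep1_a2_m2". Parents carry only their own allele
# (parent1 -> a1, parent2 -> a2); F1 libraries carry both alleles and,
# before merging, optionally two per-pseudo-genome mappings (m1, m2).
.count_col_re <- "^(parent1|parent2|F1)_rep([0-9]+)_(a1|a2)(?:_(m1|m2))?$"

#' @noRd
parse_count_columns <- function(cols) {
  m <- regmatches(cols, regexec(.count_col_re, cols))
  bad <- cols[vapply(m, length, 1L) == 0L]
  if (length(bad)) {
    stop("malformed count column name(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    column  = cols,
    class   = vapply(m, `[`, "", 2L),
    rep     = as.integer(vapply(m, `[`, "", 3L)),
    allele  = vapply(m, `[`, "", 4L),
    mapping = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
  own <- ifelse(out$class == "parent1", "a1",
                ifelse(out$class == "parent2", "a2", NA))
  mis <- !is.na(own) & out$allele != own
  if (any(mis)) {
    stop("parental libraries must carry only their own allele: ",
         paste(out$column[mis], collapse = ", "))
  }
  out
}

#' @noRd
count_columns <- function(x) {
  setdiff(names(x), c("site_id", "gene_id", "n_sites"))
}

#' @noRd
check_counts_integral <- function(x) {
  cc <- count_columns(x)
  for (col in cc) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      stop("column '", col, "' must contain nonnegative integer counts")
    }
  }
  invisible(x)
}

#' @noRd
lib_id <- function(class, rep) paste0(class, "_rep", rep)

#' Write a tab-separated table
#'
#' Plain TSV with a header row, no quoting, no row names — the dialect used
#' by every table this package reads or writes.
#'
#' @param x a data frame.
#' @param file output path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tab-separated table
#'
#' @param file input path.
#' @return a data frame.
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards so simulation is reproducible
# without clobbering the session.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
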