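# Shared fixtures: small constructed tables and simulation shortcuts.

# A minimal valid SNP-site table built from explicit per-site counts.
# f1 is a list of per-replicate c(a1, a2) vectors shared by all rows unless
# a matrix (sites x 2) is given per replicate.
toy_sites <- function(f1a1, f1a2, p1 = 30, p2 = 30, n_rep = 2,
                      gene_id = NULL) {
  n <- length(f1a1)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_len(n))
  x <- data.frame(site_id = paste0("s", seq_len(n)), gene_id = gene_id,
                  stringsAsFactors = FALSE)
  for (j in seq_len(n_rep)) {
    x[[paste0("parent1_rep", j, "_a1")]] <- rep_len(p1, n)
    x[[paste0("parent2_rep", j, "_a2")]] <- rep_len(p2, n)
    x[[paste0("F1_rep", j, "_a1")]] <- f1a1
    x[[paste0("F1_rep", j, "_a2")]] <- f1a2
  }
  x
}

# Neutral normalization factors for hand-built gene tables.
flat_factors <- function(libraries, eff = 1e6) {
  data.frame(library = libraries, lib_size = eff, tmm_factor = 1,
             eff_size = eff, stringsAsFactors = FALSE)
}

# Run filter -> aggregate -> TMM on a simulated cross.
prep_cross <- function(sites, min_minor = 2, min_total = 20) {
  merged <- merge_dual_mappings(sites)
  flt <- filter_snp_sites(merged, min_minor = min_minor,
                          min_total = min_total)
  gt <- aggregate_to_genes(flt$retained)
  list(gene_tab = gt, factors = tmm_factors(gene_totals_matrix(gt)))
}

# Relabel the two species in a SNP table: parent1 <-> parent2 and the two
# F1 alleles swap, i.e. the same cross written with the opposite parent
# ordering.
swap_parents <- function(sites) {
  nm <- names(sites)
  nm2 <- nm
  nm2 <- sub("^parent1_(rep[0-9]+)_a1", "PARENTX_\\1_a2", nm2)
  nm2 <- sub("^parent2_(rep[0-9]+)_a2", "parent1_\\1_a1", nm2)
  nm2 <- sub("^PARENTX_(rep[0-9]+)_a2", "parent2_\\1_a2", nm2)
  nm2 <- sub("^F1_(rep[0-9]+)_a1", "F1X_\\1_a2", nm2)
  nm2 <- sub("^F1_(rep[0-9]+)_a2", "F1_\\1_a1", nm2)
  nm2 <- sub("^F1X_", "F1_", nm2)
  names(sites) <- nm2
  sites
}

# Expected inheritance cluster from true F1-vs-parent log2 offsets
# (used only for constructed scenarios whose offsets are 0 or >= 0.5).
expected_cluster <- function(div, shift, female = "parent1") {
  l1 <- shift - div / 2   # F1 vs parent1
  l2 <- shift + div / 2   # F1 vs parent2
  s1 <- abs(l1) > 0.1
  s2 <- abs(l2) > 0.1
  fem_gt_male <- if (female == "parent1") div > 0 else div < 0
  if (!s1 && !s2) return("no_change")
  if (s1 && s2) {
    if (sign(l1) == sign(l2)) {
      return(if (l1 > 0) "overdominance" else "underdominance")
    }
    return(if (fem_gt_male) "additivity_f_gt_m" else "additivity_f_lt_m")
  }
  matched_p1 <- !s1
  matched_female <- (matched_p1 && female == "parent1") ||
                    (!matched_p1 && female == "parent2")
  dir_up <- if (matched_p1) l2 > 0 else l1 > 0
  paste0(if (matched_female) "female" else "male",
         "_dominance_", if (dir_up) "up" else "down")
}

# The documented cluster permutation under swapping which parent is female.
swap_female_cluster <- function(cl) {
  map <- c(additivity_f_gt_m = "additivity_f_lt_m",
           additivity_f_lt_m = "additivity_f_gt_m",
           female_dominance_up = "male_dominance_up",
           female_dominance_down = "male_dominance_down",
           male_dominance_up = "female_dominance_up",
           male_dominance_down = "female_dominance_down",
           overdominance = "overdominance",
           underdominance = "underdominance",
           no_change = "no_change")
  unname(map[cl])
}

# Concatenate simulated crosses (shared replicate structure), prefixing
# gene and site ids to keep them unique.
bind_crosses <- function(crosses, prefixes) {
  sites <- list()
  truth <- list()
  for (i in seq_along(crosses)) {
    s <- crosses[[i]]$sites
    t <- crosses[[i]]$truth
    s$site_id <- paste0(prefixes[i], s$site_id)
    s$gene_id <- paste0(prefixes[i], s$gene_id)
    t$gene_id <- paste0(prefixes[i], t$gene_id)
    sites[[i]] <- s
    truth[[i]] <- t
  }
  list(sites = do.call(rbind, sites), truth = do.call(rbind, truth))
}
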