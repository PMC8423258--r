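# Categorical allele key of a locus call in one profile: multi-copy loci
# contribute their sorted allele vector as one haplotype-style allele.
locus_allele_key <- function(genotype_matrix) {
  alleles <- rowSums(genotype_matrix)
  paste(sort(alleles), collapse = "/")
}

#' Per-locus diversity of unrelated samples
#'
#' Allele frequencies, allele range, mean allele size and discrimination
#' capacity `DC = 1 - sum(p_i^2)` over allele frequencies (multi-copy loci
#' contribute their sorted allele vector as a single categorical allele,
#' the way capillary kits treat indistinguishable copies). `DC` is 0 iff a
#' single allele is observed. An unbiased variant multiplies by
#' `n / (n - 1)`.
#'
#' @param profiles List of `haplotype_profile` (or genotype lists) from
#'   unrelated samples.
#' @param locus Locus name.
#' @param unbiased Apply the `n/(n-1)` small-sample correction.
#' @return A one-row `data.frame` with `locus`, `n`, `n_alleles`,
#'   `allele_min`, `allele_max`, `mean_allele`, `dc`, or `NULL` (with a
#'   warning) when no sample has a call.
#' @export
diversity <- function(profiles, locus, unbiased = FALSE) {
  genos <- lapply(profiles, function(p) {
    g <- if (inherits(p, "haplotype_profile")) profile_genotypes(p) else p
    g[[locus]]
  })
  genos <- genos[!vapply(genos, is.null, logical(1))]
  if (!length(genos)) {
    warning("locus ", locus, " has no called sample")
    return(NULL)
  }
  keys <- vapply(genos, locus_allele_key, character(1))
  p <- as.vector(table(keys)) / length(keys)
  dc <- 1 - sum(p^2)
  if (unbiased) dc <- dc * length(keys) / (length(keys) - 1)
  alleles <- unlist(lapply(genos, rowSums))
  data.frame(locus = locus, n = length(keys),
             n_alleles = length(unique(keys)),
             allele_min = min(alleles), allele_max = max(alleles),
             mean_allele = mean(alleles), dc = dc, stringsAsFactors = FALSE)
}

#' Diversity table over a panel
#'
#' @param profiles List of profiles of unrelated samples.
#' @param panel Named list of `str_locus`.
#' @param unbiased See [diversity()].
#' @return `data.frame`, one row per locus with at least one call.
#' @export
diversity_table <- function(profiles, panel, unbiased = FALSE) {
  rows <- lapply(names(panel), function(locus) {
    tryCatch(suppressWarnings(diversity(profiles, locus, unbiased)),
             error = function(e) NULL)
  })
  do.call(rbind, rows)
}

#' Haplotype uniqueness of a sample set
#'
#' Pairwise profile comparison over loci called in both members: counts
#' pairs indistinguishable across all shared loci and the distribution of
#' minimal differing-locus counts.
#'
#' @param profiles List of `haplotype_profile` or genotype lists.
#' @return A list with `n_profiles`, `n_pairs`, `n_identical_pairs`, and
#'   `distance_distribution` (table of differing-locus counts over pairs).
#' @export
haplotype_uniqueness <- function(profiles) {
  genos <- lapply(profiles, function(p) {
    if (inherits(p, "haplotype_profile")) profile_genotypes(p) else p
  })
  n <- length(genos)
  if (n < 2L) stop("need at least two profiles")
  dists <- integer()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- intersect(names(genos[[i]]), names(genos[[j]]))
      d <- sum(vapply(shared, function(locus) {
        locus_allele_key(genos[[i]][[locus]]) !=
          locus_allele_key(genos[[j]][[locus]])
      }, logical(1)))
      dists <- c(dists, d)
    }
  }
  list(n_profiles = n, n_pairs = length(dists),
       n_identical_pairs = sum(dists == 0L),
       distance_distribution = table(dists))
}

#' Haplogroup coverage of a panel against a reference tree
#'
#' Bookkeeping of which reference subhaplogroups carry at least one usable
#' panel SNP: per main haplogroup letter and overall, with the rounded
#' whole-percent coverage.
#'
#' @param snps Panel SNP `data.frame` (rows with `haplogroup == "unknown"`
#'   are ignored).
#' @param reference_tree `haplogroup_tree` listing the reference
#'   subhaplogroups.
#' @return A list with `per_main` (`data.frame` main letter, covered,
#'   total), `covered`, `total`, `percent` (integer), `uncovered` labels.
#' @export
haplogroup_coverage <- function(snps, reference_tree) {
  nodes <- reference_tree$label[reference_tree$label != "Y"]
  covered_nodes <- intersect(nodes, unique(snps$haplogroup))
  main <- substr(nodes, 1, 1)
  per_main <- do.call(rbind, lapply(sort(unique(main)), function(letter) {
    tot <- nodes[main == letter]
    data.frame(main = letter, covered = sum(tot %in% covered_nodes),
               total = length(tot), stringsAsFactors = FALSE)
  }))
  total <- length(nodes)
  covered <- length(covered_nodes)
  list(per_main = per_main, covered = covered, total = total,
       percent = as.integer(round_half_up(100 * covered / max(total, 1L))),
       uncovered = setdiff(nodes, covered_nodes))
}

#' Molecular factors influencing mutability
#'
#' Correlation of per-locus mutation rates with mean allele size (rank
#' correlation by default, Pearson by flag) and group means of the rate by
#' repeat-motif unit length and repeat type.
#'
#' @param rates `data.frame` with columns `locus` and `rate` (e.g. the
#'   `per_locus` part of [aggregate_rates()]).
#' @param sizes Named numeric vector of mean allele sizes per locus (e.g.
#'   from [diversity_table()]).
#' @param panel Named list of `str_locus` (provides unit lengths and repeat
#'   types).
#' @param method `"spearman"` or `"pearson"`.
#' @return A list with `correlation` (estimate, p_value, method, or an
#'   `undefined` flag for degenerate input), `by_unit_length` and `by_type`
#'   group-mean `data.frame`s.
#' @export
factor_summary <- function(rates, sizes, panel, method = "spearman") {
  if (nrow(rates) < 3L) stop("need rates for at least 3 loci")
  common <- intersect(rates$locus, names(sizes))
  r <- rates$rate[match(common, rates$locus)]
  s <- sizes[common]
  correlation <- if (stats::sd(r) == 0 || stats::sd(s) == 0) {
    list(undefined = TRUE)
  } else {
    ct <- suppressWarnings(stats::cor.test(r, s, method = method))
    list(undefined = FALSE, estimate = unname(ct$estimate),
         p_value = ct$p.value, method = method)
  }
  unit_len <- vapply(panel[rates$locus], function(l) {
    max(l$blocks$unit_len[l$blocks$variable])
  }, integer(1))
  type <- vapply(panel[rates$locus], `[[`, "", "repeat_type")
  by_unit <- stats::aggregate(rate ~ unit_len,
                              data.frame(rate = rates$rate,
                                         unit_len = unit_len),
                              FUN = mean)
  by_type <- stats::aggregate(rate ~ type,
                              data.frame(rate = rates$rate, type = type),
                              FUN = mean)
  list(correlation = correlation, by_unit_length = by_unit,
       by_type = by_type)
}
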