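# All permutations of 1..n (n <= 4 here, so at most 24 rows).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# Parsimony step bounds for two copy-count x block matrices.
# steps_min: least total |step| over all copy-to-copy assignments (optimal
# matching). steps_max: largest total after first cancelling copies with
# identical repeat vectors, so an unchanged copy is never counted as two
# opposing mutations (identical call vectors therefore compare to zero).
# Event step sizes come from the minimizing assignment.
match_steps <- function(a, b) {
  perms <- permutations(nrow(a))
  costs <- apply(perms, 1, function(p) sum(abs(a - b[p, , drop = FALSE])))
  best <- perms[which.min(costs), ]
  diffs <- abs(a - b[best, , drop = FALSE])
  red <- cancel_identical_copies(a, b)
  steps_max <- if (nrow(red$a) == 0L) 0 else {
    rp <- permutations(nrow(red$a))
    max(apply(rp, 1, function(p) {
      sum(abs(red$a - red$b[p, , drop = FALSE]))
    }))
  }
  list(steps_min = min(costs), steps_max = steps_max,
       events = as.integer(diffs[diffs > 0]))
}

# Greedily pair off copies whose repeat vectors are identical across the two
# samples; returns the unmatched remainders.
cancel_identical_copies <- function(a, b) {
  key_a <- apply(a, 1, paste, collapse = ",")
  key_b <- apply(b, 1, paste, collapse = ",")
  drop_a <- logical(nrow(a))
  drop_b <- logical(nrow(b))
  for (i in seq_along(key_a)) {
    j <- which(!drop_b & key_b == key_a[i])
    if (length(j)) {
      drop_a[i] <- TRUE
      drop_b[j[1]] <- TRUE
    }
  }
  list(a = a[!drop_a, , drop = FALSE], b = b[!drop_b, , drop = FALSE])
}

#' Compare the Y-STR haplotypes of two male relatives
#'
#' Per locus called in both samples, counts the repeat-step differences.
#' Single-copy (and flank-distinguishable) loci compare per variable-motif
#' repeat counts directly, so two parallel one-step changes in different
#' motifs of a compound locus are detected even when the summed allele call
#' is unchanged. Indistinguishable multi-copy loci are compared under
#' parsimony: `steps_min` is the least total step count over all
#' copy-to-copy assignments, `steps_max` the largest after copies with
#' identical repeat vectors are paired off (an unchanged copy is never
#' counted as two opposing mutations), and their midpoint is carried as the
#' difference estimate. Loci `no_data` in either sample are
#' skipped (excluded from that locus's meiosis denominator downstream).
#'
#' @param geno_a,geno_b Genotype lists ([profile_genotypes()] or simulator
#'   output).
#' @param panel Named list of `str_locus`.
#' @param pair_id Identifier for the pair.
#' @param meioses Number of transmissions separating the two samples.
#' @return A `pair_comparison`: list with `pair_id`, `meioses`, `loci`
#'   (`data.frame` locus/steps_min/steps_mid/steps_max) and `events`
#'   (`data.frame` locus/size, one row per mutation event of the
#'   minimizing assignment).
#' @export
compare_pair <- function(geno_a, geno_b, panel, pair_id = "pair",
                         meioses = 1L) {
  loci_rows <- list()
  event_rows <- list()
  for (locus in intersect(names(geno_a), names(geno_b))) {
    a <- geno_a[[locus]]
    b <- geno_b[[locus]]
    if (is.null(a) || is.null(b)) next
    if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
      stop("copy_count mismatch at ", locus)
    }
    l <- panel[[locus]]
    if (!is.null(l) && (l$copy_count == 1L || l$distinguishable_copies)) {
      diffs <- abs(a - b)
      res <- list(steps_min = sum(diffs), steps_max = sum(diffs),
                  events = as.integer(diffs[diffs > 0]))
    } else {
      res <- match_steps(a, b)
    }
    loci_rows[[length(loci_rows) + 1L]] <- data.frame(
      locus = locus, steps_min = res$steps_min,
      steps_mid = (res$steps_min + res$steps_max) / 2,
      steps_max = res$steps_max, stringsAsFactors = FALSE)
    if (length(res$events)) {
      event_rows[[length(event_rows) + 1L]] <- data.frame(
        locus = locus, size = res$events, stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci_rows)) do.call(rbind, loci_rows) else
    data.frame(locus = character(), steps_min = numeric(),
               steps_mid = numeric(), steps_max = numeric(),
               stringsAsFactors = FALSE)
  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(locus = character(), size = integer(),
               stringsAsFactors = FALSE)
  structure(list(pair_id = pair_id, meioses = as.integer(meioses),
                 loci = loci, events = events), class = "pair_comparison")
}

#' Mutation-rate estimate with an exact binomial confidence interval
#'
#' Frequentist direct-count estimate: observed differences divided by
#' meioses. The 95% interval is the exact Clopper-Pearson binomial interval
#' on the (half-up rounded) difference count; the point estimate keeps the
#' unrounded midpoint. Rates are classed as slow (< 1e-3 mpg), moderate
#' ([1e-3, 5e-3)), fast ([5e-3, 1e-2)) or rapid (>= 1e-2); a locus with no
#' observed difference is `non_mutating`.
#'
#' @param differences Observed number of differences (may be a fractional
#'   parsimony midpoint).
#' @param meioses Total meioses (allele transfers) observed, >= 1.
#' @param conf Confidence level.
#' @return A `mutation_rate_estimate`: list with `differences`, `meioses`,
#'   `rate` (mpg), `ci_low`, `ci_high`, `class`.
#' @export
mutation_rate <- function(differences, meioses, conf = 0.95) {
  if (meioses < 1L) stop("meioses must be >= 1")
  if (differences < 0) stop("differences must be >= 0")
  rate <- differences / meioses
  ci <- clopper_pearson(round_half_up(differences), meioses, conf)
  structure(list(differences = differences, meioses = meioses, rate = rate,
                 ci_low = ci[1], ci_high = ci[2],
                 class = classify_rate(rate, differences)),
            class = "mutation_rate_estimate")
}

#' Exact Clopper-Pearson binomial interval
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low, high)
}

classify_rate <- function(rate, differences = rate) {
  if (differences == 0) "non_mutating"
  else if (rate < 1e-3) "slow"
  else if (rate < 5e-3) "moderate"
  else if (rate < 1e-2) "fast"
  else "rapid"
}

#' Aggregate pairwise comparisons into per-locus and panel-wide rates
#'
#' Per locus, the midpoint difference counts are summed over pairs and
#' divided by the locus's covered meioses (pairs where the locus was
#' `no_data` in either sample contribute nothing to that locus's
#' denominator, so denominators fluctuate across loci). The panel-wide rate
#' divides the grand difference total by the grand meiosis total; it is
#' reported with both the exact interval and a normal-approximation
#' interval. The mutating-only average excludes loci with zero observed
#' differences. Step-size bookkeeping counts one-step, two-step and
#' multi-step events and their rounded percentage ratio.
#'
#' @param comparisons List of `pair_comparison` objects.
#' @param loci Optional character vector fixing the locus universe.
#' @param conf Confidence level.
#' @return A list with `per_locus` (`data.frame` locus, differences
#'   (min/mid/max), meioses, rate, ci_low, ci_high, class) and `panel`
#'   (totals, rate, exact and normal CIs, mutating-only average, step
#'   counts and ratio).
#' @export
aggregate_rates <- function(comparisons, loci = NULL, conf = 0.95) {
  all_loci <- loci %||%
    unique(unlist(lapply(comparisons, function(cmp) cmp$loci$locus)))
  per <- lapply(all_loci, function(locus) {
    mid <- mn <- mx <- m <- 0
    for (cmp in comparisons) {
      row <- cmp$loci[cmp$loci$locus == locus, , drop = FALSE]
      if (!nrow(row)) next  # no_data in this pair
      mid <- mid + row$steps_mid
      mn <- mn + row$steps_min
      mx <- mx + row$steps_max
      m <- m + cmp$meioses
    }
    if (m == 0) return(NULL)
    est <- mutation_rate(mid, m, conf)
    data.frame(locus = locus, steps_min = mn, steps_mid = mid,
               steps_max = mx, meioses = m, rate = est$rate,
               ci_low = est$ci_low, ci_high = est$ci_high,
               class = est$class, stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, per)
  events <- do.call(rbind, lapply(comparisons, function(cmp) cmp$events))
  step_counts <- c(
    one = sum(events$size == 1), two = sum(events$size == 2),
    multi = sum(events$size >= 3))
  panel <- panel_rate_summary(
    total_mid = sum(per_locus$steps_mid), total_meioses =
      sum(per_locus$meioses),
    mutating_mid = sum(per_locus$steps_mid[per_locus$steps_mid > 0]),
    mutating_meioses = sum(per_locus$meioses[per_locus$steps_mid > 0]),
    step_counts = step_counts, conf = conf)
  list(per_locus = per_locus, panel = panel)
}

#' Panel-wide rate summary from difference and meiosis totals
#'
#' The arithmetic core of the panel aggregation, usable directly on printed
#' difference/meiosis totals: overall rate, exact and normal-approximation
#' intervals, mutating-only average and the step-size percentage ratio.
#'
#' @param total_mid,total_meioses Grand totals over all loci.
#' @param mutating_mid,mutating_meioses Totals over loci with at least one
#'   observed difference.
#' @param step_counts Named vector `c(one=, two=, multi=)` of event counts.
#' @param conf Confidence level.
#' @return A list with `rate`, `ci_exact`, `ci_normal`, `mutating_rate`,
#'   `step_counts`, `step_ratio_pct`.
#' @export
panel_rate_summary <- function(total_mid, total_meioses,
                               mutating_mid = total_mid,
                               mutating_meioses = total_meioses,
                               step_counts = NULL, conf = 0.95) {
  rate <- total_mid / total_meioses
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(rate * (1 - rate) / total_meioses)
  ratio <- if (!is.null(step_counts) && sum(step_counts) > 0) {
    round_half_up(100 * step_counts / sum(step_counts))
  } else NULL
  list(rate = rate,
       ci_exact = clopper_pearson(round_half_up(total_mid), total_meioses,
                                  conf),
       ci_normal = c(rate - z * se, rate + z * se),
       mutating_rate = if (mutating_meioses > 0)
         mutating_mid / mutating_meioses else NA_real_,
       step_counts = step_counts, step_ratio_pct = ratio)
}

#' Chi-square comparison of an observed rate against a literature rate
#'
#' One-sample goodness-of-fit of the observed (events, non-events) split
#' against the expectation under a reference mutation rate.
#'
#' @param differences Observed differences.
#' @param meioses Observed meioses.
#' @param ref_rate Reference rate in (0, 1).
#' @param alpha Significance level for the flag.
#' @return A list with `statistic`, `p_value`, `significant`.
#' @export
compare_rate_to_reference <- function(differences, meioses, ref_rate,
                                      alpha = 0.05) {
  if (ref_rate <= 0 || ref_rate >= 1) stop("ref_rate must lie in (0, 1)")
  x <- round_half_up(differences)
  ht <- suppressWarnings(
    stats::chisq.test(c(x, meioses - x), p = c(ref_rate, 1 - ref_rate)))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Probability of distinguishing two relatives by at least one difference
#'
#' Under independent per-locus, per-meiosis mutation probabilities, two
#' males separated by `generations` transmissions differ at one or more
#' loci with probability `1 - prod((1 - rate_l)^generations)`; with a
#' uniform rate over `n_loci` loci this is `1 - (1-r)^(n_loci*generations)`.
#'
#' @param rates Per-locus rate vector, or a single rate with `n_loci` set.
#' @param generations Number of transmissions separating the pair
#'   (brothers = 2, cousins = 4).
#' @param n_loci Number of loci when `rates` is a single uniform rate.
#' @return Probability in `[0, 1]`.
#' @export
distinguish_probability <- function(rates, generations, n_loci = NULL) {
  if (!is.null(n_loci) && length(rates) == 1L) {
    rates <- rep(rates, n_loci)
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (generations < 0) stop("generations must be >= 0")
  1 - prod((1 - rates)^generations)
}

#' Expected mutations per generation of a panel
#'
#' @param rates Per-locus rates, or one uniform rate with `n_loci`.
#' @param n_loci Number of loci when `rates` is a single rate.
#' @return Expected number of mutations per single transmission.
#' @export
panel_mutations_per_generation <- function(rates, n_loci = NULL) {
  if (!is.null(n_loci) && length(rates) == 1L) rates <- rep(rates, n_loci)
  sum(rates)
}

#' Maximum difference count compatible with a claimed kinship
#'
#' Smallest `k` such that the probability of observing at most `k` total
#' differences over all loci in `generations` transmissions reaches
#' `quantile`, under independent per-locus binomial mutation counts
#' (Poisson-binomial total, evaluated by exact convolution).
#'
#' @param rates Per-locus mutation rates (mpg).
#' @param generations Transmissions separating the claimed relatives.
#' @param quantile Coverage probability of the threshold.
#' @return Integer threshold `k`.
#' @export
max_allowed_differences <- function(rates, generations, quantile = 0.95) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  pmf <- 1
  for (r in rates) {
    # per-locus mutation count over `generations` meioses ~ Binomial(g, r)
    bl <- stats::dbinom(0:generations, generations, r)
    new <- numeric(length(pmf) + generations)
    for (j in seq_along(bl)) {
      if (bl[j] == 0) next
      idx <- seq_along(pmf) + j - 1L
      new[idx] <- new[idx] + pmf * bl[j]
    }
    pmf <- new
  }
  sum(cumsum(pmf) < quantile)
}
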