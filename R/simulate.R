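#' Simulation configuration
#'
#' Parameters of the synthetic amplicon-read and pedigree generator. The
#' defaults emulate the assay conditions of a MiSeq 2x300 bp chrY amplicon
#' panel: mean per-marker depth 150 reads with a wide negative-binomial
#' spread, a small per-base substitution error rate, repeat-loss stutter
#' strongest for dinucleotide motifs, and a predominantly single-step
#' mutation model with a geometric multi-step tail.
#'
#' @param seed Integer seed; every random draw of the simulator derives from
#'   it, so identical seeds give byte-identical FASTQ output.
#' @param depth_mean Mean read depth per locus copy (and per SNP amplicon).
#' @param depth_dispersion Negative-binomial `size`; smaller = wider spread,
#'   `Inf` gives a deterministic depth equal to the mean.
#' @param error_rate Per-base substitution error probability.
#' @param stutter_ratio Named vector by motif unit length (bp): expected
#'   fraction of the parent depth observed one repeat shorter (n-1).
#' @param stutter_decay Ratio of n-2 stutter relative to n-1.
#' @param stutter_gain Fraction of parent depth gaining one repeat (n+1).
#' @param mutation_rate Per-locus, per-meiosis mutation probability (mpg);
#'   a single number or a named per-locus vector. Multi-copy loci mutate at
#'   `rate * copy_count`.
#' @param step_one_prob Probability a mutation is a single repeat step.
#' @param step_geom_p Geometric parameter for the multi-step tail
#'   (step size `k >= 2` has probability `(1-p1) * p * (1-p)^(k-2)`).
#' @param read_length Read length in bp.
#' @param degradation Depth multiplier per 100 bp of amplicon length
#'   (1 = none; < 1 down-weights long amplicons as in degraded DNA).
#' @param base_quality Constant Phred quality written to FASTQ (Phred+33).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, depth_mean = 150, depth_dispersion = 3,
                       error_rate = 0.002,
                       stutter_ratio = c(`2` = 0.30, `3` = 0.12, `4` = 0.10,
                                         `5` = 0.05, `6` = 0.05),
                       stutter_decay = 0.3, stutter_gain = 0,
                       mutation_rate = 5e-3, step_one_prob = 0.83,
                       step_geom_p = 0.7, read_length = 300L,
                       degradation = 1, base_quality = 35L) {
  rates <- c(error_rate, stutter_ratio, stutter_decay, stutter_gain,
             mutation_rate, step_one_prob, step_geom_p)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (all(c("2", "4") %in% names(stutter_ratio)) &&
      stutter_ratio[["2"]] < stutter_ratio[["4"]]) {
    stop("dinucleotide stutter must be at least as strong as tetranucleotide")
  }
  structure(list(seed = as.integer(seed), depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, error_rate = error_rate,
                 stutter_ratio = stutter_ratio, stutter_decay = stutter_decay,
                 stutter_gain = stutter_gain, mutation_rate = mutation_rate,
                 step_one_prob = step_one_prob, step_geom_p = step_geom_p,
                 read_length = as.integer(read_length),
                 degradation = degradation,
                 base_quality = as.integer(base_quality)),
            class = "sim_config")
}

locus_rate <- function(config, name) {
  r <- config$mutation_rate
  if (length(r) > 1L || !is.null(names(r))) {
    if (name %in% names(r)) unname(r[name]) else stop("no rate for ", name)
  } else r
}

#' Reference genotype for a panel
#'
#' A genotype is a named list with, per locus, an integer matrix of variable
#' block repeat counts (rows = locus copies, columns = variable blocks).
#'
#' @param panel Named list of `str_locus`.
#' @return Genotype list at the reference repeat counts.
#' @export
reference_genotype <- function(panel) {
  lapply(panel, function(l) {
    v <- l$blocks$ref_count[l$blocks$variable]
    m <- matrix(rep(v, each = l$copy_count), nrow = l$copy_count)
    rownames(m) <- l$copy_labels
    m
  })
}

draw_step <- function(config) {
  if (stats::runif(1) < config$step_one_prob) 1L
  else 2L + stats::rgeom(1, config$step_geom_p)
}

#' Simulate Y-STR transmission along a pedigree line
#'
#' Walks a genotype through `n_meioses` father-to-son transmissions. Per
#' meiosis and locus a mutation occurs with probability
#' `rate * copy_count`; the mutated copy and variable block are chosen
#' uniformly, the step size comes from the configured single-step/geometric
#' model, and the direction is +/- with equal probability, reflected when
#' the result would leave the locus repeat-count range.
#'
#' @param panel Named list of `str_locus`.
#' @param config A [sim_config()].
#' @param n_meioses Number of transmissions to simulate.
#' @param founder Founder genotype; defaults to [reference_genotype()].
#' @return A list with `profiles` (genotypes after 0..n meioses, so element
#'   `i` is the state after `i - 1` transmissions) and `truth`, a
#'   `data.frame` of planted mutations (meiosis, locus, copy, block, step,
#'   direction, from, to). Replaying `truth` on the founder reproduces every
#'   profile.
#' @export
simulate_pedigree <- function(panel, config, n_meioses,
                              founder = reference_genotype(panel)) {
  set.seed(config$seed)
  cur <- founder
  profiles <- vector("list", n_meioses + 1L)
  profiles[[1L]] <- cur
  events <- list()
  for (m in seq_len(n_meioses)) {
    for (locus in names(panel)) {
      l <- panel[[locus]]
      p <- min(1, locus_rate(config, locus) * l$copy_count)
      if (stats::runif(1) >= p) next
      g <- cur[[locus]]
      copy <- sample.int(nrow(g), 1)
      blk <- sample.int(ncol(g), 1)
      rng <- l$blocks[l$blocks$variable, ][blk, c("min_count", "max_count")]
      step <- draw_step(config)
      dir <- sample(c(-1L, 1L), 1)
      new <- g[copy, blk] + dir * step
      if (new > rng$max_count || new < rng$min_count) {
        dir <- -dir
        new <- g[copy, blk] + dir * step
      }
      new <- min(max(new, rng$min_count), rng$max_count)
      if (new == g[copy, blk]) next  # range too narrow to move
      events[[length(events) + 1L]] <- data.frame(
        meiosis = m, locus = locus, copy = l$copy_labels[copy], block = blk,
        step = abs(new - g[copy, blk]), direction = sign(new - g[copy, blk]),
        from = g[copy, blk], to = new, stringsAsFactors = FALSE)
      g[copy, blk] <- new
      cur[[locus]] <- g
    }
    profiles[[m + 1L]] <- cur
  }
  truth <- if (length(events)) do.call(rbind, events) else
    data.frame(meiosis = integer(), locus = character(), copy = character(),
               block = integer(), step = integer(), direction = integer(),
               from = integer(), to = integer(), stringsAsFactors = FALSE)
  list(profiles = profiles, truth = truth)
}

# Apply substitution errors to a character vector of reads, in place.
apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate paired-end amplicon reads for one sample
#'
#' Emits reads for every Y-STR locus copy (parent sequence
#' `anchor5 + prefix + repeats + suffix + anchor3` at a negative-binomial
#' depth, a stutter ladder at n-1/n-2 on variable blocks, per-base
#' substitution errors) and for every Y-SNP amplicon (ancestral or derived
#' base according to the planted haplogroup path). R1 is the 5' read and R2
#' the reverse complement. In female mode no chrY template exists, so only
#' unassignable background reads are produced.
#'
#' @param genotype Genotype list (see [reference_genotype()]); may be `NULL`
#'   in female mode.
#' @param panel Named list of `str_locus`.
#' @param config A [sim_config()].
#' @param snps Optional SNP `data.frame`; SNP amplicons are generated via
#'   [snp_amplicons()].
#' @param haplogroup Planted terminal haplogroup label; SNPs whose
#'   haplogroup lies on its root path carry the derived base.
#' @param tree `haplogroup_tree` used to resolve the planted path.
#' @param female Logical; simulate a no-chrY (female control) library.
#' @param n_background Number of random non-panel background reads.
#' @return A list of class `sim_reads`: `r1`, `r2` (named character
#'   vectors), `qual1`, `qual2`, and `truth` (planted genotype, per-locus
#'   parent depths, per-SNP states, haplogroup).
#' @export
simulate_reads <- function(genotype, panel, config, snps = NULL,
                           haplogroup = NULL, tree = NULL, female = FALSE,
                           n_background = if (female) 200L else 0L) {
  set.seed(config$seed)
  draw_depth <- function(mu) {
    if (is.infinite(config$depth_dispersion)) as.integer(round(mu))
    else stats::rnbinom(1, size = config$depth_dispersion, mu = mu)
  }
  min_len <- if (length(panel)) {
    max(nchar(vapply(panel, `[[`, "", "anchor5"))) + 1L
  } else 16L
  if (config$read_length < min_len) {
    stop("read_length must exceed the anchor length")
  }
  templates <- character()
  str_depths <- list()
  if (!female) {
    for (locus in names(panel)) {
      l <- panel[[locus]]
      g <- genotype[[locus]]
      if (is.null(g)) next
      amp_len <- nchar(locus_sequence(l, g[1, ], with_anchors = TRUE))
      mu <- config$depth_mean * config$degradation^(amp_len / 100)
      copy_depth <- integer(nrow(g))
      for (copy in seq_len(nrow(g))) {
        depth <- draw_depth(mu)
        copy_depth[copy] <- depth
        if (depth == 0L) next
        parent <- locus_sequence(l, g[copy, ], with_anchors = TRUE)
        templates <- c(templates, rep(parent, depth))
        # stutter ladder on each variable block
        vblocks <- which(l$blocks$variable)
        for (j in seq_along(vblocks)) {
          u <- l$blocks$unit_len[vblocks[j]]
          ratio <- config$stutter_ratio[as.character(u)]
          if (is.na(ratio)) ratio <- 0
          for (delta in c(-1L, -2L, 1L)) {
            r <- switch(as.character(delta),
                        `-1` = ratio,
                        `-2` = ratio * config$stutter_decay,
                        `1` = config$stutter_gain)
            if (r <= 0) next
            cnt <- g[copy, j] + delta
            if (cnt < 1L) next
            k <- stats::rbinom(1, depth, r)
            if (k == 0L) next
            counts <- g[copy, ]
            counts[j] <- cnt
            templates <- c(templates,
                           rep(locus_sequence(l, counts, with_anchors = TRUE),
                               k))
          }
        }
      }
      str_depths[[locus]] <- copy_depth
    }
  }
  snp_states <- NULL
  if (!female && !is.null(snps) && nrow(snps)) {
    amps <- snp_amplicons(snps)
    path <- if (!is.null(haplogroup) && !is.null(tree)) {
      tree_path(tree, haplogroup)
    } else character()
    snp_states <- ifelse(snps$haplogroup %in% path, "derived", "ancestral")
    for (i in seq_len(nrow(amps))) {
      depth <- draw_depth(config$depth_mean)
      if (depth == 0L) next
      tmpl <- amps$template[i]
      if (snp_states[i] == "derived") {
        substr(tmpl, amps$offset[i], amps$offset[i]) <- amps$derived[i]
      }
      templates <- c(templates, rep(tmpl, depth))
    }
    names(snp_states) <- snps$name
  }
  if (n_background > 0L) {
    templates <- c(templates, random_dna(n_background, 120L))
  }
  # shuffle so read order carries no locus signal, then cut to read length
  if (length(templates)) templates <- sample(templates)
  r1 <- substr(templates, 1L, config$read_length)
  r2 <- revcomp(templates)
  r2 <- substr(r2, 1L, config$read_length)
  r1 <- apply_errors(r1, config$error_rate)
  r2 <- apply_errors(r2, config$error_rate)
  ids <- sprintf("read%06d", seq_along(templates))
  names(r1) <- names(r2) <- ids
  structure(list(
    r1 = r1, r2 = r2,
    qual1 = strrep(rawToChar(as.raw(33L + config$base_quality)), nchar(r1)),
    qual2 = strrep(rawToChar(as.raw(33L + config$base_quality)), nchar(r2)),
    truth = list(genotype = if (female) NULL else genotype,
                 str_depths = str_depths, snp_states = snp_states,
                 haplogroup = if (female) NULL else haplogroup,
                 female = female, n_reads = length(templates))
  ), class = "sim_reads")
}

#' Write simulated reads as a paired FASTQ file set
#'
#' @param sim A `sim_reads` object.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (Phred+33, uncompressed).
#' @return Character vector of the two paths, invisibly.
#' @export
#' @importFrom Biostrings QualityScaledDNAStringSet PhredQuality
#'   writeQualityScaledXStringSet
write_sim_fastq <- function(sim, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_R1.fastq", "_R2.fastq")))
  for (end in 1:2) {
    reads <- if (end == 1) sim$r1 else sim$r2
    quals <- if (end == 1) sim$qual1 else sim$qual2
    x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(reads),
      Biostrings::PhredQuality(quals)))
    names(x) <- paste0(names(reads), "/", end)
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, paths[end]))
  }
  invisible(paths)
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ path (Phred+33).
#' @return A list with `seq` and `qual` character vectors.
#' @export
#' @importFrom Biostrings readQualityScaledDNAStringSet
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(seq = as.character(x), qual = as.character(x@quality))
}
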