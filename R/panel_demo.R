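#' Built-in demonstration panel of Y-STR loci
#'
#' A 30-locus panel constructed deterministically in code (anchors and
#' flanking sequences are synthetic), shaped like a sequence-based chrY
#' amplicon panel: mostly simple single-copy tetra-/tri-nucleotide markers,
#' plus dinucleotide multi-copy markers with heavy stutter, a compound
#' double-motif locus (`DYS463`-style `AAAGG[n]AAGGG[n]`), a four-copy
#' complex palindromic locus (`DYS725`-style `GT[n]GTCT[n]`) and an
#' interrupted complex locus. Repeat-count ranges bound the simulator's
#' mutation walks.
#'
#' @param n_loci Total number of loci (>= 6; extra loci beyond the named
#'   exemplars are generated simple markers).
#' @return Named list of `str_locus` objects.
#' @export
demo_panel <- function(n_loci = 30L) {
  if (n_loci < 6L) stop("demo panel needs at least 6 loci")
  with_seed(104729L, {
    loci <- list()
    add <- function(l) loci[[l$name]] <<- l
    pos <- 2650000L
    place <- function(len) {
      start <- pos
      pos <<- pos + len + sample(500:5000, 1)
      c(start, start + len - 1L)
    }
    mk <- function(name, blocks, copy_count = 1L, prefix_len = 10L,
                   suffix_len = 10L, repeat_type = NULL) {
      repeat {
        anchor5 <- random_dna(1, 15)
        anchor3 <- random_dna(1, 15)
        prefix <- random_dna(1, prefix_len)
        suffix <- random_dna(1, suffix_len)
        # flanks must not extend the adjacent repeat motif, or greedy
        # decomposition would not be the unique parse
        m1 <- blocks$motif[1]
        last_var <- blocks$motif[max(which(blocks$variable))]
        ok_p <- substring(prefix, prefix_len - nchar(m1) + 1) != m1
        ok_s <- substr(suffix, 1, nchar(last_var)) != last_var
        if (ok_p && ok_s) break
      }
      len <- 30L + prefix_len + suffix_len +
        sum(nchar(blocks$motif) * blocks$ref_count)
      coords <- place(len)
      str_locus(name, blocks, anchor5, anchor3, prefix, suffix,
                copy_count = copy_count, chr_start = coords[1],
                chr_end = coords[2], repeat_type = repeat_type)
    }
    # compound double-motif locus: reference allele 7 + 15 = 22 repeats
    add(mk("DYS463", rbind(
      motif_block("AAAGG", variable = TRUE, ref_count = 7L,
                  min_count = 3L, max_count = 15L),
      motif_block("AAGGG", variable = TRUE, ref_count = 15L,
                  min_count = 5L, max_count = 25L))))
    # four-copy palindromic complex locus
    add(mk("DYS725", rbind(
      motif_block("GT", variable = TRUE, ref_count = 19L,
                  min_count = 10L, max_count = 30L),
      motif_block("GTCT", variable = TRUE, ref_count = 4L,
                  min_count = 2L, max_count = 10L)),
      copy_count = 4L, repeat_type = "complex"))
    # two-copy dinucleotide with strong stutter
    add(mk("YCAII", rbind(
      motif_block("CA", variable = TRUE, ref_count = 21L,
                  min_count = 11L, max_count = 30L)), copy_count = 2L))
    # monomorphic-prone trinucleotide
    add(mk("DYS436", rbind(
      motif_block("AAC", variable = TRUE, ref_count = 12L,
                  min_count = 5L, max_count = 20L))))
    # interrupted complex locus
    add(mk("DYS19X", rbind(
      motif_block("TATC", variable = TRUE, ref_count = 11L,
                  min_count = 4L, max_count = 20L),
      motif_block("ATGG", interruption = TRUE),
      motif_block("TATC", variable = FALSE, ref_count = 3L))))
    # fixed-tail compound locus
    add(mk("DYS389X", rbind(
      motif_block("TAGA", variable = TRUE, ref_count = 10L,
                  min_count = 4L, max_count = 18L),
      motif_block("CAGA", variable = FALSE, ref_count = 3L))))
    # generated simple loci across motif unit lengths
    units <- c(2L, 3L, 4L, 4L, 5L)
    i <- 0L
    while (length(loci) < n_loci) {
      i <- i + 1L
      u <- units[(i - 1L) %% length(units) + 1L]
      repeat {
        motif <- random_dna(1, u)
        # homopolymer or self-periodic motifs make repeat counting ambiguous
        if (length(unique(strsplit(motif, "")[[1]])) > 1L &&
            substr(strrep(motif, 2), 2, u + 1) != motif) break
      }
      ref <- sample(8:20, 1)
      cc <- if (i %% 7L == 0L) 2L else 1L
      add(mk(sprintf("SYS%03d", i), rbind(
        motif_block(motif, variable = TRUE, ref_count = ref,
                    min_count = max(3L, ref - 6L), max_count = ref + 8L)),
        copy_count = cc))
    }
    loci
  })
}

#' Built-in demonstration Y-SNP set and haplogroup tree
#'
#' Deterministically generated SNP definitions spanning a small phylogeny:
#' main haplogroups with nested subhaplogroup chains (including a deep
#' `R1a1a...` chain), one SNP per branch, plus a few markers with unknown
#' phylogenetic position and private markers, which are reported but never
#' drive haplogroup assignment.
#'
#' @return A list with `snps` (a positions `data.frame` as returned by
#'   [read_positions_file()]) and `tree` (a [build_tree()] result covering
#'   the haplogroup-bearing SNPs).
#' @export
demo_snps <- function() {
  with_seed(224737L, {
    chain <- function(terminal) {
      # all alternating-prefix truncations of a lineage label
      vapply(seq_len(nchar(terminal)), function(k) substr(terminal, 1, k),
             character(1))
    }
    labels <- unique(c(
      chain("R1a1a1b1a3a2b2b"), chain("R1b1a2"),
      chain("E1b1b1"), chain("I2a1b1"), chain("J2a1"), chain("G2a"),
      "A", "C", "Q", "T"))
    positions <- sort(sample(2.7e6:28.8e6, length(labels) + 6L))
    snps <- data.frame(
      name = c(paste0("M", positions[seq_along(labels)]),
               paste0("U", positions[length(labels) + 1:3]),
               paste0("P", positions[length(labels) + 4:6])),
      aliases = "",
      position = positions,
      haplogroup = c(labels, rep("unknown", 3L), "R1a", "E1b", "J2"),
      private = c(rep(FALSE, length(labels) + 3L), rep(TRUE, 3L)),
      stringsAsFactors = FALSE)
    ad <- t(vapply(seq_len(nrow(snps)), function(i) {
      sample(DNA_BASES, 2)
    }, character(2)))
    snps$ancestral <- ad[, 1]
    snps$derived <- ad[, 2]
    tree <- build_tree(snps$haplogroup[!snps$private])
    list(snps = snps, tree = tree)
  })
}

#' Synthetic amplicon contexts for Y-SNP markers
#'
#' The panel definition carries SNP positions but no flanking sequence, so
#' per-SNP amplicon contexts are generated deterministically from the SNP
#' position (synthetic flanks; the same context is therefore shared by the
#' read simulator and the pileup caller). The SNP base sits at a fixed
#' offset inside the amplicon; the first and last 15 bp serve as anchors.
#'
#' @param snps SNP `data.frame` (see [read_positions_file()]).
#' @param flank Flanking length on each side of the SNP base, in bp.
#' @return `data.frame` with columns `name`, `position`, `offset`,
#'   `template` (context carrying the ancestral base), `anchor5`, `anchor3`,
#'   `ancestral`, `derived`.
#' @export
snp_amplicons <- function(snps, flank = 60L) {
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    with_seed((snps$position[i] * 7L + 13L) %% .Machine$integer.max, {
      left <- random_dna(1, flank)
      right <- random_dna(1, flank)
      template <- paste0(left, snps$ancestral[i], right)
      data.frame(name = snps$name[i], position = snps$position[i],
                 offset = flank + 1L, template = template,
                 anchor5 = substr(template, 1, 15),
                 anchor3 = substr(template, nchar(template) - 14,
                                  nchar(template)),
                 ancestral = snps$ancestral[i], derived = snps$derived[i],
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
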