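noise_free_cfg <- function(seed = 1, depth = 100) {
  sim_config(seed = seed, depth_mean = depth, depth_dispersion = Inf,
             error_rate = 0,
             stutter_ratio = c(`2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0))
}

test_that("anchor matching assigns reads within the mismatch tolerance", {
  panel <- tiny_panel()
  l <- panel$SIMPLE
  read <- locus_sequence(l, with_anchors = TRUE)
  tab <- tabulate_sequences(rep(read, 3), panel)
  expect_equal(tab$counts$locus, "SIMPLE")
  expect_equal(tab$counts$total, 3L)
  expect_equal(tab$counts$forward, 3L)
  expect_equal(tab$counts$sequence, locus_sequence(l))

  # reverse-orientation reads count on the reverse strand
  rc <- yseqpanel:::revcomp(read)
  tab2 <- tabulate_sequences(rc, panel)
  expect_equal(tab2$counts$reverse, 1L)
  expect_equal(tab2$counts$sequence, locus_sequence(l))

  # one anchor mismatch tolerated, two rejected
  one_mm <- read
  substr(one_mm, 2, 2) <- if (substr(one_mm, 2, 2) == "A") "C" else "A"
  two_mm <- one_mm
  substr(two_mm, 4, 4) <- if (substr(two_mm, 4, 4) == "G") "T" else "G"
  expect_equal(tabulate_sequences(one_mm, panel)$unassigned, 0L)
  expect_equal(tabulate_sequences(two_mm, panel,
                                  min_anchor_match = 1)$unassigned, 1L)
})

test_that("tabulated per-locus totals match the simulator's planted depths", {
  panel <- tiny_panel()
  cfg <- noise_free_cfg(seed = 44)
  sim <- simulate_reads(reference_genotype(panel), panel, cfg)
  tab <- tabulate_sequences(sim$r1, panel)$counts
  totals <- tapply(tab$total, tab$locus, sum)
  for (locus in names(panel)) {
    expect_equal(unname(totals[locus]),
                 sum(sim$truth$str_depths[[locus]]))
  }
})

test_that("the compound reference sequence decomposes to 22 repeats", {
  l <- tiny_panel()$COMPOUND  # AAAGG[7] + AAGGG[15]
  dec <- decompose(l, locus_sequence(l))
  expect_s3_class(dec, "repeat_decomposition")
  expect_equal(dec$allele_call, 22)
  expect_equal(dec$blocks$count[dec$blocks$variable], c(7, 15))
  expect_equal(format_decomposition(dec),
               "CTTGATCG|AAAGG[7]AAGGG[15]|TGCCATTA")
})

test_that("reference sequences decompose to reference counts, no variants", {
  for (l in demo_panel()) {
    dec <- decompose(l, locus_sequence(l))
    expect_s3_class(dec, "repeat_decomposition")
    expect_equal(dec$blocks$count, l$blocks$ref_count)
    expect_length(dec$variants, 0)
  }
})

test_that("decomposition matches a regex oracle on random sequences", {
  set.seed(91)
  panel <- demo_panel()
  for (i in 1:500) {
    l <- panel[[sample(length(panel), 1)]]
    x <- random_in_structure(l)
    dec <- decompose(l, x$sequence)
    expect_equal(dec$blocks$count[dec$blocks$variable], x$counts)
    # independent parse: anchored regex with one capture per block
    pat <- paste0("^", l$prefix_ref,
                  paste(vapply(seq_len(nrow(l$blocks)), function(j) {
                    b <- l$blocks[j, ]
                    if (b$variable) sprintf("((?:%s)+)", b$motif)
                    else sprintf("(%s)", strrep(b$motif, b$ref_count))
                  }, character(1)), collapse = ""),
                  l$suffix_ref, "$")
    m <- regmatches(x$sequence, regexec(pat, x$sequence))[[1]]
    expect_gt(length(m), 0)
    ora <- nchar(m[-1][l$blocks$variable]) /
      l$blocks$unit_len[l$blocks$variable]
    expect_equal(dec$blocks$count[dec$blocks$variable], ora)
  }
})

test_that("decompose-expand round-trips byte-for-byte", {
  set.seed(92)
  panel <- demo_panel()
  for (i in 1:1000) {
    l <- panel[[sample(length(panel), 1)]]
    x <- random_in_structure(l)
    dec <- decompose(l, x$sequence)
    expect_identical(expand_decomposition(dec), x$sequence)
  }
})

test_that("flank deviations beyond tolerance fail with a reason", {
  l <- tiny_panel()$SIMPLE
  seq_ref <- locus_sequence(l)
  long <- paste0("GGGGGGGGGG", seq_ref)
  fail <- decompose(l, long)
  expect_s3_class(fail, "decomposition_failure")
  # trailing garbage leaves the suffix too long at every backtrack
  tail_garbage <- paste0(seq_ref, "GGGGGGGG")
  expect_equal(decompose(l, tail_garbage)$reason, "flank_too_long")
  # a required block entirely absent
  no_block <- paste0(l$prefix_ref, l$suffix_ref)
  expect_equal(decompose(l, no_block)$reason, "block_missing")
  # small flank deviations are tolerated and reported as variants
  one_sub <- seq_ref
  substr(one_sub, 2, 2) <- if (substr(one_sub, 2, 2) == "G") "T" else "G"
  dec <- decompose(l, one_sub)
  expect_s3_class(dec, "repeat_decomposition")
  expect_match(dec$variants, "^prefix:2")
})

test_that("stutter one repeat below a strong parent is flagged", {
  l <- tiny_panel()$DICOPY
  counts <- data.frame(
    locus = "DICOPY",
    sequence = c(locus_sequence(l, 20), locus_sequence(l, 19)),
    forward = c(1000L, 250L), reverse = 0L, total = c(1000L, 250L),
    stringsAsFactors = FALSE)
  flt <- filter_stutter(counts, l)
  expect_equal(flt$genuine$allele_call, 20)
  expect_equal(flt$stutter$allele_call, 19)

  # a singleton is always genuine
  flt1 <- filter_stutter(counts[1, ], l)
  expect_equal(nrow(flt1$stutter), 0L)

  # the top-count sequence is never flagged, whatever the configuration
  flt2 <- filter_stutter(counts[order(counts$total), ], l)
  expect_true(20 %in% flt2$genuine$allele_call)
})

test_that("two-copy dinucleotide alleles survive a full stutter ladder", {
  panel <- tiny_panel()["DICOPY"]
  genotype <- list(DICOPY = matrix(c(19L, 21L), ncol = 1))
  cfg <- sim_config(seed = 7, depth_mean = 400, depth_dispersion = Inf,
                    error_rate = 0)
  sim <- simulate_reads(genotype, panel, cfg)
  tab <- tabulate_sequences(sim$r1, panel)$counts
  expect_gt(nrow(tab), 2)  # the ladder is present
  call <- call_locus(tab, panel$DICOPY)
  expect_equal(call$status, "called")
  expect_equal(vapply(call$calls, `[[`, 0, "allele"), c(19, 21))
})

test_that("locus calling walks candidates and honours the read threshold", {
  l <- tiny_panel()$SIMPLE
  expect_equal(call_locus(NULL, l)$status, "no_data")

  # below the minimum total read count
  low <- data.frame(locus = "SIMPLE", sequence = locus_sequence(l),
                    forward = 9L, reverse = 0L, total = 9L,
                    stringsAsFactors = FALSE)
  expect_equal(call_locus(low, l)$status, "no_data")

  # three invalid candidates outrank the genuine one; the 4th is called
  junk <- vapply(1:3, function(i) random_dna_local(60 + i), character(1))
  counts <- data.frame(
    locus = "SIMPLE", sequence = c(junk, locus_sequence(l, 12)),
    forward = c(500L, 400L, 300L, 200L), reverse = 0L,
    total = c(500L, 400L, 300L, 200L), stringsAsFactors = FALSE)
  call <- call_locus(counts, l)
  expect_equal(call$status, "called")
  expect_equal(call$calls[[1]]$allele, 12)

  # all top-4 invalid: no_data
  counts$sequence[4] <- random_dna_local(64)
  expect_equal(call_locus(counts, l)$status, "no_data")
})

test_that("paired-end consensus follows proximity then depth", {
  l <- tiny_panel()$SIMPLE
  mk_call <- function(allele, depth, source) {
    counts <- data.frame(locus = "SIMPLE",
                         sequence = locus_sequence(l, allele),
                         forward = depth, reverse = 0L, total = depth,
                         stringsAsFactors = FALSE)
    call_locus(counts, l, source = source)
  }
  c10 <- mk_call(10, 120L, "R1")
  c10b <- mk_call(10, 80L, "R2")
  c11 <- mk_call(11, 80L, "R2")
  nd <- call_locus(NULL, l, source = "R2")

  agree <- paired_end_consensus(c10, c10b, 5, 40)
  expect_equal(agree$source, "consensus")
  expect_equal(agree$calls[[1]]$allele, 10)

  # differing calls: repeat region closer to its anchor wins
  expect_equal(paired_end_consensus(c10, c11, 5, 40)$calls[[1]]$allele, 10)
  expect_equal(paired_end_consensus(c10, c11, 40, 5)$calls[[1]]$allele, 11)
  # equal offsets: depth wins
  expect_equal(paired_end_consensus(c10, c11, 8, 8)$calls[[1]]$allele, 10)
  expect_equal(paired_end_consensus(c11, c10, 8, 8)$calls[[1]]$allele, 10)
  # one end no_data defers to the other; both no_data stays no_data
  expect_equal(paired_end_consensus(c10, nd, 5, 40)$calls[[1]]$allele, 10)
  expect_equal(paired_end_consensus(nd, nd, 5, 40)$status, "no_data")
})

test_that("isoalleles with equal total call give distinct decompositions", {
  l <- tiny_panel()$COMPOUND
  a <- decompose(l, locus_sequence(l, c(7, 15)))
  b <- decompose(l, locus_sequence(l, c(8, 14)))
  expect_equal(a$allele_call, b$allele_call)
  expect_false(identical(a$blocks$count, b$blocks$count))
})

test_that("profiles assemble with per-locus status bookkeeping", {
  panel <- tiny_panel()
  prof <- assemble_profile(list(), panel, "empty")
  expect_equal(prof$n_called, 0L)
  expect_equal(prof$n_no_data, 3L)
  expect_named(prof$calls, names(panel))
})

test_that("noise-on calling recovers simulated single-copy truth", {
  panel <- demo_panel(12)
  snames <- names(panel)[vapply(panel, `[[`, 0L, "copy_count") == 1L]
  n_samples <- 12
  correct <- total <- 0
  for (s in seq_len(n_samples)) {
    cfg <- sim_config(seed = 1000 + s, mutation_rate = 0.3)
    ped <- simulate_pedigree(panel, cfg, 3)
    g_true <- ped$profiles[[4]]
    sim <- simulate_reads(g_true, panel, cfg)
    prof <- call_str_sample(sim$r1, sim$r2, panel, paste0("s", s))
    g_called <- profile_genotypes(prof)
    for (locus in snames) {
      if (is.null(g_called[[locus]])) next  # no_data does not count against
      total <- total + 1
      correct <- correct + genotype_matches(g_true[[locus]],
                                            g_called[[locus]])
    }
  }
  expect_gt(total, 0.8 * n_samples * length(snames))
  expect_gte(correct / total, 0.99)
})

test_that("a female-mode library yields a profile with zero called loci", {
  panel <- tiny_panel()
  cfg <- sim_config(seed = 13)
  sim <- simulate_reads(NULL, panel, cfg, female = TRUE)
  prof <- call_str_sample(sim$r1, sim$r2, panel, "female")
  expect_equal(prof$n_called, 0L)
})
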