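# Shared fixtures, built in code.

# Minimal three-locus panel with hand-picked anchors/flanks so expected
# sequences can be written out by eye.
tiny_panel <- function() {
  list(
    SIMPLE = str_locus(
      "SIMPLE",
      motif_block("TCTA", variable = TRUE, ref_count = 10L,
                  min_count = 5L, max_count = 16L),
      anchor5 = "ACGTACGTACGTACG", anchor3 = "TGCATGCATGCATGC",
      prefix_ref = "GGAACCTT", suffix_ref = "CCGGAATT",
      chr_start = 100L, chr_end = 200L),
    COMPOUND = str_locus(
      "COMPOUND",
      rbind(motif_block("AAAGG", variable = TRUE, ref_count = 7L,
                        min_count = 3L, max_count = 15L),
            motif_block("AAGGG", variable = TRUE, ref_count = 15L,
                        min_count = 5L, max_count = 25L)),
      anchor5 = "TTGACCATGGTTGAC", anchor3 = "CATGGACTTGACCAT",
      prefix_ref = "CTTGATCG", suffix_ref = "TGCCATTA",
      chr_start = 300L, chr_end = 500L),
    DICOPY = str_locus(
      "DICOPY",
      motif_block("CA", variable = TRUE, ref_count = 21L,
                  min_count = 11L, max_count = 30L),
      anchor5 = "GGCTTAACGGCTTAA", anchor3 = "AACGGTTCAACGGTT",
      prefix_ref = "TTGGTATG", suffix_ref = "ATGGTTGG",
      copy_count = 2L, chr_start = 600L, chr_end = 800L)
  )
}

# Genotype with chosen variable-block counts for one locus of a panel.
set_genotype <- function(genotype, locus, counts_matrix) {
  genotype[[locus]] <- counts_matrix
  genotype
}

# Compare a called genotype against truth, copy order ignored.
genotype_matches <- function(truth, called) {
  if (is.null(called) || is.null(truth)) return(FALSE)
  if (!all(dim(truth) == dim(called))) return(FALSE)
  key <- function(m) {
    paste(apply(m[order(rowSums(m), apply(m, 1, paste, collapse = ",")), ,
                 drop = FALSE], 1, paste, collapse = ","), collapse = ";")
  }
  key(truth) == key(called)
}

# Write a positions-file fixture and return its path.
write_positions_fixture <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "name\taliases\tposition\tmutation\thaplogroup\tflags"
  writeLines(c(header, rows), path)
  path
}

# Independent brute-force minimum/maximum parsimony cost by recursive
# enumeration of copy assignments (distinct from the package's
# permutation-matrix route). The maximum is taken after multiset
# cancellation of identical copies, mirroring the convention that an
# unchanged copy contributes no steps.
brute_force_steps <- function(a, b) {
  enumerate <- function(a, b) {
    if (!nrow(a)) return(c(0, 0))
    best <- Inf
    worst <- -Inf
    recurse <- function(rows_a, avail_b, acc) {
      if (!length(rows_a)) {
        best <<- min(best, acc)
        worst <<- max(worst, acc)
        return(invisible())
      }
      i <- rows_a[1]
      for (j in avail_b) {
        recurse(rows_a[-1], setdiff(avail_b, j),
                acc + sum(abs(a[i, ] - b[j, ])))
      }
    }
    recurse(seq_len(nrow(a)), seq_len(nrow(a)), 0)
    c(best, worst)
  }
  keys_a <- apply(a, 1, paste, collapse = "/")
  keys_b <- apply(b, 1, paste, collapse = "/")
  keep_a <- rep(TRUE, nrow(a))
  keep_b <- rep(TRUE, nrow(b))
  for (i in seq_along(keys_a)) {
    hit <- which(keep_b & keys_b == keys_a[i])
    if (length(hit)) {
      keep_a[i] <- FALSE
      keep_b[hit[1]] <- FALSE
    }
  }
  c(min = enumerate(a, b)[1],
    max = enumerate(a[keep_a, , drop = FALSE],
                    b[keep_b, , drop = FALSE])[2])
}

# Uniform random DNA string (uses the current RNG stream).
random_dna_local <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random in-structure sequence for a locus, with the drawn counts.
random_in_structure <- function(locus) {
  b <- locus$blocks
  counts <- vapply(which(b$variable), function(i) {
    sample(seq(b$min_count[i], b$max_count[i]), 1)
  }, integer(1))
  list(counts = counts,
       sequence = locus_sequence(locus, counts, with_flanks = TRUE))
}
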