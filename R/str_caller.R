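#' Tabulate unique read sequences per locus
#'
#' Assigns each read of one sequencing end to a panel locus when its 5'
#' anchor (forward orientation) or the reverse complement of its 3' anchor
#' (reverse orientation) matches within `min_anchor_match` mismatches, and
#' the matching 3' anchor is found at the read end. The stored sequence is
#' the anchor-trimmed insert in forward orientation; strand of origin is
#' counted separately, mirroring the per-end tables of sequence-based STR
#' genotyping tools.
#'
#' @param reads Character vector of reads (one end), a `list(seq=, qual=)`
#'   as from [read_fastq()], or a FASTQ path.
#' @param panel Named list of `str_locus`.
#' @param min_anchor_match Maximum mismatches tolerated per 15-bp anchor.
#' @return A list with `counts`: a `data.frame` (locus, sequence, forward,
#'   reverse, total) sorted by locus and descending total, and `unassigned`:
#'   the number of reads matching no locus.
#' @export
tabulate_sequences <- function(reads, panel, min_anchor_match = 1L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)$seq
  }
  if (is.list(reads)) reads <- reads$seq
  tab <- table(reads)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  a5 <- vapply(panel, `[[`, "", "anchor5")
  a3 <- vapply(panel, `[[`, "", "anchor3")
  # raw-byte anchor matrix for cheap mismatch-tolerant matching
  a5_raw <- vapply(a5, charToRaw, raw(15))
  rc_uniq <- if (length(uniq)) revcomp(uniq) else character()
  anchor5_candidates <- function(head15) {
    exact <- which(a5 == head15)
    if (length(exact) || min_anchor_match == 0L) return(exact)
    if (nchar(head15) != 15L) return(integer())
    which(colSums(a5_raw != charToRaw(head15)) <= min_anchor_match)
  }
  match_locus <- function(seq) {
    cand <- anchor5_candidates(substr(seq, 1, 15))
    for (i in cand) {
      hit <- find_anchor3(seq, a3[i], min_anchor_match)
      if (!is.na(hit)) return(list(i = i, insert = substr(seq, 16, hit - 1L)))
    }
    NULL
  }
  rows <- list()
  unassigned <- 0L
  for (k in seq_along(uniq)) {
    m <- match_locus(uniq[k])
    strand <- "forward"
    if (is.null(m)) {
      m <- match_locus(rc_uniq[k])
      strand <- "reverse"
    }
    if (is.null(m)) {
      unassigned <- unassigned + cnt[k]
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = names(panel)[m$i], sequence = m$insert,
      forward = if (strand == "forward") cnt[k] else 0L,
      reverse = if (strand == "reverse") cnt[k] else 0L,
      stringsAsFactors = FALSE)
  }
  counts <- if (length(rows)) {
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(cbind(forward, reverse) ~ locus + sequence,
                            data = df, FUN = sum)
    agg$total <- agg$forward + agg$reverse
    agg <- agg[order(agg$locus, -agg$total, agg$sequence), ]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(locus = character(), sequence = character(),
               forward = integer(), reverse = integer(), total = integer(),
               stringsAsFactors = FALSE)
  }
  list(counts = counts, unassigned = unassigned)
}

# Position of the 3' anchor near the read end (start index), NA if absent.
find_anchor3 <- function(seq, anchor, mm, slack = 6L) {
  n <- nchar(seq)
  w <- nchar(anchor)
  for (start in seq(n - w + 1L, max(16L, n - w + 1L - slack))) {
    if (start < 16L) break
    if (hamming(substr(seq, start, start + w - 1L), anchor) <= mm) {
      return(start)
    }
  }
  NA_integer_
}

#' Decompose an anchor-trimmed sequence into prefix, repeats and suffix
#'
#' Greedy left-to-right parse of the configured block structure: fixed
#' blocks and interruptions must match exactly, variable blocks are matched
#' maximally. Candidate prefix lengths are tried near the reference flank
#' length (reference length first); the parse succeeds only when the
#' remaining suffix length also lies within `flank_tol` of the reference.
#' Substitutions in the flanks relative to the reference (isoallele flank
#' variants) are listed in `variants` rather than causing failure.
#'
#' @param locus An `str_locus`.
#' @param sequence Anchor-trimmed insert sequence.
#' @param flank_tol Tolerated deviation (bp) of either flank from its
#'   reference length; beyond it the sequence cannot be the actual amplicon
#'   (homology capture or heavy error) and a failure object is returned.
#' @return On success, a `repeat_decomposition`: list with `prefix`,
#'   `blocks` (`data.frame` motif/count/variable), `suffix`, `allele_call`
#'   (sum of variable-block counts) and `variants`. On failure, a list of
#'   class `decomposition_failure` with a `reason`
#'   (`flank_too_short`, `flank_too_long`, `block_missing`).
#' @export
decompose <- function(locus, sequence, flank_tol = 3L) {
  P <- nchar(locus$prefix_ref)
  S <- nchar(locus$suffix_ref)
  b <- locus$blocks
  n <- nchar(sequence)
  fail_reason <- NULL
  nb <- nrow(b)
  # maximal-munch parse with backtracking: variable blocks take as many
  # units as possible, giving repeats back when the remaining blocks or the
  # suffix-length tolerance cannot otherwise be satisfied (the unique
  # leftmost-longest parse, needed when one motif is a prefix of the next,
  # e.g. GT[n]GTCT[n])
  parse_blocks <- function(i, pos, counts) {
    if (i > nb) {
      slen <- n - pos + 1L
      if (abs(slen - S) <= flank_tol) return(list(counts = counts,
                                                  end = pos))
      if (is.null(fail_reason)) {
        fail_reason <<- if (slen < S) "flank_too_short" else "flank_too_long"
      }
      return(NULL)
    }
    if (!b$variable[i]) {
      fixed <- strrep(b$motif[i], b$ref_count[i])
      w <- nchar(fixed)
      if (substr(sequence, pos, pos + w - 1L) != fixed) {
        if (is.null(fail_reason)) fail_reason <<- "block_missing"
        return(NULL)
      }
      counts[i] <- b$ref_count[i]
      return(parse_blocks(i + 1L, pos + w, counts))
    }
    u <- b$unit_len[i]
    cmax <- 0L
    p <- pos
    while (p + u - 1L <= n && substr(sequence, p, p + u - 1L) == b$motif[i]) {
      cmax <- cmax + 1L
      p <- p + u
    }
    if (cmax == 0L) {
      if (is.null(fail_reason)) fail_reason <<- "block_missing"
      return(NULL)
    }
    for (ccount in seq(cmax, 1L)) {
      counts[i] <- ccount
      res <- parse_blocks(i + 1L, pos + ccount * u, counts)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  deltas <- c(0L, as.vector(rbind(seq_len(flank_tol), -seq_len(flank_tol))))
  for (dp in deltas) {
    plen <- P + dp
    if (plen < 0L || plen > n) next
    res <- parse_blocks(1L, plen + 1L, integer(nb))
    if (is.null(res)) next
    counts <- res$counts
    prefix <- substr(sequence, 1L, plen)
    suffix <- substr(sequence, res$end, n)
    variants <- c(flank_variants(prefix, locus$prefix_ref, "prefix"),
                  flank_variants(suffix, locus$suffix_ref, "suffix"))
    blocks <- data.frame(motif = b$motif, count = counts,
                         variable = b$variable, stringsAsFactors = FALSE)
    return(structure(list(
      prefix = prefix, blocks = blocks, suffix = suffix,
      allele_call = sum(counts[b$variable]), variants = variants
    ), class = "repeat_decomposition"))
  }
  structure(list(reason = fail_reason %||% "flank_too_short"),
            class = "decomposition_failure")
}

flank_variants <- function(obs, ref, side) {
  if (obs == ref) return(character())
  if (nchar(obs) != nchar(ref)) {
    return(sprintf("%s_len:%+d", side, nchar(obs) - nchar(ref)))
  }
  o <- strsplit(obs, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  idx <- which(o != r)
  sprintf("%s:%d%s>%s", side, idx, r[idx], o[idx])
}

#' Re-expand a repeat decomposition to its sequence
#'
#' Inverse of [decompose()]: concatenating prefix, expanded blocks and
#' suffix reproduces the decomposed input byte-for-byte.
#'
#' @param dec A `repeat_decomposition`.
#' @return The anchor-trimmed sequence.
#' @export
expand_decomposition <- function(dec) {
  paste0(dec$prefix,
         paste(strrep(dec$blocks$motif, dec$blocks$count), collapse = ""),
         dec$suffix)
}

#' Decomposition string in bracketed repeat notation
#'
#' @param dec A `repeat_decomposition`.
#' @return E.g. `"CTTGA|AAAGG[7]AAGGG[15]|TGCAT"`.
#' @export
format_decomposition <- function(dec) {
  core <- paste(sprintf("%s[%d]", dec$blocks$motif, dec$blocks$count),
                collapse = "")
  paste(dec$prefix, core, dec$suffix, sep = "|")
}

# Default stutter thresholds (fraction of parent depth at n-1) by motif
# unit length; n-2 candidates use half the threshold.
default_stutter_thresholds <- c(`2` = 0.5, `3` = 0.15, `4` = 0.15,
                                `5` = 0.10, `6` = 0.10)

#' Flag stutter sequences among decomposed candidates
#'
#' A candidate is flagged as stutter when a higher-count candidate exists
#' whose decomposition differs only by one variable block carrying 1 or 2
#' more repeats (identical flanks and other blocks), and the candidate's
#' read count is below `threshold * parent count` (threshold chosen by the
#' motif unit length of the differing block; halved for n-2). The
#' highest-count candidate is never flagged. For multi-copy loci, the
#' `copy_count` highest-count distinct survivors are retained.
#'
#' @param counts `data.frame` of sequence counts for one locus (columns
#'   `sequence`, `total`).
#' @param locus The `str_locus`.
#' @param thresholds Named threshold vector by unit length.
#' @param decomps Optional list of decompositions aligned with `counts`;
#'   computed when missing (failures drop the candidate).
#' @return A list with `genuine` and `stutter` data.frames (the input rows
#'   plus an `allele_call` column), each sorted by descending count.
#' @export
filter_stutter <- function(counts, locus,
                           thresholds = default_stutter_thresholds,
                           decomps = NULL) {
  if (!nrow(counts)) {
    return(list(genuine = counts, stutter = counts))
  }
  counts <- counts[order(-counts$total, counts$sequence), , drop = FALSE]
  if (is.null(decomps)) {
    decomps <- lapply(counts$sequence, function(s) decompose(locus, s))
  }
  valid <- vapply(decomps, inherits, logical(1), "repeat_decomposition")
  counts <- counts[valid, , drop = FALSE]
  decomps <- decomps[valid]
  if (!nrow(counts)) return(list(genuine = counts, stutter = counts))
  counts$allele_call <- vapply(decomps, `[[`, numeric(1), "allele_call")
  n <- nrow(counts)
  is_stutter <- logical(n)
  vunits <- locus$blocks$unit_len[locus$blocks$variable]
  key <- function(d) paste(d$prefix, d$suffix,
                           paste(d$blocks$count[!d$blocks$variable],
                                 collapse = ","), sep = "|")
  vc <- lapply(decomps, function(d) d$blocks$count[d$blocks$variable])
  ctx <- vapply(decomps, key, character(1))
  for (i in seq(2L, length.out = max(0L, n - 1L))) {
    for (j in seq_len(i - 1L)) {       # j has the higher count
      if (is_stutter[j]) next
      if (ctx[i] != ctx[j]) next
      diff <- vc[[j]] - vc[[i]]
      nz <- which(diff != 0L)
      if (length(nz) != 1L || !diff[nz] %in% c(1L, 2L)) next
      thr <- thresholds[as.character(vunits[nz])]
      if (is.na(thr)) thr <- 0.15
      if (diff[nz] == 2L) thr <- thr / 2
      if (counts$total[i] < thr * counts$total[j]) {
        is_stutter[i] <- TRUE
        break
      }
    }
  }
  genuine <- counts[!is_stutter, , drop = FALSE]
  genuine <- utils::head(genuine, locus$copy_count)
  list(genuine = genuine, stutter = counts[is_stutter, , drop = FALSE])
}

#' Call one Y-STR locus from a single sequencing end
#'
#' Candidates are examined in order of decreasing read count (ties broken
#' lexicographically). Each is validated by [decompose()]; only the top
#' `4 * copy_count` candidates are considered, and if none validates, or
#' the locus total is below `min_reads`, the result is `no_data`. Validated
#' candidates pass the stutter filter; the `copy_count` strongest genuine
#' survivors yield the call. For indistinguishable multi-copy loci with
#' fewer distinct survivors than copies, copies are allocated to survivors
#' by read-depth share (equal-allele copies collapse into one sequence of
#' roughly multiple depth), and calls are reported sorted from short to
#' long allele.
#'
#' @param counts Per-locus `data.frame` from [tabulate_sequences()].
#' @param locus The `str_locus`.
#' @param min_reads Minimum total read count; below it the locus is
#'   `no_data`.
#' @param thresholds Stutter thresholds, see [filter_stutter()].
#' @param flank_tol Passed to [decompose()].
#' @param source Label recorded as the read end of origin.
#' @return An `allele_call`: list with `locus`, `status` (`"called"` or
#'   `"no_data"`), `calls` (each with `allele`, `decomposition`, `depth`)
#'   and `source`.
#' @export
call_locus <- function(counts, locus, min_reads = 10L,
                       thresholds = default_stutter_thresholds,
                       flank_tol = 3L, source = "R1") {
  no_data <- structure(list(locus = locus$name, status = "no_data",
                            calls = list(), source = source),
                       class = "allele_call")
  if (is.null(counts) || !nrow(counts) || sum(counts$total) < min_reads) {
    return(no_data)
  }
  counts <- counts[order(-counts$total, counts$sequence), , drop = FALSE]
  top <- utils::head(counts, 4L * locus$copy_count)
  decomps <- lapply(top$sequence, function(s) {
    decompose(locus, s, flank_tol = flank_tol)
  })
  valid <- vapply(decomps, inherits, logical(1), "repeat_decomposition")
  if (!any(valid)) return(no_data)
  flt <- filter_stutter(top[valid, , drop = FALSE], locus,
                        thresholds = thresholds, decomps = decomps[valid])
  gen <- flt$genuine
  if (!nrow(gen)) return(no_data)
  gen_dec <- lapply(gen$sequence, function(s) {
    decompose(locus, s, flank_tol = flank_tol)
  })
  take <- seq_len(min(nrow(gen), locus$copy_count))
  gen <- gen[take, , drop = FALSE]
  gen_dec <- gen_dec[take]
  # allocate copies to survivors by depth share, each survivor >= 1 copy
  mult <- rep(1L, nrow(gen))
  extra <- locus$copy_count - nrow(gen)
  if (extra > 0L) {
    share <- gen$total / sum(gen$total)
    add <- round_half_up(share * extra)
    while (sum(add) > extra) add[which.max(add)] <- add[which.max(add)] - 1L
    while (sum(add) < extra) add[which.max(share)] <- add[which.max(share)] + 1L
    mult <- mult + add
  }
  calls <- list()
  for (i in seq_len(nrow(gen))) {
    for (k in seq_len(mult[i])) {
      calls[[length(calls) + 1L]] <- list(
        allele = gen_dec[[i]]$allele_call,
        decomposition = gen_dec[[i]],
        depth = gen$total[i])
    }
  }
  ord <- order(vapply(calls, `[[`, numeric(1), "allele"),
               vapply(calls, function(cl) {
                 paste(cl$decomposition$blocks$count, collapse = ",")
               }, character(1)))
  structure(list(locus = locus$name, status = "called", calls = calls[ord],
                 source = source), class = "allele_call")
}

#' Paired-end consensus of two single-end allele calls
#'
#' Sequencing error accumulates with cycle number, so when the two ends
#' disagree, the end whose repeat region starts closer to its anchor (fewer
#' flanking bases sequenced first) is the more reliable one. Equal offsets
#' fall back to the higher supporting read depth; a `no_data` end defers to
#' the other.
#'
#' @param call_r1,call_r2 `allele_call` objects from the two ends.
#' @param offset_r1,offset_r2 Distance (bp) from each end's anchor to the
#'   start of the repeat region; defaults are the reference flank lengths
#'   (prefix for R1, suffix for R2).
#' @param locus Optional `str_locus` used to fill default offsets.
#' @return The selected `allele_call`, with `source = "consensus"` when the
#'   ends agree.
#' @export
paired_end_consensus <- function(call_r1, call_r2, offset_r1 = NULL,
                                 offset_r2 = NULL, locus = NULL) {
  if (!is.null(locus)) {
    offset_r1 <- offset_r1 %||% nchar(locus$prefix_ref)
    offset_r2 <- offset_r2 %||% nchar(locus$suffix_ref)
  }
  if (call_r1$status == "no_data" && call_r2$status == "no_data") {
    out <- call_r1
  } else if (call_r2$status == "no_data") {
    out <- call_r1
  } else if (call_r1$status == "no_data") {
    out <- call_r2
  } else if (identical(call_signature(call_r1), call_signature(call_r2))) {
    out <- call_r1
    out$source <- "consensus"
    return(out)
  } else if (is.null(offset_r1) || is.null(offset_r2)) {
    stop("offsets are required to arbitrate differing calls")
  } else if (offset_r1 < offset_r2) {
    out <- call_r1
  } else if (offset_r2 < offset_r1) {
    out <- call_r2
  } else {
    d1 <- sum(vapply(call_r1$calls, `[[`, numeric(1), "depth"))
    d2 <- sum(vapply(call_r2$calls, `[[`, numeric(1), "depth"))
    out <- if (d1 >= d2) call_r1 else call_r2
  }
  out
}

# Allele + block-split signature used for equality of calls.
call_signature <- function(call) {
  if (call$status != "called") return("no_data")
  paste(vapply(call$calls, function(cl) {
    paste(cl$decomposition$blocks$count, collapse = ",")
  }, character(1)), collapse = ";")
}

#' Assemble per-locus consensus calls into a haplotype profile
#'
#' @param calls Named list of `allele_call`, one per panel locus.
#' @param panel Named list of `str_locus` (defines the locus universe; loci
#'   without a call entry become `no_data`).
#' @param sample_id Sample identifier.
#' @return A `haplotype_profile`: list with `sample_id`, `calls`,
#'   `n_called`, `n_no_data`.
#' @export
assemble_profile <- function(calls, panel, sample_id = "sample") {
  full <- lapply(names(panel), function(locus) {
    calls[[locus]] %||% structure(
      list(locus = locus, status = "no_data", calls = list(),
           source = "consensus"), class = "allele_call")
  })
  names(full) <- names(panel)
  n_called <- sum(vapply(full, function(cl) cl$status == "called",
                         logical(1)))
  structure(list(sample_id = sample_id, calls = full, n_called = n_called,
                 n_no_data = length(full) - n_called),
            class = "haplotype_profile")
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat(sprintf("<haplotype_profile> %s: %d called, %d no_data\n",
              x$sample_id, x$n_called, x$n_no_data))
  invisible(x)
}

#' Genotype matrices of a called haplotype profile
#'
#' Converts called loci to the genotype representation used by the
#' simulator and the mutation analysis: per locus an integer matrix of
#' variable-block repeat counts (rows = copies, sorted as called).
#'
#' @param profile A `haplotype_profile`.
#' @return Named list of matrices; `no_data` loci are omitted.
#' @export
profile_genotypes <- function(profile) {
  out <- list()
  for (locus in names(profile$calls)) {
    call <- profile$calls[[locus]]
    if (call$status != "called") next
    rows <- lapply(call$calls, function(cl) {
      d <- cl$decomposition
      d$blocks$count[d$blocks$variable]
    })
    out[[locus]] <- do.call(rbind, rows)
  }
  out
}

#' Call a full Y-STR haplotype from paired FASTQ input
#'
#' End-to-end convenience wrapper: tabulates both ends, calls every panel
#' locus per end, forms the paired-end consensus and assembles the profile.
#'
#' @param r1,r2 Reads of each end (paths, character vectors, or
#'   [read_fastq()] lists).
#' @param panel Named list of `str_locus`.
#' @param sample_id Sample identifier.
#' @param min_reads,min_anchor_match,thresholds,flank_tol Tuning parameters,
#'   see [call_locus()] and [tabulate_sequences()].
#' @return A `haplotype_profile`.
#' @export
call_str_sample <- function(r1, r2, panel, sample_id = "sample",
                            min_reads = 10L, min_anchor_match = 1L,
                            thresholds = default_stutter_thresholds,
                            flank_tol = 3L) {
  t1 <- tabulate_sequences(r1, panel, min_anchor_match)$counts
  t2 <- tabulate_sequences(r2, panel, min_anchor_match)$counts
  calls <- lapply(panel, function(l) {
    c1 <- call_locus(t1[t1$locus == l$name, , drop = FALSE], l,
                     min_reads = min_reads, thresholds = thresholds,
                     flank_tol = flank_tol, source = "R1")
    c2 <- call_locus(t2[t2$locus == l$name, , drop = FALSE], l,
                     min_reads = min_reads, thresholds = thresholds,
                     flank_tol = flank_tol, source = "R2")
    paired_end_consensus(c1, c2, locus = l)
  })
  assemble_profile(calls, panel, sample_id = sample_id)
}

#' Write a haplotype profile as CSV
#'
#' One row per locus: status, allele calls joined `";"` (sorted short to
#' long for indistinguishable multi-copy loci), decomposition strings and
#' flank variants.
#'
#' @param profile A `haplotype_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  rows <- lapply(profile$calls, function(call) {
    data.frame(
      sample = profile$sample_id, locus = call$locus, status = call$status,
      calls = paste(vapply(call$calls, function(cl) {
        format(cl$allele)
      }, character(1)), collapse = ";"),
      decomposition = paste(vapply(call$calls, function(cl) {
        format_decomposition(cl$decomposition)
      }, character(1)), collapse = ";"),
      variants = paste(unique(unlist(lapply(call$calls, function(cl) {
        cl$decomposition$variants
      }))), collapse = ";"),
      source = call$source, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
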