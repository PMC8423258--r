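#' Pile up base counts at Y-SNP positions
#'
#' Assigns reads to SNP amplicons by their 15-bp anchor (forward orientation
#' or reverse complement) and tallies, per SNP, the bases observed at the
#' SNP offset among reads whose base quality there is at least
#' `min_base_quality`. Reads too short to cover the offset count as
#' uncovered.
#'
#' @param reads Reads of one or both ends: a character vector, a
#'   `list(seq=, qual=)` from [read_fastq()], a FASTQ path, or a list of
#'   several of these (e.g. `list(r1, r2)`).
#' @param amplicons SNP amplicon table from [snp_amplicons()].
#' @param min_base_quality Minimum Phred base quality (default Q20).
#' @return A `data.frame` with one row per SNP: columns `name`, `A`, `C`,
#'   `G`, `T`, `uncovered`.
#' @export
pileup_snp <- function(reads, amplicons, min_base_quality = 20L) {
  inputs <- if (is.list(reads) && !("seq" %in% names(reads))) reads
            else list(reads)
  counts <- matrix(0L, nrow = nrow(amplicons), ncol = 4L,
                   dimnames = list(amplicons$name, DNA_BASES))
  uncovered <- stats::setNames(integer(nrow(amplicons)), amplicons$name)
  for (input in inputs) {
    if (is.character(input) && length(input) == 1L && file.exists(input)) {
      input <- read_fastq(input)
    }
    if (is.character(input)) input <- list(seq = input, qual = NULL)
    seqs <- input$seq
    quals <- input$qual
    if (!length(seqs)) next
    head15 <- substr(seqs, 1, 15)
    fwd <- match(head15, amplicons$anchor5)
    rc <- revcomp(seqs)
    rev_ <- match(substr(rc, 1, 15), amplicons$anchor5)
    for (r in seq_along(seqs)) {
      i <- fwd[r]
      reverse <- FALSE
      if (is.na(i)) {
        i <- rev_[r]
        reverse <- TRUE
      }
      if (is.na(i)) next
      off <- amplicons$offset[i]
      len <- nchar(seqs[r])
      if (off > len) {
        uncovered[i] <- uncovered[i] + 1L
        next
      }
      base <- if (reverse) substr(rc[r], off, off)
              else substr(seqs[r], off, off)
      # quality position in the raw read coordinates
      qpos <- if (reverse) len - off + 1L else off
      q <- if (is.null(quals)) Inf
           else utf8ToInt(substr(quals[r], qpos, qpos)) - 33L
      if (q < min_base_quality) next
      if (base %in% DNA_BASES) counts[i, base] <- counts[i, base] + 1L
    }
  }
  out <- data.frame(name = amplicons$name, counts,
                    uncovered = unname(uncovered), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call the state of one Y-SNP
#'
#' Threshold-based calling: a SNP is reported only with at least
#' `min_reads` quality-passing reads, a majority base reaching
#' `min_fraction` of them, and that majority base equal to the marker's
#' ancestral or derived allele; otherwise the result is `no_call`.
#'
#' @param base_counts Named numeric vector of base counts (`A`,`C`,`G`,`T`)
#'   or a one-row slice of the [pileup_snp()] output.
#' @param snp One-row SNP definition (fields `name`, `ancestral`,
#'   `derived`).
#' @param min_reads Minimum depth (default 10).
#' @param min_fraction Minimum majority fraction (default 0.90).
#' @return A `snp_call`: list with `name`, `state` (`ancestral`, `derived`
#'   or `no_call`), `depth`, `majority_fraction`, `base`.
#' @export
call_snp <- function(base_counts, snp, min_reads = 10L,
                     min_fraction = 0.90) {
  if (is.data.frame(base_counts)) {
    base_counts <- unlist(base_counts[1, DNA_BASES])
  }
  base_counts <- base_counts[DNA_BASES]
  depth <- sum(base_counts)
  out <- list(name = snp$name, state = "no_call", depth = depth,
              majority_fraction = if (depth > 0) max(base_counts) / depth
                                  else NA_real_,
              base = NA_character_)
  if (depth >= min_reads) {
    maj <- DNA_BASES[which.max(base_counts)]
    frac <- base_counts[[maj]] / depth
    if (frac >= min_fraction) {
      out$base <- maj
      out$majority_fraction <- frac
      if (maj == snp$derived) out$state <- "derived"
      else if (maj == snp$ancestral) out$state <- "ancestral"
    }
  }
  structure(out, class = "snp_call")
}

#' Call all Y-SNPs of a sample
#'
#' @param reads See [pileup_snp()].
#' @param snps SNP `data.frame` (see [read_positions_file()]).
#' @param min_reads,min_fraction,min_base_quality Calling thresholds.
#' @return A `data.frame` with one row per SNP: `name`, `haplogroup`,
#'   `private`, `state`, `depth`, `majority_fraction`.
#' @export
call_snp_sample <- function(reads, snps, min_reads = 10L,
                            min_fraction = 0.90, min_base_quality = 20L) {
  amps <- snp_amplicons(snps)
  pile <- pileup_snp(reads, amps, min_base_quality = min_base_quality)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    call <- call_snp(pile[pile$name == snps$name[i], , drop = FALSE],
                     snps[i, ], min_reads = min_reads,
                     min_fraction = min_fraction)
    data.frame(name = snps$name[i], haplogroup = snps$haplogroup[i],
               private = snps$private[i], state = call$state,
               depth = call$depth,
               majority_fraction = call$majority_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign the deepest supported subhaplogroup
#'
#' The terminal assignment is the deepest tree node carrying at least one
#' derived call whose root path contains no contradicted node (a node where
#' ancestral calls outnumber derived calls). Ties are broken by the larger
#' number of supporting derived markers along the path, then
#' lexicographically. Markers with unknown phylogenetic position and
#' private markers are reported upstream but never influence the
#' assignment. A sample with no derived call is `unresolved`.
#'
#' @param snp_calls `data.frame` from [call_snp_sample()] (columns
#'   `haplogroup`, `private`, `state`).
#' @param tree A `haplogroup_tree`.
#' @return A `haplogroup_assignment`: list with `terminal`, `depth`,
#'   `path`, `supporting` (derived node count along the path),
#'   `conflicts` (`data.frame` of contradicted nodes).
#' @export
assign_haplogroup <- function(snp_calls, tree) {
  usable <- snp_calls[!snp_calls$private &
                        snp_calls$haplogroup %in% tree$label &
                        snp_calls$state %in% c("ancestral", "derived"), ,
                      drop = FALSE]
  derived_n <- tapply(usable$state == "derived", usable$haplogroup, sum)
  ancestral_n <- tapply(usable$state == "ancestral", usable$haplogroup, sum)
  node_score <- function(lab) {
    d <- unname(derived_n[lab]); a <- unname(ancestral_n[lab])
    c(der = if (is.na(d)) 0L else d, anc = if (is.na(a)) 0L else a)
  }
  contradicted <- function(lab) {
    s <- node_score(lab)
    s["anc"] > s["der"]
  }
  cand <- names(derived_n)[!is.na(derived_n) & derived_n > 0]
  cand <- cand[!vapply(cand, contradicted, logical(1))]
  ok <- vapply(cand, function(lab) {
    !any(vapply(tree_path(tree, lab), contradicted, logical(1)))
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) {
    return(structure(list(terminal = "unresolved", depth = 0L,
                          path = character(), supporting = 0L,
                          conflicts = conflict_table(usable, tree)),
                     class = "haplogroup_assignment"))
  }
  depth <- tree_depth(tree, cand)
  support <- vapply(cand, function(lab) {
    path <- tree_path(tree, lab)
    sum(vapply(path, function(p) node_score(p)[["der"]], numeric(1)))
  }, numeric(1))
  ord <- order(-depth, -support, cand)
  best <- cand[ord[1]]
  structure(list(terminal = best, depth = tree_depth(tree, best),
                 path = tree_path(tree, best),
                 supporting = support[ord[1]],
                 conflicts = conflict_table(usable, tree)),
            class = "haplogroup_assignment")
}

conflict_table <- function(usable, tree) {
  if (!nrow(usable)) {
    return(data.frame(node = character(), derived = integer(),
                      ancestral = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(derived = state == "derived",
                                ancestral = state == "ancestral") ~
                            haplogroup, data = usable, FUN = sum)
  bad <- agg[agg$ancestral > agg$derived & agg$derived > 0, , drop = FALSE]
  data.frame(node = bad$haplogroup, derived = bad$derived,
             ancestral = bad$ancestral, stringsAsFactors = FALSE)
}

#' @export
print.haplogroup_assignment <- function(x, ...) {
  cat(sprintf("<haplogroup_assignment> %s (depth %d, %d supporting)\n",
              x$terminal, x$depth, x$supporting))
  invisible(x)
}

#' Branch-depth difference between two haplogroup assignments
#'
#' Signed number of phylogenetic branches separating two terminal labels in
#' depth, e.g. to quantify how much deeper sequencing-based assignment
#' reaches than an external (capillary) reference label.
#'
#' @param a,b Haplogroup labels or `haplogroup_assignment` objects.
#' @param tree A `haplogroup_tree`.
#' @return Integer `depth(a) - depth(b)`.
#' @export
branch_depth_delta <- function(a, b, tree) {
  lab <- function(x) if (inherits(x, "haplogroup_assignment")) x$terminal
                     else x
  tree_depth(tree, lab(a)) - tree_depth(tree, lab(b))
}
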