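#' Construct a repeat-motif block
#'
#' A Y-STR locus structure is an ordered series of blocks: variable repeat
#' motifs (whose repeat counts carry the allele call), fixed repeat motifs,
#' and fixed interruption stretches between them. Only variable blocks
#' contribute to the allele designation.
#'
#' @param motif Nucleotide motif, e.g. `"AAAGG"`. For interruption stretches
#'   this is the full fixed sequence.
#' @param variable Logical; may the repeat count vary between chromosomes?
#' @param ref_count Repeat count in the reference sequence. Interruptions
#'   always have `ref_count = 1`.
#' @param min_count,max_count Allowed repeat-count range for variable blocks
#'   (used by the simulator to bound mutation walks).
#' @param interruption Logical; `TRUE` marks a fixed non-repetitive stretch
#'   (the `N[k]` notation of sequence-based STR nomenclature).
#' @return A one-row `data.frame` describing the block.
#' @export
motif_block <- function(motif, variable = FALSE, ref_count = 1L,
                        min_count = 1L, max_count = ref_count,
                        interruption = FALSE) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be an ACGT string")
  unit_len <- nchar(motif)
  if (interruption) {
    variable <- FALSE
    ref_count <- 1L
    min_count <- max_count <- 1L
  } else if (!(unit_len >= 2L && unit_len <= 6L)) {
    stop("repeat motif unit length must be 2-6 bp, got ", unit_len)
  }
  if (ref_count < 1L) stop("ref_count must be >= 1")
  if (variable && ref_count < 3L) {
    stop("variable repeat blocks require at least three homogeneous ",
         "repetitions (ref_count >= 3)")
  }
  data.frame(motif = motif, unit_len = unit_len, variable = variable,
             ref_count = as.integer(ref_count),
             min_count = as.integer(min_count),
             max_count = as.integer(max_count),
             interruption = interruption, stringsAsFactors = FALSE)
}

#' Define a Y-STR locus
#'
#' Full structural description of one locus in the panel: 15-bp anchor
#' sequences used for read assignment, reference flanking regions (prefix on
#' the 5' side, suffix on the 3' side of the repeat region), the ordered
#' block structure, the copy count (1 for single-copy markers, 2 or 4 for
#' multi-copy markers in chrY palindromes) and hg19 coordinates.
#'
#' @param name Locus name, e.g. `"DYS463"`.
#' @param blocks `data.frame` of blocks, rows from [motif_block()], in 5'->3'
#'   order.
#' @param anchor5,anchor3 Exact 15-bp anchor sequences.
#' @param prefix_ref,suffix_ref Reference flanking sequences between anchor
#'   and repeat region.
#' @param copy_count Number of locus copies (1, 2 or 4).
#' @param chr_start,chr_end 1-based inclusive hg19 chrY coordinates.
#' @param repeat_type `"simple"`, `"compound"` or `"complex"`; inferred from
#'   the block structure when `NULL` (one variable motif = simple, several
#'   adjacent variable motifs = compound, interrupted = complex).
#' @param distinguishable_copies Logical; can copies be told apart by their
#'   flanking sequence (then they are treated as separate loci)?
#' @return An object of class `str_locus`.
#' @export
str_locus <- function(name, blocks, anchor5, anchor3,
                      prefix_ref = "", suffix_ref = "",
                      copy_count = 1L, chr_start = NA_integer_,
                      chr_end = NA_integer_, repeat_type = NULL,
                      distinguishable_copies = FALSE) {
  anchor5 <- toupper(anchor5); anchor3 <- toupper(anchor3)
  prefix_ref <- toupper(prefix_ref); suffix_ref <- toupper(suffix_ref)
  if (nchar(anchor5) != 15L || nchar(anchor3) != 15L) {
    stop("locus ", name, ": anchors must be exactly 15 bp")
  }
  if (!copy_count %in% c(1L, 2L, 4L)) {
    stop("locus ", name, ": copy_count must be 1, 2 or 4")
  }
  if (!any(blocks$variable)) {
    stop("locus ", name, ": at least one variable block is required")
  }
  if (is.null(repeat_type)) {
    n_var <- sum(blocks$variable)
    repeat_type <- if (any(blocks$interruption)) "complex"
      else if (n_var > 1L) "compound" else "simple"
  }
  structure(list(
    name = name, copy_count = as.integer(copy_count),
    copy_labels = letters[seq_len(copy_count)],
    anchor5 = anchor5, anchor3 = anchor3,
    prefix_ref = prefix_ref, suffix_ref = suffix_ref,
    blocks = blocks, repeat_type = repeat_type,
    chr_start = as.integer(chr_start), chr_end = as.integer(chr_end),
    distinguishable_copies = isTRUE(distinguishable_copies)
  ), class = "str_locus")
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("<str_locus> %s (%s, %d cop%s): %s\n", x$name, x$repeat_type,
              x$copy_count, if (x$copy_count == 1) "y" else "ies",
              format_structure(x$blocks)))
  invisible(x)
}

# Structure-string grammar, blocks joined by "+":
#   MOTIF[ref:min-max]  variable repeat block
#   MOTIF[k]            fixed repeat block
#   N[k]:SEQ            fixed interruption stretch of k bp
format_structure <- function(blocks) {
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    if (b$interruption) {
      sprintf("N[%d]:%s", nchar(b$motif), b$motif)
    } else if (b$variable) {
      sprintf("%s[%d:%d-%d]", b$motif, b$ref_count, b$min_count, b$max_count)
    } else {
      sprintf("%s[%d]", b$motif, b$ref_count)
    }
  }, character(1))
  paste(parts, collapse = "+")
}

parse_structure <- function(s, locus = "?") {
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (!length(parts)) stop("locus ", locus, ": empty structure string")
  rows <- lapply(parts, function(p) {
    if (grepl("^N\\[(\\d+)\\]:([ACGT]+)$", p)) {
      m <- regmatches(p, regexec("^N\\[(\\d+)\\]:([ACGT]+)$", p))[[1]]
      if (as.integer(m[2]) != nchar(m[3])) {
        stop("locus ", locus, ": interruption length mismatch in '", p, "'")
      }
      motif_block(m[3], interruption = TRUE)
    } else if (grepl("^([ACGT]+)\\[(\\d+):(\\d+)-(\\d+)\\]$", p)) {
      m <- regmatches(p, regexec("^([ACGT]+)\\[(\\d+):(\\d+)-(\\d+)\\]$", p))[[1]]
      motif_block(m[2], variable = TRUE, ref_count = as.integer(m[3]),
                  min_count = as.integer(m[4]), max_count = as.integer(m[5]))
    } else if (grepl("^([ACGT]+)\\[(\\d+)\\]$", p)) {
      m <- regmatches(p, regexec("^([ACGT]+)\\[(\\d+)\\]$", p))[[1]]
      motif_block(m[2], variable = FALSE, ref_count = as.integer(m[3]))
    } else {
      stop("locus ", locus, ": cannot parse structure part '", p, "'")
    }
  })
  do.call(rbind, rows)
}

#' Expand a locus to its reference repeat-region sequence
#'
#' @param locus An `str_locus`.
#' @param counts Optional integer vector of repeat counts for the variable
#'   blocks (in block order); defaults to the reference counts.
#' @param with_flanks Include `prefix_ref`/`suffix_ref`.
#' @param with_anchors Include the 15-bp anchors (implies flanks).
#' @return A nucleotide string.
#' @export
locus_sequence <- function(locus, counts = NULL, with_flanks = TRUE,
                           with_anchors = FALSE) {
  b <- locus$blocks
  n <- b$ref_count
  if (!is.null(counts)) {
    if (length(counts) != sum(b$variable)) {
      stop("counts must have one entry per variable block")
    }
    n[b$variable] <- as.integer(counts)
  }
  core <- paste(vapply(seq_len(nrow(b)), function(i) {
    strrep(b$motif[i], n[i])
  }, character(1)), collapse = "")
  if (with_anchors) {
    paste0(locus$anchor5, locus$prefix_ref, core, locus$suffix_ref,
           locus$anchor3)
  } else if (with_flanks) {
    paste0(locus$prefix_ref, core, locus$suffix_ref)
  } else core
}

#' Read a panel configuration file
#'
#' Tab-separated, one row per locus, columns `name`, `copy_count`,
#' `chr_start`, `chr_end`, `anchor5`, `anchor3`, `prefix_ref`, `suffix_ref`,
#' `structure`, `repeat_type`, `distinguishable`. The structure column uses
#' the grammar described in [str_locus()]: variable blocks
#' `MOTIF[ref:min-max]`, fixed blocks `MOTIF[k]`, interruptions `N[k]:SEQ`,
#' joined with `+`.
#'
#' @param path Path to the TSV file.
#' @return Named list of `str_locus` objects.
#' @seealso [write_panel_config()]
#' @export
read_panel_config <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("name", "copy_count", "chr_start", "chr_end", "anchor5",
                "anchor3", "prefix_ref", "suffix_ref", "structure")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("panel config missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate locus name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  loci <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      str_locus(
        name = row$name,
        blocks = parse_structure(row$structure, locus = row$name),
        anchor5 = row$anchor5, anchor3 = row$anchor3,
        prefix_ref = if (is.na(row$prefix_ref)) "" else row$prefix_ref,
        suffix_ref = if (is.na(row$suffix_ref)) "" else row$suffix_ref,
        copy_count = as.integer(row$copy_count),
        chr_start = as.integer(row$chr_start),
        chr_end = as.integer(row$chr_end),
        repeat_type = if ("repeat_type" %in% names(row) &&
                          nzchar(row$repeat_type)) row$repeat_type else NULL,
        distinguishable_copies = "distinguishable" %in% names(row) &&
          tolower(row$distinguishable) %in% c("true", "1", "yes")
      ),
      error = function(e) {
        stop("panel config line ", i + 1L, " (", row$name, "): ",
             conditionMessage(e), call. = FALSE)
      })
  })
  names(loci) <- df$name
  loci
}

#' Write a panel configuration file
#'
#' Inverse of [read_panel_config()]; `read_panel_config(write_panel_config(x))`
#' reproduces the locus definitions exactly.
#'
#' @param loci Named list of `str_locus` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(loci, path) {
  df <- do.call(rbind, lapply(loci, function(l) {
    data.frame(name = l$name, copy_count = l$copy_count,
               chr_start = l$chr_start, chr_end = l$chr_end,
               anchor5 = l$anchor5, anchor3 = l$anchor3,
               prefix_ref = l$prefix_ref, suffix_ref = l$suffix_ref,
               structure = format_structure(l$blocks),
               repeat_type = l$repeat_type,
               distinguishable = l$distinguishable_copies,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and filter a Y-SNP positions file
#'
#' Tab-separated columns `name`, `aliases` (comma-joined, may be empty),
#' `position` (1-based hg19 chrY), `mutation` (`"A->G"`), `haplogroup`
#' (label or `"unknown"`), `flags` (comma-joined subset of `primer_region`,
#' `private`). Records that could mislead haplogroup determination are
#' excluded and counted by reason: markers inside amplicon primer regions,
#' equal mutations (`A->A`), unknown mutations (a non-ACGT base such as
#' `T->N`), indels (multi-base side) and poly-allelic records (multiple
#' alternative bases). Rows sharing a position are merged; the first listed
#' name is canonical and all aliases remain searchable.
#'
#' @param path Path to the TSV file.
#' @param strict Logical; if `TRUE` malformed rows abort the read instead of
#'   being recorded in the report.
#' @return A list with `snps` (a `data.frame` with columns `name`, `aliases`,
#'   `position`, `ancestral`, `derived`, `haplogroup`, `private`) and
#'   `report`, a named integer vector of exclusion counts by reason.
#' @export
read_positions_file <- function(path, strict = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("name", "position", "mutation")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("positions file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"aliases" %in% names(df)) df$aliases <- ""
  if (!"haplogroup" %in% names(df)) df$haplogroup <- "unknown"
  if (!"flags" %in% names(df)) df$flags <- ""
  df$aliases[is.na(df$aliases)] <- ""
  df$flags[is.na(df$flags)] <- ""
  filter_positions(df, strict = strict)
}

# Core positions filter; also used to show idempotence on kept records.
filter_positions <- function(df, strict = FALSE) {
  reasons <- c(primer_region = 0L, equal_mutation = 0L,
               unknown_mutation = 0L, indel = 0L, poly_allelic = 0L,
               malformed = 0L)
  keep <- logical(nrow(df))
  anc <- der <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    flags <- trimws(strsplit(df$flags[i], ",")[[1]])
    mut <- gsub("\\s", "", df$mutation[i])
    if (is.na(mut) || !grepl("->", mut, fixed = TRUE) ||
        is.na(suppressWarnings(as.integer(df$position[i])))) {
      if (strict) stop("malformed positions row ", i + 1L)
      reasons["malformed"] <- reasons["malformed"] + 1L
      next
    }
    sides <- strsplit(mut, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) {
      if (strict) stop("malformed positions row ", i + 1L)
      reasons["malformed"] <- reasons["malformed"] + 1L
      next
    }
    a <- sides[1]; d <- sides[2]
    if ("primer_region" %in% flags) {
      reasons["primer_region"] <- reasons["primer_region"] + 1L
    } else if (grepl(",", d) || grepl("/", d)) {
      reasons["poly_allelic"] <- reasons["poly_allelic"] + 1L
    } else if (nchar(a) != 1L || nchar(d) != 1L) {
      reasons["indel"] <- reasons["indel"] + 1L
    } else if (!(a %in% DNA_BASES) || !(d %in% DNA_BASES)) {
      reasons["unknown_mutation"] <- reasons["unknown_mutation"] + 1L
    } else if (a == d) {
      reasons["equal_mutation"] <- reasons["equal_mutation"] + 1L
    } else {
      keep[i] <- TRUE
      anc[i] <- a; der[i] <- d
    }
  }
  kept <- df[keep, , drop = FALSE]
  kept$ancestral <- anc[keep]
  kept$derived <- der[keep]
  kept$position <- as.integer(kept$position)
  kept$private <- vapply(kept$flags, function(f) {
    "private" %in% trimws(strsplit(f, ",")[[1]])
  }, logical(1), USE.NAMES = FALSE)
  # merge alias records sharing one position
  out <- do.call(rbind, lapply(split(kept, kept$position), function(g) {
    all_names <- unique(c(
      g$name, unlist(lapply(g$aliases, function(a) {
        trimws(strsplit(a, ",")[[1]])
      }))))
    all_names <- all_names[nzchar(all_names)]
    hg <- unique(g$haplogroup[g$haplogroup != "unknown"])
    data.frame(name = all_names[1],
               aliases = paste(all_names[-1], collapse = ","),
               position = g$position[1],
               ancestral = g$ancestral[1], derived = g$derived[1],
               haplogroup = if (length(hg)) hg[1] else "unknown",
               private = any(g$private), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(name = character(), aliases = character(),
                      position = integer(), ancestral = character(),
                      derived = character(), haplogroup = character(),
                      private = logical(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  list(snps = out, report = reasons)
}

#' Write a Y-SNP positions file
#'
#' @param snps `data.frame` as returned by [read_positions_file()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_positions_file <- function(snps, path) {
  df <- data.frame(name = snps$name, aliases = snps$aliases,
                   position = snps$position,
                   mutation = paste0(snps$ancestral, "->", snps$derived),
                   haplogroup = snps$haplogroup,
                   flags = ifelse(snps$private, "private", ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a haplogroup tree from lineage labels
#'
#' Subhaplogroup labels follow the alternating letter/number lineage naming
#' of the Y phylogeny (e.g. `R1a1a1b`). The parent of a label is its longest
#' proper prefix present in the label set; main-haplogroup letters (depth 1)
#' hang off a conventional virtual root `"Y"` (depth 0) so the tree has a
#' single root. An explicit `parent` table overrides prefix derivation.
#'
#' @param labels Character vector of haplogroup labels, or a `data.frame` of
#'   SNP definitions with a `haplogroup` column (`"unknown"` entries are
#'   ignored).
#' @param parents Optional `data.frame` with columns `label`, `parent` giving
#'   explicit parent links that override prefix matching.
#' @return An object of class `haplogroup_tree`: a `data.frame` with columns
#'   `label`, `parent`, `depth`.
#' @export
build_tree <- function(labels, parents = NULL) {
  if (is.data.frame(labels)) labels <- labels$haplogroup
  labels <- unique(labels[!is.na(labels) & labels != "unknown"])
  if ("Y" %in% labels) {
    stop("label \"Y\" is reserved for the virtual root")
  }
  labels <- sort(labels)
  explicit <- if (!is.null(parents)) {
    stats::setNames(parents$parent, parents$label)
  } else character()
  parent <- vapply(labels, function(lab) {
    if (lab %in% names(explicit)) return(explicit[[lab]])
    if (nchar(lab) == 1L) return("Y")
    # longest proper prefix present in the set
    for (k in seq(nchar(lab) - 1L, 1L)) {
      p <- substr(lab, 1L, k)
      if (p %in% labels) return(p)
    }
    stop("haplogroup label(s) with no resolvable parent: ", lab)
  }, character(1))
  extra <- setdiff(parent, c(labels, "Y"))
  if (length(extra)) {
    stop("explicit parent label(s) absent from the set: ",
         paste(extra, collapse = ", "))
  }
  df <- data.frame(label = c("Y", labels),
                   parent = c(NA_character_, unname(parent)),
                   stringsAsFactors = FALSE)
  # depths by propagation from the root
  depth <- stats::setNames(rep(NA_integer_, nrow(df)), df$label)
  depth["Y"] <- 0L
  pending <- df$label[-1]
  while (length(pending)) {
    ready <- pending[!is.na(depth[df$parent[match(pending, df$label)]])]
    if (!length(ready)) stop("haplogroup tree contains a cycle")
    depth[ready] <- depth[df$parent[match(ready, df$label)]] + 1L
    pending <- setdiff(pending, ready)
  }
  df$depth <- unname(depth[df$label])
  structure(df, class = c("haplogroup_tree", "data.frame"))
}

#' Depth of a haplogroup label
#'
#' @param tree A `haplogroup_tree`.
#' @param label Haplogroup label.
#' @return Integer branch depth (main haplogroup letter = 1).
#' @export
tree_depth <- function(tree, label) {
  i <- match(label, tree$label)
  if (anyNA(i)) {
    stop("label(s) absent from tree: ",
         paste(label[is.na(i)], collapse = ", "))
  }
  tree$depth[i]
}

#' Root-to-node path of a haplogroup label
#'
#' @inheritParams tree_depth
#' @return Character vector of labels from the root's first-level letter down
#'   to `label` (the virtual root `"Y"` is omitted).
#' @export
tree_path <- function(tree, label) {
  if (!label %in% tree$label) stop("label absent from tree: ", label)
  path <- character()
  cur <- label
  while (!is.na(cur) && cur != "Y") {
    path <- c(cur, path)
    cur <- tree$parent[match(cur, tree$label)]
  }
  path
}

#' Read a genealogical pair table
#'
#' CSV with columns `sample_a`, `sample_b`, `meioses` and an optional
#' `relationship` note. Each row is one pair of male relatives separated by
#' `meioses` father-to-son transmissions.
#'
#' @param path CSV path.
#' @return `data.frame` of pairs.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_a", "sample_b", "meioses")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("pair table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$meioses <- as.integer(df$meioses)
  if (any(df$meioses < 1L)) stop("meioses must be >= 1")
  df
}
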