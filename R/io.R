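#' Read a FASTA file into a tibble of sequence records
#'
#' One row per record. Residues are uppercased; with `rna_mode = TRUE`
#' thymine is rewritten to uracil so downstream motif arithmetic runs on a
#' single RNA alphabet. Record ids must be unique.
#'
#' @param path path to a FASTA file.
#' @param rna_mode convert T to U on read.
#' @param lenient map IUPAC ambiguity codes other than N to N instead of
#'   failing. Off by default so motif-matching semantics stay explicit.
#' @return a tibble with columns `id`, `residues`, `description`.
#' @export
read_fasta <- function(path, rna_mode = FALSE, lenient = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf(
                    "not a readable FASTA file: %s (%s)", path,
                    conditionMessage(e))))
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate record id '%s' in %s",
                  ids[duplicated(ids)][1], path))
  }
  residues <- purrr::map2_chr(as.character(set), ids,
                              ~ normalize_residues(.x, rna_mode,
                                                   lenient = lenient, id = .y))
  tibble::tibble(id = ids, residues = unname(residues),
                 description = unname(desc))
}

#' Write a tibble of sequence records to FASTA
#'
#' @param records tibble with columns `id`, `residues` (and optionally
#'   `description`).
#' @param path output path.
#' @param width line-wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  lines <- purrr::pmap(records, function(id, residues, ...) {
    dots <- list(...)
    hdr <- if (!is.null(dots$description) && !is.na(dots$description)) {
      paste0(">", id, " ", dots$description)
    } else {
      paste0(">", id)
    }
    body <- substring(residues, seq(1, nchar(residues), width),
                      pmin(seq(1, nchar(residues), width) + width - 1,
                           nchar(residues)))
    c(hdr, body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read 16S rRNA features from a GFF3 file
#'
#' Keeps features with type `rRNA` whose `product` attribute contains "16S"
#' (case-insensitive), or whose ID is listed in `feature_ids`. GFF3's
#' 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention at this boundary and nowhere else.
#'
#' @param path GFF3 file.
#' @param contigs tibble of contigs as returned by [read_fasta()]; used to
#'   validate contig ids and feature extents.
#' @param feature_ids optional character vector: select features by exact
#'   `ID` attribute instead of the product filter.
#' @return tibble with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `feature_type`, `feature_id`, `product`.
#' @export
read_gff3_16s <- function(path, contigs, feature_ids = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  product <- if ("product" %in% names(meta)) as.character(meta$product)
             else rep(NA_character_, nrow(meta))
  fid <- if ("ID" %in% names(meta)) as.character(meta$ID)
         else rep(NA_character_, nrow(meta))
  tb <- tibble::tibble(
    contig_id = as.character(meta$seqnames),
    start = as.integer(meta$start) - 1L, # to 0-based half-open
    end = as.integer(meta$end),
    strand = as.character(meta$strand),
    feature_type = as.character(meta$type),
    feature_id = fid,
    product = product
  )
  keep <- if (!is.null(feature_ids)) {
    tb$feature_id %in% feature_ids
  } else {
    tb$feature_type == "rRNA" & !is.na(tb$product) &
      grepl("16S", tb$product, ignore.case = TRUE)
  }
  tb <- tb[keep, , drop = FALSE]
  if (nrow(tb) > 0) {
    lens <- setNames(nchar(contigs$residues), contigs$id)
    unknown <- setdiff(tb$contig_id, names(lens))
    if (length(unknown) > 0) {
      abort(sprintf("feature on unknown contig '%s'", unknown[1]))
    }
    over <- tb$end > lens[tb$contig_id] | tb$start < 0
    if (any(over)) {
      abort(sprintf("feature %s extends past contig end on '%s'",
                    tb$feature_id[over][1] %||% "?", tb$contig_id[over][1]))
    }
    if (any(!tb$strand %in% c("+", "-"))) {
      abort("16S feature with missing strand")
    }
  }
  tb
}

#' Write genomic features as GFF3
#'
#' Inverse of [read_gff3_16s()]'s coordinate conversion: internal 0-based
#' half-open intervals are emitted 1-based inclusive.
#'
#' @param features tibble with `contig_id`, `start`, `end`, `strand`,
#'   `feature_type`, `feature_id`, `product`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             purrr::pmap_chr(features, function(contig_id, start, end, strand,
                                                feature_type, feature_id,
                                                product, ...) {
               attrs <- sprintf("ID=%s;product=%s", feature_id, product)
               paste(contig_id, "rrnflank", feature_type, start + 1L, end,
                     ".", strand, ".", attrs, sep = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Write an alignment with consensus structure in Stockholm 1.0 format
#'
#' Emits one `#=GC SS_cons` line in dot-bracket notation. Pairs must be
#' nested and lie within the alignment width.
#'
#' @param aln an `rna_alignment` (see [progressive_align()]) or a named
#'   character vector of equal-length gapped rows.
#' @param consensus a `consensus_structure` or a 2-column matrix of 0-based
#'   column pairs; `NULL` writes an all-dot annotation.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stockholm <- function(aln, consensus = NULL, path) {
  rows <- alignment_rows(aln)
  width <- unique(nchar(rows))
  if (length(width) != 1) abort("alignment rows differ in length")
  pairs <- consensus_pairs(consensus)
  ss <- dot_bracket_from_pairs(pairs, width)
  name_w <- max(nchar(names(rows)), nchar("#=GC SS_cons"))
  body <- sprintf(paste0("%-", name_w, "s %s"), names(rows), rows)
  lines <- c("# STOCKHOLM 1.0", "", body,
             sprintf(paste0("%-", name_w, "s %s"), "#=GC SS_cons", ss), "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a Stockholm file written by [write_stockholm()]
#'
#' @param path path to a Stockholm 1.0 file with a `#=GC SS_cons` line.
#' @return list with `aln` (named character rows) and `pairs` (2-column
#'   matrix of 0-based column pairs).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    abort(sprintf("not a Stockholm file: %s", path))
  }
  rows <- character()
  ss <- NULL
  for (ln in lines[-1]) {
    if (ln == "" || ln == "//") next
    if (grepl("^#=GC SS_cons", ln)) {
      ss <- sub("^#=GC SS_cons\\s+", "", ln)
    } else if (grepl("^#", ln)) {
      next
    } else {
      parts <- strsplit(ln, "\\s+")[[1]]
      prev <- if (parts[1] %in% names(rows)) rows[[parts[1]]] else ""
      rows[parts[1]] <- paste0(prev, parts[2])
    }
  }
  pairs <- if (is.null(ss)) matrix(integer(), 0, 2) else
    pairs_from_dot_bracket(ss)
  list(aln = rows, pairs = pairs)
}

#' Write a tree in Newick format
#'
#' Single-leaf trees are written as `label;` (a documented dialect of this
#' package); anything larger goes through [ape::write.tree()].
#'
#' @param tree a `clade_tree` (see [build_tree()]) or an [ape::phylo] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- as_phylo_tree(tree)
  if (is.character(phy)) { # single leaf label
    writeLines(paste0(phy, ";"), path)
    return(invisible(path))
  }
  if (anyDuplicated(phy$tip.label)) abort("duplicate leaf labels")
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object, or the bare leaf label for a
#'   single-leaf tree.
#' @export
read_newick <- function(path) {
  txt <- trimws(paste(readLines(path), collapse = ""))
  if (!grepl("\\(", txt)) {
    return(sub(";$", "", txt))
  }
  ape::read.tree(text = txt)
}

alignment_rows <- function(aln) {
  if (inherits(aln, "rna_alignment")) aln$rows else aln
}

consensus_pairs <- function(consensus) {
  if (is.null(consensus)) return(matrix(integer(), 0, 2))
  if (inherits(consensus, "consensus_structure")) return(consensus$pairs)
  if (inherits(consensus, "rna_structure")) return(consensus$pairs)
  consensus
}

dot_bracket_from_pairs <- function(pairs, width) {
  if (nrow(pairs) > 0 &&
      (min(pairs) < 0 || max(pairs) >= width)) {
    abort("consensus pair outside alignment width")
  }
  check_nested(pairs)
  ch <- rep(".", width)
  if (nrow(pairs) > 0) {
    ch[pairs[, 1] + 1L] <- "("
    ch[pairs[, 2] + 1L] <- ")"
  }
  paste(ch, collapse = "")
}

pairs_from_dot_bracket <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  stack <- integer()
  out <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k - 1L)
    } else if (chars[k] == ")") {
      if (length(stack) == 0) abort("unbalanced brackets in SS_cons")
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out[[length(out) + 1L]] <- c(i, k - 1L)
    }
  }
  if (length(stack) > 0) abort("unbalanced brackets in SS_cons")
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

check_nested <- function(pairs) {
  if (nrow(pairs) < 2) return(invisible(TRUE))
  idx <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(idx)) abort("position in more than one pair")
  for (a in seq_len(nrow(pairs) - 1)) {
    for (b in seq(a + 1, nrow(pairs))) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
        abort("crossing (pseudoknotted) pairs are not representable")
      }
    }
  }
  invisible(TRUE)
}
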