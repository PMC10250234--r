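#' Configuration of the flank extraction geometry
#'
#' All windows and pads of the anchored extraction are configurable; the
#' defaults are the published extraction geometry this package implements:
#' trailer anchor `AAGUCGUAACAAGGUA` searched from 100 nt upstream to 200 nt
#' downstream of the annotated 16S 3' end with the trailer taken at 1-based
#' positions 51..107 downstream of the match; boxC `UCUGUGUGGG` with up to
#' two mismatches searched 90..257 nt upstream of the annotated 5' end
#' (3'-most match kept); leader from 23 nt upstream of boxC to the 18th
#' nucleotide of the gene; pairs below 350 nt total discarded; leader and
#' trailer joined with `NNNNNN` standing in for the mature 16S rRNA.
#'
#' Note these defaults are internally tense: a 57-nt trailer plus the
#' 350-nt total-length filter implies only pairs with boxC at least 252 nt
#' upstream survive. The defaults are kept verbatim and the extraction
#' report surfaces the discard tally, so the tension stays visible; every
#' knob below can be changed consistently.
#'
#' @param trailer_anchor trailer anchor motif (RNA).
#' @param trailer_anchor_max_mm mismatch tolerance for the anchor.
#' @param trailer_window signed offsets of the anchor match start relative
#'   to the annotated 3' end, inclusive.
#' @param trailer_slice 1-based first/last trailer positions downstream of
#'   the anchor match (see `trailer_from`).
#' @param trailer_from count the slice from the anchor match `"start"`
#'   (default) or its last matched nucleotide (`"end"`).
#' @param boxC_motif boxC motif (RNA).
#' @param boxC_max_mm mismatch tolerance for boxC.
#' @param boxC_window inclusive range of upstream distances (5' end minus
#'   match start) in which a boxC match start may lie.
#' @param leader_upstream_pad nt of leader retained upstream of the boxC
#'   match start.
#' @param leader_into_gene nt of the annotated gene retained in the leader.
#' @param min_total_len minimum leader+trailer length for a pair to be kept.
#' @param spacer string joining leader and trailer.
#' @param edge_margin genes whose required windows come within this many nt
#'   of a contig edge are reported `Truncated`, never silently clipped.
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(trailer_anchor = "AAGUCGUAACAAGGUA",
                              trailer_anchor_max_mm = 0,
                              trailer_window = c(-100, 200),
                              trailer_slice = c(51, 107),
                              trailer_from = c("start", "end"),
                              boxC_motif = "UCUGUGUGGG",
                              boxC_max_mm = 2,
                              boxC_window = c(90, 257),
                              leader_upstream_pad = 23,
                              leader_into_gene = 18,
                              min_total_len = 350,
                              spacer = "NNNNNN",
                              edge_margin = 5) {
  trailer_from <- match.arg(trailer_from)
  stopifnot(nchar(trailer_anchor) > 0, nchar(boxC_motif) > 0,
            trailer_anchor_max_mm >= 0, boxC_max_mm >= 0,
            length(trailer_window) == 2,
            trailer_window[1] <= trailer_window[2],
            length(trailer_slice) == 2, trailer_slice[1] >= 1,
            trailer_slice[1] <= trailer_slice[2],
            length(boxC_window) == 2, boxC_window[1] >= 0,
            boxC_window[1] <= boxC_window[2],
            leader_upstream_pad > 0, leader_into_gene > 0,
            min_total_len >= 0, nchar(spacer) > 0)
  structure(list(trailer_anchor = toupper(trailer_anchor),
                 trailer_anchor_max_mm = as.integer(trailer_anchor_max_mm),
                 trailer_window = as.integer(trailer_window),
                 trailer_slice = as.integer(trailer_slice),
                 trailer_from = trailer_from,
                 boxC_motif = toupper(boxC_motif),
                 boxC_max_mm = as.integer(boxC_max_mm),
                 boxC_window = as.integer(boxC_window),
                 leader_upstream_pad = as.integer(leader_upstream_pad),
                 leader_into_gene = as.integer(leader_into_gene),
                 min_total_len = as.integer(min_total_len),
                 spacer = toupper(spacer),
                 edge_margin = as.integer(edge_margin)),
            class = "extraction_config")
}

#' Fuzzy motif search by Hamming distance
#'
#' Every window of the haystack whose Hamming distance to the motif is at
#' most `max_mm` and whose match start lies inside `search_range` is
#' reported, in ascending offset order. No indels; an N in the haystack
#' mismatches every motif symbol.
#'
#' @param haystack RNA string to scan.
#' @param motif RNA motif (no N).
#' @param max_mm maximum Hamming distance.
#' @param search_range inclusive 0-based interval of allowed match starts;
#'   `NULL` scans everywhere.
#' @return tibble with columns `offset` (0-based), `mismatches`,
#'   `motif_len`.
#' @export
fuzzy_find <- function(haystack, motif, max_mm = 0, search_range = NULL) {
  if (nchar(motif) == 0) abort("empty motif")
  H <- strsplit(toupper(haystack), "", fixed = TRUE)[[1]]
  M <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  n <- length(H); m <- length(M)
  lo <- 0L; hi <- n - m
  if (!is.null(search_range)) {
    lo <- max(lo, as.integer(search_range[1]))
    hi <- min(hi, as.integer(search_range[2]))
  }
  if (hi < lo) {
    return(tibble::tibble(offset = integer(), mismatches = integer(),
                          motif_len = integer()))
  }
  offs <- lo:hi
  mism <- integer(length(offs))
  for (k in seq_len(m)) {
    hk <- H[offs + k]
    mism <- mism + as.integer(hk != M[k] | hk == "N")
  }
  keep <- mism <= max_mm
  tibble::tibble(offset = offs[keep], mismatches = mism[keep],
                 motif_len = m)
}

#' Sense-strand context of a gene with flanks
#'
#' Returns the gene sequence plus `up`/`down` nt of flanking sequence on
#' the gene's sense strand (reverse-complemented for minus-strand genes),
#' truncated at contig edges (recorded, not fatal), together with an
#' invertible map back to contig coordinates. Sense coordinate 0 is the
#' first nucleotide of the annotated gene.
#'
#' @param contig_residues contig sequence (RNA, uppercase).
#' @param start,end 0-based half-open gene interval on the contig.
#' @param strand `"+"` or `"-"`.
#' @param up,down flank lengths (nt) on the sense strand.
#' @return a `gene_context` list: `seq`, `sense_start` (sense coordinate of
#'   the first context character), `gene_len`, `trunc_up`, `trunc_down`,
#'   plus the inputs needed to map back.
#' @export
gene_sense_context <- function(contig_residues, start, end, strand, up, down) {
  clen <- nchar(contig_residues)
  stopifnot(start >= 0, start < end, end <= clen, strand %in% c("+", "-"))
  if (strand == "+") {
    avail_up <- min(up, start)
    avail_down <- min(down, clen - end)
    region <- substr(contig_residues, start - avail_up + 1, end + avail_down)
    seq <- region
  } else {
    avail_up <- min(up, clen - end)
    avail_down <- min(down, start)
    region <- substr(contig_residues, start - avail_down + 1, end + avail_up)
    seq <- revcomp_rna(region)
  }
  structure(list(seq = seq, sense_start = -avail_up,
                 gene_len = end - start, start = start, end = end,
                 strand = strand, contig_len = clen,
                 trunc_up = avail_up < up, trunc_down = avail_down < down),
            class = "gene_context")
}

#' Map a sense-coordinate interval back to contig coordinates
#'
#' @param ctx a `gene_context`.
#' @param from,to 0-based half-open interval in sense coordinates.
#' @return integer `c(start, end)`, 0-based half-open on the contig.
#' @export
sense_to_contig <- function(ctx, from, to) {
  if (ctx$strand == "+") {
    c(ctx$start + from, ctx$start + to)
  } else {
    c(ctx$end - to, ctx$end - from)
  }
}

context_index <- function(ctx, sense_pos) sense_pos - ctx$sense_start

# slice the context by a sense-coordinate half-open interval; NULL if the
# interval is not fully covered
context_slice <- function(ctx, from, to) {
  i0 <- context_index(ctx, from)
  i1 <- context_index(ctx, to)
  if (i0 < 0 || i1 > nchar(ctx$seq)) return(NULL)
  substr(ctx$seq, i0 + 1, i1)
}

#' Locate the trailer via the conserved anchor
#'
#' Searches the trailer anchor in the configured window around the
#' annotated 3' end and slices the trailer downstream of the match. If
#' several anchor hits fall in the window, the one nearest the annotated 3'
#' end is used (ties broken upstream-first).
#'
#' @param ctx a [gene_sense_context()].
#' @param cfg an [extraction_config()].
#' @return list `status` (`"ok"`, `"NoAnchor"`, `"Truncated"`), `trailer`
#'   (residues), `hit` (anchor hit row), `trailer_sense` (0-based half-open
#'   sense interval).
#' @export
locate_trailer <- function(ctx, cfg) {
  L <- ctx$gene_len
  win <- L + cfg$trailer_window # allowed sense match starts, inclusive
  idx_range <- c(context_index(ctx, win[1]), context_index(ctx, win[2]))
  hits <- fuzzy_find(ctx$seq, cfg$trailer_anchor, cfg$trailer_anchor_max_mm,
                     search_range = idx_range)
  if (nrow(hits) == 0) {
    status <- if (ctx$trunc_down) "Truncated" else "NoAnchor"
    return(list(status = status, trailer = NULL, hit = NULL,
                trailer_sense = NULL))
  }
  sense_starts <- hits$offset + ctx$sense_start
  d3 <- abs(sense_starts - L)
  pick <- order(d3, sense_starts)[1]
  m0 <- sense_starts[pick]
  base <- if (cfg$trailer_from == "start") m0 else
    m0 + nchar(cfg$trailer_anchor) - 1L
  from <- base + cfg$trailer_slice[1]
  to <- base + cfg$trailer_slice[2] + 1L
  trailer <- context_slice(ctx, from, to)
  if (is.null(trailer)) {
    return(list(status = "Truncated", trailer = NULL,
                hit = hits[pick, ], trailer_sense = NULL))
  }
  list(status = "ok", trailer = trailer, hit = hits[pick, ],
       trailer_sense = c(from, to), anchor_sense = m0)
}

#' Locate the leader via boxC
#'
#' Searches boxC in the configured upstream window (distances measured from
#' the annotated 5' end to the match start, bounds inclusive), keeps the
#' 3'-most match, and slices the leader from `leader_upstream_pad` nt
#' upstream of the match to `leader_into_gene` nt inside the gene.
#'
#' @inheritParams locate_trailer
#' @return list `status` (`"ok"`, `"NoBoxC"`, `"Truncated"`), `leader`,
#'   `hit`, `boxC_distance`, `boxC_offset_in_leader`, `leader_sense`.
#' @export
locate_leader <- function(ctx, cfg) {
  # match starts at sense positions -boxC_window[2] .. -boxC_window[1]
  win <- c(-cfg$boxC_window[2], -cfg$boxC_window[1])
  idx_range <- c(context_index(ctx, win[1]), context_index(ctx, win[2]))
  hits <- fuzzy_find(ctx$seq, cfg$boxC_motif, cfg$boxC_max_mm,
                     search_range = idx_range)
  if (nrow(hits) == 0) {
    status <- if (ctx$trunc_up) "Truncated" else "NoBoxC"
    return(list(status = status, leader = NULL, hit = NULL,
                boxC_distance = NA_integer_))
  }
  sense_starts <- hits$offset + ctx$sense_start
  d <- -sense_starts # upstream distance to 5' end
  pick <- which.min(d) # 3'-most match
  s <- sense_starts[pick]
  from <- s - cfg$leader_upstream_pad
  to <- cfg$leader_into_gene
  leader <- context_slice(ctx, from, to)
  if (is.null(leader)) {
    return(list(status = "Truncated", leader = NULL, hit = hits[pick, ],
                boxC_distance = d[pick]))
  }
  list(status = "ok", leader = leader, hit = hits[pick, ],
       boxC_distance = d[pick],
       boxC_offset_in_leader = cfg$leader_upstream_pad,
       leader_sense = c(from, to))
}

#' Assemble a leader/trailer pair and apply the length filter
#'
#' `combined = leader + spacer + trailer`; the pair is kept iff
#' `nchar(leader) + nchar(trailer) >= min_total_len` (the boundary value is
#' retained).
#'
#' @param leader,trailer residue strings.
#' @param cfg an [extraction_config()].
#' @return list `combined`, `total_len`, `kept`, `discard_reason`.
#' @export
assemble_flank_pair <- function(leader, trailer, cfg = extraction_config()) {
  total <- nchar(leader) + nchar(trailer)
  kept <- total >= cfg$min_total_len
  list(combined = paste0(leader, cfg$spacer, trailer), total_len = total,
       kept = kept,
       discard_reason = if (kept) NA_character_ else "too_short")
}

required_flanks <- function(cfg) {
  anchor_extra <- if (cfg$trailer_from == "start") 0L else
    nchar(cfg$trailer_anchor) - 1L
  list(up = cfg$boxC_window[2] + cfg$leader_upstream_pad + cfg$edge_margin,
       down = cfg$trailer_window[2] + anchor_extra + cfg$trailer_slice[2] +
         1L + cfg$edge_margin)
}

#' Extract leader/trailer pairs for every annotated 16S gene
#'
#' One extraction attempt per feature row (multiple gene copies per genome
#' are processed independently). Failures are recorded per gene, never
#' fatal: `NoAnchor`, `NoBoxC`, `Truncated` (required window clipped by a
#' contig edge), `too_short` (length filter).
#'
#' @param contigs tibble from [read_fasta()] (DNA or RNA; T is converted
#'   to U internally).
#' @param features tibble from [read_gff3_16s()]; an optional
#'   `assembly_id` column is carried through.
#' @param cfg an [extraction_config()].
#' @param assembly_id fallback assembly label.
#' @return a `flank_pairs` tibble: one row per gene with contig coordinates
#'   of the leader/trailer (1-based inclusive, as in the TSV report), the
#'   extracted residues, boxC statistics, and keep/discard status. The
#'   extraction report is available via [glance()].
#' @export
extract_flank_pairs <- function(contigs, features, cfg = extraction_config(),
                                assembly_id = "assembly") {
  contig_seqs <- setNames(chartr("T", "U", toupper(contigs$residues)),
                          contigs$id)
  need <- required_flanks(cfg)
  rows <- purrr::map(seq_len(nrow(features)), function(r) {
    f <- features[r, ]
    asm <- if ("assembly_id" %in% names(features)) f$assembly_id else
      assembly_id
    gid <- if (!is.na(f$feature_id %||% NA)) f$feature_id else
      sprintf("%s:%d-%d", f$contig_id, f$start + 1L, f$end)
    ctx <- gene_sense_context(contig_seqs[[f$contig_id]], f$start, f$end,
                              f$strand, up = need$up, down = need$down)
    out <- tibble::tibble(
      assembly_id = asm, gene_id = gid, contig = f$contig_id,
      strand = f$strand,
      leader_start = NA_integer_, leader_end = NA_integer_,
      trailer_start = NA_integer_, trailer_end = NA_integer_,
      boxC_distance = NA_integer_, boxC_mismatches = NA_integer_,
      boxC_offset_in_leader = NA_integer_,
      total_len = NA_integer_, kept = FALSE, discard_reason = NA_character_,
      leader = NA_character_, trailer = NA_character_,
      combined = NA_character_)
    tr <- locate_trailer(ctx, cfg)
    if (tr$status != "ok") {
      out$discard_reason <- tr$status
      return(out)
    }
    ld <- locate_leader(ctx, cfg)
    out$boxC_distance <- ld$boxC_distance
    if (ld$status != "ok") {
      out$discard_reason <- ld$status
      return(out)
    }
    asm_pair <- assemble_flank_pair(ld$leader, tr$trailer, cfg)
    lc <- sense_to_contig(ctx, ld$leader_sense[1], ld$leader_sense[2])
    tc <- sense_to_contig(ctx, tr$trailer_sense[1], tr$trailer_sense[2])
    out$leader_start <- lc[1] + 1L; out$leader_end <- lc[2]
    out$trailer_start <- tc[1] + 1L; out$trailer_end <- tc[2]
    out$boxC_mismatches <- ld$hit$mismatches
    out$boxC_offset_in_leader <- ld$boxC_offset_in_leader
    out$total_len <- asm_pair$total_len
    out$kept <- asm_pair$kept
    out$discard_reason <- asm_pair$discard_reason
    out$leader <- ld$leader
    out$trailer <- tr$trailer
    out$combined <- asm_pair$combined
    out
  })
  res <- dplyr::bind_rows(rows)
  reasons <- c("NoAnchor", "NoBoxC", "Truncated", "too_short")
  report <- c(list(genes = nrow(res), kept = sum(res$kept)),
              as.list(setNames(
                purrr::map_int(reasons,
                               ~ sum(res$discard_reason == .x, na.rm = TRUE)),
                reasons)))
  structure(res, class = c("flank_pairs", class(res)), report = report)
}

#' @method glance flank_pairs
#' @export
glance.flank_pairs <- function(x, ...) {
  tibble::as_tibble(attr(x, "report"))
}

#' Write the extraction TSV and combined-sequence FASTA
#'
#' @param pairs a `flank_pairs` tibble.
#' @param tsv,fasta output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_flank_pairs <- function(pairs, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    cols <- c("assembly_id", "gene_id", "contig", "strand", "leader_start",
              "leader_end", "trailer_start", "trailer_end", "boxC_distance",
              "boxC_mismatches", "total_len", "kept", "discard_reason")
    write.table(as.data.frame(pairs)[, cols], tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    kept <- dplyr::filter(pairs, .data$kept)
    write_fasta(tibble::tibble(
      id = paste0(kept$assembly_id, "|", kept$gene_id),
      residues = kept$combined), fasta)
  }
  invisible(c(tsv = tsv, fasta = fasta))
}
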