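#' Default boxA motif
#'
#' The E. coli rrn boxA consensus from prior antitermination literature;
#' this package's spacing statistic does not prescribe a detection model,
#' so both motif and tolerance are explicit knobs.
#' @export
BOXA_MOTIF <- "UGCUCUUUAACA"

#' Find boxA in a leader upstream of the boxC match
#'
#' Best hit = fewest mismatches, ties broken 3'-most. Only matches lying
#' entirely upstream of the boxC match start are considered.
#'
#' @param leader leader residues.
#' @param boxC_offset 0-based offset of the boxC match start in the leader
#'   (`NULL` searches the whole leader).
#' @param motif boxA motif.
#' @param max_mm maximum mismatches (default 2).
#' @return one-row tibble (`offset`, `mismatches`, `motif_len`), or `NULL`
#'   when no hit passes.
#' @export
find_boxA <- function(leader, boxC_offset = NULL, motif = BOXA_MOTIF,
                      max_mm = 2) {
  if (nchar(leader) == 0) abort("empty leader")
  if (!is.null(boxC_offset) && is.na(boxC_offset)) boxC_offset <- NULL
  hi <- if (is.null(boxC_offset)) nchar(leader) - nchar(motif) else
    boxC_offset - nchar(motif)
  if (hi < 0) return(NULL)
  hits <- fuzzy_find(leader, motif, max_mm, search_range = c(0, hi))
  if (nrow(hits) == 0) return(NULL)
  hits[order(hits$mismatches, -hits$offset), ][1, ]
}

#' Nucleotides strictly between boxA and boxC
#'
#' Measured from the nucleotide after boxA's last residue to the
#' nucleotide before boxC's first residue. An alternative start-to-start
#' measure is available via `mode`.
#'
#' @param boxA_hit one-row tibble from [find_boxA()].
#' @param boxC_offset 0-based boxC match start on the same leader.
#' @param mode `"between"` (default) or `"start_start"`.
#' @return list `spacing` (nt, NA on overlap) and `overlap` flag.
#' @export
boxa_boxc_spacing <- function(boxA_hit, boxC_offset,
                              mode = c("between", "start_start")) {
  mode <- match.arg(mode)
  boxA_end <- boxA_hit$offset + boxA_hit$motif_len # half-open end
  sp <- switch(mode,
               between = boxC_offset - boxA_end,
               start_start = boxC_offset - boxA_hit$offset)
  if (mode == "between" && sp < 0) {
    return(list(spacing = NA_integer_, overlap = TRUE))
  }
  list(spacing = as.integer(sp), overlap = FALSE)
}

#' Quantitative flank features per pair
#'
#' For every kept flank pair: the best leader-trailer duplex (hLT
#' candidate) with its basepair count and threshold class (`hlt_bp >
#' threshold`, default 17 with strict inequality), boxA detection upstream
#' of boxC, and the boxA-boxC spacing. [glance()] summarises the fraction
#' of profiles with spacing 18 or 19 nt and the hLT length distribution.
#'
#' @param pairs a `flank_pairs` tibble (or any tibble with `leader`,
#'   `trailer`, `boxC_offset_in_leader` and an id).
#' @param threshold hLT basepair threshold (strict `>`).
#' @param boxA_motif,boxA_max_mm boxA detection knobs.
#' @param scores [duplex_scores()] for the duplex alignment.
#' @param spacing_mode see [boxa_boxc_spacing()].
#' @return a `flank_profiles` tibble.
#' @export
profile_flank_pairs <- function(pairs, threshold = 17,
                                boxA_motif = BOXA_MOTIF, boxA_max_mm = 2,
                                scores = duplex_scores(),
                                spacing_mode = "between") {
  use <- if ("kept" %in% names(pairs)) dplyr::filter(pairs, .data$kept) else
    pairs
  ids <- if (all(c("assembly_id", "gene_id") %in% names(use))) {
    paste0(use$assembly_id, "|", use$gene_id)
  } else if ("id" %in% names(use)) {
    use$id
  } else {
    sprintf("pair%03d", seq_len(nrow(use)))
  }
  rows <- purrr::map(seq_len(nrow(use)), function(r) {
    leader <- use$leader[r]; trailer <- use$trailer[r]
    dup <- duplex_align(leader, trailer, scores)
    bC <- use$boxC_offset_in_leader[r]
    bA <- find_boxA(leader, boxC_offset = bC, motif = boxA_motif,
                    max_mm = boxA_max_mm)
    sp <- if (!is.null(bA) && !is.na(bC)) {
      boxa_boxc_spacing(bA, bC, mode = spacing_mode)
    } else {
      list(spacing = NA_integer_, overlap = FALSE)
    }
    tibble::tibble(
      id = ids[r], hlt_bp = dup$bp_count, hlt_score = dup$score,
      hlt_leader_start = dup$leader_span[1],
      hlt_leader_end = dup$leader_span[2],
      hlt_trailer_start = dup$trailer_span[1],
      hlt_trailer_end = dup$trailer_span[2],
      meets_threshold = dup$bp_count > threshold,
      boxA_offset = if (is.null(bA)) NA_integer_ else bA$offset,
      boxA_mm = if (is.null(bA)) NA_integer_ else bA$mismatches,
      spacing = sp$spacing, spacing_overlap = sp$overlap)
  })
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("flank_profiles", class(res)),
            threshold = threshold)
}

#' @method glance flank_profiles
#' @export
glance.flank_profiles <- function(x, ...) {
  with_sp <- x$spacing[!is.na(x$spacing)]
  tibble::tibble(
    n = nrow(x),
    n_meets_threshold = sum(x$meets_threshold),
    frac_meets_threshold = mean(x$meets_threshold),
    n_spacing = length(with_sp),
    frac_spacing_18_19 = if (length(with_sp) > 0)
      mean(with_sp %in% c(18L, 19L)) else NA_real_,
    mean_hlt_bp = mean(x$hlt_bp),
    median_hlt_bp = stats::median(x$hlt_bp))
}

#' Write the feature-profile TSV
#'
#' @param profiles a `flank_profiles` tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
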