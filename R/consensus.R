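# ordered canonical pair types, the basis of the 6-colour covariation map
PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
COVARIATION_COLORS <- c("red", "yellow", "green", "cyan", "blue", "magenta")

pair_type_lookup <- function() {
  # 6x6 matrix over codes A0 C1 G2 U3 N4 gap5 -> type id 1..6, 0 otherwise
  L <- matrix(0L, 6, 6)
  idx <- list(AU = c(1, 4), UA = c(4, 1), GC = c(3, 2), CG = c(2, 3),
              GU = c(3, 4), UG = c(4, 3))
  for (t in seq_along(PAIR_TYPES)) {
    L[idx[[t]][1], idx[[t]][2]] <- t
  }
  L
}

new_rna_alignment <- function(rows) {
  width <- unique(nchar(rows))
  if (length(width) > 1) abort("alignment rows differ in width")
  structure(list(rows = rows, width = width), class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("RNA alignment: %d rows x %d columns\n", length(x$rows),
              x$width))
  invisible(x)
}

#' @method tidy rna_alignment
#' @export
tidy.rna_alignment <- function(x, ...) {
  tibble::tibble(id = names(x$rows), aligned = unname(x$rows))
}

alignment_codes <- function(aln) {
  rows <- alignment_rows(aln)
  t(vapply(rows, encode_residues, integer(nchar(rows[[1]]))))
}

#' Progressive multiple alignment along a guide tree
#'
#' Pairwise global profile alignment (match +2, mismatch -1, gap open -4,
#' extend -1; N and gap columns neutral) merged leaf-to-root along the
#' guide tree; once a gap is introduced it is never removed. With two
#' sequences this reduces to an optimal pairwise global alignment.
#'
#' @param seqs named character vector of (ungapped) sequences.
#' @param guide a `clade_tree` whose leaf labels equal `names(seqs)`;
#'   `NULL` merges sequences in input order (a caterpillar guide).
#' @param match,mismatch,gap_open,gap_ext alignment scores.
#' @return an `rna_alignment`.
#' @export
progressive_align <- function(seqs, guide = NULL, match = 2, mismatch = -1,
                              gap_open = -4, gap_ext = -1) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique names")
  }
  merge_profiles <- function(pa, pb) {
    al <- cpp_profile_align(pa$m, pb$m, match, mismatch, gap_open, gap_ext)
    W <- length(al$a_cols)
    ga <- matrix(5L, nrow(pa$m), W)
    gb <- matrix(5L, nrow(pb$m), W)
    ga[, al$a_cols >= 0] <- pa$m[, al$a_cols[al$a_cols >= 0] + 1,
                                 drop = FALSE]
    gb[, al$b_cols >= 0] <- pb$m[, al$b_cols[al$b_cols >= 0] + 1,
                                 drop = FALSE]
    list(m = rbind(ga, gb), ids = c(pa$ids, pb$ids))
  }
  leaf_profile <- function(id) {
    list(m = matrix(encode_residues(seqs[[id]]), nrow = 1), ids = id)
  }
  if (length(seqs) == 1) {
    prof <- leaf_profile(names(seqs))
  } else if (is.null(guide)) {
    prof <- leaf_profile(names(seqs)[1])
    for (id in names(seqs)[-1]) {
      prof <- merge_profiles(prof, leaf_profile(id))
    }
  } else {
    if (!setequal(guide$labels, names(seqs))) {
      abort("guide tree leaves do not match sequence ids")
    }
    profs <- vector("list", nrow(guide$merge))
    get_prof <- function(node) {
      if (node < 0) leaf_profile(guide$labels[-node]) else profs[[node]]
    }
    for (s in seq_len(nrow(guide$merge))) {
      profs[[s]] <- merge_profiles(get_prof(guide$merge[s, 1]),
                                   get_prof(guide$merge[s, 2]))
    }
    prof <- profs[[nrow(guide$merge)]]
  }
  rows <- setNames(apply(prof$m, 1, decode_residues), prof$ids)
  new_rna_alignment(rows[names(seqs)[names(seqs) %in% prof$ids]])
}

column_pair_scores <- function(codes, tau, beta, gamma, min_loop) {
  R <- nrow(codes); W <- ncol(codes)
  L <- pair_type_lookup()
  S <- matrix(NA_real_, W, W)
  info <- vector("list", W)
  for (i in seq_len(W)) {
    if (i + min_loop + 1 > W) break
    js <- seq(i + min_loop + 1, W)
    # type id per row per candidate column j
    Tm <- matrix(L[cbind(rep(codes[, i] + 1L, length(js)),
                         as.vector(codes[, js, drop = FALSE]) + 1L)],
                 nrow = R)
    f_can <- colSums(Tm > 0) / R
    n_types <- rowSums(matrix(vapply(seq_len(6),
                                     function(t) colSums(Tm == t) > 0,
                                     logical(length(js))),
                              nrow = length(js)))
    f_mm <- 1 - f_can
    ok <- f_can >= tau
    S[i, js[ok]] <- f_can[ok] + beta * (n_types[ok] - 1) / 5 -
      gamma * f_mm[ok]
  }
  S
}

#' Consensus structure of an alignment by covariance-bonus folding
#'
#' Nussinov-style maximisation over column pairs. A column pair is
#' admissible when the fraction of rows forming a canonical basepair is at
#' least `tau`; its score is
#' `f_can + beta * (n_types - 1) / 5 - gamma * f_mm`, rewarding observed
#' pair-type diversity (covariation) and penalising mismatched or gapped
#' rows, plus a helix-continuity bonus `delta` for each directly stacked
#' pair. The continuity term plays the role stacking energies play in
#' thermodynamic alignment folding: without it the optimum is degenerate
#' across the many isolated column pairs a conserved alignment offers, and
#' long supported helices would not be preferred over scattered chance
#' complementarity. The output is nested, respects `min_loop` in column
#' space, and uses the deterministic small-i/small-j traceback.
#'
#' @param aln an `rna_alignment` (at least 2 rows).
#' @param tau minimum canonical-row fraction (default 0.5).
#' @param beta covariation bonus weight.
#' @param gamma mismatch penalty weight.
#' @param delta stacking (helix-continuity) bonus per stacked pair.
#' @param min_loop minimum loop length in columns.
#' @return a `consensus_structure`: `width`, `pairs` (0-based column
#'   pairs), `score`.
#' @export
consensus_fold <- function(aln, tau = 0.5, beta = 1, gamma = 1,
                           delta = 0.5, min_loop = 3) {
  codes <- alignment_codes(aln)
  if (nrow(codes) < 2) abort("consensus folding needs at least 2 rows")
  S <- column_pair_scores(codes, tau, beta, gamma, min_loop)
  pr <- cpp_nussinov_general(S, as.integer(min_loop), stack_bonus = delta)
  pairs <- matrix(as.integer(pr), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(width = ncol(codes), pairs = pairs,
                 score = attr(pr, "score")),
            class = "consensus_structure")
}

#' Build a consensus structure from explicit column pairs
#'
#' Useful for scoring covariation at externally defined (e.g. planted)
#' column pairs with [covariation_stats()].
#'
#' @param pairs 2-column matrix or tibble of 0-based column pairs.
#' @param width alignment width.
#' @return a `consensus_structure`.
#' @export
as_consensus_structure <- function(pairs, width) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (nrow(pairs) > 0 && (min(pairs) < 0 || max(pairs) >= width)) {
    abort("pair outside alignment width")
  }
  check_nested(pairs)
  structure(list(width = as.integer(width), pairs = pairs, score = NA_real_),
            class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(sprintf("Consensus structure: %d columns, %d pairs\n", x$width,
              nrow(x$pairs)))
  invisible(x)
}

#' @method tidy consensus_structure
#' @export
tidy.consensus_structure <- function(x, ...) {
  tibble::tibble(i = x$pairs[, 1], j = x$pairs[, 2])
}

#' Covariation statistics and colour classes for consensus pairs
#'
#' For every consensus column pair, `n_types` counts the distinct ordered
#' canonical basepair types realised across rows (GC and CG are distinct;
#' at most 6) and `n_mismatch` counts rows that are non-canonical or
#' gapped at either column. The colour encodes `n_types`
#' (red 1, yellow 2, green 3, cyan 4, blue 5, magenta 6) and the tint the
#' mismatch count (full 0, medium 1, light 2, white for three or more).
#'
#' @param aln an `rna_alignment`.
#' @param cons a `consensus_structure` on its columns.
#' @return tibble with columns `pair_i`, `pair_j` (0-based columns),
#'   `n_types`, `n_mismatch`, `color`, `tint`.
#' @export
covariation_stats <- function(aln, cons) {
  codes <- alignment_codes(aln)
  if (nrow(cons$pairs) > 0 && max(cons$pairs) >= ncol(codes)) {
    abort("consensus pair outside alignment width")
  }
  empty <- tibble::tibble(pair_i = integer(), pair_j = integer(),
                          n_types = integer(), n_mismatch = integer(),
                          color = character(), tint = character())
  if (nrow(cons$pairs) == 0) return(empty)
  L <- pair_type_lookup()
  purrr::map_dfr(seq_len(nrow(cons$pairs)), function(r) {
    i <- cons$pairs[r, 1]; j <- cons$pairs[r, 2]
    types <- L[cbind(codes[, i + 1] + 1L, codes[, j + 1] + 1L)]
    n_types <- length(unique(types[types > 0]))
    n_mismatch <- sum(types == 0)
    tibble::tibble(
      pair_i = i, pair_j = j, n_types = n_types, n_mismatch = n_mismatch,
      color = if (n_types >= 1) COVARIATION_COLORS[n_types] else
        NA_character_,
      tint = dplyr::case_when(n_mismatch == 0 ~ "full",
                              n_mismatch == 1 ~ "medium",
                              n_mismatch == 2 ~ "light",
                              TRUE ~ "white"))
  })
}

#' Group consensus pairs into helices and flag the leader-trailer helix
#'
#' Pairs sorted by 5' column are grouped into one helix while consecutive
#' pairs stack within a one-residue bulge tolerance. The largest helix
#' whose 5' arm lies upstream of the NNNNNN spacer columns and whose 3'
#' arm lies downstream (i.e. spanning the mature-16S placeholder) is
#' labelled `hLT`.
#'
#' @param aln an `rna_alignment` of combined (leader+spacer+trailer) rows.
#' @param cons a `consensus_structure`.
#' @return tibble `helix`, `label`, `i`, `j` (one row per pair).
#' @export
label_helices <- function(aln, cons) {
  pairs <- cons$pairs
  if (nrow(pairs) == 0) {
    return(tibble::tibble(helix = integer(), label = character(),
                          i = integer(), j = integer()))
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  helix <- integer(nrow(pairs))
  helix[1] <- 1L
  if (nrow(pairs) > 1) {
    for (r in seq(2, nrow(pairs))) {
      stacked <- pairs[r, 1] - pairs[r - 1, 1] <= 2 &&
        pairs[r - 1, 2] - pairs[r, 2] <= 2 &&
        pairs[r, 2] < pairs[r - 1, 2]
      helix[r] <- if (stacked) helix[r - 1] else helix[r - 1] + 1L
    }
  }
  codes <- alignment_codes(aln)
  resid <- codes <= 4 # non-gap
  n_col <- colSums(resid)
  spacer_cols <- which(colSums(codes == 4L) == n_col & n_col > 0) - 1L
  label <- rep(NA_character_, nrow(pairs))
  if (length(spacer_cols) > 0) {
    spans <- pairs[, 1] < min(spacer_cols) & pairs[, 2] > max(spacer_cols)
    cand <- unique(helix[spans])
    if (length(cand) > 0) {
      # the hLT candidate is the largest spacer-spanning helix
      sizes <- vapply(cand, function(h) sum(helix == h), integer(1))
      label[helix == cand[which.max(sizes)]] <- "hLT"
    }
  }
  tibble::tibble(helix = helix, label = label, i = pairs[, 1],
                 j = pairs[, 2])
}

#' Fit a covariation model for one group of flank pairs
#'
#' Convenience wrapper: progressive alignment (guide tree built by WPGMA on
#' the structure-aware distance if not supplied), consensus folding, and
#' covariation statistics.
#'
#' @param seqs named character vector of combined sequences.
#' @param guide optional `clade_tree` guide.
#' @param tau,beta,gamma,delta,min_loop see [consensus_fold()].
#' @param model an [energy_model()] used if the guide must be built.
#' @return a `covariation_model`: `aln`, `consensus`, `stats`, `helices`.
#' @export
consensus_model <- function(seqs, guide = NULL, tau = 0.5, beta = 1,
                            gamma = 1, delta = 0.5, min_loop = 3,
                            model = energy_model()) {
  if (is.null(guide) && length(seqs) > 2) {
    D <- flank_distances(seqs, model = model, min_loop = min_loop)
    guide <- build_tree(D)
  }
  aln <- progressive_align(seqs, guide)
  cons <- consensus_fold(aln, tau, beta, gamma, delta, min_loop)
  stats <- covariation_stats(aln, cons)
  helices <- label_helices(aln, cons)
  structure(list(aln = aln, consensus = cons, stats = stats,
                 helices = helices),
            class = "covariation_model")
}

#' @export
print.covariation_model <- function(x, ...) {
  cat(sprintf("Covariation model: %d rows, %d consensus pairs\n",
              length(x$aln$rows), nrow(x$consensus$pairs)))
  invisible(x)
}

#' @method tidy covariation_model
#' @export
tidy.covariation_model <- function(x, ...) x$stats

#' @method glance covariation_model
#' @export
glance.covariation_model <- function(x, ...) {
  tibble::tibble(n_rows = length(x$aln$rows), width = x$aln$width,
                 n_pairs = nrow(x$consensus$pairs),
                 n_helices = length(unique(x$helices$helix)),
                 score = x$consensus$score)
}

#' Write per-group covariation outputs
#'
#' Writes `<prefix>.covar.tsv` (pair table with colour classes and helix
#' labels), `<prefix>.sto` (Stockholm with `#=GC SS_cons`) and
#' `<prefix>.dotbracket.txt`.
#'
#' @param model a `covariation_model`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
covariation_report <- function(model, prefix) {
  tsv <- paste0(prefix, ".covar.tsv")
  sto <- paste0(prefix, ".sto")
  dbr <- paste0(prefix, ".dotbracket.txt")
  tab <- dplyr::left_join(model$stats,
                          model$helices,
                          by = c(pair_i = "i", pair_j = "j"))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stockholm(model$aln, model$consensus, sto)
  writeLines(dot_bracket(model$consensus), dbr)
  invisible(c(tsv = tsv, sto = sto, dotbracket = dbr))
}
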