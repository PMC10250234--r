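#' A simple per-pair energy model
#'
#' The package scores structures with declared per-basepair pseudo-energies
#' (arbitrary units) rather than a nearest-neighbour thermodynamic model:
#' the claims downstream are about covariation and geometry, not folding
#' free energies. Non-canonical pairs are forbidden outright.
#'
#' @param gc,au,gu energies of GC/CG, AU/UA and GU/UG pairs.
#' @param kT temperature factor for Boltzmann weighting.
#' @return an `energy_model` list.
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1, kT = 1) {
  stopifnot(is.finite(gc), is.finite(au), is.finite(gu), kT > 0)
  structure(list(gc = gc, au = au, gu = gu, kT = kT),
            class = "rrnflank_energy_model")
}

pair_energy_chr <- function(a, b, model) {
  key <- paste0(a, b)
  dplyr::case_when(
    key %in% c("GC", "CG") ~ model$gc,
    key %in% c("AU", "UA") ~ model$au,
    key %in% c("GU", "UG") ~ model$gu,
    TRUE ~ Inf
  )
}

new_rna_structure <- function(n, pairs, seq = NULL, score = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(n = n, pairs = pairs, seq = seq, score = score),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d nt, %d pairs\n", x$n,
              nrow(x$pairs)))
  if (!is.null(x$seq)) cat(x$seq, "\n")
  cat(dot_bracket(x), "\n")
  invisible(x)
}

#' Dot-bracket string of a structure
#'
#' @param x an `rna_structure` or `consensus_structure`.
#' @return a dot-bracket string.
#' @export
dot_bracket <- function(x) {
  n <- if (inherits(x, "consensus_structure")) x$width else x$n
  dot_bracket_from_pairs(consensus_pairs(x), n)
}

#' @method tidy rna_structure
#' @export
tidy.rna_structure <- function(x, ...) {
  tibble::tibble(i = x$pairs[, 1], j = x$pairs[, 2])
}

score_matrix_for <- function(seq, min_loop, value_fun) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  S <- matrix(NA_real_, n, n)
  if (n >= min_loop + 2) {
    for (i in seq_len(n - min_loop - 1)) {
      js <- seq(i + min_loop + 1, n)
      ok <- is_canonical_pair(chars[i], chars[js])
      S[i, js[ok]] <- value_fun(chars[i], chars[js[ok]])
    }
  }
  S
}

#' Maximum-pairing secondary structure (Nussinov folding)
#'
#' Dynamic programme maximising the number of canonical basepairs subject
#' to nestedness and a minimum hairpin loop. Traceback is deterministic:
#' among co-optimal structures the one pairing the smallest 5' index first,
#' then the smallest partner, is returned. N never pairs.
#'
#' @param seq RNA string over `{A,C,G,U,N}`.
#' @param min_loop minimum number of unpaired residues enclosed by a pair.
#' @return an `rna_structure`.
#' @export
nussinov_fold <- function(seq, min_loop = 3) {
  seq <- toupper(seq)
  code <- encode_residues(seq) # validates alphabet
  S <- score_matrix_for(seq, min_loop, function(a, b) rep(1, length(b)))
  pr <- cpp_nussinov_general(S, as.integer(min_loop))
  new_rna_structure(length(code), pr, seq = seq,
                    score = attr(pr, "score"))
}

#' Exhaustively enumerate all admissible secondary structures
#'
#' Test oracle: every nested, canonical, min-loop-respecting structure of a
#' short sequence, including the empty one, each exactly once. Guarded to
#' 16 nt.
#'
#' @inheritParams nussinov_fold
#' @return list of `rna_structure` objects.
#' @export
enumerate_structures <- function(seq, min_loop = 3) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n > 16) abort("enumerate_structures is an oracle; sequences > 16 nt refused")
  # recursive enumeration over interval [i, j] (0-based inclusive)
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(), 0, 2)))
    # decompose on the status of position i: unpaired, or paired with l
    out <- enum(i + 1, j)
    ls <- if (i + min_loop + 1 <= j) seq(i + min_loop + 1, j) else integer()
    for (l in ls) {
      if (!is_canonical_pair(chars[i + 1], chars[l + 1])) next
      inner <- enum(i + 1, l - 1)
      outer <- enum(l + 1, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, l), a, b)
      }
    }
    out
  }
  if (n == 0) return(list(new_rna_structure(0, matrix(integer(), 0, 2), seq)))
  purrr::map(enum(0, n - 1), ~ new_rna_structure(n, .x, seq = seq))
}

#' Equilibrium basepair probabilities under the simple energy model
#'
#' McCaskill-style inside-outside recursion over exactly the structure
#' space of [enumerate_structures()]: `P(i,j)` is the Boltzmann-weighted
#' fraction of admissible structures containing the pair. Values are
#' scaled during the recursion to avoid overflow; if a scale fails the
#' computation retries with a larger one and ultimately errors.
#'
#' @inheritParams nussinov_fold
#' @param model an [energy_model()].
#' @return a `bppm` object: fields `n`, `P` (upper-triangular matrix) and
#'   `paired` (per-position total pairing probability).
#' @export
basepair_probs <- function(seq, model = energy_model(), min_loop = 3) {
  seq <- toupper(seq)
  code <- encode_residues(seq)
  n <- length(code)
  Q <- matrix(0, max(n, 1), max(n, 1))
  if (n >= min_loop + 2) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in seq_len(n - min_loop - 1)) {
      js <- seq(i + min_loop + 1, n)
      ok <- is_canonical_pair(chars[i], chars[js])
      if (any(ok)) {
        e <- pair_energy_chr(chars[i], chars[js[ok]], model)
        Q[i, js[ok]] <- exp(-e / model$kT)
      }
    }
  }
  res <- NULL
  for (s in c(1, 2, 4, 8, 16)) {
    res <- cpp_mccaskill(Q, s)
    if (isTRUE(res$ok)) break
  }
  if (!isTRUE(res$ok)) abort("partition function over/underflowed at all scales")
  P <- res$P[seq_len(n), seq_len(n), drop = FALSE]
  paired <- if (n > 0) {
    rowSums(P) + colSums(P)
  } else {
    numeric(0)
  }
  structure(list(n = n, P = P, paired = paired, seq = seq,
                 logZ = res$logZ),
            class = "bppm")
}

#' @export
print.bppm <- function(x, ...) {
  cat(sprintf("Basepair probability matrix: %d nt, logZ = %.4f\n",
              x$n, x$logZ))
  invisible(x)
}

#' @method tidy bppm
#' @export
tidy.bppm <- function(x, p_min = 1e-4, ...) {
  idx <- which(x$P >= p_min, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                 p = x$P[idx]) |> dplyr::arrange(.data$i, .data$j)
}

#' Write a basepair probability matrix as TSV
#'
#' Columns `i`, `j` (0-based) and `p`, for `p >= p_min`.
#' @param x a `bppm`.
#' @param path output path.
#' @param p_min reporting threshold.
#' @return the path, invisibly.
#' @export
write_bppm_tsv <- function(x, path, p_min = 1e-4) {
  write.table(tidy(x, p_min = p_min), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Scoring scheme for intermolecular duplex alignment
#'
#' @param gc,au,gu scores for the canonical pair classes.
#' @param mismatch,gap penalties (negative).
#' @return a named list.
#' @export
duplex_scores <- function(gc = 2, au = 2, gu = 1, mismatch = -2, gap = -3) {
  list(gc = gc, au = au, gu = gu, mismatch = mismatch, gap = gap)
}

#' Best intermolecular duplex between a leader and a trailer
#'
#' Local dynamic-programming alignment of the leader (5' to 3') against the
#' trailer (3' to 5'), scoring canonical basepairs positively; the
#' maximum-scoring duplex is reported with its canonical basepair count.
#' An empty duplex (score 0) is allowed for non-complementary inputs.
#'
#' @param leader,trailer RNA strings.
#' @param scores a [duplex_scores()] list.
#' @return a `duplex_result`: `score`, `bp_count`, `pairs` (tibble of
#'   0-based `leader_pos`, `trailer_pos`), `leader_span`, `trailer_span`
#'   (1-based inclusive, NA when empty).
#' @export
duplex_align <- function(leader, trailer, scores = duplex_scores()) {
  if (nchar(leader) == 0 || nchar(trailer) == 0) {
    abort("duplex_align requires nonempty sequences")
  }
  res <- cpp_duplex(encode_residues(toupper(leader)),
                    encode_residues(toupper(trailer)),
                    scores$gc, scores$au, scores$gu,
                    scores$mismatch, scores$gap)
  pairs <- tibble::tibble(leader_pos = res$leader_pos,
                          trailer_pos = res$trailer_pos)
  span <- function(v) if (length(v) == 0) c(NA_integer_, NA_integer_) else
    range(v) + 1L
  structure(list(score = res$score, bp_count = nrow(pairs), pairs = pairs,
                 leader_span = span(pairs$leader_pos),
                 trailer_span = span(pairs$trailer_pos)),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("Duplex: %d bp, score %.1f\n", x$bp_count, x$score))
  invisible(x)
}

#' @method tidy duplex_result
#' @export
tidy.duplex_result <- function(x, ...) x$pairs
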