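combined_string <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) return(x$combined[1])
  abort("expected a combined sequence string or a flank_pairs row")
}

align_two <- function(a, b, match = 2, mismatch = -1, gap_open = -4,
                      gap_ext = -1) {
  A <- matrix(encode_residues(a), nrow = 1)
  B <- matrix(encode_residues(b), nrow = 1)
  cpp_profile_align(A, B, match, mismatch, gap_open, gap_ext)
}

#' Structure-aware distance between two flank pairs
#'
#' `D = 1 - (w_seq * S_seq + w_str * S_str)` on the NNNNNN-joined combined
#' strings. `S_seq` is global-alignment identity (match 1, mismatch 0,
#' affine gaps; columns where either row is N carry no identity credit and
#' are excluded from the denominator, so the 16S placeholder cannot drive
#' clustering). `S_str` is one minus the mean absolute difference of the
#' per-position pairing probabilities (row sums of each basepair
#' probability matrix) over aligned residue columns.
#'
#' @param a,b combined sequences (strings or `flank_pairs` rows).
#' @param weights `c(seq = , str = )`, non-negative, summing to 1.
#' @param model an [energy_model()] for the pairing profiles.
#' @param min_loop minimum hairpin loop.
#' @param profile_a,profile_b optional precomputed pairing profiles
#'   (numeric vectors), to reuse across many pairwise calls.
#' @return a distance in `[0, 1]`.
#' @export
pair_distance <- function(a, b, weights = c(seq = 0.5, str = 0.5),
                          model = energy_model(), min_loop = 3,
                          profile_a = NULL, profile_b = NULL) {
  a <- combined_string(a); b <- combined_string(b)
  if (b < a) { # canonical orientation makes the distance exactly symmetric
    tmp <- a; a <- b; b <- tmp
    tmp <- profile_a; profile_a <- profile_b; profile_b <- tmp
  }
  if (is.null(profile_a)) profile_a <- basepair_probs(a, model, min_loop)$paired
  if (is.null(profile_b)) profile_b <- basepair_probs(b, model, min_loop)$paired
  al <- align_two(a, b)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ra <- ifelse(al$a_cols >= 0, ca[al$a_cols + 1], "-")
  rb <- ifelse(al$b_cols >= 0, cb[al$b_cols + 1], "-")
  informative <- ra != "N" & rb != "N"
  matches <- sum(informative & ra == rb & ra != "-")
  s_seq <- if (sum(informative) > 0) matches / sum(informative) else 0
  both <- al$a_cols >= 0 & al$b_cols >= 0
  s_str <- if (any(both)) {
    1 - mean(abs(profile_a[al$a_cols[both] + 1] -
                   profile_b[al$b_cols[both] + 1]))
  } else 0
  w <- weights / sum(weights)
  d <- 1 - (w[["seq"]] * s_seq + w[["str"]] * s_str)
  min(max(d, 0), 1)
}

#' All pairwise structure-aware distances for a set of flank pairs
#'
#' Pairing profiles are computed once per sequence and reused.
#'
#' @param pairs a `flank_pairs` tibble (kept rows are used) or a named
#'   character vector of combined sequences.
#' @inheritParams pair_distance
#' @return a `dist_matrix`: symmetric labelled matrix with zero diagonal.
#' @export
flank_distances <- function(pairs, weights = c(seq = 0.5, str = 0.5),
                            model = energy_model(), min_loop = 3) {
  if (is.data.frame(pairs)) {
    kept <- dplyr::filter(pairs, .data$kept)
    seqs <- setNames(kept$combined, paste0(kept$assembly_id, "|",
                                           kept$gene_id))
  } else {
    seqs <- pairs
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique names")
  }
  n <- length(seqs)
  profiles <- purrr::map(seqs, ~ basepair_probs(.x, model, min_loop)$paired)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- pair_distance(seqs[[i]], seqs[[j]], weights, model, min_loop,
                           profile_a = profiles[[i]],
                           profile_b = profiles[[j]])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  structure(D, class = c("dist_matrix", "matrix", "array"))
}

#' Agglomerative clustering of flank pairs into an ultrametric tree
#'
#' Weighted-average linkage (WPGMA) by default; single, complete and
#' unweighted-average (UPGMA) linkage are available. The merge order is
#' deterministic: at equal distance the pair of clusters whose
#' lexicographically smallest member labels sort first is merged. The
#' `height` field follows the [stats::hclust] convention (merge distance);
#' `merge_height` holds the ultrametric node heights (half the merge
#' distance), which is also the scale [write_newick()] serialises, so
#' cophenetic distances on the tree reproduce the linkage distances.
#'
#' @param D a `dist_matrix` (or any labelled symmetric matrix).
#' @param linkage one of `"wpgma"`, `"single"`, `"complete"`, `"average"`.
#' @return a `clade_tree`, which is also a valid [stats::hclust] object.
#' @export
build_tree <- function(D, linkage = c("wpgma", "single", "complete",
                                      "average")) {
  linkage <- match.arg(linkage)
  labels <- rownames(D)
  n <- length(labels)
  if (n == 1) {
    return(structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                          order = 1L, labels = labels, method = linkage,
                          single_leaf = TRUE),
                     class = c("clade_tree", "hclust")))
  }
  d <- as.matrix(D)
  active <- seq_len(n)
  id <- -seq_len(n) # hclust convention: negative leaves
  rep_lab <- labels
  size <- rep(1, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in seq(ai + 1, length(active))) {
        a <- active[ai]; b <- active[bi]
        key <- sort(c(rep_lab[a], rep_lab[b]))
        cand <- list(d = d[a, b], a = a, b = b, key = key)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best$d
    for (c in setdiff(active, c(a, b))) {
      d_new <- switch(linkage,
        wpgma = (d[a, c] + d[b, c]) / 2,
        single = min(d[a, c], d[b, c]),
        complete = max(d[a, c], d[b, c]),
        average = (size[a] * d[a, c] + size[b] * d[b, c]) /
          (size[a] + size[b]))
      d[a, c] <- d_new
      d[c, a] <- d_new
    }
    size[a] <- size[a] + size[b]
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    id[a] <- step
    active <- setdiff(active, b)
  }
  order <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height,
                 merge_height = height / 2, order = order,
                 labels = labels, method = linkage, single_leaf = FALSE),
            class = c("clade_tree", "hclust"))
}

tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  as.integer(expand(nrow(merge)))
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("Clade tree: %d leaves, %s linkage\n", length(x$labels),
              x$method))
  invisible(x)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) return(tree)
  if (inherits(tree, "clade_tree") && isTRUE(tree$single_leaf)) {
    return(tree$labels)
  }
  if (inherits(tree, "hclust")) {
    h <- tree
    class(h) <- "hclust"
    return(ape::as.phylo(h))
  }
  abort("cannot interpret tree object")
}

#' Cut a clade tree into k clades
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` tree-consistent
#' clades. Clade indices run 1..k in order of leaf labels' first
#' appearance.
#'
#' @param tree a `clade_tree`.
#' @param k number of clades, between 1 and the number of leaves.
#' @return tibble with columns `id`, `clade`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) abort(sprintf("k must be in 1..%d, got %s", n, k))
  if (n == 1) return(tibble::tibble(id = tree$labels, clade = 1L))
  h <- tree
  class(h) <- "hclust"
  cl <- cutree(h, k = k)
  tibble::tibble(id = tree$labels, clade = as.integer(cl))
}

#' @method tidy clade_tree
#' @export
tidy.clade_tree <- function(x, ...) {
  tibble::tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2],
                 distance = x$height, height = x$merge_height)
}
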