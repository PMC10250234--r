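# Synthetic pre-16S flank generator: plants the anchor/boxC/boxA/boxB
# architecture and the hLT/h0/hA/hB helices in an ancestral locus, evolves
# it along a clade-structured phylogeny with compensatory substitutions,
# and embeds each evolved locus in a random genome with GFF3 annotation and
# a ground-truth manifest.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

complement_base <- function(b) chartr("ACGU", "UGCA", b)

# admissible 3' partners of a 5' base (canonical incl. wobble)
partners_3p <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
partners_5p <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))

#' Ancestral flank template
#'
#' Lays out, in sense coordinates around a dummy 16S gene (position 0 = the
#' annotated 5' end), a boxB hairpin, boxA, the boxA-boxC spacing, an hLT
#' 5' arm containing boxC, leader helices hA and hB, the h0 helix pairing
#' the leader tail with the first gene nucleotides, a random gene body
#' whose only non-random element is the 3'-terminal trailer anchor, and an
#' hLT 3' arm in the trailer that is the reverse complement of the 5' arm.
#' The anchor is placed so its match start sits 51 nt before the gene 3'
#' end; the default trailer slice then starts exactly at the gene end,
#' mirroring the E. coli trailer geometry. All planted helices are
#' canonically complementary in the ancestor.
#'
#' Uses the current RNG stream; seed via the caller.
#'
#' @param boxC_distance nt from the boxC match start to the annotated 5'
#'   end. The default 255 keeps planted pairs above the default 350-nt
#'   total-length filter (see [extraction_config()]).
#' @param spacing nt strictly between boxA and boxC (default 18).
#' @param gene_len gene body length.
#' @param hlt_bp planted hLT length in basepairs.
#' @param hA_bp,hB_bp,h0_bp arm lengths of the leader helices.
#' @param decoy_distance upstream distance of a planted exact decoy boxC
#'   outside the legal window; `NULL` for none.
#' @param anchor,boxA_motif,boxC_motif the planted motifs.
#' @return a `flank_template` list: `seq` (ancestor locus), `offset`
#'   (sense coordinate of the first locus character), `gene_len`,
#'   `elements` (named 0-based half-open sense intervals), `pairs` (tibble
#'   of planted pairs with helix labels), `motifs` (per-motif mismatch
#'   caps), `spacing`, `boxC_distance`.
#' @export
flank_template <- function(boxC_distance = 255, spacing = 18,
                           gene_len = 1542, hlt_bp = 25, hA_bp = 6,
                           hB_bp = 9, h0_bp = 9, decoy_distance = 300,
                           anchor = "AAGUCGUAACAAGGUA",
                           boxA_motif = BOXA_MOTIF,
                           boxC_motif = "UCUGUGUGGG") {
  d <- boxC_distance
  L <- gene_len
  stopifnot(hlt_bp >= nchar(boxC_motif) + 2, d > 41, L > 120)
  # leader-side intervals (sense coords, 0-based half-open)
  boxC <- c(-d, -d + nchar(boxC_motif))
  arm5_lead <- 5L # nt of the hLT 5' arm upstream of boxC
  arm5 <- c(boxC[1] - arm5_lead, boxC[1] - arm5_lead + hlt_bp)
  stopifnot(arm5[2] <= -120) # keep the arm clear of hA/hB/h0
  boxA <- c(boxC[1] - spacing - nchar(boxA_motif), boxC[1] - spacing)
  boxB_stem <- 6L; boxB_loop <- 4L
  boxB_len <- 2L * boxB_stem + boxB_loop
  boxB <- c(boxA[1] - 29L - boxB_len, boxA[1] - 29L)
  decoy <- if (!is.null(decoy_distance)) {
    c(-decoy_distance, -decoy_distance + nchar(boxC_motif))
  } else NULL
  hA1 <- c(-90L, -90L + hA_bp)
  hA2 <- c(-90L + hA_bp + 4L, -90L + 2L * hA_bp + 4L)
  hB1 <- c(-60L, -60L + hB_bp)
  hB2 <- c(-60L + hB_bp + 5L, -60L + 2L * hB_bp + 5L)
  h0L <- c(-2L - h0_bp, -2L)
  h0G <- c(8L, 8L + h0_bp)
  anchor_iv <- c(L - 51L, L - 51L + nchar(anchor))
  trailer_end <- L + 57L
  arm3 <- c(L + 10L, L + 10L + hlt_bp)
  from <- boxB[1] - 10L
  n <- trailer_end - from
  chars <- strsplit(random_rna(n), "", fixed = TRUE)[[1]]
  at <- function(iv) (iv[1] - from + 1L):(iv[2] - from)
  put <- function(iv, s) chars[at(iv)] <<- strsplit(s, "", fixed = TRUE)[[1]]
  put(boxA, boxA_motif)
  put(boxC, boxC_motif)
  put(anchor_iv, anchor)
  if (!is.null(decoy)) put(decoy, boxC_motif)
  # helices: make each 3' arm the reverse complement of its 5' arm
  pair_up <- function(iv5, iv3, helix) {
    i <- iv5[1]:(iv5[2] - 1L)
    j <- rev(iv3[1]:(iv3[2] - 1L))
    for (k in seq_along(i)) {
      chars[j[k] - from + 1L] <<-
        complement_base(chars[i[k] - from + 1L])
    }
    tibble::tibble(helix = helix, i = i, j = j)
  }
  pairs <- dplyr::bind_rows(
    pair_up(c(boxB[1], boxB[1] + boxB_stem),
            c(boxB[2] - boxB_stem, boxB[2]), "boxB"),
    pair_up(arm5, arm3, "hLT"),
    pair_up(hA1, hA2, "hA"),
    pair_up(hB1, hB2, "hB"),
    pair_up(h0L, h0G, "h0"))
  structure(list(
    seq = paste(chars, collapse = ""), offset = from, gene_len = L,
    elements = list(boxB = boxB, boxA = boxA, boxC = boxC, arm5 = arm5,
                    arm3 = arm3, hA1 = hA1, hA2 = hA2, hB1 = hB1,
                    hB2 = hB2, h0L = h0L, h0G = h0G, anchor = anchor_iv,
                    decoy = decoy,
                    leader = c(-(d + 23L), 18L),
                    trailer = c(L, trailer_end)),
    pairs = pairs,
    motifs = list(anchor = list(iv = anchor_iv, motif = anchor, cap = 0L),
                  boxA = list(iv = boxA, motif = boxA_motif, cap = 2L),
                  boxC = list(iv = boxC, motif = boxC_motif, cap = 2L)),
    spacing = as.integer(spacing), boxC_distance = as.integer(d)),
    class = "flank_template")
}

#' Evolution parameters for the flank simulation
#'
#' @param rate substitutions per site per unit branch length.
#' @param compensatory probability that a substitution at a paired site is
#'   mirrored at its partner, restoring canonical pairing.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(rate = 0.2, compensatory = 0.8) {
  stopifnot(rate >= 0, compensatory >= 0, compensatory <= 1)
  structure(list(rate = rate, compensatory = compensatory),
            class = "evolution_params")
}

#' Simulate a clade-structured phylogeny
#'
#' Random coalescent subtrees of small height (default 0.1) for each
#' clade, attached by long stems to a backbone whose merges sit near the
#' total depth 1, giving the long-stem/short-intra-branch shape that makes
#' clades separable. Deterministic per seed.
#'
#' @param n_leaves,n_clades leaf and clade counts.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param intra_height ultrametric height of each clade subtree.
#' @param depth leaf depth of the whole tree.
#' @return list `phylo` (an [ape::phylo]), `clades` (tibble `id`,
#'   `clade`).
#' @export
simulate_phylogeny <- function(n_leaves, n_clades, seed = NULL,
                               intra_height = 0.1, depth = 1) {
  if (n_clades > n_leaves || n_clades < 1 || n_leaves < 1) {
    abort("need 1 <= n_clades <= n_leaves")
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n_leaves %/% n_clades, n_clades)
  extra <- n_leaves %% n_clades
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ids <- sprintf("g%03d", seq_len(n_leaves))
  clade_of <- rep(seq_len(n_clades), sizes)
  sub_newick <- function(tips, height) {
    if (length(tips) == 1) return(list(txt = tips, h = 0))
    phy <- ape::rcoal(length(tips), tip.label = tips)
    dep <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (height / dep)
    list(txt = sub(";$", "", ape::write.tree(phy)), h = height)
  }
  subs <- purrr::map(seq_len(n_clades), function(k) {
    sub_newick(ids[clade_of == k], intra_height)
  })
  if (n_clades == 1) {
    txt <- paste0(subs[[1]]$txt, ";")
  } else {
    merge_h <- seq(0.85 * depth, depth, length.out = n_clades - 1)
    cur <- subs[[1]]
    for (k in seq(2, n_clades)) {
      h <- merge_h[k - 1]
      cur <- list(txt = sprintf("(%s:%g,%s:%g)", cur$txt, h - cur$h,
                                subs[[k]]$txt, h - subs[[k]]$h),
                  h = h)
    }
    txt <- paste0(cur$txt, ";")
  }
  phy <- ape::read.tree(text = txt)
  list(phylo = phy, clades = tibble::tibble(id = ids, clade = clade_of))
}

template_site_maps <- function(template) {
  n <- nchar(template$seq)
  off <- template$offset
  pair_of <- rep(NA_integer_, n) # index into template$pairs
  role <- rep(NA_character_, n)
  for (r in seq_len(nrow(template$pairs))) {
    pair_of[template$pairs$i[r] - off + 1L] <- r
    role[template$pairs$i[r] - off + 1L] <- "5p"
    pair_of[template$pairs$j[r] - off + 1L] <- r
    role[template$pairs$j[r] - off + 1L] <- "3p"
  }
  motif_of <- rep(NA_character_, n)
  for (m in names(template$motifs)) {
    iv <- template$motifs[[m]]$iv
    motif_of[(iv[1] - off + 1L):(iv[2] - off)] <- m
  }
  list(pair_of = pair_of, role = role, motif_of = motif_of)
}

motif_distance <- function(chars, template, name) {
  iv <- template$motifs[[name]]$iv
  ref <- strsplit(template$motifs[[name]]$motif, "", fixed = TRUE)[[1]]
  cur <- chars[(iv[1] - template$offset + 1L):(iv[2] - template$offset)]
  sum(cur != ref)
}

#' Evolve a flank template along a phylogeny
#'
#' Sites substitute independently down the tree with probability
#' `1 - exp(-rate * branch_length)`. A substitution at a planted paired
#' site is mirrored at its partner with probability `compensatory`,
#' uniformly among partners restoring a canonical pair; otherwise the
#' mismatch stands. Motif sites (anchor, boxA, boxC) only accept
#' substitutions keeping the motif within its mismatch cap, and a
#' compensation that would push a motif past its cap is skipped. No
#' indels, so alignment truth is exact. A compensation blocked by the
#' partner's motif cap rejects the whole substitution (selection removes
#' what cannot be repaired), so full compensation keeps every planted pair
#' canonical. Uses the current RNG stream.
#'
#' @param template a [flank_template()].
#' @param phylo an [ape::phylo] with branch lengths (e.g. from
#'   [simulate_phylogeny()]).
#' @param params an [evolution_params()].
#' @return list `loci` (named character: evolved locus per leaf),
#'   `combined` (leader+NNNNNN+trailer per leaf), `events` (tibble of
#'   compensatory events: `edge_child`, `pair`, `helix`, `i`, `j`),
#'   `template`.
#' @export
evolve_flanks <- function(template, phylo, params = evolution_params()) {
  maps <- template_site_maps(template)
  n <- nchar(template$seq)
  off <- template$offset
  bases <- c("A", "C", "G", "U")
  n_node <- max(phylo$edge)
  seqs <- vector("list", n_node)
  root <- length(phylo$tip.label) + 1L
  seqs[[root]] <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  events <- list()
  # parent-before-child edge order, independent of ape's internal ordering
  edge_order <- integer(0)
  ready <- c(root)
  remaining <- seq_len(nrow(phylo$edge))
  while (length(remaining) > 0) {
    nxt <- remaining[phylo$edge[remaining, 1] %in% ready]
    edge_order <- c(edge_order, nxt)
    ready <- c(ready, phylo$edge[nxt, 2])
    remaining <- setdiff(remaining, nxt)
  }
  done_pairs <- logical(nrow(template$pairs))
  for (e in edge_order) {
    parent <- phylo$edge[e, 1]; child <- phylo$edge[e, 2]
    t_len <- phylo$edge.length[e]
    chars <- seqs[[parent]]
    p <- 1 - exp(-params$rate * t_len)
    mut <- runif(n) < p
    try_set <- function(idx, new_base) {
      # returns TRUE if the base was set (motif caps permitting)
      m <- maps$motif_of[idx]
      if (!is.na(m)) {
        old <- chars[idx]
        chars[idx] <<- new_base
        if (motif_distance(chars, template, m) >
            template$motifs[[m]]$cap) {
          chars[idx] <<- old
          return(FALSE)
        }
        return(TRUE)
      }
      chars[idx] <<- new_base
      TRUE
    }
    done_pairs[] <- FALSE
    for (idx in which(mut)) {
      pr <- maps$pair_of[idx]
      if (!is.na(pr)) {
        if (done_pairs[pr]) next
        done_pairs[pr] <- TRUE
        i_idx <- template$pairs$i[pr] - off + 1L
        j_idx <- template$pairs$j[pr] - off + 1L
        driver <- if (mut[i_idx]) i_idx else j_idx
        other <- if (driver == i_idx) j_idx else i_idx
        old_driver <- chars[driver]
        new_base <- sample(setdiff(bases, chars[driver]), 1)
        if (!try_set(driver, new_base)) next
        if (runif(1) < params$compensatory) {
          adm <- if (driver == i_idx) partners_3p[[new_base]] else
            partners_5p[[new_base]]
          partner_base <- if (length(adm) == 1) adm else sample(adm, 1)
          if (try_set(other, partner_base)) {
            events[[length(events) + 1L]] <- tibble::tibble(
              edge_child = child, pair = pr,
              helix = template$pairs$helix[pr],
              i = template$pairs$i[pr], j = template$pairs$j[pr])
          } else {
            # partner is capped by a motif: the compensated substitution
            # cannot fix, so it is rejected outright
            chars[driver] <- old_driver
          }
        } else if (mut[other]) {
          try_set(other, sample(setdiff(bases, chars[other]), 1))
        }
      } else {
        try_set(idx, sample(setdiff(bases, chars[idx]), 1))
      }
    }
    seqs[[child]] <- chars
  }
  tips <- phylo$tip.label
  loci <- setNames(purrr::map_chr(seq_along(tips),
                                  ~ paste(seqs[[.x]], collapse = "")), tips)
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(edge_child = integer(), pair = integer(),
                   helix = character(), i = integer(), j = integer())
  combined <- purrr::map_chr(loci, ~ template_combined(template, .x))
  list(loci = loci, combined = combined, events = ev, template = template)
}

locus_slice <- function(template, locus, iv) {
  substr(locus, iv[1] - template$offset + 1L, iv[2] - template$offset)
}

template_combined <- function(template, locus, spacer = "NNNNNN") {
  paste0(locus_slice(template, locus, template$elements$leader), spacer,
         locus_slice(template, locus, template$elements$trailer))
}

# count planted hLT pairs still canonical in an evolved locus
planted_hlt_bp <- function(template, locus) {
  hp <- dplyr::filter(template$pairs, .data$helix == "hLT")
  chars <- strsplit(locus, "", fixed = TRUE)[[1]]
  off <- template$offset
  sum(is_canonical_pair(chars[hp$i - off + 1L], chars[hp$j - off + 1L]))
}

# break accidental boxC look-alikes inside the legal search window so the
# planted element is the unique in-window hit (the generator's contract
# with the recovery tests); paired filler sites are repaired with their
# partner to preserve structure truth
scrub_boxC_lookalikes <- function(template, locus, boxC_motif, max_mm,
                                  window, maps) {
  off <- template$offset
  chars <- strsplit(locus, "", fixed = TRUE)[[1]]
  true_start <- template$elements$boxC[1]
  repeat {
    idx_range <- c(-window[2] - off, -window[1] - off)
    hits <- fuzzy_find(paste(chars, collapse = ""), boxC_motif, max_mm,
                       search_range = idx_range)
    hits <- hits[hits$offset + off != true_start, , drop = FALSE]
    if (nrow(hits) == 0) break
    h <- hits[1, ]
    ref <- strsplit(boxC_motif, "", fixed = TRUE)[[1]]
    cand <- (h$offset + 1L):(h$offset + h$motif_len)
    # free positions still matching the motif; flipping each adds one
    # mismatch, so push the window past the tolerance in one pass
    free <- cand[is.na(maps$motif_of[cand]) &
                   chars[cand] == ref[cand - h$offset]]
    need <- max_mm + 1L - h$mismatches
    if (length(free) < need) break # overlaps the planted motif; leave it
    for (pos in free[seq_len(need)]) {
      repl <- setdiff(c("A", "C", "G", "U"),
                      c(chars[pos], ref[pos - h$offset]))
      chars[pos] <- repl[1]
      pr <- maps$pair_of[pos]
      if (!is.na(pr)) { # keep the planted pair canonical
        i_idx <- template$pairs$i[pr] - off + 1L
        j_idx <- template$pairs$j[pr] - off + 1L
        if (pos == i_idx) {
          chars[j_idx] <- partners_3p[[chars[pos]]][1]
        } else {
          chars[i_idx] <- partners_5p[[chars[pos]]][1]
        }
      }
    }
  }
  paste(chars, collapse = "")
}

#' Planted pairs in combined-sequence column coordinates
#'
#' Maps each planted helix pair of a template from sense coordinates to
#' 0-based columns of the combined leader+NNNNNN+trailer string; pairs
#' with either side outside the extracted leader/trailer (e.g. boxB) are
#' dropped. Because the simulation is indel-free these columns are also
#' the alignment columns of any gap-free progressive alignment of the
#' combined sequences.
#'
#' @param template a [flank_template()].
#' @param spacer_len spacer length (default 6).
#' @return tibble `helix`, `i`, `j` (sense), `col_i`, `col_j` (combined).
#' @export
template_combined_pairs <- function(template, spacer_len = 6L) {
  el <- template$elements
  lead <- el$leader; tra <- el$trailer
  lead_len <- lead[2] - lead[1]
  to_col <- function(p) {
    dplyr::case_when(
      p >= lead[1] & p < lead[2] ~ p - lead[1],
      p >= tra[1] & p < tra[2] ~ lead_len + spacer_len + (p - tra[1]),
      TRUE ~ NA_integer_)
  }
  out <- dplyr::mutate(template$pairs,
                       col_i = to_col(.data$i), col_j = to_col(.data$j))
  dplyr::filter(out, !is.na(.data$col_i) & !is.na(.data$col_j))
}

#' Planted pairs with within-clade compensatory events
#'
#' A compensatory event on a branch produces covariation *within* a clade
#' only if the branch's descendant leaves are a proper subset of that
#' clade's leaves (events on a clade stem or on the backbone are shared by
#' every row of the clade and leave no within-clade signal). Returns, per
#' clade, the planted pairs carrying at least one such event.
#'
#' @param sim an [evolve_flanks()] result.
#' @param phylo the phylogeny the simulation ran on.
#' @param clades tibble `id`, `clade`.
#' @return tibble `clade`, `helix`, `i`, `j` (sense coordinates), unique.
#' @export
compensatory_positions <- function(sim, phylo, clades) {
  if (nrow(sim$events) == 0) {
    return(tibble::tibble(clade = integer(), helix = character(),
                          i = integer(), j = integer()))
  }
  n_tip <- length(phylo$tip.label)
  desc_tips <- function(node) {
    if (node <= n_tip) return(phylo$tip.label[node])
    kids <- phylo$edge[phylo$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  purrr::map_dfr(sort(unique(clades$clade)), function(cl) {
    members <- clades$id[clades$clade == cl]
    ev <- sim$events
    keep <- vapply(ev$edge_child, function(nd) {
      tips <- desc_tips(nd)
      all(tips %in% members) && length(tips) < length(members)
    }, logical(1))
    dplyr::distinct(dplyr::mutate(ev[keep, c("helix", "i", "j")],
                                  clade = cl))
  })
}

#' Embed evolved flank loci in synthetic genomes
#'
#' Each locus is wrapped in random background sequence as its own contig
#' (one contig per gene copy; 1-2 copies per genome), placed on a random
#' strand, annotated as a 16S rRNA in GFF3, and described exactly in the
#' truth manifest. Optional truncation cases cut the contig shortly after
#' the gene so the extractor must report `Truncated`. DNA is emitted
#' (U -> T); the manifest stores RNA-sense sequences.
#'
#' @param sim result of [evolve_flanks()].
#' @param clades tibble `id`, `clade` from [simulate_phylogeny()].
#' @param bg background length on each side of the locus.
#' @param copy_range inclusive range of gene copies per genome.
#' @param truncate_genomes character vector of genome ids to emit as
#'   truncation cases (single copy, contig cut 10 nt after the gene).
#' @param scrub break accidental in-window boxC look-alikes (kept on for
#'   exact-recovery guarantees; see the generator's documentation).
#' @param boxC_max_mm mismatch tolerance the scrubber assumes.
#' @param boxC_window legal upstream window the scrubber assumes.
#' @return list `contigs` (tibble `id`, `residues` — DNA), `features`
#'   (GFF3-ready tibble), `truth` (manifest tibble), `template`.
#' @export
embed_in_genomes <- function(sim, clades, bg = 400, copy_range = c(1, 2),
                             truncate_genomes = character(),
                             scrub = TRUE, boxC_max_mm = 2,
                             boxC_window = c(90, 257)) {
  template <- sim$template
  maps <- template_site_maps(template)
  off <- template$offset
  L <- template$gene_len
  locus_len <- nchar(template$seq)
  contigs <- list(); features <- list(); truth <- list()
  for (g in names(sim$loci)) {
    locus <- sim$loci[[g]]
    if (scrub) {
      locus <- scrub_boxC_lookalikes(template, locus,
                                     template$motifs$boxC$motif,
                                     boxC_max_mm, boxC_window, maps)
    }
    truncated <- g %in% truncate_genomes
    n_copies <- if (truncated) 1L else
      sample(seq(copy_range[1], copy_range[2]), 1)
    clade <- clades$clade[clades$id == g]
    for (cp in seq_len(n_copies)) {
      contig_id <- sprintf("%s_c%d", g, cp)
      strand <- sample(c("+", "-"), 1)
      left <- random_rna(bg)
      right <- if (truncated) {
        # locus already extends 57 nt past the gene; cutting it 10 nt
        # after the gene end truncates the trailer window
        NULL
      } else {
        random_rna(bg)
      }
      plus_locus <- if (truncated) {
        substr(locus, 1, (L + 10L) - off)
      } else locus
      plus <- paste0(left, plus_locus, if (is.null(right)) "" else right)
      gene_start_plus <- bg + (0L - off) # contig 0-based
      gene_end_plus <- gene_start_plus + L
      clen <- nchar(plus)
      contig_rna <- if (strand == "+") plus else revcomp_rna(plus)
      map_iv <- function(iv) {
        # sense interval -> contig 0-based half-open
        a <- gene_start_plus + iv[1]; b <- gene_start_plus + iv[2]
        if (strand == "+") c(a, b) else c(clen - b, clen - a)
      }
      gene_iv <- map_iv(c(0L, L))
      el <- template$elements
      mk <- function(iv) if (is.null(iv)) c(NA_integer_, NA_integer_) else
        map_iv(iv)
      leader_iv <- mk(el$leader); trailer_iv <- mk(el$trailer)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        genome_id = g, contig_id = contig_id, strand = strand,
        clade = clade, expect = if (truncated) "Truncated" else "kept",
        gene_start = gene_iv[1], gene_end = gene_iv[2],
        leader_start = leader_iv[1], leader_end = leader_iv[2],
        trailer_start = trailer_iv[1], trailer_end = trailer_iv[2],
        anchor_start = mk(el$anchor)[1], anchor_end = mk(el$anchor)[2],
        boxA_start = mk(el$boxA)[1], boxA_end = mk(el$boxA)[2],
        boxB_start = mk(el$boxB)[1], boxB_end = mk(el$boxB)[2],
        boxC_start = mk(el$boxC)[1], boxC_end = mk(el$boxC)[2],
        boxC_distance = template$boxC_distance,
        spacing = template$spacing,
        hlt_bp = planted_hlt_bp(template, locus),
        leader_seq = if (truncated) NA_character_ else
          locus_slice(template, locus, el$leader),
        trailer_seq = if (truncated) NA_character_ else
          locus_slice(template, locus, el$trailer),
        combined = if (truncated) NA_character_ else
          template_combined(template, locus))
      contigs[[length(contigs) + 1L]] <- tibble::tibble(
        id = contig_id, residues = chartr("U", "T", contig_rna),
        description = NA_character_)
      features[[length(features) + 1L]] <- tibble::tibble(
        contig_id = contig_id, start = gene_iv[1], end = gene_iv[2],
        strand = strand, feature_type = "rRNA",
        feature_id = sprintf("%s_rrn", contig_id),
        product = "16S ribosomal RNA", assembly_id = g)
    }
  }
  list(contigs = dplyr::bind_rows(contigs),
       features = dplyr::bind_rows(features),
       truth = dplyr::bind_rows(truth), template = template)
}

#' One-call synthetic data set
#'
#' Phylogeny + template + evolution + genome embedding, all from one seed.
#'
#' @param n_genomes,n_clades cohort shape.
#' @param seed integer seed (all randomness flows from it).
#' @param template_args,evolution_args,embed_args argument lists passed to
#'   [flank_template()], [evolution_params()] and [embed_in_genomes()].
#' @param n_truncated number of genomes emitted as truncation cases.
#' @param outdir if non-NULL, writes `genomes/<id>.fasta`,
#'   `annotations/<id>.gff3` and `truth.json` under it.
#' @return list `contigs`, `features`, `truth`, `tree` (phylo), `clades`,
#'   `evolution` (the [evolve_flanks()] result), `template`.
#' @export
simulate_genomes <- function(n_genomes, n_clades = 1, seed = 1,
                             template_args = list(),
                             evolution_args = list(), embed_args = list(),
                             n_truncated = 0, outdir = NULL) {
  set.seed(seed)
  phy <- simulate_phylogeny(n_genomes, n_clades)
  template <- do.call(flank_template, template_args)
  params <- do.call(evolution_params, evolution_args)
  sim <- evolve_flanks(template, phy$phylo, params)
  trunc <- if (n_truncated > 0) {
    tail(phy$clades$id, n_truncated)
  } else character()
  emb <- do.call(embed_in_genomes,
                 c(list(sim = sim, clades = phy$clades,
                        truncate_genomes = trunc), embed_args))
  out <- list(contigs = emb$contigs, features = emb$features,
              truth = emb$truth, tree = phy$phylo, clades = phy$clades,
              evolution = sim, template = template)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "genomes"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outdir, "annotations"), recursive = TRUE,
               showWarnings = FALSE)
    for (g in unique(emb$features$assembly_id)) {
      ct <- emb$contigs[emb$contigs$id %in%
                          emb$features$contig_id[emb$features$assembly_id ==
                                                   g], ]
      write_fasta(ct, file.path(outdir, "genomes", paste0(g, ".fasta")))
      write_gff3(emb$features[emb$features$assembly_id == g, ],
                 file.path(outdir, "annotations", paste0(g, ".gff3")))
    }
    jsonlite::write_json(emb$truth, file.path(outdir, "truth.json"),
                         dataframe = "rows", na = "null")
  }
  out
}
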