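# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own DP kernels.

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# Boltzmann pair frequencies by full enumeration (uses the package's
# enumerate_structures, itself checked against an independent counter).
boltzmann_pair_freqs <- function(seq, model, min_loop = 3) {
  structs <- enumerate_structures(seq, min_loop)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  energy_of <- function(pairs) {
    if (nrow(pairs) == 0) return(0)
    sum(vapply(seq_len(nrow(pairs)), function(r) {
      key <- paste0(ch[pairs[r, 1] + 1], ch[pairs[r, 2] + 1])
      switch(key, GC = , CG = model$gc, AU = , UA = model$au,
             GU = , UG = model$gu)
    }, numeric(1)))
  }
  w <- vapply(structs, function(s) exp(-energy_of(s$pairs) / model$kT),
              numeric(1))
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    p <- structs[[k]]$pairs
    if (nrow(p) > 0) {
      for (r in seq_len(nrow(p))) {
        P[p[r, 1] + 1, p[r, 2] + 1] <- P[p[r, 1] + 1, p[r, 2] + 1] + w[k]
      }
    }
  }
  P / sum(w)
}

# independent recursive count of admissible structures (no construction)
count_structures <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  canon <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env()
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    ls <- if (i + min_loop + 1 <= j) seq(i + min_loop + 1, j) else integer()
    for (l in ls) {
      if (canon(ch[i + 1], ch[l + 1])) {
        total <- total + cnt(i + 1, l - 1) * cnt(l + 1, j)
      }
    }
    memo[[key]] <- total
    total
  }
  cnt(0, length(ch) - 1)
}

# quadratic affine-gap global alignment score oracle (Gotoh, scores only)
global_align_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = -4, gap_ext = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + (i - 1) * gap_ext
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + (j - 1) * gap_ext
  sc <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  for (i in 0:n) for (j in 0:m) {
    if (i > 0 && j > 0) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc(A[i], B[j])
    }
    if (i > 0 && j > 0) {
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, Y[i, j + 1] + gap_open,
                             X[i, j + 1] + gap_ext)
    } else if (i > 0 && j == 0) {
      # boundary set above
    }
    if (j > 0 && i > 0) {
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, X[i + 1, j] + gap_open,
                             Y[i + 1, j] + gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force best duplex over all ungapped leader/trailer windows --
# gapless oracle; only valid for comparisons where gaps cannot help
brute_duplex_bp <- function(leader, trailer, gc = 2, au = 2, gu = 1,
                            mismatch = -2) {
  L <- strsplit(leader, "", fixed = TRUE)[[1]]
  Tr <- rev(strsplit(trailer, "", fixed = TRUE)[[1]])
  ps <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) gc else if (key %in% c("AU", "UA")) au
    else if (key %in% c("GU", "UG")) gu else mismatch
  }
  best <- list(score = 0, bp = 0)
  for (i in seq_along(L)) for (j in seq_along(Tr)) {
    sc <- 0; bp <- 0; k <- 0
    while (i + k <= length(L) && j + k <= length(Tr)) {
      s <- ps(L[i + k], Tr[j + k])
      sc <- sc + s
      if (s > 0) bp <- bp + 1
      if (sc <= 0) { sc <- 0; bp <- 0 } # local reset
      if (sc > best$score) best <- list(score = sc, bp = bp)
      k <- k + 1
    }
  }
  best
}

# tiny single-gene fixture: one plus-strand contig with configurable
# boxC distance, anchor placement and padding, all exact motifs; the
# upstream pad is an A-run so no chance boxC look-alike can appear in the
# search window (the geometry, not background realism, is under test)
make_gene_fixture <- function(boxC_distance = 255, lead_pad = 400,
                              tail_pad = 400, gene_len = 400,
                              anchor_from_end = 51,
                              boxC = "UCUGUGUGGG",
                              anchor = "AAGUCGUAACAAGGUA",
                              mutate_boxC = 0) {
  stopifnot(boxC_distance + 10 <= lead_pad)
  up <- rep("A", lead_pad)
  bc <- strsplit(boxC, "", fixed = TRUE)[[1]]
  if (mutate_boxC > 0) {
    pos <- seq_len(mutate_boxC)
    bc[pos] <- vapply(bc[pos], function(x)
      sample(setdiff(c("A", "C", "G", "U"), x), 1), character(1))
  }
  s <- lead_pad - boxC_distance
  up[(s + 1):(s + 10)] <- bc
  gene <- strsplit(rand_rna(gene_len), "", fixed = TRUE)[[1]]
  a0 <- gene_len - anchor_from_end
  gene[(a0 + 1):(a0 + nchar(anchor))] <-
    strsplit(anchor, "", fixed = TRUE)[[1]]
  contig <- paste(c(up, gene, strsplit(rand_rna(tail_pad), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  list(contig = contig, start = lead_pad, end = lead_pad + gene_len,
       boxC_distance = boxC_distance)
}

fixture_context <- function(fx, cfg = extraction_config()) {
  need <- rrnflank:::required_flanks(cfg)
  gene_sense_context(fx$contig, fx$start, fx$end, "+",
                     up = need$up, down = need$down)
}
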