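test_that("fuzzy_find matches a brute-force Hamming scan", {
  hits <- fuzzy_find("AAUCUGUGUGGGAA", "UCUGUGUGGG", 0)
  expect_equal(hits$offset, 2L)
  expect_equal(hits$mismatches, 0L)
  set.seed(1)
  for (r in 1:200) {
    hay <- rand_rna(sample(20:60, 1))
    motif <- rand_rna(sample(4:8, 1))
    mm <- sample(0:2, 1)
    got <- fuzzy_find(hay, motif, mm)
    H <- strsplit(hay, "")[[1]]; M <- strsplit(motif, "")[[1]]
    want <- integer()
    for (o in 0:(length(H) - length(M))) {
      d <- sum(H[o + seq_along(M)] != M | H[o + seq_along(M)] == "N")
      if (d <= mm) want <- c(want, o)
    }
    expect_equal(got$offset, want)
  }
})

test_that("fuzzy_find honours mismatch cap, search range, N and errors", {
  motif <- "UCUGUGUGGG"
  variant2 <- "UAUGUGUGGC" # Hamming distance 2
  variant3 <- "UAUAUGUGGC" # distance 3
  expect_equal(nrow(fuzzy_find(paste0("AA", variant2, "AA"), motif, 2)), 1)
  expect_equal(nrow(fuzzy_find(paste0("AA", variant3, "AA"), motif, 2)), 0)
  # N in haystack mismatches every motif symbol
  expect_equal(nrow(fuzzy_find(paste0("AA", "UCUGUGUGGN", "AA"), motif, 0)), 0)
  # match start must lie in search range
  hay <- paste0("AA", motif, "AA")
  expect_equal(nrow(fuzzy_find(hay, motif, 0, search_range = c(0, 1))), 0)
  expect_equal(nrow(fuzzy_find(hay, motif, 0, search_range = c(2, 2))), 1)
  expect_error(fuzzy_find(hay, "", 0), "empty motif")
})

test_that("gene_sense_context handles strands, truncation and the map", {
  contig <- "AAAACCCCGGGGUUUUACGU"
  ctx <- gene_sense_context(contig, 8, 12, "+", up = 4, down = 4)
  expect_equal(ctx$seq, "CCCCGGGGUUUU")
  expect_equal(ctx$sense_start, -4)
  expect_false(ctx$trunc_up || ctx$trunc_down)
  expect_equal(sense_to_contig(ctx, 0, 4), c(8, 12))
  # minus strand: hand-computed reverse complement of the same window
  ctxm <- gene_sense_context(contig, 8, 12, "-", up = 4, down = 4)
  expect_equal(ctxm$seq, revcomp_rna(substr(contig, 5, 16)))
  expect_equal(sense_to_contig(ctxm, 0, 4), c(8, 12))
  # every position round-trips through the map
  for (p in 0:3) {
    iv <- sense_to_contig(ctxm, p, p + 1)
    expect_equal(revcomp_rna(substr(contig, iv[1] + 1, iv[2])),
                 substr(ctxm$seq, p + 4 + 1, p + 4 + 1))
  }
  # truncation is recorded, not fatal
  ctxt <- gene_sense_context(contig, 8, 12, "+", up = 4, down = 200)
  expect_true(ctxt$trunc_down)
})

test_that("locate_trailer slices 51..107 downstream of the anchor", {
  set.seed(7)
  fx <- make_gene_fixture()
  cfg <- extraction_config()
  ctx <- fixture_context(fx, cfg)
  tr <- locate_trailer(ctx, cfg)
  expect_equal(tr$status, "ok")
  expect_equal(nchar(tr$trailer), 57)
  # first trailer residue is 51 nt downstream of the anchor match start
  m0 <- tr$anchor_sense
  expect_equal(tr$trailer_sense[1], m0 + 51)
  expect_equal(substr(ctx$seq, tr$trailer_sense[1] - ctx$sense_start + 1,
                      tr$trailer_sense[2] - ctx$sense_start),
               tr$trailer)
  # anchor absent -> NoAnchor
  fx2 <- make_gene_fixture(anchor = "AAAAAAAAAAAAAAAA")
  fx2$contig <- gsub("AAGUCGUAACAAGGUA", "CCCCCCCCCCCCCCCC", fx2$contig)
  ctx2 <- fixture_context(fx2, cfg)
  expect_equal(locate_trailer(ctx2, cfg)$status, "NoAnchor")
})

test_that("extraction is strand symmetric", {
  set.seed(8)
  fx <- make_gene_fixture()
  contigs <- tibble::tibble(id = "c1", residues = fx$contig,
                            description = NA)
  feats <- tibble::tibble(contig_id = "c1", start = fx$start, end = fx$end,
                          strand = "+", feature_type = "rRNA",
                          feature_id = "g", product = "16S")
  plus <- extract_flank_pairs(contigs, feats)
  contigs_rc <- tibble::tibble(id = "c1", residues = revcomp_rna(fx$contig),
                               description = NA)
  L <- nchar(fx$contig)
  feats_rc <- dplyr::mutate(feats, start = L - fx$end, end = L - fx$start,
                            strand = "-")
  minus <- extract_flank_pairs(contigs_rc, feats_rc)
  expect_equal(minus$leader, plus$leader)
  expect_equal(minus$trailer, plus$trailer)
  expect_equal(minus$combined, plus$combined)
  expect_equal(minus$boxC_distance, plus$boxC_distance)
})

test_that("locate_leader applies the window and keeps the 3'-most match", {
  cfg <- extraction_config()
  set.seed(9)
  # exact boxC at distance 120 -> leader length 120 + 23 + 18 = 161
  fx <- make_gene_fixture(boxC_distance = 120)
  ld <- locate_leader(fixture_context(fx, cfg), cfg)
  expect_equal(ld$status, "ok")
  expect_equal(ld$boxC_distance, 120L)
  expect_equal(nchar(ld$leader), 161)
  # verify against slicing the fixture by hand
  expect_equal(ld$leader,
               substr(fx$contig, fx$start - 120 - 23 + 1, fx$start + 18))
  # two exact hits at d = 150 and d = 110 -> d = 110 chosen
  fx2 <- make_gene_fixture(boxC_distance = 150)
  s <- fx2$start - 110
  substr(fx2$contig, s + 1, s + 10) <- "UCUGUGUGGG"
  ld2 <- locate_leader(fixture_context(fx2, cfg), cfg)
  expect_equal(ld2$boxC_distance, 110L)
  # exact motif only at d = 80 -> outside the 90..257 window
  fx3 <- make_gene_fixture(boxC_distance = 80)
  expect_equal(locate_leader(fixture_context(fx3, cfg), cfg)$status,
               "NoBoxC")
})

test_that("length filter keeps 350 and discards 349", {
  cfg <- extraction_config()
  p350 <- assemble_flank_pair(rand_rna(293), rand_rna(57), cfg)
  expect_true(p350$kept)
  p349 <- assemble_flank_pair(rand_rna(292), rand_rna(57), cfg)
  expect_false(p349$kept)
  expect_equal(p349$discard_reason, "too_short")
  # spacer sits exactly at the leader boundary
  lead <- rand_rna(293)
  expect_equal(substr(p350$combined, 294, 299), "NNNNNN")
  ap <- assemble_flank_pair(lead, rand_rna(57), cfg)
  expect_equal(substr(ap$combined, 1, 293), lead)
})

test_that("extract_flank_pairs recovers planted pairs and flags decoys", {
  sim <- simulate_genomes(10, n_clades = 2, seed = 42, n_truncated = 1)
  pairs <- extract_flank_pairs(sim$contigs, sim$features)
  rep <- glance(pairs)
  tr <- sim$truth
  merged <- dplyr::inner_join(tibble::as_tibble(pairs), tr,
                              by = c(contig = "contig_id"),
                              suffix = c("", ".t"))
  keptm <- dplyr::filter(merged, .data$expect == "kept")
  # every valid planted pair recovered with exact coordinates and sequence
  expect_true(all(keptm$kept))
  expect_equal(keptm$leader_start, keptm$leader_start.t + 1L)
  expect_equal(keptm$leader_end, keptm$leader_end.t)
  expect_equal(keptm$trailer_start, keptm$trailer_start.t + 1L)
  expect_equal(keptm$trailer_end, keptm$trailer_end.t)
  expect_equal(keptm$combined, keptm$combined.t)
  # the planted decoy boxC (distance 300) is never chosen
  expect_true(all(keptm$boxC_distance == keptm$boxC_distance.t))
  # truncation case reported as such
  truncm <- dplyr::filter(merged, .data$expect == "Truncated")
  expect_equal(unique(truncm$discard_reason), "Truncated")
  expect_equal(rep$Truncated, nrow(truncm))
  # two-copy genomes yield independent pairs
  expect_true(any(table(pairs$assembly_id) == 2))
})

test_that("extraction TSV output is deterministic", {
  sim <- simulate_genomes(4, n_clades = 1, seed = 3)
  pairs <- extract_flank_pairs(sim$contigs, sim$features)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_flank_pairs(pairs, tsv = f1)
  write_flank_pairs(extract_flank_pairs(sim$contigs, sim$features),
                    tsv = f2)
  expect_identical(readLines(f1), readLines(f2))
})
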