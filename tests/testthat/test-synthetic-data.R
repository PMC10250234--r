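test_that("simulate_phylogeny is deterministic with valid shapes", {
  p1 <- simulate_phylogeny(4, 2, seed = 1)
  p2 <- simulate_phylogeny(4, 2, seed = 1)
  expect_equal(ape::write.tree(p1$phylo), ape::write.tree(p2$phylo))
  expect_equal(p1$clades, p2$clades)
  expect_equal(as.integer(table(p1$clades$clade)), c(2L, 2L))
  # singleton clades
  ps <- simulate_phylogeny(5, 5, seed = 2)
  expect_equal(unname(table(ps$clades$clade)), rep(1L, 5),
               ignore_attr = TRUE)
  expect_error(simulate_phylogeny(3, 4), "n_clades")
  # branch lengths non-negative across seeds
  for (s in 1:25) {
    p <- simulate_phylogeny(sample(4:12, 1), sample(1:4, 1), seed = s)
    expect_true(all(p$phylo$edge.length >= 0))
  }
})

test_that("templates plant complementary helices inside the windows", {
  set.seed(51)
  tpl <- flank_template()
  ch <- strsplit(tpl$seq, "")[[1]]
  off <- tpl$offset
  # every planted pair is canonical in the ancestor
  expect_true(all(rrnflank:::is_canonical_pair(
    ch[tpl$pairs$i - off + 1], ch[tpl$pairs$j - off + 1])))
  # boxC sits at the configured upstream distance, inside the hLT 5' arm
  expect_equal(paste(ch[(tpl$elements$boxC[1] - off + 1):
                          (tpl$elements$boxC[2] - off)], collapse = ""),
               "UCUGUGUGGG")
  expect_true(tpl$elements$boxC[1] >= tpl$elements$arm5[1] &&
                tpl$elements$boxC[2] <= tpl$elements$arm5[2])
  # boxA ends `spacing` nt before boxC
  expect_equal(tpl$elements$boxC[1] - tpl$elements$boxA[2], tpl$spacing)
  # anchor match start is 51 nt before the gene 3' end, so the default
  # trailer slice starts at the gene end
  expect_equal(tpl$elements$anchor[1], tpl$gene_len - 51L)
})

test_that("evolution respects rate zero, full compensation and caps", {
  tpl_tree <- function(seed) {
    set.seed(seed)
    list(tpl = flank_template(), phy = simulate_phylogeny(6, 2)$phylo)
  }
  x <- tpl_tree(52)
  still <- evolve_flanks(x$tpl, x$phy, evolution_params(rate = 0))
  expect_true(all(still$loci == x$tpl$seq))
  # c = 1, high rate: every planted pair canonical in every leaf
  x <- tpl_tree(53)
  hot <- evolve_flanks(x$tpl, x$phy,
                       evolution_params(rate = 1, compensatory = 1))
  for (locus in hot$loci) {
    ch <- strsplit(locus, "")[[1]]
    off <- x$tpl$offset
    expect_true(all(rrnflank:::is_canonical_pair(
      ch[x$tpl$pairs$i - off + 1], ch[x$tpl$pairs$j - off + 1])))
  }
  # motifs never drift past their caps; the anchor is immutable
  for (locus in hot$loci) {
    ch <- strsplit(locus, "")[[1]]
    expect_equal(rrnflank:::motif_distance(ch, x$tpl, "anchor"), 0)
    expect_lte(rrnflank:::motif_distance(ch, x$tpl, "boxC"), 2)
    expect_lte(rrnflank:::motif_distance(ch, x$tpl, "boxA"), 2)
  }
  # c = 0 at high rate leaves mismatches behind
  x <- tpl_tree(54)
  cold <- evolve_flanks(x$tpl, x$phy,
                        evolution_params(rate = 1, compensatory = 0))
  broken <- vapply(cold$loci, function(locus) {
    ch <- strsplit(locus, "")[[1]]
    off <- x$tpl$offset
    sum(!rrnflank:::is_canonical_pair(
      ch[x$tpl$pairs$i - off + 1], ch[x$tpl$pairs$j - off + 1]))
  }, numeric(1))
  expect_gt(sum(broken), 0)
})

test_that("manifest intervals slice the emitted FASTA exactly", {
  sim <- simulate_genomes(8, n_clades = 2, seed = 55)
  seqs <- setNames(sim$contigs$residues, sim$contigs$id)
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    if (tr$expect != "kept") next
    contig <- chartr("T", "U", seqs[[tr$contig_id]])
    slice <- function(a, b) {
      s <- substr(contig, a + 1, b)
      if (tr$strand == "-") revcomp_rna(s) else s
    }
    got_leader <- if (tr$strand == "+") slice(tr$leader_start, tr$leader_end)
      else slice(tr$leader_start, tr$leader_end)
    expect_equal(got_leader, tr$leader_seq)
    expect_equal(slice(tr$trailer_start, tr$trailer_end), tr$trailer_seq)
    # boxC interval holds a <=2-mismatch copy of the motif
    bc <- slice(tr$boxC_start, tr$boxC_end)
    expect_lte(sum(strsplit(bc, "")[[1]] !=
                     strsplit("UCUGUGUGGG", "")[[1]]), 2)
  }
})

test_that("simulation output is byte-identical across equal seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_genomes(5, 2, seed = 56, outdir = d1)
  s2 <- simulate_genomes(5, 2, seed = 56, outdir = d2)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$truth, s2$truth)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("strands are drawn from both orientations", {
  sim <- simulate_genomes(30, 2, seed = 57)
  tab <- table(sim$features$strand)
  expect_true(all(c("+", "-") %in% names(tab)))
  expect_gt(stats::binom.test(tab[["+"]], sum(tab), 0.5)$p.value, 0.01)
})

test_that("planted pair bookkeeping maps to combined columns", {
  set.seed(58)
  tpl <- flank_template()
  pl <- template_combined_pairs(tpl)
  # boxB lies outside the leader and must be dropped
  expect_false("boxB" %in% pl$helix)
  expect_true(all(c("hLT", "hA", "hB", "h0") %in% pl$helix))
  lead_len <- tpl$elements$leader[2] - tpl$elements$leader[1]
  hlt <- dplyr::filter(pl, .data$helix == "hLT")
  expect_true(all(hlt$col_i < lead_len))
  expect_true(all(hlt$col_j >= lead_len + 6))
})
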