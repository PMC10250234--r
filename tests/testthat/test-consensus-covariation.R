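test_that("progressive alignment is exact for pairs and tight for sets", {
  set.seed(31)
  # identical sequences align gap-free
  seqs <- setNames(rep(rand_rna(40), 3), paste0("s", 1:3))
  aln <- progressive_align(seqs)
  expect_equal(aln$width, 40)
  expect_false(any(grepl("-", aln$rows)))
  # two sequences: score equals an independent Gotoh oracle
  for (r in 1:15) {
    a <- rand_rna(sample(10:40, 1)); b <- rand_rna(sample(10:40, 1))
    al <- rrnflank:::align_two(a, b)
    expect_equal(al$score, global_align_score(a, b), tolerance = 1e-9)
  }
  # degapping a row reproduces its input; width >= longest input
  set.seed(32)
  seqs <- setNames(purrr::map_chr(1:5, ~ rand_rna(sample(25:35, 1))),
                   paste0("q", 1:5))
  aln <- progressive_align(seqs)
  expect_gte(aln$width, max(nchar(seqs)))
  for (id in names(seqs)) {
    expect_equal(gsub("-", "", aln$rows[[id]]), seqs[[id]])
  }
  expect_error(progressive_align(seqs,
                                 guide = build_tree(matrix(0, 1, 1,
                                   dimnames = list("z", "z")))),
               "do not match")
})

test_that("consensus folding reduces to single-sequence folding", {
  rows <- setNames(rep("GGGAAACCC", 4), paste0("r", 1:4))
  aln <- progressive_align(rows)
  cons <- consensus_fold(aln)
  expect_equal(unname(cons$pairs),
               matrix(c(0L, 8L, 1L, 7L, 2L, 6L), 3, byrow = TRUE))
  # all-A alignment folds to nothing
  rowsA <- setNames(rep(strrep("A", 12), 3), paste0("a", 1:3))
  expect_equal(nrow(consensus_fold(progressive_align(rowsA))$pairs), 0)
})

test_that("covarying pairs outscore invariant pairs in the fold score", {
  # column pair with GC in half the rows and AU in the other half:
  # score 1 + beta/5; invariant GC pair: score 1
  codes_cov <- rbind(c(2L, 1L), c(2L, 1L), c(0L, 3L), c(0L, 3L))
  codes_inv <- rbind(c(2L, 1L), c(2L, 1L), c(2L, 1L), c(2L, 1L))
  S_cov <- rrnflank:::column_pair_scores(
    cbind(codes_cov[, 1], matrix(0L, 4, 4), codes_cov[, 2]),
    tau = 0.5, beta = 1, gamma = 1, min_loop = 3)
  S_inv <- rrnflank:::column_pair_scores(
    cbind(codes_inv[, 1], matrix(0L, 4, 4), codes_inv[, 2]),
    tau = 0.5, beta = 1, gamma = 1, min_loop = 3)
  expect_equal(S_cov[1, 6], 1 + 1 / 5)
  expect_equal(S_inv[1, 6], 1)
  expect_gt(S_cov[1, 6], S_inv[1, 6])
})

test_that("covariation statistics reproduce the colour legend", {
  mk_aln <- function(rows) {
    structure(list(rows = setNames(rows, paste0("r", seq_along(rows))),
                   width = nchar(rows[1])), class = "rna_alignment")
  }
  spacer <- function(x, y) paste0(x, "AAAA", y)
  cons <- as_consensus_structure(matrix(c(0L, 5L), 1), 6)
  # {GC, GC, AU} -> 2 types, 0 mismatches: yellow, full
  st <- covariation_stats(mk_aln(c(spacer("G", "C"), spacer("G", "C"),
                                   spacer("A", "U"))), cons)
  expect_equal(st$n_types, 2L)
  expect_equal(st$n_mismatch, 0L)
  expect_equal(st$color, "yellow")
  expect_equal(st$tint, "full")
  # all six ordered canonical types -> magenta
  st_all <- covariation_stats(mk_aln(c(spacer("G", "C"), spacer("C", "G"),
                                    spacer("A", "U"), spacer("U", "A"),
                                    spacer("G", "U"), spacer("U", "G"))),
                           cons)
  expect_equal(st_all$n_types, 6L)
  expect_equal(st_all$color, "magenta")
  # {GC, GA, CA, AA} -> 1 type, 3 mismatches: red, white
  stw <- covariation_stats(mk_aln(c(spacer("G", "C"), spacer("G", "A"),
                                    spacer("C", "A"), spacer("A", "A"))),
                           cons)
  expect_equal(stw$n_types, 1L)
  expect_equal(stw$n_mismatch, 3L)
  expect_equal(stw$color, "red")
  expect_equal(stw$tint, "white")
  # gaps count as mismatches; full tint map
  stg <- covariation_stats(mk_aln(c(spacer("G", "C"), spacer("-", "C"))),
                           cons)
  expect_equal(stg$n_mismatch, 1L)
  expect_equal(stg$tint, "medium")
  st2 <- covariation_stats(mk_aln(c(spacer("G", "C"), spacer("-", "C"),
                                    spacer("G", "-"))), cons)
  expect_equal(st2$tint, "light")
})

test_that("covariation counts are invariant under row reordering", {
  set.seed(33)
  seqs <- setNames(purrr::map_chr(1:6, ~ rand_rna(30)), paste0("s", 1:6))
  aln <- progressive_align(seqs)
  cons <- consensus_fold(aln)
  st1 <- covariation_stats(aln, cons)
  aln2 <- aln
  aln2$rows <- aln2$rows[rev(names(aln2$rows))]
  st2 <- covariation_stats(aln2, cons)
  expect_equal(st1, st2)
})

test_that("n_types never exceeds six", {
  set.seed(34)
  seqs <- setNames(purrr::map_chr(1:12, ~ rand_rna(40)), paste0("s", 1:12))
  aln <- progressive_align(seqs)
  cons <- consensus_fold(aln, tau = 0.3)
  st <- covariation_stats(aln, cons)
  if (nrow(st) > 0) expect_true(all(st$n_types <= 6))
})

test_that("helix labelling groups stacks and flags the hLT", {
  sim <- simulate_genomes(8, n_clades = 1, seed = 21)
  seqs <- sim$evolution$combined
  mod <- consensus_model(seqs)
  hel <- label_helices(mod$aln, mod$consensus)
  # exactly one helix labelled hLT, and it spans the spacer columns
  hlt <- dplyr::filter(hel, .data$label == "hLT")
  expect_equal(length(unique(hlt$helix)), 1)
  lead_len <- nchar(sim$truth$leader_seq[1])
  expect_true(all(hlt$i < lead_len & hlt$j >= lead_len + 6))
  # report files are consistent
  prefix <- file.path(withr::local_tempdir(), "clade_1")
  paths <- covariation_report(mod, prefix)
  tab <- read.delim(paths[["tsv"]])
  expect_equal(nrow(tab), nrow(mod$consensus$pairs))
  sto <- read_stockholm(paths[["sto"]])
  expect_equal(nrow(sto$pairs), nrow(mod$consensus$pairs))
  # empty consensus -> header-only TSV
  rowsA <- setNames(rep(strrep("A", 12), 3), paste0("a", 1:3))
  alnA <- progressive_align(rowsA)
  modA <- structure(list(aln = alnA, consensus = consensus_fold(alnA),
                         stats = covariation_stats(alnA,
                                                   consensus_fold(alnA)),
                         helices = label_helices(alnA,
                                                 consensus_fold(alnA))),
                    class = "covariation_model")
  pA <- covariation_report(modA, file.path(withr::local_tempdir(), "empty"))
  expect_equal(nrow(read.delim(pA[["tsv"]])), 0)
})
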