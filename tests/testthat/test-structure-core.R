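test_that("nussinov_fold reproduces hand-checked structures", {
  s <- nussinov_fold("GGGAAACCC")
  expect_equal(unname(s$pairs), matrix(c(0L, 8L, 1L, 7L, 2L, 6L), 3,
                                       byrow = TRUE))
  expect_equal(nrow(nussinov_fold("AAAA")$pairs), 0)
  expect_equal(dot_bracket(s), "(((...)))")
})

test_that("nussinov_fold equals the enumeration maximum on random inputs", {
  set.seed(11)
  for (r in 1:60) {
    seq <- rand_rna(sample(4:12, 1))
    best <- max(vapply(enumerate_structures(seq),
                       function(s) nrow(s$pairs), integer(1)))
    got <- nussinov_fold(seq)
    expect_equal(nrow(got$pairs), best, info = seq)
    # returned structure satisfies the invariants
    if (nrow(got$pairs) > 0) {
      ch <- strsplit(seq, "")[[1]]
      expect_true(all(got$pairs[, 2] - got$pairs[, 1] - 1 >= 3))
      expect_true(all(rrnflank:::is_canonical_pair(
        ch[got$pairs[, 1] + 1], ch[got$pairs[, 2] + 1])))
    }
  }
})

test_that("enumerate_structures is complete, unique and guarded", {
  e1 <- enumerate_structures("GAAAC")
  expect_equal(length(e1), 2) # empty and {(0,4)}
  expect_equal(sort(vapply(e1, function(s) nrow(s$pairs), integer(1))),
               c(0L, 1L))
  expect_equal(length(enumerate_structures("AAAAA")), 1)
  expect_error(enumerate_structures(strrep("A", 17)), "16")
  set.seed(12)
  for (r in 1:20) {
    seq <- rand_rna(sample(5:11, 1))
    structs <- enumerate_structures(seq)
    keys <- vapply(structs, function(s)
      paste(t(s$pairs), collapse = ","), character(1))
    expect_equal(anyDuplicated(keys), 0L)
    # count agrees with an independent recursive counter
    expect_equal(length(structs), count_structures(seq), info = seq)
  }
})

test_that("partition probabilities match enumeration Boltzmann freqs", {
  m <- energy_model(gc = -1, au = -2, gu = -1, kT = 1)
  bp <- basepair_probs("GAAAC", m)
  expect_equal(bp$P[1, 5], exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_true(all(basepair_probs(strrep("A", 10))$P == 0))
  set.seed(13)
  md <- energy_model()
  for (r in 1:40) {
    seq <- rand_rna(sample(4:12, 1))
    P <- basepair_probs(seq, md)$P
    expect_lt(max(abs(P - boltzmann_pair_freqs(seq, md))), 1e-9)
  }
})

test_that("unpairedness stays within [0,1] on long sequences", {
  set.seed(14)
  bp <- basepair_probs(rand_rna(300))
  q <- 1 - bp$paired
  expect_true(all(q >= -1e-9 & q <= 1 + 1e-9))
  # N positions never pair
  bp2 <- basepair_probs(paste0("GGG", "NNNN", "CCC"))
  expect_true(all(bp2$P[4:7, ] == 0) && all(bp2$P[, 4:7] == 0))
})

test_that("duplex_align finds perfect and near-perfect duplexes", {
  d <- duplex_align(strrep("G", 17), strrep("C", 17))
  expect_equal(d$bp_count, 17)
  expect_equal(d$score, 34)
  # antiparallel: leader positions increase, trailer positions decrease
  expect_true(all(diff(d$pairs$leader_pos) > 0))
  expect_true(all(diff(d$pairs$trailer_pos) < 0))
  # one internal C->A mismatch costs exactly one pair
  tr <- paste0(strrep("C", 8), "A", strrep("C", 8))
  d2 <- duplex_align(strrep("G", 17), tr)
  expect_equal(d2$bp_count, 16)
  oracle <- brute_duplex_bp(strrep("G", 17), tr)
  expect_equal(d2$score, oracle$score)
  expect_equal(d2$bp_count, oracle$bp)
})

test_that("duplex scores are symmetric and shuffles score below plants", {
  set.seed(7)
  null_scores <- replicate(100, {
    duplex_align(rand_rna(30), rand_rna(30))$score
  })
  arm <- rand_rna(30)
  planted <- duplex_align(arm, revcomp_rna(arm))$score
  expect_gt(planted, max(null_scores))
  for (r in 1:20) {
    a <- rand_rna(sample(10:30, 1)); b <- rand_rna(sample(10:30, 1))
    expect_equal(duplex_align(a, b)$score, duplex_align(b, a)$score)
  }
})

test_that("complementary extension never decreases the duplex", {
  set.seed(15)
  for (r in 1:20) {
    # extending a fully complementary duplex at both ends grows it
    x <- rand_rna(20)
    base <- duplex_align(x, revcomp_rna(x))$bp_count
    ext <- duplex_align(paste0("G", x), paste0(revcomp_rna(x), "C"))
    expect_gte(ext$bp_count, base)
    # and on arbitrary pairs the optimal score is monotone under extension
    a <- rand_rna(20); b <- rand_rna(20)
    s0 <- duplex_align(a, b)$score
    s1 <- duplex_align(paste0("G", a), paste0(b, "C"))$score
    expect_gte(s1, s0)
  }
})
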