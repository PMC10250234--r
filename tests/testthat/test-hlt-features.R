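test_that("find_boxA recovers plants, applies the cap, prefers best hits", {
  set.seed(41)
  bg <- rand_rna(80)
  lead <- paste0(substr(bg, 1, 20), BOXA_MOTIF, substr(bg, 33, 80))
  hit <- find_boxA(lead)
  expect_equal(hit$offset, 20L)
  expect_equal(hit$mismatches, 0L)
  # variant at three mismatches only -> no hit at the default cap of 2
  variant3 <- "AGCUCUUUAAGG" # UGCUCUUUAACA with 3 substitutions
  lead3 <- paste0(strrep("A", 20), variant3, strrep("A", 20))
  expect_null(find_boxA(lead3))
  expect_equal(find_boxA(lead3, max_mm = 3)$mismatches, 3L)
  # fewest mismatches wins over 3'-most position
  one_mm <- sub("^U", "A", BOXA_MOTIF)
  lead2 <- paste0("AAAA", BOXA_MOTIF, "CCCC", one_mm, "GGGG")
  best <- find_boxA(lead2)
  expect_equal(best$mismatches, 0L)
  expect_equal(best$offset, 4L)
  # matches must lie upstream of boxC
  expect_null(find_boxA(lead, boxC_offset = 10))
})

test_that("spacing counts nucleotides strictly between the elements", {
  hit <- tibble::tibble(offset = 10L, mismatches = 0L, motif_len = 12L)
  expect_equal(boxa_boxc_spacing(hit, 40L)$spacing, 18L)
  expect_equal(boxa_boxc_spacing(hit, 22L)$spacing, 0L) # adjacent
  ov <- boxa_boxc_spacing(hit, 15L)
  expect_true(ov$overlap)
  expect_true(is.na(ov$spacing))
  # start-to-start alternative
  expect_equal(boxa_boxc_spacing(hit, 40L, mode = "start_start")$spacing,
               30L)
  # translation invariance: prepending shifts both, spacing unchanged
  set.seed(42)
  bg <- rand_rna(40)
  lead <- paste0(bg, BOXA_MOTIF, strrep("A", 18), "UCUGUGUGGG", rand_rna(30))
  h1 <- find_boxA(lead, boxC_offset = 40 + 12 + 18)
  s1 <- boxa_boxc_spacing(h1, 40L + 12L + 18L)$spacing
  lead2 <- paste0(rand_rna(50), lead)
  h2 <- find_boxA(lead2, boxC_offset = 50 + 40 + 12 + 18)
  s2 <- boxa_boxc_spacing(h2, 50L + 40L + 12L + 18L)$spacing
  expect_equal(s1, 18L)
  expect_equal(s2, s1)
})

test_that("profiles classify planted hLT lengths against the threshold", {
  # minimal constructed pairs: G/C arms in non-pairing A background, so
  # the duplex is exactly the planted helix
  set.seed(43)
  arm25 <- paste(sample(c("G", "C"), 25, TRUE), collapse = "")
  arm15 <- paste(sample(c("G", "C"), 15, TRUE), collapse = "")
  mk_pair <- function(arm) tibble::tibble(
    id = paste0("p", nchar(arm)),
    leader = paste0(strrep("A", 10), arm, strrep("A", 10)),
    trailer = paste0(strrep("A", 5), revcomp_rna(arm), strrep("A", 5)),
    boxC_offset_in_leader = NA_integer_)
  p25 <- profile_flank_pairs(mk_pair(arm25))
  expect_equal(p25$hlt_bp, 25)
  expect_true(p25$meets_threshold)
  p15 <- profile_flank_pairs(mk_pair(arm15))
  expect_equal(p15$hlt_bp, 15)
  expect_false(p15$meets_threshold)
  # 17 is not above the strict > 17 threshold; 18 is
  arm17 <- strrep("G", 17); arm18 <- strrep("G", 18)
  expect_false(profile_flank_pairs(mk_pair(arm17))$meets_threshold)
  expect_true(profile_flank_pairs(mk_pair(arm18))$meets_threshold)
})

test_that("hlt_bp is monotone in planted helix length on clean pairs", {
  set.seed(44)
  bps <- vapply(c(8, 12, 16, 20, 24), function(n) {
    arm <- paste(sample(c("G", "C"), n, TRUE), collapse = "")
    pr <- profile_flank_pairs(tibble::tibble(
      id = "x", leader = paste0(strrep("A", 8), arm, strrep("A", 8)),
      trailer = paste0(strrep("A", 4), revcomp_rna(arm), strrep("A", 4)),
      boxC_offset_in_leader = NA_integer_))
    pr$hlt_bp
  }, numeric(1))
  expect_true(all(diff(bps) >= 0))
})

test_that("genome-scale profiles find boxA and the planted spacing", {
  sim <- simulate_genomes(6, n_clades = 1, seed = 45)
  pairs <- extract_flank_pairs(sim$contigs, sim$features,
                               extraction_config(leader_upstream_pad = 60))
  prof <- profile_flank_pairs(pairs)
  expect_true(all(prof$hlt_bp >= 24))
  expect_true(all(prof$meets_threshold))
  expect_true(all(prof$spacing == 18L))
  g <- glance(prof)
  expect_equal(g$frac_spacing_18_19, 1)
})

test_that("a planted spacing cohort is summarised exactly", {
  set.seed(46)
  spacings <- c(rep(18L, 60), rep(19L, 38), 14L, 25L)
  leads <- purrr::map_chr(spacings, function(s) {
    paste0(rand_rna(20), BOXA_MOTIF, strrep("A", s), "UCUGUGUGGG",
           rand_rna(20))
  })
  cohort <- tibble::tibble(
    id = sprintf("m%03d", seq_along(spacings)),
    leader = leads,
    trailer = purrr::map_chr(seq_along(spacings), ~ rand_rna(57)),
    boxC_offset_in_leader = 20L + 12L + spacings)
  prof <- profile_flank_pairs(cohort)
  expect_equal(prof$spacing, spacings)
  expect_equal(glance(prof)$frac_spacing_18_19, 0.98)
})
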