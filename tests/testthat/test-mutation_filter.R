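grp20 <- ma_group("g20", sprintf("L%02d", 1:20), 100)

test_that("a clean line-specific alt-homozygote passes all five criteria", {
  gcl <- c("alt_hom", rep("ref_hom", 19))
  geno <- site_geno(gcl, dp = c(8L, rep(10L, 19)), gq = c(50L, rep(60L, 19)))
  out <- find_candidates(geno, grp20)
  expect_equal(nrow(out), 1)
  expect_equal(out$line_id, "L01")
  expect_equal(out$mtype, "SNV")
  expect_equal(out$dp, 8L)
})

test_that("each criterion rejects at its stated boundary", {
  gcl <- c("alt_hom", rep("ref_hom", 19))
  base <- function(dp1 = 8L, gq1 = 50L, dp_rest = 10L) {
    site_geno(gcl, dp = c(dp1, rep(dp_rest, 19)), gq = c(gq1, rep(60L, 19)))
  }
  # (ii): focal DP 4 < 5 rejected, DP 5 accepted ("no less than five reads")
  expect_equal(nrow(find_candidates(base(dp1 = 4L), grp20)), 0)
  expect_equal(nrow(find_candidates(base(dp1 = 5L), grp20)), 1)
  # (v): GQ 20 rejected, 21 accepted ("larger than 20")
  expect_equal(nrow(find_candidates(base(gq1 = 20L), grp20)), 0)
  expect_equal(nrow(find_candidates(base(gq1 = 21L), grp20)), 1)
  # (iv): support needs DP > 5 in >= 10 lines
  g <- base()
  g$dp[g$gclass == "ref_hom"] <- c(rep(6L, 9), rep(5L, 10))  # only 9 qualify
  expect_equal(nrow(find_candidates(g, grp20)), 0)
  g$dp[g$gclass == "ref_hom"] <- c(rep(6L, 10), rep(5L, 9))
  expect_equal(nrow(find_candidates(g, grp20)), 1)
  # (iii): a single het in any other line rejects
  g <- base()
  g$gclass[5] <- "het"; g$alt_index[5] <- 1L
  expect_equal(nrow(find_candidates(g, grp20)), 0)
  # (ii): two alt-homs (same or different allele) reject
  g <- base()
  g$gclass[7] <- "alt_hom"; g$alt_index[7] <- 1L
  expect_equal(nrow(find_candidates(g, grp20)), 0)
  # all ref-hom: nothing
  g <- site_geno(rep("ref_hom", 20))
  expect_equal(nrow(find_candidates(g, grp20)), 0)
  # missing genotypes are neither support nor violations
  g <- base()
  g$gclass[10:12] <- "missing"; g$alt_index[10:12] <- NA_integer_
  expect_equal(nrow(find_candidates(g, grp20)), 1)
})

test_that("groups too small for criterion (iv) are a configuration error", {
  grp10 <- ma_group("g10", sprintf("L%02d", 1:10), 100)
  geno <- site_geno(c("alt_hom", rep("ref_hom", 9)))
  expect_error(find_candidates(geno, grp10), "criterion \\(iv\\)")
})

test_that("find_candidates matches the brute-force oracle on random matrices", {
  n_matrices <- 250
  for (seed in seq_len(n_matrices)) {
    n_lines <- sample(11:12, 1)
    geno <- random_geno(n_lines, n_sites = sample(20:40, 1), seed = seed)
    grp <- ma_group("g", sprintf("L%02d", 1:n_lines), 100)
    got <- find_candidates(geno, grp) |>
      strip_attrs() |>
      dplyr::select(line_id, contig, pos, mtype, ref, alt)
    want <- oracle_find_candidates(geno, grp)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("linked same-line candidates are both removed, cross-line pairs kept", {
  cands <- make_candidates(
    pos = c(1000L, 1002L, 5000L, 5002L, 9000L),
    ref = "A", alt = "G",
    line_id = c("L1", "L1", "L2", "L3", "L1")
  )
  out <- remove_linked(cands, window = 100)
  # the 2-bp same-line pair is gone entirely; the 2-bp cross-line pair stays
  expect_equal(sort(out$pos), c(5000L, 5002L, 9000L))
  expect_equal(attr(out, "n_removed_linked"), 2L)

  single <- make_candidates(pos = 42L, ref = "A", alt = "T")
  expect_equal(nrow(remove_linked(single, 100)), 1)

  # chain: pairwise-linked runs collapse entirely
  chain <- make_candidates(pos = c(100L, 180L, 260L), ref = "A", alt = "G")
  expect_equal(nrow(remove_linked(chain, 100)), 0)

  # matches the O(n^2) oracle on random layouts
  for (seed in 1:50) {
    cands <- withr::with_seed(seed, make_candidates(
      pos = sort(sample.int(3000, 30)), ref = "A", alt = "G",
      line_id = sample(c("L1", "L2", "L3"), 30, replace = TRUE)
    ))
    expect_equal(
      strip_attrs(remove_linked(cands, 150)),
      strip_attrs(oracle_remove_linked(cands, 150))
    )
  }
})

test_that("raising the focal DP threshold never increases candidate counts", {
  geno <- random_geno(12, 60, seed = 99)
  grp <- ma_group("g", sprintf("L%02d", 1:12), 100)
  counts <- vapply(c(0, 4, 5, 6, 8, 13), function(th) {
    nrow(find_candidates(geno, grp, ma_thresholds(min_dp_focal = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pairwise sharing counts shared alt-homozygotes at eligible loci", {
  lines <- sprintf("L%02d", 1:20)
  grp <- ma_group("g", lines, 100)
  mk_site <- function(pos, alt_lines, dp = 10L) {
    gcl <- ifelse(lines %in% alt_lines, "alt_hom", "ref_hom")
    site_geno(gcl, dp = dp, lines = lines, pos = pos)
  }
  geno <- dplyr::bind_rows(
    mk_site(100L, c("L01", "L02")),
    mk_site(200L, c("L01", "L02")),
    mk_site(300L, c("L01", "L02")),
    mk_site(400L, c("L05"), dp = c(5L, rep(10L, 19))),   # one line at DP 5: ineligible
    mk_site(500L, sprintf("L%02d", 1:7))                 # 7/20 = 35% alt hom: ineligible
  )
  sh <- pairwise_sharing(geno, grp)
  expect_equal(nrow(sh), choose(20, 2))
  expect_equal(sh$eligible[1], 3)
  expect_equal(sh$shared[sh$line_a == "L01" & sh$line_b == "L02"], 3)
  expect_equal(sum(sh$shared), 3)

  # brute-force pair enumeration over the eligible loci agrees
  expect_equal(sh$shared[sh$line_a == "L01" & sh$line_b == "L02"],
               sum(vapply(c(100, 200, 300), function(p) {
                 s <- geno[geno$pos == p, ]
                 all(s$gclass[s$line_id %in% c("L01", "L02")] == "alt_hom")
               }, logical(1))))
})

test_that("contamination flagging finds the planted outlier pair", {
  # 189 pairs share <= 2, one pair shares 50
  withr::with_seed(5, {
    pairs <- t(combn(sprintf("L%02d", 1:20), 2))
    sh <- tibble(
      line_a = pairs[, 1], line_b = pairs[, 2],
      shared = sample(0:2, nrow(pairs), replace = TRUE), eligible = 500L
    )
  })
  sh$shared[17] <- 50L
  fl <- flag_contaminated(sh)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$shared, 50L)

  sh$shared <- 0L
  expect_equal(nrow(flag_contaminated(sh)), 0)

  # end-to-end: synthetic cross-contamination is flagged
  p <- sim_params(genome_length = 1e5, n_lines = 12, seed = 77, mu_snv = 3e-7,
                  contamination = list(lines = c("L03", "L09"),
                                       shared_fraction = 0.5))
  g <- generate_founder(p)
  tr <- simulate_lines(g, p)
  calls <- emulate_calling(g, tr, p)
  geno <- read_vcf_matrix(calls$vcf, sim_group(p))
  fl <- flag_contaminated(pairwise_sharing(geno, sim_group(p)))
  expect_true(any(fl$line_a == "L03" & fl$line_b == "L09"))
})

test_that("per-site exclusivity: at most one candidate line per site", {
  for (seed in 1:20) {
    geno <- random_geno(12, 50, seed = 1000 + seed)
    grp <- ma_group("g", sprintf("L%02d", 1:12), 100)
    out <- find_candidates(geno, grp)
    expect_false(any(duplicated(out[, c("contig", "pos")])))
  }
})
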