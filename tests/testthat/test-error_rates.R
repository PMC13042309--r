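test_that("insertion plans respect flanks around detections, edges and each other", {
  p <- sim_params(genome_length = 1e5, seed = 1)
  g <- generate_founder(p)
  detected <- make_candidates(pos = c(10000L, 50000L), ref = "A", alt = "G",
                              contig = "chrI")
  plan <- plan_insertions(g, detected, n_snv = 60, n_ins = 20, n_del = 20,
                          flank = 200, seed = 5)
  expect_equal(nrow(plan), 100)
  expect_equal(sum(plan$mtype == "SNV"), 60)

  # exhaustive O(n^2) distance audit
  for (d in detected$pos) expect_true(all(abs(plan$pos - d) >= 200))
  dd <- as.matrix(dist(plan$pos))
  diag(dd) <- Inf
  expect_true(all(dd >= 200))
  expect_true(all(plan$pos > 200 & plan$pos <= 1e5 - 200))

  # planted alleles are consistent with the reference sequence
  seq <- as.character(g$seq[[1]])
  expect_equal(substr(rep(seq, nrow(plan)), plan$pos,
                      plan$pos + nchar(plan$ref) - 1), plan$ref)

  expect_equal(nrow(plan_insertions(g, detected, 0, 0, 0, seed = 2)), 0)
  # an impossible request reports achievable counts
  small <- genome_ref(c(c1 = strrep("ACGT", 300)))
  expect_error(plan_insertions(small, detected[0, ], 500, 0, 0,
                               flank = 200, seed = 3),
               "insufficient eligible space")
})

test_that("applying edits changes sequences exactly as an independent oracle", {
  g <- genome_ref(c(c1 = "AACCGGTTAACCGGTTAACC"))
  # single SNV: length unchanged, base changed
  plan <- tibble(contig = "c1", pos = 5L, mtype = "SNV", ref = "G", alt = "T",
                 length_delta = 0L)
  ed <- apply_insertions(g, plan)
  expect_equal(as.character(ed$genome$seq[["c1"]]), "AACCTGTTAACCGGTTAACC")

  # 3 bp deletion: contig shorter by 3, downstream offset -3
  plan <- tibble(contig = "c1", pos = 4L, mtype = "deletion",
                 ref = "CGGT", alt = "C", length_delta = -3L)
  ed <- apply_insertions(g, plan)
  expect_equal(nchar(as.character(ed$genome$seq[["c1"]])), 17)
  expect_equal(lift_positions(ed$liftover, "c1", 10L), 7L)
  expect_equal(lift_positions(ed$liftover, "c1", 7L, "to_original"), 10L)
  # deleted positions have no image
  expect_true(is.na(lift_positions(ed$liftover, "c1", 6L)))

  # random plans: edited sequence matches a forward-order string oracle
  for (seed in 1:10) {
    p <- sim_params(genome_length = 3000, seed = seed)
    gg <- generate_founder(p)
    plan <- plan_insertions(gg, tibble(contig = character(), pos = integer()),
                            n_snv = 3, n_ins = 3, n_del = 3, flank = 50,
                            seed = seed)
    ed <- apply_insertions(gg, plan)
    ct <- gg$composition$contig[1]
    s <- as.character(gg$seq[[ct]])
    shift <- 0L
    for (i in order(plan$pos)) {
      pos <- plan$pos[i] + shift
      if (plan$mtype[i] == "SNV") {
        substr(s, pos, pos) <- plan$alt[i]
      } else if (plan$mtype[i] == "insertion") {
        s <- paste0(substr(s, 1, pos), substr(plan$alt[i], 2, nchar(plan$alt[i])),
                    substr(s, pos + 1, nchar(s)))
        shift <- shift + plan$length_delta[i]
      } else {
        s <- paste0(substr(s, 1, pos),
                    substr(s, pos - plan$length_delta[i] + 1, nchar(s)))
        shift <- shift + plan$length_delta[i]
      }
    }
    expect_equal(as.character(ed$genome$seq[[ct]]), s, info = paste("seed", seed))
    # liftover round trip on every planted anchor
    lifted <- lift_positions(ed$liftover, plan$contig, plan$pos)
    expect_equal(lift_positions(ed$liftover, plan$contig, lifted, "to_original"),
                 plan$pos)
  }
})

test_that("matching follows the same-locus / 5 bp-upstream same-type rules", {
  plan <- tibble(
    contig = "c1", pos = c(1000L, 2000L, 3000L),
    mtype = c("deletion", "deletion", "SNV"),
    ref = c("CTTT", "CAA", "A"), alt = c("C", "C", "G"), length_delta = c(-3L, -2L, 0L)
  )
  det <- function(pos, mtype, ref = "C", alt = "CA") {
    tibble(contig = "c1", pos = pos, mtype = mtype, ref = ref, alt = alt)
  }
  # deletion detected 4 bp upstream: matched
  m <- match_detected(plan, det(996L, "deletion"))
  expect_equal(m$detected, c(TRUE, FALSE, FALSE))
  # type mismatch at the same distance: not matched
  m <- match_detected(plan, det(998L, "insertion"))
  expect_false(any(m$detected))
  # downstream or > 5 bp upstream: not matched
  expect_false(any(match_detected(plan, det(1001L, "deletion"))$detected))
  expect_false(any(match_detected(plan, det(994L, "deletion"))$detected))
  # SNV needs the same locus and the same base change
  expect_true(match_detected(plan, det(3000L, "SNV", "A", "G"))$detected[3])
  expect_false(match_detected(plan, det(3000L, "SNV", "A", "T"))$detected[3])
  expect_false(match_detected(plan, det(3001L, "SNV", "A", "G"))$detected[3])

  # injectivity: one detected indel cannot satisfy two planted ones
  plan2 <- tibble(contig = "c1", pos = c(1000L, 1002L), mtype = "deletion",
                  ref = c("CT", "CG"), alt = "C", length_delta = -1L)
  m2 <- match_detected(plan2, det(998L, "deletion"))
  expect_equal(sum(m2$detected), 1)
  expect_true(m2$detected[1])  # nearest upstream consumer wins
})

test_that("noiseless FN is zero; dropout shifts FN by the dropout probability", {
  p <- sim_params(genome_length = 5e5, n_lines = 12, seed = 17)
  g <- generate_founder(p)
  plan <- plan_insertions(g, tibble(contig = character(), pos = integer()),
                          n_snv = 150, n_ins = 50, n_del = 50, flank = 200,
                          seed = 18)
  fb <- fn_benchmark(g, plan, p)
  expect_equal(sum(fb$scored$covered & !fb$scored$detected), 0)
  expect_true(all(fb$fn$fn_rate == 0))

  d <- 0.1
  p_noise <- sim_params(genome_length = 5e5, n_lines = 12, seed = 17,
                        missing_rate = d)
  fb2 <- fn_benchmark(g, plan, p_noise)
  snv <- dplyr::filter(fb2$scored, mtype == "SNV")
  n_cov <- sum(snv$covered)
  fn_obs <- sum(snv$covered & !snv$detected) / n_cov
  expect_lt(abs(fn_obs - d), 3 * sqrt(d * (1 - d) / n_cov))
})

test_that("fn_rate reports per-line per-type fractions and undefined cases", {
  scored <- tibble(
    line_id = "L01", mtype = "SNV",
    covered = c(rep(TRUE, 100), FALSE),
    detected = c(rep(TRUE, 94), rep(FALSE, 6), FALSE)
  )
  fr <- fn_rate(scored)
  expect_equal(fr$fn_rate, 0.06)
  expect_equal(fr$n_covered, 100L)

  fr0 <- fn_rate(tibble(line_id = "L01", mtype = "SNV",
                        covered = FALSE, detected = FALSE))
  expect_true(is.nan(fr0$fn_rate))
})

test_that("ancestral-only alt-homozygote fraction estimates the FP rate", {
  lines <- c(sprintf("L%02d", 1:12), "ANC")
  grp <- ma_group("g", sprintf("L%02d", 1:12), 100)
  mk <- function(pos, carrier) {
    site_geno(ifelse(lines == carrier, "alt_hom", "ref_hom"),
              lines = lines, pos = pos)
  }
  # 50-site fixture: 2 ancestral-only, 48 carried by group lines
  carriers <- withr::with_seed(3, {
    c(rep("ANC", 2), sample(sprintf("L%02d", 1:12), 48, replace = TRUE))
  })
  geno <- dplyr::bind_rows(lapply(seq_along(carriers), function(i) {
    mk(i * 10L, carriers[i])
  }))
  fp <- fp_rate_ancestral(geno, "ANC", grp)
  expect_equal(fp$n_alt_hom_loci, 50L)
  expect_equal(fp$n_ancestral_only, 2L)
  expect_equal(fp$fp_rate, 2 / 50)

  # ancestor identical to the group consensus: no ancestral-only loci
  geno2 <- dplyr::bind_rows(lapply(1:20, function(i) mk(i * 10L, "L05")))
  expect_equal(fp_rate_ancestral(geno2, "ANC", grp)$fp_rate, 0)

  expect_warning(
    und <- fp_rate_ancestral(
      site_geno(rep("ref_hom", 13), lines = lines), "ANC", grp),
    "undefined"
  )
  expect_true(is.nan(und$fp_rate))
})
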