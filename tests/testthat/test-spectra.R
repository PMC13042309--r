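test_that("the 12 ordered base pairs collapse onto 6 classes, 2 each", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- snv_class(pairs$ref, pairs$alt)
  expect_false(anyNA(cls))
  expect_equal(unname(table(cls)), rep(2L, 6), ignore_attr = TRUE)

  expect_equal(as.character(snv_class("A", "G")), "A:T>G:C")
  expect_true(is_transition("A", "G"))
  expect_equal(as.character(snv_class("C", "A")), "G:C>T:A")
  expect_false(is_transition("C", "A"))

  # strand-collapse involution: complement pair gives the same class
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(snv_class(pairs$ref, pairs$alt),
               snv_class(comp[pairs$ref], comp[pairs$alt]))

  expect_error(snv_class("A", "A"), "differ")
})

test_that("ts/tv matches a brute-force recount and handles degenerate cases", {
  withr::with_seed(7, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, 100, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  })
  cands <- make_candidates(pos = seq_len(100), ref = ref, alt = alt)
  # independent recount by set membership
  is_ts <- mapply(function(r, a) {
    setequal(c(r, a), c("A", "G")) || setequal(c(r, a), c("C", "T"))
  }, ref, alt)
  expect_equal(ts_tv(cands), sum(is_ts) / sum(!is_ts))

  expect_equal(ts_tv(make_candidates(pos = 1:4, ref = rep("A", 4),
                                     alt = rep(c("G", "T"), 2))), 1.0)
  expect_equal(ts_tv(make_candidates(pos = 1:5, ref = rep("A", 5),
                                     alt = rep("T", 5))), 0.0)
  expect_warning(val <- ts_tv(make_candidates(pos = 1:2, ref = c("A", "C"),
                                              alt = c("G", "T"))),
                 "transversion")
  expect_true(is.nan(val))
})

test_that("AT bias is the composition-normalized flux ratio", {
  g5050 <- genome_ref(c(c1 = strrep("ACGT", 25)))  # gc == at
  spec <- tibble(class = c("G:C>A:T", "G:C>T:A", "A:T>G:C", "A:T>C:G",
                           "A:T>T:A", "G:C>C:G"),
                 n = c(10L, 10L, 2L, 2L, 0L, 0L))
  expect_equal(at_bias(spec, g5050), 5.0)

  spec_eq <- dplyr::mutate(spec, n = 4L)
  expect_equal(at_bias(spec_eq, g5050), 1.0)

  # doubling genome size at the same composition leaves the ratio unchanged
  g2x <- genome_ref(c(c1 = strrep("ACGT", 50)))
  expect_equal(at_bias(spec, g2x), 5.0)

  expect_warning(v <- at_bias(dplyr::mutate(spec, n = c(1L, 1L, 0L, 0L, 0L, 0L)),
                              g5050), "undefined")
  expect_true(is.nan(v))
})

test_that("triplet contexts collapse strands and preserve spectrum marginals", {
  #       123456789
  g <- genome_ref(c(c1 = "TTAACGGCA"))
  # T>A at the middle T of TTA (positions 1-3): center collapses to TAA
  cands <- make_candidates(pos = 2L, ref = "T", alt = "A")
  ctx <- triplet_context(cands, g)
  expect_equal(nrow(ctx), 1)
  expect_equal(ctx$context, "TAA")
  expect_equal(ctx$class, "A:T>T:A")
  # the reverse orientation lands in the same cell
  cands_rc <- make_candidates(pos = 8L, ref = "C", alt = "T")  # GCA center C
  expect_equal(triplet_context(cands_rc, g)$context, "GCA")

  # edge SNVs go to the edge bucket
  edge <- make_candidates(pos = c(1L, 9L), ref = c("T", "A"), alt = c("A", "C"))
  ctx_e <- triplet_context(edge, g)
  expect_equal(ctx_e$n[ctx_e$context == "edge"], 2L)

  # marginals over contexts reproduce the spectrum for interior SNVs
  s <- quick_sim(66)
  tr <- dplyr::filter(s$truth, mtype == "SNV")
  ctx_all <- triplet_context(tr, s$genome)
  interior <- dplyr::filter(ctx_all, context != "edge")
  spec <- spectrum_table(tr)
  marg <- interior |>
    dplyr::group_by(class) |>
    dplyr::summarise(n = sum(n))
  edge_n <- sum(ctx_all$n[ctx_all$context == "edge"])
  expect_equal(sum(marg$n) + edge_n, sum(spec$n))
  for (cl in marg$class) {
    expect_lte(marg$n[marg$class == cl], spec$n[spec$class == cl])
  }
  # all interior contexts have the collapsed center
  expect_true(all(substr(interior$context, 2, 2) %in% c("A", "C")))
})

test_that("codon consequences match on hand-built genes, both strands", {
  #              1234567890123456789012345678
  seq <- paste0("GCGCGCGCGC", "ATGTATGCTTAA", "GCGCGC")  # CDS at 11-22: M Y A *
  g <- genome_ref(c(c1 = seq))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\t.\tgene\t11\t22\t.\t+\t.\tID=g1",
    "c1\t.\tCDS\t11\t22\t.\t+\t0\tID=g1.c;Parent=g1"
  ), gff)
  ann <- read_gff(gff)

  cq <- classify_consequence(make_candidates(
    pos = c(16L, 19L, 15L, 5L),
    ref = c("T", "T", "A", "G"),
    alt = c("A", "C", "G", "A")
  ), ann, g)
  # TAT -> TAA stop gained; GCT -> GCC synonymous; TAT -> TGT missense
  expect_equal(cq$consequence, c("stop_gained", "synonymous", "missense",
                                 "noncoding"))
  expect_equal(cq$coding, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cq$genic, c(TRUE, TRUE, TRUE, FALSE))

  # same gene on the minus strand: reverse-complement the CDS region
  seq_rc <- paste0("GCGCGCGCGC", "TTAAGCATACAT", "GCGCGC")
  g2 <- genome_ref(c(c1 = seq_rc))
  writeLines(c(
    "##gff-version 3",
    "c1\t.\tgene\t11\t22\t.\t-\t.\tID=g1",
    "c1\t.\tCDS\t11\t22\t.\t-\t0\tID=g1.c;Parent=g1"
  ), gff)
  ann2 <- read_gff(gff)
  # genomic position 17 is CDS offset 6 on the minus strand (codon 2 pos 3):
  # plus-strand A>T is minus-strand T>A, TAT -> TAA stop gained
  cq2 <- classify_consequence(make_candidates(pos = 17L, ref = "A", alt = "T"),
                              ann2, g2)
  expect_equal(cq2$consequence, "stop_gained")

  # indel in CDS: coding without frame subtype; genic indel outside CDS
  cq3 <- classify_consequence(make_candidates(
    pos = c(15L, 5L), ref = c("T", "G"), alt = c("TAA", "GT")
  ), ann, g)
  expect_equal(cq3$consequence[1], "coding_indel")
  expect_true(cq3$coding[1])
})

test_that("consequences agree with whole-CDS translation on random micro-genes", {
  # oracle: translate the full mutated CDS and compare protein sequences
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n_codon <- sample(3:10, 1)
      body <- paste(sample(c("GCT", "TAT", "TGG", "CAT", "AAA", "CCG"),
                           n_codon - 2, replace = TRUE), collapse = "")
      cds <- paste0("ATG", body, "TAA")
      flank5 <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
      flank3 <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
      strand <- sample(c("+", "-"), 1)
    })
    cds_genomic <- if (strand == "+") cds else {
      paste(rev(strsplit(chartr("ACGT", "TGCA", cds), "")[[1]]), collapse = "")
    }
    seq <- paste0(flank5, cds_genomic, flank3)
    g <- genome_ref(c(c1 = seq))
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
      "##gff-version 3",
      sprintf("c1\t.\tgene\t11\t%d\t.\t%s\t.\tID=g1", 10 + nchar(cds), strand),
      sprintf("c1\t.\tCDS\t11\t%d\t.\t%s\t0\tID=g1.c;Parent=g1",
              10 + nchar(cds), strand)
    ), gff)
    ann <- read_gff(gff)

    positions <- 11:(10 + nchar(cds))
    for (pos in positions) {
      ref <- substr(seq, pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      got <- classify_consequence(
        make_candidates(pos = as.integer(pos), ref = ref, alt = alt), ann, g
      )$consequence

      mut_seq <- seq
      substr(mut_seq, pos, pos) <- alt
      extract_cds <- function(s) {
        x <- substr(s, 11, 10 + nchar(cds))
        if (strand == "-") {
          x <- paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
        }
        x
      }
      aa0 <- as.character(Biostrings::translate(Biostrings::DNAString(extract_cds(seq))))
      aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(extract_cds(mut_seq))))
      want <- if (aa0 == aa1) "synonymous"
              else if (grepl("\\*", sub("\\*$", "", aa1))) "stop_gained"
              else "missense"
      expect_equal(got, want, info = sprintf("seed %d pos %d %s", seed, pos, strand))
    }
  }
})

test_that("indel length tables carry histograms and means", {
  cands <- make_candidates(
    pos = c(10L, 50L, 90L, 130L),
    ref = c("AXX", "AXXXX", "AXXXXXXXXX", "A"),
    alt = c("A", "A", "A", "AGG")
  )
  cands$ref <- c("ACC", "ACCCC", "ACCCCCCCCC", "A")  # valid bases
  il <- indel_lengths(cands)
  means <- attr(il, "means")
  expect_equal(unname(means["deletion"]), 5.0)
  expect_equal(unname(means["insertion"]), 2.0)
  expect_equal(sum(il$n[il$mtype == "deletion"]), 3)

  no_ins <- indel_lengths(dplyr::filter(cands, mtype == "deletion"))
  expect_true(is.nan(attr(no_ins, "means")["insertion"]))
})
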