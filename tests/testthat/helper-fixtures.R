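# Fixture builders and independent brute-force oracles used across tests.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# one site's worth of long-format genotype rows
site_geno <- function(gclass, dp = 10, gq = 50,
                      lines = sprintf("L%02d", seq_along(gclass)),
                      contig = "c1", pos = 100L, ref = "A", alt = "G",
                      alt_index = NULL) {
  n <- length(gclass)
  if (is.null(alt_index)) {
    alt_index <- ifelse(gclass %in% c("het", "alt_hom"), 1L, NA_integer_)
  }
  tibble(
    contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
    line_id = lines, gclass = gclass,
    dp = as.integer(rep_len(dp, n)), gq = as.integer(rep_len(gq, n)),
    alt_index = as.integer(rep_len(alt_index, n))
  )
}

# a random multi-site genotype matrix probing the criteria boundaries:
# half the sites are "near-candidate" (one alt-hom, boundary DP/GQ values),
# half are unstructured noise, some multi-allelic
random_geno <- function(n_lines, n_sites, seed) {
  withr::with_seed(seed, {
    lines <- sprintf("L%02d", seq_len(n_lines))
    pos <- sort(sample.int(50 * n_sites, n_sites))
    sites <- lapply(seq_len(n_sites), function(si) {
      ref <- sample(c("A", "C", "G", "T"), 1)
      n_alts <- sample(1:2, 1, prob = c(0.8, 0.2))
      alts <- c(sample(setdiff(c("A", "C", "G", "T"), ref), 1), "AG")[seq_len(n_alts)]
      dp_pool <- c(0L, 4L, 5L, 6L, 7L, 12L)
      gq_pool <- c(5L, 19L, 20L, 21L, 22L, 55L)
      if (runif(1) < 0.5) {
        gclass <- rep("ref_hom", n_lines)
        gclass[sample.int(n_lines, 1)] <- "alt_hom"
        if (runif(1) < 0.3) {
          i <- sample(which(gclass == "ref_hom"), 1)
          gclass[i] <- sample(c("het", "missing", "alt_hom"), 1)
        }
      } else {
        gclass <- sample(c("ref_hom", "alt_hom", "het", "missing"),
                         n_lines, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1))
      }
      site_geno(
        gclass,
        dp = sample(dp_pool, n_lines, replace = TRUE),
        gq = sample(gq_pool, n_lines, replace = TRUE),
        lines = lines, pos = pos[si], ref = ref,
        alt = paste(alts, collapse = ","),
        alt_index = ifelse(gclass %in% c("het", "alt_hom"),
                           sample.int(n_alts, n_lines, replace = TRUE),
                           NA_integer_)
      )
    })
    bind_rows(sites)
  })
}

# independently coded brute-force evaluator of detection criteria (i)-(v):
# explicit per-line loops, no shared code with find_candidates()
oracle_find_candidates <- function(geno, group, th = ma_thresholds()) {
  lines <- group_lines(group)
  g <- geno[geno$line_id %in% lines, ]
  keys <- unique(g[, c("contig", "pos")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    s <- g[g$contig == keys$contig[r] & g$pos == keys$pos[r], ]
    n_ref <- 0L; n_het <- 0L; n_support <- 0L
    alt_hom_by_allele <- integer(0)
    focal_rows <- integer(0)
    for (i in seq_len(nrow(s))) {
      cl <- s$gclass[i]
      if (cl == "ref_hom") {
        n_ref <- n_ref + 1L
        if (s$dp[i] >= th$min_dp_support) n_support <- n_support + 1L
      } else if (cl == "het") {
        n_het <- n_het + 1L
      } else if (cl == "alt_hom") {
        k <- as.character(s$alt_index[i])
        if (!k %in% names(alt_hom_by_allele)) alt_hom_by_allele[k] <- 0L
        alt_hom_by_allele[k] <- alt_hom_by_allele[k] + 1L
        focal_rows <- c(focal_rows, i)
      }
    }
    n_multi_hom <- sum(n_ref >= 2L) + sum(alt_hom_by_allele >= 2L)
    ok <- n_multi_hom == 1L &&                               # (i)
      length(focal_rows) == 1L &&                            # (ii) uniqueness
      s$dp[focal_rows] >= th$min_dp_focal &&                 # (ii) depth
      n_het == 0L &&                                         # (iii)
      n_support >= th$min_support_lines &&                   # (iv)
      s$gq[focal_rows] >= th$min_gq                          # (v)
    if (isTRUE(ok)) {
      i <- focal_rows
      alts <- strsplit(s$alt[i], ",", fixed = TRUE)[[1]]
      a <- alts[s$alt_index[i]]
      out[[length(out) + 1]] <- tibble(
        line_id = s$line_id[i], contig = s$contig[i], pos = s$pos[i],
        mtype = if (nchar(s$ref[i]) == 1 && nchar(a) == 1) "SNV"
                else if (nchar(a) > nchar(s$ref[i])) "insertion" else "deletion",
        ref = s$ref[i], alt = a
      )
    }
  }
  if (length(out)) arrange(bind_rows(out), contig, pos, line_id) else {
    tibble(line_id = character(), contig = character(), pos = integer(),
           mtype = character(), ref = character(), alt = character())
  }
}

# O(n^2) brute-force linkage removal: drop every candidate that has another
# same-line same-contig candidate within `window` bp
oracle_remove_linked <- function(cands, window) {
  if (nrow(cands) == 0) return(cands)
  drop <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    for (j in seq_len(nrow(cands))) {
      if (i != j &&
          cands$line_id[i] == cands$line_id[j] &&
          cands$contig[i] == cands$contig[j] &&
          abs(cands$pos[i] - cands$pos[j]) <= window) {
        drop[i] <- TRUE
      }
    }
  }
  cands[!drop, , drop = FALSE]
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x); n <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  w_all <- apply(idx, 2, function(s) sum(ranks[s])) - m * (m + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# drop result-class attributes so content can be compared against oracles
strip_attrs <- function(d) {
  attr(d, "attrition") <- NULL
  attr(d, "n_removed_linked") <- NULL
  class(d) <- c("tbl_df", "tbl", "data.frame")
  tibble::as_tibble(d)
}

# small candidate tibble from scratch
make_candidates <- function(...) {
  d <- tibble(...)
  if (!"mtype" %in% names(d)) d$mtype <- mutation_type(d$ref, d$alt)
  if (!"length_delta" %in% names(d)) d$length_delta <- nchar(d$alt) - nchar(d$ref)
  if (!"line_id" %in% names(d)) d$line_id <- "L01"
  if (!"contig" %in% names(d)) d$contig <- "c1"
  d
}

# default desk-scale simulation shared by several tests (small + fast)
quick_sim <- function(seed, ...) {
  p <- sim_params(genome_length = 1e5, n_lines = 12, seed = seed,
                  min_spacing = 101, ...)
  g <- generate_founder(p)
  tr <- simulate_lines(g, p)
  calls <- emulate_calling(g, tr, p)
  list(params = p, genome = g, truth = tr, calls = calls,
       group = sim_group(p))
}
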