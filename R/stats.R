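#' Wilcoxon rank-sum comparison of per-line mutation rates
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test, as used to compare MA
#' rates between groups. The exact null distribution is used for combined
#' sample sizes up to 50 without ties; with ties or larger samples the
#' normal approximation with tie correction applies (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors of per-line rates (non-empty).
#' @return A one-row tibble of class `ma_test`: `test`, `statistic`,
#'   `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  new_ma_test("wilcoxon_rank_sum", unname(ht$statistic), ht$p.value, ht$method)
}

#' Two-sided F test on rate variances
#'
#' `F = var(x) / var(y)` with `(n_x - 1, n_y - 1)` degrees of freedom, used
#' to compare the across-line variance of mutation rates between groups.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A one-row tibble of class `ma_test`; `statistic` is the variance
#'   ratio. If `var(y)` is zero the ratio is undefined and `p_value` is `NA`
#'   with a warning.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need n >= 2 per sample")
  if (stats::var(y) == 0) {
    warn("zero variance in denominator sample: F undefined")
    return(new_ma_test("variance_f", NaN, NA_real_, "F test to compare two variances"))
  }
  ht <- var.test(x, y, alternative = "two.sided")
  new_ma_test("variance_f", unname(ht$statistic), ht$p.value, ht$method)
}

#' Fisher's exact test for r x c contingency tables
#'
#' For 2 x 2 tables the exact two-sided p-value under the probability-mass
#' criterion (sum over tables no more probable than the observed one). For
#' larger tables an exact network computation is replaced by a seeded
#' Monte-Carlo estimate over tables sampled with fixed margins,
#' `p = (hits + 1) / (n_mc + 1)`, adequate for mutation-spectrum-sized
#' tables and reproducible bit-for-bit under a fixed seed.
#'
#' @param table A non-negative integer matrix (e.g. 6 x 2 spectrum counts).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @param n_mc Number of Monte-Carlo tables (default 1e5).
#' @return A one-row tibble of class `ma_test`; `method` records whether the
#'   exact or Monte-Carlo branch was used. A table with a zero margin is
#'   degenerate: `p = 1`.
#' @export
fisher_exact_rxc <- function(table, seed = 1L, n_mc = 1e5) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    abort("`table` must contain non-negative integers")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    return(new_ma_test("fisher_exact", NA_real_, 1,
                       "degenerate table (zero margin)"))
  }
  if (all(dim(table) == c(2, 2))) {
    ht <- fisher.test(table)
    return(new_ma_test("fisher_exact", unname(ht$estimate), ht$p.value,
                       "exact (2x2, probability-mass two-sided)"))
  }
  p <- withr::with_seed(as.integer(seed), {
    fisher.test(table, simulate.p.value = TRUE, B = n_mc)$p.value
  })
  new_ma_test("fisher_exact", NA_real_, p,
              sprintf("Monte-Carlo, fixed margins, n_mc=%d, seed=%d",
                      as.integer(n_mc), as.integer(seed)))
}

new_ma_test <- function(test, statistic, p_value, method) {
  out <- tibble(test = test, statistic = as.numeric(statistic),
                p_value = as.numeric(p_value), method = as.character(method))
  structure(out, class = c("ma_test", class(out)))
}

#' Pairwise group comparisons of rates and spectra
#'
#' Runs, for every pair of groups: Wilcoxon rank-sum tests on the per-line
#' SNV/insertion/deletion rates, two-sided F tests on their variances, and
#' Fisher's exact test on the 6 x 2 spectrum table. Raw p-values are
#' reported; set `p_adjust = "BH"` for Benjamini-Hochberg adjustment across
#' the comparison report.
#'
#' @param rates_list Named list of [per_line_rates()] results.
#' @param spectra_list Optional named list of [spectrum_table()] results
#'   (same names).
#' @param seed Seed for Monte-Carlo Fisher branches.
#' @param p_adjust `"none"` (the default; raw p-values as reported in MA
#'   studies) or `"BH"`.
#' @return A tibble with one row per (pair, test) and columns `group_a`,
#'   `group_b`, `test`, `statistic`, `p_value`, `method` (and `p_adjusted`
#'   when requested).
#' @export
compare_groups <- function(rates_list, spectra_list = NULL, seed = 1L,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(rates_list) >= 2, !is.null(names(rates_list)))
  nm <- names(rates_list)
  rows <- list()
  for (i in seq_len(length(nm) - 1)) {
    for (j in seq(i + 1, length(nm))) {
      a <- rates_list[[i]]; b <- rates_list[[j]]
      for (ty in c("snv", "ins", "del")) {
        col <- paste0("rate_", ty)
        rows[[length(rows) + 1]] <- wilcoxon_rank_sum(a[[col]], b[[col]]) |>
          mutate(test = paste0("wilcoxon_", ty))
        rows[[length(rows) + 1]] <- variance_f_test(a[[col]], b[[col]]) |>
          mutate(test = paste0("var_f_", ty))
      }
      if (!is.null(spectra_list)) {
        tab <- cbind(spectra_list[[nm[i]]]$n, spectra_list[[nm[j]]]$n)
        rows[[length(rows) + 1]] <- fisher_exact_rxc(tab, seed = seed) |>
          mutate(test = "fisher_spectrum")
      }
      k <- length(rows)
      n_new <- if (is.null(spectra_list)) 6 else 7
      for (r in seq(k - n_new + 1, k)) {
        rows[[r]] <- mutate(rows[[r]], group_a = nm[i], group_b = nm[j],
                            .before = 1)
      }
    }
  }
  out <- bind_rows(rows)
  if (p_adjust == "BH") {
    out <- mutate(out, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
  }
  out
}
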