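#' Identify line-specific accumulated mutations
#'
#' Applies the five per-site detection criteria for accumulated mutations in a
#' group of MA lines. A site yields a candidate if and only if all of these
#' hold (thresholds from [ma_thresholds()]):
#'
#' * (i) exactly one homozygous genotype class (reference, or one particular
#'   alternative allele) is carried by more than one line — the ancestral
#'   state;
#' * (ii) alternative homozygotes occur in exactly one line, whose call has
#'   DP >= `min_dp_focal` (no less than five reads by default);
#' * (iii) no other line is heterozygous for any alternative allele;
#' * (iv) at least `min_support_lines` lines are reference-homozygous with
#'   DP >= `min_dp_support` (more than five reads by default);
#' * (v) the focal call has GQ >= `min_gq` (larger than 20 by default).
#'
#' Criterion (vi) — removal of linked same-line candidates — is a separate
#' pass, [remove_linked()], because it acts across sites.
#'
#' Missing genotypes count neither as criterion-(iii) violations nor as
#' criterion-(iv) support. Multi-allelic sites are evaluated jointly: hets for
#' *any* alternative allele disqualify, and two lines homozygous for
#' *different* alternative alleles still violate criterion (ii).
#'
#' @param geno A long genotype tibble from [read_vcf_matrix()].
#' @param group An [ma_group()] with at least `min_support_lines + 1` active
#'   lines (criterion iv is unsatisfiable otherwise).
#' @param thresholds An [ma_thresholds()].
#' @return A tibble of class `ma_candidates` with columns `line_id`, `contig`,
#'   `pos`, `mtype`, `ref`, `alt`, `length_delta`, `dp`, `gq`. Attribute
#'   `attrition` holds per-criterion site counts for auditing.
#' @export
find_candidates <- function(geno, group, thresholds = ma_thresholds()) {
  stopifnot(inherits(group, "ma_group"), inherits(thresholds, "ma_thresholds"))
  lines <- group_lines(group)
  if (length(lines) < thresholds$min_support_lines + 1L) {
    abort(sprintf(
      "group '%s' has %d usable lines but criterion (iv) needs at least %d support lines plus the focal line",
      group$name, length(lines), thresholds$min_support_lines
    ))
  }
  geno <- filter(geno, .data$line_id %in% lines)

  # vectorized per-site tallies (one pass over the long table; sites with
  # millions of records stay fast)
  key <- paste(geno$contig, geno$pos, sep = "\r")
  uk <- unique(key)
  fi <- match(key, uk)
  ns <- length(uk)
  first_row <- match(uk, key)

  is_alt <- geno$gclass == "alt_hom"
  is_ref <- geno$gclass == "ref_hom"
  is_het <- geno$gclass == "het"
  n_alt_hom <- tabulate(fi[is_alt], ns)
  n_ref_hom <- tabulate(fi[is_ref], ns)
  n_het <- tabulate(fi[is_het], ns)
  n_support <- tabulate(fi[is_ref & geno$dp >= thresholds$min_dp_support], ns)
  # alt-hom allele classes carried by >= 2 lines, per site
  ak <- paste(fi[is_alt], geno$alt_index[is_alt], sep = "\r")
  atab <- table(ak)
  multi_sites <- as.integer(sub("\r.*$", "", names(atab)[atab >= 2]))
  n_multi_alt <- tabulate(multi_sites, ns)
  n_multi_hom <- (n_ref_hom >= 2L) + n_multi_alt

  # the focal row of each site with exactly one alt-homozygote
  focal_row <- rep(NA_integer_, ns)
  ai <- which(is_alt)
  focal_row[fi[ai]] <- ai  # unique where n_alt_hom == 1, else irrelevant
  focal_dp <- ifelse(n_alt_hom == 1L, geno$dp[focal_row], NA_integer_)
  focal_gq <- ifelse(n_alt_hom == 1L, geno$gq[focal_row], NA_integer_)

  per_site <- tibble(
    contig = geno$contig[first_row], pos = geno$pos[first_row],
    ref = geno$ref[first_row], alt = geno$alt[first_row],
    n_alt_hom = n_alt_hom,
    focal_line = ifelse(n_alt_hom == 1L, geno$line_id[focal_row], NA_character_),
    focal_dp = focal_dp, focal_gq = focal_gq,
    focal_alt_index = ifelse(n_alt_hom == 1L, geno$alt_index[focal_row], NA_integer_),
    crit_i = n_multi_hom == 1L,
    crit_ii = n_alt_hom == 1L & !is.na(focal_dp) &
      focal_dp >= thresholds$min_dp_focal,
    crit_iii = n_het == 0L,
    crit_iv = n_support >= thresholds$min_support_lines,
    crit_v = !is.na(focal_gq) & focal_gq >= thresholds$min_gq
  ) |>
    mutate(pass = .data$crit_i & .data$crit_ii & .data$crit_iii &
             .data$crit_iv & .data$crit_v)

  attrition <- tibble(
    criterion = c("sites", "i_single_multihom_class", "ii_unique_alt_hom_dp",
                  "iii_no_other_het", "iv_support_lines", "v_focal_gq",
                  "candidates"),
    n = c(nrow(per_site), sum(per_site$crit_i), sum(per_site$crit_ii),
          sum(per_site$crit_iii), sum(per_site$crit_iv), sum(per_site$crit_v),
          sum(per_site$pass))
  )

  out <- per_site |>
    filter(.data$pass) |>
    mutate(
      alt_allele = purrr::map2_chr(
        stringr::str_split(.data$alt, stringr::fixed(",")),
        .data$focal_alt_index,
        function(a, i) if (!is.na(i) && i >= 1 && i <= length(a)) a[[i]] else NA_character_
      )
    ) |>
    mutate(
      line_id = .data$focal_line,
      mtype = mutation_type(.data$ref, .data$alt_allele),
      length_delta = nchar(.data$alt_allele) - nchar(.data$ref),
      dp = .data$focal_dp, gq = .data$focal_gq
    ) |>
    select("line_id", "contig", "pos", "mtype", ref = "ref",
           alt = "alt_allele", "length_delta", "dp", "gq") |>
    arrange(.data$contig, .data$pos, .data$line_id)

  structure(out, class = c("ma_candidates", class(out)), attrition = attrition)
}

#' Remove linked same-line candidates (criterion vi)
#'
#' Any two candidates of the *same line* on the same contig whose positions
#' lie within `window` bp of each other are **both** removed: closely linked
#' "accumulated" variants are more likely a single mis-resolved event (e.g.
#' a complex indel split by the caller) than two independent mutations.
#' Candidates of different lines never interact.
#'
#' @param candidates A candidate tibble (any table with `line_id`, `contig`,
#'   `pos`).
#' @param window Linkage window in bp (pairs at distance <= `window` are
#'   removed).
#' @return The filtered tibble, same class and columns; attribute
#'   `n_removed_linked` records how many rows were dropped.
#' @export
remove_linked <- function(candidates, window = 100) {
  if (nrow(candidates) == 0) {
    return(structure(candidates, n_removed_linked = 0L))
  }
  ord <- candidates |>
    mutate(.row = row_number()) |>
    arrange(.data$line_id, .data$contig, .data$pos)
  same_prev <- c(FALSE, ord$line_id[-1] == ord$line_id[-nrow(ord)] &
                   ord$contig[-1] == ord$contig[-nrow(ord)] &
                   (ord$pos[-1] - ord$pos[-nrow(ord)]) <= window)
  linked <- same_prev | c(same_prev[-1], FALSE)
  keep_rows <- sort(ord$.row[!linked])
  out <- candidates[keep_rows, , drop = FALSE]
  structure(out, class = class(candidates),
            n_removed_linked = sum(linked),
            attrition = attr(candidates, "attrition"))
}

#' Shared alternative-homozygote counts between line pairs
#'
#' Screens a group for cross-contamination or sample swaps. A locus is
#' *eligible* iff every line is covered by more than five reads
#' (`DP >= min_dp`) and fewer than `max_alt_fraction` of the lines are
#' alternative homozygotes (this removes loci reflecting background
#' heterozygosity of the founder rather than line-specific events). For each
#' eligible locus, every pair of lines homozygous for the *same* alternative
#' allele is counted once.
#'
#' @param geno A long genotype tibble from [read_vcf_matrix()].
#' @param group An [ma_group()]. All lines (including excluded) participate:
#'   this screen is what justifies exclusions.
#' @param min_dp Minimum DP (inclusive) for every line; default 6 ("more than
#'   five reads").
#' @param max_alt_fraction Loci with an alt-homozygote fraction at or above
#'   this value are ineligible (default 0.30).
#' @return A tibble of class `ma_sharing` with one row per unordered line
#'   pair: `line_a`, `line_b`, `shared`, `eligible` (the number of eligible
#'   loci, identical for all pairs).
#' @export
pairwise_sharing <- function(geno, group, min_dp = 6, max_alt_fraction = 0.30) {
  stopifnot(inherits(group, "ma_group"))
  lines <- group$lines
  geno <- filter(geno, .data$line_id %in% lines)

  site <- geno |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      eligible = all(.data$dp >= min_dp) &&
        mean(.data$gclass == "alt_hom") < max_alt_fraction,
      .groups = "drop"
    )
  eligible_sites <- site |> filter(.data$eligible)
  n_eligible <- nrow(eligible_sites)

  pairs <- t(utils::combn(sort(lines), 2))
  counts <- setNames(integer(nrow(pairs)),
                     paste(pairs[, 1], pairs[, 2], sep = "\r"))

  if (n_eligible > 0) {
    hom <- geno |>
      dplyr::semi_join(eligible_sites, by = c("contig", "pos")) |>
      filter(.data$gclass == "alt_hom")
    if (nrow(hom) > 0) {
      shared <- hom |>
        group_by(.data$contig, .data$pos, .data$alt_index) |>
        summarise(ids = list(sort(.data$line_id)), .groups = "drop") |>
        filter(lengths(.data$ids) >= 2)
      if (nrow(shared) > 0) {
        keys <- unlist(purrr::map(shared$ids, function(ids) {
          cmb <- utils::combn(ids, 2)
          paste(cmb[1, ], cmb[2, ], sep = "\r")
        }))
        tab <- table(keys)
        counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      }
    }
  }

  out <- tibble(
    line_a = pairs[, 1], line_b = pairs[, 2],
    shared = unname(counts), eligible = n_eligible
  )
  structure(out, class = c("ma_sharing", class(out)))
}

#' Flag line pairs with outlying sharing counts
#'
#' Pairs whose shared alternative-homozygote count exceeds
#' `median + k * MAD` (MAD without consistency scaling) over all pairs are
#' flagged as potential cross-contamination; the lines involved are listed for
#' manual exclusion via the group's `excluded` field. If all counts are equal
#' the distribution is degenerate and nothing is flagged.
#'
#' @param sharing A [pairwise_sharing()] result (needs >= 3 pairs).
#' @param k Multiplier on the MAD (default 5).
#' @return A tibble of flagged pairs (possibly empty) with columns `line_a`,
#'   `line_b`, `shared`, `threshold`.
#' @export
flag_contaminated <- function(sharing, k = 5) {
  stopifnot(is.data.frame(sharing), all(c("line_a", "line_b", "shared") %in% names(sharing)))
  if (nrow(sharing) < 3) abort("need at least 3 line pairs to assess outliers")
  x <- sharing$shared
  if (length(unique(x)) == 1) {
    return(tibble(line_a = character(), line_b = character(),
                  shared = integer(), threshold = double()))
  }
  thr <- median(x) + k * mad(x, constant = 1)
  sharing |>
    filter(.data$shared > thr) |>
    mutate(threshold = thr) |>
    select("line_a", "line_b", "shared", "threshold") |>
    as_tibble()
}

#' @export
print.ma_candidates <- function(x, ...) {
  cat(sprintf("<ma_candidates> %d candidate mutation(s)\n", nrow(x)))
  NextMethod()
}
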