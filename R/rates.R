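#' Callable-region mask from per-site depths
#'
#' A position is *callable* for a group when more than half of its active
#' lines are covered by more than five reads there (strictly more than
#' `|group|/2` lines with `DP >= min_dp`). The total callable length is the
#' denominator of every mutation rate.
#'
#' Two input shapes are accepted:
#' * a long depth tibble with columns `contig`, `pos`, `line_id`, `dp`
#'   (positions absent from the table count as DP 0 everywhere and are not
#'   callable);
#' * a pre-summarised tibble with columns `contig`, `pos`, `n_high` — the
#'   number of lines with `DP >= min_dp` — as produced by the synthetic
#'   sequencing emulator for whole-genome depth tracks.
#'
#' @param depth Depth information in one of the two shapes above.
#' @param group An [ma_group()]; only active lines count (long shape), and
#'   `n_lines` is taken from the group.
#' @param min_dp Per-line depth threshold (inclusive); default 6, i.e.
#'   "more than five reads".
#' @return A tibble of class `callable_mask` with run-length encoded callable
#'   intervals (`contig`, `start`, `end`), and attributes `callable_length`
#'   and `n_lines`.
#' @export
callable_mask <- function(depth, group, min_dp = 6) {
  stopifnot(inherits(group, "ma_group"), is.data.frame(depth))
  lines <- group_lines(group)
  n_lines <- length(lines)
  if ("n_high" %in% names(depth)) {
    counts <- depth |> select("contig", "pos", "n_high")
  } else {
    stopifnot(all(c("contig", "pos", "line_id", "dp") %in% names(depth)))
    counts <- depth |>
      filter(.data$line_id %in% lines) |>
      group_by(.data$contig, .data$pos) |>
      summarise(n_high = sum(.data$dp >= min_dp), .groups = "drop")
  }
  callable <- counts |>
    filter(.data$n_high > n_lines / 2) |>
    arrange(.data$contig, .data$pos)
  mask_from_positions(callable$contig, callable$pos, n_lines)
}

# collapse sorted callable positions into runs
mask_from_positions <- function(contig, pos, n_lines) {
  if (length(pos) == 0) {
    runs <- tibble(contig = character(), start = integer(), end = integer())
  } else {
    new_run <- c(TRUE, contig[-1] != contig[-length(contig)] |
                   pos[-1] != pos[-length(pos)] + 1L)
    id <- cumsum(new_run)
    runs <- tibble(contig = contig, pos = pos, id = id) |>
      group_by(.data$id) |>
      summarise(contig = first(.data$contig), start = min(.data$pos),
                end = max(.data$pos), .groups = "drop") |>
      select("contig", "start", "end")
  }
  new_callable_mask(runs, n_lines)
}

new_callable_mask <- function(runs, n_lines) {
  structure(
    as_tibble(runs),
    class = c("callable_mask", class(as_tibble(runs))),
    callable_length = sum(runs$end - runs$start + 1),
    n_lines = n_lines
  )
}

#' Total callable length of a mask, in bp
#' @param mask A [callable_mask()].
#' @return Numeric length.
#' @export
callable_length <- function(mask) {
  stopifnot(inherits(mask, "callable_mask"))
  attr(mask, "callable_length")
}

#' Are positions inside the callable mask?
#' @param mask A [callable_mask()].
#' @param contig,pos Vectors of positions to test.
#' @return Logical vector.
#' @export
in_mask <- function(mask, contig, pos) {
  out <- logical(length(pos))
  for (ct in unique(contig)) {
    runs <- mask[mask$contig == ct, , drop = FALSE]
    i <- which(contig == ct)
    if (nrow(runs) == 0) next
    j <- findInterval(pos[i], runs$start)
    out[i] <- j >= 1 & pos[i] <= runs$end[pmax(j, 1L)]
  }
  out
}

#' Write/read a callable mask as TSV
#' @param mask A [callable_mask()].
#' @param path File path.
#' @return `path` invisibly / the mask.
#' @export
write_mask <- function(mask, path) {
  readr::write_tsv(as_tibble(mask) |>
                     mutate(n_lines = attr(mask, "n_lines")), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), n_lines = readr::col_integer()
  ))
  new_callable_mask(select(x, -"n_lines"), if (nrow(x)) x$n_lines[1] else 0L)
}

#' Per-line mutation counts and rates
#'
#' The accumulation rate of each line is its mutation count divided by the
#' number of generations and the callable genome length:
#' `rate = n / (generations * callable_length)`, per type (SNV, insertion,
#' deletion). Candidates falling outside the callable mask are excluded from
#' the counts (numerator/denominator consistency) and their number is
#' reported in the `n_outside_mask` attribute.
#'
#' @param candidates A candidate tibble ([find_candidates()] +
#'   [remove_linked()]).
#' @param mask A [callable_mask()] with positive callable length.
#' @param group An [ma_group()]; every active line appears in the result,
#'   with zero counts if it carries no candidate.
#' @return A tibble of class `ma_rates` with columns `line_id`, `n_snv`,
#'   `n_ins`, `n_del`, `rate_snv`, `rate_ins`, `rate_del`; attributes
#'   `group_name`, `generations`, `callable_length`, `n_outside_mask`.
#' @export
per_line_rates <- function(candidates, mask, group) {
  stopifnot(inherits(mask, "callable_mask"), inherits(group, "ma_group"))
  L <- callable_length(mask)
  if (L <= 0) abort("callable length is 0; rates are undefined")
  lines <- group_lines(group)

  inside <- if (nrow(candidates)) {
    in_mask(mask, candidates$contig, candidates$pos)
  } else {
    logical(0)
  }
  n_outside <- sum(!inside)
  kept <- candidates[inside, , drop = FALSE]

  counts <- kept |>
    as_tibble() |>
    count(.data$line_id, .data$mtype) |>
    tidyr::pivot_wider(names_from = "mtype", values_from = "n", values_fill = 0L)
  for (col in c("SNV", "insertion", "deletion")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  denom <- group$generations * L
  out <- tibble(line_id = lines) |>
    left_join(counts, by = "line_id") |>
    mutate(across(c("SNV", "insertion", "deletion"), function(x) tidyr::replace_na(x, 0L))) |>
    mutate(
      n_snv = .data$SNV, n_ins = .data$insertion, n_del = .data$deletion,
      rate_snv = .data$n_snv / denom,
      rate_ins = .data$n_ins / denom,
      rate_del = .data$n_del / denom
    ) |>
    select("line_id", "n_snv", "n_ins", "n_del",
           "rate_snv", "rate_ins", "rate_del")
  structure(out, class = c("ma_rates", class(out)),
            group_name = group$name, generations = group$generations,
            callable_length = L, n_outside_mask = n_outside)
}

#' Group summary: counts, mean rates with 95% CI, and mutation properties
#'
#' Builds one summary row per group in the shape of a per-group results
#' table: total counts per type, arithmetic-mean per-line rates with a 95%
#' confidence half-width, ts/tv, coding/noncoding and genic/intergenic count
#' ratios, AT bias and mean indel lengths. Spectrum- and annotation-derived
#' columns are `NA` when `candidates`, `genome` or `annotation` are not
#' supplied.
#'
#' The half-width is `1.96 * sd / sqrt(n)` (`ci = "sem"`, the default) or the
#' plain across-line standard deviation (`ci = "sd"`); the `ci_method` column
#' records which.
#'
#' @param rates An [per_line_rates()] result (>= 2 lines for a CI).
#' @param candidates Optional candidate tibble for spectra-derived columns.
#' @param genome Optional [genome_ref()] (needed for AT bias).
#' @param annotation Optional [read_gff()] result (needed for coding/genic
#'   ratios; uses [classify_consequence()]).
#' @param ci `"sem"` or `"sd"`.
#' @return A one-row tibble of class `ma_group_summary`.
#' @export
group_summary <- function(rates, candidates = NULL, genome = NULL,
                          annotation = NULL, ci = c("sem", "sd")) {
  stopifnot(inherits(rates, "ma_rates"))
  ci <- match.arg(ci)
  n <- nrow(rates)
  half <- function(x) {
    if (n < 2) return(NA_real_)
    if (ci == "sem") 1.96 * sd(x) / sqrt(n) else sd(x)
  }

  ts_tv_val <- coding_noncoding <- genic_intergenic <- at_bias_val <- NA_real_
  mean_ins_len <- mean_del_len <- NA_real_
  if (!is.null(candidates) && nrow(candidates)) {
    snvs <- filter(candidates, .data$mtype == "SNV")
    if (nrow(snvs)) {
      ts <- sum(is_transition(snvs$ref, snvs$alt))
      tv <- nrow(snvs) - ts
      ts_tv_val <- if (tv > 0) ts / tv else NA_real_
      if (!is.null(genome)) {
        at_bias_val <- at_bias(spectrum_table(snvs), genome)
      }
    }
    il <- filter(candidates, .data$mtype != "SNV")
    if (nrow(il)) {
      mean_ins_len <- mean(abs(il$length_delta[il$mtype == "insertion"]))
      mean_del_len <- mean(abs(il$length_delta[il$mtype == "deletion"]))
    }
    if (!is.null(annotation) && !is.null(genome)) {
      cq <- classify_consequence(candidates, annotation, genome)
      n_coding <- sum(cq$coding)
      n_genic <- sum(cq$genic)
      coding_noncoding <- if (nrow(cq) > n_coding) n_coding / (nrow(cq) - n_coding) else NA_real_
      genic_intergenic <- if (nrow(cq) > n_genic) n_genic / (nrow(cq) - n_genic) else NA_real_
    }
  }

  out <- tibble(
    group = attr(rates, "group_name") %||% NA_character_,
    n_lines = n,
    generations = attr(rates, "generations") %||% NA_integer_,
    callable_length = attr(rates, "callable_length") %||% NA_real_,
    n_snv = sum(rates$n_snv), n_ins = sum(rates$n_ins), n_del = sum(rates$n_del),
    rate_snv = mean(rates$rate_snv), ci_snv = half(rates$rate_snv),
    rate_ins = mean(rates$rate_ins), ci_ins = half(rates$rate_ins),
    rate_del = mean(rates$rate_del), ci_del = half(rates$rate_del),
    ci_method = ci,
    ts_tv = ts_tv_val,
    coding_noncoding = coding_noncoding,
    genic_intergenic = genic_intergenic,
    at_bias = at_bias_val,
    mean_ins_len = mean_ins_len,
    mean_del_len = mean_del_len
  )
  structure(out, class = c("ma_group_summary", class(out)))
}

#' Fold change of mean mutation rates across groups
#'
#' `max(mean rate) / min(mean rate)` over the supplied group summaries for
#' one mutation type, rounded half-away-from-zero at `digits` decimals.
#'
#' @param summaries A tibble of group summaries (rows from [group_summary()]
#'   or any table with a `rate_<mtype>` column).
#' @param mtype One of `"snv"`, `"ins"`, `"del"`.
#' @param digits Decimals for reporting (default 1).
#' @return A single number.
#' @export
fold_change <- function(summaries, mtype = c("snv", "ins", "del"), digits = 1) {
  mtype <- match.arg(mtype)
  col <- paste0("rate_", mtype)
  stopifnot(col %in% names(summaries), nrow(summaries) >= 2)
  x <- summaries[[col]]
  if (min(x) <= 0) abort("fold change undefined: a group mean rate is 0")
  round_half_away(max(x) / min(x), digits)
}
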