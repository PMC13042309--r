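#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' kept verbatim. Values are parsed as numbers where possible. Keys mirror
#' the arguments of [sim_params()] and [ma_thresholds()] plus `outdir`,
#' `n_groups` and `seed`.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- stringr::str_split_fixed(lines, "=", 2)
  if (any(kv[, 2] == "")) abort("config lines must be 'key = value'")
  vals <- trimws(kv[, 2])
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(parsed, trimws(kv[, 1]))
}

#' Run the full synthetic MA analysis pipeline
#'
#' Orchestrates simulate -> filter -> contamination screen -> rates ->
#' spectra -> group comparison -> truth scoring, writing every stage's table
#' under `outdir`. Deterministic under the configured seed; rerunning a
#' config yields byte-identical tables. The report header serializes every
#' threshold for provenance, and per-criterion attrition counts of the
#' mutation filter are logged per group.
#'
#' @param config A named list (see [read_run_config()]) or a path to a
#'   config file. Recognized keys: all [sim_params()] arguments, all
#'   [ma_thresholds()] arguments, `n_groups` (default 2; group 2 reuses the
#'   parameters with `seed + 1000`), and `seed` (mandatory).
#' @param outdir Output directory.
#' @return Invisibly, a list of class `ma_report`: `summaries` (one row per
#'   group), `comparisons`, `scores` (precision/recall per group),
#'   `candidates` (named list), `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- read_run_config(config)
  }
  if (is.null(config$seed)) abort("config must set `seed`")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  take <- function(f, extra = list()) {
    args <- config[intersect(names(config), names(formals(f)))]
    do.call(f, c(args, extra))
  }
  thresholds <- take(ma_thresholds)
  n_groups <- as.integer(config$n_groups %||% 2L)

  summaries <- list()
  scores <- list()
  rates_list <- list()
  spectra_list <- list()
  candidates_list <- list()
  for (gi in seq_len(n_groups)) {
    gname <- sprintf("group%d", gi)
    params <- take(sim_params)
    params$seed <- as.integer(params$seed + (gi - 1L) * 1000L)
    group <- sim_group(params, gname)

    genome <- generate_founder(params)
    truth <- simulate_lines(genome, params)
    calls <- emulate_calling(genome, truth, params,
                             dir = file.path(outdir, gname))
    geno <- read_vcf_matrix(calls$vcf, group)

    sharing <- pairwise_sharing(geno, group)
    flagged <- flag_contaminated(sharing)
    readr::write_tsv(sharing, file.path(outdir, paste0("sharing_", gname, ".tsv")))
    if (nrow(flagged)) {
      inform(sprintf("[%s] contamination screen flagged: %s", gname,
                     paste(flagged$line_a, flagged$line_b, sep = "~", collapse = ", ")))
    }

    cands <- find_candidates(geno, group, thresholds)
    attrition <- attr(cands, "attrition")
    cands <- remove_linked(cands, window = thresholds$link_window)
    inform(sprintf(
      "[%s] %s; %d removed as linked",
      gname,
      paste(sprintf("%s=%d", attrition$criterion, attrition$n), collapse = " "),
      attr(cands, "n_removed_linked")
    ))
    write_candidates(cands, file.path(outdir, paste0("candidates_", gname, ".tsv")))
    candidates_list[[gname]] <- cands

    rates <- per_line_rates(cands, calls$mask, group)
    readr::write_tsv(rates, file.path(outdir, paste0("rates_", gname, ".tsv")))
    rates_list[[gname]] <- rates
    spec <- spectrum_table(cands)
    spectra_list[[gname]] <- spec
    readr::write_tsv(spec, file.path(outdir, paste0("spectrum_", gname, ".tsv")))
    readr::write_tsv(indel_lengths(cands),
                     file.path(outdir, paste0("indel_lengths_", gname, ".tsv")))

    summaries[[gname]] <- group_summary(rates, cands, genome)
    scores[[gname]] <- score_candidates(cands, truth) |>
      mutate(group = gname, .before = 1)
  }

  summary_tbl <- bind_rows(summaries)
  scores_tbl <- bind_rows(scores)
  provenance <- c(
    "# malines run report",
    sprintf("# seed=%s n_groups=%d", format(config$seed), n_groups),
    sprintf("# thresholds: focal_dp>=%d support_dp>=%d support_lines>=%d gq>=%d link_window=%d",
            thresholds$min_dp_focal, thresholds$min_dp_support,
            thresholds$min_support_lines, thresholds$min_gq,
            thresholds$link_window)
  )
  report_path <- file.path(outdir, "report.tsv")
  readr::write_lines(provenance, report_path)
  readr::write_tsv(summary_tbl, report_path, append = TRUE, col_names = TRUE)
  readr::write_tsv(scores_tbl, file.path(outdir, "truth_scores.tsv"))

  comparisons <- NULL
  if (n_groups >= 2) {
    comparisons <- compare_groups(rates_list, spectra_list,
                                  seed = as.integer(config$seed))
    readr::write_tsv(comparisons, file.path(outdir, "comparisons.tsv"))
  }

  invisible(structure(
    list(summaries = summary_tbl, comparisons = comparisons,
         scores = scores_tbl, candidates = candidates_list, outdir = outdir),
    class = "ma_report"
  ))
}

#' Published per-group MA summary statistics
#'
#' Summary rows (counts, rates with their printed 95% confidence
#' half-widths, ts/tv, coding/noncoding, genic/intergenic and AT-bias
#' columns) for five published *Pristionchus pacificus* MA groups: the
#' laboratory strain PS312 on *E. coli* OP50 and wild isolates RSC011/RSC019
#' on four bacterial diets. Rates are per site per generation (`rate_snv`
#' absolute; the `*_e9`/`*_e10` columns carry the printed mantissas).
#' Shipped so that arithmetic checks (column totals, fold changes, rate
#' ranges) run without any sequencing data.
#'
#' @return A tibble with one row per group.
#' @export
published_ma_summary <- function() {
  path <- system.file("extdata", "published_ma_summary.tsv",
                      package = "malines", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    strain = readr::col_character(), diet = readr::col_character(),
    newly_analyzed = readr::col_logical(),
    .default = readr::col_double()
  )) |>
    mutate(
      rate_snv = .data$rate_snv_e9 * 1e-9,
      rate_ins = .data$rate_ins_e10 * 1e-10,
      rate_del = .data$rate_del_e10 * 1e-10
    )
}
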