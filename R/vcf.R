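#' Read a multi-sample VCF into a long genotype tibble
#'
#' Loads per-site, per-line genotype calls with their depth (DP) and genotype
#' quality (GQ) for the lines of one group. Genotype strings are mapped to
#' classes: `0/0` -> `ref_hom`, two identical non-reference alleles -> `alt_hom`,
#' two different alleles -> `het`, and `./.` -> `missing`. Multi-allelic
#' records are preserved: `alt` holds the comma-joined ALT alleles and
#' `alt_index` records which one a het/alt-hom call carries.
#'
#' Missing DP with a present genotype is treated as `DP = 0`, which fails
#' every depth threshold (conservative).
#'
#' @param vcf_path Path to a VCF (4.x) file with per-sample GT, DP and GQ.
#' @param group An [ma_group()]; all of its lines (including excluded ones)
#'   must be sample columns of the VCF.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`, `line_id`,
#'   `gclass`, `dp`, `gq`, `alt_index`, ordered by (`contig`, `pos`) as in the
#'   input. One row per record per line.
#' @export
read_vcf_matrix <- function(vcf_path, group) {
  stopifnot(inherits(group, "ma_group"))
  vcf <- VariantAnnotation::readVcf(vcf_path)
  samples <- colnames(vcf)
  missing_samples <- setdiff(group$lines, samples)
  if (length(missing_samples)) {
    abort(paste0("sample column(s) not in VCF: ",
                 paste(missing_samples, collapse = ", ")))
  }
  gmat <- VariantAnnotation::geno(vcf)
  for (tag in c("GT", "DP", "GQ")) {
    if (!tag %in% names(gmat)) {
      abort(sprintf("VCF lacks the per-sample %s tag", tag))
    }
  }
  vcf <- vcf[, group$lines]
  gmat <- VariantAnnotation::geno(vcf)

  rr <- SummarizedExperiment::rowRanges(vcf)
  n_rec <- length(rr)
  alts <- VariantAnnotation::fixed(vcf)$ALT
  alt_str <- vapply(as.list(alts), function(a) {
    paste(as.character(a), collapse = ",")
  }, character(1))

  gt <- gmat$GT
  dp <- gmat$DP
  gq <- gmat$GQ
  dp[is.na(dp)] <- 0L
  gq[is.na(gq)] <- 0L

  long <- tibble(
    contig = rep(as.character(GenomicRanges::seqnames(rr)), times = length(group$lines)),
    pos = rep(GenomicRanges::start(rr), times = length(group$lines)),
    ref = rep(as.character(VariantAnnotation::fixed(vcf)$REF), times = length(group$lines)),
    alt = rep(alt_str, times = length(group$lines)),
    line_id = rep(group$lines, each = n_rec),
    gt = as.vector(gt),
    dp = as.integer(as.vector(dp)),
    gq = as.integer(as.vector(gq))
  )
  parsed <- parse_gt(long$gt)
  long |>
    mutate(gclass = parsed$gclass, alt_index = parsed$alt_index) |>
    select(-"gt") |>
    arrange(match(.data$contig, unique(.data$contig)), .data$pos, .data$line_id)
}

# map VCF GT strings to (gclass, alt_index); phased separators accepted
parse_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- stringr::str_split_fixed(gt, "/", 2)
  a1 <- suppressWarnings(as.integer(parts[, 1]))
  a2 <- suppressWarnings(as.integer(parts[, 2]))
  a2[parts[, 2] == ""] <- a1[parts[, 2] == ""]  # haploid call: treat as hom
  gclass <- dplyr::case_when(
    is.na(a1) | is.na(a2) ~ "missing",
    a1 == 0L & a2 == 0L ~ "ref_hom",
    a1 == a2 ~ "alt_hom",
    TRUE ~ "het"
  )
  alt_index <- dplyr::case_when(
    gclass == "alt_hom" ~ a1,
    gclass == "het" ~ pmax(a1, a2),
    TRUE ~ NA_integer_
  )
  list(gclass = gclass, alt_index = alt_index)
}

#' Write a candidate-mutation table as TSV
#'
#' Columns: `contig`, `pos`, `line_id`, `mtype`, `ref`, `alt` (and any extra
#' columns present, e.g. `consequence`), sorted stably by
#' (`contig`, `pos`, `line_id`).
#'
#' @param candidates A candidate tibble (see [find_candidates()]).
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
write_candidates <- function(candidates, out_path) {
  cols <- c("contig", "pos", "line_id", "mtype", "ref", "alt")
  stopifnot(all(cols %in% names(candidates)))
  extra <- setdiff(names(candidates), c(cols, "length_delta", "dp", "gq"))
  out <- candidates |>
    select(dplyr::all_of(c(cols, "length_delta")), dplyr::any_of(c("dp", "gq")), dplyr::all_of(extra)) |>
    arrange(.data$contig, .data$pos, .data$line_id)
  readr::write_tsv(out, out_path)
  invisible(out_path)
}

#' Read a candidate-mutation table written by [write_candidates()]
#' @param path Path to the TSV.
#' @return A tibble of candidates.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      contig = readr::col_character(), pos = readr::col_integer(),
      line_id = readr::col_character(), mtype = readr::col_character(),
      ref = readr::col_character(), alt = readr::col_character(),
      length_delta = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
}

#' Classify a ref/alt allele pair as SNV, insertion or deletion
#'
#' @param ref,alt Allele strings (VCF convention: indels carry the anchor base).
#' @return Character vector in `{"SNV", "insertion", "deletion"}`; `"MNV"` for
#'   equal-length multi-base substitutions.
#' @export
mutation_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(alt) > nchar(ref) ~ "insertion",
    nchar(alt) < nchar(ref) ~ "deletion",
    TRUE ~ "MNV"
  )
}
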