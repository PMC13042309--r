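#' Parameters of a synthetic MA experiment
#'
#' Describes the world the generator emulates: a founder genome, `n_lines`
#' isogenic lines propagated by single-individual descent for `generations`
#' generations, accumulating mutations at per-site per-generation rates
#' `mu_snv`, `mu_ins`, `mu_del`. Every surviving mutation is modelled as
#' instantly fixed homozygous in its line (the single transferred
#' hermaphrodite bottleneck); heterozygous segregation is not modelled.
#' SNV classes follow `spectrum`; indel lengths are
#' `1 + Geometric(mean = indel_length_mean - 1)`. Sequencing is emulated with
#' per-call depth `DP ~ Poisson(coverage_mean)` and genotype quality
#' `GQ ~ Normal(gq_mean, gq_sd)` clamped to `[0, 99]`; with probability
#' `het_miscall_rate` a non-carrier call is emitted heterozygous, and with
#' probability `missing_rate` any call becomes `./.`.
#'
#' The default rates are the desk-scale setting: ~50-100x the rates observed
#' in nematode MA experiments (which are ~1.7-2.4e-9 SNVs/site/generation) on
#' a 1 Mb founder, so that expected counts (~10 SNVs/line) are testable in
#' seconds. Passing the real-scale rates with a full-size `genome_length`
#' is the un-inflated mode.
#'
#' @param genome_length Founder genome length in bp.
#' @param gc_content Founder GC fraction.
#' @param n_lines Number of MA lines.
#' @param generations Generations of propagation.
#' @param mu_snv,mu_ins,mu_del Per-site per-generation mutation rates.
#' @param spectrum Probability vector over the six SNV classes (named by
#'   [SNV class][snv_class]; must sum to 1).
#' @param indel_length_mean Mean indel length in bp (>= 1).
#' @param coverage_mean Mean per-call sequencing depth.
#' @param gq_mean,gq_sd Genotype-quality distribution parameters.
#' @param het_miscall_rate Probability a non-carrier is called heterozygous.
#' @param missing_rate Probability any call is missing (`./.`).
#' @param contamination `NULL`, or `list(lines = c(donor, recipient),
#'   shared_fraction = f)`: each donor mutation is copied into the recipient
#'   line with probability `f` (cross-contamination).
#' @param min_spacing Minimum distance in bp between two mutations of the
#'   same line (0 = unconstrained). Set above the linkage window to emulate
#'   a world without linked pairs.
#' @param seed Integer seed (mandatory; all stages derive their RNG streams
#'   from it).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 1e6, gc_content = 0.42, n_lines = 20,
                       generations = 100, mu_snv = 1e-7, mu_ins = 2e-8,
                       mu_del = 3e-8,
                       spectrum = c("A:T>T:A" = 0.15, "A:T>C:G" = 0.10,
                                    "A:T>G:C" = 0.25, "G:C>A:T" = 0.30,
                                    "G:C>T:A" = 0.12, "G:C>C:G" = 0.08),
                       indel_length_mean = 3, coverage_mean = 30,
                       gq_mean = 80, gq_sd = 15, het_miscall_rate = 0,
                       missing_rate = 0, contamination = NULL,
                       min_spacing = 0, seed) {
  if (missing(seed) || !is_count(seed)) abort("an integer `seed` is mandatory")
  stopifnot(
    genome_length >= 1, gc_content >= 0, gc_content <= 1,
    is_count(n_lines), n_lines >= 1, is_count(generations), generations >= 1,
    mu_snv >= 0, mu_ins >= 0, mu_del >= 0,
    indel_length_mean >= 1, coverage_mean >= 0,
    het_miscall_rate >= 0, het_miscall_rate <= 1,
    missing_rate >= 0, missing_rate <= 1, min_spacing >= 0
  )
  if (length(spectrum) != 6 || abs(sum(spectrum) - 1) > 1e-8 || any(spectrum < 0)) {
    abort("`spectrum` must be 6 non-negative probabilities summing to 1")
  }
  if (is.null(names(spectrum))) names(spectrum) <- SNV_CLASSES
  if (!setequal(names(spectrum), SNV_CLASSES)) {
    abort("`spectrum` names must be the six SNV classes")
  }
  spectrum <- spectrum[SNV_CLASSES]
  if (!is.null(contamination)) {
    stopifnot(is.list(contamination), length(contamination$lines) == 2,
              contamination$shared_fraction >= 0,
              contamination$shared_fraction <= 1)
  }
  structure(
    list(genome_length = genome_length, gc_content = gc_content,
         n_lines = as.integer(n_lines), generations = as.integer(generations),
         mu_snv = mu_snv, mu_ins = mu_ins, mu_del = mu_del,
         spectrum = spectrum, indel_length_mean = indel_length_mean,
         coverage_mean = coverage_mean, gq_mean = gq_mean, gq_sd = gq_sd,
         het_miscall_rate = het_miscall_rate, missing_rate = missing_rate,
         contamination = contamination, min_spacing = min_spacing,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Line ids and group of a synthetic experiment
#' @param params A [sim_params()].
#' @param name Group name.
#' @return [sim_line_ids()]: character vector `L01`, `L02`, ...;
#'   [sim_group()]: the corresponding [ma_group()].
#' @export
sim_line_ids <- function(params) {
  sprintf("L%02d", seq_len(params$n_lines))
}

#' @rdname sim_line_ids
#' @export
sim_group <- function(params, name = "sim") {
  ma_group(name, sim_line_ids(params), params$generations)
}

#' Generate a random founder genome
#'
#' A single contig (`chrI`) of iid bases with expected GC fraction
#' `gc_content`; reproducible under the seed.
#'
#' @param params A [sim_params()].
#' @return A [genome_ref()].
#' @export
generate_founder <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- c(A = (1 - params$gc_content) / 2, C = params$gc_content / 2,
         G = params$gc_content / 2, T = (1 - params$gc_content) / 2)
  seq <- withr::with_seed(params$seed, {
    paste(sample(names(p), params$genome_length, replace = TRUE, prob = p),
          collapse = "")
  })
  genome_ref(c(chrI = seq))
}

#' Simulate per-line mutation accumulation
#'
#' Each line independently accrues `Poisson(mu_type * L * G)` mutations per
#' type. SNV classes are drawn from the configured spectrum and placed on a
#' site whose reference base matches the class (so empirical class
#' frequencies converge to the spectrum); indel lengths are geometric-tailed.
#' Positions are uniform over non-N sites, unique genome-wide, and respect
#' `min_spacing` within a line. With `contamination` configured, a fraction
#' of the donor line's mutations is copied into the recipient line.
#'
#' @param genome A founder [genome_ref()].
#' @param params A [sim_params()].
#' @return A truth tibble of class `ma_truth`: `line_id`, `contig`, `pos`,
#'   `mtype`, `ref`, `alt`, `generation`.
#' @export
simulate_lines <- function(genome, params) {
  stopifnot(inherits(genome, "genome_ref"), inherits(params, "sim_params"))
  withr::with_seed(params$seed + 1L, simulate_lines_impl(genome, params))
}

simulate_lines_impl <- function(genome, params) {
  contig <- genome$composition$contig[1]
  if (nrow(genome$composition) > 1) {
    # one-contig founders only; multi-contig simulation is not needed at
    # desk scale and real data enters through read_genome/read_vcf_matrix
    abort("simulate_lines supports single-contig founder genomes")
  }
  base <- strsplit(as.character(genome$seq[[1]]), "", fixed = TRUE)[[1]]
  L <- length(base)
  at_idx <- which(base %in% c("A", "T"))
  gc_idx <- which(base %in% c("G", "C"))
  non_n <- which(base != "N")
  occupied <- logical(L)
  G <- params$generations
  lam <- function(mu) mu * L * G

  alt_for_class <- function(cls_i, ref) {
    if (cls_i <= 3) {
      a <- c("T", "C", "G")[cls_i]
      if (ref == "A") a else unname(DNA_COMPLEMENT[a])
    } else {
      a <- c("A", "T", "C")[cls_i - 3]
      if (ref == "G") a else unname(DNA_COMPLEMENT[a])
    }
  }

  draw_pos <- function(pool, line_pos, spacing, span = 0L) {
    # rejection-sample a position from pool: unoccupied, spacing from the
    # line's own mutations, and (for deletions) span fits on the contig
    for (attempt in seq_len(2000L)) {
      p <- pool[sample.int(length(pool), 1L)]
      if (occupied[p]) next
      if (span > 0L && (p + span > L || any(base[p:(p + span)] == "N"))) next
      if (spacing > 0L && length(line_pos) &&
          min(abs(line_pos - p)) <= spacing) next
      return(p)
    }
    abort("could not place a mutation after 2000 retries; genome too small for the requested rates/spacing")
  }

  rows <- vector("list", params$n_lines)
  ids <- sim_line_ids(params)
  for (li in seq_len(params$n_lines)) {
    n_snv <- rpois(1, lam(params$mu_snv))
    n_ins <- rpois(1, lam(params$mu_ins))
    n_del <- rpois(1, lam(params$mu_del))
    line_pos <- integer(0)
    out <- list()
    if (n_snv > 0) {
      cls <- sample.int(6L, n_snv, replace = TRUE, prob = params$spectrum)
      for (k in seq_len(n_snv)) {
        pool <- if (cls[k] <= 3) at_idx else gc_idx
        p <- draw_pos(pool, line_pos, params$min_spacing)
        occupied[p] <- TRUE
        line_pos <- c(line_pos, p)
        out[[length(out) + 1]] <- tibble(
          line_id = ids[li], contig = contig, pos = p, mtype = "SNV",
          ref = base[p], alt = alt_for_class(cls[k], base[p]),
          generation = sample.int(G, 1L)
        )
      }
    }
    indel_len <- function() 1L + rgeom(1, 1 / params$indel_length_mean)
    if (n_ins > 0) {
      for (k in seq_len(n_ins)) {
        p <- draw_pos(non_n, line_pos, params$min_spacing)
        occupied[p] <- TRUE
        line_pos <- c(line_pos, p)
        len <- indel_len()
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c((1 - params$gc_content) / 2,
                                     params$gc_content / 2,
                                     params$gc_content / 2,
                                     (1 - params$gc_content) / 2)),
                     collapse = "")
        out[[length(out) + 1]] <- tibble(
          line_id = ids[li], contig = contig, pos = p, mtype = "insertion",
          ref = base[p], alt = paste0(base[p], ins),
          generation = sample.int(G, 1L)
        )
      }
    }
    if (n_del > 0) {
      for (k in seq_len(n_del)) {
        len <- indel_len()
        p <- draw_pos(non_n, line_pos, params$min_spacing, span = len)
        occupied[p] <- TRUE
        line_pos <- c(line_pos, p)
        out[[length(out) + 1]] <- tibble(
          line_id = ids[li], contig = contig, pos = p, mtype = "deletion",
          ref = paste(base[p:(p + len)], collapse = ""), alt = base[p],
          generation = sample.int(G, 1L)
        )
      }
    }
    rows[[li]] <- bind_rows(out)
  }
  truth <- bind_rows(rows)
  if (nrow(truth) == 0) {
    truth <- tibble(line_id = character(), contig = character(),
                    pos = integer(), mtype = character(), ref = character(),
                    alt = character(), generation = integer())
    return(structure(truth, class = c("ma_truth", class(truth))))
  }
  if (!is.null(params$contamination)) {
    donor <- params$contamination$lines[1]
    recipient <- params$contamination$lines[2]
    f <- params$contamination$shared_fraction
    src <- filter(truth, .data$line_id == donor)
    if (nrow(src)) {
      take <- runif(nrow(src)) < f
      copied <- src[take, , drop = FALSE] |> mutate(line_id = recipient)
      truth <- bind_rows(truth, copied)
    }
  }
  truth <- arrange(truth, .data$contig, .data$pos, .data$line_id)
  structure(truth, class = c("ma_truth", class(truth)))
}

#' Emulate multi-sample variant calling of an MA experiment
#'
#' Stands in for the read-alignment + joint-genotyping stage of a real
#' pipeline: every truth mutation becomes one multi-sample VCF record with
#' the carrier line called alternative-homozygous and all other lines
#' reference-homozygous, subject to the noise model of [sim_params()]
#' (heterozygous miscalls, missing calls, Poisson depth, clamped-normal GQ).
#' A record whose alternative allele survives in no call (carrier missing,
#' no het miscall) is dropped, as a real caller would emit nothing; dropped
#' records are returned for the conservation check. Instead of emitting
#' millions of invariant background records, a whole-genome depth track is
#' simulated per line and returned run-length encoded as the callable mask
#' (positions where more than half the lines have more than five reads).
#'
#' @param genome The founder [genome_ref()].
#' @param truth A [simulate_lines()] truth table.
#' @param params The same [sim_params()].
#' @param dir Output directory (created if needed).
#' @return A list of class `sim_calls`: `vcf` (path), `mask`
#'   ([callable_mask()]), `dropped` (truth rows that produced no record),
#'   `n_records`.
#' @export
emulate_calling <- function(genome, truth, params, dir = tempfile("simvcf")) {
  stopifnot(inherits(genome, "genome_ref"), inherits(params, "sim_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "calls.vcf")
  withr::with_seed(params$seed + 2L, {
    res <- emulate_calling_impl(genome, truth, params, vcf_path)
  })
  res
}

emulate_calling_impl <- function(genome, truth, params, vcf_path) {
  ids <- sim_line_ids(params)
  n_lines <- length(ids)

  # whole-genome depth track -> callable mask (DP > 5 in > half the lines)
  comp <- genome$composition
  mask_runs <- list()
  for (ci in seq_len(nrow(comp))) {
    L <- comp$length[ci]
    n_high <- integer(L)
    for (li in seq_len(n_lines)) {
      n_high <- n_high + (rpois(L, params$coverage_mean) >= 6L)
    }
    callable <- n_high > n_lines / 2
    r <- rle(callable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      mask_runs[[length(mask_runs) + 1]] <- tibble(
        contig = comp$contig[ci], start = starts[keep], end = ends[keep]
      )
    }
  }
  mask <- new_callable_mask(bind_rows(mask_runs), n_lines)

  rnd_gq <- function(n) {
    pmin(99L, pmax(0L, as.integer(round(rnorm(n, params$gq_mean, params$gq_sd)))))
  }

  # one record per (contig, pos); contamination can put 2+ carriers at a site
  sites <- truth |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      ref = first(.data$ref), alt = first(.data$alt),
      carriers = list(.data$line_id), .groups = "drop"
    ) |>
    arrange(.data$contig, .data$pos)

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", comp$contig, comp$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )

  records <- character(0)
  dropped <- list()
  for (si in seq_len(nrow(sites))) {
    carriers <- sites$carriers[[si]]
    is_carrier <- ids %in% carriers
    gclass <- ifelse(is_carrier, "alt_hom", "ref_hom")
    miscall <- !is_carrier & runif(n_lines) < params$het_miscall_rate
    gclass[miscall] <- "het"
    miss <- runif(n_lines) < params$missing_rate
    gclass[miss] <- "missing"
    if (!any(gclass %in% c("alt_hom", "het"))) {
      dropped[[length(dropped) + 1]] <- filter(
        truth, .data$contig == sites$contig[si], .data$pos == sites$pos[si]
      )
      next
    }
    dp <- rpois(n_lines, params$coverage_mean)
    gq <- rnd_gq(n_lines)
    gt <- dplyr::case_when(
      gclass == "alt_hom" ~ "1/1",
      gclass == "het" ~ "0/1",
      gclass == "missing" ~ "./.",
      TRUE ~ "0/0"
    )
    calls <- sprintf("%s:%d:%d", gt, dp, gq)
    calls[gclass == "missing"] <- sprintf(".:%d:.", dp[gclass == "missing"])
    records[length(records) + 1] <- paste(
      c(sites$contig[si], sites$pos[si], ".", sites$ref[si], sites$alt[si],
        ".", "PASS", ".", "GT:DP:GQ", calls),
      collapse = "\t"
    )
  }
  writeLines(c(header, records), vcf_path)
  structure(
    list(vcf = vcf_path, mask = mask,
         dropped = if (length(dropped)) distinct(bind_rows(dropped)) else truth[0, ],
         n_records = length(records)),
    class = "sim_calls"
  )
}

#' Precision and recall of detected candidates against simulation truth
#'
#' A candidate is a true positive when the truth table contains the same
#' (line, contig, pos, type, ref, alt) record.
#'
#' @param candidates A candidate tibble.
#' @param truth A [simulate_lines()] truth table.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
score_candidates <- function(candidates, truth) {
  key <- function(d) {
    paste(d$line_id, d$contig, d$pos, d$mtype, d$ref, d$alt, sep = "\r")
  }
  kc <- key(candidates)
  kt <- key(truth)
  tp <- sum(kc %in% kt)
  tibble(
    tp = tp, fp = length(kc) - tp, fn = length(kt) - tp,
    precision = if (length(kc)) tp / length(kc) else NA_real_,
    recall = if (length(kt)) tp / length(kt) else NA_real_
  )
}
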