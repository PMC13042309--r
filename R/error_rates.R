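#' Plan random mutation insertions into a reference genome
#'
#' Samples positions for `n_snv` SNVs, `n_ins` insertions and `n_del`
#' deletions, uniformly over the genome but keeping every planted mutation at
#' least `flank` bp away from (a) every already-detected mutation, (b) every
#' other planted mutation, and (c) the contig ends. The flank keeps the
#' re-detection of planted mutations independent of real ones.
#'
#' @param genome A [genome_ref()].
#' @param detected A tibble of detected mutations (`contig`, `pos`), or an
#'   empty tibble.
#' @param n_snv,n_ins,n_del Numbers of mutations to plant per type.
#' @param flank Exclusion flank in bp (default 200).
#' @param indel_length_mean Mean planted indel length (geometric-tailed,
#'   as in [sim_params()]).
#' @param seed Integer seed.
#' @return A tibble of class `ma_plan`: `contig`, `pos`, `mtype`, `ref`,
#'   `alt`, `length_delta`. Errors if the eligible space cannot host the
#'   requested counts, reporting how many were achievable.
#' @export
plan_insertions <- function(genome, detected, n_snv, n_ins, n_del,
                            flank = 200, indel_length_mean = 3, seed) {
  stopifnot(inherits(genome, "genome_ref"), is_count(flank))
  if (missing(seed) || !is_count(seed)) abort("an integer `seed` is mandatory")
  n_total <- n_snv + n_ins + n_del
  withr::with_seed(as.integer(seed), {
    comp <- genome$composition
    # per contig, sorted detected positions for fast distance checks
    det <- split(detected$pos, detected$contig)
    planted <- lapply(comp$contig, function(x) integer(0))
    names(planted) <- comp$contig

    types <- sample(rep(c("SNV", "insertion", "deletion"),
                        times = c(n_snv, n_ins, n_del)))
    rows <- vector("list", n_total)
    for (k in seq_len(n_total)) {
      placed <- FALSE
      for (attempt in seq_len(5000L)) {
        ci <- sample.int(nrow(comp), 1L, prob = comp$length)
        ct <- comp$contig[ci]
        len <- if (types[k] == "SNV") 0L else 1L + rgeom(1, 1 / indel_length_mean)
        lo <- flank + 1L
        hi <- comp$length[ci] - flank - len
        if (hi < lo) next
        p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        near <- function(v) length(v) && min(abs(v - p)) < flank
        if (near(det[[ct]]) || near(planted[[ct]])) next
        ref1 <- genome_base(genome, ct, p)
        if (ref1 == "N") next
        if (types[k] == "SNV") {
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref1), 1L)
          rows[[k]] <- tibble(contig = ct, pos = p, mtype = "SNV",
                              ref = ref1, alt = alt, length_delta = 0L)
        } else if (types[k] == "insertion") {
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          rows[[k]] <- tibble(contig = ct, pos = p, mtype = "insertion",
                              ref = ref1, alt = paste0(ref1, ins),
                              length_delta = len)
        } else {
          span <- genome_base(genome, ct, p, width = len + 1L)
          if (span == "" || grepl("N", span, fixed = TRUE)) next
          rows[[k]] <- tibble(contig = ct, pos = p, mtype = "deletion",
                              ref = span, alt = ref1,
                              length_delta = -len)
        }
        planted[[ct]] <- c(planted[[ct]], p)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf(
          "insufficient eligible space: placed %d of %d requested mutations",
          k - 1L, n_total
        ))
      }
    }
    out <- if (n_total > 0) {
      bind_rows(rows) |> arrange(.data$contig, .data$pos)
    } else {
      tibble(contig = character(), pos = integer(), mtype = character(),
             ref = character(), alt = character(), length_delta = integer())
    }
    structure(out, class = c("ma_plan", class(out)))
  })
}

#' Apply planted mutations to a genome
#'
#' Edits are applied right-to-left within each contig so earlier coordinates
#' are unaffected while editing: an SNV substitutes its base, an insertion
#' adds bases after its anchor, a deletion removes `|length_delta|` bases
#' after its anchor. A coordinate liftover table (original -> edited frame)
#' is returned alongside the edited genome.
#'
#' @param genome A [genome_ref()].
#' @param plan A [plan_insertions()] tibble (non-overlapping by
#'   construction).
#' @return A list of class `ma_edit`: `genome` (edited [genome_ref()]) and
#'   `liftover` (tibble `contig`, `old_start`, `offset`: original positions
#'   `>= old_start` shift by `offset`, taking the row with the largest
#'   applicable `old_start`).
#' @export
apply_insertions <- function(genome, plan) {
  stopifnot(inherits(genome, "genome_ref"))
  seqs <- as.character(genome$seq)
  lift <- list()
  for (ct in unique(plan$contig)) {
    edits <- plan |> filter(.data$contig == ct) |> arrange(dplyr::desc(.data$pos))
    s <- seqs[[ct]]
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]
      if (edits$mtype[i] == "SNV") {
        substr(s, p, p) <- edits$alt[i]
      } else if (edits$mtype[i] == "insertion") {
        s <- paste0(substr(s, 1, p), substr(edits$alt[i], 2, nchar(edits$alt[i])),
                    substr(s, p + 1, nchar(s)))
      } else {
        del_len <- -edits$length_delta[i]
        s <- paste0(substr(s, 1, p), substr(s, p + del_len + 1, nchar(s)))
      }
    }
    seqs[[ct]] <- s
    # forward-order cumulative offsets for the liftover table
    fwd <- arrange(edits, .data$pos)
    delta <- ifelse(fwd$mtype == "SNV", 0L, fwd$length_delta)
    keep <- delta != 0L
    if (any(keep)) {
      lift[[length(lift) + 1]] <- tibble(
        contig = ct,
        old_start = fwd$pos[keep] + 1L,  # positions after the anchor shift
        offset = cumsum(delta[keep])
      )
    }
  }
  liftover <- if (length(lift)) bind_rows(lift) else {
    tibble(contig = character(), old_start = integer(), offset = integer())
  }
  structure(
    list(genome = genome_ref(seqs), liftover = liftover),
    class = "ma_edit"
  )
}

#' Lift positions between original and edited coordinate frames
#'
#' Positions are mapped using the cumulative-offset liftover table from
#' [apply_insertions()]. Positions inside a deleted span have no image in
#' the edited frame and map to `NA`.
#'
#' @param liftover The liftover tibble.
#' @param contig,pos Positions to map.
#' @param direction `"to_edited"` (default) or `"to_original"`.
#' @return Integer vector of mapped positions.
#' @export
lift_positions <- function(liftover, contig, pos,
                           direction = c("to_edited", "to_original")) {
  direction <- match.arg(direction)
  out <- as.integer(pos)
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    lo <- liftover |> filter(.data$contig == ct) |> arrange(.data$old_start)
    if (nrow(lo) == 0) next
    offsets <- c(0L, lo$offset)          # offsets[j + 1] applies after breakpoint j
    delta <- diff(offsets)               # each breakpoint's own length change
    if (direction == "to_edited") {
      j <- findInterval(pos[i], lo$old_start)
      mapped <- pos[i] + offsets[j + 1L]
      # positions inside a deleted span [old_start, old_start - delta - 1]
      # have no image in the edited frame
      jj <- pmax(j, 1L)
      bad <- j >= 1L & delta[jj] < 0L &
        pos[i] <= lo$old_start[jj] - delta[jj] - 1L
      mapped[bad] <- NA_integer_
      out[i] <- mapped
    } else {
      # first edited-frame position governed by breakpoint j:
      # insertions shift it by the full offset, deletions only by the prior one
      new_start <- lo$old_start + pmax(lo$offset, offsets[-length(offsets)])
      j <- findInterval(pos[i], new_start)
      out[i] <- pos[i] - offsets[j + 1L]
    }
  }
  out
}

#' Match re-detected variants to planted mutations
#'
#' A planted SNV is detected when a variant with the same reference/alternative
#' base change is found at the same locus. A planted indel is detected when a
#' variant of the *same type* (insertion/deletion) lies within
#' `indel_window` bp upstream of the planted anchor (positions in
#' `[pos - indel_window, pos]`) — indel placement is not always unique, so
#' exact-locus matching would undercount. Matching is injective: each
#' detected variant is consumed by at most one planted mutation, ties broken
#' to the nearest (largest) upstream position.
#'
#' Both tables must be in the same coordinate frame (lift the plan with
#' [lift_positions()] when the detections come from an edited reference).
#'
#' @param plan A [plan_insertions()] tibble (optionally lifted).
#' @param redetected A tibble of detected variants (`contig`, `pos`, `mtype`,
#'   `ref`, `alt`).
#' @param indel_window Upstream window in bp (default 5).
#' @return `plan` with a logical `detected` column appended.
#' @export
match_detected <- function(plan, redetected, indel_window = 5) {
  detected <- logical(nrow(plan))
  if (nrow(redetected)) {
    used <- logical(nrow(redetected))
    for (k in order(plan$contig, plan$pos)) {
      if (plan$mtype[k] == "SNV") {
        hit <- which(!used & redetected$mtype == "SNV" &
                       redetected$contig == plan$contig[k] &
                       redetected$pos == plan$pos[k] &
                       redetected$ref == plan$ref[k] &
                       redetected$alt == plan$alt[k])
      } else {
        hit <- which(!used & redetected$mtype == plan$mtype[k] &
                       redetected$contig == plan$contig[k] &
                       redetected$pos >= plan$pos[k] - indel_window &
                       redetected$pos <= plan$pos[k])
        if (length(hit) > 1) hit <- hit[which.max(redetected$pos[hit])]
      }
      if (length(hit) >= 1) {
        used[hit[1]] <- TRUE
        detected[k] <- TRUE
      }
    }
  }
  mutate(plan, detected = detected)
}

#' False-negative rate from a scored plan
#'
#' `FN = (covered & !detected) / covered`, per line and mutation type. A
#' planting is *covered* for a line when the line has more than five reads at
#' the planted anchor (the same rule as the callable mask); uncovered
#' plantings cannot be scored and are excluded from the denominator.
#'
#' @param scored A tibble with columns `line_id`, `mtype`, `covered`,
#'   `detected` (one row per planting per line), e.g. from [fn_benchmark()].
#' @return A tibble: `line_id`, `mtype`, `n_covered`, `n_missed`, `fn_rate`
#'   (`NaN` with zero covered plantings, reported undefined).
#' @export
fn_rate <- function(scored) {
  scored |>
    group_by(.data$line_id, .data$mtype) |>
    summarise(
      n_covered = sum(.data$covered),
      n_missed = sum(.data$covered & !.data$detected),
      .groups = "drop"
    ) |>
    mutate(fn_rate = .data$n_missed / .data$n_covered)
}

#' False-positive rate from an ancestral line
#'
#' Among loci carrying at least one alternative-homozygote call (optionally
#' restricted to a callable mask), the fraction carried *only* by the
#' ancestral line: the ancestor predates the accumulation experiment, so an
#' ancestral-only alternative homozygote cannot be a real accumulated
#' mutation and estimates the false-positive rate of the calling pipeline.
#'
#' @param geno A long genotype tibble including the ancestral line.
#' @param ancestral_line The ancestral line id.
#' @param group The [ma_group()] of descendant lines.
#' @param mask Optional [callable_mask()] restricting the eligible region.
#' @return A one-row tibble: `n_ancestral_only`, `n_alt_hom_loci`, `fp_rate`
#'   (`NaN` with a warning when no alt-homozygote loci exist).
#' @export
fp_rate_ancestral <- function(geno, ancestral_line, group, mask = NULL) {
  stopifnot(inherits(group, "ma_group"))
  lines <- c(group_lines(group), ancestral_line)
  geno <- filter(geno, .data$line_id %in% lines)
  if (!is.null(mask)) {
    keep <- in_mask(mask, geno$contig, geno$pos)
    geno <- geno[keep, , drop = FALSE]
  }
  loci <- geno |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      n_alt_hom = sum(.data$gclass == "alt_hom"),
      ancestral_only = sum(.data$gclass == "alt_hom") >= 1 &&
        all(.data$line_id[.data$gclass == "alt_hom"] == ancestral_line),
      .groups = "drop"
    ) |>
    filter(.data$n_alt_hom >= 1)
  if (nrow(loci) == 0) {
    warn("no alternative-homozygote loci: FP rate undefined")
    return(tibble(n_ancestral_only = 0L, n_alt_hom_loci = 0L, fp_rate = NaN))
  }
  tibble(
    n_ancestral_only = sum(loci$ancestral_only),
    n_alt_hom_loci = nrow(loci),
    fp_rate = sum(loci$ancestral_only) / nrow(loci)
  )
}

#' End-to-end false-negative benchmark on synthetic data
#'
#' Mirrors the computational FN estimation of an MA study at desk scale:
#' plant mutations into the *reference* copy of the founder genome
#' ([apply_insertions()]), re-emulate calling of every line against the
#' edited reference, and score re-detection per line with the literal
#' matching rules of [match_detected()]. Because the reference was edited,
#' each planted mutation appears in *every* line as the inverse variant
#' (a reference insertion reads as a sample deletion); the emulated calls
#' are translated back into the planted frame before matching so the
#' same-type rule applies coherently. Detection per line requires an
#' alternative-homozygote call passing the focal thresholds
#' (DP >= `thresholds$min_dp_focal`, GQ >= `thresholds$min_gq`); coverage
#' uses the callable depth rule (DP >= `thresholds$min_dp_support`).
#' Emulated indel anchors are jittered 0-3 bp upstream to exercise the
#' fuzzy indel matching, as real callers place ambiguous indels
#' inconsistently.
#'
#' @param genome The founder [genome_ref()].
#' @param plan A [plan_insertions()] tibble.
#' @param params A [sim_params()] (noise model and line count).
#' @param thresholds An [ma_thresholds()].
#' @return A list of class `ma_fn_benchmark`: `scored` (tibble `line_id` x
#'   plan columns with `covered`, `detected`), `fn` ([fn_rate()] table),
#'   `edited` (the [apply_insertions()] result).
#' @export
fn_benchmark <- function(genome, plan, params, thresholds = ma_thresholds()) {
  stopifnot(inherits(params, "sim_params"))
  edited <- apply_insertions(genome, plan)
  ids <- sim_line_ids(params)
  plan_lifted <- plan |>
    mutate(pos_edited = lift_positions(edited$liftover, .data$contig, .data$pos))

  scored <- withr::with_seed(params$seed + 3L, {
    purrr::map(ids, function(line) {
      n <- nrow(plan)
      dp <- rpois(n, params$coverage_mean)
      gq <- pmin(99L, pmax(0L, as.integer(round(rnorm(n, params$gq_mean, params$gq_sd)))))
      missing <- runif(n) < params$missing_rate
      called <- !missing & dp >= thresholds$min_dp_focal & gq >= thresholds$min_gq
      # emulated calls, already translated into the planted frame: same type
      # and alleles as planted, indel anchors jittered <= 3 bp upstream
      jitter <- ifelse(plan$mtype == "SNV", 0L, sample(0:3, n, replace = TRUE))
      calls <- plan_lifted[called, c("contig", "mtype", "ref", "alt")]
      calls$pos <- (plan_lifted$pos_edited - jitter)[called]
      m <- match_detected(
        plan_lifted |> mutate(pos = .data$pos_edited) |> select(-"pos_edited"),
        calls
      )
      tibble(
        line_id = line, contig = plan$contig, pos = plan$pos,
        mtype = plan$mtype, covered = dp >= thresholds$min_dp_support,
        detected = m$detected
      )
    }) |> bind_rows()
  })
  structure(
    list(scored = scored, fn = fn_rate(scored), edited = edited),
    class = "ma_fn_benchmark"
  )
}
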