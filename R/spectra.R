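#' Strand-collapsed six-class SNV classification
#'
#' Every single-base substitution is assigned to one of the six
#' strand-collapsed classes `A:T>T:A`, `A:T>C:G`, `A:T>G:C`, `G:C>A:T`,
#' `G:C>T:A`, `G:C>C:G`: a change and its reverse complement (e.g. `C>A` and
#' `G>T`) fall in the same class, so the 12 ordered base pairs map 2-to-1
#' onto the 6 classes.
#'
#' @param ref,alt Single reference/alternative bases (vectors recycled to a
#'   common length); `ref != alt` elementwise.
#' @return A factor with the six classes as levels.
#' @export
snv_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T"))) {
    abort("ref and alt must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  # collapse: represent A:T sites by ref A, G:C sites by ref G
  flip <- ref %in% c("T", "C")
  r <- ifelse(flip, DNA_COMPLEMENT[ref], ref)
  a <- ifelse(flip, DNA_COMPLEMENT[alt], alt)
  cls <- dplyr::case_when(
    r == "A" & a == "T" ~ "A:T>T:A",
    r == "A" & a == "C" ~ "A:T>C:G",
    r == "A" & a == "G" ~ "A:T>G:C",
    r == "G" & a == "A" ~ "G:C>A:T",
    r == "G" & a == "T" ~ "G:C>T:A",
    r == "G" & a == "C" ~ "G:C>C:G"
  )
  factor(cls, levels = SNV_CLASSES)
}

#' Is a substitution a transition?
#' @param ref,alt Single bases.
#' @return Logical vector: `TRUE` for A<->G and C<->T.
#' @export
is_transition <- function(ref, alt) {
  as.character(snv_class(ref, alt)) %in% c("A:T>G:C", "G:C>A:T")
}

#' Six-class SNV spectrum of a candidate set
#'
#' @param candidates A candidate tibble; only rows with `mtype == "SNV"`
#'   are used (tables without an `mtype` column are taken to be all-SNV).
#' @return A tibble of class `ma_spectrum` with columns `class` (all six,
#'   in fixed order), `n` and `fraction`.
#' @export
spectrum_table <- function(candidates) {
  snvs <- if ("mtype" %in% names(candidates)) {
    filter(candidates, .data$mtype == "SNV")
  } else {
    candidates
  }
  cls <- if (nrow(snvs)) snv_class(snvs$ref, snvs$alt) else factor(character(), levels = SNV_CLASSES)
  tab <- table(cls)
  out <- tibble(
    class = SNV_CLASSES,
    n = as.integer(tab[SNV_CLASSES]),
    fraction = if (sum(tab) > 0) as.integer(tab[SNV_CLASSES]) / sum(tab) else NA_real_
  )
  structure(out, class = c("ma_spectrum", class(out)))
}

#' Transition/transversion ratio
#'
#' @param candidates A candidate tibble (SNV rows used).
#' @return `transitions / transversions`; `NaN` with a warning when there are
#'   no transversions (undefined).
#' @export
ts_tv <- function(candidates) {
  snvs <- if ("mtype" %in% names(candidates)) {
    filter(candidates, .data$mtype == "SNV")
  } else {
    candidates
  }
  if (nrow(snvs) == 0) {
    warn("no SNVs: ts/tv undefined")
    return(NaN)
  }
  ts <- sum(is_transition(snvs$ref, snvs$alt))
  tv <- nrow(snvs) - ts
  if (tv == 0) {
    warn("no transversions: ts/tv undefined")
    return(NaN)
  }
  ts / tv
}

#' Composition-normalized AT bias
#'
#' The ratio of the per-G:C-site flux toward A:T over the per-A:T-site flux
#' toward G:C:
#' `[(G:C>A:T + G:C>T:A) / gc_count] / [(A:T>G:C + A:T>C:G) / at_count]`.
#' Values above 1 indicate that mutation pressure enriches the genome in
#' A:T pairs. This composition-normalized definition is this package's own;
#' published per-study "AT bias" columns may use a different normalization
#' and are not directly comparable.
#'
#' @param spectrum A [spectrum_table()] result (or tibble with `class`, `n`).
#' @param genome A [genome_ref()] with nonzero AT and GC counts.
#' @return A single number; `NaN` with a warning if a denominator class has
#'   zero counts.
#' @export
at_bias <- function(spectrum, genome) {
  stopifnot(inherits(genome, "genome_ref"))
  comp <- genome_composition(genome)
  tot <- comp[comp$contig == "total", ]
  if (tot$gc_count == 0 || tot$at_count == 0) {
    abort("genome AT and GC counts must both be positive")
  }
  get <- function(cl) sum(spectrum$n[spectrum$class %in% cl])
  gain_at <- get(c("G:C>A:T", "G:C>T:A"))
  gain_gc <- get(c("A:T>G:C", "A:T>C:G"))
  if (gain_gc == 0) {
    warn("no A:T>G:C/C:G mutations: AT bias undefined")
    return(NaN)
  }
  (gain_at / tot$gc_count) / (gain_gc / tot$at_count)
}

#' Triplet-context table of SNVs
#'
#' Counts SNVs by the strand-collapsed reference triplet around them and by
#' SNV class. Triplets are collapsed so that the representative has an `A` or
#' `C` center (a triplet with `T`/`G` center is reverse-complemented, along
#' with the substitution); e.g. a `T>A` change inside `TTA` and an `A>T`
#' change inside `TAA` land in the same cell (`TAA`, class `A:T>T:A`).
#' SNVs at contig edges (no flanking base on either side) are tallied in an
#' `edge` bucket and excluded from context totals.
#'
#' @param candidates A candidate tibble (SNV rows used).
#' @param genome A [genome_ref()].
#' @return A tibble of class `ma_context`: columns `context`, `class`, `n`;
#'   the `edge` bucket has `class = NA`.
#' @export
triplet_context <- function(candidates, genome) {
  stopifnot(inherits(genome, "genome_ref"))
  snvs <- if ("mtype" %in% names(candidates)) {
    filter(candidates, .data$mtype == "SNV")
  } else {
    candidates
  }
  if (nrow(snvs) == 0) {
    out <- tibble(context = character(), class = character(), n = integer())
    return(structure(out, class = c("ma_context", class(out))))
  }
  lens <- genome$composition$length[match(snvs$contig, genome$composition$contig)]
  edge <- snvs$pos <= 1 | snvs$pos >= lens
  inner <- snvs[!edge, , drop = FALSE]
  rows <- list()
  if (nrow(inner)) {
    trip <- genome_base(genome, inner$contig, inner$pos - 1L, width = 3L)
    if (any(substr(trip, 2, 2) != inner$ref)) {
      warn("reference base mismatch between candidates and genome at some SNVs")
    }
    cls <- as.character(snv_class(inner$ref, inner$alt))
    flip <- substr(trip, 2, 2) %in% c("T", "G")
    trip[flip] <- revcomp(trip[flip])
    rows[[1]] <- tibble(context = trip, class = cls) |>
      count(.data$context, .data$class)
  }
  if (any(edge)) {
    rows[[2]] <- tibble(context = "edge", class = NA_character_, n = sum(edge))
  }
  out <- bind_rows(rows) |> arrange(.data$context, .data$class)
  structure(out, class = c("ma_context", class(out)))
}

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Codon-level consequence classification
#'
#' SNVs inside a CDS are classified by translating the affected codon before
#' and after the substitution (`synonymous`, `missense`, `stop_gained`;
#' amino-acid changes that destroy a stop codon are folded into `missense`).
#' SNVs inside a gene but outside any CDS are `genic_noncoding`; SNVs outside
#' genes are `noncoding`. Indels overlapping a CDS are labelled
#' `coding_indel` without frameshift subtyping; genic indels outside CDS are
#' `genic_noncoding`. A mutation coding in *any* overlapping transcript
#' counts as coding. Genes whose spliced CDS length is not a multiple of 3
#' are skipped for codon translation with a warning (their mutations stay
#' genic).
#'
#' @param candidates A candidate tibble.
#' @param annotation A [read_gff()] result.
#' @param genome A [genome_ref()].
#' @return `candidates` with columns `consequence`, `coding` (logical:
#'   missense/synonymous/stop_gained/coding_indel), `genic` (logical)
#'   appended.
#' @export
classify_consequence <- function(candidates, annotation, genome) {
  stopifnot(inherits(annotation, "gene_annotation"), inherits(genome, "genome_ref"))
  if (nrow(candidates) == 0) {
    return(mutate(candidates, consequence = character(0),
                  coding = logical(0), genic = logical(0)))
  }
  loc <- locate_positions(select(as_tibble(candidates), "contig", "pos"), annotation)
  consequence <- ifelse(loc$genic, "genic_noncoding", "noncoding")

  in_cds <- which(loc$in_cds)
  for (i in in_cds) {
    if (candidates$mtype[i] != "SNV") {
      consequence[i] <- "coding_indel"
      next
    }
    cq <- snv_codon_consequence(
      annotation, genome,
      candidates$contig[i], candidates$pos[i],
      candidates$ref[i], candidates$alt[i]
    )
    consequence[i] <- cq %||% "genic_noncoding"
  }
  candidates |>
    mutate(
      consequence = consequence,
      coding = consequence %in% c("missense", "synonymous", "stop_gained", "coding_indel"),
      genic = loc$genic
    )
}

# consequence of one SNV against every CDS gene containing it; returns the
# "most severe" single label or NULL if no translatable gene covers it
snv_codon_consequence <- function(annotation, genome, contig, pos, ref, alt) {
  pt <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L))
  hit_cds <- annotation$cds[
    GenomicRanges::countOverlaps(annotation$cds, pt, ignore.strand = TRUE) > 0
  ]
  genes <- unique(S4Vectors::mcols(hit_cds)$gene_id)
  genes <- genes[!is.na(genes)]
  if (length(genes) == 0) {
    # orphan CDS: treat the single segment as a frame-0 ORF
    genes <- NA
  }
  labels <- character()
  for (g in genes) {
    segs <- if (is.na(g)) hit_cds else {
      annotation$cds[!is.na(S4Vectors::mcols(annotation$cds)$gene_id) &
                       S4Vectors::mcols(annotation$cds)$gene_id == g]
    }
    segs <- GenomicRanges::sort(segs)
    strand <- as.character(GenomicRanges::strand(segs))[1]
    seg_tbl <- tibble(
      start = GenomicRanges::start(segs), end = GenomicRanges::end(segs)
    )
    cds_len <- sum(seg_tbl$end - seg_tbl$start + 1)
    if (cds_len %% 3 != 0) {
      warn(sprintf("CDS length of gene '%s' not a multiple of 3; skipped for codon consequence", g))
      next
    }
    # spliced CDS sequence and the offset of the mutated base within it
    pieces <- genome_base(genome, rep(contig, nrow(seg_tbl)), seg_tbl$start,
                          width = seg_tbl$end - seg_tbl$start + 1L)
    cds_seq <- paste(pieces, collapse = "")
    off_fwd <- 0L
    offset <- NA_integer_
    for (k in seq_len(nrow(seg_tbl))) {
      if (pos >= seg_tbl$start[k] && pos <= seg_tbl$end[k]) {
        offset <- off_fwd + (pos - seg_tbl$start[k]) + 1L
        break
      }
      off_fwd <- off_fwd + (seg_tbl$end[k] - seg_tbl$start[k] + 1L)
    }
    if (is.na(offset)) next
    ref_b <- ref; alt_b <- alt
    if (strand == "-") {
      cds_seq <- revcomp(cds_seq)
      offset <- cds_len - offset + 1L
      ref_b <- unname(DNA_COMPLEMENT[ref]); alt_b <- unname(DNA_COMPLEMENT[alt])
    }
    if (substr(cds_seq, offset, offset) != ref_b) next  # annotation/sequence mismatch
    codon_i <- (offset - 1L) %/% 3L
    codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    within <- (offset - 1L) %% 3L + 1L
    codon_alt <- codon
    substr(codon_alt, within, within) <- alt_b
    aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
    aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(codon_alt)))
    labels <- c(labels, if (aa_ref == aa_alt) {
      "synonymous"
    } else if (aa_alt == "*") {
      "stop_gained"
    } else {
      "missense"
    })
  }
  if (length(labels) == 0) return(NULL)
  for (sev in c("stop_gained", "missense", "synonymous")) {
    if (sev %in% labels) return(sev)
  }
  labels[1]
}

#' Indel length histogram and means
#'
#' @param candidates A candidate tibble.
#' @return A tibble of class `ma_indel_lengths` with columns `mtype`,
#'   `length` (absolute bp) and `n`; attribute `means` is a named numeric
#'   vector with the mean absolute length per type (`NaN` where a type is
#'   absent, reported undefined).
#' @export
indel_lengths <- function(candidates) {
  il <- filter(as_tibble(candidates), .data$mtype %in% c("insertion", "deletion"))
  out <- il |>
    mutate(length = abs(.data$length_delta)) |>
    count(.data$mtype, .data$length) |>
    arrange(.data$mtype, .data$length)
  means <- c(
    insertion = mean(abs(il$length_delta[il$mtype == "insertion"])),
    deletion = mean(abs(il$length_delta[il$mtype == "deletion"]))
  )
  structure(out, class = c("ma_indel_lengths", class(out)), means = means)
}
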