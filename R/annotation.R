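#' Read gene annotation from GFF3
#'
#' Loads `gene` and `CDS` features from a GFF3 file into interval sets
#' queryable by point position. CDS features without a resolvable parent gene
#' are kept as orphan CDS with a warning (they still count as coding sequence).
#'
#' @param gff_path Path to a GFF3 file with `gene` and `CDS` features.
#' @return An object of class `gene_annotation`: a list with `genes` and `cds`
#'   ([GenomicRanges::GRanges]); `cds` carries a `gene_id` metadata column.
#' @export
read_gff <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  genes <- gr[tolower(as.character(gr$type)) == "gene"]
  cds <- gr[toupper(as.character(gr$type)) == "CDS"]
  gene_ids <- as.character(genes$ID %||% rep(NA_character_, length(genes)))
  if (length(genes) && anyNA(gene_ids)) {
    gene_ids[is.na(gene_ids)] <- paste0("gene", which(is.na(gene_ids)))
  }
  names(genes) <- gene_ids

  # resolve each CDS to a gene: Parent attribute (possibly via an mRNA), else
  # containment, else orphan
  parent <- rep(NA_character_, length(cds))
  if (length(cds) && !is.null(cds$Parent)) {
    p <- vapply(as.list(cds$Parent), function(v) {
      if (length(v)) as.character(v[[1]]) else NA_character_
    }, character(1))
    mrna <- gr[tolower(as.character(gr$type)) %in% c("mrna", "transcript")]
    if (length(mrna)) {
      mrna_parent <- vapply(as.list(mrna$Parent), function(v) {
        if (length(v)) as.character(v[[1]]) else NA_character_
      }, character(1))
      names(mrna_parent) <- as.character(mrna$ID)
      via <- p %in% names(mrna_parent)
      p[via] <- mrna_parent[p[via]]
    }
    parent <- ifelse(p %in% gene_ids, p, NA_character_)
  }
  if (length(cds) && anyNA(parent)) {
    hit <- GenomicRanges::findOverlaps(cds, genes, type = "within", select = "first")
    fill <- is.na(parent) & !is.na(hit)
    parent[fill] <- gene_ids[hit[fill]]
    if (anyNA(parent)) {
      warn(sprintf("%d CDS feature(s) without a parent gene kept as orphans",
                   sum(is.na(parent))))
    }
  }
  S4Vectors::mcols(cds)$gene_id <- parent
  structure(list(genes = genes, cds = cds), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d gene(s), %d CDS segment(s)\n",
              length(x$genes), length(x$cds)))
  invisible(x)
}

#' Classify positions as genic/intergenic and coding/noncoding by location
#'
#' A position is *genic* if it falls inside any gene extent (either strand;
#' overlapping genes count once) and *in a coding region* if it falls inside
#' any CDS interval. This is purely positional; codon-level consequences are
#' computed by [classify_consequence()].
#'
#' @param positions A data frame with columns `contig` and `pos` (1-based).
#' @param annotation A [read_gff()] result.
#' @return `positions` with logical columns `genic` and `in_cds` appended.
#' @export
locate_positions <- function(positions, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (nrow(positions) == 0) {
    return(mutate(positions, genic = logical(0), in_cds = logical(0)))
  }
  pts <- GenomicRanges::GRanges(
    positions$contig, IRanges::IRanges(positions$pos, width = 1L)
  )
  positions |>
    mutate(
      genic = GenomicRanges::countOverlaps(pts, annotation$genes, ignore.strand = TRUE) > 0,
      in_cds = GenomicRanges::countOverlaps(pts, annotation$cds, ignore.strand = TRUE) > 0
    )
}

#' Write a toy gene annotation for a synthetic genome
#'
#' Places `n_genes` non-overlapping genes (one CDS each, CDS length a multiple
#' of 3, random strand) covering approximately `genic_fraction` of the genome,
#' and writes them as GFF3. Used to exercise genic/coding classification on
#' synthetic data.
#'
#' @param genome A [genome_ref()].
#' @param n_genes Number of genes to place.
#' @param seed Integer seed; placement is reproducible.
#' @param out_path Output GFF3 path.
#' @param genic_fraction Target fraction of the genome covered by genes.
#' @return `out_path`, invisibly.
#' @export
write_toy_annotation <- function(genome, n_genes, seed, out_path,
                                 genic_fraction = 0.3) {
  stopifnot(inherits(genome, "genome_ref"), is_count(n_genes))
  comp <- genome$composition
  withr::with_seed(seed, {
    rows <- list()
    if (n_genes > 0) {
      # apportion genes to contigs by length
      alloc <- table(factor(
        sample(comp$contig, n_genes, replace = TRUE, prob = comp$length),
        levels = comp$contig
      ))
      for (ct in comp$contig) {
        k <- alloc[[ct]]
        if (k == 0) next
        clen <- comp$length[comp$contig == ct]
        glen <- max(30L, floor(clen * genic_fraction / k))
        # partition the contig into k equal slots, one gene per slot
        slot <- floor(clen / k)
        glen <- min(glen, slot - 2L)
        glen <- glen - (glen %% 3L)  # keep CDS frame-compatible
        if (glen < 30L) next
        for (i in seq_len(k)) {
          lo <- (i - 1L) * slot + 1L
          start <- lo + sample.int(max(1L, slot - glen - 1L), 1L) - 1L
          end <- start + glen - 1L
          # CDS occupies the central part of the gene, frame 0, length %% 3 == 0
          pad <- min(15L, floor((glen - 9L) / 6L) * 3L)
          rows[[length(rows) + 1L]] <- tibble(
            contig = ct, start = start, end = end,
            cds_start = start + pad, cds_end = end - pad,
            strand = sample(c("+", "-"), 1L)
          )
        }
      }
    }
    genes <- bind_rows(rows)
  })
  if (nrow(genes) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    genes <- genes |> mutate(id = sprintf("g%03d", row_number()))
    gene_gr <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand, type = "gene", ID = genes$id,
      Parent = methods::as(rep(list(character(0)), nrow(genes)), "CharacterList"),
      phase = NA_integer_
    )
    cds_gr <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(genes$cds_start, genes$cds_end),
      strand = genes$strand, type = "CDS",
      ID = paste0(genes$id, ".cds"),
      Parent = methods::as(as.list(genes$id), "CharacterList"),
      phase = 0L
    )
    gr <- c(gene_gr, cds_gr)
  }
  rtracklayer::export(gr, out_path, format = "gff3")
  invisible(out_path)
}
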