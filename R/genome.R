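#' Reference genome container
#'
#' A `genome_ref` bundles the contig sequences (uppercase `A`/`C`/`G`/`T`/`N`)
#' with per-contig and genome-wide base-composition tallies. It is the
#' coordinate authority for every position handled by the package: mutation
#' positions are 1-based and inclusive, as in VCF and GFF3.
#'
#' @param seqs A named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet]. Lowercase letters are normalized to uppercase.
#' @return An object of class `genome_ref`: a list with elements `seq`
#'   (a `DNAStringSet`) and `composition` (a tibble with one row per contig and
#'   columns `contig`, `length`, `a`, `c`, `g`, `t`, `n`, `gc_count`,
#'   `at_count`).
#' @examples
#' g <- genome_ref(c(chrI = "ACGTACGT", chrII = "TTTTAAAA"))
#' genome_composition(g)
#' @export
genome_ref <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      abort("all contigs must be named")
    }
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (!methods::is(seqs, "DNAStringSet")) {
    abort("`seqs` must be a named character vector or a DNAStringSet")
  }
  if (anyDuplicated(names(seqs))) {
    abort(paste0(
      "duplicate contig name(s): ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")
    ))
  }
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(bad > 0)) {
    # IUPAC ambiguity codes other than N are not expected in an assembly here
    abort("contig sequences may only contain A, C, G, T or N")
  }
  comp <- tibble(
    contig = names(seqs),
    length = Biostrings::width(seqs),
    a = unname(freq[, "A"]), c = unname(freq[, "C"]),
    g = unname(freq[, "G"]), t = unname(freq[, "T"]),
    n = unname(freq[, "N"])
  ) |>
    mutate(gc_count = .data$g + .data$c, at_count = .data$a + .data$t)
  structure(list(seq = seqs, composition = comp), class = "genome_ref")
}

#' Read a reference genome from FASTA
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [genome_ref()] object.
#' @export
read_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions; the contig name is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_ref(Biostrings::DNAStringSet(toupper(seqs)))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_ref()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_ref"))
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Per-contig and genome-wide base composition
#'
#' @param genome A [genome_ref()].
#' @return A tibble with one row per contig plus a final `total` row.
#' @export
genome_composition <- function(genome) {
  stopifnot(inherits(genome, "genome_ref"))
  comp <- genome$composition
  total <- comp |>
    summarise(across(c("length", "a", "c", "g", "t", "n", "gc_count", "at_count"), sum)) |>
    mutate(contig = "total", .before = 1)
  bind_rows(comp, total)
}

#' Total genome length in bp
#' @param genome A [genome_ref()].
#' @return Integer length.
#' @export
genome_length <- function(genome) {
  sum(genome$composition$length)
}

#' @export
print.genome_ref <- function(x, ...) {
  comp <- genome_composition(x)
  tot <- comp[comp$contig == "total", ]
  cat(sprintf(
    "<genome_ref> %d contig(s), %s bp, GC %.1f%%\n",
    nrow(x$composition), format(tot$length, big.mark = ","),
    100 * tot$gc_count / max(1, tot$gc_count + tot$at_count)
  ))
  invisible(x)
}

# substring of length width[i] starting at (contig[i], pos[i]); "" out of range
genome_base <- function(genome, contig, pos, width = 1L) {
  w <- rep_len(as.integer(width), length(contig))
  out <- character(length(contig))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    s <- genome$seq[[ct]]
    ok <- pos[i] >= 1 & (pos[i] + w[i] - 1L) <= length(s)
    j <- i[ok]
    if (length(j)) {
      out[j] <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(start = pos[j], width = w[j])
      ))
    }
  }
  out
}
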