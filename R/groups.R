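#' Define an MA-line group
#'
#' An MA group is a set of lines propagated under one condition (strain x
#' diet), carrying the number of single-individual transfer generations used
#' in the rate denominator. Lines flagged in `excluded` (e.g. after
#' cross-contamination screening with [flag_contaminated()]) are dropped from
#' every filtering criterion and every rate denominator.
#'
#' @param name Group label, e.g. `"RSC019_OP50"`.
#' @param lines Character vector of line (sample) identifiers, at least 2.
#' @param generations Positive integer: generations of propagation (e.g. 100).
#' @param excluded Character vector of line ids to exclude from analysis.
#' @return An object of class `ma_group`.
#' @examples
#' g <- ma_group("toy", paste0("L", 1:12), generations = 100)
#' group_lines(g)
#' @export
ma_group <- function(name, lines, generations, excluded = character()) {
  stopifnot(is.character(name), length(name) == 1)
  lines <- as.character(lines)
  if (length(lines) < 2) abort("a group needs at least 2 lines")
  if (anyDuplicated(lines)) abort("duplicate line ids in group")
  if (!is_count(generations) || generations < 1) {
    abort("`generations` must be a positive integer")
  }
  excluded <- as.character(excluded)
  if (!all(excluded %in% lines)) {
    abort("`excluded` must be a subset of `lines`")
  }
  structure(
    list(name = name, lines = lines, generations = as.integer(generations),
         excluded = excluded),
    class = "ma_group"
  )
}

#' Active (non-excluded) lines of a group
#' @param group An [ma_group()].
#' @return Character vector of line ids.
#' @export
group_lines <- function(group) {
  stopifnot(inherits(group, "ma_group"))
  setdiff(group$lines, group$excluded)
}

#' @export
print.ma_group <- function(x, ...) {
  cat(sprintf("<ma_group> %s: %d line(s) (%d excluded), %d generations\n",
              x$name, length(x$lines), length(x$excluded), x$generations))
  invisible(x)
}

#' Detection thresholds for accumulated-mutation filtering
#'
#' Defaults are the criteria used throughout: the focal alternative homozygote
#' needs no less than five supporting reads (`min_dp_focal = 5`, DP >= 5) and
#' genotype quality larger than 20 (`min_gq = 21`, i.e. GQ > 20); at least 10
#' lines (`min_support_lines`) must be reference-homozygous with more than
#' five reads (`min_dp_support = 6`, i.e. DP > 5); and linked same-line
#' candidates within `link_window` bp are removed. The >=5 / >5 asymmetry
#' between the focal and supporting depth thresholds is deliberate.
#'
#' @param min_dp_focal Minimum DP (inclusive) of the focal alt-homozygote.
#' @param min_dp_support Minimum DP (inclusive) of supporting ref-homozygotes;
#'   the default 6 encodes "more than five reads".
#' @param min_support_lines Minimum number of qualifying ref-homozygous lines.
#' @param min_gq Minimum GQ (inclusive) of the focal call; 21 encodes "> 20".
#' @param link_window Linkage window in bp for [remove_linked()].
#' @return A list of class `ma_thresholds`.
#' @export
ma_thresholds <- function(min_dp_focal = 5, min_dp_support = 6,
                          min_support_lines = 10, min_gq = 21,
                          link_window = 100) {
  vals <- list(
    min_dp_focal = min_dp_focal, min_dp_support = min_dp_support,
    min_support_lines = min_support_lines, min_gq = min_gq,
    link_window = link_window
  )
  for (nm in names(vals)) {
    if (!is_count(vals[[nm]])) abort(sprintf("`%s` must be a single non-negative integer", nm))
    vals[[nm]] <- as.integer(vals[[nm]])
  }
  structure(vals, class = "ma_thresholds")
}

#' @export
print.ma_thresholds <- function(x, ...) {
  cat("<ma_thresholds>",
      sprintf("focal DP >= %d, support DP >= %d in >= %d lines, GQ >= %d, link window %d bp\n",
              x$min_dp_focal, x$min_dp_support, x$min_support_lines,
              x$min_gq, x$link_window))
  invisible(x)
}
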