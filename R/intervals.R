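#' Construct a tibble of genomic intervals
#'
#' Intervals are represented throughout the package as plain tibbles with
#' columns `chrom`, `start`, `end` and `strand`, using 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive) on every surface. Extra
#' columns (peak names, scores, narrowPeak fields) are carried along untouched.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `end > start`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @param ... Further columns to carry (recycled by [tibble::tibble()]).
#'
#' @return A tibble with at least columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", c(0, 100), c(50, 200))
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    ...
  )
  validate_intervals(out)
}

validate_intervals <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop(what, " lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"strand" %in% names(x)) x$strand <- "*"
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    stop(what, ": invalid records (need chrom non-empty, 0 <= start < end) at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_strand <- which(!x$strand %in% c("+", "-", "*"))
  if (length(bad_strand) > 0) {
    stop(what, ": strand must be one of '+', '-', '*' (rows ",
         paste(utils::head(bad_strand, 5), collapse = ", "), ")", call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' @keywords internal
#' @noRd
as_granges <- function(x) {
  x <- validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
}

#' @keywords internal
#' @noRd
granges_to_tibble <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", "*", s)
    }
  )
}

#' Symmetric promoter window around a TSS
#'
#' Returns the `[max(0, tss - flank), tss + flank)` window for each gene.
#' Windows are strand-agnostic: the interval is symmetric around the TSS
#' regardless of gene orientation, and is clipped at position 0.
#'
#' @param genes A gene-model tibble with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (0-based), e.g. from [read_gene_models()].
#' @param flank Window half-width in bp; must be positive. 1000 gives the
#'   promoter definition used for peak annotation; 5000 the wider window used
#'   for DMR-to-gene mapping.
#'
#' @return An interval tibble with one row per gene and a `gene_id` column.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000L)
#' promoter_window(g, flank = 1000)
#' @export
promoter_window <- function(genes, flank = 1000) {
  if (!is.numeric(flank) || length(flank) != 1 || !is.finite(flank) || flank <= 0) {
    stop("`flank` must be a single positive number", call. = FALSE)
  }
  validate_gene_models(genes)
  flank <- as.integer(flank)
  tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - flank),
    end = genes$tss + flank,
    strand = "*",
    gene_id = genes$gene_id
  )
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene models lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(genes$tss) || any(genes$tss < 0)) {
    stop("gene models: tss must be >= 0 and non-missing", call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene models: gene_id values must be unique", call. = FALSE)
  }
  invisible(genes)
}

#' Coverage-level intersection of two interval sets
#'
#' Returns the maximal intervals covered by at least one interval of each set,
#' with half-open semantics: intervals that merely touch (`end == start`) do
#' not overlap. The operation is commutative and its output is disjoint and
#' sorted.
#'
#' @param set_a,set_b Interval tibbles.
#' @return A disjoint, sorted interval tibble (unstranded).
#' @examples
#' a <- genomic_intervals("chr1", 0, 10)
#' b <- genomic_intervals("chr1", 5, 15)
#' interval_intersect(a, b)
#' @export
interval_intersect <- function(set_a, set_b) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    return(genomic_intervals(character(), integer(), integer())[0, ])
  }
  ga <- GenomicRanges::reduce(as_granges(set_a), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(as_granges(set_b), ignore.strand = TRUE)
  out <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  dplyr::arrange(granges_to_tibble(out), .data$chrom, .data$start)
}

#' Merge intervals into their coverage union (single-linkage merge)
#'
#' Overlapping or touching intervals (contiguous base coverage) collapse into
#' one maximal interval; `min_gap` additionally bridges gaps of up to
#' `min_gap` uncovered bases.
#'
#' @param x Interval tibble.
#' @param min_gap Maximum uncovered gap in bases to bridge (default 0:
#'   merge exactly the contiguous coverage runs).
#' @return A disjoint, sorted interval tibble.
#' @export
interval_merge <- function(x, min_gap = 0) {
  if (nrow(x) == 0) return(genomic_intervals(character(), integer(), integer())[0, ])
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = min_gap + 1L,
                              ignore.strand = TRUE)
  dplyr::arrange(granges_to_tibble(gr), .data$chrom, .data$start)
}

#' Pairs of overlapping intervals between two sets
#'
#' Half-open overlap: intervals sharing only a boundary base do not overlap.
#'
#' @param query,subject Interval tibbles.
#' @return A tibble with columns `query` and `subject` holding row indices into
#'   the two inputs, one row per overlapping pair.
#' @export
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      ignore.strand = TRUE)
  tibble::tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

#' Normalize chromosome names by adding or stripping a "chr" prefix
#'
#' Chromosome matching everywhere in the package is exact string matching;
#' this helper is provided for explicit harmonisation, never applied
#' implicitly.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"chr"` to ensure the prefix, `"plain"` to strip it.
#' @return Character vector.
#' @export
normalize_chrom_names <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  plain <- sub("^chr", "", chrom)
  if (style == "plain") plain else paste0("chr", plain)
}
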