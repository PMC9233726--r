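#' Sample design for an ordered-passage experiment
#'
#' The design table is the backbone of all trajectory logic: samples are laid
#' out over ordered timepoints (passages), replicates, and — for methylation —
#' independent series, each series contributing one sample per timepoint.
#'
#' @param sample_id Unique sample identifiers.
#' @param timepoint Timepoint label per sample; ordering is taken from
#'   `timepoint_labels`.
#' @param replicate Replicate index within timepoint.
#' @param series Series identifier (used for DMS calling); defaults to the
#'   replicate index.
#' @param timepoint_labels Ordered vector of timepoint labels, e.g.
#'   `c("P1","P3","P5","P7")`; defaults to order of first appearance.
#'
#' @return A tibble of class `sample_design` with columns `sample_id`,
#'   `timepoint` (ordered factor), `t_index` (0-based), `replicate`, `series`.
#' @examples
#' sample_design(paste0("s", 1:8), rep(c("P1", "P3"), each = 4), rep(1:4, 2))
#' @export
sample_design <- function(sample_id, timepoint, replicate,
                          series = replicate, timepoint_labels = NULL) {
  if (is.null(timepoint_labels)) timepoint_labels <- unique(as.character(timepoint))
  if (length(timepoint_labels) < 2) {
    stop("a sample design needs at least 2 timepoints", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) stop("sample_id must be unique", call. = FALSE)
  tp <- factor(as.character(timepoint), levels = timepoint_labels, ordered = TRUE)
  if (anyNA(tp)) stop("timepoint values not in timepoint_labels", call. = FALSE)
  if (!all(timepoint_labels %in% tp)) {
    stop("every timepoint label needs at least one sample", call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    timepoint = tp,
    t_index = as.integer(tp) - 1L,
    replicate = as.integer(replicate),
    series = as.character(series)
  )
  class(out) <- c("sample_design", class(out))
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Sample design:", nrow(x), "samples,",
      nlevels(x$timepoint), "timepoints (",
      paste(levels(x$timepoint), collapse = " < "), ")\n")
  NextMethod()
}

#' Read a sample design table
#'
#' Expects a TSV with columns `sample_id`, `timepoint`, `replicate` and
#' optionally `series`; timepoint order is the order of first appearance
#' unless `timepoint_labels` is given.
#'
#' @param path File path.
#' @inheritParams sample_design
#' @return A `sample_design` tibble.
#' @export
read_design <- function(path, timepoint_labels = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  series <- if ("series" %in% names(d)) d$series else d$replicate
  sample_design(d$sample_id, d$timepoint, d$replicate, series,
                timepoint_labels = timepoint_labels)
}

report_bad_lines <- function(bad, path, why) {
  stop(sprintf("%s: %s at line(s) %s", path, why,
               paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
}

#' Read intervals from BED / narrowPeak files
#'
#' Handles BED3, BED6 and narrowPeak. BED coordinates are already 0-based
#' half-open and are taken as-is. Columns beyond the sixth are preserved as
#' opaque character columns `extra1`, `extra2`, ... Records violating the
#' interval invariants (end <= start, negative start) are rejected with their
#' line numbers.
#'
#' @param path File path (plain text, tab- or space-separated).
#' @return An interval tibble; BED name/score columns become `name` and
#'   `score` when present.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(genomic_intervals(character(), integer(), integer())[0, ])
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) report_bad_lines(lineno[nf < 3], path, "fewer than 3 BED fields")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad)) report_bad_lines(lineno[bad], path, "invalid coordinates (need 0 <= start < end)")
  out <- tibble::tibble(chrom = chrom, start = start, end = end, strand = "*")
  maxf <- max(nf)
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  if (maxf >= 4) out$name <- get_col(4)
  if (maxf >= 5) out$score <- suppressWarnings(as.numeric(get_col(5)))
  if (maxf >= 6) {
    s <- get_col(6)
    s[!s %in% c("+", "-")] <- "*"
    out$strand <- s
  }
  if (maxf >= 7) {
    for (i in 7:maxf) out[[paste0("extra", i - 6)]] <- get_col(i)
  }
  validate_intervals(out, what = path)
}

#' Write intervals as BED
#'
#' Writes BED3 or BED6 (when `name`/`score`/`strand` carry information), plus
#' any `extra*` columns, tab-separated and without header. Round-trips with
#' [read_bed()].
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  extras <- grep("^extra[0-9]+$", names(x), value = TRUE)
  has_name <- "name" %in% names(x)
  has_score <- "score" %in% names(x)
  has6 <- has_name || has_score || any(x$strand != "*") || length(extras) > 0
  if (has6) {
    cols <- c(cols, list(
      if (has_name) x$name else ".",
      if (has_score) x$score else 0,
      ifelse(x$strand %in% c("+", "-"), x$strand, ".")
    ))
    for (e in extras) cols <- c(cols, list(x[[e]]))
  }
  readr::write_tsv(as.data.frame(cols, col.names = paste0("V", seq_along(cols))),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Reads a TSV with header columns `gene_id`, `chrom`, `strand`, `tss` (TSS
#' 0-based). With `format = "gtf"`, reads the gene lines of a GTF subset and
#' derives the 0-based TSS from the strand (1-based `start` for `+` genes,
#' `end` for `-` genes).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    g <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(tss = readr::col_integer()))
    g <- tibble::tibble(gene_id = as.character(g$gene_id), chrom = g$chrom,
                        strand = g$strand, tss = g$tss)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t")
    keep <- vapply(fields, function(f) length(f) >= 9 && f[[3]] == "gene", TRUE)
    fields <- fields[keep]
    if (length(fields) == 0) stop(path, ": no gene lines found", call. = FALSE)
    ids <- vapply(fields, function(f) {
      m <- regmatches(f[[9]], regexec('gene_id[ =]+"?([^";]+)"?', f[[9]]))[[1]]
      if (length(m) < 2) NA_character_ else m[[2]]
    }, "")
    if (anyNA(ids)) stop(path, ": gene line without gene_id attribute", call. = FALSE)
    strand <- vapply(fields, `[[`, "", 7)
    start1 <- as.integer(vapply(fields, `[[`, "", 4))
    end1 <- as.integer(vapply(fields, `[[`, "", 5))
    g <- tibble::tibble(
      gene_id = ids,
      chrom = vapply(fields, `[[`, "", 1),
      strand = strand,
      tss = ifelse(strand == "-", end1 - 1L, start1 - 1L)
    )
  }
  if (!all(g$strand %in% c("+", "-"))) {
    stop(path, ": gene strand must be '+' or '-'", call. = FALSE)
  }
  validate_gene_models(g)
  g
}

#' Read a bedGraph coverage track
#'
#' Returns a coverage track: an interval tibble with a `value` column and a
#' `strand_tag` attribute. Values must be non-negative.
#'
#' @param path bedGraph file path.
#' @param strand_tag Optional `"+"`/`"-"` tag describing which strand the
#'   track covers.
#' @return A tibble of class `coverage_track` with columns `chrom`, `start`,
#'   `end`, `value`.
#' @export
read_coverage <- function(path, strand_tag = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4)) report_bad_lines(lineno[nf < 4], path, "fewer than 4 bedGraph fields")
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  )
  bad <- is.na(out$start) | is.na(out$end) | out$start < 0 | out$end <= out$start |
    is.na(out$value) | out$value < 0
  if (any(bad)) report_bad_lines(lineno[bad], path, "invalid bedGraph record (coordinates or negative value)")
  coverage_track(out, strand_tag = strand_tag)
}

#' Construct a coverage track from an interval-value tibble
#'
#' @param x Tibble with `chrom`, `start`, `end`, `value` (run-length encoded
#'   per-base signal; uncovered positions are 0).
#' @param strand_tag Optional strand tag.
#' @return A `coverage_track` tibble.
#' @export
coverage_track <- function(x, strand_tag = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  if (any(x$value < 0)) stop("coverage values must be >= 0", call. = FALSE)
  x <- tibble::as_tibble(x[c("chrom", "start", "end", "value")])
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  attr(x, "strand_tag") <- strand_tag
  class(x) <- c("coverage_track", class(x))
  x
}

#' Write a coverage track as bedGraph
#' @param x A `coverage_track` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(x, path) {
  readr::write_tsv(as.data.frame(x)[c("chrom", "start", "end", "value")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Extract per-base coverage over a window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome.
#' @param start,end Half-open window; must lie within the track's extent
#'   (positions beyond the last record read as 0 up to `chrom_length`).
#' @param chrom_length Optional known chromosome length for bounds checking.
#' @return Numeric vector of length `end - start`.
#' @export
coverage_slice <- function(track, chrom, start, end, chrom_length = NULL) {
  stopifnot(end > start, start >= 0)
  if (!is.null(chrom_length) && end > chrom_length) {
    stop("window exceeds chromosome length", call. = FALSE)
  }
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ]
  out <- numeric(end - start)
  if (nrow(seg) > 0) {
    for (i in seq_len(nrow(seg))) {
      a <- max(seg$start[i], start) - start + 1L
      b <- min(seg$end[i], end) - start
      out[a:b] <- seg$value[i]
    }
  }
  out
}

#' Read a feature-by-sample counts table
#'
#' TSV with a header; first column holds feature identifiers, remaining
#' columns one sample each. Negative entries are rejected.
#'
#' @param path File path.
#' @return A tibble with `feature_id` plus one numeric column per sample.
#' @export
read_counts_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  names(d)[1] <- "feature_id"
  d$feature_id <- as.character(d$feature_id)
  vals <- as.matrix(d[-1])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0)) {
    stop(path, ": counts must be numeric and non-negative", call. = FALSE)
  }
  if (anyDuplicated(d$feature_id)) stop(path, ": duplicated feature ids", call. = FALSE)
  tibble::as_tibble(d)
}

#' Write a feature-by-sample table
#' @param x Tibble with `feature_id` plus sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read per-cytosine methylation calls
#'
#' TSV with header columns `chrom`, `pos` (0-based), `sample_id`,
#' `methylated`, `total`. Records with `methylated > total`, `total < 1` or
#' negative counts are rejected with line numbers.
#'
#' @param path File path.
#' @return A tibble of calls with a `level` column (`methylated / total`).
#' @export
read_methyl_calls <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         sample_id = readr::col_character(),
                         methylated = readr::col_integer(),
                         total = readr::col_integer()
                       ))
  bad <- which(is.na(d$pos) | d$pos < 0 | is.na(d$methylated) | is.na(d$total) |
                 d$methylated < 0 | d$total < 1 | d$methylated > d$total)
  if (length(bad) > 0) {
    # +1 for the header line
    report_bad_lines(bad + 1L, path, "invalid methylation call (need 0 <= methylated <= total, total >= 1)")
  }
  d$level <- d$methylated / d$total
  tibble::as_tibble(d)
}
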