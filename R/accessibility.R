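#' Build a consensus peak atlas with a replicate-presence rule
#'
#' Candidate consensus regions are the single-linkage merged union of all
#' per-sample peaks. A region is retained when, in at least one timepoint
#' group, the fraction of that group's samples having an overlapping peak is
#' strictly greater than `min_fraction` — so with the default 0.6, 3 of 4
#' replicates (0.75) or 2 of 3 (0.667) retain a region, while 3 of 5 (0.60)
#' does not. The result is invariant to sample order, and the retained set
#' can only shrink as `min_fraction` rises.
#'
#' @param peaks Either a tibble of intervals with a `sample_id` column, or a
#'   named list of interval tibbles (one per sample, possibly 0-row). Every
#'   design sample must appear (with an empty set if it has no peaks).
#' @param design A [sample_design()].
#' @param min_fraction Strict group-presence threshold in (0, 1); default 0.6.
#' @return An object of class `peak_atlas`: list with `peaks` (interval
#'   tibble with `peak_id`), `presence` (logical peaks-by-samples matrix),
#'   `design`, `min_fraction`.
#' @export
build_atlas <- function(peaks, design, min_fraction = 0.6) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction >= 1) {
    stop("`min_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  peaks <- stack_sample_peaks(peaks, design)
  all_pk <- peaks[peaks$sample_id %in% design$sample_id, ]
  if (nrow(all_pk) == 0) {
    consensus <- genomic_intervals(character(), integer(), integer())[0, ]
  } else {
    consensus <- interval_merge(all_pk)
  }
  presence <- presence_matrix(consensus, peaks, design)
  frac <- group_presence_fraction(presence, design)
  keep <- if (nrow(consensus) == 0) logical(0) else
    apply(frac, 1, function(f) any(f > min_fraction))
  consensus <- consensus[keep, , drop = FALSE]
  presence <- presence[keep, , drop = FALSE]
  consensus$peak_id <- if (nrow(consensus) > 0) {
    sprintf("peak_%05d", seq_len(nrow(consensus)))
  } else character(0)
  rownames(presence) <- consensus$peak_id
  structure(
    list(peaks = tibble::as_tibble(consensus), presence = presence,
         design = design, min_fraction = min_fraction),
    class = "peak_atlas"
  )
}

stack_sample_peaks <- function(peaks, design) {
  if (is.data.frame(peaks)) {
    stopifnot("sample_id" %in% names(peaks))
  } else {
    stopifnot(is.list(peaks), !is.null(names(peaks)))
    peaks <- purrr::imap_dfr(peaks, function(p, id) {
      p <- tibble::as_tibble(p)
      if (nrow(p) > 0) p$sample_id <- id
      p
    })
    if (nrow(peaks) == 0) {
      peaks <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), sample_id = character())
    }
  }
  # design samples without rows simply contribute empty peak sets
  peaks
}

presence_matrix <- function(consensus, peaks, design) {
  out <- matrix(FALSE, nrow = nrow(consensus), ncol = nrow(design),
                dimnames = list(NULL, design$sample_id))
  if (nrow(consensus) == 0 || nrow(peaks) == 0) return(out)
  for (sid in design$sample_id) {
    p <- peaks[peaks$sample_id == sid, ]
    if (nrow(p) == 0) next
    ov <- interval_overlaps(consensus, p)
    out[unique(ov$query), sid] <- TRUE
  }
  out
}

group_presence_fraction <- function(presence, design) {
  tps <- levels(design$timepoint)
  out <- vapply(tps, function(tp) {
    smp <- design$sample_id[design$timepoint == tp]
    if (nrow(presence) == 0) numeric(0)
    else rowMeans(presence[, smp, drop = FALSE])
  }, numeric(nrow(presence)))
  if (nrow(presence) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, tps))
  out
}

#' @export
print.peak_atlas <- function(x, ...) {
  cat("Consensus peak atlas:", nrow(x$peaks), "peaks x",
      ncol(x$presence), "samples (group presence >", x$min_fraction, ")\n")
  invisible(x)
}

#' Per-timepoint presence fractions of atlas peaks
#'
#' @param atlas A [build_atlas()] result.
#' @return Tibble with `peak_id` and one fraction column per timepoint.
#' @export
atlas_presence_fractions <- function(atlas) {
  frac <- group_presence_fraction(atlas$presence, atlas$design)
  dplyr::bind_cols(tibble::tibble(peak_id = atlas$peaks$peak_id),
                   tibble::as_tibble(frac))
}

#' Quantify atlas peak signal from coverage tracks
#'
#' Per-peak signal is the summed coverage inside the consensus interval, used
#' as a transparent fragment-count proxy. With `normalize = TRUE` samples are
#' library-size scaled: each sample's summed genome-wide coverage is divided
#' by the geometric mean across samples and the per-peak sums are divided by
#' that factor.
#'
#' @param atlas A `peak_atlas`.
#' @param tracks Named list (by sample id) of [coverage_track()] objects; for
#'   strand-resolved data pass the sum or either strand consistently.
#' @param normalize Library-size scale the columns (default TRUE).
#' @return Tibble with `feature_id` (= peak id) plus one column per sample,
#'   directly usable by the trajectory functions.
#' @export
count_atlas_signal <- function(atlas, tracks, normalize = TRUE) {
  design <- atlas$design
  stopifnot(all(design$sample_id %in% names(tracks)))
  peaks <- atlas$peaks
  sig <- vapply(design$sample_id, function(sid) {
    tr <- tracks[[sid]]
    vapply(seq_len(nrow(peaks)), function(i) {
      sum(coverage_slice(tr, peaks$chrom[i], peaks$start[i], peaks$end[i]))
    }, numeric(1))
  }, numeric(nrow(peaks)))
  if (nrow(peaks) == 1) {
    sig <- matrix(sig, nrow = 1, dimnames = list(NULL, design$sample_id))
  }
  if (normalize) {
    lib <- vapply(design$sample_id, function(sid) {
      tr <- tracks[[sid]]
      sum((tr$end - tr$start) * tr$value)
    }, numeric(1))
    sf <- lib / exp(mean(log(lib)))
    sig <- sweep(sig, 2, sf, "/")
  }
  dplyr::bind_cols(tibble::tibble(feature_id = peaks$peak_id),
                   tibble::as_tibble(sig))
}

#' Open/closed peak counts among high-coverage atlas peaks
#'
#' MA-style comparison of two passages restricted to peaks whose overall mean
#' normalized signal strictly exceeds `mean_threshold`. Among those, "open"
#' peaks are significantly more accessible at `t_cmp` than at `t_ref` and
#' "closed" peaks significantly less, with significance from the same
#' Welch-test/BH/fold-change machinery as [test_differential()].
#'
#' @param signal Tibble with `feature_id` plus normalized sample columns.
#' @param design A [sample_design()] covering both timepoints.
#' @param t_ref,t_cmp Timepoint labels to compare (e.g. first vs last passage).
#' @param mean_threshold Strict overall-mean cutoff (default 800).
#' @param alpha,min_fold Significance thresholds (defaults 0.05, 2).
#' @return A list with `n_open`, `n_closed`, and `table` (per above-threshold
#'   peak: mean signal, log2 ratio, adjusted p, status).
#' @export
ma_high_coverage_counts <- function(signal, design, t_ref, t_cmp,
                                    mean_threshold = 800,
                                    alpha = 0.05, min_fold = 2) {
  stopifnot(all(c(t_ref, t_cmp) %in% levels(design$timepoint)))
  m <- counts_matrix(signal)
  overall_mean <- rowMeans(m[, design$sample_id, drop = FALSE])
  keep <- overall_mean > mean_threshold
  empty <- tibble::tibble(feature_id = character(), mean_signal = numeric(),
                          log2_ratio = numeric(), p_adj = numeric(),
                          status = character())
  if (!any(keep)) return(list(n_open = 0L, n_closed = 0L, table = empty))
  sub_design <- design[design$timepoint %in% c(t_ref, t_cmp), ]
  sub_design$timepoint <- droplevels(sub_design$timepoint)
  sub <- signal[keep, c("feature_id", sub_design$sample_id)]
  da <- test_differential(sub, sub_design, reference = t_ref,
                          alpha = alpha, min_fold = min_fold)
  tab <- tidy(da) |>
    dplyr::mutate(
      mean_signal = overall_mean[keep][match(.data$feature_id, signal$feature_id[keep])],
      status = dplyr::case_when(
        .data$selected & .data$log2_fc > 0 ~ "open",
        .data$selected & .data$log2_fc < 0 ~ "closed",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::select("feature_id", "mean_signal", log2_ratio = "log2_fc",
                  "p_adj", "status")
  list(n_open = sum(tab$status == "open"),
       n_closed = sum(tab$status == "closed"),
       table = tab)
}

#' Detect peaks that newly appear during passaging
#'
#' A peak "appears at t" when its group-presence fraction is strictly above
#' `min_fraction` at t and at or below it at every earlier timepoint; later
#' re-gains after a loss are not newly appeared. Presence uses the same
#' strict rule as [build_atlas()].
#'
#' @param atlas A `peak_atlas`.
#' @param min_fraction Strict presence threshold (default 0.6).
#' @return Tibble with `peak_id`, `timepoint`, `t_index`, one row per
#'   appearance event.
#' @export
detect_appearing_peaks <- function(atlas, min_fraction = 0.6) {
  frac <- group_presence_fraction(atlas$presence, atlas$design)
  event_table(atlas, frac > min_fraction, kind = "appear")
}

#' Detect peaks that disappear during passaging
#'
#' A peak "disappears at t" (t >= 1) when it is present (fraction strictly
#' above `min_fraction`) at every earlier timepoint and, under the default
#' `mode = "all_later"`, absent at t and every later timepoint; with
#' `mode = "at_t"` only absence at t itself is required. Peaks never present
#' are not reported.
#'
#' @inheritParams detect_appearing_peaks
#' @param mode Absence requirement after the loss (see above).
#' @return Tibble with `peak_id`, `timepoint`, `t_index`.
#' @export
detect_disappearing_peaks <- function(atlas, min_fraction = 0.6,
                                      mode = c("all_later", "at_t")) {
  mode <- match.arg(mode)
  frac <- group_presence_fraction(atlas$presence, atlas$design)
  event_table(atlas, frac > min_fraction, kind = "disappear", mode = mode)
}

event_table <- function(atlas, present, kind, mode = "all_later") {
  tps <- levels(atlas$design$timepoint)
  if (nrow(atlas$peaks) == 0) {
    return(tibble::tibble(peak_id = character(), timepoint = character(),
                          t_index = integer()))
  }
  rows <- purrr::map_dfr(seq_len(nrow(present)), function(i) {
    p <- present[i, ]
    t_hit <- if (kind == "appear") {
      which(vapply(seq_along(p), function(t) {
        p[t] && (t == 1 || !any(p[seq_len(t - 1)]))
      }, TRUE))
    } else {
      which(vapply(seq_along(p), function(t) {
        t > 1 && all(p[seq_len(t - 1)]) &&
          (if (mode == "all_later") !any(p[t:length(p)]) else !p[t])
      }, TRUE))
    }
    if (length(t_hit) == 0) return(NULL)
    tibble::tibble(peak_id = atlas$peaks$peak_id[i],
                   timepoint = tps[t_hit], t_index = t_hit - 1L)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(peak_id = character(), timepoint = character(),
                          t_index = integer()))
  }
  dplyr::arrange(rows, .data$t_index, .data$peak_id)
}

#' Identify enhancers as H3K4me1 / H3K27ac double-positive regions
#'
#' Enhancer regions are the coverage-level intersection of the two
#' histone-mark peak sets: every reported interval lies under at least one
#' H3K4me1 and one H3K27ac peak.
#'
#' @param h3k4me1,h3k27ac Interval tibbles of histone-mark peaks.
#' @return A disjoint, sorted interval tibble.
#' @export
identify_enhancers <- function(h3k4me1, h3k27ac) {
  interval_intersect(h3k4me1, h3k27ac)
}

#' Annotate peaks overlapping gene promoters
#'
#' A peak is a gene-regulating (promoter) peak of a gene when it overlaps the
#' symmetric `flank` bp window around that gene's TSS (half-open). The same
#' rule, applied to a transcription factor's binding peaks, yields the
#' factor's downstream genes.
#'
#' @param peaks Interval tibble with a `peak_id` column (e.g. `atlas$peaks`),
#'   or a `peak_atlas`.
#' @param genes Gene-model tibble.
#' @param flank Promoter half-width (default 1000 bp).
#' @return Tibble with `peak_id`, `gene_id`, one row per overlap pair.
#' @export
annotate_promoter_peaks <- function(peaks, genes, flank = 1000) {
  if (inherits(peaks, "peak_atlas")) peaks <- peaks$peaks
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  win <- promoter_window(genes, flank = flank)
  ov <- interval_overlaps(peaks, win)
  tibble::tibble(peak_id = peaks$peak_id[ov$query],
                 gene_id = win$gene_id[ov$subject]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$peak_id, .data$gene_id)
}

#' Promoter-accessibility shift of up- and down-regulated genes
#'
#' Compares the accessibility change of promoter peaks of up-regulated and of
#' down-regulated genes against promoter peaks of all genes: per class, the
#' promoter-peak log2 fold changes form an empirical distribution, and a
#' two-sided Welch t-test contrasts each regulated class with the all-genes
#' class. The sign of the t statistic indicates the direction of the shift.
#'
#' @param peak_log2fc Tibble with `peak_id` and `log2_fc` (accessibility
#'   change, e.g. last vs first passage).
#' @param up_genes,down_genes,all_genes Character vectors of gene ids.
#' @param annotation Promoter annotation from [annotate_promoter_peaks()].
#' @return An object of class `promoter_shift`: list with `values` (tibble:
#'   `class`, `log2_fc`) and `tests` (tibble: `class`, `n`, `mean`,
#'   `t_statistic`, `p_value`).
#' @export
promoter_shift_test <- function(peak_log2fc, up_genes, down_genes, all_genes,
                                annotation) {
  class_values <- function(genes, label) {
    pk <- unique(annotation$peak_id[annotation$gene_id %in% genes])
    v <- peak_log2fc$log2_fc[peak_log2fc$peak_id %in% pk]
    if (length(v) < 2) {
      stop("gene class '", label, "' maps to fewer than 2 promoter peaks",
           call. = FALSE)
    }
    tibble::tibble(class = label, log2_fc = v)
  }
  vals <- dplyr::bind_rows(
    class_values(all_genes, "all"),
    class_values(up_genes, "up"),
    class_values(down_genes, "down")
  )
  ref <- vals$log2_fc[vals$class == "all"]
  tests <- purrr::map_dfr(c("up", "down"), function(cl) {
    v <- vals$log2_fc[vals$class == cl]
    tt <- stats::t.test(v, ref)
    tibble::tibble(class = cl, n = length(v), mean = mean(v),
                   t_statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  structure(list(values = vals, tests = tests), class = "promoter_shift")
}

#' @export
print.promoter_shift <- function(x, ...) {
  cat("Promoter accessibility shift vs all genes:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' @method tidy promoter_shift
#' @export
tidy.promoter_shift <- function(x, ...) x$tests

#' @method glance promoter_shift
#' @export
glance.promoter_shift <- function(x, ...) {
  tibble::tibble(
    n_all = sum(x$values$class == "all"),
    p_up = x$tests$p_value[x$tests$class == "up"],
    p_down = x$tests$p_value[x$tests$class == "down"]
  )
}
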