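#' Per-cytosine methylation level
#'
#' @param methylated Methylated read count(s) `m`.
#' @param total Total read count(s) `n`; must satisfy `n >= 1`, `0 <= m <= n`.
#' @return `m / n`, a level in `[0, 1]` (vectorized).
#' @examples
#' methylation_level(3, 10)
#' @export
methylation_level <- function(methylated, total) {
  if (any(total < 1)) stop("total coverage must be >= 1", call. = FALSE)
  if (any(methylated < 0 | methylated > total)) {
    stop("need 0 <= methylated <= total", call. = FALSE)
  }
  methylated / total
}

#' Build per-cytosine methylation trajectories over series and timepoints
#'
#' Aggregates calls to one level per cytosine, series and timepoint (pooling
#' read counts when a series/timepoint cell has several samples) and keeps
#' only cytosines covered with at least `min_coverage` reads in every cell of
#' the series-by-timepoint grid. Cytosines with incomplete coverage are
#' excluded, not errored.
#'
#' @param calls Methylation-call tibble (see [read_methyl_calls()]).
#' @param design A [sample_design()]; the `series` column partitions samples
#'   such that each series covers every timepoint.
#' @param min_coverage Minimum pooled reads per cytosine per cell (default 5).
#' @return A long tibble: `chrom`, `pos`, `series`, `timepoint`, `t_index`,
#'   `methylated`, `total`, `level`, complete over the grid for every
#'   retained cytosine.
#' @export
methylation_trajectories <- function(calls, design, min_coverage = 5) {
  d <- dplyr::inner_join(calls, as.data.frame(design)[c("sample_id", "timepoint", "t_index", "series")],
                         by = "sample_id")
  cell <- d |>
    dplyr::summarise(methylated = sum(.data$methylated), total = sum(.data$total),
                     .by = c("chrom", "pos", "series", "timepoint", "t_index"))
  n_cells <- nlevels(design$timepoint) * length(unique(design$series))
  keep <- cell |>
    dplyr::summarise(ok = dplyr::n() == n_cells && all(.data$total >= min_coverage),
                     .by = c("chrom", "pos")) |>
    dplyr::filter(.data$ok)
  cell |>
    dplyr::semi_join(keep, by = c("chrom", "pos")) |>
    dplyr::mutate(level = .data$methylated / .data$total) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$series, .data$t_index)
}

#' Identify senescence-associated differentially methylated sites (DMS)
#'
#' Applies the adjacent-passage delta rule: a cytosine is an increased DMS
#' when, in every series independently, each adjacent-passage methylation
#' change exceeds `delta_up` (strictly); a decreased DMS when each change is
#' below `-delta_down`. The lower default for the decreasing direction
#' reflects the global drift toward hypermethylation that makes monotone
#' decreases rarer. Up and down sets are disjoint by construction. With
#' `mode = "series_mean"` the rule is instead applied to the across-series
#' mean trajectory.
#'
#' @param trajectories Long tibble from [methylation_trajectories()].
#' @param delta_up Strict minimum per-step increase (default 0.05).
#' @param delta_down Strict minimum per-step decrease (default 0.03).
#' @param mode `"per_series"` (default: rule must hold in every series) or
#'   `"series_mean"`.
#' @return Tibble with `chrom`, `pos`, `direction` in `{"up","down"}`; at
#'   most one row per cytosine.
#' @examples
#' # a cytosine rising 0.1 per passage in all series is an up DMS
#' @export
identify_dms <- function(trajectories, delta_up = 0.05, delta_down = 0.03,
                         mode = c("per_series", "series_mean")) {
  mode <- match.arg(mode)
  if (delta_up <= 0 || delta_down <= 0) {
    stop("delta thresholds must be positive", call. = FALSE)
  }
  if (nrow(trajectories) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          direction = character()))
  }
  traj <- trajectories
  if (mode == "series_mean") {
    traj <- traj |>
      dplyr::summarise(level = mean(.data$level),
                       .by = c("chrom", "pos", "t_index")) |>
      dplyr::mutate(series = "mean")
  }
  per_series <- traj |>
    dplyr::arrange(.data$t_index) |>
    dplyr::summarise(
      up = all(diff(.data$level) > delta_up),
      down = all(diff(.data$level) < -delta_down),
      .by = c("chrom", "pos", "series")
    )
  per_series |>
    dplyr::summarise(up = all(.data$up), down = all(.data$down),
                     .by = c("chrom", "pos")) |>
    dplyr::filter(.data$up | .data$down) |>
    dplyr::mutate(direction = ifelse(.data$up, "up", "down")) |>
    dplyr::select("chrom", "pos", "direction") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Mean methylation level over regions
#'
#' For each region, the unweighted mean of the per-cytosine levels whose
#' position falls in `[start, end)`. Regions containing no covered cytosine
#' get `NA` (never 0). A coverage-weighted mean (total-read weights) is
#' available behind `weighted = TRUE`.
#'
#' @param calls Call tibble for one sample or pooled group, with `chrom`,
#'   `pos`, `level` (and `total` if `weighted`).
#' @param regions Interval tibble.
#' @param weighted Weight cytosines by read coverage (default FALSE).
#' @return Numeric vector, one mean level (or `NA`) per region row.
#' @export
region_mean_methylation <- function(calls, regions, weighted = FALSE) {
  regions <- validate_intervals(regions)
  out <- rep(NA_real_, nrow(regions))
  if (nrow(calls) == 0 || nrow(regions) == 0) return(out)
  sites <- genomic_intervals(calls$chrom, calls$pos, calls$pos + 1L)
  ov <- interval_overlaps(regions, sites)
  if (nrow(ov) == 0) return(out)
  w <- if (weighted) calls$total[ov$subject] else rep(1, nrow(ov))
  agg <- tibble::tibble(region = ov$query,
                        level = calls$level[ov$subject], w = w) |>
    dplyr::summarise(level = sum(.data$level * .data$w) / sum(.data$w),
                     .by = "region")
  out[agg$region] <- agg$level
  out
}

#' Methylation trend over TF binding sites across passages
#'
#' Estimates each binding site's methylation as the unweighted mean of its
#' cytosine levels per timepoint, and tests for a level shift across
#' timepoints with a one-way ANOVA. If all values are identical the p-value
#' is 1 by convention (zero between-group variance).
#'
#' @param tfbs Interval tibble of binding sites.
#' @param calls Methylation calls with a `sample_id` column.
#' @param design A [sample_design()].
#' @return A list with `levels` (tibble: `timepoint`, `tfbs`, `level`) and
#'   `anova` (tibble: `f_statistic`, `p_value`, per-timepoint n).
#' @export
tfbs_methylation_trend <- function(tfbs, calls, design) {
  d <- dplyr::inner_join(calls, as.data.frame(design)[c("sample_id", "timepoint")],
                         by = "sample_id")
  tps <- levels(design$timepoint)
  levels_tbl <- purrr::map_dfr(tps, function(tp) {
    grp <- d[d$timepoint == tp, ]
    pooled <- grp |>
      dplyr::summarise(methylated = sum(.data$methylated), total = sum(.data$total),
                       .by = c("chrom", "pos")) |>
      dplyr::mutate(level = .data$methylated / .data$total)
    lv <- region_mean_methylation(pooled, tfbs)
    tibble::tibble(timepoint = tp, tfbs = seq_len(nrow(tfbs)), level = lv)
  }) |>
    dplyr::filter(!is.na(.data$level))
  counts <- table(levels_tbl$timepoint)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 timepoints with >= 2 binding-site levels each", call. = FALSE)
  }
  if (stats::var(levels_tbl$level) == 0) {
    aout <- tibble::tibble(f_statistic = 0, p_value = 1)
  } else {
    fit <- stats::aov(level ~ factor(timepoint), data = levels_tbl)
    s <- summary(fit)[[1]]
    aout <- tibble::tibble(f_statistic = s[["F value"]][1],
                           p_value = s[["Pr(>F)"]][1])
  }
  list(levels = levels_tbl, anova = aout)
}

#' Map differentially methylated regions to genes near their TSS
#'
#' A gene is associated with a DMR when the DMR overlaps the symmetric window
#' of `flank` bp around the gene's TSS (half-open overlap; a DMR touching the
#' window boundary is not associated).
#'
#' @param dmrs Interval tibble of DMRs.
#' @param genes Gene-model tibble.
#' @param flank Window half-width (default 5000 bp).
#' @return Tibble with `dmr` (row index into `dmrs`) and `gene_id`, one row
#'   per association.
#' @export
dmr_to_genes <- function(dmrs, genes, flank = 5000) {
  win <- promoter_window(genes, flank = flank)
  ov <- interval_overlaps(dmrs, win)
  tibble::tibble(dmr = ov$query, gene_id = win$gene_id[ov$subject]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$dmr, .data$gene_id)
}

#' Merge same-direction DMSs into candidate regions
#'
#' A naive positional merge used as plumbing when no model-based DMR caller
#' has been run: consecutive DMSs of the same direction on the same
#' chromosome whose positions are at most `max_gap` apart are merged into one
#' interval spanning them.
#'
#' @param dms Tibble from [identify_dms()].
#' @param max_gap Maximum distance in bp between consecutive member sites.
#' @return Interval tibble with a `direction` and `n_sites` column.
#' @export
merge_dms_to_regions <- function(dms, max_gap = 100) {
  if (nrow(dms) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          direction = character(), n_sites = integer()))
  }
  dms |>
    dplyr::arrange(.data$chrom, .data$direction, .data$pos) |>
    dplyr::mutate(
      new_run = dplyr::if_else(
        is.na(dplyr::lag(.data$pos)) | .data$pos - dplyr::lag(.data$pos) > max_gap,
        1L, 0L),
      run = cumsum(.data$new_run),
      .by = c("chrom", "direction")
    ) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      n_sites = dplyr::n(),
      .by = c("chrom", "direction", "run")
    ) |>
    dplyr::mutate(strand = "*") |>
    dplyr::select("chrom", "start", "end", "strand", "direction", "n_sites") |>
    dplyr::arrange(.data$chrom, .data$start)
}
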