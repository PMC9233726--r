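#' Validated configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter with the package defaults: differential
#' selection at adjusted p < 0.05 and fold change > 2, the strict >60%
#' replicate-presence atlas rule, DMS deltas 0.05 (up) / 0.03 (down) with
#' minimum coverage 5, promoter windows of +/-1 kb (peaks) and +/-5 kb
#' (DMR-to-gene), the MA mean-signal cutoff 800, footprint flanks of 100 bp,
#' module counts 6/6/10 (genes/DMRs/peaks) and the CD/COI class boundaries
#' 0.45/4. Invalid values raise a classed condition
#' (`senomics_config_error`) naming the offending key.
#'
#' @param seed Integer seed driving the synthetic study.
#' @param sim A [sim_config()]; defaults to `sim_config(seed)`.
#' @param alpha,min_fold Differential selection thresholds.
#' @param min_fraction Atlas / appearance presence threshold in (0, 1).
#' @param delta_up,delta_down DMS adjacent-passage deltas (positive).
#' @param min_coverage Minimum reads per cytosine per series/timepoint cell.
#' @param promoter_flank,dmr_flank Promoter half-widths in bp.
#' @param mean_threshold MA high-coverage cutoff.
#' @param footprint_flank Footprint window half-width in bp.
#' @param k_gene_modules,k_dmr_modules,k_peak_modules Module counts.
#' @param cd_threshold,coi_threshold TF classification boundaries.
#' @param tf_values Optional tibble (`tf`, `cd`, `coi`) of upstream
#'   chromatin-dependence / opening-index values to classify; the default is
#'   a small synthetic example table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed),
                            alpha = 0.05, min_fold = 2, min_fraction = 0.6,
                            delta_up = 0.05, delta_down = 0.03,
                            min_coverage = 5,
                            promoter_flank = 1000, dmr_flank = 5000,
                            mean_threshold = 800, footprint_flank = 100,
                            k_gene_modules = 6, k_dmr_modules = 6,
                            k_peak_modules = 10,
                            cd_threshold = 0.45, coi_threshold = 4,
                            tf_values = NULL) {
  fail <- function(key, why) {
    stop(structure(
      class = c("senomics_config_error", "error", "condition"),
      list(message = sprintf("invalid configuration: `%s` %s", key, why),
           call = NULL)
    ))
  }
  check_pos <- function(key, v) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      fail(key, "must be a single positive number")
    }
  }
  check_pos("alpha", alpha); if (alpha >= 1) fail("alpha", "must be < 1")
  if (!is.numeric(min_fold) || min_fold <= 1) fail("min_fold", "must be > 1")
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction >= 1) {
    fail("min_fraction", "must lie strictly in (0, 1)")
  }
  check_pos("delta_up", delta_up)
  check_pos("delta_down", delta_down)
  check_pos("min_coverage", min_coverage)
  check_pos("promoter_flank", promoter_flank)
  check_pos("dmr_flank", dmr_flank)
  check_pos("mean_threshold", mean_threshold)
  check_pos("footprint_flank", footprint_flank)
  for (k in c("k_gene_modules", "k_dmr_modules", "k_peak_modules")) {
    v <- get(k)
    if (!is.numeric(v) || v < 2) fail(k, "must be >= 2")
  }
  check_pos("cd_threshold", cd_threshold)
  check_pos("coi_threshold", coi_threshold)
  if (is.null(tf_values)) {
    # synthetic example CD/COI values; real values come from an upstream
    # footprint model and are supplied by the user
    tf_values <- tibble::tibble(
      tf = c("tf_pioneer_a", "tf_pioneer_b", "tf_settler_a", "tf_migrator_a",
             "tf_migrator_b"),
      cd = c(0.62, 0.51, 0.55, 0.30, 0.12),
      coi = c(6.1, 4.8, 2.2, 8.0, 1.1)
    )
  }
  cfg <- as.list(environment())
  cfg$fail <- cfg$check_pos <- cfg$k <- cfg$v <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Per-sample mean methylation of regions as a feature matrix
#'
#' Averages cytosine levels within each region for every sample, yielding a
#' region-by-sample tibble usable by the trajectory functions (module
#' clustering, monotone labelling of DMRs). Regions with no covered cytosine
#' in a sample get that region's across-sample mean (they carry no trend).
#'
#' @param regions Interval tibble (e.g. merged DMS regions).
#' @param calls Methylation-call tibble with `sample_id`.
#' @param design A [sample_design()].
#' @return Tibble with `feature_id` plus one level column per sample.
#' @export
dmr_group_levels <- function(regions, calls, design) {
  ids <- sprintf("dmr_%04d", seq_len(nrow(regions)))
  m <- vapply(design$sample_id, function(sid) {
    region_mean_methylation(calls[calls$sample_id == sid, ], regions)
  }, numeric(nrow(regions)))
  if (nrow(regions) == 1) {
    m <- matrix(m, nrow = 1, dimnames = list(NULL, design$sample_id))
  }
  if (nrow(regions) > 0 && anyNA(m)) {
    rmean <- rowMeans(m, na.rm = TRUE)
    rmean[is.nan(rmean)] <- 0
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- rmean[is.na(m[, j])]
  }
  dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(m))
}

sum_strand_signal <- function(atlas, coverage) {
  fwd <- count_atlas_signal(atlas, purrr::map(coverage, "fwd"), normalize = FALSE)
  rev <- count_atlas_signal(atlas, purrr::map(coverage, "rev"), normalize = FALSE)
  m <- counts_matrix(fwd) + counts_matrix(rev)
  lib <- vapply(names(coverage), function(sid) {
    tr <- coverage[[sid]]
    sum((tr$fwd$end - tr$fwd$start) * tr$fwd$value) +
      sum((tr$rev$end - tr$rev$start) * tr$rev$value)
  }, numeric(1))
  sf <- lib / exp(mean(log(lib)))
  m <- sweep(m[, names(lib), drop = FALSE], 2, sf, "/")
  dplyr::bind_cols(tibble::tibble(feature_id = atlas$peaks$peak_id),
                   tibble::as_tibble(m))
}

#' Run the full synthetic-study pipeline
#'
#' Simulates the study, then runs the expression-trajectory, methylome,
#' accessibility and TF stages and aggregates their headline numbers into a
#' report. Stages can be restricted; later stages reuse the artifacts of
#' earlier ones within the call. With `outdir` set, the simulated inputs,
#' per-stage tables and the report JSON are written to disk; reruns with the
#' same configuration reproduce the report byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @param stages Character subset of
#'   `c("trajectory", "methylome", "atac", "tf")`; the simulation and report
#'   always run.
#' @return A list of class `pipeline_report` with one element per stage plus
#'   `summary` (the flat report written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         stages = c("trajectory", "methylome", "atac", "tf")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- simulate_study(config$sim)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, file.path(outdir, "simulated_inputs"))
  }
  report <- list()
  out <- list(config = config)

  if ("trajectory" %in% stages) {
    message("stage trajectory: ", nrow(sim$expression$counts), " genes, ",
            nrow(sim$expression$design), " samples")
    norm <- normalize_library_size(sim$expression$counts)
    da <- test_differential(norm$normalized, sim$expression$design,
                            alpha = config$alpha, min_fold = config$min_fold)
    labels <- trajectory_labels(norm$normalized, sim$expression$design)
    rs <- select_rs_features(da, labels)
    sel_ids <- rs$feature_id[rs$selected]
    modules <- if (length(sel_ids) >= config$k_gene_modules) {
      cluster_modules(norm$normalized[norm$normalized$feature_id %in% sel_ids, ],
                      sim$expression$design, k = config$k_gene_modules)
    } else NULL
    out$trajectory <- list(differential = da, labels = labels, rs = rs,
                           modules = modules, size_factors = norm$size_factors)
    report$n_genes_selected <- sum(rs$selected)
    report$n_rs_genes_up <- sum(rs$rs == "up")
    report$n_rs_genes_down <- sum(rs$rs == "down")
    report$n_gene_modules <- if (is.null(modules)) 0L else
      length(unique(modules$module))
  }

  if ("methylome" %in% stages) {
    message("stage methylome: ", nrow(sim$methylome$truth), " cytosines, ",
            nrow(sim$methylome$design), " samples")
    traj <- methylation_trajectories(sim$methylome$calls, sim$methylome$design,
                                     min_coverage = config$min_coverage)
    dms <- identify_dms(traj, delta_up = config$delta_up,
                        delta_down = config$delta_down)
    # candidate regions from the more lenient series-mean call; the strict
    # per-series set above remains the reported DMS list
    dms_cand <- identify_dms(traj, delta_up = config$delta_up,
                             delta_down = config$delta_down,
                             mode = "series_mean")
    dmrs <- merge_dms_to_regions(dms_cand, max_gap = 100)
    dmr_levels <- dmr_group_levels(dmrs, sim$methylome$calls,
                                   sim$methylome$design)
    dmr_labels <- if (nrow(dmrs) > 0) {
      trajectory_labels(dmr_levels, sim$methylome$design)$label
    } else character(0)
    dmr_modules <- if (nrow(dmrs) >= config$k_dmr_modules) {
      cluster_modules(dmr_levels, sim$methylome$design,
                      k = min(config$k_dmr_modules, nrow(dmrs)))
    } else NULL
    d2g <- dmr_to_genes(dmrs, sim$genome$genes, flank = config$dmr_flank)
    tfbs <- sim$accessibility$motif_sites |>
      dplyr::mutate(start = pmax(0L, .data$start - 200L), end = .data$end + 200L)
    trend <- tryCatch(
      tfbs_methylation_trend(tfbs, sim$methylome$calls, sim$methylome$design),
      error = function(e) NULL)
    out$methylome <- list(trajectories = traj, dms = dms, dmrs = dmrs,
                          dmr_levels = dmr_levels, dmr_labels = dmr_labels,
                          dmr_modules = dmr_modules, dmr_genes = d2g,
                          tfbs_trend = trend)
    report$n_dms_up <- sum(dms$direction == "up")
    report$n_dms_down <- sum(dms$direction == "down")
    report$n_dmr_regions <- nrow(dmrs)
    report$n_rs_dmrs <- sum(dmr_labels != "non_monotone")
    report$n_dmr_modules <- if (is.null(dmr_modules)) 0L else
      length(unique(dmr_modules$module))
    report$n_dmr_genes <- length(unique(d2g$gene_id))
    report$tfbs_trend_p <- if (is.null(trend)) NA_real_ else trend$anova$p_value
  }

  if ("atac" %in% stages) {
    acc <- sim$accessibility
    message("stage atac: ", length(acc$sample_peaks), " peak sets")
    atlas <- build_atlas(acc$sample_peaks, acc$design,
                         min_fraction = config$min_fraction)
    signal <- sum_strand_signal(atlas, acc$coverage)
    tps <- levels(acc$design$timepoint)
    t_first <- tps[1]
    t_last <- tps[length(tps)]
    ma <- ma_high_coverage_counts(signal, acc$design, t_first, t_last,
                                  mean_threshold = config$mean_threshold,
                                  alpha = config$alpha,
                                  min_fold = config$min_fold)
    appearing <- detect_appearing_peaks(atlas, min_fraction = config$min_fraction)
    disappearing <- detect_disappearing_peaks(atlas,
                                              min_fraction = config$min_fraction)
    annotation <- annotate_promoter_peaks(atlas, sim$genome$genes,
                                          flank = config$promoter_flank)
    shift <- tryCatch({
      lfc <- ma$table[c("feature_id", "log2_ratio")]
      names(lfc) <- c("peak_id", "log2_fc")
      app_late <- appearing$peak_id[appearing$t_index > 0]
      up_genes <- unique(annotation$gene_id[annotation$peak_id %in% app_late])
      down_genes <- unique(annotation$gene_id[
        annotation$peak_id %in% disappearing$peak_id])
      promoter_shift_test(lfc, up_genes, down_genes,
                          unique(annotation$gene_id), annotation)
    }, error = function(e) NULL)
    out$atac <- list(atlas = atlas, signal = signal, ma = ma,
                     appearing = appearing, disappearing = disappearing,
                     annotation = annotation, shift = shift)
    report$n_atlas_peaks <- nrow(atlas$peaks)
    report$n_ma_open <- ma$n_open
    report$n_ma_closed <- ma$n_closed
    report$n_appearing <- sum(appearing$t_index > 0)
    report$n_disappearing <- nrow(disappearing)
    report$n_promoter_peaks <- length(unique(annotation$peak_id))
    report$shift_p_up <- if (is.null(shift)) NA_real_ else
      shift$tests$p_value[shift$tests$class == "up"]
    report$shift_p_down <- if (is.null(shift)) NA_real_ else
      shift$tests$p_value[shift$tests$class == "down"]
  }

  if ("tf" %in% stages && "atac" %in% stages) {
    acc <- sim$accessibility
    atlas <- out$atac$atlas
    appearing <- out$atac$appearing
    message("stage tf: ", length(acc$pwm_library), " motifs")
    app_peaks <- atlas$peaks[atlas$peaks$peak_id %in%
                               appearing$peak_id[appearing$t_index > 0], ]
    enr <- if (nrow(app_peaks) > 0) {
      motif_enrichment(app_peaks, atlas$peaks, acc$pwm_library, acc$sequences)
    } else NULL
    hits <- scan_pwm(acc$sequences, acc$motif, regions = atlas$peaks)
    tps <- levels(acc$design$timepoint)
    profile_at <- function(tp) {
      smp <- acc$design$sample_id[acc$design$timepoint == tp]
      fwd <- mean_track(purrr::map(acc$coverage[smp], "fwd"))
      rev <- mean_track(purrr::map(acc$coverage[smp], "rev"))
      footprint_profile(fwd, rev, hits, flank = config$footprint_flank)
    }
    prof_first <- profile_at(tps[1])
    prof_last <- profile_at(tps[length(tps)])
    delta <- footprint_activity_delta(prof_first, prof_last)
    classes <- classify_tf(config$tf_values$tf, config$tf_values$cd,
                           config$tf_values$coi,
                           cd_threshold = config$cd_threshold,
                           coi_threshold = config$coi_threshold)
    out$tf <- list(enrichment = enr, hits = hits,
                   profile_first = prof_first, profile_last = prof_last,
                   activity = delta, classification = classes)
    report$n_motif_hits <- nrow(hits)
    report$enrichment_top_motif <- if (is.null(enr)) NA_character_ else
      enr$table$motif[1]
    report$enrichment_min_p_adj <- if (is.null(enr)) NA_real_ else
      min(enr$table$p_adj)
    report$footprint_activity_delta <- delta$delta
    report$n_pioneer <- sum(classes$class == "pioneer")
    report$n_settler <- sum(classes$class == "settler")
    report$n_migrator <- sum(classes$class == "migrator")
  }

  out$summary <- report
  class(out) <- "pipeline_report"
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

mean_track <- function(tracks) {
  # average several run-length tracks position-wise via a shared breakpoint set
  brk <- sort(unique(unlist(purrr::map(tracks, function(t) c(t$start, t$end)))))
  if (length(brk) < 2) return(tracks[[1]])
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  chrom <- tracks[[1]]$chrom[1]
  vals <- rowMeans(vapply(tracks, function(t) {
    idx <- findInterval(starts, t$start)
    v <- numeric(length(starts))
    ok <- idx >= 1 & idx <= nrow(t)
    hit <- ok & starts < t$end[pmax(idx, 1)]
    v[hit] <- t$value[idx[hit]]
    v
  }, numeric(length(starts))))
  coverage_track(tibble::tibble(chrom = chrom, start = starts, end = ends,
                                value = vals))
}

write_pipeline_outputs <- function(out, outdir) {
  p <- function(...) file.path(outdir, ...)
  if (!is.null(out$trajectory)) {
    readr::write_tsv(tidy(out$trajectory$differential), p("differential_genes.tsv"))
    readr::write_tsv(out$trajectory$rs, p("rs_genes.tsv"))
    if (!is.null(out$trajectory$modules)) {
      readr::write_tsv(out$trajectory$modules, p("gene_modules.tsv"))
    }
  }
  if (!is.null(out$methylome)) {
    dms_bed <- out$methylome$dms
    if (nrow(dms_bed) > 0) {
      write_bed(tibble::tibble(chrom = dms_bed$chrom, start = dms_bed$pos,
                               end = dms_bed$pos + 1L, strand = "*",
                               name = dms_bed$direction),
                p("rs_dms.bed"))
    }
    readr::write_tsv(out$methylome$dmrs, p("dms_regions.tsv"))
  }
  if (!is.null(out$atac)) {
    write_bed(out$atac$atlas$peaks, p("atlas_peaks.bed"))
    readr::write_tsv(out$atac$signal, p("atlas_signal.tsv"))
    readr::write_tsv(out$atac$appearing, p("appearing_peaks.tsv"))
    readr::write_tsv(out$atac$disappearing, p("disappearing_peaks.tsv"))
  }
  if (!is.null(out$tf)) {
    if (!is.null(out$tf$enrichment)) {
      readr::write_tsv(tidy(out$tf$enrichment), p("motif_enrichment.tsv"))
    }
    readr::write_tsv(out$tf$classification, p("tf_classification.tsv"))
    readr::write_tsv(as.data.frame(out$tf$profile_last), p("footprint_profile_last.tsv"))
  }
  jsonlite::write_json(out$summary, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %-28s %s\n", k,
                if (is.numeric(v)) format(signif(v, 6)) else as.character(v)))
  }
  invisible(x)
}
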