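# shared fixture builders; everything is generated in code, no stored data

make_design <- function(T_ = 4, reps = 4, labels = paste0("P", c(1, 3, 5, 7))[seq_len(T_)]) {
  sample_design(
    sample_id = paste0(rep(labels, each = reps), "_r", rep(seq_len(reps), T_)),
    timepoint = rep(labels, each = reps),
    replicate = rep(seq_len(reps), T_),
    timepoint_labels = labels
  )
}

# counts tibble from a features x samples matrix
make_counts <- function(m, ids = sprintf("f%03d", seq_len(nrow(m))), design = NULL) {
  if (!is.null(design)) colnames(m) <- design$sample_id
  dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(m))
}

random_intervals <- function(n, chrom = "chr1", max_pos = 5000, max_width = 200) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals(chrom, start, start + width)
}

# per-base membership oracle over one chromosome
base_coverage_set <- function(x, len) {
  covered <- logical(len)
  for (i in seq_len(nrow(x))) {
    if (x$start[i] < len) covered[(x$start[i] + 1):min(x$end[i], len)] <- TRUE
  }
  covered
}

runs_from_logical <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# long methylation trajectory tibble from a cytosine x (series x timepoint)
# array of levels
make_trajectories <- function(levels_array, positions = seq_len(dim(levels_array)[1]) * 10L) {
  dn <- dim(levels_array)
  purrr::map_dfr(seq_len(dn[2]), function(s) {
    purrr::map_dfr(seq_len(dn[3]), function(t) {
      tibble::tibble(
        chrom = "chr1", pos = positions,
        series = paste0("series", s),
        timepoint = paste0("T", t), t_index = t - 1L,
        methylated = NA_integer_, total = 100L,
        level = levels_array[, s, t]
      )
    })
  })
}

# oracles shared by the accessibility and acceptance suites

atlas_oracle <- function(peak_tbl, design, min_fraction, len = 6000L) {
  all_cov <- base_coverage_set(peak_tbl, len)
  cand <- runs_from_logical(all_cov)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    fr <- vapply(levels(design$timepoint), function(tp) {
      smp <- design$sample_id[design$timepoint == tp]
      mean(vapply(smp, function(sid) {
        p <- peak_tbl[peak_tbl$sample_id == sid, ]
        any(p$start < cand$end[i] & cand$start[i] < p$end)
      }, TRUE))
    }, numeric(1))
    any(fr > min_fraction)
  }, TRUE)
  cand[keep, ]
}

event_oracle <- function(frac, min_fraction, kind, mode = "all_later") {
  present <- frac > min_fraction
  T_ <- ncol(present)
  purrr::map_dfr(seq_len(nrow(present)), function(i) {
    hits <- integer(0)
    for (t in seq_len(T_)) {
      if (kind == "appear") {
        ok <- present[i, t] && (t == 1 || !any(present[i, seq_len(t - 1)]))
      } else {
        ok <- t > 1 && all(present[i, seq_len(t - 1)]) &&
          (if (mode == "all_later") !any(present[i, t:T_]) else !present[i, t])
      }
      if (ok) hits <- c(hits, t)
    }
    if (length(hits) == 0) return(NULL)
    tibble::tibble(peak = i, t_index = hits - 1L)
  })
}

atlas_from_presence <- function(presence, design) {
  n <- nrow(presence)
  colnames(presence) <- design$sample_id
  structure(list(
    peaks = tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1L) * 1000L,
                           end = (seq_len(n) - 1L) * 1000L + 200L, strand = "*",
                           peak_id = sprintf("peak_%05d", seq_len(n))),
    presence = presence, design = design, min_fraction = 0.6
  ), class = "peak_atlas")
}
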