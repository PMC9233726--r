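#' Median-of-ratios library-size normalization
#'
#' Computes per-sample size factors by the median-of-ratios method: each
#' feature's geometric mean across samples serves as a pseudo-reference, and a
#' sample's size factor is the median of its counts over that reference,
#' taken across features that are positive in every sample. Normalized values
#' are raw counts divided by the size factor. If no feature is positive in
#' all samples the function falls back to total-count scaling (factors
#' proportional to column sums, geometric mean 1) with a warning.
#'
#' @param counts Tibble with `feature_id` plus one non-negative numeric
#'   column per sample.
#' @return A list with `normalized` (tibble, same shape) and `size_factors`
#'   (tibble: `sample_id`, `size_factor`).
#' @examples
#' x <- tibble::tibble(feature_id = c("a", "b"), s1 = c(10, 20), s2 = c(20, 40))
#' normalize_library_size(x)$size_factors
#' @export
normalize_library_size <- function(counts) {
  m <- counts_matrix(counts)
  loggeo <- rowMeans(log(m))
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    warning("no feature positive in all samples; falling back to total-count scaling")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  } else {
    sf <- apply(m, 2, function(col) {
      exp(stats::median((log(col) - loggeo)[usable & col > 0]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size factor estimation failed (non-positive factor)", call. = FALSE)
  }
  norm <- sweep(m, 2, sf, "/")
  out <- counts
  out[colnames(m)] <- tibble::as_tibble(norm)
  list(
    normalized = out,
    size_factors = tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
  )
}

counts_matrix <- function(counts) {
  stopifnot("feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  rownames(m) <- counts$feature_id
  if (any(m < 0)) stop("negative entries in feature matrix", call. = FALSE)
  m
}

design_columns <- function(m, design) {
  missing_s <- setdiff(design$sample_id, colnames(m))
  if (length(missing_s) > 0) {
    stop("design samples absent from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Any-versus-reference differential testing over a time course
#'
#' Tests every non-reference timepoint against the reference with a two-sided
#' Welch t-test on `log2(normalized + 1)` values, applies Benjamini-Hochberg
#' correction across features within each contrast, and flags a feature as
#' selected when any contrast passes both the adjusted-p and the fold-change
#' threshold. Fold change is the ratio of normalized group means with a
#' pseudocount of 1, so a constant-zero feature has log2 fold change 0.
#'
#' @param normalized Tibble with `feature_id` plus normalized sample columns
#'   (see [normalize_library_size()]).
#' @param design A [sample_design()] covering the matrix columns.
#' @param reference Reference timepoint label; defaults to the first level.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_fold Fold-change cutoff: a contrast passes when the mean ratio
#'   is `> min_fold` or `< 1/min_fold` (default 2).
#' @param test_fun Pluggable two-sample test; a function of two numeric
#'   vectors of `log2(x + 1)` values returning a list with a `p.value`.
#'   Defaults to `stats::t.test` (Welch).
#'
#' @return An object of class `senomics_da`: a list with `table` (tibble:
#'   `feature_id`, `contrast`, `log2_fc`, `p_value`, `p_adj`), `selected`
#'   (tibble: `feature_id`, `selected`), and the parameters used. Use
#'   [generics::tidy()] / [generics::glance()] to extract results.
#' @export
test_differential <- function(normalized, design, reference = NULL,
                              alpha = 0.05, min_fold = 2,
                              test_fun = function(x, y) stats::t.test(x, y)) {
  m <- counts_matrix(normalized)
  design_columns(m, design)
  tps <- levels(design$timepoint)
  if (is.null(reference)) reference <- tps[1]
  stopifnot(reference %in% tps)
  ref_samples <- design$sample_id[design$timepoint == reference]
  if (length(ref_samples) < 2) {
    stop("reference timepoint needs >= 2 replicates", call. = FALSE)
  }
  lm2 <- log2(m + 1)
  ref_means <- rowMeans(m[, ref_samples, drop = FALSE])
  tabs <- list()
  for (tp in setdiff(tps, reference)) {
    smp <- design$sample_id[design$timepoint == tp]
    if (length(smp) < 2) {
      warning("timepoint ", tp, " has < 2 replicates; contrast skipped")
      next
    }
    cmp_means <- rowMeans(m[, smp, drop = FALSE])
    lfc <- log2((cmp_means + 1) / (ref_means + 1))
    pv <- vapply(seq_len(nrow(m)), function(i) {
      x <- lm2[i, smp]
      y <- lm2[i, ref_samples]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      tryCatch(test_fun(x, y)$p.value, error = function(e) NA_real_)
    }, numeric(1))
    pv[is.na(pv)] <- 1
    tabs[[tp]] <- tibble::tibble(
      feature_id = rownames(m),
      contrast = paste0(tp, "_vs_", reference),
      log2_fc = lfc,
      p_value = pv,
      p_adj = stats::p.adjust(pv, method = "BH")
    )
  }
  if (length(tabs) == 0) stop("no testable contrasts", call. = FALSE)
  table <- dplyr::bind_rows(tabs)
  hit <- table$p_adj < alpha & abs(table$log2_fc) > log2(min_fold)
  selected <- table |>
    dplyr::mutate(hit = hit) |>
    dplyr::summarise(selected = any(.data$hit), .by = "feature_id")
  structure(
    list(table = table, selected = selected,
         params = list(reference = reference, alpha = alpha, min_fold = min_fold)),
    class = "senomics_da"
  )
}

#' @export
print.senomics_da <- function(x, ...) {
  cat("Differential time-course result:",
      nrow(x$selected), "features,",
      length(unique(x$table$contrast)), "contrasts vs", x$params$reference, "\n")
  cat("Selected (padj <", x$params$alpha, ", fold >", x$params$min_fold, "):",
      sum(x$selected$selected), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy senomics_da
#' @export
tidy.senomics_da <- function(x, ...) {
  dplyr::left_join(x$table, x$selected, by = "feature_id")
}

#' @method glance senomics_da
#' @export
glance.senomics_da <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$selected),
    n_contrasts = length(unique(x$table$contrast)),
    n_selected = sum(x$selected$selected),
    alpha = x$params$alpha,
    min_fold = x$params$min_fold
  )
}

#' Per-timepoint group means of a feature matrix
#'
#' @param x Tibble with `feature_id` plus sample columns.
#' @param design Matching [sample_design()].
#' @return Tibble with `feature_id` and one column per timepoint label.
#' @export
group_means <- function(x, design) {
  m <- counts_matrix(x)
  design_columns(m, design)
  tps <- levels(design$timepoint)
  gm <- vapply(tps, function(tp) {
    rowMeans(m[, design$sample_id[design$timepoint == tp], drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(m), tps))
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), tibble::as_tibble(gm))
}

#' Classify a trajectory of group means as monotone or not
#'
#' Monotone up means every adjacent difference exceeds `min_step`; monotone
#' down means every adjacent difference is below `-min_step`. With the strict
#' default `min_step = 0`, flat segments fail in both directions. The call
#' depends only on the ordering of the means, so it is invariant under any
#' strictly increasing transform when `min_step = 0`.
#'
#' @param means Numeric vector of per-timepoint means (length >= 2, finite).
#' @param min_step Minimum adjacent increment (default 0, strict).
#' @return `"monotone_up"`, `"monotone_down"` or `"non_monotone"`.
#' @examples
#' classify_trajectory(c(2, 4, 6, 8))
#' classify_trajectory(c(5, 5, 5, 5))
#' @export
classify_trajectory <- function(means, min_step = 0) {
  if (length(means) < 2 || anyNA(means) || any(!is.finite(means))) {
    stop("`means` must be >= 2 finite values", call. = FALSE)
  }
  d <- diff(means)
  if (all(d > min_step)) "monotone_up"
  else if (all(d < -min_step)) "monotone_down"
  else "non_monotone"
}

#' Trajectory labels for every feature of a matrix
#'
#' Computes per-timepoint group means on the supplied (normalized) values and
#' applies [classify_trajectory()] row-wise.
#'
#' @inheritParams group_means
#' @param min_step Passed to [classify_trajectory()].
#' @return Tibble with `feature_id`, `label`, and the per-timepoint means.
#' @export
trajectory_labels <- function(x, design, min_step = 0) {
  gm <- group_means(x, design)
  vals <- as.matrix(gm[-1])
  gm$label <- apply(vals, 1, classify_trajectory, min_step = min_step)
  dplyr::relocate(gm, "label", .after = "feature_id")
}

#' Cluster features into trajectory modules
#'
#' Features are reduced to per-timepoint group means, z-scored per feature
#' (zero-variance rows map to all-zero profiles), then clustered by
#' hierarchical clustering with Ward linkage on Euclidean distances and cut
#' at `k` modules. Duplicated profiles have distance zero and always land in
#' the same module.
#'
#' @inheritParams group_means
#' @param k Number of modules (>= 2, <= number of features).
#' @return Tibble with `feature_id`, `module` (integer in `1..k`).
#' @export
cluster_modules <- function(x, design, k) {
  gm <- group_means(x, design)
  n <- nrow(gm)
  if (k < 2 || k > n) stop("`k` must be in [2, n_features]", call. = FALSE)
  vals <- as.matrix(gm[-1])
  z <- t(apply(vals, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  tibble::tibble(feature_id = gm$feature_id,
                 module = unname(stats::cutree(hc, k = k)))
}

#' Select senescence-associated features
#'
#' A feature is senescence-associated (RS) when it is both differentially
#' changed versus the reference passage and its per-timepoint trajectory is
#' strictly monotone: `rs_up` features are selected and monotone up, `rs_down`
#' selected and monotone down. The two sets are disjoint by construction.
#'
#' @param diff A `senomics_da` object from [test_differential()].
#' @param labels Tibble from [trajectory_labels()] over the same features.
#' @return Tibble with `feature_id`, `selected`, `label`, `rs` in
#'   `{"up","down","none"}`.
#' @export
select_rs_features <- function(diff, labels) {
  stopifnot(inherits(diff, "senomics_da"))
  joined <- dplyr::inner_join(diff$selected, labels[c("feature_id", "label")],
                              by = "feature_id")
  if (nrow(joined) != nrow(diff$selected)) {
    stop("`diff` and `labels` must cover the same features", call. = FALSE)
  }
  joined |>
    dplyr::mutate(rs = dplyr::case_when(
      .data$selected & .data$label == "monotone_up" ~ "up",
      .data$selected & .data$label == "monotone_down" ~ "down",
      TRUE ~ "none"
    ))
}
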