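#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix A 4-by-L numeric matrix of base probabilities with rows
#'   A, C, G, T; every column must sum to 1 (tolerance 1e-6) and L >= 4.
#'   A count matrix is accepted and normalized per column.
#' @param family Optional TF family label.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, matrix, family = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4)
  if (ncol(matrix) < 4) stop("PWM length must be >= 4", call. = FALSE)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  cs <- colSums(matrix)
  if (any(cs <= 0)) stop("PWM has a zero column", call. = FALSE)
  if (any(abs(cs - 1) > 1e-6)) matrix <- sweep(matrix, 2, cs, "/")
  structure(list(name = name, family = family, matrix = matrix), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, if (!is.null(x$family)) paste0("(", x$family, ")"),
      "- length", ncol(x$matrix), "\n")
  invisible(x)
}

#' Read a JASPAR-style plain-text motif library
#'
#' Parses records of the form `>name [family]` followed by four rows
#' `A [ 1 2 3 ... ]` (brackets optional). Count matrices are normalized to
#' probabilities.
#'
#' @param path File path.
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop(path, ": no motif records found", call. = FALSE)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(sub("^>", "", lines[starts[i]])), "[ \t]+")[[1]]
    name <- hdr[1]
    family <- if (length(hdr) > 1) hdr[2] else NULL
    body_end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    body <- lines[(starts[i] + 1):body_end]
    if (length(body) < 4) stop(path, ": motif ", name, " needs 4 base rows", call. = FALSE)
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "[ \t]+")[[1]]
      list(base = parts[1], vals = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop(path, ": motif ", name, " rows must be labelled A, C, G, T", call. = FALSE)
    }
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- bases
    out[[name]] <- pwm(name, m, family = family)
  }
  out
}

#' Write motifs in JASPAR-style text
#' @param pwms A list of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name, if (!is.null(p$family)) paste0(" ", p$family)),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, " [ ", paste(formatC(p$matrix[b, ], format = "f", digits = 4),
                               collapse = " "), " ]")
      }, ""))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

revcomp_pwm_matrix <- function(m) {
  m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  m
}

pwm_score_matrix <- function(m, background) {
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  log2((m + 1e-3) / background)
}

scan_one <- function(seq_chars_idx, smat) {
  L <- ncol(smat)
  W <- length(seq_chars_idx)
  if (W < L) return(numeric(0))
  n_off <- W - L + 1
  scores <- numeric(n_off)
  for (i in seq_len(L)) {
    v <- smat[, i][seq_chars_idx[i:(i + n_off - 1)]]
    v[is.na(v)] <- -Inf
    scores <- scores + v
  }
  unname(scores)
}

#' Scan sequences for PWM matches on both strands
#'
#' Log-odds scoring: each position contributes `log2((p + 1e-3) / bg)` for
#' the observed base, and an offset is a hit when its total score reaches
#' `min_score_fraction` of the maximum attainable score. The reverse strand
#' is scanned with the reverse-complemented matrix; minus-strand hits are
#' reported in forward coordinates. Scanning a sequence and its reverse
#' complement yields mirror-image hit sets with identical scores.
#'
#' @param sequences Named character vector of sequences (or a
#'   `Biostrings::DNAStringSet`); names are the chromosome namespace.
#' @param motif A [pwm()].
#' @param regions Optional interval tibble restricting the scan; regions
#'   shorter than the motif are skipped with a warning. Default: whole
#'   sequences.
#' @param background Base frequencies (A, C, G, T); positive, sum 1.
#' @param min_score_fraction Hit threshold as a fraction of the maximum
#'   score (default 0.8).
#' @return Hit tibble: `chrom`, `start`, `end`, `strand`, `score`, `motif`;
#'   interval length equals the motif length.
#' @export
scan_pwm <- function(sequences, motif, regions = NULL,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     min_score_fraction = 0.8) {
  stopifnot(inherits(motif, "pwm"))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  smat_f <- pwm_score_matrix(motif$matrix, background)
  smat_r <- pwm_score_matrix(revcomp_pwm_matrix(motif$matrix), background)
  max_score <- sum(apply(smat_f, 2, max))
  threshold <- min_score_fraction * max_score
  L <- ncol(motif$matrix)
  if (is.null(regions)) {
    regions <- tibble::tibble(chrom = names(sequences), start = 0L,
                              end = nchar(sequences), strand = "*")
  }
  short <- regions$end - regions$start < L
  if (any(short)) {
    warning(sum(short), " region(s) shorter than the motif skipped")
    regions <- regions[!short, , drop = FALSE]
  }
  hits <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    chrom <- regions$chrom[i]
    s0 <- regions$start[i]
    subseq <- substr(sequences[[chrom]], s0 + 1L, regions$end[i])
    idx <- match(strsplit(subseq, "")[[1]], c("A", "C", "G", "T"))
    fwd <- scan_one(idx, smat_f)
    rev <- scan_one(idx, smat_r)
    hf <- which(fwd >= threshold)
    hr <- which(rev >= threshold)
    tibble::tibble(
      chrom = chrom,
      start = s0 + c(hf, hr) - 1L,
      strand = rep(c("+", "-"), c(length(hf), length(hr))),
      score = c(fwd[hf], rev[hr])
    )
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          score = numeric(), motif = character()))
  }
  hits <- hits |>
    dplyr::mutate(end = .data$start + L, motif = motif$name) |>
    dplyr::select("chrom", "start", "end", "strand", "score", "motif") |>
    dplyr::distinct()
  # a palindromic motif matches both strands at one offset with one score;
  # report such occurrences once, on the plus strand
  plus_key <- with(hits[hits$strand == "+", ], paste(chrom, start, score))
  drop <- hits$strand == "-" &
    paste(hits$chrom, hits$start, hits$score) %in% plus_key
  dplyr::arrange(hits[!drop, ], .data$chrom, .data$start, .data$strand)
}

#' Hypergeometric motif enrichment against a region background
#'
#' For each motif, regions are scored present/absent (a region counts once
#' however many hits it contains). With N background regions of which K
#' contain the motif, and n target regions of which k contain it, the
#' enrichment p-value is the upper hypergeometric tail P(X >= k). P-values
#' are BH-adjusted across motifs and motifs are ranked by adjusted then raw
#' p. The full set of accessibility peaks is the intended background.
#'
#' @param target_regions,background_regions Interval tibbles; the target is
#'   expected to be a subset of the background (a warning is issued if not).
#' @param pwms List of [pwm()] objects.
#' @param sequences Named sequence vector (see [scan_pwm()]).
#' @inheritParams scan_pwm
#' @return An object of class `motif_enrichment` whose `table` has one row
#'   per motif: `motif`, `family`, `k`, `n`, `K`, `N`, `p_value`, `p_adj`,
#'   `rank`.
#' @export
motif_enrichment <- function(target_regions, background_regions, pwms, sequences,
                             background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             min_score_fraction = 0.8) {
  if (nrow(target_regions) == 0 || nrow(background_regions) == 0) {
    stop("target and background region sets must be non-empty", call. = FALSE)
  }
  key <- function(x) paste(x$chrom, x$start, x$end)
  if (!all(key(target_regions) %in% key(background_regions))) {
    warning("target regions are not a subset of the background")
  }
  region_has_motif <- function(regions, motif) {
    h <- scan_pwm(sequences, motif, regions = regions, background = background,
                  min_score_fraction = min_score_fraction)
    if (nrow(h) == 0) return(logical(nrow(regions)))
    ov <- interval_overlaps(regions, h)
    seq_len(nrow(regions)) %in% ov$query
  }
  N <- nrow(background_regions)
  n <- nrow(target_regions)
  tab <- purrr::map_dfr(pwms, function(p) {
    K <- sum(region_has_motif(background_regions, p))
    k <- sum(region_has_motif(target_regions, p))
    tibble::tibble(
      motif = p$name,
      family = if (is.null(p$family)) NA_character_ else p$family,
      k = k, n = n, K = K, N = N,
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- dplyr::arrange(tab, .data$p_adj, .data$p_value)
  tab$rank <- seq_len(nrow(tab))
  structure(list(table = tab), class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat("Motif enrichment:", nrow(x$table), "motifs;",
      sum(x$table$p_adj < 0.05), "at adjusted p < 0.05\n")
  print(as.data.frame(utils::head(x$table, 10)), row.names = FALSE)
  invisible(x)
}

#' @method tidy motif_enrichment
#' @export
tidy.motif_enrichment <- function(x, ...) x$table

#' @method glance motif_enrichment
#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble::tibble(n_motifs = nrow(x$table),
                 n_significant = sum(x$table$p_adj < 0.05),
                 min_p_adj = min(x$table$p_adj))
}

#' Aggregate TF footprint profile around motif hits
#'
#' For every motif hit, the window motif +/- `flank` bp is extracted from the
#' forward- and reverse-strand coverage tracks, the two strands are averaged
#' per position, minus-strand hits are reversed so profiles are
#' motif-oriented, and positions are averaged across hits. A bound factor
#' leaves a dip over the motif body inside an otherwise open region.
#'
#' @param track_fwd,track_rev Forward-/reverse-strand [coverage_track()]s
#'   (library-size normalized).
#' @param hits Hit tibble from [scan_pwm()]; all hits must share one motif
#'   length. At least one in-bounds hit is required.
#' @param flank Bases either side of the motif (default 100).
#' @param chrom_lengths Optional named vector used to drop out-of-bounds
#'   windows; defaults to the track extent.
#' @return An object of class `footprint_profile`: tibble with `position`
#'   (−flank .. L−1+flank relative to motif start) and `coverage`, plus
#'   attributes `motif_length`, `flank`, `n_hits`.
#' @export
footprint_profile <- function(track_fwd, track_rev, hits, flank = 100,
                              chrom_lengths = NULL) {
  if (nrow(hits) == 0) stop("need at least one motif hit", call. = FALSE)
  L <- unique(hits$end - hits$start)
  if (length(L) != 1) stop("hits must share one motif length", call. = FALSE)
  if (is.null(chrom_lengths)) {
    ext <- dplyr::bind_rows(track_fwd, track_rev) |>
      dplyr::summarise(len = max(.data$end), .by = "chrom")
    chrom_lengths <- stats::setNames(ext$len, ext$chrom)
  }
  acc <- numeric(L + 2L * flank)
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(hits))) {
    a <- hits$start[i] - flank
    b <- hits$end[i] + flank
    cl <- chrom_lengths[[hits$chrom[i]]]
    if (is.null(cl) || is.na(cl) || a < 0 || b > cl) {
      skipped <- skipped + 1L
      next
    }
    v <- (coverage_slice(track_fwd, hits$chrom[i], a, b) +
            coverage_slice(track_rev, hits$chrom[i], a, b)) / 2
    if (hits$strand[i] == "-") v <- rev(v)
    acc <- acc + v
    used <- used + 1L
  }
  if (skipped > 0) warning(skipped, " hit window(s) out of chromosome bounds skipped")
  if (used == 0) stop("no in-bounds hits to profile", call. = FALSE)
  out <- tibble::tibble(position = seq(-flank, L - 1L + flank),
                        coverage = acc / used)
  attr(out, "motif_length") <- L
  attr(out, "flank") <- flank
  attr(out, "n_hits") <- used
  class(out) <- c("footprint_profile", class(out))
  out
}

#' Footprint depth of an aggregate profile
#'
#' Depth is the mean coverage over the flanking positions minus the mean over
#' the motif-body positions; a bound factor protects the body from
#' transposition, so deeper dips mean more occupancy.
#'
#' @param profile A [footprint_profile()].
#' @return A single number (flank mean − body mean).
#' @export
footprint_depth <- function(profile) {
  L <- attr(profile, "motif_length")
  body <- profile$position >= 0 & profile$position < L
  mean(profile$coverage[!body]) - mean(profile$coverage[body])
}

#' Change in footprint occupancy between two timepoints
#'
#' A transparent activity statistic: the difference of [footprint_depth()]
#' between two profiles of the same motif. Positive values indicate deeper
#' footprints, i.e. increased occupancy/activity, at the second timepoint.
#'
#' @param profile_t1,profile_t2 [footprint_profile()]s of equal length.
#' @return List with `delta` (= depth(t2) − depth(t1)), `depth_t1`,
#'   `depth_t2`.
#' @export
footprint_activity_delta <- function(profile_t1, profile_t2) {
  if (nrow(profile_t1) != nrow(profile_t2) ||
      attr(profile_t1, "motif_length") != attr(profile_t2, "motif_length")) {
    stop("profiles must have identical length and motif length", call. = FALSE)
  }
  d1 <- footprint_depth(profile_t1)
  d2 <- footprint_depth(profile_t2)
  list(delta = d2 - d1, depth_t1 = d1, depth_t2 = d2)
}

#' Classify TFs as pioneer, settler or migrator factors
#'
#' Applies the chromatin-dependence (CD) / chromatin-opening-index (COI)
#' rule: pioneer factors have CD > 0.45 and COI > 4, settler factors
#' CD > 0.45 and COI <= 4, migrator factors CD <= 0.45. The published rule
#' uses three strict inequalities, leaving the exact boundary values
#' undefined; here boundaries fall to the lesser class (settler / migrator),
#' or to the greater class with `boundary = "greater"`. CD and COI are taken
#' as inputs from an upstream footprint model.
#'
#' @param tf TF names.
#' @param cd,coi Finite numeric vectors of CD and COI values.
#' @param cd_threshold,coi_threshold Class boundaries (defaults 0.45 and 4).
#' @param boundary `"lesser"` (default) or `"greater"`: which side boundary
#'   values fall to.
#' @return Tibble with `tf`, `cd`, `coi`, `class`.
#' @examples
#' classify_tf(c("a", "b", "c"), cd = c(0.5, 0.5, 0.3), coi = c(5, 3, 10))
#' @export
classify_tf <- function(tf, cd, coi, cd_threshold = 0.45, coi_threshold = 4,
                        boundary = c("lesser", "greater")) {
  boundary <- match.arg(boundary)
  if (anyNA(cd) || anyNA(coi) || any(!is.finite(cd)) || any(!is.finite(coi))) {
    stop("`cd` and `coi` must be finite", call. = FALSE)
  }
  high_cd <- if (boundary == "lesser") cd > cd_threshold else cd >= cd_threshold
  high_coi <- if (boundary == "lesser") coi > coi_threshold else coi >= coi_threshold
  tibble::tibble(
    tf = as.character(tf), cd = cd, coi = coi,
    class = dplyr::case_when(
      high_cd & high_coi ~ "pioneer",
      high_cd ~ "settler",
      TRUE ~ "migrator"
    )
  )
}
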