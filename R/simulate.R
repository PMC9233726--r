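#' Configuration for the synthetic multi-omic study
#'
#' One seeded configuration drives every generator. The defaults emulate the
#' study design the package targets: four ordered passages (P1, P3, P5, P7);
#' expression with 4 replicates per passage, negative-binomial counts and
#' planted monotone genes at one doubling per passage step; methylation with
#' 3 independent replicate series and planted adjacent-passage deltas of
#' +0.10 (increasing) and −0.04 (decreasing); accessibility with 4 replicates
#' at the first passage and 3 thereafter, scheduled appearing/disappearing
#' peaks, planted motif occurrences and footprint dips.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param timepoint_labels Ordered passage labels.
#' @param n_genes,n_up,n_down,step_log2fc,dispersion,expr_reps Expression
#'   generator: gene count, planted monotone-up/-down counts, per-step log2
#'   fold change, NB dispersion, replicates per passage.
#' @param n_cytosines,n_dms_up,n_dms_down,delta_up_step,delta_down_step,
#'   n_series,meth_depth,depth_mode Methylome generator: cytosine count,
#'   planted DMS counts, per-step level deltas, series count, mean read
#'   depth, and `"binomial"` (sampled reads) or `"exact"` (deterministic
#'   high-depth) noise mode.
#' @param genome_length,gc,n_genome_genes,tss_spacing Genome generator.
#' @param atac_reps Replicates per passage for accessibility (default
#'   `c(4, 3, 3, 3)`).
#' @param n_peaks,peak_width,n_appear,n_disappear,presence_p,absence_p,
#'   peak_height,bg_height Accessibility generator: total peaks, width,
#'   scheduled appearances/disappearances per later passage, presence
#'   probability when scheduled present/absent, enrichment and background
#'   coverage heights.
#' @param motif_consensus,n_motif_peaks,bound_fraction,footprint_dip
#'   Footprint generator: planted consensus, number of peaks carrying a
#'   motif instance, per-passage bound fraction, multiplicative body dip for
#'   a bound instance.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       timepoint_labels = c("P1", "P3", "P5", "P7"),
                       n_genes = 5000, n_up = 200, n_down = 200,
                       step_log2fc = 1, dispersion = 0.1, expr_reps = 4,
                       n_cytosines = 2000, n_dms_up = 60, n_dms_down = 60,
                       delta_up_step = 0.10, delta_down_step = 0.04,
                       n_series = 3, meth_depth = 30,
                       depth_mode = c("binomial", "exact"),
                       genome_length = 100000, gc = 0.5,
                       n_genome_genes = 30, tss_spacing = 3000,
                       atac_reps = c(4, 3, 3, 3),
                       n_peaks = 60, peak_width = 400,
                       n_appear = 8, n_disappear = 8,
                       presence_p = 0.95, absence_p = 0.05,
                       peak_height = 10, bg_height = 1,
                       motif_consensus = "TGACTCATCG",
                       decoy_consensus = c("CACGTGACCA", "GGGATTCCGG",
                                           "TTATCAGCTA"),
                       n_motif_peaks = 20,
                       bound_fraction = c(0.2, 0.4, 0.6, 0.8),
                       footprint_dip = 0.5) {
  depth_mode <- match.arg(depth_mode)
  T_ <- length(timepoint_labels)
  stopifnot(T_ >= 2, length(atac_reps) == T_, length(bound_fraction) == T_)
  fracs <- c(presence_p, absence_p, gc, bound_fraction, footprint_dip)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (0.1 + (T_ - 1) * delta_up_step > 1 || 0.6 - (T_ - 1) * delta_down_step < 0) {
    stop("planted methylation deltas escape [0,1] over the time course", call. = FALSE)
  }
  if (genome_length < 10000) stop("genome length must be >= 10 kb", call. = FALSE)
  if ((n_genome_genes + 1) * tss_spacing > genome_length) {
    stop("too many genes for the genome length", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$T_ <- NULL
  class(cfg) <- "sim_config"
  cfg
}

sub_seed <- function(config, offset) (config$seed * 101L + offset) %% 2147483647L

#' Simulate a random genome with spaced gene models
#'
#' Sequence bases are drawn i.i.d. at the configured GC content; gene TSSs
#' are laid out on a regular grid with at least `tss_spacing` bp between
#' neighbours (always at least twice the promoter flank used downstream) and
#' random strands.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character, one chromosome `chrS`)
#'   and `genes` (gene-model tibble).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(sub_seed(config, 1L), {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seq <- paste(sample(names(p), config$genome_length, replace = TRUE, prob = p),
                 collapse = "")
    tss <- as.integer(seq(config$tss_spacing, by = config$tss_spacing,
                          length.out = config$n_genome_genes))
    genes <- tibble::tibble(
      gene_id = sprintf("gene_%03d", seq_len(config$n_genome_genes)),
      chrom = "chrS",
      strand = sample(c("+", "-"), config$n_genome_genes, replace = TRUE),
      tss = tss
    )
    list(sequences = c(chrS = seq), genes = genes)
  })
}

#' Simulate a time-course expression count table with planted monotone genes
#'
#' Null genes keep a constant negative-binomial mean over passages; planted
#' genes multiply their mean by `2^step_log2fc` (up) or `2^-step_log2fc`
#' (down) at each passage step. Baseline means are log-normal.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (feature-by-sample tibble), `design`
#'   ([sample_design()]) and `truth` (tibble: `feature_id`, `label`).
#' @export
simulate_expression <- function(config) {
  withr::with_seed(sub_seed(config, 2L), {
    tps <- config$timepoint_labels
    T_ <- length(tps)
    design <- sample_design(
      sample_id = paste0(rep(tps, each = config$expr_reps), "_r",
                         rep(seq_len(config$expr_reps), T_)),
      timepoint = rep(tps, each = config$expr_reps),
      replicate = rep(seq_len(config$expr_reps), T_),
      timepoint_labels = tps
    )
    n <- config$n_genes
    ids <- sprintf("gene_%05d", seq_len(n))
    label <- rep("null", n)
    planted <- sample(n, config$n_up + config$n_down)
    label[planted[seq_len(config$n_up)]] <- "monotone_up"
    label[planted[config$n_up + seq_len(config$n_down)]] <- "monotone_down"
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    step <- ifelse(label == "monotone_up", config$step_log2fc,
                   ifelse(label == "monotone_down", -config$step_log2fc, 0))
    counts <- matrix(0, nrow = n, ncol = nrow(design),
                     dimnames = list(ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- base * 2^(step * design$t_index[j])
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    list(
      counts = dplyr::bind_cols(tibble::tibble(feature_id = ids),
                                tibble::as_tibble(counts)),
      design = design,
      truth = tibble::tibble(feature_id = ids, label = label)
    )
  })
}

#' Simulate per-cytosine methylation calls with planted DMS trajectories
#'
#' Null cytosines hold a constant level drawn uniformly from (0.05, 0.95);
#' planted increasing cytosines start at 0.10 and gain `delta_up_step` per
#' passage; planted decreasing cytosines start at 0.60 and lose
#' `delta_down_step` per passage, in every series. Observed methylated reads
#' are Binomial(depth, level) per sample (`depth_mode = "binomial"`), or the
#' rounded expectation at depth 10000 (`"exact"`, for noise-free recovery
#' checks).
#'
#' @param config A [sim_config()].
#' @return List with `calls` (methylation-call tibble over all samples),
#'   `design` (series-structured [sample_design()]) and `truth` (tibble:
#'   `chrom`, `pos`, `label`).
#' @export
simulate_methylome <- function(config) {
  withr::with_seed(sub_seed(config, 3L), {
    tps <- config$timepoint_labels
    T_ <- length(tps)
    S <- config$n_series
    design <- sample_design(
      sample_id = paste0("M_", rep(tps, each = S), "_s", rep(seq_len(S), T_)),
      timepoint = rep(tps, each = S),
      replicate = rep(seq_len(S), T_),
      series = paste0("series", rep(seq_len(S), T_)),
      timepoint_labels = tps
    )
    n <- config$n_cytosines
    pos <- sort(sample.int(config$genome_length - 1L, n))
    label <- rep("null", n)
    planted <- sample(n, config$n_dms_up + config$n_dms_down)
    label[planted[seq_len(config$n_dms_up)]] <- "up"
    label[planted[config$n_dms_up + seq_len(config$n_dms_down)]] <- "down"
    base <- stats::runif(n, 0.05, 0.95)
    base[label == "up"] <- 0.10
    base[label == "down"] <- 0.60
    step <- ifelse(label == "up", config$delta_up_step,
                   ifelse(label == "down", -config$delta_down_step, 0))
    calls <- purrr::map_dfr(seq_len(nrow(design)), function(j) {
      level <- pmin(1, pmax(0, base + step * design$t_index[j]))
      if (config$depth_mode == "exact") {
        depth <- rep(10000L, n)
        m <- as.integer(round(level * depth))
      } else {
        depth <- pmax(config$meth_depth %/% 3,
                      stats::rpois(n, config$meth_depth))
        m <- stats::rbinom(n, depth, level)
      }
      tibble::tibble(chrom = "chrS", pos = pos, sample_id = design$sample_id[j],
                     methylated = m, total = depth)
    })
    calls$level <- calls$methylated / calls$total
    list(calls = calls, design = design,
         truth = tibble::tibble(chrom = "chrS", pos = pos, label = label))
  })
}

#' Simulate per-sample peak sets, strand coverage and planted footprints
#'
#' Peaks are laid out without overlap: the first peaks are centred on gene
#' promoters (so promoter annotation has signal), the rest fall between
#' genes. Each peak follows a presence schedule — stable, appearing at a
#' later passage, or disappearing at a later passage — and is observed in a
#' sample with probability `presence_p` when scheduled present and
#' `absence_p` otherwise. Coverage per strand is a flat background plus the
#' peak enrichment for observed peaks; motif instances embedded at the
#' centre of selected stable peaks receive a multiplicative dip over the
#' motif body in samples where the instance is bound (probability =
#' per-passage bound fraction).
#'
#' @param config A [sim_config()].
#' @param genome Result of [simulate_genome()].
#' @return List with `design`, `sample_peaks` (named list of interval
#'   tibbles), `coverage` (per sample: list with `fwd`/`rev`
#'   [coverage_track()]s), `sequences` (genome with embedded motif
#'   instances), `motif` (the planted [pwm()]), `motif_sites` (interval
#'   tibble), and `truth` (per-peak schedule tibble: `chrom`, `start`,
#'   `end`, `schedule`, `event_t`).
#' @export
simulate_accessibility <- function(config, genome) {
  withr::with_seed(sub_seed(config, 4L), {
    tps <- config$timepoint_labels
    T_ <- length(tps)
    design <- sample_design(
      sample_id = unlist(purrr::map2(tps, config$atac_reps, function(tp, r) {
        paste0("A_", tp, "_r", seq_len(r))
      })),
      timepoint = rep(tps, config$atac_reps),
      replicate = unlist(purrr::map(config$atac_reps, seq_len)),
      timepoint_labels = tps
    )
    w <- config$peak_width
    n_prom <- min(config$n_genome_genes, ceiling(config$n_peaks / 2))
    prom_centers <- genome$genes$tss[seq_len(n_prom)]
    n_inter <- config$n_peaks - n_prom
    # intergenic peaks: midway between consecutive TSSs
    gaps <- genome$genes$tss[seq_len(config$n_genome_genes - 1)] +
      round(config$tss_spacing / 2)
    inter_centers <- gaps[seq_len(min(n_inter, length(gaps)))]
    centers <- sort(c(prom_centers, inter_centers))
    n_pk <- length(centers)
    peaks <- tibble::tibble(
      chrom = "chrS",
      start = as.integer(centers - w / 2),
      end = as.integer(centers + w / 2)
    )
    # presence schedule
    schedule <- rep("stable", n_pk)
    event_t <- rep(NA_integer_, n_pk)
    movable <- sample(n_pk, config$n_appear + config$n_disappear)
    app <- movable[seq_len(config$n_appear)]
    dis <- movable[config$n_appear + seq_len(config$n_disappear)]
    schedule[app] <- "appearing"
    schedule[dis] <- "disappearing"
    event_t[app] <- sample(seq_len(T_ - 1), config$n_appear, replace = TRUE)
    event_t[dis] <- sample(seq_len(T_ - 1), config$n_disappear, replace = TRUE)
    scheduled_present <- function(i, t) {
      switch(schedule[i],
             stable = TRUE,
             appearing = t >= event_t[i],
             disappearing = t < event_t[i])
    }
    # motif instances embedded at peak centres: every appearing peak carries
    # one (so appearing-peak enrichment has signal), the rest go to stable
    # peaks (so footprints can be profiled across all passages)
    consensus <- config$motif_consensus
    Lm <- nchar(consensus)
    stable_idx <- which(schedule == "stable")
    motif_idx <- c(app,
                   stable_idx[seq_len(min(max(0, config$n_motif_peaks - length(app)),
                                          length(stable_idx)))])
    seqs <- genome$sequences
    motif_sites <- tibble::tibble(
      chrom = "chrS",
      start = as.integer(centers[motif_idx] - floor(Lm / 2)),
      end = as.integer(centers[motif_idx] - floor(Lm / 2) + Lm),
      strand = "+"
    )
    chr <- seqs[["chrS"]]
    for (i in seq_len(nrow(motif_sites))) {
      substr(chr, motif_sites$start[i] + 1L, motif_sites$end[i]) <- consensus
    }
    seqs[["chrS"]] <- chr
    consensus_pwm <- function(name, cons) {
      pm <- matrix(0.01, nrow = 4, ncol = nchar(cons),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
      for (i in seq_len(nchar(cons))) pm[substr(cons, i, i), i] <- 0.97
      pwm(name, pm, family = "synthetic")
    }
    planted_pwm <- consensus_pwm("planted_motif", consensus)
    pwm_library <- c(list(planted_pwm),
                     purrr::imap(config$decoy_consensus, function(cons, i) {
                       consensus_pwm(paste0("decoy_", i), cons)
                     }))
    names(pwm_library) <- vapply(pwm_library, `[[`, "", "name")
    # per-sample peaks and coverage
    glen <- config$genome_length
    sample_peaks <- list()
    coverage <- list()
    for (j in seq_len(nrow(design))) {
      t <- design$t_index[j]
      obs <- vapply(seq_len(n_pk), function(i) {
        p <- if (scheduled_present(i, t)) config$presence_p else config$absence_p
        stats::runif(1) < p
      }, TRUE)
      jitter <- sample(-5:5, n_pk, replace = TRUE)
      sp <- peaks[obs, ]
      sp$start <- sp$start + jitter[obs]
      sp$end <- sp$end + jitter[obs]
      sample_peaks[[design$sample_id[j]]] <- sp
      cov <- rep(config$bg_height, glen)
      for (i in which(obs)) {
        cov[(peaks$start[i] + 1):peaks$end[i]] <- config$bg_height + config$peak_height
      }
      bf <- config$bound_fraction[t + 1]
      for (k in seq_len(nrow(motif_sites))) {
        i_pk <- motif_idx[k]
        if (obs[i_pk] && stats::runif(1) < bf) {
          body <- (motif_sites$start[k] + 1):motif_sites$end[k]
          cov[body] <- cov[body] * (1 - config$footprint_dip)
        }
      }
      # multiplicative noise on 50-bp blocks (locally correlated, keeps the
      # run-length encoding compact)
      nblk <- ceiling(glen / 50)
      noise_f <- rep(stats::rnorm(nblk, 1, 0.02), each = 50)[seq_len(glen)]
      noise_r <- rep(stats::rnorm(nblk, 1, 0.02), each = 50)[seq_len(glen)]
      coverage[[design$sample_id[j]]] <- list(
        fwd = vector_to_track(pmax(0, cov * noise_f), "chrS", "+"),
        rev = vector_to_track(pmax(0, cov * noise_r), "chrS", "-")
      )
    }
    truth <- dplyr::bind_cols(peaks, tibble::tibble(schedule = schedule,
                                                    event_t = event_t))
    list(design = design, sample_peaks = sample_peaks, coverage = coverage,
         sequences = seqs, motif = planted_pwm, pwm_library = pwm_library,
         motif_sites = motif_sites, truth = truth)
  })
}

#' Run-length encode a per-base signal vector into a coverage track
#'
#' @param values Non-negative per-base values for one chromosome (position 0
#'   onward).
#' @param chrom Chromosome name.
#' @param strand_tag Optional strand tag.
#' @return A [coverage_track()].
#' @export
vector_to_track <- function(values, chrom, strand_tag = NULL) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  coverage_track(
    tibble::tibble(chrom = chrom, start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]), value = r$values[keep]),
    strand_tag = strand_tag
  )
}

#' Simulate the full synthetic study
#'
#' Runs all generators off one configuration; sub-streams are seeded by fixed
#' offsets so the generators do not perturb each other.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `expression`, `methylome`, `accessibility`,
#'   and the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  list(
    genome = genome,
    expression = simulate_expression(config),
    methylome = simulate_methylome(config),
    accessibility = simulate_accessibility(config, genome),
    config = config
  )
}

#' Write a simulated study to disk in standard formats
#'
#' Emits FASTA (genome), TSV (gene models, counts, designs, methylation
#' calls, truth tables), BED (per-sample peaks, motif sites), bedGraph
#' (per-sample strand coverage) and JASPAR text (planted motif), plus a
#' manifest JSON listing every file and the configuration. Given the same
#' configuration the files are byte-identical across runs.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- function(...) file.path(outdir, ...)
  fa <- Biostrings::DNAStringSet(sim$accessibility$sequences)
  Biostrings::writeXStringSet(fa, p("genome.fa"))
  paths$genome_fasta <- "genome.fa"
  readr::write_tsv(sim$genome$genes, p("gene_models.tsv"))
  paths$gene_models <- "gene_models.tsv"
  write_counts_table(sim$expression$counts, p("expression_counts.tsv"))
  readr::write_tsv(as.data.frame(sim$expression$design)[
    c("sample_id", "timepoint", "replicate", "series")], p("expression_design.tsv"))
  readr::write_tsv(sim$expression$truth, p("expression_truth.tsv"))
  paths$expression <- c("expression_counts.tsv", "expression_design.tsv",
                        "expression_truth.tsv")
  readr::write_tsv(sim$methylome$calls[
    c("chrom", "pos", "sample_id", "methylated", "total")],
    p("methylation_calls.tsv"))
  readr::write_tsv(as.data.frame(sim$methylome$design)[
    c("sample_id", "timepoint", "replicate", "series")], p("methylation_design.tsv"))
  readr::write_tsv(sim$methylome$truth, p("methylation_truth.tsv"))
  paths$methylome <- c("methylation_calls.tsv", "methylation_design.tsv",
                       "methylation_truth.tsv")
  dir.create(p("peaks"), showWarnings = FALSE)
  dir.create(p("coverage"), showWarnings = FALSE)
  acc <- sim$accessibility
  for (sid in names(acc$sample_peaks)) {
    write_bed(acc$sample_peaks[[sid]], p("peaks", paste0(sid, ".bed")))
    write_coverage(acc$coverage[[sid]]$fwd,
                   p("coverage", paste0(sid, "_fwd.bedgraph")))
    write_coverage(acc$coverage[[sid]]$rev,
                   p("coverage", paste0(sid, "_rev.bedgraph")))
  }
  readr::write_tsv(as.data.frame(acc$design)[
    c("sample_id", "timepoint", "replicate", "series")], p("atac_design.tsv"))
  readr::write_tsv(acc$truth, p("peak_truth.tsv"))
  write_bed(acc$motif_sites, p("motif_sites.bed"))
  write_jaspar(acc$pwm_library, p("motifs.jaspar"))
  paths$accessibility <- c("atac_design.tsv", "peak_truth.tsv",
                           "motif_sites.bed", "motifs.jaspar",
                           "peaks/", "coverage/")
  manifest <- list(config = unclass(sim$config), files = paths)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(p("manifest.json"))
}
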