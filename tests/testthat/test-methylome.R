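test_that("methylation level is the simple read ratio with validated inputs", {
  expect_equal(methylation_level(3, 10), 0.3)
  expect_equal(methylation_level(0, 7), 0)
  expect_equal(methylation_level(7, 7), 1)
  expect_equal(methylation_level(c(1, 2), c(4, 8)), c(0.25, 0.25))
  expect_error(methylation_level(1, 0), ">= 1")
  expect_error(methylation_level(5, 3), "<= total")
})

test_that("region mean methylation averages member cytosines, never fabricates 0", {
  calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 100L),
                          level = c(0.2, 0.4, 0.9), total = c(10L, 30L, 10L))
  regions <- genomic_intervals("chr1", c(0L, 50L), c(30L, 60L))
  got <- region_mean_methylation(calls, regions)
  expect_equal(got[1], 0.3)
  expect_true(is.na(got[2]))
  # weighted variant respects coverage
  w <- region_mean_methylation(calls, regions, weighted = TRUE)
  expect_equal(w[1], (0.2 * 10 + 0.4 * 30) / 40)
  # mean is bounded by member levels
  expect_true(got[1] >= 0.2 && got[1] <= 0.4)
})

test_that("DMS calling applies the strict adjacent-delta rule in every series", {
  up <- array(rep(c(0.1, 0.2, 0.3, 0.4), each = 3), dim = c(1, 3, 4))
  expect_equal(identify_dms(make_trajectories(up))$direction, "up")
  # one series with a 0.04 step fails the 0.05 threshold
  mixed <- up
  mixed[1, 1, ] <- c(0.10, 0.14, 0.30, 0.40)
  expect_equal(nrow(identify_dms(make_trajectories(mixed))), 0)
  down <- array(rep(c(0.50, 0.46, 0.42, 0.38), each = 3), dim = c(1, 3, 4))
  expect_equal(identify_dms(make_trajectories(down))$direction, "down")
  expect_error(identify_dms(make_trajectories(up), delta_up = 0), "positive")
})

test_that("DMS calls match the exhaustive per-cytosine loop oracle exactly", {
  set.seed(31)
  n <- 1000
  lv <- array(runif(n * 3 * 4), dim = c(n, 3, 4))
  # sprinkle planted monotone cytosines of both directions
  for (i in 1:50) lv[i, , ] <- matrix(rep(0.1 + 0.12 * (0:3), each = 3), 3)
  for (i in 51:100) lv[i, , ] <- matrix(rep(0.8 - 0.05 * (0:3), each = 3), 3)
  traj <- make_trajectories(lv)
  got <- identify_dms(traj, delta_up = 0.05, delta_down = 0.03)
  # independent oracle: plain loops over cytosines, series, steps
  oracle_dir <- character(0)
  oracle_pos <- integer(0)
  positions <- seq_len(n) * 10L
  for (i in seq_len(n)) {
    up_ok <- TRUE
    down_ok <- TRUE
    for (s in 1:3) {
      for (t in 1:3) {
        d <- lv[i, s, t + 1] - lv[i, s, t]
        if (!(d > 0.05)) up_ok <- FALSE
        if (!(d < -0.03)) down_ok <- FALSE
      }
    }
    if (up_ok || down_ok) {
      oracle_pos <- c(oracle_pos, positions[i])
      oracle_dir <- c(oracle_dir, if (up_ok) "up" else "down")
    }
  }
  o <- order(oracle_pos)
  expect_identical(got$pos, oracle_pos[o])
  expect_identical(got$direction, oracle_dir[o])
  # disjoint directions, and shrinking deltas only grow the called set
  expect_equal(anyDuplicated(got[c("chrom", "pos")]), 0)
  looser <- identify_dms(traj, delta_up = 0.02, delta_down = 0.01)
  expect_true(all(got$pos %in% looser$pos))
})

test_that("coverage-incomplete cytosines are excluded from trajectories", {
  cfg <- sim_config(seed = 5, n_cytosines = 50, n_dms_up = 5, n_dms_down = 5)
  sim <- simulate_methylome(cfg)
  calls <- sim$calls
  # drop one sample's calls for the first cytosine, starve another below coverage
  drop_pos <- sort(unique(calls$pos))[1]
  starve_pos <- sort(unique(calls$pos))[2]
  calls <- calls[!(calls$pos == drop_pos & calls$sample_id == calls$sample_id[1]), ]
  calls$total[calls$pos == starve_pos] <- 2L
  calls$methylated[calls$pos == starve_pos] <- 1L
  traj <- methylation_trajectories(calls, sim$design, min_coverage = 5)
  expect_false(drop_pos %in% traj$pos)
  expect_false(starve_pos %in% traj$pos)
  # retained cytosines cover the full series x timepoint grid
  cnt <- dplyr::count(traj, pos)
  expect_true(all(cnt$n == 12))
})

test_that("TFBS methylation trend test is calibrated and powered", {
  design <- make_design(T_ = 4, reps = 1)
  tfbs <- genomic_intervals("chr1", seq(0, by = 100, length.out = 150) + 0L,
                            seq(0, by = 100, length.out = 150) + 50L)
  gen_calls <- function(shift_per_t) {
    purrr::map_dfr(seq_len(nrow(design)), function(j) {
      t <- design$t_index[j]
      pos <- as.integer(tfbs$start + 10)
      lvl <- pmin(0.95, pmax(0.05, rnorm(150, 0.4 + shift_per_t * t, 0.08)))
      n <- 50L
      m <- rbinom(150, n, lvl)
      tibble::tibble(chrom = "chr1", pos = pos, sample_id = design$sample_id[j],
                     methylated = m, total = rep(n, 150))
    })
  }
  set.seed(32)
  null_p <- replicate(60, tfbs_methylation_trend(tfbs, gen_calls(0), design)$anova$p_value)
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)
  power_p <- replicate(20, tfbs_methylation_trend(tfbs, gen_calls(0.05), design)$anova$p_value)
  expect_gte(mean(power_p < 0.01), 0.95)
  # degenerate identical values give p = 1; single timepoint errors
  flat <- gen_calls(0)
  flat$methylated <- as.integer(flat$total / 2)
  expect_equal(tfbs_methylation_trend(tfbs, flat, design)$anova$p_value, 1)
  one_tp <- flat[flat$sample_id == design$sample_id[1], ]
  expect_error(tfbs_methylation_trend(tfbs, one_tp, design), ">= 2 timepoints")
})

test_that("DMR-to-gene mapping follows half-open +/-5 kb windows and the brute-force oracle", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000L)
  dmr_in <- genomic_intervals("chr1", 9000, 9100)
  dmr_out <- genomic_intervals("chr1", 15000, 15100)
  expect_equal(dmr_to_genes(dmr_in, genes)$gene_id, "g1")
  expect_equal(nrow(dmr_to_genes(dmr_out, genes)), 0)
  set.seed(33)
  genes_r <- tibble::tibble(gene_id = sprintf("g%03d", 1:80), chrom = "chr1",
                            strand = sample(c("+", "-"), 80, TRUE),
                            tss = sample.int(50000, 80))
  dmrs_r <- random_intervals(120, max_pos = 50000, max_width = 500)
  got <- dmr_to_genes(dmrs_r, genes_r, flank = 5000)
  brute <- purrr::map_dfr(seq_len(nrow(dmrs_r)), function(i) {
    hits <- purrr::keep(seq_len(nrow(genes_r)), function(j) {
      lo <- max(0, genes_r$tss[j] - 5000)
      hi <- genes_r$tss[j] + 5000
      dmrs_r$start[i] < hi && lo < dmrs_r$end[i]
    })
    if (length(hits) == 0) return(NULL)
    tibble::tibble(dmr = i, gene_id = genes_r$gene_id[hits])
  })
  expect_equal(got, dplyr::arrange(brute, dmr, gene_id))
})

test_that("DMS merging groups same-direction neighbours within the gap", {
  dms <- tibble::tibble(chrom = "chr1", pos = c(100L, 150L), direction = "up")
  got <- merge_dms_to_regions(dms, max_gap = 100)
  expect_equal(got[c("start", "end", "n_sites")],
               tibble::tibble(start = 100L, end = 151L, n_sites = 2L))
  mixed <- tibble::tibble(chrom = "chr1", pos = c(100L, 150L),
                          direction = c("up", "down"))
  expect_equal(nrow(merge_dms_to_regions(mixed, max_gap = 100)), 2)
  far <- tibble::tibble(chrom = "chr1", pos = c(100L, 400L), direction = "up")
  expect_equal(nrow(merge_dms_to_regions(far, max_gap = 100)), 2)
  expect_equal(nrow(merge_dms_to_regions(dms[0, ], 100)), 0)
})
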