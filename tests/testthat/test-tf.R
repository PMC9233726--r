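one_hot_pwm <- function(name, cons) {
  m <- matrix(1e-9, nrow = 4, ncol = nchar(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nchar(cons))) m[substr(cons, i, i), i] <- 1
  pwm(name, m)
}

revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("PWM construction validates and JASPAR text round-trips", {
  m <- matrix(c(10, 0, 0, 0), nrow = 4, ncol = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("polyA", m)
  expect_equal(colSums(p$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_error(pwm("short", m[, 1:3, drop = FALSE]), ">= 4")
  path <- withr::local_tempfile(fileext = ".jaspar")
  lib <- list(a = pwm("motif_a", matrix(c(0.7, 0.1, 0.1, 0.1), 4, 5,
                                        dimnames = list(c("A", "C", "G", "T"), NULL)),
                      family = "famX"))
  write_jaspar(lib, path)
  back <- read_jaspar(path)
  expect_equal(back$motif_a$matrix, lib$a$matrix, tolerance = 1e-3)
  expect_equal(back$motif_a$family, "famX")
})

test_that("PWM scanning finds consensus occurrences on both strands", {
  p <- one_hot_pwm("acgt", "ACGT")
  seqs <- c(chr1 = "TTTTTACGTTTTT")
  hits <- scan_pwm(seqs, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$strand, "+")
  # maximal score at the consensus
  smax <- sum(apply(log2((p$matrix + 1e-3) / 0.25), 2, max))
  expect_equal(hits$score, smax)
  # reverse complement of ACGT is ACGT itself; use an asymmetric motif
  q <- one_hot_pwm("acgg", "ACGG")
  rc_seq <- c(chr1 = paste0("TTTTT", revcomp("ACGG"), "TTTT"))
  rhits <- scan_pwm(rc_seq, q)
  expect_equal(rhits$strand, "-")
  expect_equal(rhits$start, 5L)
  expect_equal(nrow(scan_pwm(c(chr1 = "TTTTTTTTTT"), q)), 0)
  expect_warning(scan_pwm(seqs, q, regions = genomic_intervals("chr1", 0, 3)),
                 "shorter")
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(51)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  p <- one_hot_pwm("m", "ACGGTA")
  h_f <- scan_pwm(c(chr = s), p, min_score_fraction = 0.6)
  h_r <- scan_pwm(c(chr = revcomp(s)), p, min_score_fraction = 0.6)
  expect_equal(nrow(h_f), nrow(h_r))
  # positions mirror: start' = len - end
  expect_equal(sort(500L - h_f$end), sort(h_r$start))
  expect_equal(sort(h_f$score), sort(h_r$score))
})

test_that("motif hit sets agree with Biostrings matchPWM on plus-strand consensus hits", {
  set.seed(52)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  cons <- "TGACTCA"
  m <- matrix(0.02, 4, nchar(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nchar(cons))) m[substr(cons, i, i), i] <- 0.94
  p <- pwm("jun", m)
  got <- scan_pwm(c(chr = s), p, min_score_fraction = 0.9)
  got_plus <- got[got$strand == "+", ]
  counts <- round(m * 100)
  storage.mode(counts) <- "integer"
  ref <- Biostrings::matchPWM(Biostrings::PWM(counts,
                                              prior.params = c(A = 0.25, C = 0.25,
                                                               G = 0.25, T = 0.25)),
                              s, min.score = "90%")
  expect_setequal(got_plus$start, BiocGenerics::start(ref) - 1L)
})

test_that("hypergeometric enrichment matches the exhaustive tail-sum oracle", {
  set.seed(53)
  # construct regions over a sequence where the motif is planted in the
  # first 10 of 100 background regions, and the target is exactly those 10
  cons <- "ACGGTCAA"
  blocks <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  }, "")
  blocks[1:10] <- vapply(blocks[1:10], function(b) {
    paste0(substr(b, 1, 10), cons, substr(b, 19, 30))
  }, "")
  genome <- c(chr = paste(blocks, collapse = ""))
  regions <- genomic_intervals("chr", (0:99) * 30L, (0:99) * 30L + 30L)
  p <- one_hot_pwm("planted", cons)
  enr <- motif_enrichment(regions[1:10, ], regions, list(p), genome)
  tab <- tidy(enr)
  expect_equal(tab$k, 10)
  expect_equal(tab$K, 10)
  # independent oracle: direct combinatorial tail sum
  tail_sum <- sum(vapply(10:10, function(i) {
    choose(10, i) * choose(90, 10 - i) / choose(100, 10)
  }, numeric(1)))
  expect_equal(tab$p_value, tail_sum, tolerance = 1e-10)
  expect_equal(tab$p_value, 1 / choose(100, 10), tolerance = 1e-10)
  # motif present in every background region gives p = 1
  all_m <- genomic_intervals("chr", (0:9) * 30L, (0:9) * 30L + 30L)
  enr_all <- motif_enrichment(all_m[1:3, ], all_m, list(p), genome)
  expect_equal(tidy(enr_all)$p_value, 1)
  expect_error(motif_enrichment(regions[0, ], regions, list(p), genome),
               "non-empty")
  expect_warning(
    motif_enrichment(genomic_intervals("chr", 1L, 31L), regions, list(p), genome),
    "subset"
  )
})

test_that("enrichment p-values are null-uniform and detect planted enrichment", {
  set.seed(54)
  cons <- "ACGGTCAA"
  p <- one_hot_pwm("planted", cons)
  make_tabs <- function(rate_target, rate_bg, n_runs) {
    purrr::map_dfr(seq_len(n_runs), function(r) {
      blocks <- vapply(1:60, function(i) {
        paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
      }, "")
      has <- c(runif(20) < rate_target, runif(40) < rate_bg)
      blocks[has] <- vapply(blocks[has], function(b) {
        paste0(substr(b, 1, 10), cons, substr(b, 19, 30))
      }, "")
      genome <- c(chr = paste(blocks, collapse = ""))
      regions <- genomic_intervals("chr", (0:59) * 30L, (0:59) * 30L + 30L)
      tidy(motif_enrichment(regions[1:20, ], regions, list(p), genome))
    })
  }
  tabs <- make_tabs(0.4, 0.4, 300)
  # the exact tail p of a discrete count is super-uniform; its randomized
  # transform p - U * P(X = k) is exactly Uniform(0,1) under the null
  p_rand <- tabs$p_value -
    runif(nrow(tabs)) * dhyper(tabs$k, tabs$K, tabs$N - tabs$K, tabs$n)
  expect_gt(stats::ks.test(p_rand, "punif")$p.value, 0.01)
  # and the raw p is never anti-conservative
  expect_gte(mean(tabs$p_value < 0.05), 0)
  expect_lte(mean(tabs$p_value < 0.05), 0.08)
  strong_p <- make_tabs(0.9, 0.18, 20)$p_value  # ~5x planted enrichment
  expect_gte(mean(p.adjust(strong_p, "BH") < 0.05), 0.9)
})

test_that("footprint profiles are flat on constant coverage and show planted dips", {
  glen <- 2000L
  flat_fwd <- vector_to_track(rep(3, glen), "chr")
  flat_rev <- vector_to_track(rep(3, glen), "chr")
  hits <- tibble::tibble(chrom = "chr", start = c(500L, 1200L),
                         end = c(510L, 1210L), strand = c("+", "-"),
                         score = 1, motif = "m")
  prof <- footprint_profile(flat_fwd, flat_rev, hits, flank = 100)
  expect_equal(nrow(prof), 210)
  expect_true(all(prof$coverage == 3))
  expect_equal(footprint_depth(prof), 0)
  # 50% dip over every motif body
  cov <- rep(10, glen)
  for (s in c(500L, 1200L)) cov[(s + 1):(s + 10)] <- 5
  dip_f <- vector_to_track(cov, "chr")
  prof_dip <- footprint_profile(dip_f, dip_f, hits, flank = 100)
  body <- prof_dip$position >= 0 & prof_dip$position < 10
  ratio <- mean(prof_dip$coverage[body]) / mean(prof_dip$coverage[!body])
  expect_equal(ratio, 0.5, tolerance = 0.05)
  # invariant to hit order and strand-track swap
  prof_swap <- footprint_profile(flat_rev, flat_fwd, hits[2:1, ], flank = 100)
  expect_equal(prof_swap$coverage, prof$coverage)
  # out-of-bounds hits are skipped with a warning; zero hits error
  edge <- dplyr::bind_rows(hits, tibble::tibble(chrom = "chr", start = 10L,
                                                end = 20L, strand = "+",
                                                score = 1, motif = "m"))
  expect_warning(pe <- footprint_profile(flat_fwd, flat_rev, edge, flank = 100),
                 "out of chromosome bounds")
  expect_equal(attr(pe, "n_hits"), 2L)
  expect_error(footprint_profile(flat_fwd, flat_rev, hits[0, ]), "at least one")
})

test_that("footprint activity delta tracks occupancy differences", {
  glen <- 1000L
  hits <- tibble::tibble(chrom = "chr", start = 400L, end = 410L,
                         strand = "+", score = 1, motif = "m")
  mk_prof <- function(dip) {
    cov <- rep(8, glen)
    cov[401:410] <- 8 * (1 - dip)
    tr <- vector_to_track(cov, "chr")
    footprint_profile(tr, tr, hits, flank = 100)
  }
  same <- footprint_activity_delta(mk_prof(0.3), mk_prof(0.3))
  expect_equal(same$delta, 0)
  deeper <- footprint_activity_delta(mk_prof(0.1), mk_prof(0.6))
  expect_gt(deeper$delta, 0)
  flat <- footprint_activity_delta(mk_prof(0), mk_prof(0))
  expect_equal(flat$depth_t1, 0)
  expect_equal(flat$delta, 0)
  short <- mk_prof(0.3)[1:100, ]
  attr(short, "motif_length") <- 10L
  expect_error(footprint_activity_delta(mk_prof(0.3), short), "identical length")
})

test_that("TF classification partitions the CD/COI plane per the three-rule definition", {
  expect_equal(classify_tf("a", 0.50, 5.0)$class, "pioneer")
  expect_equal(classify_tf("b", 0.50, 3.0)$class, "settler")
  expect_equal(classify_tf("c", 0.30, 10.0)$class, "migrator")
  # exhaustive grid including the boundary values 0.45 and 4
  grid <- expand.grid(cd = c(0, 0.2, 0.44, 0.45, 0.46, 0.7, 1),
                      coi = c(0, 2, 3.99, 4, 4.01, 6, 10))
  got <- classify_tf(sprintf("tf%02d", seq_len(nrow(grid))), grid$cd, grid$coi)
  ref <- ifelse(grid$cd > 0.45 & grid$coi > 4, "pioneer",
                ifelse(grid$cd > 0.45, "settler", "migrator"))
  expect_equal(got$class, ref)
  expect_true(all(table(got$class) > 0))
  # every finite point gets exactly one class
  expect_equal(sum(is.na(got$class)), 0)
  # boundary policy flips with the configurable rule
  greater <- classify_tf("x", 0.45, 4, boundary = "greater")
  expect_equal(greater$class, "pioneer")
  expect_error(classify_tf("y", NaN, 1), "finite")
})
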