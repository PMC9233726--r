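# brute-force oracle for the atlas rule: per-base union regions, then strict
# group-presence counting

test_that("the atlas presence rule is strictly greater-than 60%", {
  design <- make_design(T_ = 2, reps = 4, labels = c("P1", "P3"))
  pk <- function(ids) {
    tibble::tibble(chrom = "chr1", start = 100L, end = 300L, sample_id = ids)
  }
  # 3 of 4 replicates in one group (0.75) retains
  a <- build_atlas(pk(c("P1_r1", "P1_r2", "P1_r3")), design)
  expect_equal(nrow(a$peaks), 1)
  # 2 of 4 (0.50) in every group drops
  b <- build_atlas(pk(c("P1_r1", "P1_r2", "P3_r1", "P3_r2")), design)
  expect_equal(nrow(b$peaks), 0)
  # 2 of 3 (0.667) retains
  design3 <- make_design(T_ = 2, reps = 3, labels = c("P5", "P7"))
  c3 <- build_atlas(pk(c("P5_r1", "P5_r2")), design3)
  expect_equal(nrow(c3$peaks), 1)
  # exactly 3 of 5 (0.60) fails the strict rule
  design5 <- make_design(T_ = 2, reps = 5, labels = c("P1", "P3"))
  d5 <- build_atlas(pk(c("P1_r1", "P1_r2", "P1_r3")), design5)
  expect_equal(nrow(d5$peaks), 0)
  expect_error(build_atlas(pk("P1_r1"), design, min_fraction = 1.2), "strictly")
})

test_that("build_atlas equals the brute-force oracle and is order-invariant", {
  design <- make_design(T_ = 4, reps = 3)
  set.seed(41)
  for (rep in 1:3) {
    peak_tbl <- purrr::map_dfr(design$sample_id, function(sid) {
      n <- 200 %/% nrow(design) + sample(0:3, 1)
      p <- random_intervals(n, max_pos = 5500, max_width = 300)
      p$sample_id <- sid
      p
    })
    atlas <- build_atlas(peak_tbl, design)
    oracle <- atlas_oracle(peak_tbl, design, 0.6)
    expect_equal(atlas$peaks$start, oracle$start)
    expect_equal(atlas$peaks$end, oracle$end)
    # invariance to sample order
    shuffled <- peak_tbl[sample.int(nrow(peak_tbl)), ]
    atlas2 <- build_atlas(shuffled, design)
    expect_equal(atlas2$peaks, atlas$peaks)
    # retained set shrinks as min_fraction rises
    stricter <- build_atlas(peak_tbl, design, min_fraction = 0.8)
    expect_true(all(stricter$peaks$start %in% atlas$peaks$start))
    expect_lte(nrow(stricter$peaks), nrow(atlas$peaks))
  }
})

test_that("MA open/closed counting restricts to high-coverage peaks", {
  design <- make_design(T_ = 2, reps = 4, labels = c("P1", "P7"))
  set.seed(42)
  n_open <- 30; n_closed <- 60; n_low <- 40
  mk <- function(mu1, mu7, n) {
    t(vapply(seq_len(n), function(i) {
      c(rnorm(4, mu1, mu1 * 0.03), rnorm(4, mu7, mu7 * 0.03))
    }, numeric(8)))
  }
  m <- rbind(
    mk(1000, 2500, n_open),   # clear gain above threshold
    mk(2500, 1000, n_closed), # clear loss above threshold
    mk(300, 900, n_low)       # overall mean (600) below threshold
  )
  sig <- make_counts(pmax(m, 1), design = design)
  res <- ma_high_coverage_counts(sig, design, "P1", "P7", mean_threshold = 800)
  expect_equal(res$n_open, n_open)
  expect_equal(res$n_closed, n_closed)
  expect_lte(res$n_open + res$n_closed, nrow(res$table))
  # a peak with mean 799.9 is excluded; none above threshold gives (0, 0)
  border <- make_counts(matrix(799.9, 1, 8), design = design)
  res0 <- ma_high_coverage_counts(border, design, "P1", "P7")
  expect_equal(c(res0$n_open, res0$n_closed), c(0L, 0L))
  expect_equal(nrow(res0$table), 0)
})

# direct-definition oracle over a presence-fraction matrix

# atlas object with a prescribed presence matrix

test_that("appearing and disappearing peaks follow the stated definitions", {
  design <- make_design(T_ = 4, reps = 4)
  frac_to_presence <- function(frac_rows) {
    t(apply(frac_rows, 1, function(f) {
      unlist(lapply(f, function(p) rep(c(TRUE, FALSE), c(round(p * 4), 4 - round(p * 4)))))
    }))
  }
  fr <- rbind(
    c(0.25, 0.75, 1.0, 1.0),   # appears at t1
    c(0.75, 0.25, 0.75, 0.75), # appears at t0 only (re-gain is not new)
    c(1.0, 1.0, 0.25, 0.25),   # disappears at t2
    c(0.25, 0.25, 0.25, 0.25)  # never present: no events
  )
  atlas <- atlas_from_presence(frac_to_presence(fr), design)
  app <- detect_appearing_peaks(atlas)
  expect_equal(app$t_index[app$peak_id == "peak_00001"], 1L)
  expect_equal(app$t_index[app$peak_id == "peak_00002"], 0L)
  dis <- detect_disappearing_peaks(atlas)
  expect_equal(dis$t_index[dis$peak_id == "peak_00003"], 2L)
  expect_false("peak_00004" %in% c(app$peak_id, dis$peak_id))
  # appearing and disappearing at one timepoint are disjoint
  both <- dplyr::inner_join(app, dis, by = c("peak_id", "t_index"))
  expect_equal(nrow(both), 0)
})

test_that("appearance/disappearance detection equals the definition oracle on random matrices", {
  design <- make_design(T_ = 4, reps = 3)
  set.seed(43)
  for (rep in 1:5) {
    presence <- matrix(runif(40 * 12) < 0.5, nrow = 40)
    atlas <- atlas_from_presence(presence, design)
    frac <- t(apply(presence, 1, function(p) {
      vapply(levels(design$timepoint), function(tp) {
        mean(p[design$timepoint == tp])
      }, numeric(1))
    }))
    for (kind in c("appear", "disappear")) {
      got <- if (kind == "appear") detect_appearing_peaks(atlas) else
        detect_disappearing_peaks(atlas)
      want <- event_oracle(frac, 0.6, kind)
      got$peak <- match(got$peak_id, atlas$peaks$peak_id)
      expect_equal(dplyr::arrange(got[c("peak", "t_index")], peak, t_index),
                   dplyr::arrange(want, peak, t_index), ignore_attr = TRUE)
    }
    # "at_t" mode relaxes only the post-loss requirement
    dis_at <- detect_disappearing_peaks(atlas, mode = "at_t")
    want_at <- event_oracle(frac, 0.6, "disappear", mode = "at_t")
    expect_equal(nrow(dis_at), nrow(want_at))
  }
})

test_that("enhancers are the double-positive histone-mark intersection", {
  k4 <- genomic_intervals("chr1", 0, 100)
  k27 <- genomic_intervals("chr1", 50, 150)
  got <- identify_enhancers(k4, k27)
  expect_equal(got[c("start", "end")], tibble::tibble(start = 50L, end = 100L))
  expect_equal(nrow(identify_enhancers(k4, genomic_intervals("chr1", 200, 300))), 0)
  # result is covered by both inputs
  set.seed(44)
  a <- random_intervals(100); b <- random_intervals(100)
  enh <- identify_enhancers(a, b)
  if (nrow(enh) > 0) {
    cov_a <- base_coverage_set(a, 6000L); cov_b <- base_coverage_set(b, 6000L)
    cov_e <- base_coverage_set(enh, 6000L)
    expect_true(all(!cov_e | (cov_a & cov_b)))
  }
})

test_that("promoter peak annotation is half-open and matches brute force", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000L)
  inside <- genomic_intervals("chr1", 9500, 9900)
  inside$peak_id <- "p1"
  touching <- genomic_intervals("chr1", 11000, 11200)
  touching$peak_id <- "p2"
  ann <- annotate_promoter_peaks(dplyr::bind_rows(inside, touching), genes, flank = 1000)
  expect_equal(ann$peak_id, "p1")
  set.seed(45)
  genes_r <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
                            strand = "+", tss = sample.int(30000, 40))
  peaks_r <- random_intervals(200, max_pos = 30000, max_width = 400)
  peaks_r$peak_id <- sprintf("p%03d", seq_len(nrow(peaks_r)))
  got <- annotate_promoter_peaks(peaks_r, genes_r, flank = 1000)
  brute <- purrr::map_dfr(seq_len(nrow(peaks_r)), function(i) {
    hit <- purrr::keep(seq_len(nrow(genes_r)), function(j) {
      lo <- max(0, genes_r$tss[j] - 1000); hi <- genes_r$tss[j] + 1000
      peaks_r$start[i] < hi && lo < peaks_r$end[i]
    })
    if (length(hit) == 0) return(NULL)
    tibble::tibble(peak_id = peaks_r$peak_id[i], gene_id = genes_r$gene_id[hit])
  })
  expect_equal(got, dplyr::arrange(brute, peak_id, gene_id))
})

test_that("promoter shift test is calibrated under the null and detects planted shifts", {
  make_instance <- function(shift) {
    # 200 genes per regulated class against the full gene universe
    n <- 200
    n_all <- 2400
    all_ids <- sprintf("g%04d", seq_len(n_all))
    up <- all_ids[1:n]; down <- all_ids[(n + 1):(2 * n)]
    ann <- tibble::tibble(peak_id = sprintf("pk%04d", seq_len(n_all)),
                          gene_id = all_ids)
    lfc <- tibble::tibble(
      peak_id = ann$peak_id,
      log2_fc = rnorm(n_all) + c(rep(shift, n), rep(0, n_all - n))
    )
    promoter_shift_test(lfc, up, down, all_ids, ann)
  }
  set.seed(46)
  null_p <- replicate(60, make_instance(0)$tests$p_value[1])
  expect_gte(mean(null_p >= 1e-3), 0.95)
  power_p <- replicate(40, make_instance(0.5)$tests$p_value[1])
  expect_gte(mean(power_p < 1e-3), 0.95)
  # a single-peak class is a hard error naming the class
  tiny_ann <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                             gene_id = c("u1", "a1", "a2"))
  tiny_lfc <- tibble::tibble(peak_id = c("p1", "p2", "p3"), log2_fc = c(1, 0, 0))
  expect_error(promoter_shift_test(tiny_lfc, "u1", c("a1", "a2"), c("u1", "a1", "a2"),
                                   tiny_ann), "'up'")
})
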