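test_that("mapping_stats reports percentages of the initial count", {
  r <- make_reads(character(0), numeric(0), numeric(0))
  s <- mapping_stats(r, 10)
  expect_equal(c(s$pct_mapped, s$pct_unique, s$pct_repeated), c(0, 0, 0))

  r <- make_reads(rep("chr1", 4), 0:3 * 100, 0:3 * 100 + 50,
                  c("unique", "unique", "unique", "repeated"))
  s <- mapping_stats(r, 5)
  expect_equal(s$n_mapped, 4)
  expect_equal(s$pct_mapped, 80)
  expect_equal(s$pct_unique, 60)
  expect_equal(s$pct_repeated, 20)

  expect_error(mapping_stats(r, 0), "undefined")
  expect_error(mapping_stats_from_counts(3, 2, 2), "exceed")
  # unique + repeated adds up to mapped within rounding
  s <- mapping_stats_from_counts(997, 700, 211)
  expect_lt(abs(s$pct_unique + s$pct_repeated - s$pct_mapped), 0.011)
})

test_that("scale factor is the exact control/IP ratio with 2-dp display", {
  expect_equal(compute_scale_factor(100, 100)$value, 1)
  expect_equal(compute_scale_factor(300, 100)$value, 3)
  expect_equal(compute_scale_factor(300, 100)$display, "3.00")
  expect_error(compute_scale_factor(100, 0), "> 0")
  # scale symmetry: sf(a,b) * sf(b,a) = 1 (to double precision)
  set.seed(1)
  for (i in 1:20) {
    a <- sample(1e7, 1); b <- sample(1e7, 1)
    expect_equal(compute_scale_factor(a, b)$value *
                   compute_scale_factor(b, a)$value, 1, tolerance = 1e-14)
  }
})

test_that("make_windows follows the 100/50 overlapping-grid rule", {
  g <- make_windows(c(chrA = 200), 100, 50)
  expect_equal(g$windows$start, c(0, 50, 100))
  expect_equal(g$windows$end, c(100, 150, 200))
  expect_equal(nrow(make_windows(c(c1 = 100))$windows), 1)
  # shorter than width: single truncated window [0, L)
  g80 <- make_windows(c(c1 = 80))
  expect_equal(g80$windows[, c("start", "end")],
               data.frame(start = 0, end = 80))
  expect_equal(nrow(make_windows(stats::setNames(numeric(0), character(0)))$windows), 0)
  expect_error(make_windows(c(c1 = 100), width = 50, step = 60))
})

test_that("count_reads uses any-overlap semantics and class filters", {
  g <- make_windows(c(chrA = 200), 100, 50)
  r <- make_reads("chrA", 60, 110)        # overlaps all 3 windows
  expect_equal(as.vector(count_reads(g, r)), c(1, 1, 1))
  expect_equal(as.vector(count_reads(g, r[0, ])), c(0, 0, 0))
  expect_equal(as.vector(count_reads(g, r, "repeated_only")), c(0, 0, 0))
  # off-grid reads are skipped and tallied
  r2 <- make_reads(c("chrA", "chrZ"), c(0, 0), c(50, 50))
  cnt <- count_reads(g, r2)
  expect_equal(attr(cnt, "skipped"), 1)
  expect_equal(as.vector(cnt), c(1, 0, 0))
})

test_that("count_reads equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(300:5000, 1)
    g <- make_windows(c(chr1 = L), 100, 50)
    n <- sample(1:120, 1)
    st <- sample(0:(L - 50), n, replace = TRUE)
    r <- make_reads("chr1", st, st + 50,
                    sample(c("unique", "repeated"), n, replace = TRUE))
    cf <- sample(c("all", "unique_only", "repeated_only"), 1)
    expect_equal(as.vector(count_reads(g, r, cf)), brute_count(g, r, cf))
  }
})

test_that("count conservation: window-count total equals per-read overlaps", {
  set.seed(11)
  L <- 4000
  g <- make_windows(c(chr1 = L))
  st <- sample(0:(L - 50), 500, replace = TRUE)
  r <- make_reads("chr1", st, st + 50)
  per_read <- vapply(seq_len(nrow(r)), function(i)
    sum(r$start[i] < g$windows$end & g$windows$start < r$end[i]), numeric(1))
  expect_equal(sum(count_reads(g, r)), sum(per_read))
})

test_that("window_scores applies scaling and double-sided pseudocounts", {
  expect_equal(window_scores(10, 5, 1.62), 16.2 / 5)
  expect_equal(window_scores(0, 0, 1.62), 1)
  expect_equal(window_scores(10, 0, 1.62), 16.2)
  expect_equal(window_scores(0, 10, 1.62), 0.1)   # IP zero -> numerator 1
  expect_error(window_scores(1:3, 1:2, 1), "lengths")
})

test_that("score is monotone in IP (up) and control (down)", {
  ip <- 0:60
  expect_true(all(diff(window_scores(ip, rep(7, 61), 1.3)) >= 0))
  ct <- 0:60
  expect_true(all(diff(window_scores(rep(9, 61), ct, 1.3)) <= 0))
})

test_that("call_peaks merges abutting seeds and rescores the area", {
  # windows [0,100) and [50,150) both score 2; [100,200) scores 1
  g <- make_windows(c(chr1 = 400))
  ip <- make_reads("chr1", c(10, 95, 300), c(60, 145, 350))
  ct <- make_reads("chr1", 300, 350)
  pk <- call_peaks(g, ip, ct, scale = 1, threshold = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 0)
  expect_equal(pk$end, 150)   # overlapping seeds merged into their union
  # area rescoring counts each read once even across seed windows
  expect_equal(pk$reads_ip, 2)
  expect_equal(pk$reads_control, 0)
  expect_equal(pk$score, 2)
  # nothing above threshold -> empty set
  expect_equal(nrow(call_peaks(g, ct, ct, scale = 1, threshold = 50)), 0)
})

test_that("call_peaks recovers a planted enriched region", {
  sim <- plant_peaks_and_motif(generate_genome(small_sim_config(7)))
  reads <- simulate_reads(sim)
  g <- make_windows(sim$chrom_lengths)
  pk <- call_peaks(g, reads$ip, reads$control)
  hits <- peaks_hit_truth(pk, sim$truth)
  expect_true(all(hits))
})

test_that("rank_peaks sorts by score with the stated tie-break", {
  pk <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(100, 50, 0), end = c(200, 150, 100),
                   score = c(3, 15, 4), stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  rk <- rank_peaks(pk)
  expect_equal(rk$score, c(15, 4, 3))
  expect_equal(rk$rank, 1:3)
  # equal scores: chr1:50 before chr1:100
  tie <- pk; tie$score <- c(5, 5, 1)
  rk <- rank_peaks(tie)
  expect_equal(rk$start[1:2], c(50, 100))
  one <- rank_peaks(pk[1, ])
  expect_equal(one$rank, 1)
})
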