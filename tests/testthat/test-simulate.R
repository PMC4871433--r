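test_that("generators are deterministic per seed (byte-identical files)", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_dataset(small_sim_config(99), d1)
  simulate_dataset(small_sim_config(99), d2)
  for (f in c("genome.fa", "features.tsv", "ip.bed", "control.bed",
              "truth.tsv", "ct.csv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the genome
  d3 <- file.path(tempdir(), "simC")
  simulate_dataset(small_sim_config(100), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("generated world matches its own truth table", {
  sim <- plant_peaks_and_motif(generate_genome(small_sim_config(55)))
  # catalog: featured blocks only (4 of 5 classes), strands present
  expect_equal(nrow(sim$catalog), 4)
  expect_true(all(sim$catalog$strand %in% c("+", "-")))
  # planted motif instance is really in the genome at the recorded offset
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    got <- substr(sim$genome[[tr$chrom]], tr$motif_start + 1,
                  tr$motif_start + nchar(tr$motif_instance))
    expect_equal(got, tr$motif_instance)
    # and the instance matches the degenerate motif pattern
    expect_equal(motif_match_count(tr$motif_instance, "ANAGAAGTGG"), 10L)
  }
})

test_that("zero-gene config yields an empty catalog", {
  cfg <- simulation_config(
    seed = 1,
    peak_spec = data.frame(location_class = c("I", "I"), fold = 8,
                           width = 300),
    repeat_family = list(n_copies = 0, copy_length = 500, divergence = 0.02),
    lnc_every = 0)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$catalog), 0)
  expect_equal(nrow(sim$truth), 2)
})

test_that("repeat copies stay near-identical at 2% divergence", {
  sim <- generate_genome(small_sim_config(7))
  copies <- vapply(seq_len(nrow(sim$repeats)), function(k)
    substr(sim$genome[[sim$repeats$chrom[k]]], sim$repeats$start[k] + 1,
           sim$repeats$end[k]), character(1))
  base <- strsplit(copies[1], "")[[1]]
  for (k in 2:length(copies)) {
    other <- strsplit(copies[k], "")[[1]]
    expect_gte(mean(base == other), 0.95)
  }
})

test_that("repeated-read labels equal repeat-copy origins (conservation)", {
  sim <- plant_peaks_and_motif(generate_genome(small_sim_config(12)))
  reads <- simulate_reads(sim)
  for (track in reads) {
    expect_identical(track$mapping_class == "repeated", track$origin_repeat)
    # relocated reads still lie inside a repeat copy
    rep_reads <- track[track$origin_repeat, , drop = FALSE]
    if (nrow(rep_reads)) {
      inside <- vapply(seq_len(nrow(rep_reads)), function(i)
        any(sim$repeats$chrom == rep_reads$chrom[i] &
              rep_reads$start[i] >= sim$repeats$start &
              rep_reads$start[i] < sim$repeats$end), logical(1))
      expect_true(all(inside))
    }
    expect_gt(nrow(rep_reads), 0)
  }
})

test_that("planted fold-8 peaks show > 4x IP/control window ratio", {
  for (seed in 1:5) {
    sim <- plant_peaks_and_motif(generate_genome(small_sim_config(200 + seed)))
    reads <- simulate_reads(sim)
    grid <- make_windows(sim$chrom_lengths)
    ipc <- count_reads(grid, reads$ip)
    ctc <- count_reads(grid, reads$control)
    w <- grid$windows
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      inpeak <- w$chrom == tr$chrom & w$start >= tr$start & w$end <= tr$end
      expect_gt(mean(ipc[inpeak]) / mean(pmax(ctc[inpeak], 1)), 4)
    }
  }
})

test_that("fold-1 world leaves IP and control indistinguishable", {
  cfg <- small_sim_config(31, fold = 1)
  sim <- plant_peaks_and_motif(generate_genome(cfg))
  reads <- simulate_reads(sim)
  grid <- make_windows(sim$chrom_lengths)
  ipc <- as.vector(count_reads(grid, reads$ip))
  ctc <- as.vector(count_reads(grid, reads$control))
  # every 3rd window: counts 150 bp apart share no 50 nt read, so the
  # rank test sees independent observations
  keep <- grid$windows$start %% 150 == 0
  p <- stats::wilcox.test(ipc[keep], ctc[keep])$p.value
  expect_gt(p, 0.01)
})

test_that("near-zero depth still produces parseable files", {
  d <- file.path(tempdir(), "simTiny")
  cfg <- simulation_config(
    seed = 3,
    peak_spec = data.frame(location_class = "O", fold = 8, width = 300),
    window_depth = 1e-4,
    repeat_family = list(n_copies = 1, copy_length = 500, divergence = 0.02))
  simulate_dataset(cfg, d)
  expect_s3_class(read_alignments(file.path(d, "ip.bed"), "bed"),
                  "data.frame")
  expect_s3_class(read_features(file.path(d, "features.tsv"), "tsv"),
                  "feature_catalog")
})

test_that("end-to-end recovery on the small world across seeds", {
  # module-scale version of the full round trip: 6 seeds, 5 planted peaks
  hit <- cls_ok <- total <- 0
  motif_ok <- 0
  for (seed in 301:306) {
    sim <- plant_peaks_and_motif(generate_genome(small_sim_config(seed)))
    reads <- simulate_reads(sim)
    grid <- make_windows(sim$chrom_lengths)
    pk <- rank_peaks(call_peaks(grid, reads$ip, reads$control))
    ann <- annotate_peaks(pk, sim$catalog)
    hits <- peaks_hit_truth(ann, sim$truth)
    total <- total + nrow(sim$truth)
    hit <- hit + sum(hits)
    for (i in which(hits)) {
      j <- which(ann$chrom == sim$truth$chrom[i] &
                   ann$start < sim$truth$end[i] &
                   ann$end > sim$truth$start[i])[1]
      if (ann$location_class[j] == sim$truth$intended_class[i])
        cls_ok <- cls_ok + 1
    }
    # top-K with K = number of planted peaks (the fold-8 peaks outscore
    # null fluctuations, so these are the planted sites)
    seqs <- peak_sequences(utils::head(ann, nrow(sim$truth)), sim$genome)
    m <- discover_motif(seqs[nchar(seqs) >= 10], width = 10)
    if (motif_match_count(m$consensus, "ANAGAAGTGG") >= 8)
      motif_ok <- motif_ok + 1
  }
  expect_gte(hit / total, 0.9)
  expect_gte(cls_ok / hit, 0.8)
  expect_gte(motif_ok, 5)   # planted word recovered in >= 5 of 6 seeds
})
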