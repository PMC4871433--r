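test_that("nearest_feature geometry: overlap, upstream sign, boundary", {
  cat <- make_catalog("chr1", 50000, 60000, "+")
  # peak inside the gene body
  nf <- nearest_feature(list(chrom = "chr1", start = 52000, end = 52300), cat)
  expect_equal(nf$distance, 0)
  expect_equal(nf$feature$feature_id, "f001")
  # peak ending 10 kb before the only '+' TSS: distance -10000 (upstream)
  nf <- nearest_feature(list(chrom = "chr1", start = 39700, end = 40000), cat)
  expect_equal(nf$distance, -10000)
  expect_equal(nf$distance_to_tss, -10001)  # edge-to-TSS, one past the gap
  # 100,001 bp away -> excluded (inclusive <= 100000 boundary)
  far <- make_catalog("chr1", 200001 + 100000, 200001 + 101000, "+")
  nf <- nearest_feature(list(chrom = "chr1", start = 199000, end = 200000), far)
  expect_null(nf$feature)
  # exactly 100,000 away -> kept
  at <- make_catalog("chr1", 200000 + 100000, 200000 + 101000, "+")
  nf <- nearest_feature(list(chrom = "chr1", start = 199000, end = 200000), at)
  expect_equal(abs(nf$distance), 100000)
  # absent chromosome
  nf <- nearest_feature(list(chrom = "chrZ", start = 0, end = 100), cat)
  expect_null(nf$feature)
})

test_that("nearest_feature agrees with the brute-force scan", {
  set.seed(202)
  n_feat <- 80
  st <- sample(0:500000, n_feat)
  cat <- make_catalog(sample(c("chr1", "chr2"), n_feat, TRUE), st,
                      st + sample(500:5000, n_feat, TRUE),
                      sample(c("+", "-"), n_feat, TRUE),
                      sample(c("protein_coding", "lncRNA", "other"),
                             n_feat, TRUE))
  for (i in 1:300) {
    ps <- sample(0:500000, 1)
    peak <- list(chrom = sample(c("chr1", "chr2"), 1), start = ps,
                 end = ps + sample(100:550, 1))
    got <- nearest_feature(peak, cat)
    want <- brute_nearest(peak, cat)
    if (is.null(want)) {
      expect_null(got$feature)
    } else {
      expect_equal(got$feature$feature_id, cat$feature_id[want$i])
      expect_equal(abs(got$distance), want$gap)
    }
  }
})

test_that("classify_location follows TSS > O > DU/DD > I precedence", {
  cat <- make_catalog("chr1", 100000, 180000, "+")   # TSS at 100000
  peak <- function(s, e) list(chrom = "chr1", start = s, end = e)
  expect_equal(classify_location(peak(97800, 98000), cat), "TSS")  # 2001 bp
  expect_equal(classify_location(peak(97500, 97501), cat), "TSS")  # 2500 inclusive
  expect_equal(classify_location(peak(97499, 97500), cat), "DU")   # 2501 bp
  expect_equal(classify_location(peak(170000, 170300), cat), "O")  # body, 70 kb in
  expect_equal(classify_location(peak(99000, 101000), cat), "TSS") # overlap + near TSS
  expect_equal(classify_location(peak(50000, 50300), cat), "DU")
  expect_equal(classify_location(peak(200000, 200300), cat), "DD")
  expect_equal(classify_location(peak(300000, 300300), cat), "I")  # > 100 kb
  expect_equal(classify_location(list(chrom = "chrZ", start = 0, end = 100),
                                 cat), "I")
  # minus strand mirrors: TSS at end-1, downstream to the left
  catm <- make_catalog("chr1", 100000, 180000, "-")
  expect_equal(classify_location(peak(181000, 181300), catm), "TSS")
  expect_equal(classify_location(peak(200000, 200300), catm), "DU")
  expect_equal(classify_location(peak(50000, 50300), catm), "DD")
})

test_that("location class is invariant under coordinate reflection", {
  set.seed(33)
  M <- 1e6
  for (i in 1:60) {
    fs <- sample(2e5:6e5, 1)
    fe <- fs + sample(2000:50000, 1)
    strand <- sample(c("+", "-"), 1)
    cat <- make_catalog("chr1", fs, fe, strand)
    ps <- sample(0:(M - 400), 1)
    pe <- ps + sample(100:400, 1)
    cls <- classify_location(list(chrom = "chr1", start = ps, end = pe), cat)
    # reflect: x -> M - x, flip strand
    catR <- make_catalog("chr1", M - fe, M - fs,
                         if (strand == "+") "-" else "+")
    clsR <- classify_location(list(chrom = "chr1", start = M - pe,
                                   end = M - ps), catR)
    expect_equal(clsR, cls)
  }
})

test_that("lncrna_tier applies inclusive 5 kb / 100 kb precedence", {
  cat <- make_catalog(rep("chr1", 2), c(100000, 400000),
                      c(102000, 402000), "+",
                      c("lncRNA", "protein_coding"))
  peak <- function(s, e) list(chrom = "chr1", start = s, end = e)
  expect_equal(lncrna_tier(peak(100500, 100800), cat), "lnc_within_5kb")  # overlap
  expect_equal(lncrna_tier(peak(95000, 95300), cat), "lnc_within_5kb")    # gap 4700
  expect_equal(lncrna_tier(peak(49700, 50000), cat), "lnc_within_100kb")  # gap 50000
  expect_equal(lncrna_tier(peak(401000, 401300), cat), "other")           # coding only nearby...
  # no lncRNA in catalog at all -> other
  nolnc <- make_catalog("chr1", 100000, 102000, "+", "protein_coding")
  expect_equal(lncrna_tier(peak(100500, 100800), nolnc), "other")
  # tiers are mutually exclusive by precedence
  expect_false(lncrna_tier(peak(95000, 95300), cat) == "lnc_within_100kb")
})

test_that("summarize_classes partitions annotated peaks exactly", {
  expect_equal(summarize_classes(
    structure(data.frame(chrom = character(), location_class = character(),
                         lnc_tier = character()),
              class = c("peak_set", "data.frame")))$location,
    c(TSS = 0L, O = 0L, DU = 0L, DD = 0L, I = 0L))

  # a 21-peak world constructed as 2 TSS / 8 O / 3 DD / 6 DU / 2 I
  sim <- plant_peaks_and_motif(generate_genome(simulation_config(seed = 23)))
  truth_pk <- sim$truth
  pk <- data.frame(chrom = truth_pk$chrom, start = truth_pk$start,
                   end = truth_pk$end, score = 5, stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  ann <- annotate_peaks(pk, sim$catalog)
  cls <- summarize_classes(ann)
  expect_equal(cls$location,
               c(TSS = 2L, O = 8L, DU = 6L, DD = 3L, I = 2L))
  expect_equal(sum(cls$location), nrow(ann))
  expect_equal(sum(cls$lnc), nrow(ann))
  # every peak got exactly one class matching the generator's intent
  expect_equal(ann$location_class, truth_pk$intended_class)
  expect_equal(ann$lnc_tier, truth_pk$lnc_tier)
})
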