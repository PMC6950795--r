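test_that("signed TSS distances follow the strand convention", {
  # + strand gene with TSS 1000, - strand gene with TSS 1000
  models <- make_models(
    make_tx("GP", "chr1", "+", cbind(1000, 1999)),
    make_tx("GM", "chr1", "-", cbind(1, 1000)))
  man <- make_manifest(c("a", "b", "c"), pos = c(1030, 1120, 1000),
                       genes = c("GP", "GM", "GP"))
  d <- tss_distances(man, models)
  expect_equal(d$nearest_d[d$probe_id == "a"], 30)
  expect_true(all(as.logical(d[d$probe_id == "a",
                               paste0("win_", tss_windows())])))
  # - strand: probe downstream in genome is upstream of the gene
  expect_equal(d$nearest_d[d$probe_id == "b"], -120)
  expect_identical(unname(unlist(d[d$probe_id == "b",
                                   paste0("win_", tss_windows())])),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  # probe exactly at the TSS: d = 0, downstream side
  expect_equal(d$nearest_d[d$probe_id == "c"], 0)
})

test_that("multiple TSSs use the nearest distance with upstream ties", {
  models <- make_models(
    make_tx("G2", "chr1", "+", cbind(1000, 1500)),
    make_tx("G2", "chr1", "+", cbind(5000, 5500)))
  man <- make_manifest(c("x", "y"), pos = c(1400, 3000), genes = "G2")
  d <- tss_distances(man, models)
  expect_equal(d$nearest_d[d$probe_id == "x"], 400)
  expect_equal(d$n_tss[d$probe_id == "x"], 2)
  # 3000 is 2000 downstream of TSS1 and 2000 upstream of TSS2: tie -> upstream
  expect_equal(d$nearest_d[d$probe_id == "y"], -2000)
  # window membership is any-TSS: probe x is within 2000 of both
  expect_true(d[d$probe_id == "x", "win_500"])
})

test_that("chromosome mismatches are skipped and reported", {
  models <- make_models(make_tx("G1", "chr2", "+", cbind(1000, 2000)))
  man <- make_manifest(c("ok", "wrong"), pos = c(1100, 1100),
                       chrom = c("chr2", "chr7"), genes = "G1")
  d <- tss_distances(man, models)
  expect_identical(d$probe_id, "ok")
  expect_identical(attr(d, "skipped"), "wrong")
})

test_that("distance bins are half-open with d = 0 downstream", {
  models <- make_models(make_tx("G1", "chr1", "+", cbind(10000, 20000)))
  pos <- 10000 + c(-50, 0, 49, 50, -1500, -1501, 1999, 2000, 2500)
  man <- make_manifest(sprintf("p%d", seq_along(pos)), pos = pos, genes = "G1")
  d <- tss_distances(man, models)
  diff <- make_diff(man$probe_id, rep("HYPER", nrow(man)),
                    delta = c(0.3, 0.1, 0.3, 0.1, 0.3, 0.1, 0.3, 0.1, 0.3))
  h <- bin_distances(d, diff)
  cnt <- function(bin, col) h[h$bin == bin, col]
  expect_equal(cnt("[-50,0)", "high_count"), 1)   # d = -50
  expect_equal(cnt("[0,50)", "low_count"), 1)     # d = 0
  expect_equal(cnt("[0,50)", "high_count"), 1)    # d = 49
  expect_equal(cnt("[50,100)", "low_count"), 1)   # d = 50
  expect_equal(cnt("[-1500,-1000)", "high_count"), 1)
  expect_equal(cnt("(-Inf,-1500)", "low_count"), 1)
  expect_equal(cnt("[1500,2000)", "high_count"), 1)
  expect_equal(cnt("[2000,Inf)", "low_count"), 1)
  expect_equal(cnt("[2000,Inf)", "high_count"), 1)
  # every defined pair lands in exactly one bin
  expect_equal(sum(h$high_count) + sum(h$low_count), nrow(d))
})

test_that("window counts match brute force and are monotone on random fixtures", {
  set.seed(41)
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    tsss <- sort(sample(5000:15000, sample(1:3, 1)))
    txs <- lapply(tsss, function(t) {
      if (strand == "+") make_tx("G", "chr1", "+", cbind(t, t + 500))
      else make_tx("G", "chr1", "-", cbind(t - 500, t))
    })
    models <- do.call(make_models, txs)
    pos <- sample(3000:17000, 12)
    man <- make_manifest(sprintf("p%02d", 1:12), pos = pos, genes = "G")
    d <- tss_distances(man, models)
    wc <- window_counts(d)
    brute <- vapply(tss_windows(), function(w)
      sum(vapply(pos, brute_window, logical(1), tsss = gene_tss(models, "G"),
                 strand = strand, w = w)), integer(1))
    expect_equal(wc$n_probes, brute)
    expect_true(all(diff(wc$n_probes) >= 0))
    expect_equal(d$nearest_d,
                 vapply(pos, brute_nearest, numeric(1),
                        tsss = gene_tss(models, "G"), strand = strand))
  }
})

test_that("mirroring coordinates and strands preserves |d| and window counts", {
  set.seed(43)
  for (rep in 1:20) {
    tss <- sample(10000:20000, 1)
    pos <- sample(8000:22000, 10)
    mirror <- 30001
    models_f <- make_models(make_tx("G", "chr1", "+", cbind(tss, tss + 800)))
    models_r <- make_models(make_tx("G", "chr1", "-",
                                    cbind(mirror - (tss + 800), mirror - tss)))
    man_f <- make_manifest(sprintf("p%02d", 1:10), pos = pos, genes = "G")
    man_r <- make_manifest(sprintf("p%02d", 1:10), pos = mirror - pos, genes = "G")
    df <- tss_distances(man_f, models_f)
    dr <- tss_distances(man_r, models_r)
    expect_equal(abs(df$nearest_d), abs(dr$nearest_d))
    expect_equal(df$nearest_d, dr$nearest_d)  # signs are strand-aware too
    expect_equal(window_counts(df)$n_probes, window_counts(dr)$n_probes)
  }
})

test_that("CGI summaries count probes, pooled regions and any-region genes", {
  man <- make_manifest(sprintf("p%d", 1:7), pos = 1:7,
                       genes = c("G1", "G1", "G2", "G3", "G3", "G4", "G4"),
                       cgi = c("Island", "None", "N_Shore", "S_Shelf", "None",
                               "None", "None"))
  s <- cgi_summary(man, genes = c("G1", "G2", "G3", "G4"))
  per <- s$per_relation
  expect_equal(per$n_probes[per$cgi_relation == "Island"], 1)
  expect_equal(per$n_probes[per$cgi_relation == "None"], 4)
  pooled <- s$pooled
  expect_equal(pooled$n_probes[pooled$region == "shore"], 1)
  expect_equal(pooled$n_probes[pooled$region == "shelf"], 1)
  # G1 (island), G2 (shore), G3 (shelf) have a feature probe; G4 does not
  expect_equal(s$any_gene_fraction, 3 / 4)
  all_none <- cgi_summary(make_manifest("q1", genes = "G9", cgi = "None"), "G9")
  expect_equal(all_none$any_gene_fraction, 0)
})

test_that("region fractions match brute-force interval checks on a toy gene", {
  # two transcripts of G1: a probe is first-exon if in the first exon of ANY
  tx1 <- make_tx("G1", "chr1", "+", cbind(c(1000, 2000, 3000),
                                          c(1199, 2199, 3499)),
                 cds = c(1100, 3200))
  tx2 <- make_tx("G1", "chr1", "+", cbind(c(2000, 3000), c(2199, 3499)),
                 cds = c(2050, 3200))
  models <- make_models(tx1, tx2)
  pos <- c(1050, 1150, 2100, 2600, 3050, 3300, 5000)
  calls <- c("HYPER", "HYPER", "HYPER", "HYPER", "NS", "NS", "HYPER")
  man <- make_manifest(sprintf("p%d", seq_along(pos)), pos = pos, genes = "G1",
                       in_sparse = FALSE)
  diff <- make_diff(man$probe_id, calls)
  rf <- region_fractions(man, diff, models, "G1")
  get <- function(region, status, col = "fraction") {
    rf[rf$region == region & rf$status == status, col]
  }
  # hyper pairs: 1050 (exon1/utr5 tx1), 1150 (exon1/coding tx1), 2100
  # (exon in both, first exon of tx2, coding in tx2), 2600 (intron tx1,
  # first intron of tx2 gap? no - tx2 intron is 2200-2999), 5000 (outside)
  expect_equal(get("exons", "hyper"), 3 / 5)
  expect_equal(get("5'UTR", "hyper"), 1 / 5)
  expect_equal(get("coding exons", "hyper"), 2 / 5)
  expect_equal(get("introns", "hyper"), 1 / 5)
  expect_equal(get("3'UTR", "hyper"), 0 / 5)
  # first exon: among the 3 exonic hyper pairs, 1050+1150 (tx1 first exon)
  # and 2100 (tx2 first exon) -> all 3
  expect_equal(get("first exon", "hyper"), 1)
  expect_equal(get("first exon", "hyper", "denominator"), 3)
  # first coding exon: coding hyper pairs are 1150 (tx1 first coding) and
  # 2100 (tx2 first coding) -> 2/2
  expect_equal(get("first coding exon", "hyper"), 1)
  # nondiff: 3050 (exon3 tx1 / exon2 tx2, coding), 3300 (3'UTR exon)
  expect_equal(get("exons", "nondiff"), 1)
  expect_equal(get("3'UTR", "nondiff"), 1 / 2)
  expect_equal(get("coding exons", "nondiff"), 1 / 2)
  # 3050 is not the first exon of either transcript
  expect_equal(get("first exon", "nondiff"), 0)
  # first-region count can never exceed the any-region count
  firsts <- rf[grepl("^first", rf$region), ]
  expect_true(all(firsts$count <= firsts$denominator))
})

test_that("probes in the second intron do not count as first intron", {
  tx <- make_tx("G1", "chr1", "+", cbind(c(1000, 2000, 3000),
                                         c(1199, 2199, 3499)))
  models <- make_models(tx)
  man <- make_manifest(c("i1", "i2"), pos = c(1500, 2500), genes = "G1",
                       in_sparse = FALSE)
  diff <- make_diff(c("i1", "i2"), c("HYPER", "HYPER"))
  rf <- region_fractions(man, diff, models, "G1")
  expect_equal(rf$count[rf$region == "introns" & rf$status == "hyper"], 2)
  expect_equal(rf$count[rf$region == "first intron" & rf$status == "hyper"], 1)
  # minus-strand gene: first intron is the genomically last gap
  txm <- make_tx("GM", "chr1", "-", cbind(c(1000, 2000, 3000),
                                          c(1199, 2199, 3499)))
  manm <- make_manifest(c("m1", "m2"), pos = c(1500, 2500), genes = "GM",
                        in_sparse = FALSE)
  rfm <- region_fractions(manm, make_diff(c("m1", "m2"), c("HYPER", "HYPER")),
                          make_models(txm), "GM")
  expect_equal(rfm$count[rfm$region == "first intron" & rfm$status == "hyper"], 1)
})
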