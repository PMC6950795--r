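test_that("config validation rejects impossible settings", {
  expect_error(sim_config(group_fractions = c(UPUP = 0.5, UPDOWN = 0.5,
                                              DOWNUP = 0, DOWNDOWN = 0,
                                              "NULL" = 0.1)), "sum to 1")
  expect_error(sim_config(delta_beta_effect = 0.7), "delta_beta")
  expect_error(sim_config(probes_per_gene_sparse = 5,
                          probes_per_gene_dense = 2), "dense")
  expect_error(generate_cohort(small_config(), generate_truth(small_config()),
                               "nope"), "unknown cohort")
})

test_that("degenerate mixtures plant exactly what they promise", {
  cfg <- small_config(group_fractions = c(UPUP = 1, UPDOWN = 0, DOWNUP = 0,
                                          DOWNDOWN = 0, "NULL" = 0),
                      frac_inconsistent = 0)
  truth <- generate_truth(cfg)
  expect_true(all(truth$genes$group == "UPUP"))
  expect_true(all(truth$probes$direction == "HYPER"))
  expect_true(all(truth$genes$expr_status == "UP"))
  # direction NONE <=> planted delta 0
  cfg2 <- small_config(frac_inconsistent = 0)
  t2 <- generate_truth(cfg2)
  expect_identical(t2$probes$direction == "NONE", t2$probes$planted_delta == 0)
  # no gene mixes directions when frac_inconsistent = 0
  mixed <- tapply(t2$probes$direction, t2$probes$gene,
                  function(d) all(c("HYPER", "HYPO") %in% d))
  expect_false(any(mixed))
})

test_that("inconsistent genes get exactly one opposite probe, on the dense-only set", {
  cfg <- small_config(n_genes = 100, frac_inconsistent = 0.5,
                      group_fractions = c(UPUP = 0.5, UPDOWN = 0.5, DOWNUP = 0,
                                          DOWNDOWN = 0, "NULL" = 0))
  truth <- generate_truth(cfg)
  n_hypo <- tapply(truth$probes$direction == "HYPO", truth$probes$gene, sum)
  expect_identical(sort(unique(as.integer(n_hypo))), c(0L, 1L))
  expect_equal(sum(n_hypo == 1), 50)
  flipped <- truth$probes[truth$probes$direction == "HYPO", ]
  expect_true(all(!flipped$in_sparse))
})

test_that("planted group counts fall within exact binomial 99% bounds", {
  fr <- c(UPUP = 0.2, UPDOWN = 0.3, DOWNUP = 0.1, DOWNDOWN = 0.1, "NULL" = 0.3)
  cfg <- sim_config(seed = 7, n_genes = 200, group_fractions = fr,
                    probes_per_gene_sparse = 1, probes_per_gene_dense = 2,
                    cohorts = data.frame(name = "a", n_cancer = 5, n_normal = 5,
                                         platform = "dense"))
  truth <- generate_truth(cfg)
  counts <- table(factor(truth$genes$group, levels = names(fr)))
  for (g in names(fr)) {
    lo <- qbinom(0.005, 200, fr[[g]])
    hi <- qbinom(0.995, 200, fr[[g]])
    expect_gte(counts[[g]], lo)
    expect_lte(counts[[g]], hi)
  }
})

test_that("cohort generation is deterministic, in range, and cohort-stable", {
  cfg <- small_config()
  truth <- generate_truth(cfg)
  a1 <- generate_cohort(cfg, truth, "a")
  a2 <- generate_cohort(cfg, truth, "a")
  expect_identical(a1$beta, a2$beta)
  expect_identical(a1$samples, a2$samples)
  expect_true(all(a1$beta > 0 & a1$beta < 1))
  expect_false(anyNA(a1$beta))
  # sparse platform exposes only the sparse subset
  expect_identical(rownames(a1$beta),
                   truth$probes$probe_id[truth$probes$in_sparse])
  # per-cohort streams: cohort c unaffected by having generated a and b first
  c_alone <- generate_cohort(cfg, truth, "c")
  b <- generate_cohort(cfg, truth, "b")
  c_after <- generate_cohort(cfg, truth, "c")
  expect_identical(c_alone$beta, c_after$beta)
  expect_identical(rownames(b$beta), truth$probes$probe_id)
})

test_that("whole-study simulation is byte-identical under a fixed seed", {
  cfg <- small_config(n_genes = 30)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  f1 <- sort(list.files(d1))
  expect_true(length(f1) > 5)
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
})

test_that("planted delta-beta is recovered empirically at large n", {
  cfg <- sim_config(seed = 5, n_genes = 40, probes_per_gene_sparse = 2,
                    probes_per_gene_dense = 4,
                    cohorts = data.frame(name = "big", n_cancer = 50,
                                         n_normal = 50, platform = "dense"),
                    group_fractions = c(UPUP = 1, UPDOWN = 0, DOWNUP = 0,
                                        DOWNDOWN = 0, "NULL" = 0),
                    delta_beta_effect = 0.2, beta_noise_sd = 0.1,
                    frac_inconsistent = 0,
                    baseline_shapes = list(c(2, 10), c(2, 10)))
  truth <- generate_truth(cfg)
  co <- generate_cohort(cfg, truth, "big")
  cond <- co$samples$condition[match(colnames(co$beta), co$samples$sample_id)]
  emp <- rowMeans(co$beta[, cond == "cancer"]) -
    rowMeans(co$beta[, cond == "normal"])
  # low-mode baselines keep the +0.2 shift clear of the unit-interval edge
  expect_lt(max(abs(emp - 0.2)), 0.05)
})

test_that("expression coupling hits its target correlation", {
  cfg <- sim_config(seed = 13, n_genes = 60, probes_per_gene_sparse = 2,
                    probes_per_gene_dense = 6,
                    cohorts = data.frame(name = "m", n_cancer = 250,
                                         n_normal = 250, platform = "dense"),
                    group_fractions = c(UPUP = 0.4, UPDOWN = 0.4, DOWNUP = 0,
                                        DOWNDOWN = 0, "NULL" = 0.2),
                    expr_coupling = 0.6, frac_inconsistent = 0)
  truth <- generate_truth(cfg)
  co <- generate_cohort(cfg, truth, "m")
  ex <- generate_expression(cfg, truth, co)
  r_gene <- vapply(truth$genes$gene, function(g) {
    pr <- truth$probes$probe_id[truth$probes$gene == g]
    cor(colMeans(co$beta[pr, , drop = FALSE]), ex$expr[g, ])
  }, numeric(1))
  upup <- truth$genes$group == "UPUP"
  updown <- truth$genes$group == "UPDOWN"
  nullg <- truth$genes$group == "NULL"
  # Fisher-z: at n = 500 the sampling sd of z is ~0.045, so gene-level r
  # stays well inside (0.5, 0.7) around the 0.6 target
  expect_true(all(r_gene[upup] > 0.5 & r_gene[upup] < 0.7))
  expect_true(all(r_gene[updown] < -0.5 & r_gene[updown] > -0.7))
  expect_lt(max(abs(r_gene[nullg])), 0.2)
  expect_lt(abs(median(r_gene[nullg])), 0.05)
  # status table mirrors the planted labels
  expect_identical(ex$status$status, truth$genes$expr_status)
  expect_true(all(ex$status$logFC[ex$status$status == "UP"] > 0))
  expect_true(all(ex$status$logFC[ex$status$status == "DOWN"] < 0))
})

test_that("planted-null probes keep the two-sample test at nominal level", {
  cfg <- sim_config(seed = 17, n_genes = 250, probes_per_gene_sparse = 2,
                    probes_per_gene_dense = 8,
                    cohorts = data.frame(name = "n", n_cancer = 50,
                                         n_normal = 50, platform = "dense"),
                    group_fractions = c(UPUP = 0, UPDOWN = 0, DOWNUP = 0,
                                        DOWNDOWN = 0, "NULL" = 1))
  truth <- generate_truth(cfg)
  co <- generate_cohort(cfg, truth, "n")
  res <- run_cohort(co$beta, co$samples)
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_gte(nrow(res), 2000)
  expect_lt(abs(rate - 0.05), 3 * se)
})
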