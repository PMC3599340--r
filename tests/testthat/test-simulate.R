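test_that("identical seed and config give byte-identical outputs", {
  cfg <- small_sim_cfg(12)
  r1 <- simulate_reference(cfg); r2 <- simulate_reference(cfg)
  expect_identical(r1$fasta, r2$fasta)
  expect_identical(r1$gtf, r2$gtf)
  s1 <- simulate_pair(cfg, r1); s2 <- simulate_pair(cfg, r2)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulation(r1, s1, d1); p2 <- write_simulation(r2, s2, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
  # a different seed changes the world
  s3 <- simulate_pair(small_sim_cfg(13))
  expect_false(identical(as.data.frame(s1$pair$tumor$calls),
                         as.data.frame(s3$pair$tumor$calls)))
})

test_that("simulated reference has valid ORFs and respects n_genes = 0", {
  cfg <- simulation_config(seed = 2, n_chroms = 1, chrom_length = 20000,
                           n_genes = 3)
  ref <- simulate_reference(cfg)
  expect_equal(length(unique(ref$genes$transcript_id)), 3)
  for (tx in unique(ref$genes$transcript_id)) {
    rows <- ref$genes[ref$genes$transcript_id == tx, ]
    cds <- splice_str(ref$genome[[rows$chrom[1]]], rows$cds_start,
                      rows$cds_end)
    if (rows$strand[1] == "-") cds <- revcomp_str(cds)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- translate_str(cds)
    expect_match(aa, "^M[^*]*\\*$")
  }
  ref0 <- simulate_reference(simulation_config(seed = 2, n_chroms = 1,
                                               chrom_length = 20000,
                                               n_genes = 0))
  expect_length(ref0$gtf, 0)
  expect_equal(nchar(ref0$genome[[1]]), 20000)
})

test_that("truth labels are exhaustive and statuses derivable", {
  sim <- simulate_pair(small_sim_cfg(3))
  expect_true(all(sim$truth$label %in%
    c("germline_known", "germline_novel", "somatic", "editing",
      "artifact_lowqual", "artifact_spike", "artifact_onesample",
      "artifact_cluster", "artifact_shared")))
  expect_equal(sim$truth$expected_final_status,
               ifelse(sim$truth$label == "somatic", "tumor_specific",
                      "removed"))
  # planted calls and truth agree: every truth row is called somewhere
  keys <- c(variant_key(sim$pair$tumor$calls),
            variant_key(sim$pair$normal$calls))
  tkeys <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref,
                 sim$truth$alt, sep = ":")
  expect_true(all(tkeys %in% keys))
  # call depths match the coverage tracks
  tc <- sim$pair$tumor$calls
  for (ch in unique(tc$chrom)) {
    sel <- tc$chrom == ch
    expect_equal(tc$depth[sel],
                 coverage_depth(sim$pair$tumor$coverage, ch, tc$pos[sel]))
  }
})

test_that("somatic_rate 0 gives an empty tumor-specific set", {
  sim <- simulate_pair(small_sim_cfg(6, somatic_rate = 0))
  expect_false("somatic" %in% sim$truth$label)
  res <- run_cascade(sim$pair, sim$db)
  expect_equal(nrow(res$tumor_specific), 0)
})

test_that("clean simulation is recovered exactly by the cascade", {
  cfg <- small_sim_cfg(9)
  cfg$artifact_rates <- list(lowqual = 0, spike = 0, onesample = 0,
                             cluster = 0, shared = 0)
  sim <- simulate_pair(cfg)
  res <- run_cascade(sim$pair, sim$db)
  som <- sim$truth[sim$truth$label == "somatic", ]
  expect_setequal(variant_key(res$tumor_specific),
                  paste(som$chrom, som$pos, som$ref, som$alt, sep = ":"))
  ev <- evaluate_against_truth(res$tumor_specific, res$normal_specific,
                               sim$truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
})

test_that("each artifact class dies at its targeted filter", {
  targets <- c(lowqual = "1.1_qual", spike = "1.2_coverage",
               onesample = "2.1_paired_coverage", shared = "2.3_shared",
               cluster = "2.4_local_mismatch")
  base_rates <- list(lowqual = 0, spike = 0, onesample = 0, cluster = 0,
                     shared = 0)
  for (cls in names(targets)) {
    rates <- base_rates
    rates[[cls]] <- 4e-4
    cfg <- small_sim_cfg(20 + match(cls, names(targets)))
    cfg$artifact_rates <- rates
    sim <- simulate_pair(cfg)
    lab <- paste0("artifact_", cls)
    planted <- sim$truth[sim$truth$label == lab, ]
    expect_gt(nrow(planted), 0)
    res <- run_cascade(sim$pair, sim$db)
    # 100% of the class is removed...
    ev <- evaluate_against_truth(res$tumor_specific, res$normal_specific,
                                 sim$truth)
    row <- ev$by_label[ev$by_label$label == lab, ]
    expect_equal(row$removed, row$planted)
    # ...and the targeted tumor-side stage accounts for >= the class size
    rep <- as.data.frame(res$report)
    drop_at <- rep$variants_in[rep$sample == "tumor" &
                                 rep$stage == targets[[cls]]] -
      rep$variants_out[rep$sample == "tumor" & rep$stage == targets[[cls]]]
    expect_gte(drop_at, nrow(planted))
    # somatic recovery is unaffected by the artifact class
    expect_equal(ev$sensitivity, 1)
  }
})

test_that("editing inflates Ti/Tv of the raw callsets across seeds", {
  wins <- 0
  for (seed in 1:10) {
    base <- simulate_pair(small_sim_cfg(100 + seed, editing_rate = 0,
                                        n_genes = 6))
    edit <- simulate_pair(small_sim_cfg(100 + seed, editing_rate = 0.02,
                                        n_genes = 6))
    t_base <- titv_ratio(base$pair$tumor$calls)
    t_edit <- titv_ratio(edit$pair$tumor$calls)
    if (t_edit > t_base) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("evaluate_against_truth degenerate cases", {
  sim <- simulate_pair(small_sim_cfg(31))
  empty <- call_set(sample_id = "x")
  ev <- evaluate_against_truth(empty, empty, sim$truth)
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
})

test_that("unsatisfiable spacing constraints raise an error", {
  cfg <- simulation_config(seed = 1, n_chroms = 1, chrom_length = 1000,
                           n_genes = 0, germline_rate = 0.2,
                           somatic_rate = 0, editing_rate = 0,
                           artifact_rates = list(), db_decoys = 0)
  expect_error(simulate_pair(cfg), "spacing")
})
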