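test_that("quality filter boundary is inclusive at the threshold", {
  cs <- make_cs(pos = 1:4, qual = c(20, 19.99, 80, 0))
  out <- filter_min_quality(cs, 20)
  expect_equal(out$pos, c(1L, 3L))
  expect_equal(nrow(filter_min_quality(call_set(sample_id = "e"), 20)), 0)
})

test_that("coverage-cutoff training is the nearest-rank quantile", {
  db <- known_db(data.frame(chrom = "c", pos = 1:200, ref = "A", alt = "G"))
  cs <- make_cs(chrom = "c", pos = 1:200, depth = 1:200)
  expect_equal(train_coverage_cutoff(cs, db, 0.975), 195L)
  cs30 <- make_cs(chrom = "c", pos = 1:7, depth = rep(30L, 7))
  db7 <- known_db(data.frame(chrom = "c", pos = 1:7, ref = "A", alt = "G"))
  expect_equal(train_coverage_cutoff(cs30, db7, 0.975), 30L)
  cs4 <- make_cs(chrom = "c", pos = 1:4, depth = c(10L, 20L, 30L, 40L))
  db4 <- known_db(data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "G"))
  expect_equal(train_coverage_cutoff(cs4, db4, 0.5), 20L)
  # no known calls -> actionable error
  empty_db <- known_db()
  expect_error(train_coverage_cutoff(cs4, empty_db, 0.975),
               "manual coverage cutoff")
})

test_that("cutoff training matches the sort-based oracle on random vectors", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(c(1:20, 500, 10000), 1)
    depths <- sample.int(300L, n, replace = TRUE)
    q <- runif(1, 0.01, 1)
    cs <- make_cs(chrom = "c", pos = seq_len(n), depth = depths)
    db <- known_db(data.frame(chrom = "c", pos = seq_len(n),
                              ref = "A", alt = "G"))
    expect_equal(train_coverage_cutoff(cs, db, q),
                 as.integer(oracle_quantile(depths, q)))
  }
})

test_that("max-coverage filter keeps depth <= cutoff (47 boundary)", {
  cs <- make_cs(pos = 1:3, depth = c(47L, 48L, 0L))
  expect_equal(filter_max_coverage(cs, 47)$pos, c(1L, 3L))
  expect_equal(filter_max_coverage(cs, 0)$pos, 3L)
})

test_that("paired-coverage filter requires depth in both samples", {
  own <- coverage_track(list(c1 = c(9L, 9L, 9L)))
  other <- coverage_track(list(c1 = c(0L, 1L, 4L)))
  cs <- make_cs(chrom = "c1", pos = 1:3)
  expect_equal(filter_covered_in_both(cs, own, other, 1)$pos, c(2L, 3L))
  expect_equal(filter_covered_in_both(cs, own, other, 5)$pos, integer(0))
})

test_that("known-variant subtraction is allele-aware", {
  db <- known_db(data.frame(chrom = "c1", pos = 10, ref = "A", alt = "G"))
  cs <- make_cs(chrom = "c1", pos = c(10L, 10L, 20L),
                ref = "A", alt = c("G", "T", "G"))
  out <- filter_known_variants(cs, db)
  expect_equal(variant_key(out), c("c1:10:A:T", "c1:20:A:G"))
  expect_equal(nrow(filter_known_variants(cs, known_db())), 3)
  # positional mode removes every call at the position
  expect_equal(variant_key(filter_known_variants(cs, db, positional = TRUE)),
               "c1:20:A:G")
})

test_that("shared-call subtraction is symmetric and exact on the key", {
  a <- make_cs(pos = c(1L, 2L, 3L), sample_id = "t")
  b <- make_cs(pos = c(2L, 3L, 4L), sample_id = "n")
  expect_equal(filter_shared_calls(a, b)$pos, 1L)
  expect_equal(filter_shared_calls(b, a)$pos, 4L)
  shared_removed_from_a <- setdiff(a$pos, filter_shared_calls(a, b)$pos)
  shared_removed_from_b <- setdiff(b$pos, filter_shared_calls(b, a)$pos)
  expect_equal(shared_removed_from_a, shared_removed_from_b)
  expect_equal(nrow(filter_shared_calls(a, a)), 0)
})

test_that("local mismatch stats count neighbors in the +/-flank window", {
  base <- make_cs(pos = c(100L, 97L, 110L, 111L))
  expect_equal(local_mismatch_stats("chr1", 100, base, 10),
               list(count = 2L, rate = 0.1))     # 97 and 110 in window
  expect_equal(local_mismatch_stats("chr1", 300, base, 10),
               list(count = 0L, rate = 0))
  expect_equal(local_mismatch_stats("chr1", 121, base, 10),
               list(count = 1L, rate = 0.05))    # 111 at distance 10
  expect_error(local_mismatch_stats("chr1", 100, base, 0), "positive")
})

test_that("mismatch filter discards rate >= 0.1 OR count >= 2", {
  all_sites <- make_cs(pos = c(100L, 105L, 108L, 500L, 505L, 900L))
  cs <- cs_focus <- make_cs(pos = c(100L, 500L, 900L))
  out <- filter_local_mismatch(cs, all_sites, filter_config())
  # 100 has neighbors {105,108} -> count 2 -> dropped;
  # 500 has one neighbor (rate 0.05) -> kept; 900 isolated -> kept
  expect_equal(out$pos, c(500L, 900L))
})

test_that("each filter matches a brute-force predicate on random callsets", {
  set.seed(99)
  for (i in 1:10) {
    cs <- random_cs(sample(50:200, 1))
    partner <- random_cs(sample(50:150, 1), sample_id = "p")
    db <- known_db(as.data.frame(random_cs(60, sample_id = "d")))
    qmin <- runif(1, 0, 100)
    expect_equal(variant_key(filter_min_quality(cs, qmin)),
                 variant_key(cs)[cs$qual >= qmin])
    cut <- sample(0:80, 1)
    expect_equal(variant_key(filter_max_coverage(cs, cut)),
                 variant_key(cs)[cs$depth <= cut])
    expect_equal(variant_key(filter_known_variants(cs, db)),
                 variant_key(cs)[!variant_key(cs) %in% db$keys])
    expect_equal(variant_key(filter_shared_calls(cs, partner)),
                 setdiff(variant_key(cs), variant_key(partner)))
    cfg <- filter_config(flank = sample(5:15, 1),
                         mismatch_count_max = sample(2:4, 1))
    got <- variant_key(filter_local_mismatch(cs, cs, cfg))
    want <- vapply(seq_len(nrow(cs)), function(j) {
      n <- sum(cs$chrom == cs$chrom[j] &
                 abs(cs$pos - cs$pos[j]) <= cfg$flank &
                 cs$pos != cs$pos[j])
      !(n / (2 * cfg$flank) >= cfg$mismatch_rate_max ||
          n >= cfg$mismatch_count_max)
    }, logical(1))
    expect_equal(got, variant_key(cs)[want])
  }
})

test_that("filters are idempotent and monotone", {
  set.seed(7)
  cs <- random_cs(150)
  db <- known_db(as.data.frame(random_cs(40, sample_id = "d")))
  f1 <- filter_min_quality(cs, 30)
  expect_equal(as.data.frame(filter_min_quality(f1, 30)), as.data.frame(f1))
  f2 <- filter_max_coverage(cs, 40)
  expect_equal(as.data.frame(filter_max_coverage(f2, 40)), as.data.frame(f2))
  f4 <- filter_known_variants(cs, db)
  expect_equal(as.data.frame(filter_known_variants(f4, db)),
               as.data.frame(f4))
  for (f in list(f1, f2, f4))
    expect_true(all(variant_key(f) %in% variant_key(cs)))
})

test_that("run_cascade on an empty pair yields empty outputs and report", {
  pair <- sample_pair(
    tumor = list(calls = call_set(sample_id = "t"),
                 coverage = coverage_track()),
    normal = list(calls = call_set(sample_id = "n"),
                  coverage = coverage_track()))
  res <- run_cascade(pair, known_db())
  expect_equal(nrow(res$tumor_specific), 0)
  expect_equal(nrow(res$normal_specific), 0)
  expect_true(all(res$report$variants_in == 0))
  expect_true(all(res$report$variants_out == 0))
})

test_that("cascade report counts are non-increasing along each sample", {
  sim <- simulate_pair(small_sim_cfg(5))
  res <- run_cascade(sim$pair, sim$db)
  rep <- as.data.frame(res$report)
  for (s in c("tumor", "normal")) {
    r <- rep[rep$sample == s, ]
    expect_true(all(r$variants_out <= r$variants_in))
    # chained: out of one stage equals in of the next
    expect_equal(r$variants_in[-1], r$variants_out[-nrow(r)])
  }
  expect_false(any(is.na(attr(res$report, "cutoffs"))))
})

test_that("germline variants in DB and both tissues never survive", {
  sim <- simulate_pair(small_sim_cfg(8, known_db_fraction = 1))
  res <- run_cascade(sim$pair, sim$db)
  germ <- sim$truth[grepl("germline", sim$truth$label), ]
  keys <- paste(germ$chrom, germ$pos, germ$ref, germ$alt, sep = ":")
  expect_false(any(keys %in% variant_key(res$tumor_specific)))
  expect_false(any(keys %in% variant_key(res$normal_specific)))
})
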