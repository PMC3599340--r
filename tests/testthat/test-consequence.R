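# one shared indexed toy annotation for the file
local_toy_index <- local({
  d <- tempfile(); dir.create(d)
  writeLines(c(">chrT", "ATGGCGTAAGGGTTTAAACCCAAATTTGGG"), file.path(d, "g.fa"))
  at <- 'gene_id "g1"; transcript_id "g1.t1";'
  writeLines(c(paste("chrT", "x", "exon", 1, 12, ".", "+", ".", at, sep = "\t"),
               paste("chrT", "x", "CDS", 1, 9, ".", "+", 0, at, sep = "\t")),
             file.path(d, "g.gtf"))
  function() index_gene_models(file.path(d, "g.gtf"), file.path(d, "g.fa"))
})

test_that("GTF+FASTA indexing reconstructs the CDS on both strands", {
  cfg <- simulation_config(seed = 4, n_chroms = 1, chrom_length = 20000,
                           n_genes = 6)
  ref <- simulate_reference(cfg)
  d <- tempfile(); dir.create(d)
  writeLines(ref$fasta, file.path(d, "g.fa"))
  writeLines(ref$gtf, file.path(d, "g.gtf"))
  models <- index_gene_models(file.path(d, "g.gtf"), file.path(d, "g.fa"))
  expect_length(models$models, 6)
  strands <- vapply(models$models, `[[`, "", "strand")
  expect_setequal(unique(strands), c("+", "-"))
  for (m in models$models) {
    aa <- as.character(Biostrings::translate(m$cds_seq))
    expect_match(aa, "^M[^*]*\\*$")   # ORF: start, no internal stop, stop
    # independent check: splice with base-R strings and reverse complement
    rows <- ref$genes[ref$genes$transcript_id == m$transcript_id, ]
    spl <- splice_str(ref$genome[[m$chrom]], rows$cds_start, rows$cds_end)
    if (m$strand == "-") spl <- revcomp_str(spl)
    expect_equal(as.character(m$cds_seq), spl)
  }
  # empty GTF -> empty index
  writeLines(character(0), file.path(d, "empty.gtf"))
  expect_length(index_gene_models(file.path(d, "empty.gtf"),
                                  file.path(d, "g.fa"))$models, 0)
})

test_that("variants are assigned to overlapping transcripts or intergenic", {
  models <- local_toy_index()
  cs <- call_set(data.frame(
    chrom = "chrT", pos = c(5L, 20L, 11L),
    ref = c("C", "C", "GG"), alt = c("A", "A", "G"),
    qual = 50, depth = 9), "s")
  asg <- assign_to_genes(cs, models)
  expect_equal(asg$transcript_id[asg$pos == 5], "g1.t1")
  expect_true(is.na(asg$transcript_id[asg$pos == 20]))
  # deletion spanning the exon boundary (12|13) still assigned
  expect_equal(asg$transcript_id[asg$pos == 11], "g1.t1")
})

test_that("toy gene worked examples: missense/synonymous/frameshift", {
  models <- local_toy_index()
  tx <- models$models[["g1.t1"]]
  expect_equal(as.character(tx$cds_seq), "ATGGCGTAA")
  m <- classify_consequence("chrT", 5L, "C", "A", tx)   # GCG -> GAG
  expect_equal(m$category, "missense"); expect_true(m$disruptive)
  s <- classify_consequence("chrT", 6L, "G", "A", tx)   # GCG -> GCA
  expect_equal(s$category, "synonymous"); expect_false(s$disruptive)
  f <- classify_consequence("chrT", 4L, "G", "GT", tx)  # +1 bp after pos 4
  expect_equal(f$category, "frameshift"); expect_true(f$disruptive)
  i3 <- classify_consequence("chrT", 4L, "G", "GTTT", tx)
  expect_equal(i3$category, "inframe_indel"); expect_true(i3$disruptive)
  sg <- classify_consequence("chrT", 5L, "C", "A", tx)
  # stop codon disruption: TAA (7-9) pos 8 A->G gives TGA (still stop)
  st <- classify_consequence("chrT", 8L, "A", "G", tx)
  expect_equal(st$category, "synonymous")
  # stop loss: pos 7 T->C gives CAA (Gln)
  sl <- classify_consequence("chrT", 7L, "T", "C", tx)
  expect_equal(sl$category, "stop_loss"); expect_true(sl$disruptive)
  # exonic but outside the CDS (positions 10-12) -> noncoding
  nc <- classify_consequence("chrT", 10L, "G", "C", tx)
  expect_equal(nc$category, "noncoding"); expect_false(nc$disruptive)
  expect_error(classify_consequence("chrT", 25L, "A", "C", tx),
               "does not overlap")
})

test_that("classification matches the full-translation oracle", {
  set.seed(23)
  n_checked <- 0
  for (rep in 1:40) {
    toy <- random_toy_tx()
    for (v in 1:8) {
      var <- random_cds_variant(toy)
      got <- classify_consequence("chrT", var$pos, var$ref, var$alt,
                                  toy$model)$category
      want <- oracle_consequence(toy$genome, toy$starts, toy$ends,
                                 toy$strand, var$pos, var$ref, var$alt)
      expect_equal(got, want,
                   label = sprintf("strand %s pos %d %s>%s: %s",
                                   toy$strand, var$pos, var$ref, var$alt,
                                   got))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 300)
})

test_that("strand mirror yields identical categories", {
  set.seed(29)
  for (rep in 1:10) {
    toy <- random_toy_tx(cds_codons = 20, n_exons = 1)
    L <- nchar(toy$genome)
    # mirror the world: reverse-complement genome, flip coordinates
    mir_genome <- revcomp_str(toy$genome)
    mir_start <- L - toy$ends + 1L
    mir_end <- L - toy$starts + 1L
    mir_strand <- if (toy$strand == "+") "-" else "+"
    mir_model <- toy$model
    mir_model$strand <- mir_strand
    mir_model$exons <- IRanges::IRanges(mir_start, mir_end)
    mir_model$cds <- mir_model$exons
    var <- random_cds_variant(toy, kind = "SNV")
    mir_pos <- L - var$pos + 1L
    mir_ref <- revcomp_str(var$ref)
    mir_alt <- revcomp_str(var$alt)
    expect_equal(
      classify_consequence("chrT", mir_pos, mir_ref, mir_alt,
                           mir_model)$category,
      classify_consequence("chrT", var$pos, var$ref, var$alt,
                           toy$model)$category)
  }
})

test_that("disruptive flag equals membership of the disruptive set", {
  set.seed(37)
  toy <- random_toy_tx()
  for (v in 1:30) {
    var <- random_cds_variant(toy)
    cc <- classify_consequence("chrT", var$pos, var$ref, var$alt, toy$model)
    expect_equal(cc$disruptive,
                 cc$category %in% c("missense", "stop_gain", "stop_loss",
                                    "inframe_indel", "frameshift"))
  }
})

test_that("recurrence table counts disruptive hits across samples", {
  mk <- function(genes, cats) data.frame(
    chrom = "c", pos = seq_along(genes), ref = "A", alt = "G",
    gene_id = genes, transcript_id = paste0(genes, ".t1"),
    category = cats,
    disruptive = cats %in% c("missense", "frameshift"),
    stringsAsFactors = FALSE)
  t1 <- mk(c("gA", "gB", "gC"), c("missense", "missense", "synonymous"))
  t2 <- mk(c("gA", "gB"), c("frameshift", "synonymous"))
  tab <- recurrent_gene_table(list(s1 = t1, s2 = t2))
  expect_equal(tab$gene_id, c("gA", "gB"))     # gC never disruptive
  gA <- tab[tab$gene_id == "gA", ]
  expect_equal(c(gA$total, gA$samples_hit), c(2L, 2L))
  expect_true(gA$in_all_samples)
  expect_false(tab$in_all_samples[tab$gene_id == "gB"])
  # a 10-hit gene reports total 10
  t3 <- mk(rep("gM", 10), rep("missense", 10))
  t3$pos <- 1:10
  expect_equal(recurrent_gene_table(list(s1 = t3))$total, 10L)
})

test_that("a variant assigned to k transcripts yields k consequence calls", {
  d <- tempfile(); dir.create(d)
  writeLines(c(">chrT", "ATGGCGTAAGGGTTTAAACCCAAATTTGGG"), file.path(d, "g.fa"))
  gtf <- c()
  for (tx in c("t1", "t2")) {
    at <- sprintf('gene_id "g1"; transcript_id "g1.%s";', tx)
    gtf <- c(gtf,
             paste("chrT", "x", "exon", 1, 12, ".", "+", ".", at, sep = "\t"),
             paste("chrT", "x", "CDS", 1, 9, ".", "+", 0, at, sep = "\t"))
  }
  writeLines(gtf, file.path(d, "g.gtf"))
  models <- index_gene_models(file.path(d, "g.gtf"), file.path(d, "g.fa"))
  cs <- make_cs(chrom = "chrT", pos = 5L, ref = "C", alt = "A")
  cc <- annotate_consequences(cs, models)
  expect_equal(nrow(cc), 2)
  expect_setequal(cc$transcript_id, c("g1.t1", "g1.t2"))
  expect_true(all(cc$category == "missense"))
})
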