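# builders and independent oracles shared by the test files

make_cs <- function(chrom = "chr1", pos, ref = "A", alt = "G",
                    qual = 50, depth = 10, sample_id = "s") {
  n <- length(pos)
  call_set(data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      qual = rep_len(qual, n), depth = rep_len(depth, n),
                      stringsAsFactors = FALSE),
           sample_id = sample_id)
}

random_cs <- function(n, sample_id = "s", chroms = c("c1", "c2"),
                      span = 5000L) {
  pos <- sample.int(span, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  df <- unique(data.frame(chrom = sample(chroms, n, replace = TRUE),
                          pos = pos, ref = ref, alt = alt,
                          qual = round(runif(n, 0, 100), 2),
                          depth = sample.int(80L, n, replace = TRUE),
                          stringsAsFactors = FALSE))
  df <- df[!duplicated(df[, c("chrom", "pos", "ref", "alt")]), ]
  call_set(df, sample_id = sample_id)
}

small_sim_cfg <- function(seed, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 20000L,
               n_genes = 4L, germline_rate = 2e-3, somatic_rate = 5e-4,
               artifact_rates = list(lowqual = 2e-4, spike = 2e-4,
                                     onesample = 2e-4, cluster = 1e-4,
                                     shared = 2e-4),
               editing_rate = 2e-3, db_decoys = 5L)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher by explicit enumeration with binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  total <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / total
  p_obs <- choose(m, a) * choose(n, k - a) / total
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# nearest-rank quantile: smallest sorted element with rank >= q*n
oracle_quantile <- function(depths, q) {
  d <- sort(depths)
  n <- length(d)
  for (i in seq_len(n)) if (i >= q * n) return(d[i])
  d[n]
}

# base-R string helpers, independent of Biostrings
revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
splice_str <- function(genome, starts, ends) {
  paste(vapply(seq_along(starts), function(i)
    substr(genome, starts[i], ends[i]), ""), collapse = "")
}
translate_str <- function(s) {
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# full-CDS-translation consequence oracle: applies the edit to the
# chromosome, shifts downstream CDS intervals, re-splices and translates
# both proteins entirely. Assumes the edit lies inside one CDS interval.
oracle_consequence <- function(genome, cds_start, cds_end, strand,
                               pos, ref, alt) {
  stopifnot(substr(genome, pos, pos + nchar(ref) - 1L) == ref)
  delta <- nchar(alt) - nchar(ref)
  mut <- paste0(substr(genome, 1L, pos - 1L), alt,
                substr(genome, pos + nchar(ref), nchar(genome)))
  s2 <- cds_start; e2 <- cds_end
  hit <- which(pos >= cds_start & pos <= cds_end)
  e2[hit] <- e2[hit] + delta
  after <- which(cds_start > pos)
  s2[after] <- s2[after] + delta
  e2[setdiff(after, hit)] <- e2[setdiff(after, hit)] + delta
  cds_ref <- splice_str(genome, cds_start, cds_end)
  cds_mut <- splice_str(mut, s2, e2)
  if (strand == "-") {
    cds_ref <- revcomp_str(cds_ref)
    cds_mut <- revcomp_str(cds_mut)
  }
  if (delta != 0L) {
    return(if (delta %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  p_ref <- translate_str(cds_ref)
  p_mut <- translate_str(cds_mut)
  if (p_ref == p_mut) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  aa_ref <- substr(p_ref, i, i); aa_mut <- substr(p_mut, i, i)
  if (aa_mut == "*") "stop_gain"
  else if (aa_ref == "*") "stop_loss"
  else "missense"
}

# a random single-transcript toy genome built in code (no file IO);
# returns the raw layout plus a package-format transcript model
random_toy_tx <- function(cds_codons = NULL, n_exons = NULL) {
  if (is.null(cds_codons)) cds_codons <- sample(4:100, 1)
  cds_len <- 3L * cds_codons
  if (is.null(n_exons)) n_exons <- sample(1:min(5L, max(1L, cds_len %/% 12L)), 1)
  orf <- paste0("ATG",
                paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                     c("TAA", "TAG", "TGA")),
                             cds_codons - 2L, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  # split into exon chunks of >= 6 bp
  widths <- rep(cds_len %/% n_exons, n_exons)
  widths[n_exons] <- widths[n_exons] + cds_len %% n_exons
  introns <- if (n_exons > 1) sample(20:60, n_exons - 1, replace = TRUE)
  else integer(0)
  pad <- 50L
  span <- sum(widths) + sum(introns)
  L <- span + 2L * pad
  strand <- sample(c("+", "-"), 1)
  genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  starts <- pad + 1L + cumsum(c(0L, widths[-n_exons] + introns))
  ends <- starts + widths - 1L
  laid <- if (strand == "+") orf else revcomp_str(orf)
  off <- 0L
  for (e in seq_len(n_exons)) {
    substr(genome, starts[e], ends[e]) <- substr(laid, off + 1L,
                                                 off + widths[e])
    off <- off + widths[e]
  }
  model <- list(gene_id = "gX", transcript_id = "gX.t1", chrom = "chrT",
                strand = strand, exons = IRanges::IRanges(starts, ends),
                cds = IRanges::IRanges(starts, ends),
                cds_seq = Biostrings::DNAString(orf), partial = FALSE)
  list(genome = genome, starts = starts, ends = ends, strand = strand,
       model = model, cds_len = cds_len)
}

# a random CDS variant for the toy transcript; SNV / INS / DEL kept
# strictly inside one exon so the oracle's coordinate shifting is exact
random_cds_variant <- function(toy, kind = NULL) {
  if (is.null(kind)) kind <- sample(c("SNV", "INS", "DEL"),
                                    1, prob = c(0.6, 0.2, 0.2))
  e <- sample(seq_along(toy$starts), 1)
  lo <- toy$starts[e]; hi <- toy$ends[e]
  if (kind == "SNV") {
    pos <- sample(seq(lo, hi), 1)
    ref <- substr(toy$genome, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  } else if (kind == "INS") {
    pos <- sample(seq(lo, max(lo, hi - 1L)), 1)
    ref <- substr(toy$genome, pos, pos)
    k <- sample(1:4, 1)
    alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k,
                                    replace = TRUE), collapse = ""))
  } else {
    k <- sample(1:min(4L, hi - lo), 1)
    pos <- sample(seq(lo, hi - k), 1)
    ref <- substr(toy$genome, pos, pos + k)
    alt <- substr(toy$genome, pos, pos)
  }
  list(pos = pos, ref = ref, alt = alt, kind = kind)
}

mini_dag <- function() {
  go_dag(
    terms = data.frame(
      id = c("root", "A", "B", "L", "M"),
      name = c("root", "termA", "termB", "leafL", "leafM"),
      namespace = "biological_process", stringsAsFactors = FALSE),
    edges = data.frame(child = c("A", "B", "L", "L", "M"),
                       parent = c("root", "root", "A", "B", "A"),
                       stringsAsFactors = FALSE))
}

write_tmp_vcf <- function(lines, ext = ".vcf") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

vcf_header <- function(sample = NULL) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) cols <- c(cols, "FORMAT", sample)
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    paste(cols, collapse = "\t"))
}
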