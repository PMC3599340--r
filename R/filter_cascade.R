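#' Filter cascade configuration
#'
#' Thresholds for the six-stage somatic filter cascade. Defaults are the
#' published values: phred QUAL >= 20, coverage ceiling at the 97.5th
#' percentile of known-variant depths, a +/-10 bp mismatch window with
#' discard rule (rate >= 0.1 OR >= 2 mismatches), and paired-coverage
#' support of at least 1 read in each sample.
#'
#' @param qual_min minimum variant quality (phred; stage 1.1).
#' @param coverage_quantile quantile in (0,1] of known-variant depths
#'   used as the per-sample coverage ceiling (stage 1.2).
#' @param flank half-width in bp of the local mismatch window (stage 2.4).
#' @param mismatch_rate_max discard when neighbor rate >= this (stage 2.4).
#' @param mismatch_count_max discard when neighbor count >= this (stage 2.4).
#' @param min_depth_both minimum depth required in both samples (stage 2.1).
#' @param db_positional match the known DB on position only (default
#'   allele-aware exact matching).
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(qual_min = 20, coverage_quantile = 0.975,
                          flank = 10L, mismatch_rate_max = 0.1,
                          mismatch_count_max = 2L, min_depth_both = 1L,
                          db_positional = FALSE) {
  stopifnot(qual_min >= 0, coverage_quantile > 0, coverage_quantile <= 1,
            flank >= 1, mismatch_rate_max >= 0, mismatch_count_max >= 0,
            min_depth_both >= 0)
  structure(list(qual_min = qual_min, coverage_quantile = coverage_quantile,
                 flank = as.integer(flank),
                 mismatch_rate_max = mismatch_rate_max,
                 mismatch_count_max = as.integer(mismatch_count_max),
                 min_depth_both = as.integer(min_depth_both),
                 db_positional = isTRUE(db_positional)),
            class = "FilterConfig")
}

#' Stage 1.1: minimum variant quality
#'
#' Retains calls with `qual >= qual_min` (a phred QUAL of 20 keeps the
#' mis-call probability below 0.01).
#'
#' @param cs a CallSet.
#' @param qual_min quality threshold (inclusive).
#' @return filtered CallSet.
#' @export
filter_min_quality <- function(cs, qual_min = 20) {
  cs_subset(cs, cs$qual >= qual_min)
}

#' Train the per-sample coverage ceiling (stage 1.2)
#'
#' Returns the nearest-rank `q`-quantile of read depths at calls that are
#' members of the known-variant database: depths sorted ascending, element
#' `ceiling(q * n)`. The published choice q = 0.975 means 97.5% of known
#' variants have coverage at or below the cutoff.
#'
#' @param cs a CallSet (typically after the quality filter).
#' @param db a [known_db()].
#' @param q quantile in (0, 1].
#' @param positional positional DB matching (see [db_contains()]).
#' @return integer cutoff.
#' @export
train_coverage_cutoff <- function(cs, db, q = 0.975, positional = FALSE) {
  stopifnot(q > 0, q <= 1)
  depths <- cs$depth[db_contains(db, cs, positional = positional)]
  if (!length(depths))
    stop("no calls in this callset are present in the known-variant DB; ",
         "supply a manual coverage cutoff instead of training one")
  d <- sort(depths)
  as.integer(d[ceiling(q * length(d))])
}

#' Stage 1.2: maximum-coverage filter
#'
#' Retains calls with `depth <= cutoff`. Sites above the trained ceiling
#' are treated as PCR-duplicate/collapsed-repeat artifacts.
#'
#' @param cs a CallSet.
#' @param cutoff inclusive depth ceiling (>= 0).
#' @return filtered CallSet.
#' @export
filter_max_coverage <- function(cs, cutoff) {
  stopifnot(cutoff >= 0)
  cs_subset(cs, cs$depth <= cutoff)
}

#' Stage 2.1: paired-coverage support
#'
#' Retains calls at positions covered by at least `min_depth` reads in
#' BOTH samples of the pair; sites covered in only one sample cannot be
#' interpreted as somatic or germline.
#'
#' @param cs a CallSet.
#' @param own CoverageTrack of the sample the calls belong to.
#' @param other CoverageTrack of the paired sample.
#' @param min_depth minimum depth required in each track.
#' @return filtered CallSet.
#' @export
filter_covered_in_both <- function(cs, own, other, min_depth = 1L) {
  if (nrow(cs) == 0L) return(cs)
  keep <- logical(nrow(cs))
  for (ch in unique(cs$chrom)) {
    sel <- cs$chrom == ch
    keep[sel] <- coverage_depth(own, ch, cs$pos[sel]) >= min_depth &
      coverage_depth(other, ch, cs$pos[sel]) >= min_depth
  }
  cs_subset(cs, keep)
}

#' Stage 2.2: known-variant subtraction
#'
#' Removes calls present in the known-variant database, leaving novel
#' variants.
#'
#' @param cs a CallSet.
#' @param db a [known_db()].
#' @param positional match on position only (default allele-aware).
#' @return filtered CallSet.
#' @export
filter_known_variants <- function(cs, db, positional = FALSE) {
  if (nrow(cs) == 0L) return(cs)
  cs_subset(cs, !db_contains(db, cs, positional = positional))
}

#' Stage 2.3: shared-call subtraction
#'
#' Removes calls whose (chrom, pos, ref, alt) also occurs in the paired
#' sample's callset; what remains is tissue-specific.
#'
#' @param cs a CallSet.
#' @param partner CallSet of the paired sample.
#' @return filtered CallSet.
#' @export
filter_shared_calls <- function(cs, partner) {
  if (nrow(cs) == 0L) return(cs)
  cs_subset(cs, !(variant_key(cs) %in% variant_key(partner)))
}

#' Local mismatch statistics around a variant (stage 2.4 support)
#'
#' Counts OTHER called variant sites on the same chromosome within
#' `flank` bp of the focal call; the rate is count / (2 * flank). With
#' the default flank of 10 the window holds 20 flanking bases, so the
#' published thresholds (rate >= 0.1, count >= 2) coincide.
#'
#' @param chrom,pos focal variant coordinates.
#' @param all_sites CallSet used as the neighbor universe (by
#'   convention the same sample's callset before known-variant
#'   subtraction, so known variants still flag misalignment-prone
#'   regions).
#' @param flank window half-width in bp (> 0).
#' @return list with `count` and `rate`.
#' @export
local_mismatch_stats <- function(chrom, pos, all_sites, flank = 10L) {
  if (flank <= 0) stop("flank must be positive")
  sel <- all_sites$chrom == chrom & abs(all_sites$pos - pos) <= flank &
    all_sites$pos != pos
  n <- sum(sel)
  list(count = n, rate = n / (2 * flank))
}

#' Stage 2.4: local mismatch-cluster filter
#'
#' Discards calls whose flanking window contains a high density of other
#' called sites (`rate >= mismatch_rate_max` OR
#' `count >= mismatch_count_max`), the signature of misalignment around
#' indels.
#'
#' @param cs a CallSet.
#' @param all_sites neighbor universe (see [local_mismatch_stats()]).
#' @param cfg a [filter_config()].
#' @return filtered CallSet.
#' @export
filter_local_mismatch <- function(cs, all_sites, cfg = filter_config()) {
  if (nrow(cs) == 0L) return(cs)
  keep <- logical(nrow(cs))
  for (ch in unique(cs$chrom)) {
    sel <- which(cs$chrom == ch)
    sites <- sort(all_sites$pos[all_sites$chrom == ch])
    for (i in sel) {
      p <- cs$pos[i]
      n <- sum(sites >= p - cfg$flank & sites <= p + cfg$flank & sites != p)
      rate <- n / (2 * cfg$flank)
      keep[i] <- !(rate >= cfg$mismatch_rate_max ||
                     n >= cfg$mismatch_count_max)
    }
  }
  cs_subset(cs, keep)
}

new_filter_report <- function(rows, cutoffs) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, cutoffs = cutoffs, class = c("FilterReport", "data.frame"))
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport (coverage cutoffs:",
      paste(names(attr(x, "cutoffs")), attr(x, "cutoffs"),
            sep = "=", collapse = ", "), ")\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Run the full six-stage somatic filter cascade on a tumor/normal pair
#'
#' Executes, independently for the tumor and the normal sample and in the
#' published order: (1.1) minimum QUAL, (1.2) train and apply the
#' known-variant coverage ceiling, (2.1) paired-coverage support, (2.2)
#' known-variant subtraction, (2.3) shared-call subtraction against the
#' partner's quality-filtered callset, (2.4) local mismatch-cluster
#' filter (neighbor universe: the same sample's post-2.1, pre-2.2
#' callset). Returns the tissue-specific callsets plus an audit report of
#' per-stage in/out counts and the trained cutoffs.
#'
#' @param pair a [sample_pair()].
#' @param db a [known_db()].
#' @param cfg a [filter_config()].
#' @return list with `tumor_specific`, `normal_specific`, `report`
#'   (a `FilterReport` data frame with attribute `cutoffs`).
#' @export
run_cascade <- function(pair, db, cfg = filter_config()) {
  sides <- list(tumor = pair$tumor, normal = pair$normal)
  stage1 <- list(); post21 <- list(); post22 <- list()
  rows <- list(); cutoffs <- c(tumor = NA_integer_, normal = NA_integer_)
  rec <- function(sample, stage, n_in, n_out)
    data.frame(sample = sample, stage = stage, variants_in = n_in,
               variants_out = n_out, stringsAsFactors = FALSE)

  for (s in names(sides)) {
    other <- setdiff(names(sides), s)
    cs0 <- sides[[s]]$calls
    cs1 <- filter_min_quality(cs0, cfg$qual_min)
    rows[[length(rows) + 1L]] <- rec(s, "1.1_qual", nrow(cs0), nrow(cs1))
    if (nrow(cs1)) {
      cutoff <- train_coverage_cutoff(cs1, db, cfg$coverage_quantile,
                                      positional = cfg$db_positional)
    } else cutoff <- 0L
    cutoffs[s] <- cutoff
    cs2 <- filter_max_coverage(cs1, cutoff)
    rows[[length(rows) + 1L]] <- rec(s, "1.2_coverage", nrow(cs1), nrow(cs2))
    cs3 <- filter_covered_in_both(cs2, sides[[s]]$coverage,
                                  sides[[other]]$coverage,
                                  cfg$min_depth_both)
    rows[[length(rows) + 1L]] <- rec(s, "2.1_paired_coverage",
                                     nrow(cs2), nrow(cs3))
    stage1[[s]] <- cs1
    post21[[s]] <- cs3
    cs4 <- filter_known_variants(cs3, db, positional = cfg$db_positional)
    rows[[length(rows) + 1L]] <- rec(s, "2.2_known_db", nrow(cs3), nrow(cs4))
    post22[[s]] <- cs4
  }

  out <- list()
  for (s in names(sides)) {
    other <- setdiff(names(sides), s)
    cs4 <- post22[[s]]
    # the partner reference set is the partner's quality-credible calls:
    # a call seen in the other tissue at QUAL >= qual_min is not somatic
    cs5 <- filter_shared_calls(cs4, stage1[[other]])
    rows[[length(rows) + 1L]] <- rec(s, "2.3_shared", nrow(cs4), nrow(cs5))
    cs6 <- filter_local_mismatch(cs5, post21[[s]], cfg)
    rows[[length(rows) + 1L]] <- rec(s, "2.4_local_mismatch",
                                     nrow(cs5), nrow(cs6))
    out[[s]] <- cs6
  }
  # order report rows by sample then execution order
  report <- new_filter_report(rows, cutoffs)
  list(tumor_specific = out$tumor, normal_specific = out$normal,
       report = report)
}

#' Write a FilterReport as TSV
#' @param report a FilterReport.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  df <- as.data.frame(report)
  cutoffs <- attr(report, "cutoffs")
  df$coverage_cutoff <- cutoffs[df$sample]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
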