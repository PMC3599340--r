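DISRUPTIVE_CATEGORIES <- c("missense", "stop_gain", "stop_loss",
                           "inframe_indel", "frameshift")

#' Index gene models from a GTF and reference FASTA
#'
#' Builds transcript models (strand, exon and CDS intervals, spliced CDS
#' sequence) supporting point overlap queries and codon-level consequence
#' calls. Minus-strand CDS sequences are reverse-complemented into
#' translation orientation. Transcripts whose CDS length is not a
#' multiple of 3 are kept but flagged partial (with a warning).
#'
#' @param gtf path to an Ensembl-style GTF (gene_id/transcript_id
#'   attributes; exon and CDS features).
#' @param fasta path to the reference FASTA supplying every chromosome
#'   named in the GTF.
#' @return a `GeneModelSet`: list of transcript models plus an exon
#'   interval index.
#' @export
index_gene_models <- function(gtf, fasta) {
  gtf_lines <- read_text_lines(gtf)
  gr <- if (any(nzchar(gtf_lines) & !grepl("^#", gtf_lines)))
    rtracklayer::import(gtf, format = "gtf")
  else GenomicRanges::GRanges()
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  models <- list()
  if (length(gr)) {
    keep <- S4Vectors::mcols(gr)$type %in% c("exon", "CDS")
    gr <- gr[keep]
    tx_ids <- S4Vectors::mcols(gr)$transcript_id
    for (tx in unique(tx_ids)) {
      sub <- gr[tx_ids == tx]
      chrom <- as.character(GenomicRanges::seqnames(sub))[1]
      strand <- as.character(GenomicRanges::strand(sub))[1]
      exon <- sub[S4Vectors::mcols(sub)$type == "exon"]
      cds <- sub[S4Vectors::mcols(sub)$type == "CDS"]
      exon <- sort(exon); cds <- sort(cds)
      if (!chrom %in% names(genome))
        stop("transcript ", tx, " references absent chromosome ", chrom)
      cds_ir <- IRanges::ranges(cds)
      exon_ir <- if (length(exon)) IRanges::ranges(exon) else cds_ir
      cds_seq <- NULL
      partial <- FALSE
      if (length(cds_ir)) {
        pieces <- Biostrings::extractAt(genome[[chrom]], cds_ir)
        spliced <- Biostrings::DNAString(paste(as.character(pieces),
                                               collapse = ""))
        if (strand == "-") spliced <- Biostrings::reverseComplement(spliced)
        if (length(spliced) %% 3L != 0L) {
          warning("transcript ", tx, " CDS length ", length(spliced),
                  " not divisible by 3; flagged partial")
          partial <- TRUE
        }
        cds_seq <- spliced
      }
      models[[tx]] <- list(
        gene_id = S4Vectors::mcols(sub)$gene_id[1],
        transcript_id = tx, chrom = chrom, strand = strand,
        exons = exon_ir, cds = cds_ir, cds_seq = cds_seq,
        partial = partial)
    }
  }
  exon_index <- if (length(models)) {
    GenomicRanges::GRanges(
      seqnames = rep(vapply(models, `[[`, "", "chrom"),
                     vapply(models, function(m) length(m$exons), 0L)),
      ranges = do.call(c, unname(lapply(models, `[[`, "exons"))),
      tx = rep(names(models),
               vapply(models, function(m) length(m$exons), 0L)))
  } else GenomicRanges::GRanges()
  structure(list(models = models, exon_index = exon_index,
                 chrom_lengths = stats::setNames(Biostrings::width(genome),
                                                 names(genome))),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", length(x$models), "transcripts on",
      length(unique(vapply(x$models, `[[`, "", "chrom"))), "chromosomes\n")
  invisible(x)
}

variant_span <- function(cs) {
  # reference footprint; for pure insertions this is the anchor base
  GenomicRanges::GRanges(cs$chrom,
                         IRanges::IRanges(cs$pos,
                                          cs$pos + nchar(cs$ref) - 1L))
}

#' Assign variants to overlapping transcripts
#'
#' A variant overlaps a transcript iff its reference footprint intersects
#' any exon interval; variants touching nothing are reported intergenic.
#'
#' @param cs a CallSet.
#' @param models a [index_gene_models()] result.
#' @return data frame with one row per (variant, transcript) pair:
#'   variant key columns plus `gene_id`, `transcript_id`; intergenic
#'   variants get a single row with `transcript_id = NA`.
#' @export
assign_to_genes <- function(cs, models) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cs) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(variant_span(cs), models$exon_index)
  qi <- S4Vectors::queryHits(hits)
  tx <- S4Vectors::mcols(models$exon_index)$tx[S4Vectors::subjectHits(hits)]
  df <- unique(data.frame(i = qi, transcript_id = tx,
                          stringsAsFactors = FALSE))
  orphan <- setdiff(seq_len(nrow(cs)), df$i)
  if (length(orphan))
    df <- rbind(df, data.frame(i = orphan, transcript_id = NA_character_))
  df <- df[order(df$i, df$transcript_id), , drop = FALSE]
  out <- cbind(as.data.frame(cs)[df$i, c("chrom", "pos", "ref", "alt"),
                                 drop = FALSE],
               gene_id = ifelse(is.na(df$transcript_id), NA_character_,
                                vapply(df$transcript_id, function(t)
                                  if (is.na(t)) NA_character_
                                  else models$models[[t]]$gene_id, "")),
               transcript_id = df$transcript_id)
  rownames(out) <- NULL
  out
}

# genomic position -> 1-based coordinate along the spliced CDS in
# translation orientation; NA when pos not inside any CDS interval
cds_coordinate <- function(m, pos) {
  st <- IRanges::start(m$cds); en <- IRanges::end(m$cds)
  w <- en - st + 1L
  hit <- which(pos >= st & pos <= en)
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
  fwd <- before + (pos - st[hit] + 1L)           # 5'->3' on + strand
  if (m$strand == "+") fwd else sum(w) - fwd + 1L
}

translate_codon <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[codon])
}

#' Classify the coding consequence of a variant on one transcript
#'
#' SNVs inside the CDS are classified by translating the affected codon
#' before and after the change (standard genetic code, strand-aware):
#' synonymous, missense, stop_gain or stop_loss. Indels touching the CDS
#' are frameshift when the length difference is not a multiple of 3,
#' inframe_indel otherwise. Exonic positions outside the CDS are
#' noncoding. The `disruptive` flag marks categories that change encoded
#' amino acids or the reading frame (missense, stop gain/loss, in-frame
#' and frameshift indels).
#'
#' @param chrom,pos,ref,alt one variant (minimal representation).
#' @param m one transcript model from a `GeneModelSet`.
#' @return a one-row data frame: variant key, gene_id, transcript_id,
#'   `category`, `disruptive`.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, m) {
  if (chrom != m$chrom) stop("variant on ", chrom,
                             " does not overlap transcript on ", m$chrom)
  span <- IRanges::IRanges(pos, pos + nchar(ref) - 1L)
  if (!any(IRanges::overlapsAny(span, m$exons)))
    stop("variant does not overlap transcript ", m$transcript_id)
  in_cds <- any(IRanges::overlapsAny(span, m$cds))
  category <- "noncoding"
  if (in_cds && !is.null(m$cds_seq)) {
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      i <- cds_coordinate(m, pos)
      if (is.na(i)) {
        category <- "noncoding"
      } else {
        cds <- as.character(m$cds_seq)
        ref_tx <- if (m$strand == "+") ref else unname(COMPLEMENT[ref])
        alt_tx <- if (m$strand == "+") alt else unname(COMPLEMENT[alt])
        if (substr(cds, i, i) != ref_tx)
          warning("reference mismatch at CDS position ", i, " of ",
                  m$transcript_id)
        j <- (i - 1L) %/% 3L                      # codon index, 0-based
        codon <- substr(cds, 3L * j + 1L, 3L * j + 3L)
        k <- i - 3L * j                           # position in codon
        mut <- codon
        substr(mut, k, k) <- alt_tx
        if (nchar(codon) == 3L) {
          aa_ref <- translate_codon(codon)
          aa_alt <- translate_codon(mut)
          category <- if (aa_ref == aa_alt) "synonymous"
          else if (aa_alt == "*") "stop_gain"
          else if (aa_ref == "*") "stop_loss"
          else "missense"
        } else category <- "noncoding"            # truncated terminal codon
      }
    } else {
      delta <- nchar(alt) - nchar(ref)
      category <- if (delta %% 3L != 0L) "frameshift" else "inframe_indel"
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene_id = m$gene_id, transcript_id = m$transcript_id,
             category = category,
             disruptive = category %in% DISRUPTIVE_CATEGORIES,
             stringsAsFactors = FALSE)
}

#' Classify consequences for every variant/transcript assignment
#'
#' @param cs a CallSet.
#' @param models a `GeneModelSet`.
#' @param keep_intergenic include intergenic variants (category
#'   `"intergenic"`, never disruptive).
#' @return data frame of consequence calls (one per variant/transcript
#'   pair) with attribute `sample_id`.
#' @export
annotate_consequences <- function(cs, models, keep_intergenic = TRUE) {
  asg <- assign_to_genes(cs, models)
  rows <- list()
  for (i in seq_len(nrow(asg))) {
    if (is.na(asg$transcript_id[i])) {
      if (keep_intergenic)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = asg$chrom[i], pos = asg$pos[i], ref = asg$ref[i],
          alt = asg$alt[i], gene_id = NA_character_,
          transcript_id = NA_character_, category = "intergenic",
          disruptive = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- classify_consequence(
        asg$chrom[i], asg$pos[i], asg$ref[i], asg$alt[i],
        models$models[[asg$transcript_id[i]]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    classify_consequence_empty()
  attr(out, "sample_id") <- sample_id(cs)
  out
}

classify_consequence_empty <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene_id = character(),
             transcript_id = character(), category = character(),
             disruptive = logical(), stringsAsFactors = FALSE)
}

#' Cross-sample recurrence of disruptively hit genes
#'
#' One row per gene carrying at least one disruptive call in any sample:
#' per-sample disruptive counts, the total, the number of samples hit,
#' and a flag for genes hit in every sample. A gene counts as hit when
#' ANY of its transcripts yields a disruptive call; a variant hitting
#' several transcripts of the same gene is counted once per variant.
#'
#' @param per_sample named list `sample_id -> consequence data frame`
#'   (from [annotate_consequences()]).
#' @return data frame sorted by `gene_id` with columns `gene_id`, one
#'   `n_<sample>` column per sample, `total`, `samples_hit`,
#'   `in_all_samples`.
#' @export
recurrent_gene_table <- function(per_sample) {
  stopifnot(length(per_sample) >= 1L)
  samples <- names(per_sample)
  per_gene <- list()
  for (s in samples) {
    cc <- per_sample[[s]]
    cc <- cc[cc$disruptive & !is.na(cc$gene_id), , drop = FALSE]
    if (!nrow(cc)) next
    # one count per distinct variant per gene, however many transcripts
    key <- unique(paste(cc$gene_id, cc$chrom, cc$pos, cc$ref, cc$alt,
                        sep = "|"))
    genes <- sub("\\|.*", "", key)
    tab <- table(genes)
    per_gene[[s]] <- tab
  }
  all_genes <- sort(unique(unlist(lapply(per_gene, names))))
  if (!length(all_genes)) {
    out <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("n_", s)]] <- integer()
    out$total <- integer(); out$samples_hit <- integer()
    out$in_all_samples <- logical()
    return(out)
  }
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (s in samples) {
    v <- integer(length(all_genes))
    if (!is.null(per_gene[[s]])) {
      idx <- match(names(per_gene[[s]]), all_genes)
      v[idx] <- as.integer(per_gene[[s]])
    }
    out[[paste0("n_", s)]] <- v
  }
  cnt <- as.matrix(out[, paste0("n_", samples), drop = FALSE])
  out$total <- as.integer(rowSums(cnt))
  out$samples_hit <- as.integer(rowSums(cnt > 0))
  out$in_all_samples <- out$samples_hit == length(samples)
  out
}
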