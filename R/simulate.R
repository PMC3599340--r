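#' Configuration for the paired tumor/normal callset simulator
#'
#' The defaults describe a desk-scale RNA-seq-like world: two 100 kb
#' chromosomes carrying 20 non-overlapping transcribed genes; germline
#' variants planted in both tissues (60% of them present in the known
#' DB, leaving ~40% novel as observed in real tumor/normal callsets);
#' tumor-only somatic variants; a fourfold panel of artifact classes
#' each violating exactly one cascade filter; and an excess of A-to-G
#' changes on transcribed strands mimicking A-to-I RNA editing. Coverage
#' is negative-binomial with occasional multiplicative duplicate spikes,
#' giving the trained 97.5% coverage ceiling something real to remove.
#'
#' @param seed RNG seed (all randomness derives from it).
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes,cds_length_range,n_exons_range,strand_prob gene models;
#'   CDS lengths are rounded to codon multiples.
#' @param germline_rate,somatic_rate variants per base (counts are
#'   `round(rate * genome_size)`, deterministic given the config).
#' @param known_db_fraction fraction of germline variants entered in the
#'   known-variant DB.
#' @param artifact_rates named list of per-base rates for the classes
#'   `lowqual` (QUAL < 20), `spike` (depth above the trained ceiling),
#'   `onesample` (no coverage in the partner), `cluster` (3 calls within
#'   8 bp) and `shared` (identical non-DB call in both tissues).
#' @param editing_rate A-to-G events per transcribed base (planted in
#'   both tissues on the transcribed strand).
#' @param indel_fraction fraction of germline/somatic variants planted
#'   as 1-3 bp indels.
#' @param transition_prob probability a planted SNV is a transition
#'   (2/3 gives the genome-wide Ti/Tv of ~2 before editing).
#' @param coverage list: `mean` and `size` of the negative binomial,
#'   `spike_prob` and `spike_mult` for duplicate spikes.
#' @param qual list: `true_mean`/`true_sd` (truncated at >= 25) for real
#'   calls, `artifact_mean`/`artifact_sd` (truncated at < 20) for the
#'   lowqual class.
#' @param db_decoys extra known-DB entries at positions never called.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L, chrom_length = 100000L,
                              n_genes = 20L,
                              cds_length_range = c(300L, 900L),
                              n_exons_range = c(1L, 3L),
                              strand_prob = 0.5,
                              germline_rate = 1e-3,
                              known_db_fraction = 0.6,
                              somatic_rate = 2.5e-4,
                              artifact_rates = list(lowqual = 5e-5,
                                                    spike = 5e-5,
                                                    onesample = 5e-5,
                                                    cluster = 2e-5,
                                                    shared = 5e-5),
                              editing_rate = 5e-4,
                              indel_fraction = 0.1,
                              transition_prob = 2 / 3,
                              coverage = list(mean = 20, size = 5,
                                              spike_prob = 0.01,
                                              spike_mult = 10),
                              qual = list(true_mean = 60, true_sd = 10,
                                          artifact_mean = 8,
                                          artifact_sd = 4),
                              db_decoys = 20L) {
  stopifnot(seed == floor(seed), n_chroms >= 1, chrom_length >= 1000,
            n_genes >= 0, germline_rate >= 0, somatic_rate >= 0,
            known_db_fraction >= 0, known_db_fraction <= 1,
            editing_rate >= 0, indel_fraction >= 0, indel_fraction <= 1,
            transition_prob >= 0, transition_prob <= 1)
  ar <- list(lowqual = 0, spike = 0, onesample = 0, cluster = 0, shared = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(unlist(ar) < 0)) stop("artifact rates must be >= 0")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 cds_length_range = as.integer(cds_length_range),
                 n_exons_range = as.integer(n_exons_range),
                 strand_prob = strand_prob,
                 germline_rate = germline_rate,
                 known_db_fraction = known_db_fraction,
                 somatic_rate = somatic_rate, artifact_rates = ar,
                 editing_rate = editing_rate,
                 indel_fraction = indel_fraction,
                 transition_prob = transition_prob,
                 coverage = coverage, qual = qual,
                 db_decoys = as.integer(db_decoys)),
            class = "SimulationConfig")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# sample() that never falls into the scalar-expansion trap
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_orf <- function(n_codons) {
  # ATG + (n-2) sense codons + stop; no internal stops by construction
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a toy reference genome and gene annotation
#'
#' Generates uniform-composition chromosomes, then stamps non-overlapping
#' multi-exon transcripts with valid ORFs (ATG start, terminal stop, no
#' internal stop) into them, on both strands, with short UTR flanks on
#' the terminal exons. Byte-identical output for identical (seed,
#' config).
#'
#' @param cfg a [simulation_config()].
#' @return list with `fasta` and `gtf` (character vectors of file
#'   lines), `genome` (named character vector of chromosome sequences)
#'   and `genes` (data frame of transcript layouts).
#' @export
simulate_reference <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- vapply(chroms, function(ch)
      paste(sample(VALID_BASES, cfg$chrom_length, replace = TRUE),
            collapse = ""), "")
    genes <- list()
    occupied <- stats::setNames(vector("list", cfg$n_chroms), chroms)
    if (cfg$n_genes > 0L) {
      for (g in seq_len(cfg$n_genes)) {
        n_codons <- round(stats::runif(1, cfg$cds_length_range[1] / 3,
                                       cfg$cds_length_range[2] / 3))
        cds_len <- as.integer(3L * n_codons)
        n_exons <- resample(seq(cfg$n_exons_range[1], cfg$n_exons_range[2]))
        cut_sites <- if (cds_len >= 60L) seq(30L, cds_len - 30L) else integer(0)
        n_exons <- min(n_exons, length(cut_sites) + 1L)
        cuts <- sort(resample(cut_sites, n_exons - 1L))
        widths <- diff(c(0L, cuts, cds_len))
        introns <- if (n_exons > 1L)
          sample(50:200, n_exons - 1L, replace = TRUE) else integer(0)
        utr5 <- sample(0:30, 1L); utr3 <- sample(0:30, 1L)
        span <- sum(widths) + sum(introns) + utr5 + utr3
        placed <- FALSE
        for (try in 1:200) {
          ch <- resample(chroms)
          start_range <- seq(100L, cfg$chrom_length - span - 100L)
          if (!length(start_range))
            stop("chromosomes too short for gene span ", span,
                 "; use longer chromosomes")
          start <- resample(start_range)
          iv <- c(start - 50L, start + span + 50L)
          clash <- any(vapply(occupied[[ch]], function(o)
            iv[1] <= o[2] && o[1] <= iv[2], logical(1)))
          if (!clash) { placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place gene ", g, " without overlap; ",
               "use longer chromosomes or fewer genes")
        occupied[[ch]] <- c(occupied[[ch]], list(c(start, start + span)))
        strand <- if (stats::runif(1) < cfg$strand_prob) "-" else "+"
        # genomic CDS intervals, left to right
        cds_start <- start + utr5
        starts <- cds_start + cumsum(c(0L, widths[-n_exons] +
                                         introns))[seq_len(n_exons)]
        ends <- starts + widths - 1L
        orf <- random_orf(n_codons)
        laid <- if (strand == "+") orf else revcomp_chr(orf)
        # stamp the spliced CDS into the genome, exon by exon
        off <- 0L
        seq_ch <- genome[[ch]]
        for (e in seq_len(n_exons)) {
          piece <- substr(laid, off + 1L, off + widths[e])
          substr(seq_ch, starts[e], ends[e]) <- piece
          off <- off + widths[e]
        }
        genome[[ch]] <- seq_ch
        gid <- sprintf("g%04d", g)
        genes[[g]] <- data.frame(
          gene_id = gid, transcript_id = paste0(gid, ".t1"),
          chrom = ch, strand = strand,
          exon_start = c(starts[1] - utr5, starts[-1]),
          exon_end = c(ends[-n_exons], ends[n_exons] + utr3),
          cds_start = starts, cds_end = ends,
          stringsAsFactors = FALSE)
      }
    }
    genes_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), transcript_id = character(),
                 chrom = character(), strand = character(),
                 exon_start = integer(), exon_end = integer(),
                 cds_start = integer(), cds_end = integer(),
                 stringsAsFactors = FALSE)
    fasta <- unlist(lapply(chroms, function(ch) {
      s <- genome[[ch]]
      c(paste0(">", ch),
        substring(s, seq(1L, nchar(s), 60L),
                  pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
    }))
    gtf <- character(0)
    for (tx in unique(genes_df$transcript_id)) {
      rows <- genes_df[genes_df$transcript_id == tx, , drop = FALSE]
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                          rows$gene_id[1], tx)
      strand <- rows$strand[1]
      gtf <- c(gtf, paste(rows$chrom, "rnasomatic", "exon",
                          rows$exon_start, rows$exon_end, ".", strand, ".",
                          attr_str, sep = "\t"))
      # CDS frame along translation order
      w <- rows$cds_end - rows$cds_start + 1L
      idx <- if (strand == "+") seq_along(w) else rev(seq_along(w))
      before <- cumsum(c(0L, w[idx]))[seq_along(w)]
      frame <- (3L - before %% 3L) %% 3L
      frame_by_row <- integer(length(w)); frame_by_row[idx] <- frame
      gtf <- c(gtf, paste(rows$chrom, "rnasomatic", "CDS",
                          rows$cds_start, rows$cds_end, ".", strand,
                          frame_by_row, attr_str, sep = "\t"))
    }
    list(fasta = fasta, gtf = gtf, genome = genome, genes = genes_df)
  })
}

# sample n positions (chrom x pos) keeping pairwise per-chromosome
# distance > gap from already-taken positions; candidates: data frame
# (chrom, pos) or NULL for uniform over the genome
place_points <- function(n, cfg, taken, gap, candidates = NULL,
                         max_tries = 200L) {
  chroms <- names(taken)
  chosen <- data.frame(chrom = character(), pos = integer(),
                       stringsAsFactors = FALSE)
  if (n <= 0L) return(list(points = chosen, taken = taken))
  if (!is.null(candidates) && nrow(candidates))
    candidates <- candidates[sample.int(nrow(candidates)), , drop = FALSE]
  ci <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      if (is.null(candidates)) {
        ch <- sample(chroms, 1L)
        p <- sample.int(cfg$chrom_length - 20L, 1L) + 10L
      } else {
        ci <- ci + 1L
        if (ci > nrow(candidates)) break
        ch <- candidates$chrom[ci]; p <- candidates$pos[ci]
      }
      if (!length(taken[[ch]]) || all(abs(taken[[ch]] - p) > gap)) {
        taken[[ch]] <- c(taken[[ch]], p)
        chosen <- rbind(chosen, data.frame(chrom = ch, pos = p,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("variant spacing constraints unsatisfiable: rates too ",
                  "high for the genome size")
  }
  list(points = chosen, taken = taken)
}

draw_alt_snv <- function(ref, ti_prob) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < ti_prob) return(unname(ti[ref]))
  sample(setdiff(VALID_BASES, c(ref, ti[ref])), 1L)
}

truncated_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate a paired tumor/normal callset with ground truth
#'
#' Plants, with global inter-variant spacing wider than the mismatch
#' window: germline variants in both tissues (a configured fraction
#' entered into the known DB), tumor-only somatic variants constructed
#' to pass every cascade filter (QUAL above threshold, depth within the
#' ceiling the cascade will train, coverage in both tissues, no planted
#' neighbors), editing-like A-to-G changes on transcribed strands in
#' both tissues, and five artifact classes that each violate exactly one
#' filter. Coverage tracks are negative-binomial with duplicate spikes
#' and are kept consistent with the planted depths.
#'
#' @param cfg a [simulation_config()].
#' @param ref a [simulate_reference()] result built from the same config.
#' @return list with `pair` ([sample_pair()]), `db` ([known_db()]),
#'   `truth` (data frame: chrom, pos, ref, alt, label,
#'   expected_final_status) and `cutoff_estimate` (the per-sample
#'   ceilings the cascade will train).
#' @export
simulate_pair <- function(cfg = simulation_config(),
                          ref = simulate_reference(cfg)) {
  with_seed(cfg$seed + 1L, {
    chroms <- names(ref$genome)
    L <- cfg$chrom_length
    G <- length(chroms) * L
    cov <- cfg$coverage
    tracks <- list()
    for (s in c("tumor", "normal")) {
      tracks[[s]] <- lapply(stats::setNames(chroms, chroms), function(ch) {
        d <- stats::rnbinom(L, mu = cov$mean, size = cov$size)
        spike <- stats::runif(L) < cov$spike_prob
        d[spike] <- d[spike] * cov$spike_mult
        pmax(d, 1L)                      # expressed everywhere (toy world)
      })
    }

    base_at <- function(ch, p, len = 1L) substr(ref$genome[[ch]], p, p + len - 1L)
    gap <- 11L                           # > flank so windows stay clean
    taken <- stats::setNames(rep(list(integer(0)), length(chroms)), chroms)

    # exonic candidates for editing: genomic A on + strand genes, T on -
    edit_cand <- NULL
    n_exonic <- 0L
    if (nrow(ref$genes)) {
      rows <- ref$genes
      cand <- list()
      for (i in seq_len(nrow(rows))) {
        pos <- seq(rows$exon_start[i], rows$exon_end[i])
        n_exonic <- n_exonic + length(pos)
        want <- if (rows$strand[i] == "+") "A" else "T"
        bases <- strsplit(substr(ref$genome[[rows$chrom[i]]],
                                 rows$exon_start[i], rows$exon_end[i]),
                          "")[[1]]
        hit <- pos[bases == want]
        if (length(hit))
          cand[[length(cand) + 1L]] <- data.frame(
            chrom = rows$chrom[i], pos = hit, strand = rows$strand[i],
            stringsAsFactors = FALSE)
      }
      if (length(cand)) edit_cand <- do.call(rbind, cand)
    }

    mk_var <- function(points, label, indel_frac = 0) {
      n <- nrow(points)
      if (!n) return(NULL)
      out <- points
      out$ref <- NA_character_; out$alt <- NA_character_
      for (i in seq_len(n)) {
        ch <- out$chrom[i]; p <- out$pos[i]
        r1 <- base_at(ch, p)
        if (stats::runif(1) < indel_frac) {
          k <- sample(1:3, 1L)
          if (stats::runif(1) < 0.5) {            # insertion after p
            out$ref[i] <- r1
            out$alt[i] <- paste0(r1, paste(sample(VALID_BASES, k,
                                                  replace = TRUE),
                                           collapse = ""))
          } else {                                # deletion of k bases
            out$ref[i] <- base_at(ch, p, k + 1L)
            out$alt[i] <- r1
          }
        } else {
          out$ref[i] <- r1
          out$alt[i] <- draw_alt_snv(r1, cfg$transition_prob)
        }
      }
      out$label <- label
      out
    }

    plant <- list()

    # editing: A->G on the transcribed strand, both tissues
    n_edit <- round(cfg$editing_rate * n_exonic)
    if (n_edit > 0L && !is.null(edit_cand)) {
      pl <- place_points(n_edit, cfg, taken, gap, candidates = edit_cand)
      taken <- pl$taken
      pts <- pl$points
      if (nrow(pts)) {
        pts$ref <- vapply(seq_len(nrow(pts)), function(i)
          base_at(pts$chrom[i], pts$pos[i]), "")
        pts$alt <- ifelse(pts$ref == "A", "G", "C")   # T->C mirrors A->G
        pts$label <- "editing"
        plant$editing <- pts
      }
    }

    # germline (both tissues; known_db_fraction recorded in the DB)
    n_germ <- round(cfg$germline_rate * G)
    pl <- place_points(n_germ, cfg, taken, gap)
    taken <- pl$taken
    germ <- mk_var(pl$points, "germline_novel", cfg$indel_fraction)
    if (!is.null(germ) && nrow(germ)) {
      in_db <- stats::runif(nrow(germ)) < cfg$known_db_fraction
      germ$label[in_db] <- "germline_known"
    }
    plant$germline <- germ

    # somatic (tumor only)
    n_som <- round(cfg$somatic_rate * G)
    pl <- place_points(n_som, cfg, taken, gap)
    taken <- pl$taken
    plant$somatic <- mk_var(pl$points, "somatic", cfg$indel_fraction)

    # artifact classes
    ar <- cfg$artifact_rates
    for (cls in c("lowqual", "spike", "onesample", "shared")) {
      n <- round(ar[[cls]] * G)
      pl <- place_points(n, cfg, taken, gap)
      taken <- pl$taken
      plant[[cls]] <- mk_var(pl$points, paste0("artifact_", cls))
    }
    n_clust <- round(ar$cluster * G)
    if (n_clust > 0L) {
      rows <- list()
      for (i in seq_len(n_clust)) {
        ok <- FALSE
        for (try in 1:200) {
          ch <- sample(chroms, 1L)
          p <- sample.int(L - 40L, 1L) + 20L
          offs <- c(0L, cumsum(sample(2:4, 2L, replace = TRUE)))
          ps <- p + offs
          if (!length(taken[[ch]]) ||
              all(vapply(ps, function(q)
                all(abs(taken[[ch]] - q) > gap), logical(1)))) {
            taken[[ch]] <- c(taken[[ch]], ps)
            rows[[i]] <- data.frame(chrom = ch, pos = ps,
                                    stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("cannot place mismatch cluster: genome too crowded")
      }
      plant$cluster <- mk_var(do.call(rbind, rows), "artifact_cluster")
    }

    all_vars <- do.call(rbind, Filter(Negate(is.null), unname(plant)))
    if (is.null(all_vars))
      all_vars <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             label = character(), stringsAsFactors = FALSE)
    all_vars <- all_vars[, c("chrom", "pos", "ref", "alt", "label")]

    # the cascade trains its ceiling on known (DB-member) germline depths;
    # compute the same nearest-rank quantile here so somatic and
    # filter-targeted artifacts can be kept safely inside or outside it
    q <- 0.975
    cutoff_est <- c(tumor = NA_integer_, normal = NA_integer_)
    for (s in c("tumor", "normal")) {
      known <- all_vars[all_vars$label == "germline_known", , drop = FALSE]
      if (nrow(known)) {
        d <- vapply(seq_len(nrow(known)), function(i)
          tracks[[s]][[known$chrom[i]]][known$pos[i]], 0)
        d <- sort(d)
        cutoff_est[s] <- as.integer(d[ceiling(q * length(d))])
      }
    }
    safe_depth <- function(s) {
      hi <- cutoff_est[[s]]
      if (is.na(hi)) hi <- cov$mean * 3
      max(1L, min(as.integer(round(cov$mean)), as.integer(hi)))
    }
    clamp <- function(s, ch, p, lo = 1L, hi = NULL) {
      # force track depth into [lo, hi] at one site
      d <- tracks[[s]][[ch]][p]
      if (is.null(hi)) hi <- .Machine$integer.max
      if (d < lo || d > hi)
        tracks[[s]][[ch]][p] <<- min(max(d, lo), hi, safe_depth(s))
    }

    qual_true <- function(n) truncated_norm(n, cfg$qual$true_mean,
                                            cfg$qual$true_sd, lo = 25)
    qual_art <- function(n) truncated_norm(n, cfg$qual$artifact_mean,
                                           cfg$qual$artifact_sd,
                                           lo = 0, hi = 19.5)

    tumor_rows <- list(); normal_rows <- list()
    add <- function(side, df) {
      if (side == "tumor") tumor_rows[[length(tumor_rows) + 1L]] <<- df
      else normal_rows[[length(normal_rows) + 1L]] <<- df
    }

    ceiling_frac <- 0.9   # planted 'clean' depths stay within 90% of ceiling
    for (i in seq_len(nrow(all_vars))) {
      v <- all_vars[i, ]
      ch <- v$chrom; p <- v$pos
      lab <- v$label
      if (lab %in% c("germline_known", "germline_novel", "editing")) {
        q1 <- qual_true(1); q2 <- qual_true(1)
        add("tumor", data.frame(v, qual = q1,
                                depth = tracks$tumor[[ch]][p]))
        add("normal", data.frame(v, qual = q2,
                                 depth = tracks$normal[[ch]][p]))
      } else if (lab == "somatic") {
        hiT <- max(1L, as.integer(floor(cutoff_est[["tumor"]] * ceiling_frac)))
        clamp("tumor", ch, p, lo = 1L, hi = hiT)
        clamp("normal", ch, p, lo = 1L)
        add("tumor", data.frame(v, qual = qual_true(1),
                                depth = tracks$tumor[[ch]][p]))
      } else if (lab == "artifact_lowqual") {
        clamp("tumor", ch, p, lo = 1L); clamp("normal", ch, p, lo = 1L)
        add("tumor", data.frame(v, qual = qual_art(1),
                                depth = tracks$tumor[[ch]][p]))
      } else if (lab == "artifact_spike") {
        hi <- cutoff_est[["tumor"]]
        if (is.na(hi)) hi <- as.integer(cov$mean * 5)
        tracks$tumor[[ch]][p] <- as.integer(hi * 10L + 50L)
        clamp("normal", ch, p, lo = 1L)
        add("tumor", data.frame(v, qual = qual_true(1),
                                depth = tracks$tumor[[ch]][p]))
      } else if (lab == "artifact_onesample") {
        hiT <- max(1L, as.integer(floor(cutoff_est[["tumor"]] * ceiling_frac)))
        clamp("tumor", ch, p, lo = 1L, hi = hiT)
        tracks$normal[[ch]][p] <- 0L
        add("tumor", data.frame(v, qual = qual_true(1),
                                depth = tracks$tumor[[ch]][p]))
      } else if (lab == "artifact_shared") {
        hiT <- max(1L, as.integer(floor(cutoff_est[["tumor"]] * ceiling_frac)))
        hiN <- max(1L, as.integer(floor(cutoff_est[["normal"]] * ceiling_frac)))
        clamp("tumor", ch, p, lo = 1L, hi = hiT)
        clamp("normal", ch, p, lo = 1L, hi = hiN)
        add("tumor", data.frame(v, qual = qual_true(1),
                                depth = tracks$tumor[[ch]][p]))
        add("normal", data.frame(v, qual = qual_true(1),
                                 depth = tracks$normal[[ch]][p]))
      } else if (lab == "artifact_cluster") {
        hiT <- max(1L, as.integer(floor(cutoff_est[["tumor"]] * ceiling_frac)))
        clamp("tumor", ch, p, lo = 1L, hi = hiT)
        clamp("normal", ch, p, lo = 1L)
        add("tumor", data.frame(v, qual = qual_true(1),
                                depth = tracks$tumor[[ch]][p]))
      }
    }

    build_cs <- function(rows, id) {
      if (!length(rows)) return(call_set(sample_id = id))
      df <- do.call(rbind, rows)
      call_set(df[, c("chrom", "pos", "ref", "alt", "qual", "depth")],
               sample_id = id)
    }
    tumor_cs <- build_cs(tumor_rows, "tumor")
    normal_cs <- build_cs(normal_rows, "normal")

    # known DB: germline_known entries plus uncalled decoys
    dbdf <- all_vars[all_vars$label == "germline_known",
                     c("chrom", "pos", "ref", "alt"), drop = FALSE]
    if (cfg$db_decoys > 0L) {
      pl <- place_points(cfg$db_decoys, cfg, taken, gap)
      taken <- pl$taken
      dec <- mk_var(pl$points, "decoy")
      if (!is.null(dec))
        dbdf <- rbind(dbdf, dec[, c("chrom", "pos", "ref", "alt")])
    }
    db <- known_db(dbdf)

    truth <- all_vars
    truth$expected_final_status <- ifelse(truth$label == "somatic",
                                          "tumor_specific", "removed")
    o <- order(truth$chrom, truth$pos, truth$ref, truth$alt,
               method = "radix")
    truth <- truth[o, , drop = FALSE]
    rownames(truth) <- NULL

    pair <- sample_pair(
      tumor = list(calls = tumor_cs,
                   coverage = coverage_track(tracks$tumor)),
      normal = list(calls = normal_cs,
                    coverage = coverage_track(tracks$normal)),
      pair_id = paste0("sim", cfg$seed))
    list(pair = pair, db = db, truth = truth,
         cutoff_estimate = cutoff_est)
  })
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `known.tsv`, `tumor.vcf`,
#' `normal.vcf`, `tumor.cov.tsv`, `normal.cov.tsv`, `truth.tsv`.
#'
#' @param ref a [simulate_reference()] result.
#' @param sim a [simulate_pair()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths.
#' @export
write_simulation <- function(ref, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             known = file.path(dir, "known.tsv"),
             tumor_vcf = file.path(dir, "tumor.vcf"),
             normal_vcf = file.path(dir, "normal.vcf"),
             tumor_cov = file.path(dir, "tumor.cov.tsv"),
             normal_cov = file.path(dir, "normal.cov.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(ref$fasta, paths["genome"])
  writeLines(ref$gtf, paths["gtf"])
  write_known_db(sim$db, paths["known"])
  write_vcf(sim$pair$tumor$calls, paths["tumor_vcf"])
  write_vcf(sim$pair$normal$calls, paths["normal_vcf"])
  write_coverage(sim$pair$tumor$coverage, paths["tumor_cov"])
  write_coverage(sim$pair$normal$coverage, paths["normal_cov"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Score cascade output against simulation ground truth
#'
#' @param tumor_specific,normal_specific CallSets from [run_cascade()].
#' @param truth truth table from [simulate_pair()].
#' @return list with `by_label` (per-label planted/retained/removed
#'   counts), `sensitivity` and `specificity` for the somatic label, and
#'   `unplanted` (calls retained that were never planted).
#' @export
evaluate_against_truth <- function(tumor_specific, normal_specific, truth) {
  retained <- unique(c(variant_key(tumor_specific),
                       variant_key(normal_specific)))
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  truth$retained <- tkey %in% retained
  by_label <- do.call(rbind, lapply(split(truth, truth$label), function(d)
    data.frame(label = d$label[1], planted = nrow(d),
               retained = sum(d$retained), removed = sum(!d$retained),
               stringsAsFactors = FALSE)))
  rownames(by_label) <- NULL
  som <- truth$label == "somatic"
  n_som <- sum(som)
  tp <- sum(tkey[som] %in% variant_key(tumor_specific))
  fp <- sum(truth$retained[!som])
  sens <- if (n_som) tp / n_som else NA_real_
  spec <- if (sum(!som)) 1 - fp / sum(!som) else NA_real_
  list(by_label = by_label,
       sensitivity = sens, specificity = spec,
       unplanted = sum(!retained %in% tkey))
}
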