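VALID_BASES <- c("A", "C", "G", "T")

read_text_lines <- function(path) {
  # gzfile() transparently reads both plain and gzip-compressed text
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Normalize variant alleles to their minimal left-anchored representation
#'
#' Trims bases shared between `ref` and `alt` (suffix first, then prefix,
#' shifting `pos` right for every trimmed leading base) so that equivalent
#' indel records index identically in known-variant and shared-call lookups.
#' At least one base is always kept on each allele.
#'
#' @param pos 1-based position vector.
#' @param ref,alt character vectors of alleles.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim common suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

#' Construct a CallSet
#'
#' A CallSet is a data frame of variant calls for one sample, sorted by
#' (chrom, pos, ref, alt) and unique on that key. Columns: `chrom`, `pos`
#' (1-based), `ref`, `alt`, `qual` (phred-scaled), `depth` (reads at the
#' site), `vclass` (SNV/INS/DEL, derived).
#'
#' @param df data frame with columns chrom, pos, ref, alt, qual, depth.
#' @param sample_id sample label.
#' @param validate check allele alphabet and key uniqueness.
#' @return an object of class `CallSet`.
#' @export
call_set <- function(df = NULL, sample_id = "sample", validate = TRUE) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     qual = numeric(), depth = integer(),
                     stringsAsFactors = FALSE)
  }
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CallSet missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$qual <- as.numeric(df$qual)
  df$depth <- as.integer(df$depth)
  if (validate && nrow(df)) {
    bases <- strsplit(paste0(df$ref, df$alt), "")
    ok <- vapply(bases, function(b) all(b %in% VALID_BASES), logical(1))
    if (!all(ok)) stop("non-ACGT allele at row ", which(!ok)[1])
    if (any(df$ref == df$alt)) stop("ref and alt identical at row ",
                                    which(df$ref == df$alt)[1])
    if (any(df$qual < 0)) stop("negative qual")
    if (any(df$depth < 0)) stop("negative depth")
  }
  df$vclass <- variant_class(df$ref, df$alt)
  o <- order(df$chrom, df$pos, df$ref, df$alt, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (validate && nrow(df)) {
    k <- variant_key(df)
    if (anyDuplicated(k)) stop("duplicate variant key: ", k[duplicated(k)][1])
  }
  structure(df, sample_id = sample_id,
            class = c("CallSet", "data.frame"))
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' @export
sample_id <- function(cs) attr(cs, "sample_id")

cs_subset <- function(cs, keep) {
  call_set(as.data.frame(cs)[keep, , drop = FALSE],
           sample_id = sample_id(cs), validate = FALSE)
}

#' @export
print.CallSet <- function(x, ...) {
  cat("CallSet [", sample_id(x), "]: ", nrow(x), " calls (",
      sum(x$vclass == "SNV"), " SNV, ", sum(x$vclass == "INS"), " INS, ",
      sum(x$vclass == "DEL"), " DEL)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read a single-sample VCF into a CallSet
#'
#' Accepts VCF 4.x, plain or gzip-compressed. Multi-allelic records are
#' split into one call per ALT allele; alleles are trimmed to their
#' minimal representation. `depth` is taken from the INFO `DP` field
#' (0 when absent); a missing QUAL (`.`) becomes 0. Multi-sample files
#' are rejected.
#'
#' @param path VCF file path.
#' @param sample_id override the sample label (default: header sample
#'   name, or the file basename for sites-only files).
#' @return a [call_set()] object.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- read_text_lines(path)
  hdr <- grepl("^#", lines)
  if (!any(hdr) || !grepl("^##fileformat=VCF", lines[1]))
    stop("parse error at line 1: missing ##fileformat=VCF header")
  chrom_line <- grep("^#CHROM\t", lines)
  if (length(chrom_line) != 1L)
    stop("parse error: expected exactly one #CHROM header line")
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  if (length(cols) > 10L)
    stop("multi-sample VCF not supported (", length(cols) - 9L, " samples)")
  if (is.null(sample_id)) {
    sample_id <- if (length(cols) == 10L) cols[10] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  body_idx <- which(!hdr)
  recs <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("parse error at line ", i, ": expected >= 8 fields, got ", length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos))
      stop("parse error at line ", i, ": bad POS '", f[2], "'")
    qual <- if (f[6] == ".") 0 else suppressWarnings(as.numeric(f[6]))
    if (is.na(qual))
      stop("parse error at line ", i, ": bad QUAL '", f[6], "'")
    dp <- 0L
    m <- regmatches(f[8], regexec("(?:^|;)DP=([0-9]+)", f[8]))[[1]]
    if (length(m) == 2L) dp <- as.integer(m[2])
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    recs[[j]] <- data.frame(chrom = f[1], pos = pos, ref = toupper(f[4]),
                            alt = toupper(alts), qual = qual, depth = dp,
                            stringsAsFactors = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, recs) else NULL
  if (!is.null(df) && nrow(df)) {
    nz <- normalize_alleles(df$pos, df$ref, df$alt)
    df$pos <- nz$pos; df$ref <- nz$ref; df$alt <- nz$alt
  }
  call_set(df, sample_id = sample_id)
}

#' Write a CallSet as a minimal sites-only VCF 4.2 file
#'
#' Round-trips through [read_vcf()] losslessly for the CallSet fields.
#'
#' @param cs a CallSet.
#' @param path output path (".gz" suffix triggers gzip compression).
#' @export
write_vcf <- function(cs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rnasomatic",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- character(0)
  if (nrow(cs)) {
    body <- paste(cs$chrom, cs$pos, ".", cs$ref, cs$alt,
                  sprintf("%.10g", cs$qual), ".",
                  paste0("DP=", cs$depth), sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  ok <- tryCatch({ writeLines(c(hdr, body), con); TRUE },
                 error = function(e) e)
  close(con)
  if (!isTRUE(ok)) stop("cannot write VCF to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Construct a CoverageTrack from per-position depths
#'
#' Stores one dense integer vector per chromosome; positions beyond the
#' stored range (and chromosomes never seen) report depth 0.
#'
#' @param depths named list, chromosome -> integer vector indexed by
#'   1-based position.
#' @return object of class `CoverageTrack`.
#' @export
coverage_track <- function(depths = list()) {
  depths <- lapply(depths, function(v) {
    v <- as.integer(v)
    if (any(v < 0, na.rm = TRUE)) stop("negative depth in coverage track")
    v[is.na(v)] <- 0L
    v
  })
  structure(list(depths = depths), class = "CoverageTrack")
}

#' Query read depth at positions
#'
#' @param track a CoverageTrack.
#' @param chrom chromosome name (scalar).
#' @param pos integer vector of 1-based positions.
#' @return integer vector of depths (0 outside stored ranges).
#' @export
coverage_depth <- function(track, chrom, pos) {
  v <- track$depths[[chrom]]
  if (is.null(v)) return(integer(length(pos)))
  out <- integer(length(pos))
  inside <- pos >= 1L & pos <= length(v)
  out[inside] <- v[pos[inside]]
  out
}

#' Read a per-position coverage track
#'
#' Accepts a 3-column TSV (`chrom  pos  depth`, 1-based positions) or a
#' 4-column BEDGraph (`chrom  start  end  depth`, 0-based half-open
#' intervals); gzip input allowed. A BEDGraph interval \[a,b) covers the
#' 1-based positions a+1 .. b.
#'
#' @param path input file.
#' @return a [coverage_track()].
#' @export
read_coverage <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(coverage_track())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(parts[[1]])
  if (!ncol %in% c(3L, 4L))
    stop("coverage file must have 3 (TSV) or 4 (BEDGraph) columns, got ", ncol)
  bad <- which(lengths(parts) != ncol)
  if (length(bad)) stop("parse error at line ", bad[1], ": ragged row")
  chrom <- vapply(parts, `[[`, "", 1L)
  if (ncol == 3L) {
    pos <- as.integer(vapply(parts, `[[`, "", 2L))
    dep <- as.integer(vapply(parts, `[[`, "", 3L))
    if (any(is.na(pos)) || any(is.na(dep))) stop("non-numeric coverage row")
    if (any(dep < 0)) stop("negative depth at line ", which(dep < 0)[1])
    depths <- list()
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      v <- integer(max(pos[sel]))
      v[pos[sel]] <- dep[sel]
      depths[[ch]] <- v
    }
  } else {
    a <- as.integer(vapply(parts, `[[`, "", 2L))
    b <- as.integer(vapply(parts, `[[`, "", 3L))
    dep <- as.integer(vapply(parts, `[[`, "", 4L))
    if (any(is.na(a)) || any(is.na(b)) || any(is.na(dep)))
      stop("non-numeric BEDGraph row")
    if (any(dep < 0)) stop("negative depth at line ", which(dep < 0)[1])
    if (any(b <= a)) stop("empty BEDGraph interval at line ", which(b <= a)[1])
    depths <- list()
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      v <- integer(max(b[sel]))
      for (i in sel) v[(a[i] + 1L):b[i]] <- dep[i]
      depths[[ch]] <- v
    }
  }
  coverage_track(depths)
}

#' Write a CoverageTrack as a 3-column TSV (non-zero positions only)
#' @param track a CoverageTrack.
#' @param path output path (".gz" supported).
#' @export
write_coverage <- function(track, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (ch in names(track$depths)) {
    v <- track$depths[[ch]]
    nz <- which(v > 0L)
    if (length(nz))
      writeLines(paste(ch, nz, v[nz], sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a known-variant membership index
#'
#' Exact-match set over (chrom, pos, ref, alt), with a secondary
#' positional index for positional (allele-blind) matching.
#'
#' @param df data frame with columns chrom, pos, ref, alt.
#' @return object of class `KnownVariantDB`.
#' @export
known_db <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    return(structure(list(keys = character(), pos_keys = character()),
                     class = "KnownVariantDB"))
  }
  nz <- normalize_alleles(as.integer(df$pos), toupper(as.character(df$ref)),
                          toupper(as.character(df$alt)))
  keys <- unique(paste(df$chrom, nz$pos, nz$ref, nz$alt, sep = ":"))
  pos_keys <- unique(paste(df$chrom, nz$pos, sep = ":"))
  structure(list(keys = keys, pos_keys = pos_keys), class = "KnownVariantDB")
}

#' @export
print.KnownVariantDB <- function(x, ...) {
  cat("KnownVariantDB:", length(x$keys), "variants at",
      length(x$pos_keys), "positions\n")
  invisible(x)
}

#' @export
db_size <- function(db) length(db$keys)

#' Test membership of calls in a known-variant database
#'
#' @param db a [known_db()].
#' @param cs a CallSet (or data frame with chrom/pos/ref/alt).
#' @param positional match on (chrom, pos) only, ignoring alleles.
#' @return logical vector, one element per call.
#' @export
db_contains <- function(db, cs, positional = FALSE) {
  if (nrow(cs) == 0L) return(logical(0))
  if (positional) paste(cs$chrom, cs$pos, sep = ":") %in% db$pos_keys
  else variant_key(cs) %in% db$keys
}

#' Read a known-variant database (dbSNP-like)
#'
#' Accepts a VCF (multi-allelic records split) or a headerless 4-column
#' TSV (`chrom pos ref alt`); gzip allowed. Duplicate entries collapse.
#'
#' @param path input file.
#' @return a [known_db()].
#' @export
read_known_db <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) && grepl("^##fileformat=VCF", lines[1])) {
    cs <- read_vcf(path, sample_id = "db")
    return(known_db(as.data.frame(cs)))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(known_db())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) stop("parse error at line ", bad[1],
                        ": expected 4 columns (chrom pos ref alt)")
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  if (any(is.na(pos))) stop("parse error at line ", which(is.na(pos))[1],
                            ": non-integer position")
  known_db(data.frame(chrom = vapply(parts, `[[`, "", 1L), pos = pos,
                      ref = vapply(parts, `[[`, "", 3L),
                      alt = vapply(parts, `[[`, "", 4L),
                      stringsAsFactors = FALSE))
}

#' Write a KnownVariantDB as 4-column TSV
#' @param db a KnownVariantDB.
#' @param path output path.
#' @export
write_known_db <- function(db, path) {
  writeLines(gsub(":", "\t", db$keys, fixed = TRUE), path)
  invisible(path)
}

#' Bundle the two samples of a tumor/normal pair
#'
#' @param tumor,normal lists with elements `calls` (CallSet) and
#'   `coverage` (CoverageTrack).
#' @param pair_id pair label.
#' @return object of class `SamplePair`.
#' @export
sample_pair <- function(tumor, normal, pair_id = "pair") {
  stopifnot(inherits(tumor$calls, "CallSet"),
            inherits(normal$calls, "CallSet"),
            inherits(tumor$coverage, "CoverageTrack"),
            inherits(normal$coverage, "CoverageTrack"))
  if (identical(sample_id(tumor$calls), sample_id(normal$calls)))
    stop("tumor and normal must have distinct sample_ids")
  structure(list(tumor = tumor, normal = normal, pair_id = pair_id),
            class = "SamplePair")
}
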