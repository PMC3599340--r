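SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

check_snv_alleles <- function(ref, alt) {
  if (!all(ref %in% VALID_BASES) || !all(alt %in% VALID_BASES))
    stop("alleles must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
}

#' Collapse a base substitution into one of six pyrimidine-reference classes
#'
#' A substitution and its reverse complement are the same molecular event,
#' so the twelve directed changes collapse to six classes keyed on a
#' pyrimidine (C or T) reference base.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param collapse collapse to the 6 pyrimidine-reference classes
#'   (default); `FALSE` returns the directed 12-class label.
#' @return character vector of class labels, e.g. `"C>T"`.
#' @export
classify_substitution <- function(ref, alt, collapse = TRUE) {
  ref <- toupper(ref); alt <- toupper(alt)
  check_snv_alleles(ref, alt)
  if (collapse) {
    flip <- ref %in% c("A", "G")
    ref[flip] <- COMPLEMENT[ref[flip]]
    alt[flip] <- COMPLEMENT[alt[flip]]
  }
  paste0(ref, ">", alt)
}

#' Is a substitution a transition?
#'
#' Transitions are purine<->purine (A<->G) or pyrimidine<->pyrimidine
#' (C<->T); everything else is a transversion.
#'
#' @param ref,alt single bases (vectorized).
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  check_snv_alleles(ref, alt)
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Tabulate the mutation spectrum of a callset
#'
#' Counts SNVs per collapsed substitution class plus insertions and
#' deletions.
#'
#' @param cs a CallSet.
#' @return a `SpectrumTable`: named integer vector over
#'   `C>A, C>G, C>T, T>A, T>C, T>G, INS, DEL` with attribute `sample_id`.
#' @export
build_spectrum <- function(cs) {
  counts <- stats::setNames(integer(8), c(SUBSTITUTION_CLASSES, "INS", "DEL"))
  snv <- cs$vclass == "SNV"
  if (any(snv)) {
    tab <- table(classify_substitution(cs$ref[snv], cs$alt[snv]))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts["INS"] <- sum(cs$vclass == "INS")
  counts["DEL"] <- sum(cs$vclass == "DEL")
  structure(counts, sample_id = sample_id(cs), class = "SpectrumTable")
}

#' @export
print.SpectrumTable <- function(x, ...) {
  cat("SpectrumTable [", attr(x, "sample_id"), "]\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Transition/transversion ratio of a callset
#'
#' Computed over SNVs only; indels are excluded. Errors when the callset
#' contains no transversions (the ratio is undefined).
#'
#' @param cs a CallSet.
#' @return numeric Ti/Tv ratio.
#' @export
titv_ratio <- function(cs) {
  snv <- cs$vclass == "SNV"
  if (!any(snv)) stop("no SNVs: Ti/Tv undefined")
  ti <- is_transition(cs$ref[snv], cs$alt[snv])
  if (!any(!ti)) stop("no transversions: Ti/Tv undefined")
  sum(ti) / sum(!ti)
}

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude (unlike base
#' [round()]'s round-half-even), matching how ratios and percentages are
#' conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ratio of two counts, rounded half-up
#'
#' @param n_tumor,n_normal non-negative counts (`n_normal` > 0).
#' @param decimals decimal places for the printed ratio.
#' @return rounded numeric ratio.
#' @export
count_ratio <- function(n_tumor, n_normal, decimals = 2) {
  if (n_normal <= 0) stop("denominator must be positive")
  round_half_up(n_tumor / n_normal, decimals)
}

as_2x2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == 2L))
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  stopifnot(length(t) == 4L, all(t >= 0), all(t == floor(t)))
  as.numeric(t)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: with margins fixed, sums the hypergeometric
#' probabilities of every table whose point probability does not exceed
#' that of the observed table (point-probability rule, relative tolerance
#' 1e-7 — the convention of `stats::fisher.test`).
#'
#' @param t 2x2 matrix or length-4 vector `c(a, b, c, d)` read row-wise.
#' @return two-sided p-value in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(t) {
  v <- as_2x2(t)
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  if (sum(v) == 0) stop("all-zero table")
  m <- a + b            # row 1 total
  n <- cc + d           # row 2 total
  k <- a + cc           # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact by complete enumeration of rank assignments when both samples
#' have at most `exact_max` observations (ties handled through average
#' ranks); otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max enumeration size limit per sample (default 8).
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    N <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  }
  min(p, 1)
}

#' Write a SpectrumTable (or several) as TSV
#' @param spectra a SpectrumTable or list of them.
#' @param path output path.
#' @export
write_spectrum <- function(spectra, path) {
  if (inherits(spectra, "SpectrumTable")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(sample = attr(s, "sample_id"), class = names(s),
               count = as.integer(s), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
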