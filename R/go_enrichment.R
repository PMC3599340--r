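#' Parse an OBO 1.2 ontology file into a GO DAG
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a parents); obsolete
#' terms are dropped. Only `is_a` edges are kept.
#'
#' @param path OBO file (gzip allowed).
#' @return a `GODag`: list with `terms` (data frame id/name/namespace)
#'   and `parents` (named list id -> character vector of parent ids).
#' @export
read_obo <- function(path) {
  lines <- read_text_lines(path)
  terms <- list(); parents <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <<- data.frame(
        id = cur$id, name = cur$name %||% cur$id,
        namespace = cur$namespace %||% "biological_process",
        stringsAsFactors = FALSE)
      parents[[cur$id]] <<- cur$parents %||% character(0)
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)                 # strip trailing comments
    if (ln == "[Term]") { flush(cur); cur <- list(parents = character(0))
                          in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-zA-Z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, sub("\\s.*", "", val))
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  flush(cur)
  dag <- structure(list(terms = do.call(rbind, unname(terms)),
                        parents = parents),
                   class = "GODag")
  validate_dag(dag)
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a GO DAG from data frames (for tests and simulation)
#' @param terms data frame with id, name, namespace.
#' @param edges data frame with child, parent (is_a edges).
#' @return a `GODag`.
#' @export
go_dag <- function(terms, edges) {
  parents <- lapply(stats::setNames(terms$id, terms$id), function(id)
    edges$parent[edges$child == id])
  dag <- structure(list(terms = as.data.frame(terms), parents = parents),
                   class = "GODag")
  validate_dag(dag)
  dag
}

validate_dag <- function(dag) {
  # cycle check via iterative ancestor closure
  for (id in names(dag$parents)) {
    seen <- character(0); frontier <- dag$parents[[id]]
    while (length(frontier)) {
      if (id %in% frontier) stop("cycle in ontology involving ", id)
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
    }
  }
  invisible(dag)
}

#' All is_a ancestors of a term (excluding the term itself)
#' @param dag a `GODag`.
#' @param id term id.
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, id) {
  seen <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  seen
}

#' Read gene -> GO term annotations
#'
#' Accepts a 2-column TSV (`gene_id  term_id`) or GAF (comment lines
#' start with `!`; gene from column 2, term from column 5).
#'
#' @param path input file (gzip allowed).
#' @return named list gene_id -> character vector of directly annotated
#'   term ids.
#' @export
read_gene_annotations <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  gaf <- any(grepl("^!", lines))
  lines <- lines[!grepl("^[!#]", lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (gaf || length(parts[[1]]) >= 15L) {
    gene <- vapply(parts, `[[`, "", 2L)
    term <- vapply(parts, `[[`, "", 5L)
  } else {
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop("parse error at line ", bad[1],
                          ": expected 2 columns (gene term)")
    gene <- vapply(parts, `[[`, "", 1L)
    term <- vapply(parts, `[[`, "", 2L)
  }
  lapply(split(term, gene), unique)
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor
#' of that term; each gene's propagated set is the union of its direct
#' terms and all their is_a ancestors. Terms absent from the DAG are
#' skipped with a warning.
#'
#' @param direct named list gene -> direct term ids.
#' @param dag a `GODag`.
#' @return named list gene -> propagated term ids.
#' @export
propagate_annotations <- function(direct, dag) {
  known <- names(dag$parents)
  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    a <- go_ancestors(dag, t)
    anc_cache[[t]] <- a
    a
  }
  lapply(direct, function(ts) {
    unknown <- setdiff(ts, known)
    if (length(unknown))
      warning("skipping unknown term(s): ", paste(unknown, collapse = ", "))
    ts <- intersect(ts, known)
    unique(c(ts, unlist(lapply(ts, get_anc), use.names = FALSE)))
  })
}

#' Expected study-set hits for a term under the null
#'
#' `annotated * study_size / universe_size`, the mean of the
#' hypergeometric null, reported to two decimals.
#'
#' @param annotated universe genes annotated to the term.
#' @param study_size study-set size.
#' @param universe_size universe size (> 0).
#' @return numeric.
#' @export
expected_count <- function(annotated, study_size, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive")
  if (annotated > universe_size) stop("annotated exceeds universe")
  round_half_up(annotated * study_size / universe_size, 2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values (same order as input), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Per-term hypergeometric enrichment of a study gene set
#'
#' The classic one-sided (over-representation) test: for each term with
#' at least one annotated universe gene, the upper-tail hypergeometric
#' p-value of drawing >= `significant` annotated genes in a study of the
#' given size. Namespaces are tested separately; multiple-testing
#' correction (BH by default, Bonferroni optional) is applied within
#' each namespace.
#'
#' @param study character vector of study gene ids (subset of universe).
#' @param universe character vector of universe gene ids.
#' @param ann propagated annotations (named list gene -> term ids).
#' @param dag a `GODag`.
#' @param correction `"BH"` or `"bonferroni"`.
#' @param namespaces which namespaces to test.
#' @return data frame sorted by namespace then p-value: `term_id`,
#'   `name`, `namespace`, `annotated`, `significant`, `expected`,
#'   `p_value`, `corrected_p`.
#' @export
enrich_terms <- function(study, universe, ann, dag,
                         correction = c("BH", "bonferroni"),
                         namespaces = c("biological_process",
                                        "molecular_function",
                                        "cellular_component")) {
  correction <- match.arg(correction)
  study <- unique(study); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(study %in% universe))
    stop("study set is not a subset of the universe: ",
         paste(utils::head(setdiff(study, universe)), collapse = ", "))
  ann_u <- ann[intersect(names(ann), universe)]
  N <- length(universe); k <- length(study)
  term_genes <- split(rep(names(ann_u), lengths(ann_u)),
                      unlist(ann_u, use.names = FALSE))
  rows <- list()
  for (t in names(term_genes)) {
    g <- term_genes[[t]]
    annotated <- length(g)
    if (annotated < 1L) next
    significant <- length(intersect(g, study))
    p <- stats::phyper(significant - 1L, annotated, N - annotated, k,
                       lower.tail = FALSE)
    info <- dag$terms[match(t, dag$terms$id), ]
    rows[[t]] <- data.frame(
      term_id = t,
      name = if (nrow(info)) info$name else t,
      namespace = if (nrow(info)) info$namespace else NA_character_,
      annotated = annotated, significant = significant,
      expected = expected_count(annotated, k, N),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(term_id = character(), name = character(),
               namespace = character(), annotated = integer(),
               significant = integer(), expected = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  out <- out[out$namespace %in% namespaces | is.na(out$namespace), ,
             drop = FALSE]
  out$corrected_p <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- which(if (is.na(ns)) is.na(out$namespace) else
      !is.na(out$namespace) & out$namespace == ns)
    out$corrected_p[sel] <- if (correction == "BH")
      bh_adjust(out$p_value[sel])
    else pmin(1, out$p_value[sel] * length(sel))
  }
  out <- out[order(out$namespace, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
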