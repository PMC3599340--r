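#' Pipeline configuration
#'
#' Collects every input path, the filter thresholds and the enrichment
#' options for a full simulate/filter/spectrum/consequence/enrich run.
#' Either supply the four callset inputs (`tumor_vcf`, `normal_vcf`,
#' `tumor_cov`, `normal_cov`, plus `known_db`) or set `simulate = TRUE`
#' to generate them first. Serializable to/from JSON with
#' [read_pipeline_config()].
#'
#' @param out_dir output directory.
#' @param seed integer seed used for simulation.
#' @param simulate generate inputs with the synthetic-data module.
#' @param sim a [simulation_config()] (used when `simulate = TRUE`).
#' @param tumor_vcf,normal_vcf,tumor_cov,normal_cov,known_db,gtf,fasta
#'   input paths (ignored when simulating).
#' @param filter a [filter_config()].
#' @param obo,gene2go ontology and annotation paths (enrichment is
#'   skipped when either is NULL).
#' @param correction multiple-testing correction for enrichment.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            sim = simulation_config(seed = seed),
                            tumor_vcf = NULL, normal_vcf = NULL,
                            tumor_cov = NULL, normal_cov = NULL,
                            known_db = NULL, gtf = NULL, fasta = NULL,
                            obo = NULL, gene2go = NULL,
                            filter = filter_config(),
                            correction = "BH") {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate), sim = sim,
                 tumor_vcf = tumor_vcf, normal_vcf = normal_vcf,
                 tumor_cov = tumor_cov, normal_cov = normal_cov,
                 known_db = known_db, gtf = gtf, fasta = fasta,
                 obo = obo, gene2go = gene2go, filter = filter,
                 correction = correction),
            class = "PipelineConfig")
}

log_info <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [rnasomatic] ", ...)
}

#' Run the full screening pipeline
#'
#' Stages, in order: (optionally) simulate inputs; run the six-filter
#' cascade; tabulate mutation spectra and the comparison statistics
#' (tissue count ratio, novel-vs-total and Ti/Tv Fisher tests, the
#' known-vs-novel coverage rank-sum test); classify coding consequences
#' and gene recurrence; GO enrichment of disruptively hit genes. Writes
#' `filter_report.tsv`, `spectrum.tsv`, `stats.tsv`, `consequence.tsv`,
#' `recurrence.tsv`, `enrichment.tsv` and `manifest.json` under
#' `out_dir`. Deterministic for a fixed (seed, config).
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) list of in-memory stage results and the report
#'   file paths.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  if (cfg$simulate) {
    log_info("stage simulate: seed ", cfg$seed)
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    ref <- simulate_reference(sim_cfg)
    sim <- simulate_pair(sim_cfg, ref)
    sim_dir <- out("sim")
    paths <- write_simulation(ref, sim, sim_dir)
    cfg$tumor_vcf <- paths[["tumor_vcf"]]
    cfg$normal_vcf <- paths[["normal_vcf"]]
    cfg$tumor_cov <- paths[["tumor_cov"]]
    cfg$normal_cov <- paths[["normal_cov"]]
    cfg$known_db <- paths[["known"]]
    cfg$gtf <- paths[["gtf"]]
    cfg$fasta <- paths[["genome"]]
  }

  for (f in c("tumor_vcf", "normal_vcf", "tumor_cov", "normal_cov")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("missing input '", f, "': ", cfg[[f]] %||% "<unset>")
  }
  if (is.null(cfg$known_db) || !file.exists(cfg$known_db))
    stop("known-variant DB not found (required by Filter 2.2): ",
         cfg$known_db %||% "<unset>")

  log_info("stage filter: reading callsets")
  tumor <- list(calls = read_vcf(cfg$tumor_vcf, sample_id = "tumor"),
                coverage = read_coverage(cfg$tumor_cov))
  normal <- list(calls = read_vcf(cfg$normal_vcf, sample_id = "normal"),
                 coverage = read_coverage(cfg$normal_cov))
  pair <- sample_pair(tumor, normal)
  db <- read_known_db(cfg$known_db)
  res <- run_cascade(pair, db, cfg$filter)
  write_filter_report(res$report, out("filter_report.tsv"))
  write_vcf(res$tumor_specific, out("tumor_specific.vcf"))
  write_vcf(res$normal_specific, out("normal_specific.vcf"))
  log_info("stage filter: tumor-specific ", nrow(res$tumor_specific),
           ", normal-specific ", nrow(res$normal_specific))

  log_info("stage spectrum")
  spectra <- list(build_spectrum(res$tumor_specific),
                  build_spectrum(res$normal_specific))
  write_spectrum(spectra, out("spectrum.tsv"))
  stats_rows <- pipeline_stats(pair, db, res, cfg$filter)
  utils::write.table(stats_rows, out("stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cons_t <- cons_n <- NULL
  recur <- NULL
  if (!is.null(cfg$gtf) && !is.null(cfg$fasta)) {
    log_info("stage consequence")
    models <- index_gene_models(cfg$gtf, cfg$fasta)
    cons_t <- annotate_consequences(res$tumor_specific, models)
    cons_n <- annotate_consequences(res$normal_specific, models)
    tag <- function(lbl, df)
      cbind(sample = rep(lbl, nrow(df)), df, stringsAsFactors = FALSE)
    both <- rbind(tag("tumor", cons_t), tag("normal", cons_n))
    utils::write.table(both, out("consequence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    recur <- recurrent_gene_table(list(tumor = cons_t))
    utils::write.table(recur, out("recurrence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  enrich <- NULL
  if (!is.null(cfg$obo) && !is.null(cfg$gene2go) && !is.null(cons_t)) {
    log_info("stage enrich")
    dag <- read_obo(cfg$obo)
    direct <- read_gene_annotations(cfg$gene2go)
    ann <- propagate_annotations(direct, dag)
    universe <- names(ann)
    study <- intersect(unique(cons_t$gene_id[cons_t$disruptive]), universe)
    enrich <- enrich_terms(study, universe, ann, dag,
                           correction = cfg$correction)
    utils::write.table(enrich, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "rnasomatic",
    version = as.character(utils::packageVersion("rnasomatic")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = c("filter", "spectrum",
               if (!is.null(cons_t)) "consequence",
               if (!is.null(enrich)) "enrich"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_info("done: reports in ", cfg$out_dir)
  invisible(list(cascade = res, spectra = spectra, stats = stats_rows,
                 consequence = list(tumor = cons_t, normal = cons_n),
                 recurrence = recur, enrichment = enrich,
                 out_dir = cfg$out_dir))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                              auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# the comparison statistics mirrored on whatever scale the data has
pipeline_stats <- function(pair, db, res, fcfg) {
  rows <- list()
  add <- function(name, a = NA, b = NA, c = NA, d = NA, value = NA,
                  p = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = name, a = a, b = b, c = c, d = d, value = value,
      p_value = p, stringsAsFactors = FALSE)

  nt <- nrow(res$tumor_specific); nn <- nrow(res$normal_specific)
  if (nn > 0) add("tumor_vs_normal_count_ratio", a = nt, b = nn,
                  value = count_ratio(nt, nn))

  # known-vs-novel coverage (post quality filter, pooled tissues)
  all1 <- rbind(as.data.frame(filter_min_quality(pair$tumor$calls,
                                                 fcfg$qual_min)),
                as.data.frame(filter_min_quality(pair$normal$calls,
                                                 fcfg$qual_min)))
  if (nrow(all1)) {
    known <- db_contains(db, all1)
    if (any(known) && any(!known))
      add("known_vs_novel_coverage_ranksum",
          a = sum(known), b = sum(!known),
          p = rank_sum_test(all1$depth[known], all1$depth[!known]))
  }

  # Ti/Tv balance between tissue-specific sets
  ti_tv <- function(cs) {
    snv <- cs$vclass == "SNV"
    if (!any(snv)) return(c(0L, 0L))
    ti <- is_transition(cs$ref[snv], cs$alt[snv])
    c(sum(ti), sum(!ti))
  }
  t1 <- ti_tv(res$tumor_specific); n1 <- ti_tv(res$normal_specific)
  if (all(c(t1, n1) >= 0) && sum(t1) > 0 && sum(n1) > 0)
    add("titv_tumor_vs_normal_fisher", a = t1[1], b = t1[2],
        c = n1[1], d = n1[2],
        p = fisher_exact_two_sided(c(t1[1], t1[2], n1[1], n1[2])))

  do.call(rbind, rows)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `filter`, `spectrum`, `consequence`,
#' `enrich`, `run-all`; also `--version`. Designed for
#' `Rscript -e 'rnasomatic::rnasomatic_cli()' <subcommand> ...` or the
#' installed `inst/cli/rnasomatic` launcher. Exits non-zero on stage
#' failure when not interactive.
#'
#' @param args character vector of CLI arguments (default: the
#'   command line).
#' @return invisibly, the subcommand's result.
#' @export
rnasomatic_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(e) {
    message("rnasomatic error: ", conditionMessage(e))
    if (interactive() || identical(Sys.getenv("TESTTHAT"), "true")) stop(e)
    else quit(status = 1L, save = "no")
  }
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message("usage: rnasomatic <simulate|filter|spectrum|consequence|",
            "enrich|run-all> [options]")
    return(invisible(NULL))
  }
  if (args[1] == "--version") {
    message("rnasomatic ", utils::packageVersion("rnasomatic"))
    return(invisible(NULL))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(...) optparse::parse_args(
    optparse::OptionParser(option_list = list(...)), args = rest)
  o <- optparse::make_option
  tryCatch(switch(
    cmd,
    "simulate" = {
      p <- opt(o("--out", type = "character"),
               o("--seed", type = "integer", default = 1L),
               o("--config", type = "character", default = NULL))
      sim_cfg <- if (!is.null(p$config))
        do.call(simulation_config,
                jsonlite::read_json(p$config, simplifyVector = TRUE))
      else simulation_config(seed = p$seed)
      sim_cfg$seed <- p$seed
      ref <- simulate_reference(sim_cfg)
      sim <- simulate_pair(sim_cfg, ref)
      paths <- write_simulation(ref, sim, p$out)
      message("wrote ", length(paths), " files to ", p$out)
      invisible(paths)
    },
    "filter" = {
      p <- opt(o("--tumor-vcf", type = "character", dest = "tumor_vcf"),
               o("--normal-vcf", type = "character", dest = "normal_vcf"),
               o("--tumor-cov", type = "character", dest = "tumor_cov"),
               o("--normal-cov", type = "character", dest = "normal_cov"),
               o("--known-db", type = "character", dest = "known_db"),
               o("--out", type = "character"),
               o("--qual-min", type = "double", default = 20,
                 dest = "qual_min"),
               o("--coverage-quantile", type = "double", default = 0.975,
                 dest = "coverage_quantile"),
               o("--flank", type = "integer", default = 10L),
               o("--min-depth", type = "integer", default = 1L,
                 dest = "min_depth"))
      fcfg <- filter_config(qual_min = p$qual_min,
                            coverage_quantile = p$coverage_quantile,
                            flank = p$flank, min_depth_both = p$min_depth)
      cfg <- pipeline_config(out_dir = p$out, simulate = FALSE,
                             tumor_vcf = p$tumor_vcf,
                             normal_vcf = p$normal_vcf,
                             tumor_cov = p$tumor_cov,
                             normal_cov = p$normal_cov,
                             known_db = p$known_db, filter = fcfg)
      run_pipeline(cfg)
    },
    "spectrum" = {
      p <- opt(o("--vcf", type = "character"),
               o("--out", type = "character"))
      cs <- read_vcf(p$vcf)
      write_spectrum(build_spectrum(cs), p$out)
      invisible(p$out)
    },
    "consequence" = {
      p <- opt(o("--vcf", type = "character"),
               o("--gtf", type = "character"),
               o("--fasta", type = "character"),
               o("--out", type = "character"))
      models <- index_gene_models(p$gtf, p$fasta)
      cc <- annotate_consequences(read_vcf(p$vcf), models)
      utils::write.table(cc, p$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(p$out)
    },
    "enrich" = {
      p <- opt(o("--study", type = "character"),
               o("--obo", type = "character"),
               o("--gene2go", type = "character"),
               o("--out", type = "character"),
               o("--correction", type = "character", default = "BH"))
      dag <- read_obo(p$obo)
      ann <- propagate_annotations(read_gene_annotations(p$gene2go), dag)
      study <- readLines(p$study)
      res <- enrich_terms(intersect(study, names(ann)), names(ann), ann,
                          dag, correction = p$correction)
      utils::write.table(res, p$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(p$out)
    },
    "run-all" = {
      p <- opt(o("--out", type = "character"),
               o("--seed", type = "integer", default = 1L),
               o("--config", type = "character", default = NULL),
               o("--obo", type = "character", default = NULL),
               o("--gene2go", type = "character", default = NULL))
      cfg <- if (!is.null(p$config)) read_pipeline_config(p$config)
      else pipeline_config(out_dir = p$out, seed = p$seed)
      cfg$out_dir <- p$out; cfg$seed <- p$seed
      if (!is.null(p$obo)) cfg$obo <- p$obo
      if (!is.null(p$gene2go)) cfg$gene2go <- p$gene2go
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd)), error = fail)
}

#' Read a pipeline configuration from JSON
#'
#' Flat JSON with the same field names as [pipeline_config()]; the
#' `filter` and `sim` sub-objects map onto [filter_config()] and
#' [simulation_config()].
#'
#' @param path JSON file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fcfg <- if (!is.null(j$filter)) do.call(filter_config, j$filter)
  else filter_config()
  scfg <- if (!is.null(j$sim)) do.call(simulation_config, j$sim)
  else simulation_config(seed = j$seed %||% 1L)
  args <- j[setdiff(names(j), c("filter", "sim"))]
  args$filter <- fcfg; args$sim <- scfg
  do.call(pipeline_config, args)
}
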