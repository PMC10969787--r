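# End-to-end pipeline: read VCF -> extract catalog genotypes -> call
# diplotypes -> assign phenotypes -> render and write reports, with a
# machine-readable run log. This is the programmatic core behind the
# inst/exec/pgxkit command-line entry point.

#' Build a validated pipeline run configuration
#'
#' @param vcf Character vector of input VCF paths.
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @param db Knowledge-base TSV path; default the packaged catalog.
#' @param genes Gene selection; default all catalog genes.
#' @param drugs Optional drug selection (single drug for the
#'   single-gene-drug format, else named list gene -> drugs).
#' @param format Report format: `"summary"`, `"single"`
#'   (single-gene-drug), or `"full"`.
#' @param out Output directory.
#' @param style Report serialization style: `"tsv"`, `"json"`, `"text"`.
#' @param genotype_complete Does absence of a VCF record mean homozygous
#'   reference?
#' @param created Timestamp override for reproducible outputs.
#' @return An object of class `pgx_run_config`.
#' @export
run_config <- function(vcf, build = c("GRCh38", "GRCh37"),
                       db = pgx_catalog_path(), genes = NULL, drugs = NULL,
                       format = c("summary", "single", "full"),
                       out = ".", style = c("text", "tsv", "json"),
                       genotype_complete = FALSE, created = NULL) {
  build <- match.arg(build)
  format <- match.arg(format)
  style <- match.arg(style)
  missing_vcf <- vcf[!file.exists(vcf)]
  if (length(missing_vcf)) {
    stop("input VCF not found: ", paste(missing_vcf, collapse = ", "),
         call. = FALSE)
  }
  kb <- load_knowledgebase(db)
  if (is.null(genes)) genes <- kb$genes
  bad <- setdiff(genes, kb$genes)
  if (length(bad)) {
    stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(drugs)) {
    if (format == "single") {
      if (length(genes) != 1L) {
        stop("single-gene-drug format requires exactly one gene", call. = FALSE)
      }
      invalid <- setdiff(drugs, kb$gene_drugs[[genes]])
      if (length(invalid)) {
        stop(paste(invalid, collapse = ", "), " not associated with ", genes,
             "; valid drugs: ", paste(kb$gene_drugs[[genes]], collapse = ", "),
             call. = FALSE)
      }
    } else {
      for (g in names(drugs)) {
        invalid <- setdiff(drugs[[g]], kb$gene_drugs[[g]])
        if (length(invalid)) {
          stop(paste(invalid, collapse = ", "), " not associated with ", g,
               "; valid drugs: ", paste(kb$gene_drugs[[g]], collapse = ", "),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(
    vcf = vcf, build = build, db = db, kb = kb, genes = genes,
    drugs = drugs, format = format, out = out, style = style,
    genotype_complete = genotype_complete, created = created
  ), class = "pgx_run_config")
}

#' Run the PGx pipeline over one or more VCFs
#'
#' For each input VCF: read catalog-region calls, project onto catalog
#' loci, call diplotypes for the selected genes, assign phenotypes, render
#' the configured report format, and write it next to a JSON run log with
#' per-stage counts (variants read, catalog loci matched, calls per
#' quality class).
#'
#' @param cfg A `pgx_run_config`.
#' @return Invisibly, a list per sample with `report_path`, `log`, and the
#'   `pgx_report` object.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pgx_run_config"))
  kb <- cfg$kb
  regions <- catalog_regions(kb, cfg$build)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  fmt_map <- c(summary = "summary", single = "single_gene_drug", full = "full")
  ext <- c(tsv = ".tsv", json = ".json", text = ".txt")[[cfg$style]]
  results <- list()
  for (path in cfg$vcf) {
    calls_tab <- read_vcf(path, regions)
    sample_ids <- unique(calls_tab$sample_id)
    if (!length(sample_ids)) {
      sample_ids <- tools::file_path_sans_ext(basename(path))
    }
    for (sid in sample_ids) {
      sg <- extract_catalog_genotypes(
        calls_tab, kb, build = cfg$build, sample_id = sid,
        genotype_complete = cfg$genotype_complete)
      calls <- call_all_genes(kb, sg)[cfg$genes]
      phenos <- lapply(calls, function(cl) {
        if (cl$quality %in% c("no_call", "unresolved")) NULL
        else assign_phenotype(kb, cl)
      })
      created <- cfg$created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      doc <- render_report(
        calls, phenos, kb, format = fmt_map[[cfg$format]],
        genes = cfg$genes, drugs = cfg$drugs, sample_id = sid,
        build = cfg$build, created = created)
      report_path <- file.path(cfg$out, paste0(sid, "_", cfg$format, ext))
      serialize_report(doc, report_path, style = cfg$style)
      log <- list(
        sample_id = sid, vcf = path, build = cfg$build,
        catalog_version = kb$version,
        n_variants_read = sum(calls_tab$sample_id == sid),
        n_catalog_loci = nrow(sg$obs),
        n_loci_observed = sum(sg$obs$state != "no_call"),
        calls_by_quality = as.list(table(
          vapply(calls, `[[`, character(1), "quality"))),
        report = report_path)
      log_path <- file.path(cfg$out, paste0(sid, "_runlog.json"))
      jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
      results[[sid]] <- list(report_path = report_path, log = log, doc = doc)
    }
  }
  invisible(results)
}
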