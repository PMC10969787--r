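# Clinical decision-support reports in three formats: a single-gene-drug
# detail report, an all-gene summary (no interpretation or dosing, for
# high-level pre-emptive screening), and the comprehensive all-gene
# all-drug report organized by gene. Ambiguous or incomplete calls are
# surfaced as caveats, never dropped.

REPORT_ROW_COLUMNS <- c("gene", "drug", "genotype_alias", "nucleotide_change",
                        "aa_change", "phenotype_category", "interpretation",
                        "dosing_recommendation", "references")

#' Render a PGx report document
#'
#' @param calls Named list of `pgx_diplotype_call` (e.g. from
#'   [call_all_genes()]).
#' @param phenotypes Named list of `pgx_phenotype` keyed by gene; entries
#'   are computed on the fly (per drug) for detailed formats, so this may
#'   be the drug-agnostic set used for the summary.
#' @param kb A `pgx_kb` object.
#' @param format `"single_gene_drug"`, `"summary"`, or `"full"`.
#' @param genes Gene selection; default all catalog genes. For
#'   `single_gene_drug` exactly one gene.
#' @param drugs Drug selection: named list gene -> drugs, or (for
#'   `single_gene_drug`) a single drug name. Default: all catalogued drugs
#'   of each selected gene.
#' @param sample_id Sample identifier for the header.
#' @param build Genome build string for the header.
#' @param created Timestamp string; injectable for reproducible outputs
#'   (default `format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")`).
#' @return An object of class `pgx_report`: list with `format`,
#'   `sample_id`, `build`, `created`, `catalog_version`, `rows` (data
#'   frame in `REPORT_ROW_COLUMNS` order), and `caveats`.
#' @export
render_report <- function(calls, phenotypes, kb,
                          format = c("summary", "single_gene_drug", "full"),
                          genes = NULL, drugs = NULL,
                          sample_id = "sample", build = "GRCh38",
                          created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  fmt <- match.arg(format)
  if (is.null(genes)) genes <- kb$genes
  bad <- setdiff(genes, kb$genes)
  if (length(bad)) {
    stop("unknown gene(s): ", paste(bad, collapse = ", "),
         "; catalog genes: ", paste(kb$genes, collapse = ", "), call. = FALSE)
  }
  if (fmt == "single_gene_drug") {
    if (length(genes) != 1L) {
      stop("single_gene_drug format requires exactly one gene", call. = FALSE)
    }
    if (is.null(drugs)) drugs <- kb$gene_drugs[[genes]][1]
    if (length(drugs) != 1L || !is.character(drugs)) {
      stop("single_gene_drug format requires exactly one drug", call. = FALSE)
    }
    drug_map <- stats::setNames(list(drugs), genes)
  } else if (is.null(drugs)) {
    drug_map <- kb$gene_drugs[genes]
  } else {
    drug_map <- drugs
  }
  for (g in genes) {
    sel <- drug_map[[g]]
    if (is.null(sel)) next
    invalid <- setdiff(sel, kb$gene_drugs[[g]])
    if (length(invalid)) {
      stop("drug(s) not associated with ", g, ": ",
           paste(invalid, collapse = ", "), "; valid drugs: ",
           paste(kb$gene_drugs[[g]], collapse = ", "), call. = FALSE)
    }
  }

  caveats <- character(0)
  rows <- list()
  for (g in genes) {
    cl <- calls[[g]]
    if (is.null(cl)) next
    if (cl$quality != "exact") {
      caveats <- c(caveats, sprintf(
        "%s: call quality '%s'%s%s", g, cl$quality,
        if (length(cl$candidates) > 1L)
          paste0("; candidates: ", paste(cl$candidates, collapse = ", ")) else "",
        if (length(cl$uncovered))
          paste0("; uncovered loci: ", paste(cl$uncovered, collapse = ", ")) else ""))
    }
    if (cl$quality %in% c("no_call", "unresolved")) {
      rows[[length(rows) + 1L]] <- report_row(
        gene = g, drug = NA, alias = NA, nuc = NA, aa = NA,
        category = paste0("not callable (", cl$quality, ")"),
        interp = NA, dosing = NA, refs = NA)
      next
    }
    chg <- diplotype_changes(kb, g, cl$allele_pair)
    if (fmt == "summary") {
      ph <- phenotypes[[g]]
      rows[[length(rows) + 1L]] <- report_row(
        gene = g, drug = NA, alias = cl$alias, nuc = chg$nuc, aa = chg$aa,
        category = if (!is.null(ph) && !ph$indeterminate) ph$category
                   else "indeterminate",
        interp = NA, dosing = NA, refs = NA)
    } else {
      for (d in drug_map[[g]]) {
        ph <- assign_phenotype(kb, cl, drug = d)
        rec <- lookup_record(kb, g, cl$alias, d)
        rows[[length(rows) + 1L]] <- report_row(
          gene = g, drug = d, alias = cl$alias, nuc = chg$nuc, aa = chg$aa,
          category = if (ph$indeterminate) "indeterminate" else ph$category,
          interp = if (is.null(rec)) NA else rec$interpretation,
          dosing = if (is.null(rec)) NA else rec$dosing_recommendation,
          refs = if (is.null(rec)) NA else rec$references)
      }
    }
  }
  rows <- if (length(rows)) {
    rows <- do.call(rbind, rows)
    row.names(rows) <- NULL
    rows
  } else {
    empty_rows()
  }
  structure(list(
    format = fmt, sample_id = sample_id, build = build, created = created,
    catalog_version = kb$version, rows = rows, caveats = caveats
  ), class = "pgx_report")
}

report_row <- function(gene, drug, alias, nuc, aa, category, interp, dosing, refs) {
  data.frame(gene = gene, drug = as.character(drug),
             genotype_alias = as.character(alias),
             nucleotide_change = as.character(nuc), aa_change = as.character(aa),
             phenotype_category = category,
             interpretation = as.character(interp),
             dosing_recommendation = as.character(dosing),
             references = as.character(refs), stringsAsFactors = FALSE)
}

empty_rows <- function() {
  as.data.frame(stats::setNames(rep(list(character(0)), length(REPORT_ROW_COLUMNS)),
                                REPORT_ROW_COLUMNS), stringsAsFactors = FALSE)
}

# cDNA and amino-acid change strings for the non-reference alleles of a pair
diplotype_changes <- function(kb, gene, pair) {
  vs <- do.call(rbind, lapply(unique(pair[pair != "*1"]), function(s)
    allele_variants(kb, gene, s)))
  if (is.null(vs) || !nrow(vs)) return(list(nuc = "none", aa = "none"))
  aa <- unique(vs$aa_change[vs$aa_change != "none"])
  list(nuc = paste(unique(vs$cdna), collapse = "; "),
       aa = if (length(aa)) paste(aa, collapse = "; ") else "none")
}

#' Serialize a report document
#'
#' Serialization is deterministic given identical inputs and a fixed
#' `created` timestamp.
#'
#' @param doc A `pgx_report`.
#' @param sink Output file path.
#' @param style `"tsv"` (comment preamble + one row per line, fixed
#'   header), `"json"` (the full document), or `"text"` (human-readable
#'   layout).
#' @return The sink path, invisibly.
#' @export
serialize_report <- function(doc, sink, style = c("tsv", "json", "text")) {
  style <- match.arg(style)
  stopifnot(inherits(doc, "pgx_report"))
  con <- tryCatch(file(sink, open = "wb"),
                  error = function(e) stop("cannot write report to ", sink,
                                           ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (style == "tsv") {
    writeLines(c(
      paste0("# pgx_report format=", doc$format, " sample=", doc$sample_id,
             " build=", doc$build, " catalog=", doc$catalog_version,
             " created=", doc$created),
      if (length(doc$caveats)) paste0("# caveat: ", doc$caveats)), con)
    rows <- doc$rows
    rows[] <- lapply(rows, function(x) ifelse(is.na(x), "", x))
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else if (style == "json") {
    payload <- list(
      format = doc$format, sample_id = doc$sample_id, build = doc$build,
      created = doc$created, catalog_version = doc$catalog_version,
      rows = doc$rows, caveats = as.list(doc$caveats))
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null",
                                pretty = TRUE, digits = NA), con)
  } else {
    writeLines(format_report_text(doc), con)
  }
  invisible(sink)
}

#' Read back a JSON report
#'
#' @param path Path written by [serialize_report()] with `style = "json"`.
#' @return A `pgx_report` equal to the serialized document.
#' @export
read_report_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rows <- if (is.data.frame(p$rows) && nrow(p$rows)) {
    r <- p$rows[REPORT_ROW_COLUMNS]
    r[] <- lapply(r, as.character)  # all-null JSON columns come back logical
    row.names(r) <- NULL
    r
  } else {
    empty_rows()
  }
  structure(list(
    format = p$format, sample_id = p$sample_id, build = p$build,
    created = p$created, catalog_version = p$catalog_version,
    rows = rows, caveats = as.character(unlist(p$caveats))
  ), class = "pgx_report")
}

format_report_text <- function(doc) {
  hdr <- c(
    paste0("PGx report (", doc$format, ")"),
    paste0("Sample:  ", doc$sample_id, "    Build: ", doc$build),
    paste0("Catalog: ", doc$catalog_version, "    Created: ", doc$created),
    strrep("=", 72))
  body <- character(0)
  rows <- doc$rows
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    body <- c(body,
      paste0(r$gene,
             if (!is.na(r$drug)) paste0(" / ", r$drug) else "",
             "  ", if (is.na(r$genotype_alias)) "-" else r$genotype_alias),
      paste0("  Phenotype:        ", r$phenotype_category),
      paste0("  Nucleotide change: ", if (is.na(r$nucleotide_change)) "-" else r$nucleotide_change),
      paste0("  Amino acid change: ", if (is.na(r$aa_change)) "-" else r$aa_change),
      if (!is.na(r$interpretation))
        paste0("  Interpretation:   ", r$interpretation),
      if (!is.na(r$dosing_recommendation))
        paste0("  Dosing:           ", r$dosing_recommendation),
      if (!is.na(r$references))
        paste0("  References:       ", r$references),
      strrep("-", 72))
  }
  cav <- if (length(doc$caveats)) {
    c("Caveats:", paste0("  * ", doc$caveats))
  } else character(0)
  c(hdr, body, cav)
}

#' @export
print.pgx_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
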