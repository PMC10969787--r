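# PGx knowledge base: catalog of genes, star-allele definitions, and
# diplotype interpretation rows, stored as a single TSV with a record_type
# discriminator ("allele" rows define star alleles variant-by-variant,
# "diplotype" rows carry clinical interpretations per gene/drug/diplotype).

KB_COLUMNS <- c(
  "record_type", "gene", "drug", "genotype_alias", "genotype_code",
  "star_name", "rsid", "chrom", "pos_grch37", "pos_grch38", "ref", "alt",
  "cdna", "aa_change", "activity_value", "function_label", "tier",
  "variants_result", "interpretation", "dosing_recommendation", "references"
)

EVIDENCE_STRENGTHS <- c("Strong", "Moderate", "Optional", "No recommendation")

#' Path to the packaged PGx catalog
#'
#' The packaged catalog covers 13 pharmacogenes (COMT, CYP2B6, CYP2C9,
#' CYP2C19, CYP2D6, CYP3A5, CYP4F2, DPYD, IL28B, NUDT15, SLCO1B1, TPMT,
#' VKORC1) with star-allele definitions on both GRCh37 and GRCh38 and
#' CPIC-style diplotype interpretation rows.
#'
#' @return Filesystem path to the packaged catalog TSV.
#' @export
pgx_catalog_path <- function() {
  system.file("extdata", "pgx_catalog.tsv", package = "pgxkit", mustWork = TRUE)
}

#' Load and validate a PGx knowledge base
#'
#' Reads a knowledge-base TSV (see the packaged catalog for the schema: one
#' header row, a `record_type` column distinguishing allele-definition rows
#' from diplotype interpretation rows, and an optional leading
#' `# catalog_version:` comment). All structural invariants are checked:
#' every gene carries the reference allele `*1` with an empty defining set,
#' star names and defining-variant sets are unique within a gene,
#' `(gene, drug, genotype_alias)` is unique, every interpretation starts
#' with a bracketed CPIC evidence strength, and every diplotype row's gene
#' has allele definitions.
#'
#' @param path Path to the knowledge-base TSV (defaults to the packaged
#'   catalog).
#' @return An object of class `pgx_kb`: a list with elements `version`,
#'   `genes` (catalog order), `alleles`, `variants`, `records`,
#'   `gene_drugs`, and the raw `table` used for lossless re-serialization.
#' @examples
#' kb <- load_knowledgebase()
#' kb$genes
#' @export
load_knowledgebase <- function(path = pgx_catalog_path()) {
  if (!file.exists(path)) {
    stop("knowledge-base file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  version <- "unversioned"
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#")) {
    m <- regmatches(lines[n_comment + 1L],
                    regexec("^#\\s*catalog_version:\\s*(\\S+)", lines[n_comment + 1L]))[[1]]
    if (length(m) == 2L) version <- m[2]
    n_comment <- n_comment + 1L
  }
  body <- lines[seq.int(n_comment + 1L, length.out = length(lines) - n_comment)]
  if (length(body) < 1L || !nzchar(body[1])) {
    stop("knowledge-base validation: no records in ", path, call. = FALSE)
  }
  tab <- utils::read.delim(text = body, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  if (!identical(names(tab), KB_COLUMNS)) {
    stop("knowledge-base validation: expected columns\n  ",
         paste(KB_COLUMNS, collapse = ", "), "\nbut found\n  ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("knowledge-base validation: no records in ", path, call. = FALSE)
  }
  dup <- duplicated(tab)
  if (any(dup)) {
    stop("knowledge-base validation: duplicate row(s) at data line(s) ",
         paste(which(dup), collapse = ", "), " (first duplicate: gene=",
         tab$gene[which(dup)[1]], ")", call. = FALSE)
  }
  bad_type <- !tab$record_type %in% c("allele", "diplotype")
  if (any(bad_type)) {
    stop("knowledge-base validation: unknown record_type at data line(s) ",
         paste(which(bad_type), collapse = ", "), call. = FALSE)
  }

  arows <- tab[tab$record_type == "allele", , drop = FALSE]
  drows <- tab[tab$record_type == "diplotype", , drop = FALSE]
  genes <- unique(arows$gene)

  alleles <- unique(data.frame(
    gene = arows$gene,
    star_name = arows$star_name,
    activity_value = suppressWarnings(as.numeric(arows$activity_value)),
    function_label = arows$function_label,
    tier = suppressWarnings(as.integer(arows$tier)),
    stringsAsFactors = FALSE
  ))
  has_var <- nzchar(arows$rsid)
  variants <- data.frame(
    gene = arows$gene[has_var],
    star_name = arows$star_name[has_var],
    rsid = arows$rsid[has_var],
    chrom = arows$chrom[has_var],
    pos_grch37 = suppressWarnings(as.integer(arows$pos_grch37[has_var])),
    pos_grch38 = suppressWarnings(as.integer(arows$pos_grch38[has_var])),
    ref = arows$ref[has_var],
    alt = arows$alt[has_var],
    cdna = arows$cdna[has_var],
    aa_change = arows$aa_change[has_var],
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    gene = drows$gene, drug = drows$drug,
    genotype_alias = drows$genotype_alias,
    genotype_code = drows$genotype_code,
    variants_result = drows$variants_result,
    interpretation = drows$interpretation,
    dosing_recommendation = drows$dosing_recommendation,
    references = drows$references,
    stringsAsFactors = FALSE
  )

  kb <- structure(list(
    version = version, genes = genes, alleles = alleles,
    variants = variants, records = records,
    gene_drugs = lapply(stats::setNames(nm = genes), function(g)
      unique(records$drug[records$gene == g])),
    table = tab
  ), class = "pgx_kb")
  validate_knowledgebase(kb)
  kb
}

validate_knowledgebase <- function(kb) {
  al <- kb$alleles
  va <- kb$variants
  re <- kb$records

  dup_star <- duplicated(al[c("gene", "star_name")])
  if (any(dup_star)) {
    stop("knowledge-base validation: duplicate star allele ",
         al$gene[dup_star][1], " ", al$star_name[dup_star][1], call. = FALSE)
  }
  for (g in kb$genes) {
    ga <- al[al$gene == g, , drop = FALSE]
    if (!"*1" %in% ga$star_name) {
      stop("knowledge-base validation: gene ", g,
           " lacks the reference allele *1", call. = FALSE)
    }
    if (any(va$gene == g & va$star_name == "*1")) {
      stop("knowledge-base validation: reference allele *1 of ", g,
           " must have an empty defining-variant set", call. = FALSE)
    }
    # no two alleles of one gene may share an identical defining set
    sets <- vapply(ga$star_name, function(s)
      paste(sort(va$rsid[va$gene == g & va$star_name == s]), collapse = ";"),
      character(1))
    nonref <- sets[ga$star_name != "*1"]
    if (anyDuplicated(nonref)) {
      d <- nonref[duplicated(nonref)][1]
      stop("knowledge-base validation: alleles of ", g,
           " with identical defining-variant sets: ",
           paste(ga$star_name[ga$star_name != "*1"][nonref == d], collapse = ", "),
         call. = FALSE)
    }
  }
  if (nrow(va)) {
    bad_rs <- !grepl("^rs[0-9]+$", va$rsid)
    if (any(bad_rs)) {
      stop("knowledge-base validation: malformed rsid ", va$rsid[bad_rs][1],
           call. = FALSE)
    }
    if (any(va$ref == va$alt)) {
      stop("knowledge-base validation: ref == alt for ",
           va$rsid[va$ref == va$alt][1], call. = FALSE)
    }
    no_pos <- is.na(va$pos_grch37) & is.na(va$pos_grch38)
    if (any(no_pos)) {
      stop("knowledge-base validation: ", va$rsid[no_pos][1],
           " has no position on either build", call. = FALSE)
    }
    neg_act <- !is.na(kb$alleles$activity_value) & kb$alleles$activity_value < 0
    if (any(neg_act)) {
      stop("knowledge-base validation: negative activity value for ",
           al$gene[neg_act][1], " ", al$star_name[neg_act][1], call. = FALSE)
    }
  }
  if (nrow(re)) {
    unknown <- !re$gene %in% kb$genes
    if (any(unknown)) {
      stop("knowledge-base validation: diplotype row for gene ",
           re$gene[unknown][1], " which has no allele definitions",
           call. = FALSE)
    }
    key <- paste(re$gene, re$drug, normalize_diplotype(re$genotype_alias))
    if (anyDuplicated(key)) {
      stop("knowledge-base validation: duplicate (gene, drug, diplotype) row: ",
           key[duplicated(key)][1], call. = FALSE)
    }
    strengths <- vapply(re$interpretation,
                        function(x) parse_interpretation(x)$strength,
                        character(1))
    bad <- !strengths %in% EVIDENCE_STRENGTHS
    if (any(bad)) {
      stop("knowledge-base validation: interpretation without a bracketed ",
           "evidence strength for ", re$gene[bad][1], " ",
           re$genotype_alias[bad][1], call. = FALSE)
    }
  }
  invisible(kb)
}

#' Re-serialize a knowledge base
#'
#' Writes a loaded knowledge base back to its TSV form. Loading and
#' re-serializing the packaged catalog is byte-identical (round-trip
#' stability).
#'
#' @param kb A `pgx_kb` object.
#' @param path Output path.
#' @export
write_knowledgebase <- function(kb, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!identical(kb$version, "unversioned")) {
    writeLines(paste0("# catalog_version: ", kb$version), con)
  }
  utils::write.table(kb$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Parse an interpretation string into evidence strength and body
#'
#' @param x Interpretation string beginning with a bracketed CPIC evidence
#'   strength, e.g. `"[Strong] Poor metabolizer: ..."`.
#' @return List with `strength` and `body`. Strength is `NA` when no
#'   bracketed prefix is present.
#' @export
parse_interpretation <- function(x) {
  m <- regmatches(x, regexec("^\\[([^]]+)\\]\\s*(.*)$", x))[[1]]
  if (length(m) != 3L) return(list(strength = NA_character_, body = x))
  list(strength = m[2], body = m[3])
}

#' Look up the interpretation row for a diplotype
#'
#' The alias is normalized before lookup, so `"*17/*1"` and `"*1/*17"`
#' retrieve the same row. An unknown gene is an error (a configuration
#' problem), while an uncatalogued diplotype returns `NULL` (an expected
#' outcome for rare genotypes).
#'
#' @param kb A `pgx_kb` object.
#' @param gene Gene symbol.
#' @param diplotype Diplotype alias, e.g. `"*1/*17"`.
#' @param drug Drug name (must be one of the gene's catalogued drugs).
#' @return The matching row of `kb$records` as a one-row data frame, or
#'   `NULL` if the diplotype is not catalogued for that gene/drug.
#' @examples
#' kb <- load_knowledgebase()
#' lookup_record(kb, "CYP2C19", "*1/*17", "Clopidogrel")$variants_result
#' @export
lookup_record <- function(kb, gene, diplotype, drug) {
  stopifnot(inherits(kb, "pgx_kb"))
  if (!gene %in% kb$genes) {
    stop("unknown gene: ", gene, " (catalog genes: ",
         paste(kb$genes, collapse = ", "), ")", call. = FALSE)
  }
  alias <- normalize_diplotype(diplotype)
  re <- kb$records
  hit <- re$gene == gene & re$drug == drug &
    normalize_diplotype(re$genotype_alias) == alias
  if (!any(hit)) return(NULL)
  re[which(hit)[1], , drop = FALSE]
}

#' Genomic regions spanned by each gene's defining variants
#'
#' @param kb A `pgx_kb` object.
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @param margin Non-negative padding (bp) added to both ends of each span.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive). Genes with no variant positioned on the requested
#'   build are omitted with a warning.
#' @export
catalog_regions <- function(kb, build = c("GRCh38", "GRCh37"), margin = 0) {
  build <- match.arg(build)
  stopifnot(margin >= 0)
  pos_col <- if (build == "GRCh37") "pos_grch37" else "pos_grch38"
  out <- list()
  skipped <- character(0)
  for (g in kb$genes) {
    gv <- kb$variants[kb$variants$gene == g, , drop = FALSE]
    pos <- gv[[pos_col]]
    keep <- !is.na(pos)
    if (nrow(gv) == 0L || !any(keep)) {
      if (nrow(gv) > 0L) skipped <- c(skipped, g)
      next
    }
    # span must cover the full REF length of indels
    ends <- pos[keep] + nchar(gv$ref[keep]) - 1L
    out[[g]] <- data.frame(
      gene = g, chrom = gv$chrom[keep][1],
      start = max(1L, min(pos[keep]) - as.integer(margin)),
      end = max(ends) + as.integer(margin),
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("no ", build, " positions for gene(s): ",
            paste(skipped, collapse = ", "), "; omitted from regions",
            call. = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# All star names of a gene, reference first then catalog order.
gene_alleles <- function(kb, gene) {
  st <- kb$alleles$star_name[kb$alleles$gene == gene]
  c("*1", sort_stars(setdiff(st, "*1")))
}

# Defining variants of one allele (possibly zero rows for *1).
allele_variants <- function(kb, gene, star) {
  kb$variants[kb$variants$gene == gene & kb$variants$star_name == star, ,
              drop = FALSE]
}

#' Genes eligible for the activity-score phenotype path
#'
#' A gene opts into the activity-score system when every one of its alleles
#' carries an activity value (packaged catalog: CYP2D6 only).
#'
#' @param kb A `pgx_kb` object.
#' @return Character vector of gene symbols.
#' @export
activity_genes <- function(kb) {
  kb$genes[vapply(kb$genes, function(g)
    all(!is.na(kb$alleles$activity_value[kb$alleles$gene == g])), logical(1))]
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat("PGx knowledge base (version ", x$version, ")\n",
      "  genes:    ", length(x$genes), " (",
      paste(x$genes, collapse = ", "), ")\n",
      "  alleles:  ", nrow(x$alleles), "\n",
      "  variants: ", nrow(x$variants), "\n",
      "  diplotype records: ", nrow(x$records), "\n", sep = "")
  invisible(x)
}
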