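# Concordance harness: per-gene variant-set concordance against a truth
# set, diplotype concordance against a consensus panel, and triage of
# adjudicated discordant calls into five categories. "Reported correctly"
# is exact set equality of catalog-locus variant calls per sample per
# gene; there is no partial credit.

TRIAGE_CATEGORIES <- c("caller_only_correct", "truth_only_correct",
                       "both_correct", "neither_correct", "no_contig")

#' Read a truth-set TSV
#'
#' Columns: `sample_id`, `gene`, `payload`. For `kind = "variant_sets"`
#' the payload is a semicolon-separated list of `chrom:pos:ref:alt` keys
#' (empty for no variants); for `kind = "consensus_diplotypes"` it is a
#' diplotype alias.
#'
#' @param path Path to the TSV.
#' @param kind `"variant_sets"` or `"consensus_diplotypes"`.
#' @return An object of class `pgx_truthset`: list with `kind` and `data`,
#'   a per-sample named list of per-gene entries (character vector of
#'   variant keys, or a single alias).
#' @export
read_truthset <- function(path, kind = c("variant_sets", "consensus_diplotypes")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  need <- c("sample_id", "gene", "payload")
  if (!all(need %in% names(tab))) {
    stop("truth-set file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$sample_id, tab$gene)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, gene) in truth set: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  data <- list()
  for (i in seq_len(nrow(tab))) {
    s <- tab$sample_id[i]; g <- tab$gene[i]
    val <- if (kind == "variant_sets") {
      if (nzchar(tab$payload[i]))
        strsplit(tab$payload[i], ";", fixed = TRUE)[[1]]
      else character(0)
    } else {
      normalize_diplotype(tab$payload[i])
    }
    data[[s]][[g]] <- val
  }
  structure(list(kind = kind, data = data), class = "pgx_truthset")
}

#' Write a truth set to TSV
#'
#' @param truth A `pgx_truthset`.
#' @param path Output path.
#' @export
write_truthset <- function(truth, path) {
  rows <- list()
  for (s in names(truth$data)) {
    for (g in names(truth$data[[s]])) {
      val <- truth$data[[s]][[g]]
      payload <- if (truth$kind == "variant_sets") {
        paste(val, collapse = ";")
      } else val
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = g, payload = payload, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Are two per-gene variant sets concordant?
#'
#' @param called,truth Character vectors of variant keys
#'   (`chrom:pos:ref:alt`) on the same build.
#' @return `TRUE` iff the sets are equal (both empty counts as agreement).
#' @export
sample_variant_concordant <- function(called, truth) {
  setequal(called, truth)
}

#' Per-gene variant-set concordance table
#'
#' One result per gene over the intersection of sample ids between cohort
#' and truth; a sample is concordant for a gene when its called variant
#' set equals the truth set exactly.
#'
#' @param cohort Named list: sample_id -> named list gene -> character
#'   vector of variant keys.
#' @param truth A `pgx_truthset` of kind `variant_sets`.
#' @param genes Genes to tabulate; default all genes present in the truth.
#' @return Data frame with `gene`, `n_samples`, `n_concordant`, `percent`
#'   (rounded to 2 decimals).
#' @export
concordance_table <- function(cohort, truth, genes = NULL) {
  stopifnot(inherits(truth, "pgx_truthset"))
  if (truth$kind != "variant_sets") {
    stop("concordance_table requires a variant_sets truth set", call. = FALSE)
  }
  samples <- intersect(names(cohort), names(truth$data))
  if (!length(samples)) {
    stop("no overlapping sample ids between cohort and truth set",
         call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(truth$data[samples], names)))
  }
  do.call(rbind, lapply(genes, function(g) {
    conc <- vapply(samples, function(s) {
      sample_variant_concordant(cohort[[s]][[g]] %||% character(0),
                                truth$data[[s]][[g]] %||% character(0))
    }, logical(1))
    concordance_result(g, length(samples), sum(conc))
  }))
}

#' Diplotype concordance against a consensus panel
#'
#' Concordant iff the normalized aliases are equal. Genes absent from the
#' truth panel are skipped and reported in the `skipped` attribute (the
#' consensus panel need not cover every catalog gene).
#'
#' @param calls Named list: sample_id -> named list gene -> diplotype
#'   alias.
#' @param truth A `pgx_truthset` of kind `consensus_diplotypes`.
#' @param genes Genes to tabulate; default all genes called in the cohort.
#' @return Data frame as in [concordance_table()], with attribute
#'   `skipped` listing genes not covered by the truth panel.
#' @export
diplotype_concordance <- function(calls, truth, genes = NULL) {
  stopifnot(inherits(truth, "pgx_truthset"))
  if (truth$kind != "consensus_diplotypes") {
    stop("diplotype_concordance requires a consensus_diplotypes truth set",
         call. = FALSE)
  }
  samples <- intersect(names(calls), names(truth$data))
  if (!length(samples)) {
    stop("no overlapping sample ids between calls and truth set",
         call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(calls[samples], names)))
  }
  truth_genes <- unique(unlist(lapply(truth$data[samples], names)))
  skipped <- setdiff(genes, truth_genes)
  if (length(skipped)) {
    message("gene(s) not in the truth panel, skipped: ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, lapply(setdiff(genes, skipped), function(g) {
    conc <- vapply(samples, function(s) {
      a <- calls[[s]][[g]]
      b <- truth$data[[s]][[g]]
      !is.null(a) && !is.null(b) &&
        normalize_diplotype(a) == normalize_diplotype(b)
    }, logical(1))
    concordance_result(g, length(samples), sum(conc))
  }))
  attr(res, "skipped") <- skipped
  res
}

concordance_result <- function(gene, n_samples, n_concordant) {
  data.frame(gene = gene, n_samples = n_samples,
             n_concordant = n_concordant,
             percent = round_half_up(100 * n_concordant / n_samples, 2),
             stringsAsFactors = FALSE)
}

#' Triage adjudicated discordances into five categories
#'
#' Mirrors manual adjudication of discordant variant calls: for each
#' variant, which side(s) called it correctly (caller alone, truth set
#' alone, both, neither) or whether no contig was available for calling.
#' Percentages are rounded to 1 decimal and may not sum to exactly 100.
#'
#' @param labels Character vector of adjudications, each one of
#'   `caller_only_correct`, `truth_only_correct`, `both_correct`,
#'   `neither_correct`, `no_contig`.
#' @return Data frame with `category`, `count`, `percent` in the fixed
#'   category order.
#' @export
triage_discordances <- function(labels) {
  if (!length(labels)) {
    stop("no adjudications to triage", call. = FALSE)
  }
  bad <- setdiff(unique(labels), TRIAGE_CATEGORIES)
  if (length(bad)) {
    stop("unknown adjudication category: ", paste(bad, collapse = ", "),
         "; valid: ", paste(TRIAGE_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  counts <- vapply(TRIAGE_CATEGORIES, function(cat) sum(labels == cat),
                   integer(1))
  data.frame(category = TRIAGE_CATEGORIES, count = as.integer(counts),
             percent = round_half_up(100 * counts / length(labels), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a variant-key string
#'
#' @param chrom,pos,ref,alt Variant coordinates (chrom is normalized).
#' @return `"chrom:pos:ref:alt"` keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}
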