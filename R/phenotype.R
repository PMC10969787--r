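# Diplotype-to-phenotype translation. Two rule paths: the CYP2D6-style
# activity-score system (diplotype score = sum of the two allele activity
# values, binned into metabolizer categories) and direct knowledge-base
# lookup for genes whose guidelines assign phenotypes per diplotype.

#' Activity score of a diplotype
#'
#' The diplotype score is the sum of the two alleles' activity values
#' (reference allele *1 carries 1.0 in the packaged catalog; CYP2D6 *10
#' carries the consensus-revised 0.25).
#'
#' @param kb A `pgx_kb` object.
#' @param gene Gene symbol.
#' @param allele_pair Length-2 character vector of star-allele names.
#' @return The summed score, or `NA` if either allele lacks an activity
#'   value.
#' @examples
#' kb <- load_knowledgebase()
#' diplotype_activity_score(kb, "CYP2D6", c("*10", "*10"))  # 0.5
#' @export
diplotype_activity_score <- function(kb, gene, allele_pair) {
  stopifnot(length(allele_pair) == 2L)
  al <- kb$alleles[kb$alleles$gene == gene, , drop = FALSE]
  vals <- vapply(allele_pair, function(s) {
    i <- match(s, al$star_name)
    if (is.na(i)) stop("unknown allele ", s, " for gene ", gene, call. = FALSE)
    al$activity_value[i]
  }, numeric(1))
  if (anyNA(vals)) return(NA_real_)
  sum(vals)
}

#' Metabolizer category for an activity score
#'
#' Bins follow the revised CPIC consensus: ultrarapid strictly above 2.25,
#' normal on the closed interval 1.25 to 2.25, intermediate on the open
#' interval 0 to 1.25, and poor at exactly 0.
#'
#' @param score Non-negative activity score.
#' @return One of `"Ultrarapid metabolizer"`, `"Normal metabolizer"`,
#'   `"Intermediate metabolizer"`, `"Poor metabolizer"`.
#' @examples
#' classify_activity_score(0.5)   # Intermediate metabolizer
#' classify_activity_score(2.25)  # Normal metabolizer (upper edge inclusive)
#' @export
classify_activity_score <- function(score) {
  if (is.na(score)) return(NA_character_)
  if (score < 0) stop("activity score must be non-negative", call. = FALSE)
  if (score > 2.25) "Ultrarapid metabolizer"
  else if (score >= 1.25) "Normal metabolizer"
  else if (score > 0) "Intermediate metabolizer"
  else "Poor metabolizer"
}

#' Assign a metabolizer phenotype to a diplotype call
#'
#' Genes opted into the activity-score system (packaged catalog: CYP2D6)
#' are classified by the summed allele activity score; all other genes by
#' knowledge-base lookup of the diplotype row for the given drug, whose
#' `variants_result` column carries the phenotype category. CYP2C19
#' *1/*17 resolves to Rapid metabolizer via the catalog. When neither path
#' resolves, the assignment is flagged indeterminate (a value, not an
#' error).
#'
#' @param kb A `pgx_kb` object.
#' @param call A `pgx_diplotype_call` (quality must not be `no_call` or
#'   `unresolved`).
#' @param drug Drug name; default the gene's first catalogued drug.
#' @param use_activity Genes using the activity-score path; default
#'   [activity_genes()] of the catalog.
#' @return An object of class `pgx_phenotype`: list with `gene`,
#'   `genotype_alias`, `activity_score` (`NA` unless the activity path was
#'   used), `category`, `rule_source` (`"activity_score"`,
#'   `"table_lookup"`, or `"indeterminate"`), and `indeterminate` flag.
#' @export
assign_phenotype <- function(kb, call, drug = NULL,
                             use_activity = activity_genes(kb)) {
  stopifnot(inherits(call, "pgx_diplotype_call"))
  gene <- call$gene
  if (call$quality %in% c("no_call", "unresolved")) {
    stop("cannot assign a phenotype to a ", call$quality, " call for ",
         gene, call. = FALSE)
  }
  if (is.null(drug)) drug <- kb$gene_drugs[[gene]][1]
  alias <- normalize_diplotype(call$alias)

  if (gene %in% use_activity) {
    score <- diplotype_activity_score(kb, gene, call$allele_pair)
    if (!is.na(score)) {
      return(new_phenotype(gene, alias, score, classify_activity_score(score),
                           "activity_score"))
    }
    # fall through to table lookup when an allele is unscored
  }
  rec <- if (!is.null(drug) && !is.na(drug)) {
    lookup_record(kb, gene, alias, drug)
  } else NULL
  if (!is.null(rec)) {
    return(new_phenotype(gene, alias, NA_real_, rec$variants_result,
                         "table_lookup"))
  }
  new_phenotype(gene, alias, NA_real_, NA_character_, "indeterminate")
}

new_phenotype <- function(gene, alias, score, category, rule_source) {
  structure(list(
    gene = gene, genotype_alias = alias, activity_score = score,
    category = category, rule_source = rule_source,
    indeterminate = identical(rule_source, "indeterminate")
  ), class = "pgx_phenotype")
}

#' @export
print.pgx_phenotype <- function(x, ...) {
  cat(x$gene, " ", x$genotype_alias, ": ",
      if (x$indeterminate) "indeterminate" else x$category, sep = "")
  if (!is.na(x$activity_score)) {
    cat(" (activity score ", format(x$activity_score), ")", sep = "")
  }
  cat(" [", x$rule_source, "]\n", sep = "")
  invisible(x)
}
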