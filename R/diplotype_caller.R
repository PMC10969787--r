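# Star-allele diplotype assignment from unphased catalog genotype
# observations. A candidate allele pair is consistent when, at every
# observed catalog locus of the gene, the alternate-allele dosage implied
# by the pair equals the observed dosage; no-call loci carry no
# information and are excluded from the check.

#' Is an allele pair consistent with the observed genotypes?
#'
#' @param kb A `pgx_kb` object.
#' @param sg A `pgx_sample_genotypes` object.
#' @param gene Gene symbol.
#' @param a1,a2 Star-allele names of the candidate pair (order irrelevant).
#' @return `TRUE` iff at every catalog locus of the gene with an observed
#'   (non-no-call) state, the expected dosage implied by the pair equals
#'   the observed dosage.
#' @export
pair_consistent <- function(kb, sg, gene, a1, a2) {
  loci <- gene_loci(kb, gene)
  if (!nrow(loci)) return(TRUE)
  set1 <- allele_variants(kb, gene, a1)$rsid
  set2 <- allele_variants(kb, gene, a2)$rsid
  obs <- sg$obs[sg$obs$gene == gene, , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    rs <- loci$rsid[i]
    st <- obs$state[obs$rsid == rs]
    if (!length(st) || st[1] == "no_call") next
    expected <- (rs %in% set1) + (rs %in% set2)
    if (state_dosage(st[1]) != expected) return(FALSE)
  }
  TRUE
}

gene_loci <- function(kb, gene) {
  unique(kb$variants[kb$variants$gene == gene, c("rsid"), drop = FALSE])
}

#' Call the star-allele diplotype for one gene
#'
#' Enumerates all unordered pairs over the gene's catalogued alleles and
#' keeps the consistent ones as candidates. The reported pair is the best
#' candidate under a deterministic ranking: (1) most observed alt-bearing
#' loci explained, (2) fewest non-reference alleles (parsimony), (3)
#' normalized-alias lexicographic order. Ambiguity and missing data are
#' surfaced in the quality flag, never silently resolved:
#' * `exact` — a single candidate, all of its defining loci observed;
#' * `incomplete` — the chosen pair has no-call defining loci;
#' * `ambiguous` — several candidates (all listed);
#' * `no_call` — every catalog locus of the gene is no-call;
#' * `unresolved` — no pair is consistent with the observations.
#'
#' @param kb A `pgx_kb` object.
#' @param sg A `pgx_sample_genotypes` object.
#' @param gene Gene symbol.
#' @return An object of class `pgx_diplotype_call`: list with `gene`,
#'   `allele_pair` (length-2 character, normalized order; empty when
#'   unresolved), `alias`, `quality`, `candidates` (character vector of
#'   normalized aliases), and `uncovered` (rsids with no-call state).
#' @export
call_diplotype <- function(kb, sg, gene) {
  if (!gene %in% kb$genes) stop("unknown gene: ", gene, call. = FALSE)
  stars <- gene_alleles(kb, gene)
  loci <- gene_loci(kb, gene)$rsid
  obs <- sg$obs[sg$obs$gene == gene, , drop = FALSE]
  state_of <- function(rs) {
    st <- obs$state[obs$rsid == rs]
    if (!length(st)) "no_call" else st[1]
  }
  states <- vapply(loci, state_of, character(1))
  uncovered <- loci[states == "no_call"]

  pairs <- list()
  for (i in seq_along(stars)) for (j in i:length(stars)) {
    pairs[[length(pairs) + 1L]] <- c(stars[i], stars[j])
  }
  consistent <- vapply(pairs, function(p)
    pair_consistent(kb, sg, gene, p[1], p[2]), logical(1))
  cands <- pairs[consistent]

  if (!length(cands)) {
    return(new_diplotype_call(gene, character(0), "unresolved",
                              character(0), uncovered))
  }

  alt_loci <- loci[states %in% c("het", "hom_alt")]
  score <- function(p) {
    s1 <- allele_variants(kb, gene, p[1])$rsid
    s2 <- allele_variants(kb, gene, p[2])$rsid
    explained <- sum(alt_loci %in% union(s1, s2))
    nonref <- sum(p != "*1")
    c(explained, nonref)
  }
  sc <- vapply(cands, score, numeric(2))
  aliases <- vapply(cands, function(p)
    normalize_diplotype(paste(p, collapse = "/")), character(1))
  ord <- order(-sc[1, ], sc[2, ], aliases)
  best <- cands[[ord[1]]]
  best <- sort_stars(best)

  best_loci <- union(allele_variants(kb, gene, best[1])$rsid,
                     allele_variants(kb, gene, best[2])$rsid)
  quality <- if (length(loci) > 0L && all(states == "no_call")) {
    "no_call"
  } else if (any(best_loci %in% uncovered)) {
    "incomplete"
  } else if (length(cands) > 1L) {
    "ambiguous"
  } else {
    "exact"
  }
  new_diplotype_call(gene, best, quality, sort(unique(aliases)), uncovered)
}

new_diplotype_call <- function(gene, pair, quality, candidates, uncovered) {
  structure(list(
    gene = gene, allele_pair = pair,
    alias = if (length(pair) == 2L) paste(pair, collapse = "/") else NA_character_,
    quality = quality, candidates = candidates, uncovered = uncovered
  ), class = "pgx_diplotype_call")
}

#' Call diplotypes for every catalog gene
#'
#' @param kb A `pgx_kb` object.
#' @param sg A `pgx_sample_genotypes` object.
#' @return Named list of `pgx_diplotype_call`, one per gene in catalog
#'   order.
#' @export
call_all_genes <- function(kb, sg) {
  stats::setNames(lapply(kb$genes, function(g) call_diplotype(kb, sg, g)),
                  kb$genes)
}

#' @export
print.pgx_diplotype_call <- function(x, ...) {
  cat(x$gene, " ", if (is.na(x$alias)) "(unresolved)" else x$alias,
      " [", x$quality, "]", sep = "")
  if (length(x$candidates) > 1L) {
    cat("  candidates:", paste(x$candidates, collapse = ", "))
  }
  if (length(x$uncovered)) {
    cat("  uncovered:", paste(x$uncovered, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Summarize diplotype calls as a data frame
#'
#' @param calls Named list of `pgx_diplotype_call` from [call_all_genes()].
#' @return Data frame with one row per gene: `gene`, `alias`, `quality`,
#'   `n_candidates`, `uncovered`.
#' @export
calls_summary <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) data.frame(
    gene = cl$gene, alias = cl$alias, quality = cl$quality,
    n_candidates = length(cl$candidates),
    uncovered = paste(cl$uncovered, collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)))
}
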