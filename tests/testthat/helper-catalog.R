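# Shared fixtures: the packaged catalog (loaded once), in-code synthetic
# catalogs, and an independent brute-force oracle for diplotype candidate
# enumeration.

pkg_kb <- load_knowledgebase()

# Build a minimal pgx_kb in code: `alleles` is a named list
# gene -> named list star -> character vector of rsids (*1 implied).
# Positions are synthetic but internally consistent on both builds.
make_test_kb <- function(alleles, chrom = "9", base_pos = 1000L,
                         records = NULL) {
  al <- list(); va <- list()
  rs_seen <- character(0)
  for (g in names(alleles)) {
    al[[length(al) + 1L]] <- data.frame(
      gene = g, star_name = "*1", activity_value = NA_real_,
      function_label = "normal function", tier = 1L,
      stringsAsFactors = FALSE)
    for (s in names(alleles[[g]])) {
      al[[length(al) + 1L]] <- data.frame(
        gene = g, star_name = s, activity_value = NA_real_,
        function_label = "no function", tier = 1L, stringsAsFactors = FALSE)
      for (rs in alleles[[g]][[s]]) {
        num <- as.integer(sub("^rs", "", rs))
        va[[length(va) + 1L]] <- data.frame(
          gene = g, star_name = s, rsid = rs, chrom = chrom,
          pos_grch37 = base_pos + num, pos_grch38 = base_pos + 10000L + num,
          ref = "A", alt = "G", cdna = paste0("c.", num, "A>G"),
          aa_change = "none", stringsAsFactors = FALSE)
        rs_seen <- c(rs_seen, rs)
      }
    }
  }
  records <- records %||% data.frame(
    gene = character(0), drug = character(0), genotype_alias = character(0),
    genotype_code = character(0), variants_result = character(0),
    interpretation = character(0), dosing_recommendation = character(0),
    references = character(0), stringsAsFactors = FALSE)
  genes <- names(alleles)
  structure(list(
    version = "test", genes = genes,
    alleles = do.call(rbind, c(al, list(make.row.names = FALSE))),
    variants = if (length(va)) do.call(rbind, c(va, list(make.row.names = FALSE)))
               else data.frame(gene = character(0), star_name = character(0),
                               rsid = character(0), chrom = character(0),
                               pos_grch37 = integer(0), pos_grch38 = integer(0),
                               ref = character(0), alt = character(0),
                               cdna = character(0), aa_change = character(0)),
    records = records,
    gene_drugs = lapply(stats::setNames(nm = genes), function(g)
      unique(records$drug[records$gene == g])),
    table = NULL
  ), class = "pgx_kb")
}

# SampleGenotypes built directly from a named state vector rsid -> state.
make_sg <- function(gene, states, sample_id = "T", build = "GRCh38") {
  structure(list(
    sample_id = sample_id, build = build,
    obs = data.frame(gene = gene, rsid = names(states),
                     state = unname(states), source = "observed",
                     stringsAsFactors = FALSE)
  ), class = "pgx_sample_genotypes")
}

# Independent oracle: enumerate unordered allele pairs via indicator-matrix
# arithmetic (a different code path from pair_consistent's set logic) and
# return the normalized aliases of all pairs consistent with the observed
# dosage vector. `defs` is a named list star -> rsids (*1 implied if absent),
# `dosages` a named integer vector rsid -> observed dosage (NA = no call).
oracle_candidates <- function(defs, dosages) {
  if (!"*1" %in% names(defs)) defs <- c(list("*1" = character(0)), defs)
  loci <- names(dosages)
  ind <- sapply(defs, function(rs) as.integer(loci %in% rs))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = length(loci))
  colnames(ind) <- names(defs)
  stars <- names(defs)
  res <- character(0)
  for (i in seq_along(stars)) for (j in i:length(stars)) {
    expected <- ind[, i] + ind[, j]
    ok <- is.na(dosages) | expected == dosages
    if (all(ok)) {
      res <- c(res, normalize_diplotype(paste(stars[i], stars[j], sep = "/")))
    }
  }
  sort(unique(res))
}

# Random synthetic catalog + genotype configuration for property tests.
random_config <- function(max_alleles = 8, max_loci = 6) {
  n_loci <- sample(1:max_loci, 1)
  loci <- paste0("rs", sample(100:999, n_loci))
  n_all <- sample(1:(max_alleles - 1), 1)  # non-reference alleles
  defs <- list()
  for (k in seq_len(n_all)) {
    sz <- sample(1:n_loci, 1)
    set <- sort(sample(loci, sz))
    defs[[paste0("*", k + 1)]] <- set
  }
  # drop alleles with duplicate defining sets (catalog invariant)
  keys <- vapply(defs, paste, character(1), collapse = ";")
  defs <- defs[!duplicated(keys)]
  # catalog loci are exactly the loci defining some allele
  loci <- sort(unique(unlist(defs)))
  dosages <- stats::setNames(sample(c(0:2, NA), length(loci), replace = TRUE),
                             loci)
  list(defs = defs, dosages = dosages)
}

# Convert a random_config into package objects for call_diplotype.
config_to_pkg <- function(cfg, gene = "GX") {
  kb <- make_test_kb(stats::setNames(list(cfg$defs), gene))
  states <- vapply(cfg$dosages, function(d) {
    if (is.na(d)) "no_call"
    else c("hom_ref", "het", "hom_alt")[d + 1L]
  }, character(1))
  sg <- make_sg(gene, states)
  list(kb = kb, sg = sg)
}
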