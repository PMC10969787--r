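# Seeded fixture generator: synthesizes per-sample VCFs realizing any
# catalog diplotypes, with optional noise (record dropout, spurious
# in-region records, genotype no-calls), plus matching truth sets for the
# concordance harness. All randomness flows from the spec seed through a
# single generator in a fixed order (drop draws per record in catalog
# order, then spurious draws per gene region, then no-call draws per
# surviving record), so identical specs give byte-identical VCFs.

#' Construct a fixture specification
#'
#' @param sample_id Sample name.
#' @param diplotypes Named character vector gene -> diplotype alias (e.g.
#'   `c(CYP2C19 = "*2/*2")`). Genes omitted default to `"*1/*1"`.
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @param drop_rate,spurious_rate,nocall_rate Noise rates in \[0, 1\]:
#'   probability of deleting each true record, of adding a spurious
#'   non-catalog record per gene region, and of rewriting each surviving
#'   genotype to `./.`.
#' @param seed Integer RNG seed.
#' @return An object of class `pgx_fixture_spec`.
#' @export
fixture_spec <- function(sample_id, diplotypes = character(0),
                         build = c("GRCh38", "GRCh37"),
                         drop_rate = 0, spurious_rate = 0, nocall_rate = 0,
                         seed = 1L) {
  build <- match.arg(build)
  rates <- c(drop_rate, spurious_rate, nocall_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    sample_id = sample_id, build = build,
    diplotypes = diplotypes,
    noise = list(drop_rate = drop_rate, spurious_rate = spurious_rate,
                 nocall_rate = nocall_rate),
    seed = as.integer(seed)
  ), class = "pgx_fixture_spec")
}

#' Generate a synthetic sample VCF for chosen diplotypes
#'
#' Emits a VCF 4.2 file containing exactly the alternate-allele records
#' implied by the union of the two alleles' defining variants per gene
#' (GT `1/1` where both alleles share a variant, else `0/1`), on the
#' spec's build coordinates. GRCh38 fixtures use "chr"-prefixed contig
#' names and GRCh37 fixtures bare names, mirroring the conventions of the
#' respective reference distributions. Noise is applied after
#' construction; spurious records are placed only inside catalog regions
#' (at non-catalog positions) so they stress region filtering and catalog
#' matching.
#'
#' @param spec A `pgx_fixture_spec`.
#' @param kb A `pgx_kb` object; every alias in the spec must be
#'   resolvable here.
#' @param sink Output VCF path.
#' @return Invisibly, the manifest: data frame of emitted records with
#'   columns `gene`, `rsid`, `chrom`, `pos`, `ref`, `alt`, `gt`,
#'   `spurious`.
#' @export
generate_sample_vcf <- function(spec, kb, sink) {
  stopifnot(inherits(spec, "pgx_fixture_spec"), inherits(kb, "pgx_kb"))
  truth <- fixture_truth_records(spec, kb)
  with_seed(spec$seed, {
    recs <- truth
    # 1) dropout, one draw per true record in catalog order
    if (nrow(recs) && spec$noise$drop_rate > 0) {
      keep <- stats::runif(nrow(recs)) >= spec$noise$drop_rate
      recs <- recs[keep, , drop = FALSE]
    }
    # 2) spurious records, one draw per gene region in catalog order
    if (spec$noise$spurious_rate > 0) {
      regions <- suppressWarnings(catalog_regions(kb, spec$build))
      pos_col <- if (spec$build == "GRCh37") "pos_grch37" else "pos_grch38"
      for (i in seq_len(nrow(regions))) {
        if (stats::runif(1) < spec$noise$spurious_rate) {
          taken <- kb$variants[[pos_col]][kb$variants$gene == regions$gene[i]]
          cand <- setdiff(seq.int(regions$start[i], regions$end[i]), taken)
          if (!length(cand)) next
          p <- cand[sample.int(length(cand), 1L)]
          ra <- sample(c("A", "C", "G", "T"), 2L)
          recs <- rbind(recs, data.frame(
            gene = regions$gene[i], rsid = ".", chrom = regions$chrom[i],
            pos = p, ref = ra[1], alt = ra[2], gt = "0/1", spurious = TRUE,
            stringsAsFactors = FALSE))
        }
      }
    }
    # 3) genotype no-calls, one draw per surviving record
    if (nrow(recs) && spec$noise$nocall_rate > 0) {
      hit <- stats::runif(nrow(recs)) < spec$noise$nocall_rate
      recs$gt[hit] <- "./."
    }
    recs
  }) -> recs

  chrom_out <- if (spec$build == "GRCh38") paste0("chr", recs$chrom) else recs$chrom
  ord <- order(recs$chrom, recs$pos, recs$ref, recs$alt)
  recs <- recs[ord, , drop = FALSE]
  chrom_out <- chrom_out[ord]

  contigs <- unique(chrom_out)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgxkit-fixtures",
    paste0("##reference=", spec$build),
    paste0("##contig=<ID=", contigs, ">"),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", spec$sample_id, sep = "\t"))
  body <- if (nrow(recs)) {
    paste(chrom_out, recs$pos, recs$rsid, recs$ref, recs$alt, "100", "PASS",
          ".", "GT", recs$gt, sep = "\t")
  } else character(0)
  con <- file(sink, open = "wb")
  writeLines(c(header, body), con)
  close(con)
  invisible(recs)
}

# True (pre-noise) alternate records implied by the spec's diplotypes.
fixture_truth_records <- function(spec, kb) {
  pos_col <- if (spec$build == "GRCh37") "pos_grch37" else "pos_grch38"
  out <- list()
  for (g in kb$genes) {
    alias <- if (g %in% names(spec$diplotypes)) spec$diplotypes[[g]] else "*1/*1"
    pair <- strsplit(normalize_diplotype(alias), "/", fixed = TRUE)[[1]]
    stars <- gene_alleles(kb, g)
    if (!all(pair %in% stars)) {
      stop("alias ", alias, " not resolvable for gene ", g,
           " (catalog alleles: ", paste(stars, collapse = ", "), ")",
           call. = FALSE)
    }
    both <- rbind(allele_variants(kb, g, pair[1]),
                  allele_variants(kb, g, pair[2]))
    vs <- unique(both[setdiff(names(both), "star_name")])
    if (!nrow(vs)) next
    in1 <- vs$rsid %in% allele_variants(kb, g, pair[1])$rsid
    in2 <- vs$rsid %in% allele_variants(kb, g, pair[2])$rsid
    dosage <- in1 + in2
    if (any(is.na(vs[[pos_col]]))) {
      stop("gene ", g, " has defining variants without ", spec$build,
           " positions; cannot synthesize", call. = FALSE)
    }
    out[[g]] <- data.frame(
      gene = g, rsid = vs$rsid, chrom = vs$chrom, pos = vs[[pos_col]],
      ref = vs$ref, alt = vs$alt,
      gt = ifelse(dosage == 2L, "1/1", "0/1"), spurious = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), rsid = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), spurious = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate a synthetic cohort with matching truth sets
#'
#' Draws a diplotype per gene per sample (uniformly over the gene's
#' unordered allele pairs, or from a per-gene weight table), writes one
#' VCF per sample, and writes both truth-set kinds: the per-gene
#' variant-key sets implied by the drawn diplotypes, and the drawn
#' diplotype aliases themselves.
#'
#' @param n Number of samples (>= 1).
#' @param kb A `pgx_kb` object.
#' @param dir Output directory (created if needed).
#' @param build Genome build.
#' @param seed Master seed; per-sample generator seeds are derived from
#'   it.
#' @param drop_rate,spurious_rate,nocall_rate Noise rates passed to each
#'   sample's [fixture_spec()].
#' @param weights Optional named list gene -> named numeric vector
#'   (alias -> weight) steering the diplotype sampler.
#' @param genes Genes to vary; others stay `*1/*1`. Default all catalog
#'   genes.
#' @return List with `specs`, `vcf_paths`, `truth_variants` /
#'   `truth_diplotypes` (`pgx_truthset` objects), and the paths of the two
#'   truth TSVs written alongside the VCFs.
#' @export
generate_cohort <- function(n, kb, dir, build = c("GRCh38", "GRCh37"),
                            seed = 1L, drop_rate = 0, spurious_rate = 0,
                            nocall_rate = 0, weights = NULL, genes = NULL) {
  build <- match.arg(build)
  if (n < 1L) stop("cohort size must be >= 1", call. = FALSE)
  if (is.null(genes)) genes <- kb$genes
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  pair_space <- lapply(stats::setNames(nm = genes), function(g) {
    stars <- gene_alleles(kb, g)
    out <- character(0)
    for (i in seq_along(stars)) for (j in i:length(stars)) {
      out <- c(out, normalize_diplotype(paste(stars[i], stars[j], sep = "/")))
    }
    out
  })

  drawn <- with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    dip <- lapply(seq_len(n), function(i) {
      vapply(genes, function(g) {
        space <- pair_space[[g]]
        w <- weights[[g]]
        if (is.null(w)) {
          space[sample.int(length(space), 1L)]
        } else {
          aliases <- normalize_diplotype(names(w))
          aliases[sample.int(length(aliases), 1L, prob = as.numeric(w))]
        }
      }, character(1))
    })
    list(sub_seeds = sub_seeds, dip = dip)
  })

  specs <- vector("list", n)
  vcf_paths <- character(n)
  tv <- list(); td <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    specs[[i]] <- fixture_spec(
      sample_id = sid, diplotypes = drawn$dip[[i]], build = build,
      drop_rate = drop_rate, spurious_rate = spurious_rate,
      nocall_rate = nocall_rate, seed = drawn$sub_seeds[i])
    vcf_paths[i] <- file.path(dir, paste0(sid, ".vcf"))
    generate_sample_vcf(specs[[i]], kb, vcf_paths[i])
    truth <- fixture_truth_records(specs[[i]], kb)
    tv[[sid]] <- lapply(stats::setNames(nm = genes), function(g) {
      tr <- truth[truth$gene == g, , drop = FALSE]
      if (!nrow(tr)) character(0)
      else variant_key(tr$chrom, tr$pos, tr$ref, tr$alt)
    })
    td[[sid]] <- as.list(drawn$dip[[i]])
  }
  truth_variants <- structure(list(kind = "variant_sets", data = tv),
                              class = "pgx_truthset")
  truth_diplotypes <- structure(list(kind = "consensus_diplotypes", data = td),
                                class = "pgx_truthset")
  tv_path <- file.path(dir, "truth_variants.tsv")
  td_path <- file.path(dir, "truth_diplotypes.tsv")
  write_truthset(truth_variants, tv_path)
  write_truthset(truth_diplotypes, td_path)
  list(specs = specs, vcf_paths = vcf_paths,
       truth_variants = truth_variants, truth_diplotypes = truth_diplotypes,
       truth_variants_path = tv_path, truth_diplotypes_path = td_path)
}
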