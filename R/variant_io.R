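# VCF input: read records overlapping catalog regions and project each
# sample onto genotype states at catalog-defining loci. Parsing is done by
# vcfR; this module adds region restriction, multi-allelic splitting with
# per-allele dosage, contig-name normalization, and the genotype-complete
# semantics that decide between assumed-reference and no-call.

#' Read catalog-region variant calls from a VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped), restricts records to the given
#' regions, and splits multi-allelic records into one row per alternate
#' allele with the dosage recomputed per split allele. Records failing
#' FILTER are kept with `filter_pass = FALSE` so downstream policy decides
#' their fate. Contig naming differences ("chr22" vs "22") are normalized,
#' never an error.
#'
#' @param path Path to the VCF file.
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [catalog_regions()]. `NULL` keeps all
#'   records.
#' @param samples Sample names to extract; default all samples in the file.
#' @return Data frame of variant calls: `sample_id`, `chrom` (normalized),
#'   `pos`, `ref`, `alt`, `rsid` (`NA` when absent), `dosage` (0/1/2 copies
#'   of that alternate allele; `NA` for missing genotypes), `filter_pass`.
#' @export
read_vcf <- function(path, regions = NULL, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  check_vcf_structure(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      rsid = character(0), dosage = integer(0),
                      filter_pass = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) NULL)
  file_samples <- if (is.null(gt)) character(0) else colnames(gt)
  if (is.null(samples)) samples <- file_samples
  missing_s <- setdiff(samples, file_samples)
  if (length(missing_s)) {
    stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }

  chrom <- normalize_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]
  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")

  keep <- rep(TRUE, n)
  if (!is.null(regions) && nrow(regions) > 0L) {
    rchrom <- normalize_chrom(regions$chrom)
    keep <- vapply(seq_len(n), function(i) {
      rec_end <- pos[i] + nchar(ref[i]) - 1L
      any(rchrom == chrom[i] & regions$start <= rec_end & regions$end >= pos[i])
    }, logical(1))
  } else if (!is.null(regions)) {
    keep <- rep(FALSE, n)
  }

  out <- vector("list", sum(keep) * max(1L, length(samples)))
  k <- 0L
  for (i in which(keep)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      g <- gt[i, s]
      alleles <- if (is.na(g)) NA_character_ else strsplit(g, "[/|]")[[1]]
      for (ai in seq_along(alts)) {
        dosage <- if (length(alleles) == 1L && is.na(alleles[1])) {
          NA_integer_
        } else if (any(alleles == ".")) {
          NA_integer_
        } else {
          sum(alleles == as.character(ai))
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          sample_id = s, chrom = chrom[i], pos = pos[i], ref = ref[i],
          alt = alts[ai],
          rsid = if (is.na(id[i]) || id[i] == ".") NA_character_ else id[i],
          dosage = dosage, filter_pass = pass[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

# Structural pre-check: every data line must have as many tab-separated
# fields as the #CHROM header line, so a truncated record is reported with
# its line number instead of being silently mangled.
check_vcf_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("not a VCF (no #CHROM header line): ", path, call. = FALSE)
  want <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  for (i in seq.int(hdr[1] + 1L, length.out = length(lines) - hdr[1])) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) next
    got <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (got != want) {
      stop("malformed VCF record at line ", i, " of ", path, ": ", got,
           " fields, expected ", want, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Project variant calls onto catalog genotype states
#'
#' For every defining variant in the knowledge base, determines the
#' sample's genotype state. A call matching (chrom, pos, ref, alt) on the
#' stated build sets the state from its dosage (0 = hom_ref, 1 = het,
#' 2 = hom_alt; missing genotype = no_call). When no call covers the locus,
#' the state is assumed-reference hom_ref if the VCF is declared
#' genotype-complete (typical for WGS genotyped VCFs), else no_call
#' (typical for sparse call sets). A call at the catalog position whose REF
#' disagrees with the catalog yields a warning and no_call, never silent
#' acceptance; a call whose rsid matches but whose position differs is used
#' as a fallback with a message.
#'
#' @param calls Data frame from [read_vcf()].
#' @param kb A `pgx_kb` object.
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @param sample_id Sample to project; default the only sample in `calls`.
#' @param genotype_complete Logical: does absence of a record mean
#'   homozygous reference?
#' @param include_filtered Logical: use calls with `filter_pass = FALSE`?
#'   Default `FALSE` (conservative clinical posture).
#' @return An object of class `pgx_sample_genotypes`: list with
#'   `sample_id`, `build`, and `obs`, a data frame keyed by (gene, rsid)
#'   with columns `state` (hom_ref/het/hom_alt/no_call) and `source`
#'   (observed/assumed_ref).
#' @export
extract_catalog_genotypes <- function(calls, kb, build = c("GRCh38", "GRCh37"),
                                      sample_id = NULL,
                                      genotype_complete = FALSE,
                                      include_filtered = FALSE) {
  build <- match.arg(build)
  stopifnot(inherits(kb, "pgx_kb"))
  if (is.null(sample_id)) {
    ids <- unique(calls$sample_id)
    if (length(ids) > 1L) {
      stop("calls contain ", length(ids),
           " samples; pass sample_id explicitly", call. = FALSE)
    }
    sample_id <- if (length(ids)) ids else "unknown"
  }
  calls <- calls[calls$sample_id == sample_id, , drop = FALSE]
  if (!include_filtered) calls <- calls[calls$filter_pass, , drop = FALSE]
  pos_col <- if (build == "GRCh37") "pos_grch37" else "pos_grch38"

  va <- unique(kb$variants[c("gene", "rsid", "chrom", pos_col, "ref", "alt")])
  names(va)[names(va) == pos_col] <- "pos"
  va$chrom <- normalize_chrom(va$chrom)

  state <- character(nrow(va))
  source <- character(nrow(va))
  for (i in seq_len(nrow(va))) {
    if (is.na(va$pos[i])) { state[i] <- "no_call"; source[i] <- "observed"; next }
    at_pos <- calls$chrom == va$chrom[i] & calls$pos == va$pos[i]
    exact <- at_pos & calls$ref == va$ref[i] & calls$alt == va$alt[i]
    if (any(exact)) {
      d <- calls$dosage[which(exact)[1]]
      state[i] <- dosage_state(d)
      source[i] <- "observed"
      next
    }
    if (any(at_pos & calls$ref != va$ref[i])) {
      warning("reference-allele mismatch at ", va$chrom[i], ":", va$pos[i],
              " (catalog ", va$ref[i], ", VCF ",
              calls$ref[which(at_pos)[1]], ") for ", va$rsid[i],
              "; recorded as no_call", call. = FALSE)
      state[i] <- "no_call"; source[i] <- "observed"
      next
    }
    # rsid fallback when the position differs (e.g. other-build coordinates)
    by_rs <- !is.na(calls$rsid) & calls$rsid == va$rsid[i] &
      calls$alt == va$alt[i]
    if (any(by_rs)) {
      message("matched ", va$rsid[i], " by rsid at ",
              calls$chrom[which(by_rs)[1]], ":", calls$pos[which(by_rs)[1]],
              " (catalog ", build, " position ", va$pos[i], ")")
      state[i] <- dosage_state(calls$dosage[which(by_rs)[1]])
      source[i] <- "observed"
      next
    }
    if (any(at_pos)) {
      # record at the position with matching ref but a different alt allele:
      # the catalog alt was not called there
      state[i] <- if (is.na(calls$dosage[which(at_pos)[1]])) "no_call" else "hom_ref"
      source[i] <- "observed"
      next
    }
    if (genotype_complete) {
      state[i] <- "hom_ref"; source[i] <- "assumed_ref"
    } else {
      state[i] <- "no_call"; source[i] <- "observed"
    }
  }
  structure(list(
    sample_id = sample_id, build = build,
    obs = data.frame(gene = va$gene, rsid = va$rsid, state = state,
                     source = source, stringsAsFactors = FALSE)
  ), class = "pgx_sample_genotypes")
}

dosage_state <- function(d) {
  if (is.na(d)) "no_call"
  else if (d == 0L) "hom_ref"
  else if (d == 1L) "het"
  else if (d == 2L) "hom_alt"
  else stop("dosage out of range: ", d, call. = FALSE)
}

state_dosage <- function(s) {
  c(hom_ref = 0L, het = 1L, hom_alt = 2L, no_call = NA_integer_)[[s]]
}

#' @export
print.pgx_sample_genotypes <- function(x, ...) {
  tab <- table(x$obs$state)
  cat("Sample ", x$sample_id, " (", x$build, "): ",
      nrow(x$obs), " catalog loci [",
      paste(names(tab), tab, sep = "=", collapse = ", "), "]\n", sep = "")
  invisible(x)
}
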