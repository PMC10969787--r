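test_that("noise-free fixtures encode exactly the implied alternate records", {
  # all-reference sample: no data lines at all
  spec0 <- fixture_spec("F0", character(0), build = "GRCh38", seed = 1)
  v0 <- withr::local_tempfile(fileext = ".vcf")
  generate_sample_vcf(spec0, pkg_kb, v0)
  expect_length(grep("^[^#]", readLines(v0)), 0)

  # CYP2C19 *2/*2: the single *2-defining record, homozygous
  spec2 <- fixture_spec("F2", c(CYP2C19 = "*2/*2"), build = "GRCh38", seed = 1)
  v2 <- withr::local_tempfile(fileext = ".vcf")
  m <- generate_sample_vcf(spec2, pkg_kb, v2)
  body <- grep("^[^#]", readLines(v2), value = TRUE)
  expect_length(body, 1)
  expect_match(body, "rs4244285")
  expect_match(body, "1/1$")

  # a shared-variant diplotype (SLCO1B1 *5/*15) emits the shared locus once
  # at dosage 2 and the private locus at dosage 1
  spec5 <- fixture_spec("F5", c(SLCO1B1 = "*5/*15"), build = "GRCh37", seed = 1)
  v5 <- withr::local_tempfile(fileext = ".vcf")
  m5 <- generate_sample_vcf(spec5, pkg_kb, v5)
  expect_equal(sum(m5$rsid == "rs4149056"), 1)
  expect_identical(m5$gt[m5$rsid == "rs4149056"], "1/1")
  expect_identical(m5$gt[m5$rsid == "rs2306283"], "0/1")

  expect_error(
    generate_sample_vcf(fixture_spec("FX", c(CYP2C19 = "*42/*1")), pkg_kb,
                        tempfile()),
    "not resolvable")
})

test_that("identical spec and seed give byte-identical VCFs", {
  spec <- fixture_spec("FD", c(CYP2D6 = "*4/*10", TPMT = "*2/*3C"),
                       build = "GRCh38", drop_rate = 0.3,
                       spurious_rate = 0.5, nocall_rate = 0.3, seed = 314)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  generate_sample_vcf(spec, pkg_kb, f1)
  generate_sample_vcf(spec, pkg_kb, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free round trip recovers every spec'd diplotype exactly", {
  diplos <- c(CYP2C19 = "*2/*17", CYP2D6 = "*3/*41", CYP2B6 = "*6/*18",
              TPMT = "*3A/*3C", SLCO1B1 = "*15/*15", DPYD = "*2A/*13")
  spec <- fixture_spec("RT", diplos, build = "GRCh38", seed = 21)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  generate_sample_vcf(spec, pkg_kb, vcf)
  calls_tab <- read_vcf(vcf, catalog_regions(pkg_kb, "GRCh38"))
  sg <- extract_catalog_genotypes(calls_tab, pkg_kb, "GRCh38",
                                  genotype_complete = TRUE)
  dip <- call_all_genes(pkg_kb, sg)
  for (g in names(diplos)) {
    expect_identical(dip[[g]]$alias, normalize_diplotype(diplos[[g]]),
                     label = g)
    expect_identical(dip[[g]]$quality, "exact", label = g)
  }
  # genotype states recovered are exactly what the fixture encoded
  expect_identical(sg$obs$state[sg$obs$rsid == "rs4244285"], "het")
  expect_identical(sg$obs$state[sg$obs$rsid == "rs4149056"], "hom_alt")
})

test_that("dropout count matches its binomial expectation across seeds", {
  diplos <- c(CYP2D6 = "*4/*10", CYP2C19 = "*2/*3", TPMT = "*3A/*3C",
              CYP2B6 = "*6/*6", SLCO1B1 = "*5/*15", CYP3A5 = "*3/*6",
              DPYD = "*2A/*13", CYP2C9 = "*2/*3")
  n_true <- nrow(fixture_truth_records(
    fixture_spec("X", diplos, build = "GRCh38", seed = 1), pkg_kb))
  rate <- 0.2
  kept <- vapply(1:60, function(s) {
    spec <- fixture_spec("X", diplos, build = "GRCh38",
                         drop_rate = rate, seed = s)
    f <- tempfile(fileext = ".vcf")
    on.exit(unlink(f))
    nrow(generate_sample_vcf(spec, pkg_kb, f))
  }, numeric(1))
  dropped <- n_true * 60 - sum(kept)
  expectation <- rate * n_true * 60
  sd_binom <- sqrt(n_true * 60 * rate * (1 - rate))
  expect_lt(abs(dropped - expectation), 4 * sd_binom)
})

test_that("no-call noise only ever downgrades calls, never flips an observed exact diplotype", {
  diplos <- c(CYP2C19 = "*2/*17", TPMT = "*1/*3A", CYP2D6 = "*10/*41")
  for (s in 1:25) {
    spec <- fixture_spec("NC", diplos, build = "GRCh38",
                         nocall_rate = 0.4, seed = s)
    vcf <- tempfile(fileext = ".vcf")
    generate_sample_vcf(spec, pkg_kb, vcf)
    calls_tab <- read_vcf(vcf, catalog_regions(pkg_kb, "GRCh38"))
    sg <- extract_catalog_genotypes(calls_tab, pkg_kb, "GRCh38",
                                    genotype_complete = TRUE)
    dip <- call_all_genes(pkg_kb, sg)
    for (g in names(diplos)) {
      truth_alias <- normalize_diplotype(diplos[[g]])
      cl <- dip[[g]]
      if (cl$quality == "exact") {
        expect_identical(cl$alias, truth_alias, label = paste(g, "seed", s))
      } else {
        expect_true(cl$quality %in% c("ambiguous", "incomplete"),
                    label = paste(g, "seed", s))
        expect_true(truth_alias %in% cl$candidates,
                    label = paste(g, "seed", s))
      }
    }
    unlink(vcf)
  }
})

test_that("spurious records land inside catalog regions at non-catalog loci", {
  spec <- fixture_spec("SP", character(0), build = "GRCh38",
                       spurious_rate = 1, seed = 8)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  m <- generate_sample_vcf(spec, pkg_kb, vcf)
  expect_true(all(m$spurious))
  # one spurious record per region that has room for a non-catalog position
  rg <- catalog_regions(pkg_kb, "GRCh38")
  n_positions <- vapply(rg$gene, function(g)
    length(unique(pkg_kb$variants$pos_grch38[pkg_kb$variants$gene == g])),
    integer(1))
  eligible <- sum(rg$end - rg$start + 1L > n_positions)
  expect_equal(nrow(m), eligible)
  keys <- variant_key(m$chrom, m$pos, m$ref, m$alt)
  cat_keys <- variant_key(pkg_kb$variants$chrom, pkg_kb$variants$pos_grch38,
                          pkg_kb$variants$ref, pkg_kb$variants$alt)
  expect_length(intersect(keys, cat_keys), 0)
  # and they perturb variant-set concordance but not the *1/*1 calls
  calls_tab <- read_vcf(vcf, catalog_regions(pkg_kb, "GRCh38"))
  sg <- extract_catalog_genotypes(calls_tab, pkg_kb, "GRCh38",
                                  genotype_complete = TRUE)
  dip <- call_all_genes(pkg_kb, sg)
  expect_true(all(vapply(dip, `[[`, character(1), "alias") == "*1/*1"))
})

test_that("cohorts are reproducible and degenerate samplers honored", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- generate_cohort(4, pkg_kb, d1, build = "GRCh38", seed = 77)
  co2 <- generate_cohort(4, pkg_kb, d2, build = "GRCh38", seed = 77)
  for (i in 1:4) {
    expect_identical(readLines(co1$vcf_paths[i]), readLines(co2$vcf_paths[i]))
  }
  expect_identical(co1$truth_diplotypes$data, co2$truth_diplotypes$data)

  expect_error(generate_cohort(0, pkg_kb, d1), ">= 1")

  # a weight table putting all mass on *1/*1 yields an all-reference cohort
  w <- lapply(stats::setNames(nm = pkg_kb$genes),
              function(g) c("*1/*1" = 1))
  co3 <- generate_cohort(3, pkg_kb, withr::local_tempdir(), seed = 5,
                         weights = w)
  for (s in names(co3$truth_diplotypes$data)) {
    expect_true(all(unlist(co3$truth_diplotypes$data[[s]]) == "*1/*1"))
  }
})
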