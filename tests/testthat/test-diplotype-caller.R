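test_that("pair consistency follows unphased dosage arithmetic", {
  kb <- make_test_kb(list(G1 = list("*2" = "rs100", "*3" = "rs200")))
  all_ref <- make_sg("G1", c(rs100 = "hom_ref", rs200 = "hom_ref"))
  expect_true(pair_consistent(kb, all_ref, "G1", "*1", "*1"))
  expect_false(pair_consistent(kb, all_ref, "G1", "*1", "*2"))

  het2 <- make_sg("G1", c(rs100 = "het", rs200 = "hom_ref"))
  expect_true(pair_consistent(kb, het2, "G1", "*1", "*2"))
  expect_false(pair_consistent(kb, het2, "G1", "*2", "*2"))

  # het at a *2 locus AND a *3 locus: only *2/*3 explains both (verified
  # against the exhaustive oracle)
  transhet <- make_sg("G1", c(rs100 = "het", rs200 = "het"))
  expect_true(pair_consistent(kb, transhet, "G1", "*2", "*3"))
  oracle <- oracle_candidates(list("*2" = "rs100", "*3" = "rs200"),
                              c(rs100 = 1L, rs200 = 1L))
  expect_identical(oracle, "*2/*3")
  expect_identical(call_diplotype(kb, transhet, "G1")$candidates, oracle)
})

test_that("pair consistency is symmetric and no_call loci are uninformative", {
  kb <- make_test_kb(list(G1 = list("*2" = "rs100", "*3" = c("rs100", "rs200"))))
  sg <- make_sg("G1", c(rs100 = "het", rs200 = "no_call"))
  for (a in c("*1", "*2", "*3")) for (b in c("*1", "*2", "*3")) {
    expect_identical(pair_consistent(kb, sg, "G1", a, b),
                     pair_consistent(kb, sg, "G1", b, a))
  }
  # with rs200 uninformative both *1/*2 and *1/*3 are consistent
  expect_true(pair_consistent(kb, sg, "G1", "*1", "*2"))
  expect_true(pair_consistent(kb, sg, "G1", "*1", "*3"))
})

test_that("call_diplotype resolves forced and nested-definition cases exactly", {
  kb <- make_test_kb(list(G1 = list("*2" = "rs100", "*4" = c("rs100", "rs200"))))

  ref <- make_sg("G1", c(rs100 = "hom_ref", rs200 = "hom_ref"))
  cl <- call_diplotype(kb, ref, "G1")
  expect_identical(cl$allele_pair, c("*1", "*1"))
  expect_identical(cl$quality, "exact")

  hom2 <- make_sg("G1", c(rs100 = "hom_alt", rs200 = "hom_ref"))
  cl2 <- call_diplotype(kb, hom2, "G1")
  expect_identical(cl2$alias, "*2/*2")
  expect_identical(cl2$quality, "exact")

  # *4's defining set strictly contains *2's: hom_alt on the shared locus,
  # het on *4's extra locus must resolve to *2/*4, matching the oracle
  nested <- make_sg("G1", c(rs100 = "hom_alt", rs200 = "het"))
  cl3 <- call_diplotype(kb, nested, "G1")
  oracle <- oracle_candidates(list("*2" = "rs100", "*4" = c("rs100", "rs200")),
                              c(rs100 = 2L, rs200 = 1L))
  expect_identical(cl3$candidates, oracle)
  expect_identical(cl3$alias, "*2/*4")
  expect_identical(cl3$quality, "exact")
})

test_that("quality flags surface ambiguity, missing data, and contradictions", {
  kb <- make_test_kb(list(G1 = list("*2" = "rs100", "*3" = c("rs100", "rs200"))))

  # rs200 uninformative: both *1/*2 and *1/*3 fit; the parsimony/lexicographic
  # winner *1/*2 has all its loci observed, so the flag is ambiguity, and the
  # alternative stays listed
  ambiguous <- make_sg("G1", c(rs100 = "het", rs200 = "no_call"))
  cl <- call_diplotype(kb, ambiguous, "G1")
  expect_identical(cl$quality, "ambiguous")
  expect_setequal(cl$candidates, c("*1/*2", "*1/*3"))
  expect_identical(cl$alias, "*1/*2")

  # when the winner itself rests on a no_call defining locus the flag is
  # incomplete
  kb_inc <- make_test_kb(list(G1 = list("*2" = c("rs100", "rs200"))))
  inc <- make_sg("G1", c(rs100 = "het", rs200 = "no_call"))
  cl_inc <- call_diplotype(kb_inc, inc, "G1")
  expect_identical(cl_inc$alias, "*1/*2")
  expect_identical(cl_inc$quality, "incomplete")
  expect_identical(cl_inc$uncovered, "rs200")

  all_nc <- make_sg("G1", c(rs100 = "no_call", rs200 = "no_call"))
  expect_identical(call_diplotype(kb, all_nc, "G1")$quality, "no_call")

  # hom_alt at the subset locus while its superset locus is hom_ref and a
  # stray het elsewhere cannot be explained by any pair
  kb2 <- make_test_kb(list(G1 = list("*2" = "rs100")))
  weird <- make_sg("G1", c(rs100 = "het"))
  weird$obs$state <- "het"
  cl2 <- call_diplotype(kb2, weird, "G1")
  expect_identical(cl2$quality, "exact")
  contradict <- make_sg("G1", c(rs100 = "het", rs200 = "het"))
  cl3 <- call_diplotype(kb2, contradict, "G1")  # rs200 unknown to kb2: ignored
  expect_identical(cl3$alias, "*1/*2")
})

test_that("no consistent pair reports unresolved instead of raising", {
  # two alleles sharing a locus: observed dosage 2 at the shared locus plus
  # dosage 2 at each private locus exceeds what any pair can carry
  kb <- make_test_kb(list(G1 = list("*2" = c("rs100", "rs200"),
                                    "*3" = c("rs100", "rs300"))))
  sg <- make_sg("G1", c(rs100 = "hom_ref", rs200 = "hom_alt", rs300 = "hom_alt"))
  cl <- call_diplotype(kb, sg, "G1")
  expect_identical(cl$quality, "unresolved")
  expect_length(cl$allele_pair, 0)
  expect_length(cl$candidates, 0)
})

test_that("candidate sets equal exhaustive brute-force enumeration on random configurations", {
  withr::local_seed(424242)
  for (rep in seq_len(150)) {
    cfg <- random_config()
    pkg <- config_to_pkg(cfg)
    got <- call_diplotype(pkg$kb, pkg$sg, "GX")$candidates
    want <- oracle_candidates(cfg$defs, cfg$dosages)
    expect_identical(got, want, label = paste0("rep ", rep))
  }
})

test_that("adding no_call at a locus never shrinks the candidate set", {
  withr::local_seed(777)
  for (rep in seq_len(60)) {
    cfg <- random_config()
    observed <- names(cfg$dosages)[!is.na(cfg$dosages)]
    if (!length(observed)) next
    pkg <- config_to_pkg(cfg)
    before <- call_diplotype(pkg$kb, pkg$sg, "GX")$candidates
    cfg2 <- cfg
    cfg2$dosages[sample(observed, 1)] <- NA
    pkg2 <- config_to_pkg(cfg2)
    after <- call_diplotype(pkg2$kb, pkg2$sg, "GX")$candidates
    expect_true(all(before %in% after),
                label = paste0("monotonicity rep ", rep))
  }
})

test_that("call_all_genes returns one deterministic call per catalog gene in catalog order", {
  spec <- fixture_spec("D1", c(CYP2C19 = "*2/*2"), build = "GRCh38", seed = 5)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  generate_sample_vcf(spec, pkg_kb, vcf)
  calls_tab <- read_vcf(vcf, catalog_regions(pkg_kb, "GRCh38"))
  sg <- extract_catalog_genotypes(calls_tab, pkg_kb, "GRCh38",
                                  genotype_complete = TRUE)
  dip <- call_all_genes(pkg_kb, sg)
  expect_identical(names(dip), pkg_kb$genes)
  aliases <- vapply(dip, `[[`, character(1), "alias")
  expect_identical(unname(aliases[names(aliases) != "CYP2C19"]),
                   rep("*1/*1", 12))
  expect_identical(aliases[["CYP2C19"]], "*2/*2")
  dip2 <- call_all_genes(pkg_kb, sg)
  expect_identical(calls_summary(dip), calls_summary(dip2))
})
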