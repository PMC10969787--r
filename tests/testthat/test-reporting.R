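# Report rendering over an all-reference sample plus one CYP2C19 *1/*17
# carrier, which exercises summary information-hiding, bracketed
# strengths, and caveat surfacing.

make_report_inputs <- function(diplotypes = c(CYP2C19 = "*1/*17")) {
  spec <- fixture_spec("R1", diplotypes, build = "GRCh38", seed = 11)
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  generate_sample_vcf(spec, pkg_kb, vcf)
  calls_tab <- read_vcf(vcf, catalog_regions(pkg_kb, "GRCh38"))
  sg <- extract_catalog_genotypes(calls_tab, pkg_kb, "GRCh38",
                                  genotype_complete = TRUE)
  calls <- call_all_genes(pkg_kb, sg)
  phenos <- lapply(calls, function(cl) assign_phenotype(pkg_kb, cl))
  list(calls = calls, phenos = phenos)
}

test_that("summary format has one row per gene and hides interpretations", {
  inp <- make_report_inputs()
  doc <- render_report(inp$calls, inp$phenos, pkg_kb, format = "summary",
                       sample_id = "R1", created = "2026-01-01T00:00:00+0000")
  expect_equal(nrow(doc$rows), 13)
  expect_true(all(is.na(doc$rows$interpretation)))
  expect_true(all(is.na(doc$rows$dosing_recommendation)))
  expect_true(all(is.na(doc$rows$drug)))
  # no dosing text from the catalog leaks into any serialization of it
  out <- tempfile(fileext = ".tsv")
  serialize_report(doc, out, "tsv")
  txt <- paste(readLines(out), collapse = "\n")
  dosings <- unique(pkg_kb$records$dosing_recommendation)
  expect_false(any(vapply(dosings, function(d) grepl(d, txt, fixed = TRUE),
                          logical(1))))
  unlink(out)
})

test_that("single-gene-drug format reports one pair with a bracketed strength", {
  inp <- make_report_inputs()
  doc <- render_report(inp$calls, inp$phenos, pkg_kb,
                       format = "single_gene_drug", genes = "CYP2C19",
                       drugs = "Clopidogrel", sample_id = "R1",
                       created = "2026-01-01T00:00:00+0000")
  expect_equal(nrow(doc$rows), 1)
  expect_identical(doc$rows$gene, "CYP2C19")
  expect_identical(doc$rows$drug, "Clopidogrel")
  expect_identical(doc$rows$genotype_alias, "*1/*17")
  expect_match(doc$rows$interpretation,
               "^\\[(Strong|Moderate|Optional|No recommendation)\\]")
  expect_match(doc$rows$phenotype_category, "Rapid metabolizer")

  expect_error(
    render_report(inp$calls, inp$phenos, pkg_kb, format = "single_gene_drug",
                  genes = "CYP2C19", drugs = "Warfarin"),
    "valid drugs")
})

test_that("full format over an all-reference sample reports *1/*1 everywhere with catalog rows", {
  inp <- make_report_inputs(diplotypes = character(0))
  doc <- render_report(inp$calls, inp$phenos, pkg_kb, format = "full",
                       sample_id = "R0", created = "2026-01-01T00:00:00+0000")
  expect_setequal(unique(doc$rows$gene), pkg_kb$genes)
  expect_true(all(doc$rows$genotype_alias == "*1/*1"))
  # every detailed row corresponds to an existing catalog record
  for (i in seq_len(nrow(doc$rows))) {
    rec <- lookup_record(pkg_kb, doc$rows$gene[i], doc$rows$genotype_alias[i],
                         doc$rows$drug[i])
    expect_false(is.null(rec))
    expect_identical(doc$rows$interpretation[i], rec$interpretation)
  }
})

test_that("ambiguous and incomplete calls appear in caveats, never dropped", {
  inp <- make_report_inputs()
  calls <- inp$calls
  calls$CYP2C19$quality <- "incomplete"
  calls$CYP2C19$uncovered <- "rs12248560"
  doc <- render_report(calls, inp$phenos, pkg_kb, format = "summary",
                       created = "2026-01-01T00:00:00+0000")
  expect_match(doc$caveats, "CYP2C19", all = FALSE)
  expect_true("CYP2C19" %in% doc$rows$gene)
})

test_that("serialization is deterministic and JSON round-trips the document", {
  inp <- make_report_inputs()
  doc <- render_report(inp$calls, inp$phenos, pkg_kb, format = "full",
                       sample_id = "R1", created = "2026-01-01T00:00:00+0000")
  for (style in c("tsv", "json", "text")) {
    f1 <- tempfile(); f2 <- tempfile()
    serialize_report(doc, f1, style)
    serialize_report(doc, f2, style)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)),
                     label = style)
    unlink(c(f1, f2))
  }
  jf <- tempfile(fileext = ".json")
  serialize_report(doc, jf, "json")
  back <- read_report_json(jf)
  expect_identical(back$rows, doc$rows)
  expect_identical(back$format, doc$format)
  expect_identical(back$created, doc$created)
  expect_identical(back$catalog_version, doc$catalog_version)
  unlink(jf)

  # degenerate: a document with zero rows still serializes validly
  empty <- doc
  empty$rows <- doc$rows[0, ]
  tf <- tempfile(fileext = ".tsv")
  serialize_report(empty, tf, "tsv")
  expect_true(file.exists(tf))
  unlink(tf)
})
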