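#!/usr/bin/env Rscript
# Builds inst/extdata/pgx_catalog.tsv: the packaged 13-gene PGx catalog.
# Allele definitions (rsids, dual-build coordinates, functional effect,
# activity values for CYP2D6, AMP tier) follow CPIC/PharmVar-published
# definitions; diplotype interpretation rows are generated from per-gene
# phenotype rules with CPIC-style bracketed evidence strengths.
# Re-run from the repository root: Rscript tools/make_catalog.R

suppressWarnings(dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE))

V <- function(gene, star, rsid, chrom, p37, p38, ref, alt, cdna, aa,
              act = NA_real_, fn, tier) {
  data.frame(gene = gene, star = star, rsid = rsid, chrom = chrom,
             pos_grch37 = p37, pos_grch38 = p38, ref = ref, alt = alt,
             cdna = cdna, aa = aa, activity = act, fn = fn, tier = tier,
             stringsAsFactors = FALSE)
}

variants <- rbind(
  # COMT (chr22): Val158Met, reduced enzymatic activity
  V("COMT", "*2", "rs4680", "22", 19951271L, 19963748L, "G", "A",
    "c.472G>A", "p.V158M", NA, "decreased activity", 2L),
  # CYP2B6 (chr19): *6 is the two-SNP haplotype Q172H + K262R
  V("CYP2B6", "*6", "rs3745274", "19", 41512841L, 41006936L, "G", "T",
    "c.516G>T", "p.Q172H", NA, "decreased function", 1L),
  V("CYP2B6", "*6", "rs2279343", "19", 41515263L, 41009358L, "A", "G",
    "c.785A>G", "p.K262R", NA, "decreased function", 1L),
  V("CYP2B6", "*18", "rs28399499", "19", 41518221L, 41012316L, "T", "C",
    "c.983T>C", "p.I328T", NA, "no function", 2L),
  # CYP2C9 (chr10)
  V("CYP2C9", "*2", "rs1799853", "10", 96702047L, 94942290L, "C", "T",
    "c.430C>T", "p.R144C", NA, "decreased function", 1L),
  V("CYP2C9", "*3", "rs1057910", "10", 96741053L, 94981296L, "A", "C",
    "c.1075A>C", "p.I359L", NA, "no function", 1L),
  # CYP2C19 (chr10)
  V("CYP2C19", "*2", "rs4244285", "10", 96541616L, 94781859L, "G", "A",
    "c.681G>A", "none", NA, "no function", 1L),
  V("CYP2C19", "*3", "rs4986893", "10", 96540410L, 94780653L, "G", "A",
    "c.636G>A", "p.W212X", NA, "no function", 1L),
  V("CYP2C19", "*17", "rs12248560", "10", 96521657L, 94761900L, "C", "T",
    "c.-806C>T", "none", NA, "increased function", 1L),
  # CYP2D6 (chr22): the only gene on the activity-score path
  V("CYP2D6", "*3", "rs35742686", "22", 42524243L, 42128241L, "AA", "A",
    "c.775delA", "p.R259fs", 0, "no function", 1L),
  V("CYP2D6", "*4", "rs3892097", "22", 42524947L, 42128945L, "C", "T",
    "c.506-1G>A", "none", 0, "no function", 1L),
  V("CYP2D6", "*6", "rs5030655", "22", 42525085L, 42129083L, "TT", "T",
    "c.454delT", "p.W152fs", 0, "no function", 1L),
  V("CYP2D6", "*10", "rs1065852", "22", 42526694L, 42130692L, "G", "A",
    "c.100C>T", "p.P34S", 0.25, "decreased function", 1L),
  V("CYP2D6", "*17", "rs28371706", "22", 42525772L, 42129770L, "G", "A",
    "c.320C>T", "p.T107I", 0.5, "decreased function", 1L),
  V("CYP2D6", "*41", "rs28371725", "22", 42523805L, 42127803L, "C", "T",
    "c.985+39G>A", "none", 0.25, "decreased function", 1L),
  # CYP3A5 (chr7)
  V("CYP3A5", "*3", "rs776746", "7", 99270539L, 99672916L, "T", "C",
    "c.219-237A>G", "none", NA, "no function", 1L),
  V("CYP3A5", "*6", "rs10264272", "7", 99262835L, 99665212L, "C", "T",
    "c.624G>A", "none", NA, "no function", 2L),
  V("CYP3A5", "*7", "rs41303343", "7", 99250393L, 99652770L, "A", "AT",
    "c.1035_1036insT", "p.T346fs", NA, "no function", 2L),
  # CYP4F2 (chr19)
  V("CYP4F2", "*3", "rs2108622", "19", 15990431L, 15879621L, "C", "T",
    "c.1297G>A", "p.V433M", NA, "decreased function", 1L),
  # DPYD (chr1)
  V("DPYD", "*2A", "rs3918290", "1", 97915614L, 97450058L, "C", "T",
    "c.1905+1G>A", "none", NA, "no function", 1L),
  V("DPYD", "*13", "rs55886062", "1", 97981343L, 97515787L, "A", "C",
    "c.1679T>G", "p.I560S", NA, "no function", 1L),
  # IL28B / IFNL3 (chr19): response-predictive upstream variant
  V("IL28B", "*2", "rs12979860", "19", 39738787L, 39248147L, "C", "T",
    "c.-3176C>T", "none", NA, "unfavorable response", 2L),
  # NUDT15 (chr13)
  V("NUDT15", "*3", "rs116855232", "13", 48611934L, 48037782L, "C", "T",
    "c.415C>T", "p.R139C", NA, "no function", 1L),
  # SLCO1B1 (chr12): *15 = N130D + V174A haplotype (contains the *5 variant)
  V("SLCO1B1", "*5", "rs4149056", "12", 21331549L, 21178615L, "T", "C",
    "c.521T>C", "p.V174A", NA, "decreased function", 1L),
  V("SLCO1B1", "*15", "rs2306283", "12", 21329738L, 21176804L, "A", "G",
    "c.388A>G", "p.N130D", NA, "decreased function", 1L),
  V("SLCO1B1", "*15", "rs4149056", "12", 21331549L, 21178615L, "T", "C",
    "c.521T>C", "p.V174A", NA, "decreased function", 1L),
  # TPMT (chr6): *3A = *3B-variant + *3C-variant haplotype
  V("TPMT", "*2", "rs1800462", "6", 18143955L, 18143724L, "C", "G",
    "c.238G>C", "p.A80P", NA, "no function", 1L),
  V("TPMT", "*3A", "rs1800460", "6", 18139228L, 18138997L, "C", "T",
    "c.460G>A", "p.A154T", NA, "no function", 1L),
  V("TPMT", "*3A", "rs1142345", "6", 18130918L, 18130687L, "A", "G",
    "c.719A>G", "p.Y240C", NA, "no function", 1L),
  V("TPMT", "*3C", "rs1142345", "6", 18130918L, 18130687L, "A", "G",
    "c.719A>G", "p.Y240C", NA, "no function", 1L),
  # VKORC1 (chr16): warfarin-sensitivity promoter variant
  V("VKORC1", "*2", "rs9923231", "16", 31107689L, 31096368L, "C", "T",
    "c.-1639G>A", "none", NA, "increased warfarin sensitivity", 1L)
)

genes <- c("COMT", "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A5",
           "CYP4F2", "DPYD", "IL28B", "NUDT15", "SLCO1B1", "TPMT", "VKORC1")

# one fully catalogued (diplotype-row) drug set per gene
drugs <- list(
  COMT = "Opioid", CYP2B6 = "Efavirenz", CYP2C9 = "Warfarin",
  CYP2C19 = c("Clopidogrel", "Voriconazole"),
  CYP2D6 = c("Codeine", "Tamoxifen"),
  CYP3A5 = "Tacrolimus", CYP4F2 = "Warfarin",
  DPYD = "Fluoropyrimidines", IL28B = "PEG Interferon-alpha",
  NUDT15 = "Thiopurine", SLCO1B1 = "Simvastatin", TPMT = "Thiopurine",
  VKORC1 = "Warfarin"
)

refs <- list(
  COMT = "CPIC opioid guideline 2020;PharmGKB PA117",
  CYP2B6 = "CPIC efavirenz guideline 2019;PharmGKB PA123",
  CYP2C9 = "CPIC warfarin guideline 2017;PharmGKB PA126",
  CYP2C19 = "CPIC clopidogrel guideline 2022;CPIC voriconazole guideline 2016;PharmGKB PA124",
  CYP2D6 = "CPIC opioid guideline 2021;CPIC tamoxifen guideline 2018;CYP2D6 genotype-phenotype consensus 2020",
  CYP3A5 = "CPIC tacrolimus guideline 2015;PharmGKB PA131",
  CYP4F2 = "CPIC warfarin guideline 2017;PharmGKB PA27121",
  DPYD = "CPIC fluoropyrimidine guideline 2017;PharmGKB PA145",
  IL28B = "CPIC PEG interferon-alpha guideline 2014;PharmGKB PA134952671",
  NUDT15 = "CPIC thiopurine guideline 2018;PharmGKB PA134963132",
  SLCO1B1 = "CPIC statin guideline 2022;PharmGKB PA134865839",
  TPMT = "CPIC thiopurine guideline 2018;PharmGKB PA356",
  VKORC1 = "CPIC warfarin guideline 2017;PharmGKB PA133787052"
)

star_num <- function(s) as.integer(sub("^\\*([0-9]+).*$", "\\1", s))
star_sfx <- function(s) sub("^\\*[0-9]+", "", s)
sort2 <- function(a, b) {
  k <- order(c(star_num(a), star_num(b)), c(star_sfx(a), star_sfx(b)))
  c(a, b)[k]
}

fn_of <- function(g, s) {
  if (s == "*1") return("normal function")
  unique(variants$fn[variants$gene == g & variants$star == s])[1]
}
act_of <- function(g, s) {
  if (s == "*1") return(1.0)
  unique(variants$activity[variants$gene == g & variants$star == s])[1]
}

# per-gene diplotype -> phenotype category
category_of <- function(g, a, b) {
  f <- c(fn_of(g, a), fn_of(g, b))
  nf <- sum(f == "no function")
  dec <- sum(f == "decreased function")
  inc <- sum(f == "increased function")
  switch(g,
    CYP2D6 = {
      s <- act_of(g, a) + act_of(g, b)
      if (s > 2.25) "Ultrarapid metabolizer"
      else if (s >= 1.25) "Normal metabolizer"
      else if (s > 0) "Intermediate metabolizer"
      else "Poor metabolizer"
    },
    CYP2C19 = {
      if (nf == 2) "Poor metabolizer"
      else if (nf == 1) "Intermediate metabolizer"
      else if (inc == 2) "Ultrarapid metabolizer"
      else if (inc == 1) "Rapid metabolizer"
      else "Normal metabolizer"
    },
    CYP2B6 = {
      imp <- nf + dec
      if (imp == 2) "Poor metabolizer"
      else if (imp == 1) "Intermediate metabolizer"
      else "Normal metabolizer"
    },
    CYP2C9 = {
      s <- sum(c(1, 0.5, 0)[match(f, c("normal function", "decreased function", "no function"))])
      if (s >= 2) "Normal metabolizer"
      else if (s >= 1) "Intermediate metabolizer"
      else "Poor metabolizer"
    },
    CYP3A5 = if (nf == 2) "Poor metabolizer (CYP3A5 non-expresser)"
             else if (nf == 1) "Intermediate metabolizer"
             else "Normal metabolizer (CYP3A5 expresser)",
    CYP4F2 = if (dec >= 1) "Decreased function" else "Normal function",
    DPYD = if (nf == 2) "DPYD poor metabolizer (complete DPD deficiency)"
           else if (nf == 1) "DPYD intermediate metabolizer (partial DPD deficiency)"
           else "DPYD normal metabolizer",
    IL28B = if (sum(c(a, b) != "*1") == 0) "Favorable response genotype"
            else "Unfavorable response genotype",
    NUDT15 = if (nf == 2) "Poor metabolizer"
             else if (nf == 1) "Intermediate metabolizer"
             else "Normal metabolizer",
    TPMT = if (nf == 2) "Poor metabolizer"
           else if (nf == 1) "Intermediate metabolizer"
           else "Normal metabolizer",
    SLCO1B1 = if (dec == 2) "Poor function"
              else if (dec == 1) "Decreased function"
              else "Normal function",
    COMT = if (sum(c(a, b) != "*1") >= 1) "Reduced COMT activity"
           else "Normal COMT activity",
    VKORC1 = if (sum(c(a, b) != "*1") == 2) "High warfarin sensitivity"
             else if (sum(c(a, b) != "*1") == 1) "Increased warfarin sensitivity"
             else "Normal warfarin sensitivity"
  )
}

# interpretation body + dosing per gene x drug x category; strength chosen
# per CPIC convention (actionable: Strong; modest/emerging evidence lower)
interp_of <- function(g, drug, cat) {
  strong <- function(b, d) list(strength = "Strong", body = b, dosing = d)
  mod <- function(b, d) list(strength = "Moderate", body = b, dosing = d)
  opt <- function(b, d) list(strength = "Optional", body = b, dosing = d)
  none <- function(b, d) list(strength = "No recommendation", body = b, dosing = d)
  low <- grepl("Poor|poor", cat); mid <- grepl("Intermediate|intermediate|Decreased|Reduced", cat)
  hi <- grepl("Ultrarapid|Rapid", cat)
  switch(g,
    CYP2C19 = if (drug == "Clopidogrel") {
      if (low) strong(paste0(cat, ": significantly reduced formation of clopidogrel active metabolite; increased risk of adverse cardiovascular events."),
                      "Avoid standard-dose clopidogrel; use prasugrel or ticagrelor if no contraindication.")
      else if (mid) strong(paste0(cat, ": reduced clopidogrel active metabolite formation."),
                           "Consider alternative antiplatelet therapy (prasugrel or ticagrelor).")
      else if (hi) strong(paste0(cat, ": normal or increased clopidogrel active metabolite formation."),
                          "Standard dosing; label-recommended dosage and administration.")
      else strong(paste0(cat, ": normal clopidogrel active metabolite formation."),
                  "Standard dosing; label-recommended dosage and administration.")
    } else {
      if (low) mod(paste0(cat, ": markedly increased voriconazole exposure."),
                   "Choose an alternative agent (e.g. isavuconazole) or reduce dose with therapeutic drug monitoring.")
      else if (mid) mod(paste0(cat, ": increased voriconazole exposure."),
                        "Initiate standard dosing with therapeutic drug monitoring.")
      else if (hi) mod(paste0(cat, ": subtherapeutic voriconazole exposure likely."),
                       "Choose an alternative agent that is not dependent on CYP2C19 metabolism.")
      else mod(paste0(cat, ": normal voriconazole metabolism."), "Standard dosing.")
    },
    CYP2D6 = if (drug == "Codeine") {
      if (low) strong(paste0(cat, ": greatly reduced morphine formation; insufficient analgesia expected."),
                      "Avoid codeine; use a non-tramadol alternative analgesic.")
      else if (mid) mod(paste0(cat, ": reduced morphine formation."),
                        "Use codeine per label; monitor analgesia closely and consider an alternative if inadequate.")
      else if (hi) strong(paste0(cat, ": greatly increased morphine formation; risk of serious toxicity."),
                          "Avoid codeine; use a non-tramadol alternative analgesic.")
      else strong(paste0(cat, ": expected morphine formation."), "Standard age- and weight-specific codeine dosing.")
    } else {
      if (low) strong(paste0(cat, ": greatly reduced endoxifen concentrations; higher risk of breast cancer recurrence."),
                      "Consider an alternative hormonal therapy such as an aromatase inhibitor.")
      else if (mid) mod(paste0(cat, ": reduced endoxifen concentrations."),
                        "Consider an aromatase inhibitor, or tamoxifen 40 mg/day if aromatase inhibitor is contraindicated.")
      else strong(paste0(cat, ": therapeutic endoxifen concentrations expected."), "Standard tamoxifen 20 mg/day.")
    },
    CYP2C9 = {
      if (low) strong(paste0(cat, ": greatly reduced S-warfarin clearance; high bleeding risk at standard doses."),
                      "Calculate dose with a validated pharmacogenetic algorithm; decrease calculated dose 20-40%.")
      else if (mid) strong(paste0(cat, ": reduced S-warfarin clearance."),
                           "Calculate dose with a validated pharmacogenetic algorithm including genotype.")
      else strong(paste0(cat, ": normal S-warfarin clearance."),
                  "Dose per validated clinical algorithm.")
    },
    CYP2B6 = {
      if (low) strong(paste0(cat, ": markedly higher efavirenz exposure; increased CNS adverse events."),
                      "Initiate efavirenz at decreased dose (400 mg/day) with monitoring.")
      else if (mid) mod(paste0(cat, ": higher efavirenz exposure."),
                        "Initiate standard dosing; consider dose reduction if adverse events occur.")
      else strong(paste0(cat, ": normal efavirenz metabolism."), "Standard 600 mg/day efavirenz dosing.")
    },
    CYP3A5 = {
      if (grepl("expresser\\)$", cat) && grepl("Normal", cat))
        strong(paste0(cat, ": rapid tacrolimus clearance; subtherapeutic troughs at standard doses."),
               "Increase starting dose to 1.5-2x standard with therapeutic drug monitoring.")
      else if (mid) strong(paste0(cat, ": increased tacrolimus clearance."),
                           "Increase starting dose to 1.5-2x standard with therapeutic drug monitoring.")
      else strong(paste0(cat, ": standard tacrolimus clearance."),
                  "Standard starting dose with therapeutic drug monitoring.")
    },
    CYP4F2 = {
      if (mid) mod(paste0(cat, ": reduced vitamin K1 oxidation; higher warfarin dose requirement."),
                   "Consider a 5-10% increase in calculated warfarin dose.")
      else none(paste0(cat, ": no effect on warfarin dose requirement expected."),
                "No genotype-driven adjustment.")
    },
    DPYD = {
      if (low) strong(paste0(cat, ": complete DPD deficiency; risk of severe or fatal fluoropyrimidine toxicity."),
                      "Avoid 5-fluorouracil and capecitabine.")
      else if (mid) strong(paste0(cat, ": partial DPD deficiency; increased risk of severe toxicity."),
                           "Reduce starting dose by 50% followed by titration based on toxicity.")
      else strong(paste0(cat, ": normal DPD activity."), "Standard fluoropyrimidine dosing.")
    },
    IL28B = {
      if (grepl("Unfavorable", cat))
        mod(paste0(cat, ": reduced likelihood of sustained virologic response to PEG interferon-alpha-based regimens."),
            "Consider regimens with higher response rates; weigh genotype with other predictors.")
      else mod(paste0(cat, ": favorable likelihood of sustained virologic response."),
               "Standard PEG interferon-alpha-based regimen.")
    },
    NUDT15 = {
      if (low) strong(paste0(cat, ": severely reduced thiopurine tolerance; risk of life-threatening myelosuppression."),
                      "Reduce thiopurine dose to 10% of standard or use an alternative agent.")
      else if (mid) strong(paste0(cat, ": reduced thiopurine tolerance."),
                           "Start at 30-80% of standard thiopurine dose; titrate by myelosuppression.")
      else strong(paste0(cat, ": normal thiopurine tolerance."), "Standard thiopurine dosing.")
    },
    TPMT = {
      if (low) strong(paste0(cat, ": minimal TPMT activity; risk of life-threatening myelosuppression."),
                      "Reduce thiopurine dose to 10% of standard given thrice weekly, or use an alternative agent.")
      else if (mid) strong(paste0(cat, ": reduced TPMT activity."),
                           "Start at 30-80% of standard thiopurine dose; titrate by myelosuppression.")
      else strong(paste0(cat, ": normal TPMT activity."), "Standard thiopurine dosing.")
    },
    SLCO1B1 = {
      if (grepl("Poor", cat)) strong(paste0(cat, ": markedly increased simvastatin exposure; high myopathy risk."),
                                     "Prescribe an alternative statin (e.g. rosuvastatin or pravastatin).")
      else if (mid) strong(paste0(cat, ": increased simvastatin exposure; increased myopathy risk."),
                           "Limit simvastatin to 20 mg/day or prescribe an alternative statin.")
      else strong(paste0(cat, ": normal simvastatin transport."), "Standard simvastatin dosing.")
    },
    COMT = {
      if (grepl("Reduced", cat)) opt(paste0(cat, ": altered catecholamine inactivation; possibly increased opioid analgesic sensitivity."),
                                     "No routine adjustment; evidence optional, consider in refractory pain management.")
      else opt(paste0(cat, ": normal catecholamine inactivation."), "No genotype-driven adjustment.")
    },
    VKORC1 = {
      if (grepl("High", cat)) strong(paste0(cat, ": greatly reduced VKORC1 expression; low warfarin dose requirement."),
                                     "Calculate dose with a validated pharmacogenetic algorithm; expect substantially lower maintenance dose.")
      else if (grepl("Increased", cat)) strong(paste0(cat, ": reduced VKORC1 expression; lower warfarin dose requirement."),
                                               "Calculate dose with a validated pharmacogenetic algorithm including genotype.")
      else strong(paste0(cat, ": typical warfarin dose requirement."), "Dose per validated clinical algorithm.")
    }
  )
}

blank_row <- function() {
  r <- as.list(stats::setNames(rep("", 21), c(
    "record_type", "gene", "drug", "genotype_alias", "genotype_code",
    "star_name", "rsid", "chrom", "pos_grch37", "pos_grch38", "ref", "alt",
    "cdna", "aa_change", "activity_value", "function_label", "tier",
    "variants_result", "interpretation", "dosing_recommendation", "references")))
  r
}

rows <- list()
for (g in genes) {
  gv <- variants[variants$gene == g, , drop = FALSE]
  stars <- unique(gv$star)
  # reference allele row (empty defining set)
  r <- blank_row()
  r$record_type <- "allele"; r$gene <- g; r$star_name <- "*1"
  r$activity_value <- if (g == "CYP2D6") "1" else ""
  r$function_label <- "normal function"; r$tier <- "1"
  rows[[length(rows) + 1L]] <- r
  for (i in seq_len(nrow(gv))) {
    r <- blank_row()
    r$record_type <- "allele"; r$gene <- g; r$star_name <- gv$star[i]
    r$rsid <- gv$rsid[i]; r$chrom <- gv$chrom[i]
    r$pos_grch37 <- as.character(gv$pos_grch37[i])
    r$pos_grch38 <- as.character(gv$pos_grch38[i])
    r$ref <- gv$ref[i]; r$alt <- gv$alt[i]
    r$cdna <- gv$cdna[i]; r$aa_change <- gv$aa[i]
    r$activity_value <- if (is.na(gv$activity[i])) "" else format(gv$activity[i])
    r$function_label <- gv$fn[i]; r$tier <- as.character(gv$tier[i])
    rows[[length(rows) + 1L]] <- r
  }
  # diplotype rows: all unordered pairs over the gene's alleles, per drug
  all_stars <- c("*1", stars[!duplicated(stars)])
  all_stars <- unique(all_stars)
  pairs <- list()
  for (i in seq_along(all_stars)) for (j in i:length(all_stars)) {
    pairs[[length(pairs) + 1L]] <- sort2(all_stars[i], all_stars[j])
  }
  for (drug in drugs[[g]]) {
    for (p in pairs) {
      alias <- paste(p, collapse = "/")
      cat_ <- category_of(g, p[1], p[2])
      it <- interp_of(g, drug, cat_)
      r <- blank_row()
      r$record_type <- "diplotype"; r$gene <- g; r$drug <- drug
      r$genotype_alias <- alias
      r$genotype_code <- paste0(g, "-", gsub("[*/]", "", gsub("/", "x", alias)))
      r$variants_result <- cat_
      r$interpretation <- paste0("[", it$strength, "] ", it$body)
      r$dosing_recommendation <- it$dosing
      r$references <- refs[[g]]
      rows[[length(rows) + 1L]] <- r
    }
  }
}

tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
out <- "inst/extdata/pgx_catalog.tsv"
con <- file(out, open = "wb")
writeLines("# catalog_version: 2024.1", con)
write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
close(con)
cat("wrote", out, ":", nrow(tab), "rows,",
    sum(tab$record_type == "allele"), "allele rows,",
    sum(tab$record_type == "diplotype"), "diplotype rows\n")
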