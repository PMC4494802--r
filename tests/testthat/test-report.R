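smallModel <- function(full = TRUE) {
  sim <- simulateReference(simulationConfig(nGenes = 600, nTumor = 8,
                                            nNormal = 6, seed = 61))
  ref <- buildFrozenReference(sim$counts, sim$sampleGroup)
  mu <- normalMeans(ref)
  spikes <- pickSpikes(mu[mu > 0], simulationConfig(nSpikes = 10),
                       seed = 62)
  pat <- simulatePatient(mu, normalDispersions(ref), spikes, seed = 63)
  prof <- buildPatientProfile("pt1", pat$counts, ref)
  de <- callDE(prof, ref)
  if (!full)
    return(buildReportModel(prof, ref, de,
                            thresholds = list(alpha = 0.05),
                            seeds = list(pathway_seed = 1)))
  dir <- tempfile("clin")
  spec <- makeAnnotationTables(dir)
  bundle <- readAnnotationBundle(file.path(dir, "annotation_bundle"))
  variants <- filterVariants(readVariants(file.path(dir, "patient.vcf")),
                             bundle)
  ann <- annotateVariants(variants[variants$retained, ], bundle)
  fus <- ingestFusions(file.path(dir, "fusions.tsv"))
  pwGenes <- spikes$gene[spikes$lfc > 0][1:5]
  pw <- pathwayTopology("PWX", data.frame(
    source_gene = pwGenes[1], target_gene = pwGenes[2:5],
    interaction = "activation", stringsAsFactors = FALSE))
  pwRes <- analyzePathways(list(pw), de, reliableGenes(prof), seed = 9)
  drugTab <- readDrugTable(file.path(dir, "drugs.tsv"))
  matches <- rbind(
    matchExpressionDrugs(de, drugTab),
    matchVariantDrugs(variants[variants$retained, ],
                      bundle$clinical_tables$drug_variant_rules),
    matchPathwayDrugs(pwRes, drugTab))
  unlink(dir, recursive = TRUE)
  buildReportModel(prof, ref, de,
                   predictions = NULL, pathways = pwRes,
                   variants = variants, annotations = ann, fusions = fus,
                   drugs = consolidateDrugMatches(matches),
                   thresholds = list(alpha = 0.05, lfc_min = 1,
                                     bg_quantile = 0.95,
                                     maf_threshold = 0.1),
                   seeds = list(pathway_seed = 9))
}

test_that("mismatched patient identifiers are an integration error", {
  m <- smallModel(full = FALSE)
  expect_identical(m@patient$patient_id, "pt1")
  sim <- simulateReference(simulationConfig(nGenes = 300, nTumor = 4,
                                            nNormal = 4, seed = 64))
  ref <- buildFrozenReference(sim$counts, sim$sampleGroup)
  prof <- buildPatientProfile(
    "pt1", simulatePatient(normalMeans(ref), normalDispersions(ref),
                           seed = 65)$counts, ref)
  expect_error(buildReportModel(prof, ref, callDE(prof, ref),
                                patientMeta = list(patient_id = "other"),
                                thresholds = list(), seeds = list()),
               "mismatch")
})

test_that("missing sections render as explicit not-run blocks", {
  m <- smallModel(full = FALSE)
  dir <- withr::local_tempdir()
  renderReport(m, dir)
  html <- paste(readLines(file.path(dir, "report.html")), collapse = "\n")
  expect_match(html, "Variants</h2>\\s*<p class=\"notrun\">not run")
  expect_match(html, "Drug candidates</h2>\\s*<p class=\"notrun\">not run")
  expect_match(html, "Differential expression</h2>(?!\\s*<p class=\"notrun\")",
               perl = TRUE)
  expect_false(file.exists(file.path(dir, "tables", "variants.csv")))
})

test_that("rendered CSVs re-parse to the report model tables", {
  m <- smallModel()
  dir <- withr::local_tempdir()
  renderReport(m, dir)
  expect_true(file.exists(file.path(dir, "report.html")))
  expect_true(file.exists(file.path(dir, "report_model.json")))
  de <- utils::read.csv(file.path(dir, "tables",
                                  "differential_expression.csv"),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(de), nrow(m@deTable))
  expect_equal(de$p_value, m@deTable$p_value, tolerance = 1e-12)
  expect_identical(de$gene, m@deTable$gene)
  vr <- utils::read.csv(file.path(dir, "tables", "variants.csv"),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(vr), nrow(m@variants$table))
  dr <- utils::read.csv(file.path(dir, "tables", "drug_candidates.csv"),
                        stringsAsFactors = FALSE)
  expect_identical(dr$drug_id, m@drugs$table$drug_id)
  # rendering is deterministic: byte-identical CSVs on a second pass
  dir2 <- withr::local_tempdir()
  renderReport(m, dir2)
  for (f in list.files(file.path(dir, "tables"))) {
    expect_identical(readLines(file.path(dir, "tables", f)),
                     readLines(file.path(dir2, "tables", f)))
  }
})

test_that("the clinical summary lists drugs in rank order with provenance", {
  m <- smallModel()
  dir <- withr::local_tempdir()
  renderSummary(m, file.path(dir, "summary.html"))
  html <- paste(readLines(file.path(dir, "summary.html")),
                collapse = "\n")
  expect_match(html, "Recommended approved drugs")
  if (nrow(m@drugs$table)) {
    first <- m@drugs$table$drug_name[1]
    expect_match(html, first, fixed = TRUE)
  }
  expect_match(html, "pathway_seed")
  expect_match(html, "maf_threshold")
  # a model with no matches states the absence explicitly
  m2 <- smallModel(full = FALSE)
  m2@drugs <- consolidateDrugMatches(NULL)
  renderSummary(m2, file.path(dir, "summary2.html"))
  expect_match(paste(readLines(file.path(dir, "summary2.html")),
                     collapse = "\n"), "no actionable findings")
})
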