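toyDE <- function() {
  data.frame(gene = c("ERBB2", "ESR1", "NR3C1", "PTEN", "EGFR", "MKI67"),
             log2_fold_change = c(3, 2.5, -3, -2.8, 1.6, 0.2),
             significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
             direction = c("up", "up", "down", "down", "up", "none"),
             stringsAsFactors = FALSE)
}

drugFixture <- function() {
  readDrugTable(data.frame(
    drug_id = c("DB001", "DB002", "DB003", "DB004", "DB005", "DB006"),
    name = c("Trastuzumab", "Tamoxifen", "Dexamethasone", "Alpelisib",
             "Investigationib", "Modulatorix"),
    approved = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    targets = c("ERBB2:antibody", "ESR1:antagonist", "NR3C1:agonist",
                "PTEN:inhibitor", "ERBB2:antibody", "PTEN:other"),
    pathway_ids = c("PW1,PW2", "", "", "", "PW1", ""),
    stringsAsFactors = FALSE))
}

test_that("expression matching follows the action/direction rule table", {
  m <- matchExpressionDrugs(toyDE(), drugFixture())
  # antibody/antagonist on up genes and agonist on down genes match;
  # inhibitor on a down gene does not; "other" matches either direction
  expect_setequal(m$drug_id, c("DB001", "DB002", "DB003", "DB006"))
  expect_false("DB004" %in% m$drug_id)        # inhibitor vs down: no
  expect_false("DB005" %in% m$drug_id)        # not approved
  expect_identical(m$direction_concordant[m$drug_id == "DB006"],
                   "not-applicable")
  expect_true(all(m$direction_concordant[m$drug_id %in%
                                           c("DB001", "DB002",
                                             "DB003")] == "yes"))
  # without the concordance requirement the inhibitor/down pair appears
  mAll <- matchExpressionDrugs(toyDE(), drugFixture(),
                               requireConcordance = FALSE)
  expect_true("DB004" %in% mAll$drug_id)
  expect_identical(mAll$direction_concordant[mAll$drug_id == "DB004"],
                   "no")
  expect_equal(nrow(matchExpressionDrugs(toyDE()[0, ], drugFixture())), 0)
})

test_that("variant matching joins rules on the exact key", {
  vars <- data.frame(key = c("7:55259515:T:G", "13:32914438:T:C"),
                     stringsAsFactors = FALSE)
  rules <- data.frame(chrom = c("7", "17"), pos = c(55259515L, 7577120L),
                      ref = c("T", "C"), alt = c("G", "T"),
                      drug_id = c("DB010", "DB011"),
                      drug_name = c("Afatinib", "Adavosertib"),
                      stringsAsFactors = FALSE)
  m <- matchVariantDrugs(vars, rules)
  expect_equal(nrow(m), 1)
  expect_identical(m$drug_id, "DB010")
  expect_identical(m$matched_entity, "7:55259515:T:G")
  # a rule pointing at a filtered-out variant finds nothing
  expect_equal(nrow(matchVariantDrugs(vars[2, , drop = FALSE], rules)), 0)
  expect_equal(nrow(matchVariantDrugs(vars, NULL)), 0)
})

test_that("pathway matching uses significant pathways only", {
  pw <- data.frame(pathway_id = c("PW1", "PW2", "PW3"),
                   pG_fdr = c(0.01, 0.03, 0.4), stringsAsFactors = FALSE)
  m <- matchPathwayDrugs(pw, drugFixture())
  # DB001 sits on both significant pathways: one match per pathway
  expect_equal(sum(m$drug_id == "DB001"), 2)
  expect_false("DB005" %in% m$drug_id)  # unapproved never matches
  none <- matchPathwayDrugs(pw[pw$pathway_id == "PW3", ], drugFixture())
  expect_equal(nrow(none), 0)
})

test_that("consolidation ranks by evidence breadth with a total order", {
  de <- toyDE()
  drugs <- drugFixture()
  matches <- rbind(
    matchExpressionDrugs(de, drugs),
    matchPathwayDrugs(data.frame(pathway_id = "PW1", pG_fdr = 0.001,
                                 stringsAsFactors = FALSE), drugs))
  cons <- consolidateDrugMatches(matches)
  tab <- cons$table
  # DB001 has expression + pathway evidence and must outrank all others
  expect_identical(tab$drug_id[1], "DB001")
  expect_equal(tab$n_evidence_types[1], 2)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_false(any(duplicated(tab$drug_id)))
  # single-evidence drugs tie on counts and resolve alphabetically
  singles <- tab$drug_name[tab$n_evidence_types == 1]
  expect_identical(singles, sort(singles))
  # every evidence row cites exactly one entity
  expect_true(all(nzchar(cons$evidence$matched_entity)))
  empty <- consolidateDrugMatches(NULL)
  expect_equal(nrow(empty$table), 0)
})
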