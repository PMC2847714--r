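test_that("recapitulation classifies recovered, missed and novel exactly", {
  suite <- generate_suite(generator_params(seed = 5))
  gt <- suite$ground_truth
  rec <- recapitulate(suite$documents$phenotype, suite$xp_defs,
                      suite$documents[c("quality", "entity")])
  expect_equal(rec$recall_all, gt$recall_all)
  expect_equal(rec$recall_defined, gt$recall_defined)
  expect_identical(pair_set(rec$novel), pair_set(gt$withheld))
  expect_identical(pair_set(rec$missed), pair_set(gt$unsupported))
  # partition invariants
  expect_equal(nrow(rec$recovered) + nrow(rec$missed), rec$n_asserted)
  expect_length(intersect(pair_set(rec$recovered), pair_set(rec$missed)), 0)
  expect_length(intersect(pair_set(rec$novel),
                          pair_set(phenoxp:::doc_asserted_edges(
                            suite$documents$phenotype))), 0)
  expect_true(rec$recall_all <= rec$recall_defined)
  g <- glance(rec)
  expect_equal(g$recall_all, gt$recall_all)
  expect_equal(nrow(tidy(rec)),
               nrow(rec$recovered) + nrow(rec$missed) + nrow(rec$novel))
})

test_that("recapitulation is reproducible and edge cases behave", {
  suite <- generate_suite(generator_params(seed = 9))
  args <- list(suite$documents$phenotype, suite$xp_defs,
               suite$documents[c("quality", "entity")])
  r1 <- do.call(recapitulate, args)
  r2 <- do.call(recapitulate, args)
  expect_identical(glance(r1), glance(r2))
  expect_identical(tidy(r1), tidy(r2))

  # no definitions: nothing recovered
  empty_defs <- obo_document("empty-xp", header = "format-version: 1.2")
  r0 <- recapitulate(suite$documents$phenotype, empty_defs,
                     suite$documents[c("quality", "entity")])
  expect_equal(nrow(r0$recovered), 0)
  expect_equal(r0$recall_all, 0)

  expect_error(
    recapitulate(obo_document("x", header = "format-version: 1.2"),
                 empty_defs),
    class = "phenoxp_empty_report")
})

test_that("the degeneration link moves between novel and recovered", {
  withheld <- build_paper_fixture(withhold_fig2_link = TRUE)
  support <- list(withheld$mini_pato, withheld$mini_cl, withheld$mini_ma,
                  withheld$mini_go, withheld$mini_chebi)
  rec_w <- recapitulate(withheld$mini_mp, withheld$xp_defs, support)
  expect_true("MP:9000012 MP:9000011" %in% pair_set(rec_w$novel))

  full <- build_paper_fixture()
  rec_f <- recapitulate(full$mini_mp, full$xp_defs, support)
  expect_true("MP:9000012 MP:9000011" %in% pair_set(rec_f$recovered))
  expect_false("MP:9000012 MP:9000011" %in% pair_set(rec_f$novel))
})

test_that("curation reports round-trip and recover verdict counts", {
  suite <- generate_suite(generator_params(seed = 12, withheld_links = 3))
  rec <- recapitulate(suite$documents$phenotype, suite$xp_defs,
                      suite$documents[c("quality", "entity")])
  path <- withr::local_tempfile(fileext = ".tsv")
  report <- missing_link_report(rec, "GP", path, provenance = "seed 12")
  expect_equal(nrow(report), 3)
  expect_true(all(report$verdict == "pending"))

  # curator triage: edit verdicts, re-read, count by category
  triaged <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  triaged$verdict <- c("accepted", "rejected", "partially-correct")
  readr::write_tsv(triaged, path)
  back <- read_curation_file(path)
  expect_equal(sort(back$verdicts$verdict),
               c("accepted", "partially-correct", "rejected"))
  expect_equal(back$verdicts$n, c(1, 1, 1))
})

test_that("an empty novel set writes a header-only report", {
  fx <- build_paper_fixture()
  cl <- compute_closure(fixture_merged(fx))
  path <- withr::local_tempfile(fileext = ".tsv")
  report <- missing_link_report(cl, "MP", path)
  expect_equal(nrow(report), 0)
  lines <- readLines(path)
  expect_equal(lines[1], paste("subject_id", "subject_label", "object_id",
                               "object_label", "rule_chain", "verdict",
                               "note", sep = "\t"))
  expect_length(lines, 1)
})

test_that("the snout/face case lints, then heals once the part_of link exists", {
  broken <- build_paper_fixture(snout_part_of_face = FALSE)$snout_case
  findings <- consistency_lint(broken$phenotype, broken$xp_defs,
                               broken$support)
  expect_equal(findings$type, "missing-path")
  expect_equal(findings$filler_subject, "MA:0002445")
  expect_equal(findings$filler_object, "MA:0002446")

  fixed <- build_paper_fixture(snout_part_of_face = TRUE)$snout_case
  expect_equal(nrow(consistency_lint(fixed$phenotype, fixed$xp_defs,
                                     fixed$support)), 0)
  rec <- recapitulate(fixed$phenotype, fixed$xp_defs, fixed$support,
                      rule_config(quality_propagates_over_part_of = TRUE))
  expect_true("MP:9000020 MP:9000021" %in% pair_set(rec$recovered))
})

test_that("the delta-cell case yields a missing-counterpart finding", {
  dc <- build_paper_fixture()$delta_case
  findings <- consistency_lint(dc$phenotype, dc$xp_defs, dc$support)
  expect_equal(findings$type, "missing-counterpart")
  expect_equal(findings$subject, "MP:9000030")
  expect_equal(findings$object, "MP:9000031")
  expect_equal(findings$filler_subject, "CL:0000173")
  expect_equal(findings$filler_object, "CL:0000164")
})

test_that("coverage statistics count defined classes and entity prefixes", {
  fx <- build_paper_fixture()
  cov <- coverage_stats(fx$mini_mp, fx$xp_defs)
  n <- length(fx$mini_mp$stanzas)
  n_def <- sum(names(fx$mini_mp$stanzas) %in% names(fx$xp_defs$stanzas))
  expect_equal(cov$summary$total_classes, n)
  expect_equal(cov$summary$defined, n_def)
  expect_equal(cov$summary$pct, 100 * n_def / n)
  expect_true(all(c("MA", "CL", "GO", "CHEBI") %in% cov$by_prefix$prefix))
  expect_false("PATO" %in% cov$by_prefix$prefix)
  # a definition may touch several ontologies
  expect_gte(sum(cov$by_prefix$n_definitions), n_def)

  # obsolete classes leave the denominator
  with_obs <- fx$mini_mp
  with_obs$stanzas[["MP:9999999"]] <-
    term_stanza("MP:9999999", name = "retired", is_obsolete = TRUE)
  cov2 <- coverage_stats(with_obs, fx$xp_defs)
  expect_equal(cov2$summary$total_classes, n)

  # zero definitions
  cov0 <- coverage_stats(fx$mini_mp,
                         obo_document("none", header = "format-version: 1.2"))
  expect_equal(cov0$summary$defined, 0)
  expect_equal(cov0$summary$pct, 0)
  expect_identical(glance(cov), cov$summary)
})

test_that("recap summaries and plots are produced", {
  suite <- generate_suite(generator_params(seed = 4))
  rec <- recapitulate(suite$documents$phenotype, suite$xp_defs,
                      suite$documents[c("quality", "entity")])
  path <- withr::local_tempfile(fileext = ".txt")
  write_recap_summary(rec, path)
  lines <- readLines(path)
  expect_true(any(grepl("^recall_all=", lines)))
  expect_s3_class(autoplot(rec), "ggplot")
  expect_s3_class(autoplot(coverage_stats(suite$documents$phenotype,
                                          suite$xp_defs)), "ggplot")
})
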