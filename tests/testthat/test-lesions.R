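test_that("lesion tables are validated against the closed vocabularies", {
  df <- data.frame(patient_id = c("p1", "p2", "p3"),
                   timepoint = "diagnosis",
                   allele = c("A*02:01", "DRB1*15:01", "C*07:01"),
                   category = c("missense", "loss", "splicing"),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(read_lesion_table(write_genotype_tsv(df))), 3L)
  bad <- df; bad$category[2] <- "promoter"
  expect_error(read_lesion_table(bad), "row\\(s\\) 2")
  bad2 <- df; bad2$timepoint <- "relapse2"
  expect_error(read_lesion_table(bad2), "unknown timepoint")
  bad3 <- df; bad3$vaf <- c(0.2, 1.4, 0.1)
  expect_error(read_lesion_table(bad3), "vaf")
})

test_that("fixture landscape reproduces the printed marginals", {
  f3 <- fixture_f3()
  tab <- lesion_tabulate(f3$lesions, f3$patients, group_by = "timepoint")
  tab <- tab[match(lesion_timepoints(), tab$group), ]
  expect_equal(tab$n_lesioned, c(9L, 0L, 17L))
  expect_equal(tab$n_assayed[1:2], c(40L, 9L))
  expect_equal(tab$percent[2], 0)       # no hits after chemotherapy relapse
  expect_equal(sum(tab$n_lesioned), 26L)

  post <- f3$patients[f3$patients$timepoint == "post_hct_relapse", ]
  les_post <- f3$lesions[f3$lesions$timepoint == "post_hct_relapse", ]
  don <- lesion_tabulate(les_post, post, group_by = "donor_type")
  don <- don[match(c("MRD", "Haplo", "MUD"), don$group), ]
  expect_equal(don$n_lesioned, c(10L, 2L, 5L))
  expect_equal(don$n_assayed, c(20L, 8L, 17L))
  expect_equal(don$percent, c(50, 25, 29))
  # donor-type numerators partition the overall post-HCT numerator
  expect_equal(sum(don$n_lesioned), tab$n_lesioned[3])

  # DLI: 25 recipients, complete response in 5 (20%)
  expect_equal(sum(post$dli), 25L)
  expect_equal(sum(post$dli_cr), 5L)
  dli <- dli_response_table(f3$patients, f3$lesions)
  expect_equal(sum(dli), 25L)
  expect_equal(sum(dli[, "TRUE"]), 5L)
  expect_equal(dli["exonic_or_loss", "TRUE"], 0L)   # exonic/loss: no CR
  expect_equal(unname(dli["UTR_or_intronic", "FALSE"]), 3L)
})

test_that("tabulation collapses to patient level and ignores row order/duplication", {
  f3 <- fixture_f3()
  # one patient with several lesions contributes once to the numerator
  p4 <- lesion_tabulate(
    f3$lesions[f3$lesions$patient_id == "P04" &
                 f3$lesions$timepoint == "diagnosis", ],
    f3$patients[f3$patients$timepoint == "diagnosis", ])
  expect_equal(p4$n_lesioned, 1L)
  expect_equal(p4$n_mutation_lesions + p4$n_loss_lesions, 2L)
  base <- lesion_tabulate(f3$lesions, f3$patients)
  shuf <- f3$lesions[rev(seq_len(nrow(f3$lesions))), ]
  dup <- rbind(f3$lesions, f3$lesions[1:5, ])
  expect_equal(lesion_tabulate(shuf, f3$patients), base)
  expect_equal(lesion_tabulate(dup, f3$patients), base)
  # lesions for unassayed patients are an error
  orphan <- rbind(f3$lesions,
                  data.frame(patient_id = "P99", timepoint = "diagnosis",
                             allele = "A*02:01", category = "missense"))
  expect_error(lesion_tabulate(orphan, f3$patients), "unassayed")
})

test_that("early/late split is strict at the threshold and ordered as published", {
  f3 <- fixture_f3()
  el <- lesion_early_late(f3$lesions, f3$patients, threshold = 6)
  expect_equal(el$group, c("early", "late"))
  expect_equal(sum(el$n_lesioned), 17L)
  expect_gt(el$percent[2], el$percent[1])   # late relapses more often lesioned
  # a relapse at exactly the threshold is early
  pats <- data.frame(patient_id = c("a", "b"), timepoint = "post_hct_relapse",
                     relapse_time_months = c(6, 6.01))
  les <- data.frame(patient_id = "b", timepoint = "post_hct_relapse",
                    allele = "A*02:01", category = "missense")
  el2 <- lesion_early_late(les, pats)
  expect_equal(el2$n_assayed, c(1L, 1L))
  expect_equal(el2$n_lesioned, c(0L, 1L))
  # all early -> late stratum empty and flagged
  pats$relapse_time_months <- c(1, 2)
  el3 <- lesion_early_late(les, pats)
  expect_true(el3$empty[el3$group == "late"])
  expect_true(is.na(el3$percent[el3$group == "late"]))
  pats$relapse_time_months[1] <- NA
  expect_error(lesion_early_late(les, pats), "missing")
})

test_that("percent rounding is half away from zero", {
  f3 <- fixture_f3()
  post <- f3$patients[f3$patients$timepoint == "post_hct_relapse", ]
  # 17/45 = 37.8 -> 38; and a constructed half case 1/8 = 12.5 -> 13
  tab <- lesion_tabulate(f3$lesions, f3$patients)
  expect_equal(tab$percent[tab$group == "post_hct_relapse"], 38)
  half <- lesion_tabulate(
    data.frame(patient_id = "H1", timepoint = "diagnosis",
               allele = "A*02:01", category = "missense"),
    data.frame(patient_id = paste0("H", 1:8), timepoint = "diagnosis"))
  expect_equal(half$percent, 13)
})

test_that("Fisher enrichment matches exhaustive enumeration and flags degeneracy", {
  # spec toy table (3,1,1,3) plus a scan of all tables with n <= 20
  expect_equal(stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               oracle_fisher(3, 1, 1, 3))
  set.seed(2)
  for (i in 1:25) {
    cells <- stats::rmultinom(1, sample(6:20, 1), rep(0.25, 4))
    expect_equal(
      stats::fisher.test(matrix(cells, 2))$p.value,
      oracle_fisher(cells[1], cells[3], cells[2], cells[4]),
      tolerance = 1e-10)
  }
  pats <- data.frame(patient_id = paste0("p", 1:12),
                     timepoint = "post_hct_relapse")
  les <- data.frame(patient_id = paste0("p", 1:4),
                    timepoint = "post_hct_relapse",
                    allele = "A*02:01", category = "missense")
  my <- data.frame(patient_id = c("p1", "p2", "p3", "p5"),
                   timepoint = "post_hct_relapse",
                   gene = c("RUNX1", "RUNX1", "DNMT3A", "RUNX1"))
  enr <- comutation_enrichment(les, my, pats)
  expect_setequal(enr$gene, c("RUNX1", "DNMT3A"))
  r <- enr[enr$gene == "RUNX1", ]
  expect_equal(r$p_value, oracle_fisher(2, 2, 1, 7))
  expect_equal(r$odds_ratio, (2.5 * 7.5) / (2.5 * 1.5))
  expect_equal(enr$q_value, stats::p.adjust(enr$p_value, "BH"))
  # gene mutated in nobody is degenerate: OR display 1, p = 1, warned
  expect_warning(
    enr2 <- comutation_enrichment(les, my, pats,
                                  genes = c("RUNX1", "EZH2")),
    "degenerate")
  z <- enr2[enr2$gene == "EZH2", ]
  expect_equal(z$odds_ratio, 1)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  # need both altered and wild-type patients
  all_alt <- data.frame(patient_id = paste0("p", 1:12),
                        timepoint = "post_hct_relapse",
                        allele = "A*02:01", category = "missense")
  expect_error(comutation_enrichment(all_alt, my, pats), "wild-type")
})
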