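test_that("single-locus simulation honours boundary frequencies", {
  g0 <- simulate_genotypes(0, 100, rsid = "rs1367117", ref = "G", alt = "A",
                           seed = 1)
  expect_true(all(g0$allele1 == "G" & g0$allele2 == "G"))
  g1 <- simulate_genotypes(1, 100, rsid = "rs1367117", ref = "G", alt = "A",
                           seed = 1)
  expect_true(all(g1$allele1 == "A" & g1$allele2 == "A"))
  expect_error(simulate_genotypes(1.2, 10), "\\[0, 1\\]")
  expect_error(simulate_genotypes(0.5, 0), ">= 1")
})

test_that("large-sample genotype draws match Hardy-Weinberg expectations", {
  n <- 20000L
  p <- 0.25
  g <- simulate_genotypes(p, n, ref = "G", alt = "A", seed = 20)
  dose <- (g$allele1 == "A") + (g$allele2 == "A")
  # allele frequency within 3 binomial SEs
  se_p <- sqrt(p * (1 - p) / (2 * n))
  expect_lt(abs(mean(dose) / 2 - p), 3 * se_p)
  # genotype class proportions within 3 SEs of (0.5625, 0.375, 0.0625)
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  observed <- tabulate(dose + 1, 3) / n
  se_cls <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) < 3 * se_cls))
  # the three genotype classes partition the cohort
  expect_identical(sum(tabulate(dose + 1, 3)), n)
})

test_that("cohort simulation is byte-deterministic in config and seed", {
  cfg <- cohort_config()
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c_ <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("the default cohort reproduces the study structure", {
  coh <- simulate_cohort(cohort_config(), seed = 42)
  ph <- coh$phenotypes
  expect_identical(sum(ph$group == "patient"), 93L)
  expect_identical(sum(ph$group == "comparison"), 61L)
  # genotype and phenotype tables share one sample_id set
  expect_setequal(unique(coh$genotypes$sample_id), ph$sample_id)
  # all 7 SNPs called for every sample
  calls <- table(coh$genotypes$sample_id)
  expect_true(all(calls == 7))
  expect_false(any(is.na(coh$genotypes$allele1)))
  # LDL-C within the configured ranges
  pat <- ph$ldl_c[ph$group == "patient"]
  cmp <- ph$ldl_c[ph$group == "comparison"]
  expect_true(all(pat >= 2.87 & pat <= 6.63))
  expect_true(all(cmp >= 3.19 & cmp <= 9.7))
  # seed recorded in provenance
  expect_identical(coh$provenance$seed, 42L)
})

test_that("simulated APOE genotypes never leave the epsilon system", {
  # the joint haplotype draw enforces no e1; every sample must resolve
  coh <- simulate_cohort(cohort_config(n_patients = 300, n_comparison = 300),
                         seed = 5)
  calls <- call_apoe(coh$genotypes, policy = "strict")
  # strict policy may refuse only the phase-ambiguous double heterozygote
  expect_true(all(calls$apoe %in% c("e2e2", "e2e3", "e2e4", "e3e3",
                                    "e3e4", "e4e4", "unresolved")))
  default_calls <- call_apoe(coh$genotypes, policy = "default")
  expect_false(any(default_calls$apoe == "unresolved"))
})

test_that("carrier-frequency inputs are converted under Hardy-Weinberg", {
  freq <- default_group_frequencies()
  cfg <- cohort_config(freq = freq, freq_kind = "carrier",
                       n_patients = 4000, n_comparison = 2)
  coh <- simulate_cohort(cfg, seed = 31)
  # carrier fraction of rs6511720-T among patients should approach 16.13%
  gt <- dplyr::filter(coh$genotypes, rsid == "rs6511720",
                      startsWith(sample_id, "S"))
  ids <- coh$phenotypes$sample_id[coh$phenotypes$group == "patient"]
  gt <- dplyr::filter(gt, sample_id %in% ids)
  carrier <- mean(gt$allele1 == "T" | gt$allele2 == "T")
  expect_lt(abs(carrier - 0.1613), 3 * sqrt(0.1613 * (1 - 0.1613) / 4000))
})

test_that("the logistic disease model fills quotas and shapes the groups", {
  dm <- list(intercept = -2.5, beta_prs = log(12.044),
             beta_smoking = log(24.962))
  cfg <- cohort_config(n_patients = 250, n_comparison = 250,
                       disease_model = dm)
  coh <- simulate_cohort(cfg, seed = 12)
  ph <- coh$phenotypes
  expect_identical(unname(table(ph$group)["patient"]), 250L)
  scores <- compute_prs(coh$genotypes)
  merged <- dplyr::inner_join(scores, ph, by = "sample_id")
  # cases should carry higher scores and more smokers than controls
  expect_gt(median(merged$prs[merged$group == "patient"]),
            median(merged$prs[merged$group == "comparison"]))
  expect_gt(mean(merged$smoking[merged$group == "patient"]),
            mean(merged$smoking[merged$group == "comparison"]))
})

test_that("an unsatisfiable case quota errors instead of spinning", {
  dm <- list(intercept = -60, beta_prs = 0.1, beta_smoking = 0.1,
             max_draws = 20000)
  cfg <- cohort_config(n_patients = 5, n_comparison = 5, disease_model = dm)
  expect_error(simulate_cohort(cfg, seed = 1), "quota")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), ">= 1")
  bad_freq <- default_group_frequencies()
  bad_freq$patient[1] <- 1.4
  expect_error(cohort_config(freq = bad_freq), "\\[0, 1\\]")
  expect_error(cohort_config(disease_model = list(intercept = 1)),
               "beta_prs")
  expect_error(simulate_cohort(cohort_config()), "seed")
})
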