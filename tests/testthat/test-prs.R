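test_that("the published landmark genotypes score to their printed values", {
  lm <- landmark_genotypes()
  res <- compute_prs(dplyr::select(lm, -expected))
  expect_true(all(res$complete))
  expect_equal(res$prs, lm$expected, tolerance = 1e-12)
})

test_that("an all-zero-dosage genotype with e3e3 scores exactly zero", {
  g <- make_sample("Z", rs629301 = "G/G", rs1367117 = "G/G",
                   rs11220462 = "G/G", rs6511720 = "T/T", rs1800562 = "A/A",
                   rs429358 = "T/T", rs7412 = "C/C")
  expect_identical(compute_prs(g)$prs, 0)
})

test_that("the score equals the sum of its contribution breakdown", {
  lm <- landmark_genotypes()
  g <- dplyr::select(lm, -expected)
  res <- compute_prs(g)
  contrib <- prs_contributions(g)
  sums <- dplyr::summarise(dplyr::group_by(contrib, sample_id),
                           total = sum(contribution))
  merged <- dplyr::left_join(res, sums, by = "sample_id")
  expect_true(all(abs(merged$prs - merged$total) < 1e-12))
})

test_that("raising one locus dosage by one copy adds exactly its weight", {
  panel <- ldl_panel()
  base <- make_sample("B", rs629301 = "G/G", rs1367117 = "G/G",
                      rs11220462 = "G/G", rs6511720 = "T/T",
                      rs1800562 = "A/A", rs429358 = "T/T", rs7412 = "C/C")
  het <- list(rs629301 = "G/T", rs1367117 = "G/A", rs11220462 = "G/A",
              rs6511720 = "G/T", rs1800562 = "G/A")
  s0 <- compute_prs(base, panel)$prs
  for (rs in names(het)) {
    g <- base
    g[[rs]] <- het[[rs]]
    w <- panel$snps$weight[panel$snps$rsid == rs]
    expect_equal(compute_prs(g, panel)$prs - s0, w, tolerance = 1e-12)
  }
})

test_that("sample order does not change any score", {
  coh <- simulate_cohort(cohort_config(n_patients = 15, n_comparison = 10),
                         seed = 11)
  gt <- coh$genotypes
  res1 <- compute_prs(gt)
  shuffled <- gt[withr::with_seed(1, sample(nrow(gt))), ]
  res2 <- compute_prs(shuffled)
  res2 <- res2[match(res1$sample_id, res2$sample_id), ]
  expect_equal(res1$prs, res2$prs)
})

test_that("missing loci produce NA scores with a structured reason", {
  g <- dplyr::bind_rows(
    make_sample("OK", rs629301 = "T/T", rs1367117 = "G/G",
                rs11220462 = "G/G", rs6511720 = "G/G", rs1800562 = "G/G",
                rs429358 = "T/T", rs7412 = "C/C"),
    make_sample("NO7412", rs629301 = "T/T", rs1367117 = "G/G",
                rs11220462 = "G/G", rs6511720 = "G/G", rs1800562 = "G/G",
                rs429358 = "T/T"),
    make_sample("NOHFE", rs629301 = "T/T", rs1367117 = "G/G",
                rs11220462 = "G/G", rs6511720 = "G/G",
                rs429358 = "T/T", rs7412 = "C/C")
  )
  res <- compute_prs(g)
  expect_identical(res$complete, c(TRUE, FALSE, FALSE))
  expect_true(is.na(res$prs[2]) && is.na(res$prs[3]))
  expect_match(res$reason[2], "APOE")
  expect_match(res$reason[3], "rs1800562")
  # partial mode scores the available loci instead
  part <- compute_prs(g, on_missing = "partial")
  expect_false(any(is.na(part$prs)))
  expect_identical(part$complete, c(TRUE, FALSE, FALSE))
  expect_equal(part$prs[3], part$prs[1] - 2 * 0.057, tolerance = 1e-12)
})

test_that("score_cohort scores a full synthetic cohort completely", {
  coh <- simulate_cohort(cohort_config(), seed = 7)
  expect_message(res <- score_cohort(coh$genotypes), "154 sample")
  expect_identical(nrow(res), 154L)
  expect_true(all(res$complete))
  expect_true(all(res$prs >= -0.9 & res$prs <= 1.274))
})
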