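#' Compute the weighted LDL-C SNP score
#'
#' The score of a sample is the weighted sum of risk-allele dosages over
#' the five panel SNPs plus the APOE diplotype weight:
#' `S = sum_i d_i * w_i + w_APOE`. With the built-in panel the attainable
#' range is -0.9 (all-zero dosage with e2e2) to 1.274 (full dosage with
#' e4e4); the published observed extremes -0.62 and 1.174 and the group
#' medians 0.824 and 0.674 are all attainable scores. rs429358 and rs7412
#' are never weighted individually; they enter only through the diplotype.
#'
#' A sample missing any of the seven genotypes (or with an unresolved APOE
#' diplotype) gets an `NA` score by default, with the reason recorded.
#' With `on_missing = "partial"` the available loci are summed instead and
#' the score is flagged incomplete.
#'
#' @param genotypes Genotype tibble (long or wide; see [as_genotypes()]).
#' @param panel A `prs_panel`.
#' @param apoe_policy Passed to [call_apoe()]: `"default"` or `"strict"`.
#' @param on_missing `"na"` (default) or `"partial"`.
#' @return A tibble with one row per sample, in input order: `sample_id`,
#'   `prs`, `complete`, `apoe`, one `dosage_<rsid>` column per panel SNP,
#'   and `reason` (`NA` for complete scores).
#' @examples
#' g <- data.frame(
#'   sample_id = "S1",
#'   rs629301 = "T/T", rs1367117 = "G/A", rs11220462 = "A/A",
#'   rs6511720 = "G/G", rs1800562 = "G/G",
#'   rs429358 = "C/C", rs7412 = "C/C"
#' )
#' compute_prs(g)$prs  # 1.174
#' @export
compute_prs <- function(genotypes, panel = ldl_panel(),
                        apoe_policy = c("default", "strict"),
                        on_missing = c("na", "partial")) {
  apoe_policy <- match.arg(apoe_policy)
  on_missing <- match.arg(on_missing)
  gt <- validate_genotypes(genotypes, panel)
  samples <- unique(gt$sample_id)
  ns <- length(samples)

  rsids <- panel$snps$rsid
  w <- panel$snps$weight
  D <- matrix(NA_integer_, nrow = ns, ncol = length(rsids),
              dimnames = list(samples, rsids))
  for (j in seq_along(rsids)) {
    s <- gt[gt$rsid == rsids[j], ]
    risk <- panel$snps$risk_allele[j]
    d <- (s$allele1 == risk) + (s$allele2 == risk)
    D[match(s$sample_id, samples), j] <- as.integer(d)
  }

  apoe <- .apoe_calls(gt, policy = apoe_policy)
  apoe <- apoe$apoe[match(samples, apoe$sample_id)]
  w_apoe <- panel$apoe_weights$weight[
    match(apoe, panel$apoe_weights$diplotype)]

  complete <- unname(!apply(is.na(D), 1, any) & apoe != "unresolved")
  if (on_missing == "na") {
    prs <- ifelse(complete, drop(ifelse(is.na(D), 0L, D) %*% w) + w_apoe,
                  NA_real_)
  } else {
    prs <- drop(ifelse(is.na(D), 0L, D) %*% w) +
      ifelse(apoe == "unresolved", 0, w_apoe)
  }
  prs <- unname(prs)

  reason <- rep(NA_character_, ns)
  for (i in which(!complete)) {
    missing_loci <- rsids[is.na(D[i, ])]
    bits <- c(
      if (length(missing_loci) > 0)
        sprintf("missing genotype at %s", paste(missing_loci, collapse = ", ")),
      if (apoe[i] == "unresolved") "APOE diplotype unresolved"
    )
    reason[i] <- paste(bits, collapse = "; ")
  }

  out <- tibble(sample_id = samples, prs = prs, complete = complete,
                apoe = apoe)
  for (j in seq_along(rsids)) out[[paste0("dosage_", rsids[j])]] <- D[, j]
  out$reason <- reason
  out
}

#' Per-locus contribution breakdown of the score
#'
#' @inheritParams compute_prs
#' @return A tibble with one row per sample x locus: `sample_id`, `locus`
#'   (rsid or `"APOE"`), `dosage` (`NA` for the APOE row), `diplotype`
#'   (`NA` for SNP rows), `weight` and `contribution`. Summing
#'   `contribution` within a sample recovers its score.
#' @export
prs_contributions <- function(genotypes, panel = ldl_panel(),
                              apoe_policy = c("default", "strict")) {
  apoe_policy <- match.arg(apoe_policy)
  res <- compute_prs(genotypes, panel, apoe_policy, on_missing = "partial")
  snp <- tidyr::pivot_longer(
    select(res, "sample_id", dplyr::starts_with("dosage_")),
    cols = -"sample_id", names_to = "locus", names_prefix = "dosage_",
    values_to = "dosage"
  )
  snp <- left_join(snp, select(panel$snps, locus = "rsid", "weight"),
                   by = "locus")
  snp <- mutate(snp, diplotype = NA_character_,
                contribution = .data$dosage * .data$weight)
  ap <- select(res, "sample_id", diplotype = "apoe")
  ap <- left_join(ap, panel$apoe_weights, by = "diplotype")
  ap <- mutate(ap, locus = "APOE", dosage = NA_integer_,
               contribution = .data$weight)
  bind_rows(snp, ap) |>
    select("sample_id", "locus", "dosage", "diplotype", "weight",
           "contribution") |>
    arrange(match(.data$sample_id, unique(res$sample_id)))
}

#' Score a cohort of samples
#'
#' Convenience wrapper around [compute_prs()] that accepts a genotype file
#' path (VCF or wide TSV, dispatched by [read_genotypes()]) or an
#' in-memory genotype table, and logs a one-line summary of how many
#' samples scored complete, partial and missing.
#'
#' @param x Path to a genotype file, or a genotype data frame.
#' @inheritParams compute_prs
#' @param format Passed to [read_genotypes()] when `x` is a path.
#' @return The [compute_prs()] tibble.
#' @export
score_cohort <- function(x, panel = ldl_panel(),
                         apoe_policy = c("default", "strict"),
                         on_missing = c("na", "partial"),
                         format = c("auto", "vcf", "tsv")) {
  if (is.character(x) && length(x) == 1) {
    x <- read_genotypes(x, format = match.arg(format), panel = panel)
  }
  res <- compute_prs(x, panel, apoe_policy, on_missing)
  n_complete <- sum(res$complete)
  n_scored <- sum(!is.na(res$prs))
  inform(sprintf(
    "scored %d sample(s): %d complete, %d partial, %d missing",
    nrow(res), n_complete, n_scored - n_complete, nrow(res) - n_scored
  ))
  res
}
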