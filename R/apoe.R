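#' Call APOE epsilon diplotypes from rs429358 and rs7412
#'
#' The two APOE coding SNPs jointly define three haplotypes:
#' e2 = (rs429358-T, rs7412-T), e3 = (T, C), e4 = (C, C). The fourth
#' combination (C, T), sometimes labelled e1, is vanishingly rare and lies
#' outside this three-allele system. Given unphased calls at the two sites,
#' the diplotype is the unordered pair of haplotypes consistent with both
#' genotypes.
#'
#' Eight of the nine genotype combinations resolve without phase
#' information (or are impossible within the e2/e3/e4 system and raise an
#' error). The doubly heterozygous combination (T/C at rs429358 with C/T at
#' rs7412) is consistent with e2e4 or with the e1-bearing pair e1e3;
#' under `policy = "default"` it is called e2e4 (the conventional call,
#' since e1 is essentially absent from populations), under
#' `policy = "strict"` it is returned as `"unresolved"`. A missing genotype
#' at either site always yields `"unresolved"`.
#'
#' @param genotypes Genotype tibble containing calls at rs429358 and rs7412
#'   (other rsids are ignored). Accepts long or wide layout.
#' @param policy `"default"` (phase-ambiguous double heterozygote called
#'   e2e4) or `"strict"` (returned unresolved).
#' @param panel A `prs_panel` supplying the APOE allele sets.
#' @return A tibble `sample_id`, `apoe` with `apoe` one of `"e2e2"`,
#'   `"e2e3"`, `"e2e4"`, `"e3e3"`, `"e3e4"`, `"e4e4"`, `"unresolved"`.
#' @examples
#' g <- data.frame(sample_id = "S1", rs429358 = "T/T", rs7412 = "C/C")
#' call_apoe(g)  # e3e3
#' @export
call_apoe <- function(genotypes, policy = c("default", "strict"),
                      panel = ldl_panel()) {
  policy <- match.arg(policy)
  gt <- validate_genotypes(genotypes, panel)
  .apoe_calls(gt, policy)
}

# assumes a validated long genotype tibble
.apoe_calls <- function(gt, policy = "default") {
  samples <- unique(gt$sample_id)
  site <- function(rs) {
    s <- filter(gt, .data$rsid == rs)
    s[match(samples, s$sample_id), c("allele1", "allele2")]
  }
  g1 <- site("rs429358")
  g2 <- site("rs7412")
  # only 9 unphased genotype combinations exist: resolve each once
  key <- paste(pmin(g1$allele1, g1$allele2), pmax(g1$allele1, g1$allele2),
               pmin(g2$allele1, g2$allele2), pmax(g2$allele1, g2$allele2))
  calls <- character(length(samples))
  for (k in unique(key)) {
    i <- which(key == k)[1]
    calls[key == k] <- apoe_diplotype_one(
      g1$allele1[i], g1$allele2[i], g2$allele1[i], g2$allele2[i],
      policy = policy, sample_id = samples[i]
    )
  }
  tibble(sample_id = samples, apoe = calls)
}

# haplotype (rs429358 allele, rs7412 allele) -> epsilon label
apoe_haplotype <- function(a429358, a7412) {
  dplyr::case_when(
    a429358 == "T" & a7412 == "T" ~ "e2",
    a429358 == "T" & a7412 == "C" ~ "e3",
    a429358 == "C" & a7412 == "C" ~ "e4",
    a429358 == "C" & a7412 == "T" ~ "e1"
  )
}

apoe_diplotype_one <- function(a1, a2, b1, b2, policy = "default",
                               sample_id = "?") {
  if (is.na(a1) || is.na(b1)) return("unresolved")
  # the two possible phasings of the unphased pair of genotypes
  phasings <- list(
    sort(c(apoe_haplotype(a1, b1), apoe_haplotype(a2, b2))),
    sort(c(apoe_haplotype(a1, b2), apoe_haplotype(a2, b1)))
  )
  labels <- unique(vapply(phasings, paste, "", collapse = ""))
  valid <- labels[!grepl("e1", labels)]
  e1_possible <- any(grepl("e1", labels))
  if (length(valid) == 0) {
    abort(sprintf(
      "sample %s: genotype rs429358 %s/%s, rs7412 %s/%s implies diplotype outside the e2/e3/e4 system",
      sample_id, a1, a2, b1, b2
    ))
  }
  if (e1_possible && policy == "strict") return("unresolved")
  # within the no-e1 system the call is unique
  valid[1]
}
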