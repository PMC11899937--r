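#' Tidy genotype tables
#'
#' Genotypes travel through the package as a long tibble with one row per
#' sample x locus and columns `sample_id`, `rsid`, `allele1`, `allele2`.
#' Calls are unphased; allele order carries no meaning. A missing genotype
#' has both alleles `NA` (half-calls are rejected). `as_genotypes()` accepts
#' either that long layout or the wide TSV layout (`sample_id` plus one
#' `"X/Y"` column per rsid; `"./."`, `"."`, `""` and `NA` denote missing).
#'
#' @param x A data frame in long or wide genotype layout.
#' @return A long genotype tibble.
#' @examples
#' wide <- data.frame(sample_id = "S1", rs629301 = "T/T", rs7412 = "C/C")
#' as_genotypes(wide)
#' @export
as_genotypes <- function(x) {
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("genotype input must have a 'sample_id' column")
  }
  long <- all(c("rsid", "allele1", "allele2") %in% names(x))
  if (long) {
    out <- select(x, "sample_id", "rsid", "allele1", "allele2")
  } else {
    rs_cols <- setdiff(names(x), "sample_id")
    if (length(rs_cols) == 0) abort("no genotype columns found")
    out <- tidyr::pivot_longer(x, cols = dplyr::all_of(rs_cols),
                               names_to = "rsid", values_to = "gt")
    parsed <- parse_gt_strings(out$gt, context = out)
    out <- bind_cols(select(out, "sample_id", "rsid"), parsed)
  }
  out <- mutate(out,
    sample_id = as.character(.data$sample_id),
    rsid = as.character(.data$rsid),
    allele1 = toupper(as.character(.data$allele1)),
    allele2 = toupper(as.character(.data$allele2))
  )
  half <- is.na(out$allele1) != is.na(out$allele2)
  if (any(half)) {
    abort(sprintf(
      "half-called genotypes (one allele missing) for: %s",
      paste(sprintf("%s@%s", out$sample_id[half], out$rsid[half])[
        seq_len(min(5, sum(half)))], collapse = ", ")
    ))
  }
  dup <- duplicated(out[, c("sample_id", "rsid")])
  if (any(dup)) {
    abort(sprintf(
      "more than one call per sample and rsid: %s",
      paste(unique(sprintf("%s@%s", out$sample_id[dup], out$rsid[dup])),
            collapse = ", ")
    ))
  }
  out
}

# "X/Y" or "X|Y" -> two allele columns; "./.", ".", "" -> missing
parse_gt_strings <- function(gt, context = NULL) {
  gt <- as.character(gt)
  gt[gt %in% c("", ".", "./.", ".|.", NA)] <- NA_character_
  parts <- strsplit(gt, "[/|]")
  bad <- !is.na(gt) & lengths(parts) != 2
  if (any(bad)) {
    where <- which(bad)[1]
    lab <- if (!is.null(context)) {
      sprintf(" (sample %s, rsid %s)",
              context$sample_id[where], context$rsid[where])
    } else ""
    abort(sprintf("malformed genotype string '%s'%s; expected 'X/Y'",
                  gt[where], lab))
  }
  a1 <- vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_, "")
  a2 <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, "")
  a1[a1 == "."] <- NA_character_
  a2[a2 == "."] <- NA_character_
  tibble(allele1 = a1, allele2 = a2)
}

#' Validate genotype calls against a panel's allele sets
#'
#' Each called allele must belong to the {reference, alternate} pair the
#' panel declares for that rsid. No strand flipping is attempted: a
#' mismatching allele is an error naming the sample and rsid, never a
#' silent correction. rsids not in the panel are also rejected.
#'
#' @param genotypes A long genotype tibble (see [as_genotypes()]).
#' @param panel A `prs_panel`.
#' @return `genotypes`, invisibly, if valid.
#' @export
validate_genotypes <- function(genotypes, panel = ldl_panel()) {
  gt <- as_genotypes(genotypes)
  loci <- panel_loci(panel)
  unknown <- setdiff(unique(gt$rsid), loci$rsid)
  if (length(unknown) > 0) {
    abort(sprintf("rsid(s) not in panel '%s': %s", panel$name,
                  paste(unknown, collapse = ", ")))
  }
  chk <- left_join(gt, loci, by = "rsid")
  ok_allele <- function(a) is.na(a) | a == chk$reference_allele |
    a == chk$alt_allele
  bad <- !(ok_allele(chk$allele1) & ok_allele(chk$allele2))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "allele outside declared set {%s,%s} at %s for sample %s: '%s/%s' (%d call(s) affected)",
      chk$reference_allele[i], chk$alt_allele[i], chk$rsid[i],
      chk$sample_id[i], chk$allele1[i], chk$allele2[i], sum(bad)
    ))
  }
  invisible(gt)
}

#' Risk-allele dosage at the weighted panel loci
#'
#' Counts copies of the panel's risk allele (0, 1 or 2) for every call at
#' the five dosage-weighted SNPs. Dosage is symmetric in allele order, and
#' a missing genotype yields `NA` dosage. Samples and loci absent from the
#' input are absent from the output; [compute_prs()] completes the grid.
#'
#' @param genotypes A genotype tibble (long or wide; see [as_genotypes()]).
#' @param panel A `prs_panel`.
#' @return A tibble `sample_id`, `rsid`, `dosage`, `weight`.
#' @examples
#' g <- data.frame(sample_id = "S1", rsid = "rs629301",
#'                 allele1 = "G", allele2 = "T")
#' allele_dosage(g)
#' @export
allele_dosage <- function(genotypes, panel = ldl_panel()) {
  gt <- validate_genotypes(genotypes, panel)
  gt <- inner_join(gt, select(panel$snps, "rsid", "risk_allele", "weight"),
                   by = "rsid")
  mutate(gt,
    dosage = (.data$allele1 == .data$risk_allele) +
      (.data$allele2 == .data$risk_allele),
    dosage = as.integer(.data$dosage)
  ) |>
    select("sample_id", "rsid", "dosage", "weight")
}
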