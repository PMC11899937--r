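#' Read genotypes from VCF or wide TSV
#'
#' VCF records are matched to the panel by the `ID` column (rsIDs); only
#' the `GT` field is consumed, phased separators are accepted and phase is
#' discarded. Samples with no record at a panel locus (or a `./.` call)
#' get a missing call there. Wide TSV input needs a `sample_id` column
#' plus one `"X/Y"` column per rsid.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param panel A `prs_panel`; genotypes are validated against its allele
#'   sets (mismatches are errors, never silent strand flips).
#' @return A long genotype tibble covering every panel locus for every
#'   sample (missing calls as `NA`/`NA`).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           panel = ldl_panel()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  gt <- switch(format,
    vcf = read_genotypes_vcf(path, panel),
    tsv = as_genotypes(readr::read_tsv(path, show_col_types = FALSE,
                                       progress = FALSE,
                                       col_types = readr::cols(.default = "c")))
  )
  gt <- complete_panel_grid(gt, panel)
  validate_genotypes(gt, panel)
  inform(sprintf(
    "read %d sample(s) x %d panel loci from %s (%d missing call(s))",
    length(unique(gt$sample_id)), length(panel_loci(panel)$rsid), path,
    sum(is.na(gt$allele1))
  ))
  gt
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  loci <- panel_loci(panel)
  keep <- fix$ID %in% loci$rsid
  if (!any(keep)) abort(sprintf("no panel rsIDs found in the ID column of %s", path))
  if (anyDuplicated(fix$ID[keep])) {
    abort(sprintf("duplicate VCF records for rsid(s): %s",
                  paste(unique(fix$ID[keep][duplicated(fix$ID[keep])]),
                        collapse = ", ")))
  }
  # allele sets must match the panel declaration (order-insensitive)
  fx <- fix[keep, , drop = FALSE]
  li <- match(fx$ID, loci$rsid)
  declared <- Map(c, loci$reference_allele[li], loci$alt_allele[li])
  seen <- Map(c, fx$REF, fx$ALT)
  bad <- !mapply(function(a, b) setequal(toupper(a), toupper(b)),
                 seen, declared)
  if (any(bad)) {
    abort(sprintf(
      "VCF REF/ALT disagree with panel allele set at %s (record %s)",
      paste(fx$ID[bad], collapse = ", "),
      paste(which(keep)[bad], collapse = ", ")
    ))
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  gt_mat <- gt_mat[keep, , drop = FALSE]
  rownames(gt_mat) <- fx$ID
  samples <- colnames(gt_mat)
  long <- tidyr::expand_grid(sample_id = samples, rsid = fx$ID)
  codes <- gt_mat[cbind(match(long$rsid, rownames(gt_mat)),
                        match(long$sample_id, samples))]
  alleles <- decode_gt_indices(codes, fx$REF[match(long$rsid, fx$ID)],
                               fx$ALT[match(long$rsid, fx$ID)], long)
  bind_cols(long, alleles)
}

# "0/1"-style index genotypes -> nucleotide pairs
decode_gt_indices <- function(codes, ref, alt, context) {
  codes[codes %in% c(".", "./.", ".|.", "")] <- NA_character_
  parts <- strsplit(codes, "[/|]")
  pick <- function(k) {
    idx <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) NA_character_ else p[k]
    }, "")
    num <- suppressWarnings(as.integer(idx))
    bad <- !is.na(idx) & (is.na(num) | num > 1)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("malformed or multiallelic GT '%s' at %s for sample %s",
                    codes[i], context$rsid[i], context$sample_id[i]))
    }
    ifelse(is.na(num), NA_character_, ifelse(num == 0L, ref, alt))
  }
  tibble(allele1 = pick(1), allele2 = pick(2))
}

# ensure every sample has a row (possibly missing) at every panel locus
complete_panel_grid <- function(gt, panel) {
  gt <- as_genotypes(gt)
  loci <- panel_loci(panel)$rsid
  grid <- tidyr::expand_grid(sample_id = unique(gt$sample_id), rsid = loci)
  left_join(grid, gt, by = c("sample_id", "rsid"))
}

#' Write genotypes to a VCFv4.2 file
#'
#' Emits one record per panel locus with the panel's GRCh38 coordinates,
#' rsID, REF/ALT alleles and per-sample unphased `GT` fields. Round trip
#' with [read_genotypes()] preserves every call (and hence every score).
#'
#' @param genotypes Genotype tibble (long or wide).
#' @param path Output path.
#' @param panel A `prs_panel`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, panel = ldl_panel()) {
  gt <- validate_genotypes(complete_panel_grid(genotypes, panel), panel)
  loci <- arrange(panel_loci(panel), .data$chrom, .data$pos)
  samples <- unique(gt$sample_id)
  code <- function(allele, ref) ifelse(is.na(allele), ".",
                                       ifelse(allele == ref, "0", "1"))
  rows <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    calls <- gt[gt$rsid == l$rsid, ]
    calls <- calls[match(samples, calls$sample_id), ]
    fields <- paste0(code(calls$allele1, l$reference_allele), "/",
                     code(calls$allele2, l$reference_allele))
    paste(c(l$chrom, l$pos, l$rsid, l$reference_allele, l$alt_allele,
            ".", "PASS", sprintf("GENE=%s", l$gene), "GT", fields),
          collapse = "\t")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldlprs",
    "##reference=GRCh38",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Nearest gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Phenotype TSVs carry one row per sample with columns `sample_id`,
#' `group` (`"patient"` or `"comparison"`), `sex`, `age`, `ldl_c`
#' (mmol/L), `smoking`, `statin`, `hypertension` (binary 0/1).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "group", "ldl_c")
  miss <- setdiff(need, names(ph))
  if (length(miss) > 0) {
    abort(sprintf("phenotype table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  mutate(ph, sample_id = as.character(.data$sample_id))
}

#' @rdname read_phenotypes
#' @param phenotypes A phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, progress = FALSE)
  invisible(path)
}

#' Write a score table as TSV
#'
#' Scores are printed to three decimal places (full precision is kept in
#' memory); dosage and flag columns pass through unchanged.
#'
#' @param scores A [compute_prs()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- mutate(scores, prs = ifelse(is.na(.data$prs), NA,
                                     sprintf("%.3f", .data$prs)))
  readr::write_tsv(out, path, progress = FALSE, na = "NA")
  invisible(path)
}
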