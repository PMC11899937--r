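#' SNP panels for the LDL-C score
#'
#' A panel bundles everything needed to score a sample: the five
#' dosage-weighted SNP definitions (rsid, nearest gene, reference and risk
#' allele, per-copy weight), the two APOE loci (rs429358, rs7412) whose joint
#' genotype is resolved into an epsilon diplotype, and the six diplotype
#' weights. The built-in `"futema2015_modified"` panel carries the published
#' constants of the seven-SNP LDL-C score: five additive loci weighted
#' 0.15 (CELSR2 rs629301), 0.1 (APOB rs1367117), 0.05 (ST3GAL4 rs11220462),
#' 0.18 (LDLR rs6511720), 0.057 (HFE rs1800562) per risk-allele copy, plus
#' diplotype weights from -0.9 (e2e2) to 0.2 (e4e4).
#'
#' Two of the additive loci (rs6511720, rs1800562) have `risk_allele` equal
#' to `reference_allele`: the weighted allele is the major/reference allele
#' and the minor allele (T resp. A) is the LDL-lowering one, so typical
#' homozygotes contribute the full `2 * weight`.
#'
#' Genomic coordinates are GRCh38 metadata used when genotypes are written
#' to VCF; genotype matching is always by rsID, never by position.
#'
#' @param name Panel identifier. Currently the single built-in panel
#'   `"futema2015_modified"`.
#' @return A `prs_panel`: a list with tibbles `snps` (columns `rsid`, `gene`,
#'   `chrom`, `pos`, `reference_allele`, `alt_allele`, `risk_allele`,
#'   `weight`), `apoe_snps` (the two APOE loci with their allele sets) and
#'   `apoe_weights` (columns `diplotype`, `weight`), plus `name` and
#'   `version` fields.
#' @examples
#' panel <- ldl_panel()
#' panel$snps
#' panel$apoe_weights
#' @export
ldl_panel <- function(name = "futema2015_modified") {
  panels <- .builtin_panels()
  if (!name %in% names(panels)) {
    abort(sprintf(
      "Unknown panel '%s'. Available panels: %s",
      name, paste(sQuote(names(panels)), collapse = ", ")
    ))
  }
  panels[[name]]
}

.builtin_panels <- function() {
  snps <- tibble(
    rsid = c("rs629301", "rs1367117", "rs11220462", "rs6511720", "rs1800562"),
    gene = c("CELSR2", "APOB", "ST3GAL4", "LDLR", "HFE"),
    chrom = c("1", "2", "11", "19", "6"),
    pos = c(109275684L, 21044073L, 126374058L, 11091630L, 26092913L),
    reference_allele = c("G", "G", "G", "G", "G"),
    alt_allele = c("T", "A", "A", "T", "A"),
    risk_allele = c("T", "A", "A", "G", "G"),
    weight = c(0.15, 0.1, 0.05, 0.18, 0.057)
  )
  apoe_snps <- tibble(
    rsid = c("rs429358", "rs7412"),
    gene = c("APOE", "APOE"),
    chrom = c("19", "19"),
    pos = c(44908684L, 44908822L),
    reference_allele = c("T", "C"),
    alt_allele = c("C", "T")
  )
  apoe_weights <- tibble(
    diplotype = c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4"),
    weight = c(-0.9, -0.4, -0.2, 0, 0.1, 0.2)
  )
  list(
    futema2015_modified = new_prs_panel(
      snps, apoe_snps, apoe_weights,
      name = "futema2015_modified", version = "1"
    )
  )
}

new_prs_panel <- function(snps, apoe_snps, apoe_weights, name, version = "1") {
  validate_panel_tables(snps, apoe_snps, apoe_weights)
  structure(
    list(
      snps = as_tibble(snps),
      apoe_snps = as_tibble(apoe_snps),
      apoe_weights = as_tibble(apoe_weights),
      name = name,
      version = version
    ),
    class = "prs_panel"
  )
}

validate_panel_tables <- function(snps, apoe_snps, apoe_weights) {
  nts <- c("A", "C", "G", "T")
  stopifnot(
    all(c("rsid", "gene", "reference_allele", "alt_allele", "risk_allele",
          "weight") %in% names(snps)),
    all(snps$reference_allele %in% nts),
    all(snps$alt_allele %in% nts),
    all(snps$risk_allele %in% nts),
    all(is.finite(snps$weight)),
    !anyDuplicated(snps$rsid)
  )
  # the risk allele must be one of the two declared alleles
  ok <- snps$risk_allele == snps$reference_allele |
    snps$risk_allele == snps$alt_allele
  if (!all(ok)) {
    abort(sprintf(
      "risk_allele outside declared allele set for: %s",
      paste(snps$rsid[!ok], collapse = ", ")
    ))
  }
  dips <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
  if (!identical(sort(apoe_weights$diplotype), dips)) {
    abort("apoe_weights must contain exactly the six epsilon diplotypes")
  }
  if (!all(is.finite(apoe_weights$weight))) {
    abort("apoe_weights$weight must be finite")
  }
  invisible(TRUE)
}

#' All loci of a panel
#'
#' Returns the seven loci (five weighted SNPs plus the two APOE sites) with
#' their declared allele sets, for genotype validation and VCF writing.
#'
#' @param panel A `prs_panel`.
#' @return A tibble with columns `rsid`, `gene`, `chrom`, `pos`,
#'   `reference_allele`, `alt_allele`.
#' @export
panel_loci <- function(panel) {
  stopifnot(inherits(panel, "prs_panel"))
  bind_rows(
    select(panel$snps, "rsid", "gene", "chrom", "pos",
           "reference_allele", "alt_allele"),
    panel$apoe_snps
  )
}

#' @exportS3Method base::print
print.prs_panel <- function(x, ...) {
  cat(sprintf("<prs_panel '%s' v%s>\n", x$name, x$version))
  cat(sprintf("  %d dosage-weighted SNPs + APOE diplotype weighting\n",
              nrow(x$snps)))
  print(x$snps, ...)
  cat("  APOE diplotype weights:\n")
  w <- setNames(x$apoe_weights$weight, x$apoe_weights$diplotype)
  cat("   ", paste(sprintf("%s=%g", names(w), w), collapse = "  "), "\n")
  invisible(x)
}

#' Read and write panel weight files
#'
#' The weight-file format (version 1) is plain tab-separated text with two
#' sections introduced by `[snps]` and `[apoe]` headers, preceded by a
#' `# ldlprs-panel v1` magic line and `# name:` metadata. `write_panel()`
#' followed by `read_panel()` round-trips a panel losslessly.
#'
#' @param path File path.
#' @param panel A `prs_panel` to serialise.
#' @return `read_panel()` returns a `prs_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# ldlprs-panel v1", lines[[1]])) {
    abort(sprintf("'%s' is not a v1 panel weight file", path))
  }
  name <- sub("^# name:\\s*", "", grep("^# name:", lines, value = TRUE)[1])
  if (is.na(name)) name <- "custom"
  sec_snps <- which(lines == "[snps]")
  sec_apoe <- which(lines == "[apoe]")
  if (length(sec_snps) != 1 || length(sec_apoe) != 1 || sec_apoe < sec_snps) {
    abort("panel file must contain one [snps] section followed by one [apoe] section")
  }
  read_block <- function(block) {
    block <- block[nzchar(block) & !grepl("^#", block)]
    df <- readr::read_tsv(I(paste(block, collapse = "\n")),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
    # parse numerics with base R's correctly rounded reader so that
    # write_panel() -> read_panel() is bit-exact
    for (col in intersect(c("weight", "pos"), names(df))) {
      df[[col]] <- as.numeric(df[[col]])
    }
    if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
    df
  }
  snps <- read_block(lines[(sec_snps + 1):(sec_apoe - 1)])
  apoe <- read_block(lines[(sec_apoe + 1):length(lines)])
  apoe_snps <- .builtin_panels()[[1]]$apoe_snps
  new_prs_panel(snps, apoe_snps, apoe, name = name, version = "1")
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "prs_panel"))
  fmt_tsv <- function(df) {
    body <- do.call(paste, c(lapply(df, format_plain), sep = "\t"))
    c(paste(names(df), collapse = "\t"), body)
  }
  lines <- c(
    "# ldlprs-panel v1",
    sprintf("# name: %s", panel$name),
    "[snps]",
    fmt_tsv(panel$snps),
    "[apoe]",
    fmt_tsv(panel$apoe_weights)
  )
  writeLines(lines, path)
  invisible(path)
}

# format without precision loss (17 significant digits round-trips doubles)
format_plain <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}
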