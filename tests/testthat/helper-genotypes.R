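# Build a wide one-row genotype table for a single sample. Arguments are
# "X/Y" strings per rsid; NA leaves the locus missing.
make_sample <- function(id, rs629301 = NA, rs1367117 = NA, rs11220462 = NA,
                        rs6511720 = NA, rs1800562 = NA, rs429358 = NA,
                        rs7412 = NA) {
  tibble::tibble(
    sample_id = id,
    rs629301 = rs629301, rs1367117 = rs1367117, rs11220462 = rs11220462,
    rs6511720 = rs6511720, rs1800562 = rs1800562,
    rs429358 = rs429358, rs7412 = rs7412
  )
}

# genotypes at the two APOE sites realising each epsilon diplotype
apoe_genotype <- function(diplotype) {
  switch(diplotype,
    e2e2 = c(rs429358 = "T/T", rs7412 = "T/T"),
    e2e3 = c(rs429358 = "T/T", rs7412 = "C/T"),
    e2e4 = c(rs429358 = "T/C", rs7412 = "C/T"),
    e3e3 = c(rs429358 = "T/T", rs7412 = "C/C"),
    e3e4 = c(rs429358 = "T/C", rs7412 = "C/C"),
    e4e4 = c(rs429358 = "C/C", rs7412 = "C/C"),
    stop("unknown diplotype")
  )
}

# The published landmark genotypes with their printed score values:
# observed group extremes and the two group medians (all attainable
# scores under the weight tables).
landmark_genotypes <- function() {
  mk <- function(id, celsr2, apob, st3gal4, ldlr, hfe, dip, expected) {
    ap <- apoe_genotype(dip)
    cbind(
      make_sample(id, rs629301 = celsr2, rs1367117 = apob,
                  rs11220462 = st3gal4, rs6511720 = ldlr, rs1800562 = hfe,
                  rs429358 = ap[["rs429358"]], rs7412 = ap[["rs7412"]]),
      tibble::tibble(expected = expected)
    )
  }
  dplyr::bind_rows(
    mk("patient_max", "T/T", "G/A", "A/A", "G/G", "G/G", "e4e4", 1.174),
    mk("patient_min", "G/G", "G/A", "G/G", "G/T", "A/A", "e2e2", -0.62),
    mk("comparison_max", "G/G", "A/A", "A/A", "G/G", "G/G", "e4e4", 0.974),
    mk("comparison_min", "G/G", "A/A", "G/A", "G/G", "G/G", "e2e2", -0.176),
    mk("patient_median", "G/T", "A/A", "G/G", "G/G", "G/G", "e3e3", 0.824),
    mk("comparison_median", "G/G", "A/A", "G/G", "G/G", "G/G", "e3e3", 0.674)
  )
}
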