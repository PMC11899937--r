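#' Configuration for synthetic two-group cohorts
#'
#' Bundles every parameter of the cohort generator. The defaults are the
#' published study conditions: a patient group of 93 STEMI cases and a
#' comparison group of 61 individuals with elevated LDL-C, the per-group
#' variant-allele frequencies of the seven score SNPs, LDL-C medians and
#' ranges (patients 3.88, 2.87-6.63 mmol/L; comparison 5.67,
#' 3.19-9.7 mmol/L), and the group prevalences of male sex, ever-smoking,
#' statin use and hypertension. Frequencies are interpreted as
#' variant-allele frequencies by default; `freq_kind = "carrier"` instead
#' treats them as carrier frequencies and converts via
#' `p = 1 - sqrt(1 - c)` under Hardy-Weinberg proportions.
#'
#' When `disease_model` is supplied (a list with `intercept`, `beta_prs`,
#' `beta_smoking`, optionally `base_group` and `max_draws`), group labels
#' are no longer assigned directly: individuals are drawn from the base
#' group's allele-frequency and smoking parameters, case status is
#' Bernoulli with probability
#' `plogis(intercept + beta_prs * PRS + beta_smoking * smoking)`, and
#' cases/controls fill the patient/comparison quotas.
#'
#' @param n_patients,n_comparison Group sizes (defaults 93 and 61).
#' @param freq Data frame with columns `rsid`, `patient`, `comparison`
#'   giving per-group variant-allele frequencies in `[0, 1]` for the seven
#'   score SNPs. Defaults to the published group frequencies.
#' @param freq_kind `"allele"` (default) or `"carrier"`.
#' @param ldl Named list of `c(median, min, max)` per group (mmol/L).
#' @param sex_male,smoking,statin,hypertension Named numeric prevalences
#'   per group in `[0, 1]`.
#' @param age Named list of `c(min, max)` per group; ages are drawn
#'   uniformly (age is not used downstream by default).
#' @param disease_model `NULL` (default) or the logistic case-assignment
#'   model described above.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 93L,
                          n_comparison = 61L,
                          freq = default_group_frequencies(),
                          freq_kind = c("allele", "carrier"),
                          ldl = list(
                            patient = c(median = 3.88, min = 2.87, max = 6.63),
                            comparison = c(median = 5.67, min = 3.19, max = 9.7)
                          ),
                          sex_male = c(patient = 48 / 93, comparison = 34 / 61),
                          smoking = c(patient = 55 / 93, comparison = 17 / 61),
                          statin = c(patient = 29 / 93, comparison = 3 / 61),
                          hypertension = c(patient = 48 / 93, comparison = 0.75),
                          age = list(patient = c(min = 42, max = 96),
                                     comparison = c(min = 45, max = 72)),
                          disease_model = NULL) {
  freq_kind <- match.arg(freq_kind)
  freq <- as_tibble(freq)
  stopifnot(all(c("rsid", "patient", "comparison") %in% names(freq)))
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      n_comparison = as.integer(n_comparison),
      freq = freq, freq_kind = freq_kind, ldl = ldl,
      sex_male = sex_male, smoking = smoking, statin = statin,
      hypertension = hypertension, age = age,
      disease_model = disease_model
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' Published per-group variant-allele frequencies of the score SNPs
#'
#' @return Tibble with columns `rsid`, `patient`, `comparison`
#'   (frequencies as proportions).
#' @export
default_group_frequencies <- function() {
  tibble(
    rsid = c("rs6511720", "rs1800562", "rs629301", "rs11220462",
             "rs1367117", "rs7412", "rs429358"),
    patient = c(0.1613, 0.04301, 0.7527, 0.4301, 0.5699, 0.1505, 0.2258),
    comparison = c(0.3607, 0.0492, 0.5574, 0.2623, 0.5902, 0.1967, 0.1639)
  )
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1 || cfg$n_comparison < 1) {
    abort("group sizes must be >= 1")
  }
  fr <- c(cfg$freq$patient, cfg$freq$comparison)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    abort("allele/carrier frequencies must lie in [0, 1]")
  }
  prev <- c(cfg$sex_male, cfg$smoking, cfg$statin, cfg$hypertension)
  if (any(prev < 0) || any(prev > 1)) {
    abort("prevalences must lie in [0, 1]")
  }
  dm <- cfg$disease_model
  if (!is.null(dm) &&
      !all(c("intercept", "beta_prs", "beta_smoking") %in% names(dm))) {
    abort("disease_model needs intercept, beta_prs and beta_smoking")
  }
  invisible(cfg)
}

#' Simulate unphased genotypes at one locus under Hardy-Weinberg
#'
#' Draws `n` unphased diploid genotypes with variant-allele frequency
#' `freq`, i.e. genotype classes at proportions `(1-p)^2`, `2p(1-p)`,
#' `p^2`.
#'
#' @param freq Variant(alt)-allele frequency in `[0, 1]`.
#' @param n Number of individuals.
#' @param rsid,ref,alt Locus metadata for the returned calls.
#' @param seed Optional seed; when supplied the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A genotype tibble (`sample_id`, `rsid`, `allele1`, `allele2`).
#' @examples
#' simulate_genotypes(0.25, 5, rsid = "rs1367117", ref = "G", alt = "A",
#'                    seed = 1)
#' @export
simulate_genotypes <- function(freq, n, rsid = "snp", ref = "G", alt = "A",
                               seed = NULL) {
  if (!is.numeric(freq) || length(freq) != 1 || is.na(freq) ||
      freq < 0 || freq > 1) {
    abort("freq must be a single value in [0, 1]")
  }
  if (n < 1) abort("n must be >= 1")
  draw <- function() rbinom(n, 2L, freq)
  dose <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(
    sample_id = sprintf("S%0*d", nchar(n), seq_len(n)),
    rsid = rsid,
    allele1 = ifelse(dose == 2L, alt, ref),
    allele2 = ifelse(dose >= 1L, alt, ref)
  )
}

#' Simulate a seeded two-group cohort
#'
#' Generates genotypes at the seven score SNPs and a phenotype table for
#' a patient and a comparison group. The five additive loci are drawn
#' independently under Hardy-Weinberg proportions at the configured
#' group frequencies (no linkage disequilibrium). rs429358/rs7412
#' genotypes are drawn jointly as pairs of epsilon haplotypes whose
#' frequencies derive from the two marginal variant-allele frequencies
#' under a no-e1 constraint: `p(e4) = freq(rs429358-C)`,
#' `p(e2) = freq(rs7412-T)`, `p(e3) = 1 - p(e2) - p(e4)`.
#'
#' LDL-C is drawn from a log-normal matched to the configured group
#' median and truncated by rejection to the configured range; binary
#' covariates are Bernoulli at the configured prevalences; age is uniform
#' within the configured range. With a `disease_model` in the config,
#' case status is assigned by the logistic model on PRS and smoking and
#' the two groups are filled to quota (see [cohort_config()]); an error
#' is raised if the quotas cannot be met within `max_draws` candidate
#' draws (default 1e6).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of `(config, seed)`.
#' @param panel A `prs_panel` (allele definitions and score weights).
#' @return A `synthetic_cohort`: list with tibbles `genotypes` (long) and
#'   `phenotypes` (`sample_id`, `group`, `sex`, `age`, `ldl_c`, `smoking`,
#'   `statin`, `hypertension`), plus `provenance` (config and seed).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 5, n_comparison = 4),
#'                        seed = 42)
#' coh$phenotypes
#' @export
simulate_cohort <- function(config = cohort_config(), seed,
                            panel = ldl_panel()) {
  validate_cohort_config(config)
  if (missing(seed)) abort("simulate_cohort requires an explicit seed")
  withr::with_seed(as.integer(seed), .simulate_cohort_impl(config, seed, panel))
}

.simulate_cohort_impl <- function(config, seed, panel) {
  if (is.null(config$disease_model)) {
    n <- c(patient = config$n_patients, comparison = config$n_comparison)
    pops <- lapply(names(n), function(g) {
      .draw_population(n[[g]], group_allele_freqs(config, g), panel)
    })
    names(pops) <- names(n)
    group <- rep(names(n), times = n)
    pop <- .bind_populations(pops)
    smoking <- unlist(lapply(names(n), function(g)
      rbinom(n[[g]], 1L, config$smoking[[g]])))
  } else {
    dm <- config$disease_model
    base <- dm$base_group %||% "comparison"
    max_draws <- dm$max_draws %||% 1e6
    freqs <- group_allele_freqs(config, base)
    quota <- c(patient = config$n_patients, comparison = config$n_comparison)
    got <- list(patient = NULL, comparison = NULL)
    got_smoke <- list(patient = integer(), comparison = integer())
    drawn <- 0
    batch <- max(1000L, 4L * sum(quota))
    while (any(vapply(got, .pop_n, 0L) < quota)) {
      if (drawn >= max_draws) {
        abort(sprintf(
          "disease-model quota not met within %g draws (have %d cases / %d controls)",
          max_draws, .pop_n(got$patient), .pop_n(got$comparison)
        ))
      }
      b <- min(batch, max_draws - drawn)
      cand <- .draw_population(b, freqs, panel)
      smoke <- rbinom(b, 1L, config$smoking[[base]])
      p_case <- plogis(dm$intercept + dm$beta_prs * cand$score +
                         dm$beta_smoking * smoke)
      case <- rbinom(b, 1L, p_case) == 1L
      for (g in c("patient", "comparison")) {
        want <- quota[[g]] - .pop_n(got[[g]])
        idx <- which(if (g == "patient") case else !case)
        idx <- head(idx, want)
        got[[g]] <- .pop_append(got[[g]], .pop_subset(cand, idx))
        got_smoke[[g]] <- c(got_smoke[[g]], smoke[idx])
      }
      drawn <- drawn + b
    }
    pop <- .bind_populations(got)
    group <- rep(c("patient", "comparison"), times = quota)
    smoking <- c(got_smoke$patient, got_smoke$comparison)
  }

  n_total <- length(group)
  ids <- sprintf("S%04d", seq_len(n_total))
  genotypes <- .materialize_genotypes(pop, ids, panel)
  phenotypes <- tibble(
    sample_id = ids,
    group = group,
    sex = ifelse(
      runif(n_total) < unname(config$sex_male[group]), "male", "female"),
    age = round(runif(
      n_total,
      vapply(config$age[group], `[[`, 0, "min"),
      vapply(config$age[group], `[[`, 0, "max")
    )),
    ldl_c = .draw_ldl(config$ldl, group),
    smoking = as.integer(smoking),
    statin = rbinom(n_total, 1L, unname(config$statin[group])),
    hypertension = rbinom(n_total, 1L, unname(config$hypertension[group]))
  )
  structure(
    list(
      genotypes = genotypes,
      phenotypes = phenotypes,
      provenance = list(config = config, seed = as.integer(seed),
                        panel = panel$name)
    ),
    class = "synthetic_cohort"
  )
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  n <- table(x$phenotypes$group)
  cat(sprintf(
    "<synthetic_cohort: %d samples (%s), seed %d>\n",
    nrow(x$phenotypes),
    paste(sprintf("%s = %d", names(n), n), collapse = ", "),
    x$provenance$seed
  ))
  invisible(x)
}

# per-group alt-allele frequencies as a named vector over the 7 rsids,
# converting carrier frequencies if configured
group_allele_freqs <- function(config, group) {
  p <- setNames(config$freq[[group]], config$freq$rsid)
  if (config$freq_kind == "carrier") p <- 1 - sqrt(1 - p)
  p
}

# draw n individuals: alt-allele dosages at the 5 weighted SNPs, epsilon
# haplotype pair, and the resulting score
.draw_population <- function(n, freqs, panel) {
  rsids <- panel$snps$rsid
  alt_dose <- matrix(0L, nrow = n, ncol = length(rsids),
                     dimnames = list(NULL, rsids))
  for (rs in rsids) alt_dose[, rs] <- rbinom(n, 2L, freqs[[rs]])
  p4 <- freqs[["rs429358"]]
  p2 <- freqs[["rs7412"]]
  if (p2 + p4 > 1) {
    abort("epsilon-haplotype frequencies infeasible: freq(rs429358) + freq(rs7412) > 1")
  }
  eps <- c("e2", "e3", "e4")
  prob <- c(p2, 1 - p2 - p4, p4)
  hap1 <- sample(eps, n, replace = TRUE, prob = prob)
  hap2 <- sample(eps, n, replace = TRUE, prob = prob)
  risk_dose <- alt_dose
  ref_is_risk <- panel$snps$risk_allele == panel$snps$reference_allele
  risk_dose[, ref_is_risk] <- 2L - risk_dose[, ref_is_risk]
  dip <- paste0(pmin(hap1, hap2), pmax(hap1, hap2))
  score <- drop(risk_dose %*% panel$snps$weight) +
    panel$apoe_weights$weight[match(dip, panel$apoe_weights$diplotype)]
  list(alt_dose = alt_dose, hap1 = hap1, hap2 = hap2, score = score)
}

.pop_n <- function(pop) if (is.null(pop)) 0L else length(pop$score)
.pop_subset <- function(pop, idx) {
  list(alt_dose = pop$alt_dose[idx, , drop = FALSE],
       hap1 = pop$hap1[idx], hap2 = pop$hap2[idx], score = pop$score[idx])
}
.pop_append <- function(a, b) {
  if (is.null(a)) return(b)
  list(alt_dose = rbind(a$alt_dose, b$alt_dose),
       hap1 = c(a$hap1, b$hap1), hap2 = c(a$hap2, b$hap2),
       score = c(a$score, b$score))
}
.bind_populations <- function(pops) Reduce(.pop_append, pops)

# expand the internal dosage/haplotype representation into genotype calls
.materialize_genotypes <- function(pop, ids, panel) {
  snps <- panel$snps
  blocks <- lapply(seq_len(nrow(snps)), function(j) {
    d <- pop$alt_dose[, snps$rsid[j]]
    tibble(
      sample_id = ids, rsid = snps$rsid[j],
      allele1 = ifelse(d == 2L, snps$alt_allele[j], snps$reference_allele[j]),
      allele2 = ifelse(d >= 1L, snps$alt_allele[j], snps$reference_allele[j])
    )
  })
  apoe <- bind_rows(
    tibble(sample_id = ids, rsid = "rs429358",
           allele1 = ifelse(pop$hap1 == "e4", "C", "T"),
           allele2 = ifelse(pop$hap2 == "e4", "C", "T")),
    tibble(sample_id = ids, rsid = "rs7412",
           allele1 = ifelse(pop$hap1 == "e2", "T", "C"),
           allele2 = ifelse(pop$hap2 == "e2", "T", "C"))
  )
  bind_rows(c(blocks, list(apoe))) |>
    arrange(match(.data$sample_id, ids))
}

# truncated log-normal matched to the configured median; sdlog set so the
# configured min-max spans the central 99% of the untruncated law
.draw_ldl <- function(ldl_cfg, group) {
  out <- numeric(length(group))
  for (g in unique(group)) {
    i <- which(group == g)
    pars <- ldl_cfg[[g]]
    meanlog <- log(pars[["median"]])
    sdlog <- (log(pars[["max"]]) - log(pars[["min"]])) / (2 * qnorm(0.995))
    x <- rlnorm(length(i), meanlog, sdlog)
    bad <- x < pars[["min"]] | x > pars[["max"]]
    while (any(bad)) {
      x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
      bad <- x < pars[["min"]] | x > pars[["max"]]
    }
    out[i] <- x
  }
  round(out, 2)
}
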