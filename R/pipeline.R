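#' Run configuration for the end-to-end pipeline
#'
#' Either point `genotypes`/`phenotypes` at input files, or supply
#' `simulate = cohort_config(...)` to generate the cohort in place. All
#' paths are checked before the run starts; the configuration is
#' serialised verbatim into the output directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every random stage of the run.
#' @param genotypes,phenotypes Input file paths (VCF/TSV and TSV), or
#'   `NULL` when simulating.
#' @param simulate A [cohort_config()], or `NULL` when reading inputs.
#' @param panel Panel name (see [ldl_panel()]) or path to a weight file.
#' @param apoe_policy `"default"` or `"strict"` (see [call_apoe()]).
#' @param ldl_threshold LDL-C dichotomization threshold in mmol/L.
#' @param alpha Backward-selection retention threshold.
#' @param candidates Candidate model terms for the case model; must be
#'   columns of the scored/phenotype table.
#' @param ldl_model_group Group in which the high-LDL-C model is fitted
#'   (default `"comparison"`, or `"all"`).
#' @param format Genotype input format, see [read_genotypes()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, genotypes = NULL,
                       phenotypes = NULL, simulate = NULL,
                       panel = "futema2015_modified",
                       apoe_policy = c("default", "strict"),
                       ldl_threshold = 4.9, alpha = 0.05,
                       candidates = c("prs", "smoking", "sex_male", "age",
                                      "hypertension", "statin"),
                       ldl_model_group = c("comparison", "all"),
                       format = c("auto", "vcf", "tsv")) {
  apoe_policy <- match.arg(apoe_policy)
  ldl_model_group <- match.arg(ldl_model_group)
  format <- match.arg(format)
  if (is.null(simulate)) {
    if (is.null(genotypes) || is.null(phenotypes)) {
      abort("either supply 'simulate' or both 'genotypes' and 'phenotypes' paths")
    }
    for (p in c(genotypes, phenotypes)) {
      if (!file.exists(p)) abort(sprintf("input path not resolvable: %s", p))
    }
  } else {
    stopifnot(inherits(simulate, "cohort_config"))
  }
  if (is.character(panel) && !panel %in% names(.builtin_panels()) &&
      !file.exists(panel)) {
    abort(sprintf("panel '%s' is neither a built-in panel nor a file", panel))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), genotypes = genotypes,
         phenotypes = phenotypes, simulate = simulate, panel = panel,
         apoe_policy = apoe_policy, ldl_threshold = ldl_threshold,
         alpha = alpha, candidates = candidates,
         ldl_model_group = ldl_model_group, format = format),
    class = "run_config"
  )
}

resolve_panel <- function(panel) {
  if (inherits(panel, "prs_panel")) return(panel)
  if (panel %in% names(.builtin_panels())) return(ldl_panel(panel))
  read_panel(panel)
}

#' Run the full simulate/score/analyze pipeline
#'
#' Executes the configured stages and writes, under `out_dir`:
#' `genotypes.vcf` and `phenotypes.tsv` (when simulating), `scores.tsv`,
#' `analysis.json`, `report.txt` (a group-characteristics report with
#' medians, counts, percentages and test statistics), `config.yaml` and
#' `run.log`. Reruns with the same config and seed reproduce the bundle
#' exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `scores`, `phenotypes`, `analysis` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  panel <- resolve_panel(config$panel)
  log("panel %s v%s; weight checksum %s; seed %d", panel$name, panel$version,
      panel_checksum(panel), config$seed)

  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate, seed = config$seed,
                              panel = panel)
    gt <- cohort$genotypes
    ph <- cohort$phenotypes
    write_genotypes_vcf(gt, file.path(config$out_dir, "genotypes.vcf"), panel)
    write_phenotypes(ph, file.path(config$out_dir, "phenotypes.tsv"))
    log("simulated cohort: %d patients, %d comparison",
        sum(ph$group == "patient"), sum(ph$group == "comparison"))
  } else {
    gt <- read_genotypes(config$genotypes, format = config$format,
                         panel = panel)
    ph <- read_phenotypes(config$phenotypes)
    log("read %d samples of genotypes, %d phenotype rows",
        length(unique(gt$sample_id)), nrow(ph))
  }

  scores <- compute_prs(gt, panel, apoe_policy = config$apoe_policy)
  excluded <- scores$sample_id[is.na(scores$prs)]
  if (length(excluded) > 0) {
    log("excluded %d unscored sample(s): %s", length(excluded),
        paste(head(excluded, 10), collapse = ", "))
  }
  log("scored %d/%d samples complete", sum(scores$complete), nrow(scores))
  write_scores(scores, file.path(config$out_dir, "scores.tsv"))

  joined <- inner_join(filter(scores, !is.na(.data$prs)), ph,
                       by = "sample_id")
  analysis <- analyze_cohort(joined, ldl_threshold = config$ldl_threshold,
                             alpha = config$alpha,
                             candidates = config$candidates,
                             ldl_model_group = config$ldl_model_group)
  jsonlite::write_json(analysis_as_json(analysis),
                       file.path(config$out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(render_report(analysis),
             file.path(config$out_dir, "report.txt"))
  yaml::write_yaml(config_as_yaml(config),
                   file.path(config$out_dir, "config.yaml"))
  log("analysis written: %s", file.path(config$out_dir, "analysis.json"))
  writeLines(log_lines, log_path)

  invisible(list(
    scores = scores, phenotypes = ph, analysis = analysis,
    paths = file.path(config$out_dir,
                      c("scores.tsv", "analysis.json", "report.txt",
                        "config.yaml", "run.log"))
  ))
}

panel_checksum <- function(panel) {
  x <- paste(c(
    sprintf("%s:%s:%.17g", panel$snps$rsid, panel$snps$risk_allele,
            panel$snps$weight),
    sprintf("%s:%.17g", panel$apoe_weights$diplotype,
            panel$apoe_weights$weight)
  ), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 0xffffffff)
}

#' Statistical analysis of a scored two-group cohort
#'
#' Runs the association stage on a joined score + phenotype table:
#' rank tests on the quantitative variables (score, LDL-C, age),
#' contingency-table tests on the categorical ones (Pearson chi-square
#' for sex and hypertension, Fisher exact for smoking and statin use),
#' a case-status logistic model over the candidate terms with backward
#' selection, and a high-LDL-C (`> ldl_threshold` mmol/L) logistic model
#' fitted inside `ldl_model_group`.
#'
#' @param data Data frame with at least `sample_id`, `group`, `prs`,
#'   `ldl_c` and the candidate columns.
#' @param ldl_threshold LDL-C dichotomization threshold (mmol/L).
#' @param alpha Backward-selection threshold.
#' @param candidates Candidate terms for the case model.
#' @param ldl_model_group `"comparison"` or `"all"`.
#' @return A list with elements `characteristics`, `prs_comparison`,
#'   `case_model`, `ldl_model`.
#' @export
analyze_cohort <- function(data, ldl_threshold = 4.9, alpha = 0.05,
                           candidates = c("prs", "smoking", "sex_male",
                                          "age", "hypertension", "statin"),
                           ldl_model_group = c("comparison", "all")) {
  ldl_model_group <- match.arg(ldl_model_group)
  data <- as_tibble(data)
  if (!all(c("group", "prs", "ldl_c") %in% names(data))) {
    abort("analysis input needs 'group', 'prs' and 'ldl_c' columns")
  }
  if ("sex" %in% names(data) && !"sex_male" %in% names(data)) {
    data$sex_male <- as.integer(data$sex == "male")
  }
  data$case <- as.integer(data$group == "patient")

  quantitative <- intersect(c("age", "ldl_c", "prs"), names(data))
  quant <- purrr::map(setNames(quantitative, quantitative), function(v) {
    kt <- kruskal_rank_test(data, dplyr::all_of(v), group)
    list(test = kt, groups = attr(kt, "groups"))
  })

  cat_tests <- list(sex_male = "chi2", smoking = "fisher",
                    hypertension = "chi2", statin = "fisher")
  cat_tests <- cat_tests[intersect(names(cat_tests), names(data))]
  categorical <- purrr::imap(cat_tests, function(test, v) {
    tab <- table(data$group, data[[v]])
    res <- if (test == "chi2") pearson_chi2(tab) else fisher_exact(tab)
    counts <- as_tibble(as.data.frame(tab)) |>
      rlang::set_names(c("group", "level", "n")) |>
      group_by(.data$group) |>
      mutate(denominator = sum(.data$n),
             percent = 100 * .data$n / sum(.data$n)) |>
      ungroup()
    list(test = test, result = res, counts = counts)
  })

  case_model <- backward_select(
    data, stats::reformulate(intersect(candidates, names(data)),
                             response = "case"),
    alpha = alpha, on_separation = "warn"
  )

  ldl_data <- if (ldl_model_group == "comparison") {
    filter(data, .data$group == "comparison")
  } else {
    data
  }
  ldl_data$ldl_high <- dichotomize_ldl(ldl_data$ldl_c, ldl_threshold)
  ldl_model <- tryCatch(
    logistic_fit(ldl_data, ldl_high ~ prs, on_separation = "warn"),
    error = function(e) e$message
  )

  list(
    characteristics = list(quantitative = quant, categorical = categorical),
    prs_comparison = quant$prs,
    case_model = case_model,
    ldl_model = list(group = ldl_model_group, threshold = ldl_threshold,
                     fit = ldl_model)
  )
}

analysis_as_json <- function(analysis) {
  quant <- purrr::map(analysis$characteristics$quantitative, function(q) {
    list(test = as.data.frame(q$test), groups = as.data.frame(q$groups))
  })
  cate <- purrr::map(analysis$characteristics$categorical, function(cq) {
    list(test = cq$test, result = as.data.frame(cq$result),
         counts = as.data.frame(cq$counts))
  })
  ldl_fit <- analysis$ldl_model$fit
  list(
    quantitative = quant,
    categorical = cate,
    case_model = list(
      trace = as.data.frame(analysis$case_model$trace),
      alpha = analysis$case_model$alpha,
      terms = as.data.frame(tidy(analysis$case_model)),
      fit = as.data.frame(glance(analysis$case_model))
    ),
    ldl_model = if (inherits(ldl_fit, "ldl_logit")) {
      list(group = analysis$ldl_model$group,
           threshold = analysis$ldl_model$threshold,
           terms = as.data.frame(tidy(ldl_fit)),
           fit = as.data.frame(glance(ldl_fit)))
    } else {
      list(group = analysis$ldl_model$group,
           threshold = analysis$ldl_model$threshold, error = ldl_fit)
    }
  )
}

render_report <- function(analysis) {
  lines <- c("Group characteristics", strrep("=", 60))
  for (v in names(analysis$characteristics$quantitative)) {
    q <- analysis$characteristics$quantitative[[v]]
    gs <- q$groups
    per_group <- sprintf("%s: median %.3g (%.3g-%.3g, n=%d)", gs$group,
                         gs$median, gs$min, gs$max, gs$n)
    lines <- c(lines, sprintf("%-14s %s  [H = %.3f, p = %.4g]", v,
                              paste(per_group, collapse = "; "),
                              q$test$statistic, q$test$p.value))
  }
  for (v in names(analysis$characteristics$categorical)) {
    cq <- analysis$characteristics$categorical[[v]]
    pos <- filter(cq$counts, .data$level == tail(levels(factor(cq$counts$level)), 1))
    per_group <- sprintf("%s: %d/%d (%.1f%%)", pos$group, pos$n,
                         pos$denominator, pos$percent)
    stat <- if (cq$test == "chi2") {
      sprintf("chi2 = %.3f, p = %.4g", cq$result$statistic, cq$result$p.value)
    } else {
      sprintf("Fisher p = %.4g", cq$result$p.value)
    }
    lines <- c(lines, sprintf("%-14s %s  [%s]", v,
                              paste(per_group, collapse = "; "), stat))
  }
  lines <- c(lines, "", "Case-status model (backward selection)",
             strrep("=", 60))
  td <- tidy(analysis$case_model)
  lines <- c(lines, sprintf(
    "%-14s OR %.3f (95%% CI %.3f-%.3f), p = %.4g",
    td$term, td$odds.ratio, td$conf.low, td$conf.high, td$p.value
  ))
  lines <- c(lines, "", sprintf(
    "High-LDL-C model (> %.3g mmol/L, %s group)",
    analysis$ldl_model$threshold, analysis$ldl_model$group
  ), strrep("=", 60))
  fit <- analysis$ldl_model$fit
  if (inherits(fit, "ldl_logit")) {
    td <- tidy(fit)
    lines <- c(lines, sprintf(
      "%-14s OR %.3f (95%% CI %.3f-%.3f), p = %.4g",
      td$term, td$odds.ratio, td$conf.low, td$conf.high, td$p.value
    ))
  } else {
    lines <- c(lines, sprintf("not fitted: %s", fit))
  }
  lines
}

config_as_yaml <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) {
    sim <- unclass(cfg$simulate)
    sim$freq <- as.list(as.data.frame(sim$freq))
    sim$ldl <- purrr::map(sim$ldl, as.list)
    sim$age <- purrr::map(sim$age, as.list)
    sim$sex_male <- as.list(sim$sex_male)
    sim$smoking <- as.list(sim$smoking)
    sim$statin <- as.list(sim$statin)
    sim$hypertension <- as.list(sim$hypertension)
    cfg$simulate <- sim
  }
  if (inherits(cfg$panel, "prs_panel")) cfg$panel <- cfg$panel$name
  cfg
}
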