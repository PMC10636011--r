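#' Default pipeline configuration
#'
#' A fully synthetic demonstration run, small enough to complete in
#' seconds: every stage enabled, seeded, writing TSV report tables to
#' `out_dir`. Any element can be overridden via `...` or by editing the
#' returned list; [run_pipeline()] also accepts a YAML file with the same
#' structure.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every random stage derives its own seed from
#'   it.
#' @param ... Named overrides of top-level elements.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("fallmr_run_"),
                               seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_individuals = 4000L,
    n_variants = 60L,
    ld_block_size = 5L,
    case_prevalence = 0.10,
    exposure_h2 = 0.25,
    true_causal_effect = 0.3,
    confounder_effect_x = 0.4,
    confounder_effect_y = 0.4,
    overlap_fraction = 0.5,
    n_gwas = 50000L,
    selection_pvalue = 5e-8,
    stages = list(
      synthdata = TRUE, phenotyping = TRUE, assoc = TRUE,
      ldsc = TRUE, mr2s = TRUE, mr1s = TRUE, mroverlap = TRUE,
      report = TRUE
    ),
    firth_n_variants = 8L,
    ldsc_window = 25L,
    n_boot = 200L,
    bidirectional = FALSE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  base[names(cfg)] <- cfg
  base$seed <- as.integer(base$seed)
  base
}

validate_run_config <- function(config) {
  st <- config$stages
  if (isTRUE(st$mr2s) && !isTRUE(st$synthdata)) {
    config_error("mr2s stage requires synthdata to supply summary statistics")
  }
  if (isTRUE(st$mroverlap) && !isTRUE(st$synthdata)) {
    config_error("mroverlap stage requires synthdata")
  }
  if (isTRUE(st$phenotyping) && !isTRUE(st$synthdata)) {
    config_error("phenotyping stage requires synthdata to supply an event log")
  }
  if (is.null(config$seed)) config_error("config must carry an explicit seed")
  invisible(config)
}

#' Run the full synthetic falls analysis pipeline
#'
#' Executes the enabled stages in dependency order — data generation,
#' phenotyping, variant QC + Firth association + observational models,
#' LD score regression, two-sample MR, one-sample MR, overlap-corrected
#' MR, report rendering — writing each stage's tables as TSV under
#' `config$out_dir` and appending a plain-text log line (stage,
#' parameters, seed, output file MD5 hashes) per stage. A failure inside
#' one analysis stage is caught and logged without aborting the others.
#'
#' @param config A [default_run_config()] list, a YAML file path, or
#'   `NULL` for the default demo run.
#' @return Invisible list of stage results (also written to disk).
#' @export
run_pipeline <- function(config = NULL) {
  if (is.null(config)) config <- default_run_config()
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg),
        file = log_path, append = TRUE)
  }
  emit <- function(stage, name, tbl) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path, progress = FALSE)
    log_line(stage, sprintf("wrote %s (md5 %s)", basename(path),
                            unname(tools::md5sum(path))))
    path
  }
  results <- list(config = config)
  st <- config$stages
  safely <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_line(stage, paste("FAILED:", conditionMessage(e)))
      NULL
    })
  }

  if (isTRUE(st$synthdata)) {
    log_line("synthdata", sprintf("seed=%d n=%d m=%d", config$seed,
                                  config$n_individuals, config$n_variants))
    scfg <- sim_config(
      n_individuals = config$n_individuals,
      n_variants = config$n_variants,
      ld_block_size = config$ld_block_size,
      case_prevalence = config$case_prevalence,
      exposure_h2 = config$exposure_h2,
      true_causal_effect = config$true_causal_effect,
      confounder_effect_x = config$confounder_effect_x,
      confounder_effect_y = config$confounder_effect_y,
      overlap_fraction = config$overlap_fraction,
      selection_pvalue = config$selection_pvalue,
      seed = config$seed
    )
    geno <- simulate_genotypes(scfg)
    ct <- simulate_traits(geno)
    log_obj <- simulate_event_log(ct$cohort, seed = config$seed)
    pair_cfg <- sim_config(
      n_variants = 2000L, exposure_h2 = config$exposure_h2,
      true_causal_effect = config$true_causal_effect,
      overlap_fraction = config$overlap_fraction,
      selection_pvalue = 1, seed = config$seed
    )
    pair <- simulate_sumstats_pair(pair_cfg, n_exposure = config$n_gwas,
                                   n_outcome = config$n_gwas)
    results$synthdata <- list(genotypes = geno, cohort = ct,
                              event_log = log_obj, sumstats_pair = pair)
    emit("synthdata", "cohort", ct$cohort)
    emit("synthdata", "event_log", log_obj$events)
    emit("synthdata", "exposure_sumstats", pair$exposure_stats)
    emit("synthdata", "outcome_sumstats", pair$outcome_stats)
    # ground truth sidecar
    yaml::write_yaml(
      list(seed = config$seed,
           true_causal_effect = config$true_causal_effect,
           error_correlation = pair$truth$error_correlation,
           case_prevalence = config$case_prevalence),
      file.path(config$out_dir, "truth.yaml")
    )
  }

  if (isTRUE(st$phenotyping)) {
    results$phenotyping <- safely("phenotyping", {
      codes <- example_code_list()
      log_obj <- results$synthdata$event_log
      all_persons <- results$synthdata$cohort$cohort$person_id
      phen <- derive_fall_status(log_obj$events, codes,
                                 persons = all_persons)
      emit("phenotyping", "phenotype", phen)
      phen
    })
  }

  if (isTRUE(st$assoc)) {
    results$assoc <- safely("assoc", {
      geno <- results$synthdata$genotypes
      ct <- results$synthdata$cohort
      qc <- variant_qc(geno$variants)
      scan_idx <- head(match(qc$retained$variant_id,
                             colnames(geno$dosages)),
                       config$firth_n_variants)
      scan <- firth_scan(
        geno$dosages[, scan_idx, drop = FALSE],
        ct$cohort$fall_status,
        covariates = ct$cohort[, c("age", "sex")]
      )
      obs <- bind_rows(
        observational_model(ct$cohort, "exposure", "fall_status",
                            family = "logistic"),
        observational_model(
          dplyr::filter(ct$cohort, fall_status == "case"),
          "exposure", "fall_count", family = "poisson"
        )
      )
      emit("assoc", "variant_exclusions", qc$exclusions)
      emit("assoc", "firth_scan", scan)
      emit("assoc", "observational", obs)
      list(qc = qc, scan = scan, observational = obs)
    })
  }

  if (isTRUE(st$ldsc)) {
    results$ldsc <- safely("ldsc", {
      geno <- results$synthdata$genotypes
      ld <- compute_ld_scores(geno$dosages, window = config$ldsc_window)
      tr <- simulate_correlated_traits(geno, seed = config$seed)
      ss_a <- linear_scan(geno$dosages, tr$trait_a,
                          variants = geno$variants[, 1:6])
      ss_b <- linear_scan(geno$dosages, tr$trait_b,
                          variants = geno$variants[, 1:6])
      nb <- max(2L, min(20L, nrow(ld) %/% 10L))
      h2 <- estimate_h2(ss_a, ld, n_blocks = nb)
      rg <- estimate_rg(ss_a, ss_b, ld, n_blocks = nb)
      rg_rep <- bonferroni_report(rg)
      emit("ldsc", "ld_scores", ld)
      emit("ldsc", "heritability", h2)
      emit("ldsc", "genetic_correlation", rg_rep)
      list(ld = ld, h2 = h2, rg = rg_rep)
    })
  }

  if (isTRUE(st$mr2s)) {
    results$mr2s <- safely("mr2s", {
      pair <- results$synthdata$sumstats_pair
      ex <- pair$exposure_stats
      keep <- ex$pvalue < config$selection_pvalue
      if (sum(keep) < 3) keep <- rank(ex$pvalue) <= 30
      if (config$bidirectional) {
        ins <- harmonise_instruments(pair$outcome_stats[keep, ],
                                     pair$exposure_stats[keep, ])
      } else {
        ins <- harmonise_instruments(pair$exposure_stats[keep, ],
                                     pair$outcome_stats[keep, ])
      }
      res <- mr_all_methods(ins, n_boot = config$n_boot,
                            seed = config$seed)
      emit("mr2s", "mr2s_results", res)
      list(instruments = ins, results = res)
    })
  }

  if (isTRUE(st$mr1s)) {
    results$mr1s <- safely("mr1s", {
      geno <- results$synthdata$genotypes
      ct <- results$synthdata$cohort
      dat <- ct$cohort
      dat$score <- build_allele_score(geno$dosages,
                                      ct$truth$variant_effects)
      fits <- list(
        logistic = mr_tsls(dat, "score", "exposure", "fall_status",
                           family = "logistic"),
        poisson = mr_tsls(dplyr::filter(dat, fall_status == "case"),
                          "score", "exposure", "fall_count",
                          family = "poisson")
      )
      res <- bind_rows(lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        tibble(method = paste0("TSLS_", nm), beta = f$beta, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
               first_stage_F = f$first_stage_F, n = f$n)
      }))
      emit("mr1s", "mr1s_results", res)
      list(fits = fits, results = res)
    })
  }

  if (isTRUE(st$mroverlap)) {
    results$mroverlap <- safely("mroverlap", {
      pair <- results$synthdata$sumstats_pair
      oc <- mr_corrected_ivw(pair$exposure_stats_full,
                             pair$outcome_stats_full,
                             pair$ld_scores, selection_threshold = 1e-4)
      tab <- bind_rows(
        mutate(oc$observed, method = "observed_IVW"),
        oc$corrected
      ) |>
        mutate(difference_p = oc$difference$p)
      emit("mroverlap", "mroverlap_results", tab)
      oc
    })
  }

  if (isTRUE(st$report)) {
    results$report <- safely("report", {
      rep <- render_reports(results)
      for (nm in names(rep)) emit("report", paste0("report_", nm), rep[[nm]])
      rep
    })
  }
  log_line("pipeline", "done")
  invisible(results)
}

fmt_ratio <- function(x) sprintf("%.3f", x)

#' Render paper-style report tables from pipeline results
#'
#' Shapes the stage outputs into tidy report tables: cohort
#' demographics, observational associations, genome-wide-significant
#' hits, genetic correlations with Bonferroni significance flags, and an
#' MR forest table (odds ratios to 3 decimals, percentages to integers).
#'
#' @param results The list returned by [run_pipeline()] (stages may be
#'   missing; their tables are omitted or empty but well-formed).
#' @return Named list of tibbles.
#' @export
render_reports <- function(results) {
  out <- list()
  if (!is.null(results$phenotyping) && !is.null(results$synthdata)) {
    phen <- results$phenotyping
    cohort <- results$synthdata$cohort$cohort
    covs <- cohort |>
      mutate(sex_male = sex == "male") |>
      select(person_id, age, sex, sex_male, exposure)
    out$demographics <- summarize_cohort(phen, covs,
                                         traits = c("sex_male", "exposure"))
  }
  if (!is.null(results$assoc)) {
    out$observational <- results$assoc$observational
    hits <- dplyr::filter(results$assoc$scan, gws_flag)
    out$gws_hits <- if (nrow(hits) == 0) {
      tibble(variant_id = character(), beta = numeric(), se = numeric(),
             p = numeric())
    } else {
      hits |> select(variant_id, beta, se, p)
    }
  }
  if (!is.null(results$ldsc)) {
    out$genetic_correlations <- results$ldsc$rg
    out$heritability <- results$ldsc$h2
  }
  mr_rows <- list()
  if (!is.null(results$mr2s)) {
    mr_rows$two_sample <- results$mr2s$results |>
      mutate(analysis = "two_sample")
  }
  if (!is.null(results$mroverlap)) {
    oc <- results$mroverlap
    mr_rows$overlap <- bind_rows(
      mutate(oc$observed, method = "observed_IVW"),
      oc$corrected
    ) |>
      mutate(analysis = "overlap_corrected")
  }
  if (length(mr_rows) > 0) {
    out$mr_forest <- bind_rows(mr_rows) |>
      mutate(
        or = fmt_ratio(exp(beta)),
        or_ci = sprintf("%s (%s-%s)", fmt_ratio(exp(beta)),
                        fmt_ratio(exp(ci_low)), fmt_ratio(exp(ci_high)))
      ) |>
      select(analysis, method, beta, se, ci_low, ci_high, p, k, or, or_ci)
  } else {
    out$mr_forest <- tibble(analysis = character(), method = character(),
                            beta = numeric(), p = numeric())
  }
  if (!is.null(results$mr1s)) {
    out$one_sample <- results$mr1s$results
  }
  out
}
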