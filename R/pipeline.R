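.pipeline_defaults <- function() {
  list(
    input = NULL,                    # CSV path; NULL = synthetic
    n = 2000L, seed = 1L, wave = "2018",
    treatment_effect_tau = 0, confounding_strength = 0, missing_rate = 0,
    tau_rural_only = FALSE,
    dimensions = c("srh", "adl", "iadl", "cognition"),
    exposures = "access",            # subset of {"access", "use"}
    subgroups = character(0),        # e.g. c("sex", "hukou")
    min_subgroup = 50L,
    psm = TRUE, psm_caliper = NULL,
    outdir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; fills defaults and rejects
#' unknown keys by name before any stage runs.
#'
#' @param config named list of options, or path to a YAML file.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
    # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
    names(config)[names(config) == "FALSE"] <- "n"
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path",
                             call. = FALSE)
  def <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L)
    stop("unknown configuration key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, config)
  bad_dim <- setdiff(cfg$dimensions, c("srh", "adl", "iadl", "cognition"))
  if (length(bad_dim) > 0L)
    stop("unknown dimension: ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  bad_exp <- setdiff(cfg$exposures, c("access", "use"))
  if (length(bad_exp) > 0L)
    stop("unknown exposure: ", paste(bad_exp, collapse = ", "),
         call. = FALSE)
  # delegate numeric validation of the generator block
  synth_config(n = cfg$n, seed = cfg$seed,
               treatment_effect_tau = cfg$treatment_effect_tau,
               confounding_strength = cfg$confounding_strength,
               missing_rate = cfg$missing_rate, wave = cfg$wave,
               tau_rural_only = cfg$tau_rural_only)
  structure(cfg, class = "pipeline_config")
}

#' Sequential sample-exclusion report
#'
#' Counts exclusions in survey-flow order: first respondents below the
#' minimum age, then (among those retained) respondents with a missing
#' value in any key variable. Percentages are reported against the initial
#' sample size (the survey-flowchart convention) and, for comparison,
#' against the pre-stage denominator.
#'
#' @param table a data.frame with an `age` column.
#' @param min_age minimum age retained (default 50).
#' @param key_vars columns whose missingness triggers the second exclusion;
#'   default none.
#' @return A data.frame with one row per step (`age`, `missing_key`):
#'   excluded and retained counts, `pct_initial`, `pct_prestage`.
#' @export
exclusion_report <- function(table, min_age = 50, key_vars = character(0)) {
  n0 <- nrow(table)
  if (n0 == 0L)
    return(data.frame(step = c("age", "missing_key"),
                      excluded = c(0L, 0L), retained = c(0L, 0L),
                      pct_initial = c(0, 0), pct_prestage = c(0, 0)))
  drop_age <- !is.na(table$age) & table$age < min_age
  n_age <- sum(drop_age)
  t1 <- table[!drop_age, , drop = FALSE]
  if (length(key_vars) > 0L) {
    kv <- intersect(key_vars, names(t1))
    drop_miss <- !stats::complete.cases(t1[kv])
  } else drop_miss <- rep(FALSE, nrow(t1))
  n_miss <- sum(drop_miss)
  data.frame(
    step = c("age", "missing_key"),
    excluded = c(n_age, n_miss),
    retained = c(nrow(t1), nrow(t1) - n_miss),
    pct_initial = 100 * c(n_age, n_miss) / n0,
    pct_prestage = 100 * c(n_age / n0,
                           if (nrow(t1) > 0) n_miss / nrow(t1) else 0)
  )
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on a synthetic or ingested cohort: cohort ->
#' exclusions -> health scoring -> divide indicators -> deprivation indices
#' (with univariate screening) -> standardized regressions (with optional
#' subgroups) -> matched sensitivity analysis. Per-stage CSV/JSON artifacts
#' and a manifest are written under `config$outdir`; rerunning with an
#' identical config and seed reproduces every artifact byte-for-byte.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one). `outdir` must be set.
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$outdir)) stop("config$outdir must be set", call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  manifest <- list(package = "digigap",
                   version = as.character(utils::packageVersion("digigap")),
                   seed = config$seed, wave = config$wave, stages = list())
  results <- list()
  stage <- function(name, n_in, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(stage = name, status = "failed",
                                       error = conditionMessage(e))
      write_json_artifact(manifest, out("manifest.json"))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(stage = name, status = "ok",
                                     n_in = n_in, n_out = res$n_out)
    res$value
  }

  # 1. cohort -----------------------------------------------------------
  cohort <- stage("cohort", 0L, {
    coh <- if (!is.null(config$input)) {
      utils::read.csv(config$input)
    } else {
      generate_cohort(synth_config(
        n = config$n, seed = config$seed,
        treatment_effect_tau = config$treatment_effect_tau,
        confounding_strength = config$confounding_strength,
        missing_rate = config$missing_rate, wave = config$wave,
        tau_rural_only = config$tau_rural_only))
    }
    utils::write.csv(coh, out("cohort.csv"), row.names = FALSE)
    write_json_artifact(cohort_dictionary(), out("cohort_dictionary.json"))
    list(value = coh, n_out = nrow(coh))
  })

  # 2. exclusions -------------------------------------------------------
  cohort <- stage("exclusions", nrow(cohort), {
    rep_ <- exclusion_report(cohort, min_age = 50,
                             key_vars = c("age", "sex", "income"))
    utils::write.csv(rep_, out("exclusions.csv"), row.names = FALSE)
    keep <- !is.na(cohort$age) & cohort$age >= 50
    list(value = cohort[keep, , drop = FALSE], n_out = sum(keep))
  })

  # 3. scores -----------------------------------------------------------
  scored <- stage("scores", nrow(cohort), {
    s <- score_health(cohort)
    list(value = s, n_out = nrow(s))
  })

  # 4. divide -----------------------------------------------------------
  scored <- stage("divide", nrow(scored), {
    s <- derive_divide(scored)
    utils::write.csv(s, out("scored.csv"), row.names = FALSE)
    list(value = s, n_out = nrow(s))
  })

  # 5. deprivation + univariate screen ----------------------------------
  depr <- stage("deprivation", nrow(scored), {
    summ <- list()
    tabs <- scored
    for (dim in config$dimensions) {
      ycol <- paste0("oriented_", dim)
      okrows <- which(!is.na(tabs[[ycol]]))
      k <- kakwani_rd(tabs[[ycol]][okrows], dimension = dim)
      rdcol <- paste0("rd_", dim)
      tabs[[rdcol]] <- NA_real_
      tabs[[rdcol]][okrows] <- k$rd
      summ[[dim]] <- list(n = k$n, mu = k$mu, gini = mean(k$rd))
    }
    write_json_artifact(summ, out("deprivation_summary.json"))
    uni <- univariate_screen(
      tabs, "access",
      vars = c("sex", "age", "marital", "education", "hukou", "chronic",
               "disability", "intergenerational_support", "income",
               "outpatient_visits"))
    utils::write.csv(uni, out("univariate.csv"), row.names = FALSE)
    utils::write.csv(tabs, out("deprivation.csv"), row.names = FALSE)
    list(value = tabs, n_out = nrow(tabs))
  })

  # 6. models -----------------------------------------------------------
  models <- stage("models", nrow(depr), {
    rows <- list()
    fits <- list()
    for (dim in config$dimensions) {
      for (expo in config$exposures) {
        fit <- fit_cohort(cohort, dim, exposure = expo)
        key <- paste(dim, expo, sep = ".")
        fits[[key]] <- fit
        tab <- fit$coefficients
        rows[[key]] <- data.frame(dimension = dim, exposure = expo,
                                  subgroup = "(all)", term = tab$term,
                                  beta = tab$beta, se = tab$se, p = tab$p,
                                  r_squared = fit$r.squared, n = fit$n)
        for (sg in config$subgroups) {
          dat <- prepare_analysis(cohort, dim, exposure = expo)
          spl <- if (sg == "age") age_band(dat$age) else dat[[sg]]
          f <- stats::reformulate(
            c(if (expo == "access") "access" else "use",
              setdiff(control_terms(), if (sg == "hukou") "hukou" else sg)),
            response = "rd")
          sfits <- subgroup_fit(f, dat, spl,
                                exposure = if (expo == "access") "access"
                                           else "use",
                                min_n = config$min_subgroup)
          for (lev in names(sfits)) {
            st <- sfits[[lev]]$coefficients
            rows[[paste(key, sg, lev)]] <- data.frame(
              dimension = dim, exposure = expo,
              subgroup = paste0(sg, "=", lev), term = st$term,
              beta = st$beta, se = st$se, p = st$p,
              r_squared = sfits[[lev]]$r.squared, n = sfits[[lev]]$n)
          }
        }
      }
    }
    tidy <- do.call(rbind, rows)
    rownames(tidy) <- NULL
    utils::write.csv(tidy, out("models.csv"), row.names = FALSE)
    list(value = fits, n_out = length(fits))
  })

  # 7. psm --------------------------------------------------------------
  psm <- NULL
  if (isTRUE(config$psm)) {
    psm <- stage("psm", nrow(depr), {
      atts <- list()
      bal_rows <- list()
      pair_rows <- list()
      for (dim in config$dimensions) {
        for (expo in config$exposures) {
          m <- rd_psm(cohort, dim, exposure = expo,
                      caliper = config$psm_caliper)
          key <- paste(dim, expo, sep = ".")
          atts[[key]] <- list(dimension = dim, exposure = expo,
                              treated_mean = m$treated_mean,
                              control_mean = m$control_mean,
                              att = m$att, se = m$att_se, p = m$att_p,
                              n_pairs = m$n_pairs,
                              dropped_treated = m$dropped_treated)
          b <- as.data.frame(m$balance)
          b$dimension <- dim; b$exposure <- expo
          bal_rows[[key]] <- b
          pr <- m$pairs; pr$dimension <- dim; pr$exposure <- expo
          pair_rows[[key]] <- pr
        }
      }
      write_json_artifact(atts, out("att.json"))
      utils::write.csv(do.call(rbind, bal_rows), out("balance.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, pair_rows), out("pairs.csv"),
                       row.names = FALSE)
      list(value = atts, n_out = length(atts))
    })
  }

  write_json_artifact(manifest, out("manifest.json"))
  invisible(list(manifest = manifest, cohort = cohort, scored = depr,
                 models = models, psm = psm))
}
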