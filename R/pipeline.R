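## Pipeline orchestration: simulate -> score -> endpoints -> fit ->
## interact -> orm -> report, with a reproducibility manifest.

pipeline_stages <- c("simulate", "score", "endpoints", "fit", "interact",
                     "orm", "report")

#' Run the gene-lifestyle analysis pipeline
#'
#' Executes the requested stages in their canonical order, writing every
#' artifact (tab-delimited tables, JSON metadata) to `out_dir` together with
#' a run manifest (config hash, seed, per-file MD5 digests, package version,
#' timestamp). Re-running with the same config and seed reproduces
#' byte-identical analytic outputs.
#'
#' @param config A [sim_config()] (or a full plain list with the same
#'   fields, which is validated); ignored for the simulate stage when
#'   `cohort_file` is supplied.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `simulate`, `score`, `endpoints`, `fit`,
#'   `interact`, `orm`, `report`.
#' @param endpoint `"incident"` or `"prevalent"` for the joint grid /
#'   isolated effects.
#' @param weighted Also compute weighted-score analyses.
#' @param cohort_file Optional pre-existing cohort TSV; skips simulation.
#' @param interaction_ci,interaction_B CI method and bootstrap size for the
#'   additive-interaction decomposition.
#' @return The run manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("gxlife_run_"),
                         stages = pipeline_stages,
                         endpoint = c("incident", "prevalent"),
                         weighted = FALSE, cohort_file = NULL,
                         interaction_ci = c("bootstrap", "delta", "none"),
                         interaction_B = 1000) {
  endpoint <- match.arg(endpoint)
  interaction_ci <- match.arg(interaction_ci)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop_gx("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (!inherits(config, "sim_config")) {
    class(config) <- "sim_config"
    config$n_participants <- config$n_participants %||% -1
    config$seed <- config$seed %||% 1L
  }
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(out_dir, f)
  manifest <- list(package = "gxlife",
                   version = as.character(utils::packageVersion("gxlife")),
                   seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = list())
  record <- function(stage, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(outputs = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files))))
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(failed = TRUE,
                                      error = conditionMessage(err))
    manifest$failed_stage <<- stage
    write_manifest()
    stop_gx("stage '%s' failed: %s", stage, conditionMessage(err))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  cohort <- NULL
  if (!is.null(cohort_file)) {
    cohort <- read_cohort(cohort_file)
    stages <- setdiff(stages, "simulate")
  }

  if ("simulate" %in% stages) {
    tryCatch({
      cohort <- generate_cohort(config)
      if (config$n_orm > 0) cohort <- simulate_orm_endpoints(cohort, config)
      cohort <- inject_missingness(cohort, config)
      write_cohort(cohort, art("cohort.tsv"))
      record("simulate", art(c("cohort.tsv", "cohort.tsv.provenance.json")))
    }, error = function(e) fail("simulate", e))
  }
  if (is.null(cohort)) stop_gx("no cohort: run the simulate stage or pass cohort_file")

  if ("endpoints" %in% stages) {
    tryCatch({
      ex <- apply_exclusions(cohort)
      cohort <- ex$cohort
      write_ledger(ex$ledger, art("exclusion_ledger.json"))
      record("endpoints", art("exclusion_ledger.json"))
    }, error = function(e) fail("endpoints", e))
  }

  weights <- NULL
  if ("score" %in% stages) {
    tryCatch({
      cohort <- add_genetic_risk(cohort)
      cohort <- add_lifestyle(cohort)
      weights <- estimate_weights(cohort)
      cohort <- add_lifestyle(cohort, weights = weights)
      write_weights(weights, art("lifestyle_weights.json"))
      write_cohort(cohort, art("cohort_scored.tsv"))
      record("score", art(c("lifestyle_weights.json", "cohort_scored.tsv")))
    }, error = function(e) fail("score", e))
  }

  if ("fit" %in% stages) {
    tryCatch({
      grid <- joint_category_grid(cohort, endpoint, weighted = weighted)
      utils::write.table(as.data.frame(grid), art("joint_grid.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (dom in c("genetic", "lifestyle")) {
        iso <- isolated_effect(cohort, endpoint, dom, weighted = weighted)
        tab <- as.data.frame(iso)
        tab$trend_p <- attr(iso, "trend_p")
        utils::write.table(tab, art(sprintf("isolated_%s.tsv", dom)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      rm_fit <- fit_risk_model(cohort, weighted = weighted)
      curve <- risk_gradient_curve(rm_fit)
      utils::write.table(as.data.frame(curve), art("risk_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("fit", art(c("joint_grid.tsv", "isolated_genetic.tsv",
                          "isolated_lifestyle.tsv", "risk_curve.tsv")))
    }, error = function(e) fail("fit", e))
  }

  if ("interact" %in% stages) {
    tryCatch({
      mt <- multiplicative_test(cohort)
      jsonlite::write_json(list(term = mt$term, coefficient = mt$coefficient,
                                se = mt$se, p = mt$p, estimable = mt$estimable),
                           art("multiplicative.json"), auto_unbox = TRUE,
                           digits = NA)
      dec <- gxe_interaction(cohort, ci = interaction_ci, B = interaction_B,
                             seed = config$seed)
      write_decomposition(dec, art("decomposition.json"), art("decomposition.tsv"))
      record("interact", art(c("multiplicative.json", "decomposition.json",
                               "decomposition.tsv")))
    }, error = function(e) fail("interact", e))
  }

  if ("orm" %in% stages && length(orm_endpoints(cohort))) {
    tryCatch({
      scan <- orm_association_scan(cohort)
      utils::write.table(as.data.frame(scan), art("orm_scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sub <- orm_lifestyle_subgroups(cohort)
      utils::write.table(as.data.frame(sub), art("orm_subgroups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      med <- orm_bmi_adjusted_scan(cohort)
      utils::write.table(as.data.frame(med), art("orm_bmi_adjusted.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("orm", art(c("orm_scan.tsv", "orm_subgroups.tsv",
                          "orm_bmi_adjusted.tsv")))
    }, error = function(e) fail("orm", e))
  }

  write_manifest()
  if ("report" %in% stages) {
    tryCatch({
      pipeline_report(out_dir)
      record("report", art("summary.txt"))
      write_manifest()
    }, error = function(e) fail("report", e))
  }
  manifest <- structure(manifest, class = "run_manifest")
  invisible(manifest)
}

#' Render the plain-text pipeline report
#'
#' Reads the artifacts in a run directory and writes `summary.txt`. Required
#' artifacts (the manifest) raise a named error if absent; optional sections
#' (risk curve, decomposition, morbidity scan) are omitted with a warning.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Path to `summary.txt`, invisibly.
#' @export
pipeline_report <- function(run_dir) {
  art <- function(f) file.path(run_dir, f)
  if (!file.exists(art("manifest.json")))
    stop_gx("missing artifact: manifest.json")
  lines <- c("gxlife pipeline summary", strrep("=", 23))
  if (file.exists(art("exclusion_ledger.json"))) {
    led <- jsonlite::read_json(art("exclusion_ledger.json"), simplifyVector = TRUE)
    lines <- c(lines, sprintf("Exclusions: %d -> %d participants",
                              led$initial_n, led$final_n))
  }
  if (file.exists(art("joint_grid.tsv"))) {
    grid <- utils::read.delim(art("joint_grid.tsv"))
    ref <- grid$genetic == "low" & grid$lifestyle == "healthy"
    lines <- c(lines, "", sprintf("Joint grid: %d cells (%d reference)",
                                  nrow(grid), sum(ref)),
               utils::capture.output(print(grid, row.names = FALSE)))
  } else warning("report: joint_grid.tsv absent, section omitted")
  if (file.exists(art("risk_curve.tsv"))) {
    cv <- utils::read.delim(art("risk_curve.tsv"))
    lines <- c(lines, "",
               sprintf("Risk by age 75: median healthy %.2f%%, median poor %.2f%%",
                       stats::median(cv$healthy), stats::median(cv$poor)))
  } else warning("report: risk_curve.tsv absent, section omitted")
  if (file.exists(art("decomposition.json"))) {
    dec <- jsonlite::read_json(art("decomposition.json"), simplifyVector = TRUE)
    ap_sum <- sum(unlist(dec[c("AP_G", "AP_L", "AP_I")]))
    lines <- c(lines, "",
               sprintf("RERI %.3f; AP genetic %.1f%%, lifestyle %.1f%%, interaction %.1f%% (sum %.6f)",
                       dec$RERI, 100 * dec$AP_G, 100 * dec$AP_L, 100 * dec$AP_I,
                       ap_sum))
  } else warning("report: decomposition.json absent, section omitted")
  if (file.exists(art("orm_scan.tsv"))) {
    scan <- utils::read.delim(art("orm_scan.tsv"))
    lines <- c(lines, "",
               sprintf("Morbidity scan: %d endpoints, %d replicated (nominal), %d Bonferroni",
                       nrow(scan), sum(scan$replicated, na.rm = TRUE),
                       sum(scan$bonferroni, na.rm = TRUE)))
  } else warning("report: orm_scan.tsv absent, section omitted")
  writeLines(lines, art("summary.txt"))
  invisible(art("summary.txt"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("gxlife run (v%s), seed %d, config %s\n", x$version, x$seed,
              substr(x$config_hash, 1, 8)))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    if (isTRUE(s$failed)) {
      cat(sprintf("  %-10s FAILED: %s\n", st, s$error))
    } else {
      cat(sprintf("  %-10s %s\n", st, paste(names(s$outputs), collapse = ", ")))
    }
  }
  invisible(x)
}
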