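#' Run the full signal-detection pipeline
#'
#' Orchestrates simulate/ingest -> MGPS prior fit -> per-drug
#' disproportionality -> strong-condition resolution -> MedDRA aggregation
#' -> demographic and outcome summaries, writing deterministic TSV/JSON
#' artifacts and a machine-readable run manifest. Identical config gives
#' byte-identical outputs. Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param config named list (or path to a YAML/JSON file) with fields:
#' \describe{
#'   \item{source}{a `synthetic_config` object, or a directory of FAERS
#'     ASCII tables, or a list of generator arguments under `synthetic`.}
#'   \item{synonyms}{drug synonym config (named list or file); defaults to
#'     the synthetic catalog when the source is synthetic.}
#'   \item{meddra}{path to a PT/HLGT/SOC TSV, or `"synthetic"` to derive the
#'     map from a synthetic source's event catalog.}
#'   \item{window}{`c(from_year, to_year)` or NULL.}
#'   \item{policy}{combined-signal policy (`"all"`, `"any"`, `"per-method"`).}
#'   \item{top_k}{rows in the top-signal table (default 15).}
#'   \item{out_dir}{output directory.}
#'   \item{drugs}{drug groups to analyze; default: all synonym groups.}
#' }
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        config_error("reading YAML pipeline configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (is.null(config$out_dir)) config_error("config field 'out_dir' is required")
  if (is.null(config$source)) config_error("config field 'source' is required")
  policy <- config$policy %||% "all"
  top_k <- config$top_k %||% 15L

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  on_fail <- function(stage, e) {
    unlink(written)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }

  manifest <- list(policy = policy, top_k = top_k)

  # --- source stage: synthetic generation or directory read ---------------
  synth <- NULL
  tables <- stage("source", {
    src <- config$source
    if (inherits(src, "synthetic_config")) {
      synth <- generate_dataset(src)
      manifest$source <- list(type = "synthetic", seed = src$seed,
                              n_cases = src$n_cases)
      synth$tables
    } else if (is.list(src) && !is.null(src$synthetic)) {
      sc <- do.call(synthetic_config, src$synthetic)
      synth <- generate_dataset(sc)
      manifest$source <- list(type = "synthetic", seed = sc$seed,
                              n_cases = sc$n_cases)
      synth$tables
    } else if (is.character(src)) {
      manifest$source <- list(type = "directory", path = src)
      read_faers_tables(src, window = config$window)
    } else {
      config_error("'source' must be a synthetic_config, a synthetic spec, or a directory")
    }
  })
  synthetic_source <- !is.null(synth)

  synonyms <- stage("synonyms", {
    if (!is.null(config$synonyms)) {
      load_drug_synonyms(config$synonyms)
    } else if (synthetic_source) {
      load_drug_synonyms(config_of(synth, config)$drug_catalog)
    } else {
      config_error("'synonyms' is required for a directory source")
    }
  })

  meddra <- stage("meddra", {
    m <- config$meddra
    if (is.null(m) || identical(m, "synthetic")) {
      if (!synthetic_source) config_error("'meddra' map file is required for a directory source")
      synthetic_meddra(config_of(synth, config))
    } else {
      load_meddra_map(m)
    }
  })

  cases <- stage("ingest", assemble_cases(tables, synonyms))
  raw_rows <- if (!is.null(tables$DEMO)) nrow(tables$DEMO) else NA_integer_
  manifest$counts <- list(
    demo_rows = raw_rows,
    outside_window = if (!is.null(tables$log)) tables$log$outside_window else 0L,
    removed_duplicates = cases$log$removed_duplicates,
    dropped_no_events = cases$log$dropped_no_events,
    cases_analyzed = nrow(cases$demo)
  )

  drugs <- config$drugs %||% names(synonyms$groups)
  prior <- stage("mgps-prior", fit_database_prior(cases))
  manifest$mgps_prior <- as.list(coef(prior))

  fits <- stage("signals", {
    f <- lapply(drugs, function(d) {
      disprop(cases, d, prior = prior, policy = policy, meddra = meddra)
    })
    names(f) <- drugs
    resolve_condition_d(f)
  })

  manifest$drugs <- list()
  for (d in drugs) {
    stage(paste0("report-", d), {
      fit <- fits[[d]]
      s <- fit$stats
      emit(format_signal_table(s), sprintf("signals_%s.tsv", d))
      sig <- s[!is.na(s$signal) & s$signal, , drop = FALSE]
      emit(format_signal_table(rank_top_k(sig, top_k)), sprintf("top%d_%s.tsv", top_k, d))
      emit(aggregate_signals(sig, meddra, "SOC"), sprintf("soc_%s.tsv", d))
      emit(aggregate_signals(sig, meddra, "HLGT"), sprintf("hlgt_%s.tsv", d))
      if (fit$cohort_size > 0) {
        cs <- summarize_cohort(cases, d)
        jsonlite::write_json(unclass_deep(cs),
                             file.path(config$out_dir, sprintf("cohort_%s.json", d)),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        written <- c(written, file.path(config$out_dir, sprintf("cohort_%s.json", d)))
        oc <- tryCatch(summarize_outcomes(cases, d), error = function(e) NULL)
        if (!is.null(oc)) emit(oc, sprintf("outcomes_%s.tsv", d))
      }
      manifest$drugs[[d]] <- list(
        cohort_size = fit$cohort_size,
        pts_evaluated = nrow(s),
        signals = sum(sig$signal),
        signal_cases = sum(sig$a)
      )
    })
  }

  manifest$n_database <- nrow(cases$demo)
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# the synthetic_config used by a pipeline run (for catalogs)
config_of <- function(synth, config) {
  src <- config$source
  if (inherits(src, "synthetic_config")) return(src)
  do.call(synthetic_config, src$synthetic)
}

format_signal_table <- function(s) {
  cols <- intersect(c("pt", "hlgt", "soc", "a", "b", "c", "d", "n",
                      "ror", "ror_ci_low", "ror_ci_high", "prr", "chi2",
                      "ic", "ic_minus_2sd", "ebgm", "eb05", "zero_flag",
                      "ror_sig", "prr_sig", "bcpnn_sig", "mgps_sig",
                      "signal", "strong_condition"), names(s))
  out <- s[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & !names(out) %in% c("a", "b", "c", "d", "n")
  out[num] <- lapply(out[num], function(x) signif(x, 8))
  out
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
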