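#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> rank -> select -> predict -> report as one
#' reproducible run.  The configuration (a named list, or the path of a
#' YAML/JSON file) has a single master `seed` from which each stage derives
#' its own substream, so stages can be re-run in isolation; identical
#' configurations produce identical artefacts (checksummed in the manifest).
#'
#' Config fields (all optional except `out_dir`):
#' \describe{
#'   \item{out_dir}{output directory (created if needed)}
#'   \item{seed}{master seed (default 1)}
#'   \item{stages}{character subset of `c("simulate", "rank", "predict",
#'     "report")`; later stages require the earlier ones' outputs}
#'   \item{simulate}{`list(n, set)` -- cohort size and `"discovery"` or
#'     `"model"` paper-like configuration}
#'   \item{genotypes, phenotypes}{TSV paths used instead of simulation}
#'   \item{rank}{`list(reps, cutoff)`}
#'   \item{predict}{`list(panel, system)`}
#'   \item{report}{`list(policies)`, e.g. `list("pmax", 0.7)`}
#' }
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return The run manifest (named list; also written as `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "rank", "predict", "report")
  artefacts <- character(0)
  log_msg <- function(...) inform(paste0("[ec11] ", ...))

  # resolve the panel up front so a bad name fails before any compute
  predict_cfg <- config$predict %||% list()
  panel <- get_panel(predict_cfg$panel %||% "ec11")
  system <- predict_cfg$system %||% "two_category"
  if (!system %in% c("quantitative", "two_category", "three_category")) {
    abort(paste0("unknown reporting system: ", system))
  }

  if ("simulate" %in% stages) {
    sim_cfg <- config$simulate %||% list()
    cfg <- paper_like_config(
      n = sim_cfg$n %||% 523,
      seed = derive_seed(seed, 11L),
      set = sim_cfg$set %||% "model"
    )
    log_msg("simulating cohort (n = ", cfg$n_samples, ", set = ", sim_cfg$set %||% "model", ")")
    cht <- simulate_cohort(cfg)
    write_cohort(
      cht,
      file.path(out_dir, "genotypes.tsv"),
      file.path(out_dir, "phenotypes.tsv")
    )
    artefacts <- c(artefacts, "genotypes.tsv", "phenotypes.tsv")
  } else {
    cht <- read_cohort(config$genotypes, config$phenotypes)
  }

  if ("rank" %in% stages) {
    rank_cfg <- config$rank %||% list()
    ranking_panel <- if (is.null(rank_cfg$panel)) {
      if (all(unlist(panel_discovery44()$variables$rsids) %in%
        names(cht$genotypes))) {
        panel_discovery44()
      } else {
        panel # fall back to the prediction panel's variants
      }
    } else {
      get_panel(rank_cfg$panel)
    }
    log_msg("ranking ", nrow(ranking_panel$variables), " variables (",
      rank_cfg$reps %||% 100, " replicates)")
    imp <- rank_variants(cht,
      panel = ranking_panel,
      n_reps = rank_cfg$reps %||% 100, seed = derive_seed(seed, 13L)
    )
    readr::write_tsv(as_tibble(imp), file.path(out_dir, "importance.tsv"),
      progress = FALSE
    )
    selected <- select_top(imp, cutoff = rank_cfg$cutoff %||% 0.003)
    writeLines(selected, file.path(out_dir, "selected.txt"))
    artefacts <- c(artefacts, "importance.tsv", "selected.txt")
  }

  if ("predict" %in% stages) {
    log_msg("LOOCV prediction (panel ", panel$name, ", ", system, " system)")
    loocv <- loocv_predict(cht, panel, system)
    readr::write_tsv(loocv$predictions, file.path(out_dir, "loocv.tsv"),
      progress = FALSE
    )
    jsonlite::write_json(
      list(
        error = as.numeric(loocv$error), n = loocv$n,
        panel = panel$name, system = system,
        error_scale = if (system == "quantitative") "transformed (logit) PIE" else "mean -log p"
      ),
      file.path(out_dir, "loocv_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    artefacts <- c(artefacts, "loocv.tsv", "loocv_summary.json")
  }

  if ("report" %in% stages) {
    if (!"predict" %in% stages) {
      abort("the report stage needs the predict stage in the same run")
    }
    if (system == "quantitative") {
      log_msg("skipping report stage: quantitative system has no category calls")
    } else {
      policies <- (config$report %||% list())$policies %||% list("pmax", 0.7)
      reports <- purrr::map(policies, function(thr) {
        rep <- report(loocv, call_policy(thr))
        list(
          policy = if (identical(thr, "pmax")) "pmax" else thr,
          outcome = rep$outcome, per_class = rep$per_class
        )
      })
      jsonlite::write_json(reports, file.path(out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA
      )
      artefacts <- c(artefacts, "report.json")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ec11")),
    seed = seed,
    stages = stages,
    config = config[setdiff(names(config), "out_dir")],
    artefacts = purrr::map(
      setNames(artefacts, artefacts),
      ~ unname(tools::md5sum(file.path(out_dir, .x)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a named list or a file path")
  if (is.null(config$out_dir)) abort("config needs an out_dir")
  config
}
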