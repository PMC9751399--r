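# Pipeline orchestration: read inputs, run the stages in the published order
# (metabolome screen -> correlation table -> over-representation ->
# expression associations / GSEA -> synergy), write result tables and a run
# manifest.

default_pipeline_params <- function() {
  list(
    alpha = 0.05,
    adjust = "none",
    log10_ic50 = FALSE,
    gsea = list(n_perm = 1000, weight_p = 1, min_size = 15, max_size = 500,
                phenotype = "mtx_ic50_96_nM"),
    synergy = list(time_h = NULL, threshold = 0.25, metric = "ld50",
                   method = "auto")
  )
}

#' Read and validate a pipeline configuration file
#'
#' YAML key-value file with an `inputs:` block (paths to `metabolites`,
#' `phenotypes`, `metabolite_sets`, `expression`, `gene_sets`, `viability`;
#' all optional -- stages without inputs are skipped), an optional
#' `combinations:` list for the synergy stage (each entry: `drug_a`,
#' `drug_b`, `combo`, `ratio_rho`, optional `dose_reference`), and optional
#' parameter overrides (`alpha`, `adjust`, `log10_ic50`, `gsea:`,
#' `synergy:`, `seed`).
#'
#' @param path Path to the YAML file.
#' @returns A `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("config file not found: %s", path),
               class = "metresist_config_error")
  }
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw, base_dir = dirname(path))
}

as_pipeline_config <- function(raw, base_dir = ".") {
  params <- utils::modifyList(default_pipeline_params(),
                              raw[setdiff(names(raw),
                                          c("inputs", "combinations", "seed"))])
  inputs <- raw$inputs %||% list()
  inputs <- purrr::map(inputs, function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  })
  if (!is_scalar_number(params$alpha) || params$alpha <= 0 || params$alpha >= 1) {
    stop_input("config: alpha must lie in (0, 1)",
               class = "metresist_config_error")
  }
  if (!params$adjust %in% c("none", "bh")) {
    stop_input("config: adjust must be 'none' or 'bh'",
               class = "metresist_config_error")
  }
  structure(
    list(inputs = inputs, combinations = raw$combinations %||% list(),
         params = params, seed = raw$seed %||% 1L),
    class = "pipeline_config"
  )
}

require_input <- function(config, name, stage) {
  path <- config$inputs[[name]]
  if (is.null(path)) {
    stop_input(sprintf("config: stage '%s' is enabled but input '%s' is missing",
                       stage, name),
               class = "metresist_config_error")
  }
  if (!file.exists(path)) {
    stop_input(sprintf("config: input '%s' does not exist: %s", name, path),
               class = "metresist_config_error")
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are configured and writes the result
#' tables plus a reproducibility manifest to `out_dir`. Stages: metabolome
#' screen (`modulated.tsv`), concentration-versus-phenotype correlations
#' (`correlation_table.tsv`), metabolite-set over-representation (`ora.tsv`),
#' gene-phenotype correlations (`gene_correlations.tsv`), continuous-phenotype
#' GSEA (`gsea_results.tsv`), combination synergy (`synergy.tsv`), and
#' `manifest.json`. A stage error is logged with the stage name; partial
#' outputs are retained and the error is rethrown.
#'
#' @param config A `"pipeline_config"`, a path to a YAML config, or a plain
#'   list in the same shape.
#' @param out_dir Output directory (created if missing).
#' @param stages Stages to run; default all available. Subset of
#'   `c("metabolome", "correlate", "ora", "expression", "gsea", "synergy")`.
#' @returns Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("metabolome", "correlate", "ora",
                                    "expression", "gsea", "synergy")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- as_pipeline_config(config)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  params <- config$params
  inputs <- config$inputs
  have <- function(name) {
    !is.null(inputs[[name]]) && file.exists(inputs[[name]])
  }

  # validate the configuration up front, before any compute
  if ("gsea" %in% stages && !is.null(inputs$gene_sets) && is.null(inputs$expression)) {
    stop_input("config: gsea stage requires an 'expression' input",
               class = "metresist_config_error")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  run_stage <- function(stage, body) {
    tryCatch(body(), error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   class = "metresist_stage_error", parent = e)
    })
  }

  panel <- if (have("metabolites")) read_metabolite_table(inputs$metabolites)
  phenotypes <- if (have("phenotypes")) read_phenotype_table(inputs$phenotypes)

  screen <- NULL
  if ("metabolome" %in% stages && !is.null(panel)) {
    run_stage("metabolome", function() {
      screen <<- metabolome_screen(panel, alpha = params$alpha)
      if (params$adjust == "bh") {
        screen$q_bh <<- p.adjust(screen$p_two_sided, method = "BH")
      }
      outputs$modulated <<- write_table(screen, file.path(out_dir, "modulated.tsv"))
    })
  }

  if ("correlate" %in% stages && !is.null(panel) && !is.null(phenotypes)) {
    run_stage("correlate", function() {
      corr <- correlation_screen(
        panel, phenotypes,
        phenotype_names = intersect(
          c("doubling_time_days", "mtx_ic50_48_nM", "mtx_ic50_96_nM"),
          names(phenotypes)),
        log10_ic50 = params$log10_ic50
      )
      if (params$adjust == "bh") {
        corr$q_bh <- p.adjust(corr$p_two_sided, method = "BH")
      }
      outputs$correlation_table <<- write_table(
        corr, file.path(out_dir, "correlation_table.tsv"))
    })
  }

  if ("ora" %in% stages && !is.null(screen) && have("metabolite_sets")) {
    run_stage("ora", function() {
      sets <- read_gmt(inputs$metabolite_sets)
      cls <- classify_modulated(screen, alpha = params$alpha)
      ora <- msea_ora(c(cls$increased, cls$decreased),
                      background = unique(screen$metabolite),
                      sets = purrr::map(sets, tolower))
      outputs$ora <<- write_table(ora, file.path(out_dir, "ora.tsv"))
    })
  }

  if (any(c("expression", "gsea") %in% stages) && have("expression") &&
      !is.null(phenotypes)) {
    expr <- read_expression_matrix(inputs$expression)
    phen_col <- params$gsea$phenotype
    check_columns(phenotypes, phen_col, "phenotype table")
    phen_vec <- setNames(phenotypes[[phen_col]], phenotypes$cell_line)

    if ("expression" %in% stages) {
      run_stage("expression", function() {
        gc <- gene_phenotype_correlations(expr, phen_vec,
                                          phenotype_name = phen_col)
        outputs$gene_correlations <<- write_table(
          gc, file.path(out_dir, "gene_correlations.tsv"))
      })
    }
    if ("gsea" %in% stages && have("gene_sets")) {
      run_stage("gsea", function() {
        sets <- read_gmt(inputs$gene_sets)
        res <- gsea_permutation(
          expr, phen_vec, sets,
          n_perm = params$gsea$n_perm, weight_p = params$gsea$weight_p,
          min_size = params$gsea$min_size, max_size = params$gsea$max_size,
          seed = config$seed
        )
        outputs$gsea_results <<- write_table(
          res, file.path(out_dir, "gsea_results.tsv"))
      })
    }
  }

  if ("synergy" %in% stages && have("viability") &&
      length(config$combinations) > 0) {
    run_stage("synergy", function() {
      viab <- read_viability_table(inputs$viability)
      rows <- purrr::map(config$combinations, function(cmb) {
        design <- combination_design(
          drug_a = cmb$drug_a, drug_b = cmb$drug_b,
          ratio_rho = cmb$ratio_rho,
          dose_reference = cmb$dose_reference %||% "drug_a"
        )
        cells <- unique(viab$cell_line[viab$drug == cmb$combo])
        purrr::map(cells, function(cl) {
          sub <- function(d) dplyr::filter(viab, .data$drug == d,
                                           .data$cell_line == cl)
          synergy_score(sub(cmb$drug_a), sub(cmb$drug_b), sub(cmb$combo),
                        design, t = params$synergy$time_h,
                        method = params$synergy$method,
                        threshold = params$synergy$threshold)
        }) |> dplyr::bind_rows()
      })
      outputs$synergy <<- write_table(dplyr::bind_rows(rows),
                                      file.path(out_dir, "synergy.tsv"))
    })
  }

  manifest <- list(
    tool = "metresist",
    version = as.character(packageVersion("metresist")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    parameters = params,
    inputs = purrr::map(
      purrr::keep(inputs, ~ !is.null(.x) && file.exists(.x)),
      ~ list(path = .x, md5 = unname(tools::md5sum(.x)))
    ),
    outputs = purrr::map_chr(outputs, basename)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  invisible(outputs)
}
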