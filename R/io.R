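# Readers and writers for the pipeline's tab-separated table formats and the
# GMT gene-set dialect. All tables are UTF-8, tab-delimited with a header row
# and decimal points; CSV is accepted when the file extension says so.

read_delim_by_ext <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("file not found: %s", path),
               class = "metresist_input_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

# Documented condition aliases; matching is case-insensitive.
condition_aliases <- c(
  control = "control", ctrl = "control", untreated = "control",
  vehicle = "control", dmso = "control",
  treated = "treated", mtx = "treated", drug = "treated",
  treatment = "treated"
)

check_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  if (is.numeric(v)) return(df)
  parsed <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(parsed) & !is.na(v))
  if (length(bad) > 0) {
    stop_input(sprintf(
      "non-numeric %s in %s at data row(s): %s", col, path,
      paste(head(bad, 5), collapse = ", ")),
      class = "metresist_parse_error")
  }
  df[[col]] <- parsed
  df
}

#' Read a long-format metabolite concentration table
#'
#' Expects columns `cell_line`, `metabolite`, `condition`, `replicate`,
#' `concentration` (TSV, or CSV by extension). Condition labels are mapped to
#' `control` / `treated` through a documented alias table (`untreated`,
#' `vehicle`, `dmso`, `ctrl` -> control; `mtx`, `drug`, `treatment` ->
#' treated); unknown labels and duplicated
#' (cell_line, metabolite, condition, replicate) rows are rejected.
#'
#' @param path Path to the table.
#' @returns A validated metabolite panel tibble.
#' @export
read_metabolite_table <- function(path) {
  df <- read_delim_by_ext(path)
  check_columns(df, c("cell_line", "metabolite", "condition", "replicate",
                      "concentration"), path)
  df <- check_numeric_column(df, "concentration", path)
  df$cell_line <- trimws(df$cell_line)
  cond <- unname(condition_aliases[tolower(trimws(df$condition))])
  unknown <- unique(df$condition[is.na(cond)])
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown condition label(s) in %s: %s", path,
                       paste(unknown, collapse = ", ")),
               class = "metresist_schema_error")
  }
  df$condition <- cond
  key <- df[c("cell_line", "metabolite", "condition", "replicate")]
  if (anyDuplicated(key) > 0) {
    stop_input(sprintf("duplicated (cell_line, metabolite, condition, replicate) row(s) in %s",
                       path),
               class = "metresist_schema_error")
  }
  as_tibble(df)
}

#' Read a per-cell-line phenotype table
#'
#' Expects columns `cell_line`, `doubling_time_days`, `mtx_ic50_48_nM`,
#' `mtx_ic50_96_nM`; a `lineage` column is optional.
#'
#' @param path Path to the table.
#' @returns A phenotype tibble.
#' @export
read_phenotype_table <- function(path) {
  df <- read_delim_by_ext(path)
  check_columns(df, c("cell_line", "doubling_time_days", "mtx_ic50_48_nM",
                      "mtx_ic50_96_nM"), path)
  for (col in c("doubling_time_days", "mtx_ic50_48_nM", "mtx_ic50_96_nM")) {
    df <- check_numeric_column(df, col, path)
  }
  df$cell_line <- trimws(df$cell_line)
  as_tibble(df)
}

#' Read a wide log2 expression matrix
#'
#' First column `gene_symbol`, remaining columns one per cell line. Gene
#' symbols are uppercased; duplicate symbols are collapsed to the
#' highest-mean row (probe-to-symbol collapse by maximum value).
#'
#' @param path Path to the table.
#' @returns A wide expression tibble.
#' @export
read_expression_matrix <- function(path) {
  df <- read_delim_by_ext(path)
  check_columns(df, "gene_symbol", path)
  df$gene_symbol <- toupper(trimws(df$gene_symbol))
  value_cols <- setdiff(names(df), "gene_symbol")
  for (col in value_cols) df <- check_numeric_column(df, col, path)
  if (anyDuplicated(df$gene_symbol) > 0) {
    df <- df |>
      dplyr::mutate(.row_mean = rowMeans(dplyr::across(dplyr::all_of(value_cols)),
                                         na.rm = TRUE)) |>
      dplyr::group_by(.data$gene_symbol) |>
      dplyr::slice_max(.data$.row_mean, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".row_mean")
  }
  all_missing <- rowSums(!is.na(df[value_cols])) == 0
  if (any(all_missing)) {
    stop_input(sprintf("all-missing expression row(s) in %s: %s", path,
                       paste(df$gene_symbol[all_missing], collapse = ", ")),
               class = "metresist_schema_error")
  }
  as_tibble(df)
}

#' Read a dose-time viability table
#'
#' Expects columns `drug`, `cell_line`, `dose`, `dose_units`, `time_h`,
#' `replicate`, `value`, `value_kind` (`raw` or `live_fraction`). Rows with
#' `value_kind == "live_fraction"` are validated to lie in `[0, 1]` and
#' returned as a `"viability_surface"`-compatible tibble (column
#' `live_fraction`); raw rows are returned untouched for
#' [normalize_viability()].
#'
#' @param path Path to the table.
#' @returns A tibble; if all rows are live fractions, a
#'   `"viability_surface"`.
#' @export
read_viability_table <- function(path) {
  df <- read_delim_by_ext(path)
  check_columns(df, c("drug", "cell_line", "dose", "dose_units", "time_h",
                      "replicate", "value", "value_kind"), path)
  for (col in c("dose", "time_h", "value")) {
    df <- check_numeric_column(df, col, path)
  }
  bad_kind <- setdiff(unique(df$value_kind), c("raw", "live_fraction"))
  if (length(bad_kind) > 0) {
    stop_input(sprintf("unknown value_kind in %s: %s", path,
                       paste(bad_kind, collapse = ", ")),
               class = "metresist_schema_error")
  }
  df$cell_line <- trimws(df$cell_line)
  if (all(df$value_kind == "live_fraction")) {
    if (any(df$value < -1e-8 | df$value > 1 + 1e-8)) {
      stop_input(sprintf("live fractions outside [0, 1] in %s", path),
                 class = "metresist_schema_error")
    }
    out <- df |>
      dplyr::mutate(live_fraction = pmin(1, pmax(0, .data$value))) |>
      dplyr::select(-"value", -"value_kind")
    class(out) <- c("viability_surface", class(out))
    return(out)
  }
  as_tibble(df)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' uppercased and deduplicated (with a message); duplicate set names get a
#' deterministic numeric suffix; CRLF endings are handled; lines with fewer
#' than 3 fields are a format error reported with the line number.
#'
#' @param path Path to the GMT file.
#' @returns A named list of gene-symbol vectors, with set descriptions in the
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_input(sprintf("file not found: %s", path),
               class = "metresist_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    stop_input(sprintf("empty GMT file: %s", path),
               class = "metresist_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop_input(sprintf("GMT line %d in %s has fewer than 3 tab-separated fields",
                       line_no[short[1]], path),
               class = "metresist_format_error")
  }
  names_raw <- vapply(fields, `[[`, character(1), 1)
  descriptions <- vapply(fields, `[[`, character(1), 2)
  members <- purrr::map(fields, function(f) {
    m <- toupper(trimws(f[-(1:2)]))
    m <- m[nzchar(m)]
    if (anyDuplicated(m) > 0) {
      rlang::inform(sprintf("GMT set '%s': removed %d duplicate member(s)",
                            f[[1]], sum(duplicated(m))))
      m <- unique(m)
    }
    m
  })
  empty <- which(lengths(members) == 0)
  if (length(empty) > 0) {
    stop_input(sprintf("GMT line %d in %s has an empty member list",
                       line_no[empty[1]], path),
               class = "metresist_format_error")
  }
  nm <- names_raw
  if (anyDuplicated(nm) > 0) {
    dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
    nm[dup] <- paste(nm[dup], stats::ave(seq_along(nm), nm, FUN = seq_along)[dup],
                     sep = ".")
  }
  sets <- setNames(members, nm)
  attr(sets, "descriptions") <- setNames(descriptions, nm)
  sets
}

#' Write a result table as UTF-8 TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @returns `path`, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Write a simulated bundle as pipeline input files
#'
#' Writes `metabolites.tsv`, `phenotypes.tsv`, `expression.tsv`,
#' `gene_sets.gmt` and `truth.json` into `dir`.
#'
#' @param bundle A `"panel_bundle"` from [simulate_panel()].
#' @param dir Output directory (created if missing).
#' @returns Named vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "panel_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metabolites = file.path(dir, "metabolites.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_table(bundle$metabolite_panel, paths[["metabolites"]])
  write_table(bundle$phenotypes, paths[["phenotypes"]])
  write_table(bundle$expression, paths[["expression"]])
  gmt_lines <- purrr::imap_chr(bundle$gene_sets, function(members, nm) {
    paste(c(nm, "simulated", members), collapse = "\t")
  })
  writeLines(gmt_lines, paths[["gene_sets"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
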