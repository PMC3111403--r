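#' Read a dose-response CSV
#'
#' Expects UTF-8 CSV with header `compound,dose_um,replicate,response_pct`
#' and "." as decimal separator. Malformed rows (non-numeric dose or
#' response, missing fields) are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `compound` (character), `dose_um`
#'   (double), `replicate` (character), `response_pct` (double).
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  d <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      compound = readr::col_character(),
      dose_um = readr::col_double(),
      replicate = readr::col_character(),
      response_pct = readr::col_double()
    ),
    progress = FALSE
  ))
  need <- c("compound", "dose_um", "replicate", "response_pct")
  if (!all(need %in% names(d))) {
    stop_input(paste0("missing column(s): ",
                      paste(setdiff(need, names(d)), collapse = ", ")))
  }
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    lines <- paste(sprintf("line %d (%s)", probs$row, probs$col),
                   collapse = ", ")
    stop_input(paste0("malformed rows in ", path, ": ", lines))
  }
  d[need]
}

#' Write a dose-response table as CSV
#'
#' @param data Tibble with columns `compound`, `dose_um`, `replicate`,
#'   `response_pct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path) {
  need <- c("compound", "dose_um", "replicate", "response_pct")
  if (!all(need %in% names(data))) {
    stop_input(paste0("missing column(s): ",
                      paste(setdiff(need, names(data)), collapse = ", ")))
  }
  readr::write_csv(data[need], path, progress = FALSE)
  invisible(path)
}

read_one_feature_table <- function(path) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  d <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      feature_id = readr::col_character(),
      gene_id = readr::col_character(),
      ratio = readr::col_double(),
      p_value = readr::col_double()
    ),
    progress = FALSE
  ))
  need <- c("feature_id", "gene_id", "ratio", "p_value")
  if (!all(need %in% names(d))) {
    stop_input(paste0(path, ": missing column(s): ",
                      paste(setdiff(need, names(d)), collapse = ", ")))
  }
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    stop_input(paste0("malformed rows in ", path, ": lines ",
                      paste(unique(probs$row + 1L), collapse = ", ")))
  }
  if (anyDuplicated(d$feature_id)) {
    stop_input(paste0(path, ": duplicated feature_id: ",
                      d$feature_id[duplicated(d$feature_id)][1]))
  }
  d[need]
}

#' Read per-replicate feature tables listed in a manifest
#'
#' The manifest is a YAML file mapping each treatment label to exactly
#' three replicate TSV paths (relative paths are resolved against the
#' manifest's directory). Each TSV has header
#' `feature_id  gene_id  ratio  p_value`. Duplicate features within a
#' file and feature-universe mismatches across the three replicates are
#' rejected.
#'
#' @param manifest Path to the YAML manifest, or a named list mapping
#'   treatment to a character vector of 3 paths.
#' @return A stacked tibble (`treatment`, `replicate`, `feature_id`,
#'   `gene_id`, `ratio`, `p_value`) ready for [filter_transcripts()].
#' @export
read_feature_tables <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1) {
    base <- dirname(manifest)
    m <- yaml::read_yaml(manifest)
    m <- lapply(m, function(paths) {
      ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
    })
  } else if (is.list(manifest) && !is.null(names(manifest))) {
    m <- manifest
  } else {
    stop_input("`manifest` must be a YAML path or a named list of file paths")
  }
  out <- purrr::imap_dfr(m, function(paths, tr) {
    paths <- unlist(paths)
    if (length(paths) != 3) {
      stop_input(sprintf(
        "treatment '%s' lists %d replicate files; exactly 3 are required",
        tr, length(paths)))
    }
    purrr::imap_dfr(setNames(paths, paste0("rep", 1:3)), function(p, rep) {
      dplyr::mutate(read_one_feature_table(p), treatment = tr,
                    replicate = rep, .before = 1)
    })
  })
  # trip the universe check early, per treatment
  out |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_walk(~ invisible(validate_replicate_set(.x)))
  out
}

#' Write a response matrix as value and significance-mask TSVs
#'
#' @param x A `response_matrix` from [assemble_matrix()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"response_matrix"`); writes
#'   `<prefix>_log2.tsv` and `<prefix>_mask.tsv`.
#' @return The two paths, invisibly.
#' @export
write_response_matrix <- function(x, dir, prefix = "response_matrix") {
  if (!inherits(x, "response_matrix")) {
    stop_input("`x` must be a response_matrix")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_log2.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_mask.tsv"))
  readr::write_tsv(x$values, p1, progress = FALSE)
  readr::write_tsv(x$significant, p2, progress = FALSE)
  invisible(c(p1, p2))
}
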