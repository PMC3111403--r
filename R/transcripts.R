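#' Call a single array feature as a responder
#'
#' A feature is a responder when its treated/control ratio shows at least a
#' `fc`-fold change in either direction and its error-model P value is at
#' or below `p_max`: `(ratio >= fc | ratio <= 1/fc) & p <= p_max`. Both
#' thresholds are inclusive.
#'
#' @param ratio Treated/control intensity ratio(s), > 0.
#' @param p_value Per-feature P value(s) in \[0, 1\].
#' @param fc Fold-change threshold (default 2).
#' @param p_max P value threshold (default 0.01).
#' @return A tibble with columns `responder` (logical) and `direction`
#'   (`"up"`, `"down"`, or `NA` for non-responders).
#' @export
#' @examples
#' call_feature(c(2, 0.49, 3), c(0.01, 0.005, 0.02))
call_feature <- function(ratio, p_value, fc = 2, p_max = 0.01) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_input("`ratio` must be finite and > 0")
  }
  if (any(p_value < 0) || any(p_value > 1)) {
    stop_input("`p_value` must lie in [0, 1]")
  }
  responder <- (ratio >= fc | ratio <= 1 / fc) & p_value <= p_max
  tibble(
    responder = responder,
    direction = dplyr::if_else(responder,
                               dplyr::if_else(ratio >= fc, "up", "down"),
                               NA_character_)
  )
}

# signed fold-change display convention: r for r >= 1, -1/r for r < 1,
# so the magnitude is always >= 1
signed_fc <- function(ratio) ifelse(ratio >= 1, ratio, -1 / ratio)

validate_replicate_set <- function(reps) {
  need <- c("replicate", "feature_id", "gene_id", "ratio", "p_value")
  if (!is.data.frame(reps) || !all(need %in% names(reps))) {
    stop_input(paste0("`reps` must be a data frame with columns ",
                      paste(need, collapse = ", ")))
  }
  reps <- dplyr::mutate(reps, replicate = as.character(.data$replicate))
  ids <- unique(reps$replicate)
  if (length(ids) != 3) {
    stop_input(sprintf("expected exactly 3 replicates, got %d (%s)",
                       length(ids), paste(ids, collapse = ", ")))
  }
  dup <- dplyr::count(reps, .data$replicate, .data$feature_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_input(paste0("duplicated feature_id within a replicate: ",
                      paste(head(dup$feature_id, 5), collapse = ", ")))
  }
  universes <- split(reps$feature_id, reps$replicate)
  ref <- sort(universes[[1]])
  for (u in universes[-1]) {
    if (!identical(sort(u), ref)) {
      stop_input("replicates do not share an identical feature_id universe")
    }
  }
  reps
}

#' Keep features responding in the same direction in all three replicates
#'
#' A feature survives when it is a responder (see [call_feature()]) with
#' the same direction in every one of the three replicates. Surviving
#' features carry their ratio, fold change and P value averaged across the
#' replicates.
#'
#' @param reps A data frame of one treatment's three replicate feature
#'   tables stacked: columns `replicate`, `feature_id`, `gene_id`, `ratio`,
#'   `p_value`. The three replicates must cover an identical feature set.
#' @inheritParams call_feature
#' @return A tibble with one row per surviving feature: `feature_id`,
#'   `gene_id`, `direction`, `mean_ratio`, `mean_p`, and `fold_change`
#'   (signed, from the mean ratio).
#' @export
three_replicate_filter <- function(reps, fc = 2, p_max = 0.01) {
  reps <- validate_replicate_set(reps)
  calls <- call_feature(reps$ratio, reps$p_value, fc = fc, p_max = p_max)
  reps |>
    dplyr::mutate(responder = calls$responder, direction = calls$direction) |>
    dplyr::group_by(.data$feature_id, .data$gene_id) |>
    dplyr::summarise(
      survives = all(.data$responder) && dplyr::n_distinct(.data$direction) == 1,
      direction = .data$direction[1],
      mean_ratio = mean(.data$ratio),
      mean_p = mean(.data$p_value),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$survives) |>
    dplyr::mutate(fold_change = signed_fc(.data$mean_ratio)) |>
    dplyr::select("feature_id", "gene_id", "direction",
                  "mean_ratio", "mean_p", "fold_change") |>
    dplyr::arrange(.data$feature_id)
}

#' Resolve surviving features to unambiguous gene-level responses
#'
#' Genes represented by surviving features that disagree in direction are
#' marked `excluded_contradictory` and carry no fold change. For the rest,
#' the representative feature is the one with the smallest mean P value
#' (ties broken lexicographically by `feature_id`), and the gene inherits
#' its signed fold change, mean ratio and mean P.
#'
#' @param surviving Output of [three_replicate_filter()].
#' @return A tibble with one row per gene: `gene_id`, `status`
#'   (`"significant"` or `"excluded_contradictory"`), `feature_id` (the
#'   representative, `NA` if excluded), `direction`, `fold_change`,
#'   `mean_ratio`, `mean_p`, `n_features`.
#' @export
resolve_genes <- function(surviving) {
  need <- c("feature_id", "gene_id", "direction", "mean_ratio", "mean_p")
  if (!all(need %in% names(surviving))) {
    stop_input("`surviving` must come from three_replicate_filter()")
  }
  surviving |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$mean_p, .data$feature_id, .by_group = TRUE) |>
    dplyr::summarise(
      contradictory = dplyr::n_distinct(.data$direction) > 1,
      feature_id = .data$feature_id[1],
      direction = .data$direction[1],
      fold_change = signed_fc(.data$mean_ratio[1]),
      mean_ratio = .data$mean_ratio[1],
      mean_p = .data$mean_p[1],
      n_features = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      status = dplyr::if_else(.data$contradictory, "excluded_contradictory",
                              "significant"),
      feature_id = dplyr::if_else(.data$contradictory, NA_character_,
                                  .data$feature_id),
      direction = dplyr::if_else(.data$contradictory, NA_character_,
                                 .data$direction),
      fold_change = dplyr::if_else(.data$contradictory, NA_real_,
                                   .data$fold_change),
      mean_ratio = dplyr::if_else(.data$contradictory, NA_real_,
                                  .data$mean_ratio),
      mean_p = dplyr::if_else(.data$contradictory, NA_real_, .data$mean_p)
    ) |>
    dplyr::select("gene_id", "status", "feature_id", "direction",
                  "fold_change", "mean_ratio", "mean_p", "n_features") |>
    dplyr::arrange(.data$gene_id)
}

#' Run the full responder filter for every treatment
#'
#' Convenience wrapper: applies [three_replicate_filter()] then
#' [resolve_genes()] per treatment.
#'
#' @param tables A data frame of all feature tables stacked: columns
#'   `treatment`, `replicate`, `feature_id`, `gene_id`, `ratio`, `p_value`.
#' @inheritParams call_feature
#' @return A tibble: per-treatment [resolve_genes()] output with a leading
#'   `treatment` column.
#' @export
filter_transcripts <- function(tables, fc = 2, p_max = 0.01) {
  if (!"treatment" %in% names(tables)) {
    stop_input("`tables` must carry a `treatment` column")
  }
  tables |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ resolve_genes(three_replicate_filter(.x, fc, p_max))) |>
    dplyr::ungroup()
}

#' Count significant transcripts per treatment
#'
#' Reports both counters: `n_features`, the features surviving the
#' three-replicate same-direction filter, and `n_genes`, the genes that
#' remain significant after contradictory-feature resolution.
#'
#' @inheritParams filter_transcripts
#' @return A tibble with one row per treatment: `treatment`, `n_features`,
#'   `n_genes`.
#' @export
count_responders <- function(tables, fc = 2, p_max = 0.01) {
  if (!"treatment" %in% names(tables)) {
    stop_input("`tables` must carry a `treatment` column")
  }
  tables |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(function(d, key) {
      surv <- three_replicate_filter(d, fc, p_max)
      res <- resolve_genes(surv)
      tibble(n_features = nrow(surv),
             n_genes = sum(res$status == "significant"))
    }) |>
    dplyr::ungroup()
}

# replicate-averaged whole-array table: one row per feature with mean
# ratio / mean P across the three replicates
average_whole_array <- function(reps) {
  reps <- validate_replicate_set(reps)
  reps |>
    dplyr::group_by(.data$feature_id, .data$gene_id) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     mean_p = mean(.data$p_value), .groups = "drop")
}

#' Assemble the cross-treatment log2 response matrix
#'
#' Builds the heatmap matrix: rows are all genes significant in at least
#' one treatment, columns are treatments, and every cell is the log2 of
#' the gene's replicate-averaged normalized ratio in that treatment. Where
#' a row gene is not significant for a treatment, the cell is filled in
#' from that treatment's whole-array gene ratio tables -- replicate means
#' are computed for all features, and the gene's feature with the lowest
#' mean P (ties broken lexicographically) supplies the value -- and the
#' cell is flagged `filled_in`.
#'
#' @param tables Stacked whole-array feature tables for every treatment
#'   (columns `treatment`, `replicate`, `feature_id`, `gene_id`, `ratio`,
#'   `p_value`); the same tables drive the significance filter and the
#'   fill-in lookup.
#' @inheritParams call_feature
#' @return A `response_matrix`: list with `long` (tibble `gene_id`,
#'   `treatment`, `log2_ratio`, `status`), `values` (wide tibble, genes x
#'   treatments), `significant` (wide logical mask), and `responders` (the
#'   [filter_transcripts()] table). Empty when no gene is significant
#'   anywhere (with a warning).
#' @export
assemble_matrix <- function(tables, fc = 2, p_max = 0.01) {
  resolved <- filter_transcripts(tables, fc = fc, p_max = p_max)
  sig <- dplyr::filter(resolved, .data$status == "significant")
  treatments <- unique(tables$treatment)
  universe <- sort(unique(sig$gene_id))
  if (length(universe) == 0) {
    warn("no gene is significant in any treatment; returning an empty matrix")
    empty <- tibble(gene_id = character(), treatment = character(),
                    log2_ratio = double(), status = character())
    return(structure(list(long = empty,
                          values = tibble(gene_id = character()),
                          significant = tibble(gene_id = character()),
                          responders = resolved),
                     class = "response_matrix"))
  }

  whole <- tables |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ average_whole_array(.x)) |>
    dplyr::ungroup()

  long <- purrr::map_dfr(treatments, function(tr) {
    sig_tr <- dplyr::filter(sig, .data$treatment == tr)
    sig_cells <- tibble(
      gene_id = sig_tr$gene_id, treatment = tr,
      log2_ratio = log2(sig_tr$mean_ratio), status = "significant"
    )
    fill_genes <- setdiff(universe, sig_tr$gene_id)
    wa <- dplyr::filter(whole, .data$treatment == tr)
    missing <- setdiff(fill_genes, wa$gene_id)
    if (length(missing) > 0) {
      stop_input(paste0(
        "gene(s) absent from the whole-array table for treatment '", tr,
        "': ", paste(head(missing, 5), collapse = ", ")))
    }
    fill_cells <- wa |>
      dplyr::filter(.data$gene_id %in% fill_genes) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::arrange(.data$mean_p, .data$feature_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$gene_id, treatment = tr,
                       log2_ratio = log2(.data$mean_ratio),
                       status = "filled_in")
    dplyr::bind_rows(sig_cells, fill_cells)
  }) |>
    dplyr::arrange(.data$gene_id, .data$treatment)

  values <- tidyr::pivot_wider(
    dplyr::select(long, "gene_id", "treatment", "log2_ratio"),
    names_from = "treatment", values_from = "log2_ratio"
  )
  mask <- tidyr::pivot_wider(
    dplyr::mutate(long, significant = .data$status == "significant") |>
      dplyr::select("gene_id", "treatment", "significant"),
    names_from = "treatment", values_from = "significant"
  )

  structure(
    list(long = long, values = values, significant = mask,
         responders = resolved),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d genes x %d treatments (%d filled-in cells)\n",
              nrow(x$values), ncol(x$values) - 1,
              sum(x$long$status == "filled_in")))
  print(x$values, n = 10)
  invisible(x)
}

#' @export
#' @rdname assemble_matrix
#' @param x A `response_matrix`.
#' @param ... Unused.
tidy.response_matrix <- function(x, ...) x$long

#' Heatmap-style plot of a response matrix
#'
#' @param object A `response_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map of log2 ratios; filled-in (non-significant)
#'   cells are outlined.
#' @export
autoplot.response_matrix <- function(object, ...) {
  ggplot2::ggplot(object$long,
                  ggplot2::aes(x = .data$treatment, y = .data$gene_id,
                               fill = .data$log2_ratio)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$status == "filled_in"),
                       linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey40", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 ratio") +
    ggplot2::theme_minimal()
}
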