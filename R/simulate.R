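#' Simulate monotherapy plate-reader dose-response data
#'
#' Draws responses from a 4PL curve with additive Gaussian noise on the
#' %-of-control scale, the noise model of a well-behaved plate reader.
#' Output is bit-for-bit reproducible for a given seed and leaves the
#' caller's RNG state untouched.
#'
#' @param ed50 True ED50 (uM).
#' @param hillslope True hillslope (negative for inhibition curves).
#' @param bottom,top True asymptotes (% control).
#' @param doses Dose levels in uM; default 8 log-spaced doses from 1 to
#'   100.
#' @param n_replicates Replicate wells per dose (default 6).
#' @param noise_sd SD of the additive Gaussian noise, in % control
#'   (default 5). Zero gives exact 4PL values.
#' @param seed Integer seed; required for reproducibility.
#' @param compound Label stored in the `compound` column.
#' @return A tibble with columns `compound`, `dose_um`, `replicate`,
#'   `response_pct` -- the format [fit_4pl()] consumes.
#' @export
#' @examples
#' d <- simulate_monotherapy(ed50 = 63.8, hillslope = -2, seed = 1)
#' fit_4pl(d)$ed50
simulate_monotherapy <- function(ed50, hillslope, bottom = 0, top = 100,
                                 doses = 10^seq(0, 2, length.out = 8),
                                 n_replicates = 6, noise_sd = 5,
                                 seed, compound = "drug") {
  p <- fourpl_params(bottom, top, ed50, hillslope)
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  if (missing(seed)) stop_input("`seed` is required")
  grid <- tidyr::expand_grid(
    dose_um = doses,
    replicate = paste0("r", seq_len(n_replicates))
  )
  mu <- predict_effect(p, grid$dose_um)
  eps <- withr::with_seed(as.integer(seed), rnorm(nrow(grid), 0, noise_sd))
  tibble(
    compound = compound,
    dose_um = grid$dose_um,
    replicate = grid$replicate,
    response_pct = mu + if (noise_sd > 0) eps else 0
  )
}

# noiseless percent effect of a tau-Loewe mixture at total dose Z:
# solves f_a*Z/Dx_a(x) + f_b*Z/Dx_b(x) = tau for x by monotone bisection
tau_loewe_effect <- function(total_dose, par_a, par_b, fraction_a, tau,
                             lower = 1e-7, upper = 100 - 1e-7) {
  fb <- 1 - fraction_a
  g <- function(x) {
    fraction_a * total_dose / inverse_dose(par_a, x) +
      fb * total_dose / inverse_dose(par_b, x) - tau
  }
  if (total_dose <= 0) return(0)
  glo <- g(lower)
  ghi <- g(upper)
  if (glo < 0) return(0)    # dose too small: effect below the grid floor
  if (ghi > 0) return(100)  # dose beyond the achievable range: clamp
  uniroot(g, c(lower, upper), tol = 1e-12)$root
}

#' Simulate fixed-ratio combination dose-response data (tau-Loewe surface)
#'
#' Generates mixture data from a response surface with a known interaction
#' index `tau`: at total dose Z with components `(f_a Z, f_b Z)`, the
#' noiseless percent effect x solves
#' \deqn{f_a Z / D_{x,a} + f_b Z / D_{x,b} = \tau.}
#' `tau = 1` makes the mixture exactly Loewe-additive (its curve coincides
#' with [build_additive_curve()]); `tau < 1` is synergistic and `tau > 1`
#' antagonistic, and by construction the Combination Index of the
#' noiseless surface equals `tau` at every achievable effect. Responses
#' are placed on a % control scale with asymptotes averaged from the two
#' monotherapy curves, plus additive Gaussian noise.
#'
#' @param par_a,par_b True monotherapy curves ([fourpl_params()] or fits).
#' @param fraction_a Mixture dose fraction of compound a.
#' @param tau Interaction index > 0.
#' @param total_doses Total mixture doses in uM; default 8 log-spaced
#'   doses over 2-200, wide enough that the mixture midpoint stays
#'   interior to the design for interaction indexes between about 0.25
#'   and 2 when the additive ED50 sits in the tens of uM.
#' @param n_replicates,noise_sd,seed,compound As in
#'   [simulate_monotherapy()].
#' @return A tibble `compound`, `dose_um` (total dose), `replicate`,
#'   `response_pct`. Doses whose effect falls outside the open (0, 100)
#'   range are clamped to the corresponding asymptote with a warning.
#' @export
simulate_combination <- function(par_a, par_b, fraction_a, tau,
                                 total_doses = 10^seq(log10(2), log10(200),
                                                      length.out = 8),
                                 n_replicates = 6, noise_sd = 5,
                                 seed, compound = "mixture") {
  if (tau <= 0) stop_input("`tau` must be > 0")
  if (fraction_a <= 0 || fraction_a >= 1) {
    stop_input("`fraction_a` must lie strictly inside (0, 1)")
  }
  if (missing(seed)) stop_input("`seed` is required")
  pa <- par4(par_a)
  pb <- par4(par_b)
  top <- (pa[["top"]] + pb[["top"]]) / 2
  bottom <- (pa[["bottom"]] + pb[["bottom"]]) / 2

  eff <- vapply(total_doses, tau_loewe_effect, numeric(1),
                par_a = par_a, par_b = par_b,
                fraction_a = fraction_a, tau = tau)
  if (any(eff %in% c(0, 100) & total_doses > 0)) {
    warn("some total doses fall outside the achievable effect range; responses clamped to the asymptotes")
  }
  mu_by_dose <- top - eff / 100 * (top - bottom)

  grid <- tidyr::expand_grid(
    dose_um = total_doses,
    replicate = paste0("r", seq_len(n_replicates))
  )
  mu <- mu_by_dose[match(grid$dose_um, total_doses)]
  eps <- withr::with_seed(as.integer(seed), rnorm(nrow(grid), 0, noise_sd))
  tibble(
    compound = compound,
    dose_um = grid$dose_um,
    replicate = grid$replicate,
    response_pct = mu + if (noise_sd > 0) eps else 0
  )
}

# default deterministic error-model-style P value map: monotone decreasing
# in |log2 ratio|, crossing well below 0.01 at a 2-fold change
default_p_model <- function(l2) pmin(1, 10^(-1.5 - 3 * abs(l2)))

#' Simulate multi-feature-per-gene microarray feature tables
#'
#' Emulates the structure of per-replicate whole-array gene ratio lists:
#' each gene carries one or more array features; null features draw log2
#' ratios from a centred Gaussian, while planted responder genes have one
#' feature pushed to a stated fold-change magnitude and direction,
#' consistently in all three replicates. A configurable fraction of
#' planted genes additionally receives one opposing consistent feature
#' (a contradiction, which gene resolution must exclude). P values come
#' from a deterministic monotone map of |log2 ratio| standing in for an
#' intensity error model, so planted features always pass `p <= 0.01` and
#' null-sized changes do not.
#'
#' @param planted A data frame with columns `treatment`, `gene_id`,
#'   `direction` (`"up"`/`"down"`), `magnitude` (fold change >= 2). Every
#'   treatment named here (plus any in `treatments`) gets a full table.
#' @param n_genes Number of genes on the array (default 50).
#' @param features_per_gene Inclusive range of features per gene, sampled
#'   uniformly (default `c(1, 3)`).
#' @param contradiction_rate Fraction of planted genes per treatment that
#'   also get a consistent opposing feature (default 0).
#' @param null_ratio_log2_sd SD of null log2 ratios (default 0.25).
#' @param p_model Function mapping |log2 ratio| vectors to P values.
#' @param jitter_sd SD of the per-replicate log2 jitter on planted
#'   magnitudes (default 0.05); the planted |log2 ratio| is floored at
#'   log2 of the fold-change threshold so planting is never eroded.
#' @param treatments Optional extra treatment labels with no planted
#'   genes.
#' @param seed Integer seed.
#' @return A list: `tables`, a tibble of all feature tables stacked
#'   (`treatment`, `replicate`, `feature_id`, `gene_id`, `ratio`,
#'   `p_value`) suitable for [filter_transcripts()] /
#'   [assemble_matrix()]; and `truth`, the planting ledger with a
#'   `contradicted` flag.
#' @export
simulate_feature_tables <- function(planted, n_genes = 50,
                                    features_per_gene = c(1, 3),
                                    contradiction_rate = 0,
                                    null_ratio_log2_sd = 0.25,
                                    p_model = default_p_model,
                                    jitter_sd = 0.05,
                                    treatments = NULL, seed) {
  if (missing(seed)) stop_input("`seed` is required")
  planted <- as_tibble(planted)
  need <- c("treatment", "gene_id", "direction", "magnitude")
  if (nrow(planted) > 0 && !all(need %in% names(planted))) {
    stop_input(paste0("`planted` needs columns ", paste(need, collapse = ", ")))
  }
  if (nrow(planted) > 0 && any(planted$magnitude < 2)) {
    stop_input("planted magnitudes must be >= 2")
  }
  if (contradiction_rate < 0 || contradiction_rate > 1) {
    stop_input("`contradiction_rate` must lie in [0, 1]")
  }
  all_treatments <- union(unique(planted$treatment), treatments)
  if (length(all_treatments) == 0) stop_input("no treatments specified")

  withr::with_seed(as.integer(seed), {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    if (nrow(planted) > 0 && !all(planted$gene_id %in% gene_ids)) {
      stop_input("planted gene_ids must be among the simulated genes G0001..")
    }
    nfeat <- sample(seq(features_per_gene[1], features_per_gene[2]),
                    n_genes, replace = TRUE)
    # contradictions need a second feature on the gene
    if (contradiction_rate > 0 && nrow(planted) > 0) {
      idx <- match(unique(planted$gene_id), gene_ids)
      nfeat[idx] <- pmax(nfeat[idx], 2)
    }
    features <- tibble(
      gene_id = rep(gene_ids, nfeat),
      feature_id = unlist(lapply(seq_len(n_genes), function(i) {
        sprintf("%s_F%d", gene_ids[i], seq_len(nfeat[i]))
      }))
    )

    truth <- planted |>
      dplyr::group_by(.data$treatment) |>
      dplyr::mutate(contradicted = stats::runif(dplyr::n()) < contradiction_rate) |>
      dplyr::ungroup()

    tables <- purrr::map_dfr(all_treatments, function(tr) {
      tr_truth <- dplyr::filter(truth, .data$treatment == tr)
      purrr::map_dfr(1:3, function(r) {
        l2 <- rnorm(nrow(features), 0, null_ratio_log2_sd)
        for (i in seq_len(nrow(tr_truth))) {
          rows <- which(features$gene_id == tr_truth$gene_id[i])
          sgn <- if (tr_truth$direction[i] == "up") 1 else -1
          mag <- pmax(log2(tr_truth$magnitude[i]) + rnorm(1, 0, jitter_sd), 1)
          l2[rows[1]] <- sgn * mag
          if (tr_truth$contradicted[i]) {
            mag2 <- pmax(log2(tr_truth$magnitude[i]) + rnorm(1, 0, jitter_sd), 1)
            l2[rows[2]] <- -sgn * mag2
          }
        }
        tibble(
          treatment = tr, replicate = paste0("rep", r),
          feature_id = features$feature_id, gene_id = features$gene_id,
          ratio = 2^l2, p_value = p_model(abs(l2))
        )
      })
    })
    list(tables = tables, truth = truth)
  })
}
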