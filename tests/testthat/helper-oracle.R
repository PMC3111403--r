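# Independent brute-force reference for the transcript-filter workflow:
# plain nested loops over base data frames, no grouping shortcuts. Used to
# cross-check the dplyr implementation on small random tables.

bf_responder <- function(ratio, p, fc = 2, p_max = 0.01) {
  (ratio >= fc || ratio <= 1 / fc) && p <= p_max
}

bf_direction <- function(ratio, fc = 2) if (ratio >= fc) "up" else "down"

# one treatment: data.frame(replicate, feature_id, gene_id, ratio, p_value)
bf_filter_one <- function(d, fc = 2, p_max = 0.01) {
  feats <- sort(unique(d$feature_id))
  out <- NULL
  for (f in feats) {
    rows <- d[d$feature_id == f, ]
    ok <- TRUE
    dirs <- character(0)
    for (i in seq_len(nrow(rows))) {
      if (!bf_responder(rows$ratio[i], rows$p_value[i], fc, p_max)) {
        ok <- FALSE
        break
      }
      dirs <- c(dirs, bf_direction(rows$ratio[i], fc))
    }
    if (ok && length(unique(dirs)) == 1) {
      out <- rbind(out, data.frame(
        feature_id = f, gene_id = rows$gene_id[1], direction = dirs[1],
        mean_ratio = mean(rows$ratio), mean_p = mean(rows$p_value)
      ))
    }
  }
  out
}

bf_resolve <- function(surv) {
  if (is.null(surv) || nrow(surv) == 0) {
    return(data.frame(gene_id = character(0), status = character(0),
                      feature_id = character(0), mean_ratio = numeric(0)))
  }
  genes <- sort(unique(surv$gene_id))
  out <- NULL
  for (g in genes) {
    rows <- surv[surv$gene_id == g, ]
    if (length(unique(rows$direction)) > 1) {
      out <- rbind(out, data.frame(gene_id = g, status = "excluded_contradictory",
                                   feature_id = NA_character_,
                                   mean_ratio = NA_real_))
    } else {
      best <- rows[order(rows$mean_p, rows$feature_id), ][1, ]
      out <- rbind(out, data.frame(gene_id = g, status = "significant",
                                   feature_id = best$feature_id,
                                   mean_ratio = best$mean_ratio))
    }
  }
  out
}

# full matrix oracle over stacked tables (treatment column present);
# returns long data.frame(gene_id, treatment, log2_ratio, status)
bf_matrix <- function(tables, fc = 2, p_max = 0.01) {
  treatments <- unique(tables$treatment)
  sig <- list()
  for (tr in treatments) {
    d <- tables[tables$treatment == tr, ]
    sig[[tr]] <- bf_resolve(bf_filter_one(d, fc, p_max))
  }
  universe <- character(0)
  for (tr in treatments) {
    s <- sig[[tr]]
    universe <- union(universe, s$gene_id[s$status == "significant"])
  }
  universe <- sort(universe)
  out <- data.frame(gene_id = character(0), treatment = character(0),
                    log2_ratio = double(0), status = character(0))
  for (tr in treatments) {
    d <- tables[tables$treatment == tr, ]
    s <- sig[[tr]]
    for (g in universe) {
      row <- s[s$gene_id == g & s$status == "significant", ]
      if (nrow(row) == 1) {
        out <- rbind(out, data.frame(gene_id = g, treatment = tr,
                                     log2_ratio = log2(row$mean_ratio),
                                     status = "significant"))
      } else {
        feats <- sort(unique(d$feature_id[d$gene_id == g]))
        best_p <- Inf
        best_f <- NA
        best_r <- NA
        for (f in feats) {
          rows <- d[d$feature_id == f, ]
          mp <- mean(rows$p_value)
          if (mp < best_p || (mp == best_p && f < best_f)) {
            best_p <- mp
            best_f <- f
            best_r <- mean(rows$ratio)
          }
        }
        out <- rbind(out, data.frame(gene_id = g, treatment = tr,
                                     log2_ratio = log2(best_r),
                                     status = "filled_in"))
      }
    }
  }
  out <- out[order(out$gene_id, out$treatment), ]
  rownames(out) <- NULL
  out
}

# random small feature-table generator for oracle comparisons (base R RNG
# only; independent of the package's simulator)
bf_random_tables <- function(seed, n_genes = 30, treatments = c("T1", "T2")) {
  withr::with_seed(seed, {
    nfeat <- sample(1:3, n_genes, replace = TRUE)
    gene <- rep(sprintf("g%03d", seq_len(n_genes)), nfeat)
    feat <- paste0(gene, "_", unlist(lapply(nfeat, seq_len)))
    nf <- length(feat)
    do.call(rbind, lapply(treatments, function(tr) {
      # per-feature behaviour is a property of the treatment; replicates
      # jitter around it, so survivors, near-threshold flips and
      # contradictory sibling features all occur
      base_l2 <- ifelse(stats::runif(nf) < 0.35,
                        sample(c(-1, 1), nf, replace = TRUE) *
                          stats::runif(nf, 0.8, 3),
                        stats::rnorm(nf, 0, 0.5))
      do.call(rbind, lapply(1:3, function(r) {
        l2 <- base_l2 + stats::rnorm(nf, 0, 0.25)
        data.frame(
          treatment = tr, replicate = paste0("rep", r),
          feature_id = feat, gene_id = gene,
          ratio = 2^l2,
          p_value = round(pmin(1, 10^(-abs(l2) * stats::runif(nf, 0.8, 2.5))), 6)
        )
      }))
    }))
  })
}

# shared ground-truth curve pair (SK-BR-3-like) used across synergy tests
skbr3_pair <- function() {
  list(
    a = fourpl_params(0, 100, 63.8, -2),
    b = fourpl_params(0, 100, 39.2, -2),
    fraction_a = 63.8 / (63.8 + 39.2)
  )
}

# 8 log-spaced doses centered on an ED50 (factor ~16 each side)
centered_doses <- function(ed50, halfwidth = 1.2, n = 8) {
  10^seq(log10(ed50) - halfwidth, log10(ed50) + halfwidth, length.out = n)
}

# one full synergy-pipeline run on simulated data; returns the report
run_pipeline <- function(tau, seed, truth = skbr3_pair(), noise_sd = 5) {
  da <- simulate_monotherapy(63.8, -2, doses = centered_doses(63.8),
                             noise_sd = noise_sd, seed = seed, compound = "A")
  db <- simulate_monotherapy(39.2, -2, doses = centered_doses(39.2),
                             noise_sd = noise_sd, seed = seed + 100000,
                             compound = "B")
  dm <- simulate_combination(truth$a, truth$b, truth$fraction_a, tau = tau,
                             noise_sd = noise_sd, seed = seed + 200000)
  fit_a <- fit_4pl(da)
  fit_b <- fit_4pl(db)
  design <- design_fixed_ratio(fit_a$ed50, fit_b$ed50)
  additive <- build_additive_curve(fit_a, fit_b, design$fraction_a)
  fit_mix <- fit_4pl(dm)
  compare_curves(fit_mix, additive, design, fit_a = fit_a, fit_b = fit_b)
}
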