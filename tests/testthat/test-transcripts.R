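test_that("feature calls respect the inclusive thresholds exactly", {
  calls <- call_feature(c(2.0, 0.49, 3.0, 1.999, 2.5, 0.5),
                        c(0.01, 0.005, 0.02, 0.001, 0.0101, 0.01))
  expect_equal(calls$responder, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(calls$direction, c("up", "down", NA, NA, NA, "down"))
  expect_error(call_feature(0, 0.5), class = "drcombo_input_error")
  expect_error(call_feature(2, 1.5), class = "drcombo_input_error")
})

make_reps <- function(ratios, ps, gene = "g1", feature = "f1") {
  tibble::tibble(
    replicate = paste0("rep", 1:3), feature_id = feature, gene_id = gene,
    ratio = ratios, p_value = ps
  )
}

test_that("only same-direction three-replicate responders survive", {
  reps <- dplyr::bind_rows(
    make_reps(c(2.5, 2.2, 3.0), c(0.004, 0.002, 0.006), feature = "f_up"),
    make_reps(c(2.5, 2.2, 0.4), c(0.004, 0.002, 0.006), feature = "f_flip"),
    make_reps(c(2.5, 2.2, 3.0), c(0.004, 0.02, 0.006), feature = "f_p"),
    make_reps(c(0.3, 0.45, 0.5), c(0.01, 0.01, 0.01), feature = "f_down")
  )
  surv <- three_replicate_filter(reps)
  expect_setequal(surv$feature_id, c("f_up", "f_down"))
  up <- surv[surv$feature_id == "f_up", ]
  expect_equal(up$direction, "up")
  expect_equal(up$mean_ratio, mean(c(2.5, 2.2, 3.0)))
  expect_equal(up$mean_p, mean(c(0.004, 0.002, 0.006)))
  down <- surv[surv$feature_id == "f_down", ]
  expect_equal(down$fold_change, -1 / mean(c(0.3, 0.45, 0.5)))

  expect_error(three_replicate_filter(reps[-1, ]), class = "drcombo_input_error")
  expect_error(
    three_replicate_filter(dplyr::filter(reps, replicate != "rep3")),
    class = "drcombo_input_error"
  )
})

test_that("a planted table yields exactly its planted survivors", {
  planted <- tibble::tibble(
    treatment = "Z", gene_id = sprintf("G%04d", 1:7),
    direction = rep(c("up", "down"), length.out = 7), magnitude = 2.5
  )
  sim <- simulate_feature_tables(planted, n_genes = 50, seed = 9)
  surv <- three_replicate_filter(dplyr::select(sim$tables, -treatment))
  expect_equal(nrow(surv), 7)
  expect_setequal(unique(surv$gene_id), planted$gene_id)
})

test_that("gene resolution applies the smallest-mean-P and contradiction rules", {
  surv <- tibble::tibble(
    feature_id = c("a1", "a2", "b1", "b2", "c1", "d2", "d1"),
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD", "gD"),
    direction = c("up", "up", "up", "down", "down", "up", "up"),
    mean_ratio = c(2.2, 3.1, 2.5, 0.4, 0.135, 2.0, 4.0),
    mean_p = c(0.004, 0.002, 0.003, 0.001, 0.005, 0.002, 0.002),
    fold_change = 0
  )
  res <- resolve_genes(surv)
  gA <- res[res$gene_id == "gA", ]
  expect_equal(gA$feature_id, "a2")          # smallest mean P wins
  expect_equal(gA$fold_change, 3.1)
  gB <- res[res$gene_id == "gB", ]
  expect_equal(gB$status, "excluded_contradictory")
  expect_true(is.na(gB$fold_change))
  gC <- res[res$gene_id == "gC", ]           # single feature, down
  expect_equal(gC$fold_change, -1 / 0.135, tolerance = 1e-12)
  gD <- res[res$gene_id == "gD", ]           # mean-P tie broken by feature_id
  expect_equal(gD$feature_id, "d1")
})

test_that("row and replicate order never affect the outputs", {
  tables <- tibble::as_tibble(bf_random_tables(17))
  base_res <- filter_transcripts(tables)
  base_mat <- assemble_matrix(tables)$long
  withr::with_seed(1, {
    shuffled <- tables[sample(nrow(tables)), ]
    shuffled$replicate <- c(rep1 = "repC", rep2 = "repA", rep3 = "repB")[shuffled$replicate]
  })
  expect_equal(filter_transcripts(shuffled), base_res)
  expect_equal(assemble_matrix(shuffled)$long, base_mat)
})

test_that("the dplyr pipeline agrees with the brute-force oracle", {
  for (seed in 0:9) {
    tables <- tibble::as_tibble(bf_random_tables(seed))
    for (tr in unique(tables$treatment)) {
      d <- dplyr::filter(tables, treatment == tr)
      surv <- three_replicate_filter(dplyr::select(d, -treatment))
      bf <- bf_filter_one(as.data.frame(d))
      expect_equal(surv$feature_id, if (is.null(bf)) character(0) else bf$feature_id)
      if (!is.null(bf)) {
        expect_equal(surv$mean_ratio, bf$mean_ratio)
        expect_equal(surv$mean_p, bf$mean_p)
      }
      res <- resolve_genes(surv)
      bfres <- bf_resolve(bf)
      expect_equal(res$gene_id, bfres$gene_id)
      expect_equal(res$status, bfres$status)
    }
    got <- suppressWarnings(assemble_matrix(tables))$long
    want <- bf_matrix(as.data.frame(tables))
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("significant genes always satisfy the fold-change and P invariants", {
  for (seed in 10:14) {
    res <- filter_transcripts(tibble::as_tibble(bf_random_tables(seed)))
    sig <- dplyr::filter(res, status == "significant")
    expect_true(all(abs(sig$fold_change) >= 2))
    expect_true(all(sig$mean_p <= 0.01))
    expect_true(all((sig$fold_change > 0) == (sig$direction == "up")))
  }
})

test_that("matrix assembly fills non-significant cells from the whole-array means", {
  # gene gZ responds only in treatment Z; in C its cell must be the log2 of
  # the replicate-mean whole-array ratio, flagged filled_in
  base <- tibble::tibble(
    feature_id = c("fz1", "fc1", "fn1"),
    gene_id = c("gZ", "gC", "gN")
  )
  mk <- function(tr, ratios_by_rep) {
    purrr::map_dfr(1:3, function(r) {
      tibble::tibble(
        treatment = tr, replicate = paste0("rep", r),
        feature_id = base$feature_id, gene_id = base$gene_id,
        ratio = ratios_by_rep[[r]], p_value = c(0.005, 0.005, 0.5)
      )
    })
  }
  tabs <- dplyr::bind_rows(
    mk("Z", list(c(2.5, 2.5, 1.0), c(2.6, 2.4, 1.1), c(2.4, 2.6, 0.9))),
    mk("C", list(c(1.2, 2.5, 1.0), c(1.3, 2.4, 1.0), c(1.4, 2.6, 1.0)))
  )
  m <- assemble_matrix(tabs)
  long <- m$long
  zc <- long[long$gene_id == "gZ" & long$treatment == "C", ]
  expect_equal(zc$log2_ratio, log2(1.3))
  expect_equal(zc$status, "filled_in")
  # gene significant in both treatments has no filled-in cells
  expect_true(all(long$status[long$gene_id == "gC"] == "significant"))
  # every row has at least one significant cell
  expect_true(all(tapply(long$status == "significant", long$gene_id, any)))

  # all-null tables: empty matrix with a warning
  null_tabs <- dplyr::mutate(tabs, ratio = 1, p_value = 0.5)
  expect_warning(empty <- assemble_matrix(null_tabs), "empty matrix")
  expect_equal(nrow(empty$long), 0)

  # a universe gene missing from one treatment's whole-array table
  broken <- dplyr::filter(tabs, !(treatment == "C" & gene_id == "gZ"))
  expect_error(assemble_matrix(broken), class = "drcombo_input_error")
})

test_that("responder counts recover planted gene counts per treatment", {
  planted <- dplyr::bind_rows(
    tibble::tibble(treatment = "CCM", gene_id = sprintf("G%04d", 1:12),
                   direction = "up", magnitude = 3),
    tibble::tibble(treatment = "DHA", gene_id = sprintf("G%04d", 13:15),
                   direction = "down", magnitude = 2.5),
    tibble::tibble(treatment = "CCM+DHA", gene_id = sprintf("G%04d", 5:11),
                   direction = "up", magnitude = 4)
  )
  sim <- simulate_feature_tables(planted, n_genes = 60, seed = 21)
  counts <- count_responders(sim$tables)
  expect_equal(counts$n_genes[match(c("CCM", "DHA", "CCM+DHA"), counts$treatment)],
               c(12L, 3L, 7L))
  # sub-threshold sibling features do not contradict planted responders
  sim2 <- simulate_feature_tables(planted, n_genes = 60,
                                  features_per_gene = c(2, 3), seed = 22)
  counts2 <- count_responders(sim2$tables)
  expect_equal(counts2$n_genes[match(c("CCM", "DHA", "CCM+DHA"), counts2$treatment)],
               c(12L, 3L, 7L))
  # all-null arrays count zero
  null_sim <- simulate_feature_tables(planted[0, ], treatments = c("A", "B"),
                                      n_genes = 40, seed = 23)
  expect_equal(count_responders(null_sim$tables)$n_genes, c(0L, 0L))
})
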