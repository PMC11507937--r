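test_that("simulation is deterministic given the seed, down to FASTA bytes", {
  cfg <- simulation_config(n_v = 3, n_j = 3, regime = "both",
                           n_sequences = 300, seed = 15)
  out1 <- tempfile(); out2 <- tempfile()
  p1 <- make_fixture_germlines(cfg, out_prefix = out1)
  p2 <- make_fixture_germlines(cfg, out_prefix = out2)
  expect_identical(readLines(paste0(out1, "_V.fasta")),
                   readLines(paste0(out2, "_V.fasta")))
  expect_identical(readLines(paste0(out1, "_J.fasta")),
                   readLines(paste0(out2, "_J.fasta")))
  r1 <- simulate_repertoire(p1, cfg)
  r2 <- simulate_repertoire(p2, cfg)
  expect_identical(r1, r2)
  # a different seed changes the panel
  cfg2 <- simulation_config(n_v = 3, n_j = 3, regime = "both",
                            n_sequences = 300, seed = 16)
  p3 <- make_fixture_germlines(cfg2)
  expect_false(identical(vapply(p1$v, `[[`, "", "sequence"),
                         vapply(p3$v, `[[`, "", "sequence")))
})

test_that("microhomology planting controls the feasible ligation structure", {
  cfg0 <- simulation_config(n_v = 5, n_j = 5, mh_plant_rate = 0,
                            n_sequences = 10, seed = 21)
  p0 <- make_fixture_germlines(cfg0)
  frac_blunt <- vapply(panel_pairs(p0), function(pr)
    mean(build_pair_table(pr)$n_lig == 1L), numeric(1))
  # chance matches only: most trimming scenarios admit only the blunt join
  expect_gt(mean(frac_blunt), 0.5)

  cfg1 <- simulation_config(n_v = 5, n_j = 5, mh_plant_rate = 1,
                            n_sequences = 10, seed = 22)
  p1 <- make_fixture_germlines(cfg1)
  # every planted J gene shares a >= 2 nt word with some V: each J gene
  # participates in at least one pair with a deep ligation option
  for (j in seq_along(p1$j)) {
    has_deep <- any(vapply(seq_along(p1$v), function(v)
      any(build_pair_table(gene_pair(p1$v[[v]], p1$j[[j]]))$cells$m >= 2L),
      logical(1)))
    expect_true(has_deep)
  }
})

test_that("the fast sampling path equals the product of the two public step models", {
  set.seed(33)
  pr <- random_pair()
  params <- random_params()
  pt <- build_pair_table(pr)
  jp <- vdjmh:::cell_log_joint(pt, params, "both")$joint
  tp <- trim_probabilities(pt, params)
  for (i in sample(nrow(pt$cells), 25)) {
    s <- pt$cells$scen_id[i]
    lp <- ligation_probabilities(pr, pt$cells$t_v[i], pt$cells$t_j[i],
                                 params)
    expect_equal(jp[i],
                 tp$prob[s] * lp$prob[lp$m == pt$cells$m[i]],
                 tolerance = 1e-8)
  }
})

test_that("under the null regime the sampled microhomology matches the uniform mean", {
  cfg <- simulation_config(n_v = 3, n_j = 3, regime = "none",
                           n_sequences = 20000, seed = 25)
  panel <- make_fixture_germlines(cfg)
  rec <- simulate_repertoire(panel, cfg)
  # E[m] under the uniform model = mean over pairs of mean(avg_mh),
  # weighted by the (uniform) pair usage
  expected <- mean(vapply(panel_pairs(panel), function(pr)
    mean(build_pair_table(pr)$avg_mh), numeric(1)))
  sd_m <- stats::sd(rec$truth_m)
  expect_lt(abs(mean(rec$truth_m) - expected),
            3.5 * sd_m / sqrt(nrow(rec)))
})

test_that("regimes with active effects enrich microhomology-bearing annotations", {
  base <- simulation_config(n_v = 3, n_j = 3, regime = "none",
                            n_sequences = 8000, seed = 27)
  panel <- make_fixture_germlines(base)
  r_none <- simulate_repertoire(panel, base)
  both <- simulation_config(n_v = 3, n_j = 3, regime = "both",
                            n_sequences = 8000, seed = 27)
  r_both <- simulate_repertoire(panel, both)
  expect_gt(mean(r_both$truth_m), mean(r_none$truth_m))
})

test_that("every emitted sequence is reproducible and its truth is in the annotation set", {
  w <- small_sim_world(29, n = 400)
  ds <- w$dataset
  cell_key <- unlist(lapply(ds$tables, function(pt)
    paste(pt$cells$t_v, pt$cells$t_j, pt$cells$m)), use.names = FALSE)
  truth_key <- paste(w$records$truth_t_v, w$records$truth_t_j,
                     w$records$truth_m)
  found <- vapply(seq_len(ds$n_seq), function(i) {
    g <- ds$amap$gcell[ds$amap$seq_id == i]
    truth_key[i] %in% cell_key[g]
  }, logical(1))
  expect_true(all(found))
})

test_that("truth columns are ignored by annotation and fitting", {
  w <- small_sim_world(35, n = 500)
  stripped <- w$records[, !grepl("^truth_", names(w$records))]
  ds2 <- annotate_records(stripped, w$panel)
  cfg_em <- em_config(max_iter = 8)
  f1 <- suppressWarnings(fit_em(w$dataset, em_config = cfg_em))
  f2 <- suppressWarnings(fit_em(ds2, em_config = cfg_em))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the productivity filter is honoured or fails loudly when impossible", {
  cfg <- simulation_config(n_v = 3, n_j = 3, regime = "none",
                           n_sequences = 400, q_filter = "nonproductive",
                           seed = 37)
  panel <- make_fixture_germlines(cfg)
  rec <- simulate_repertoire(panel, cfg)
  expect_true(all(rec$productivity == "nonproductive"))
  expect_equal(nrow(rec), 400L)
  # a panel whose every junction carries an in-frame stop cannot yield
  # productive sequences
  vs <- germline_gene("vs", "TAATAATAATAATAAT", end = "V_3prime")
  js <- germline_gene("js", "AAAAAAAAAAAAAAAA", end = "J_5prime")
  stop_panel <- germline_panel(list(vs), list(js))
  cfg_bad <- simulation_config(n_v = 1, n_j = 1, regime = "none",
                               n_sequences = 10, q_filter = "productive",
                               seed = 38)
  expect_error(simulate_repertoire(stop_panel, cfg_bad),
               "rejected everything")
})

test_that("simulation_config enforces regime consistency and a mandatory seed", {
  expect_error(simulation_config(regime = "none"), "seed")
  bad <- zero_params()
  bad$beta_trim["mh_trim_avg"] <- 0.4
  expect_error(simulation_config(regime = "none", true_params = bad,
                                 seed = 1),
               "forbids")
  bad2 <- zero_params()
  bad2$beta_lig <- 0.2
  expect_error(simulation_config(regime = "trim_only", true_params = bad2,
                                 seed = 1),
               "forbids")
  ok <- simulation_config(regime = "trim_only", seed = 1)
  expect_equal(unname(ok$true_params$beta_trim["mh_trim_avg"]), 0.4484)
  expect_equal(ok$true_params$beta_lig, 0)
})

test_that("parameter recovery reporting compares against stored truth", {
  w <- small_sim_world(39, n = 3000)
  fit <- fit_em(w$dataset)
  rep <- parameter_recovery_report(w$records, fit, w$dataset)
  tab <- rep$param_table
  expect_equal(tab$truth[tab$parameter == "mh_trim_avg"], 0.4484)
  expect_equal(tab$truth[tab$parameter == "mh_lig_count"], 0.1272)
  expect_true(all(is.finite(tab$estimate)))
  expect_true(rep$argmax_agreement > 0 && rep$argmax_agreement <= 1)
  expect_error(parameter_recovery_report(
    w$records[, !grepl("^truth_", names(w$records))], fit),
    "truth columns")
})
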