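test_that("all-zero parameters give the uniform model at both steps", {
  p0 <- zero_params()
  tp <- trim_probabilities(long_pair(), p0)
  expect_equal(nrow(tp), 289L)
  expect_true(all(abs(tp$prob - 1 / 289) < 1e-14))
  lp <- ligation_probabilities(long_pair(), 0, 0, p0)
  expect_equal(lp$prob, rep(0.5, 2))  # feasible {0, 2}
  expect_equal(joint_probability(long_pair(), 0, 0, 2, p0),
               (1 / 289) * (1 / 2))
})

test_that("softmax scores are gauge-invariant per motif position", {
  set.seed(31)
  params <- random_params()
  shifted <- params
  # p-1 is in range for every scenario of a 16-nt gene on the 289 grid
  sel <- grep("^v_motif_p-1_", names(shifted$beta_trim))
  shifted$beta_trim[sel] <- shifted$beta_trim[sel] + 0.7
  expect_equal(trim_probabilities(long_pair(), params)$prob,
               trim_probabilities(long_pair(), shifted)$prob,
               tolerance = 1e-12)
})

test_that("ligation probabilities follow the two-outcome closed form and its limits", {
  params <- model_params(c(mh_trim_avg = 0), beta_lig = 0.1272)
  lp <- ligation_probabilities(long_pair(), 0, 0, params)
  expect_equal(lp$prob[lp$m == 2], 10^0.2544 / (1 + 10^0.2544),
               tolerance = 1e-12)
  # singleton feasible set
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  expect_equal(ligation_probabilities(gene_pair(vA, jC), 0, 0, params)$prob,
               1)
  # beta_lig -> +inf: maximal feasible m takes all the mass
  big <- model_params(c(mh_trim_avg = 0), beta_lig = 10)
  lp2 <- ligation_probabilities(long_pair(), 0, 0, big)
  expect_gt(lp2$prob[lp2$m == 2], 1 - 1e-10)
})

test_that("step distributions and the joint are proper for random parameters", {
  set.seed(41)
  for (rep in 1:10) {
    pr <- random_pair()
    params <- random_params()
    pt <- build_pair_table(pr)
    expect_lt(abs(sum(trim_probabilities(pt, params)$prob) - 1), 1e-10)
    jp <- vdjmh:::cell_log_joint(pt, params, "both")$joint
    expect_lt(abs(sum(jp) - 1), 1e-10)
    expect_true(all(jp >= 0))
    # productivity conditioning renormalises within the class
    for (q in c("productive", "nonproductive")) {
      if (any(pt$cells$productivity == q)) {
        jq <- vdjmh:::cell_log_joint(pt, params, q)$joint
        expect_lt(abs(sum(jq) - 1), 1e-10)
        expect_true(all(jq[pt$cells$productivity != q] == 0))
      }
    }
  }
})

test_that("degenerate productivity conditioning errors", {
  # every junction of this pair starts with an in-frame TAA stop
  v <- germline_gene("vs", "TAATAATAATAATAAT", end = "V_3prime")
  j <- germline_gene("js", "AAAAAAAAAAAAAAAA", end = "J_5prime")
  pt <- build_pair_table(gene_pair(v, j))
  expect_true(all(pt$cells$productivity == "nonproductive"))
  expect_error(vdjmh:::cell_log_joint(pt, zero_params(), "productive"),
               "degenerate")
})

test_that("annotation posteriors normalise, and respond monotonically to beta_lig", {
  cfg <- toy_config()
  aset <- enumerate_annotations("CATTGATCAC", toy_pair(),
                                trim_bounds = c(-2, 4))
  ratio_for <- function(bl) {
    po <- annotation_posteriors(
      aset, model_params(c(mh_trim_avg = 0), beta_lig = bl), config = cfg)
    w2 <- po$posterior[po$t_v == 0 & po$t_j == 0 & po$m == 2]
    w0 <- po$posterior[po$t_v == 2 & po$t_j == 0 & po$m == 0]
    w2 / w0
  }
  r <- vapply(c(0, 0.3, 0.6, 1.2), ratio_for, numeric(1))
  expect_true(all(diff(r) > 0))
  po <- annotation_posteriors(aset, zero_params(cfg), config = cfg)
  expect_equal(sum(po$posterior), 1)
  # singleton set gets weight one
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  prA <- gene_pair(vA, jC)
  single <- enumerate_annotations(
    paste0(vA$extended_sequence, jC$extended_sequence), prA)
  expect_equal(annotation_posteriors(single, zero_params())$posterior, 1)
})

test_that("observed log-likelihood is additive and matches the brute-force evaluator", {
  w <- small_sim_world(101, n = 60)
  params <- suppressWarnings(
    fit_em(w$dataset, em_config = em_config(max_iter = 3)))$params
  ll <- observed_loglik(w$dataset, params)
  # duplicating the dataset doubles the log-likelihood
  rec2 <- rbind(w$records, w$records)
  ds2 <- annotate_records(rec2, w$panel)
  expect_equal(observed_loglik(ds2, params), 2 * ll, tolerance = 1e-9)
  # multiplicity weighting is equivalent to physical duplication
  expect_equal(observed_loglik(w$dataset, params,
                               multiplicity = rep(2L, w$dataset$n_seq)),
               2 * ll, tolerance = 1e-9)

  # explicit-enumeration oracle agreement, per sequence, to 1e-8
  cfg <- w$dataset$config
  for (i in c(1L, 7L, 33L)) {
    rec <- w$records[i, ]
    pr <- gene_pair(w$panel$v[[rec$v_gene]], w$panel$j[[rec$j_gene]])
    lik <- oracle_sequence_lik(rec$sequence, pr, params, cfg)
    pt <- build_pair_table(pr, cfg)
    jp <- vdjmh:::cell_log_joint(pt, params, "both")$joint
    ids <- pt$junction_index[[rec$sequence]]
    expect_equal(sum(jp[ids]), lik, tolerance = 1e-8)
  }
  # single sequence with a single annotation: loglik = log p
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  panelA <- germline_panel(list(vA), list(jC))
  recA <- data.frame(sequence = paste0(vA$extended_sequence,
                                       jC$extended_sequence),
                     v_gene = "vA", j_gene = "jC",
                     productivity = "nonproductive", n_insertions = 0L)
  dsA <- annotate_records(recA, panelA)
  expect_equal(observed_loglik(dsA, zero_params()),
               log(joint_probability(gene_pair(vA, jC), -2, -2, 0,
                                     zero_params())))
})

test_that("productivity-conditioned likelihoods match the oracle", {
  w <- small_sim_world(113, n = 40, q_filter = "nonproductive")
  params <- random_params()
  set.seed(2)
  cfg <- w$dataset$config
  i <- 5L
  rec <- w$records[i, ]
  pr <- gene_pair(w$panel$v[[rec$v_gene]], w$panel$j[[rec$j_gene]])
  lik <- oracle_sequence_lik(rec$sequence, pr, params, cfg,
                             q = "nonproductive")
  pt <- build_pair_table(pr, cfg)
  jp <- vdjmh:::cell_log_joint(pt, params, "nonproductive")$joint
  ids <- pt$junction_index[[rec$sequence]]
  expect_equal(sum(jp[ids]), lik, tolerance = 1e-8)
})

test_that("ablated parameter blocks are structurally absent", {
  p <- zero_params(ablation = c("mh_trim", "mh_lig"))
  expect_false("mh_trim_avg" %in% names(p$beta_trim))
  expect_null(p$beta_lig)
  expect_length(p$beta_trim, 30L)
  p2 <- zero_params(ablation = "motif")
  expect_false(any(grepl("_motif_", names(p2$beta_trim))))
  expect_error(zero_params(ablation = "nonsense"))
})
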