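test_that("feasible_ligations finds shared stretches bounded by cap and lengths", {
  expect_equal(feasible_ligations(toy_pair(), 0, 0), c(0L, 2L))
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  expect_equal(feasible_ligations(gene_pair(vA, jC), 0, 0), 0L)
  vG <- germline_gene("vG", "GGGGGGGGGGGGGGGG", end = "V_3prime")
  jG <- germline_gene("jG", "GGGGGGGGGGGGGGGG", end = "J_5prime")
  # homopolymer: identity at every m, m_cap = 4
  expect_equal(feasible_ligations(gene_pair(vG, jG), 0, 0, m_cap = 4),
               0:4)
  # bounded by trimmed lengths
  expect_equal(feasible_ligations(gene_pair(vG, jG), 14, 14, m_cap = 4),
               0:2)
})

test_that("average_mh is the mean of the feasible ligation set", {
  expect_equal(average_mh(toy_pair(), 0, 0), 1.0)       # {0, 2}
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  expect_equal(average_mh(gene_pair(vA, jC), 3, 5), 0.0)  # {0}
  # {0, 1, 2}: V ends "TGG", J starts "GGA"
  v <- germline_gene("v", "CCCCCCCCCCCCCTGG", end = "V_3prime")
  j <- germline_gene("j", "GGACCCCCCCCCCCCC", end = "J_5prime")
  expect_equal(feasible_ligations(gene_pair(v, j), 0, 0), 0:2)
  expect_equal(average_mh(gene_pair(v, j), 0, 0), 1.0)
})

test_that("enumerate_annotations reproduces the junction and matches the brute-force oracle", {
  aset <- enumerate_annotations("CATTGATCAC", toy_pair(),
                                trim_bounds = c(-2, 4), m_cap = 10)
  key <- with(aset$annotations, paste(t_v, t_j, m))
  expect_true(all(c("0 0 2", "2 0 0", "0 2 0") %in% key))
  # exact agreement with the independent triple scan
  orc <- oracle_enumerate("CATTGATCAC", toy_pair(), c(-2, 4), 10)
  expect_equal(aset$annotations, orc)

  # full untrimmed merge of a no-overlap pair: single m = 0 annotation
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  pr <- gene_pair(vA, jC)
  x_full <- paste0(vA$extended_sequence, jC$extended_sequence)
  aset2 <- enumerate_annotations(x_full, pr)
  expect_equal(aset2$annotations,
               data.frame(t_v = -2L, t_j = -2L, m = 0L))

  err <- tryCatch(enumerate_annotations("AAAA", toy_pair(),
                                        trim_bounds = c(-2, 4)),
                  condition = identity)
  expect_s3_class(err, "vdjmh_unexplainable")
  expect_match(conditionMessage(err), "unexplainable junction")
})

test_that("annotation sets satisfy round-trip, uniqueness and m_cap monotonicity", {
  set.seed(23)
  for (rep in 1:15) {
    pr <- random_pair()
    # draw a junction from a random feasible merge (independent string ops)
    t_v <- sample(-2:8, 1); t_j <- sample(-2:8, 1)
    ms <- oracle_feasible(pr, t_v, t_j)
    m <- ms[sample.int(length(ms), 1)]
    vtr <- oracle_trimmed(pr$v, t_v); jtr <- oracle_trimmed(pr$j, t_j)
    x <- paste0(vtr, substr(jtr, m + 1, nchar(jtr)))
    aset <- enumerate_annotations(x, pr)
    ann <- aset$annotations
    # the generating annotation is found
    expect_true(any(ann$t_v == t_v & ann$t_j == t_j & ann$m == m))
    # every member reproduces x, overlap counted once
    for (i in seq_len(nrow(ann))) {
      vi <- oracle_trimmed(pr$v, ann$t_v[i])
      ji <- oracle_trimmed(pr$j, ann$t_j[i])
      expect_identical(paste0(vi, substr(ji, ann$m[i] + 1, nchar(ji))), x)
    }
    # at most one m per trimming scenario (length-forced)
    expect_false(anyDuplicated(paste(ann$t_v, ann$t_j)) > 0)
    # extending m_cap never removes annotations
    bigger <- enumerate_annotations(x, pr, m_cap = 14)$annotations
    expect_true(all(paste(ann$t_v, ann$t_j, ann$m) %in%
                      paste(bigger$t_v, bigger$t_j, bigger$m)))
  }
})

test_that("filter_records applies the insertion, productivity and trim-depth criteria", {
  v <- germline_gene("Vl", "AAAAAAAAAAAAAAAC", end = "V_3prime")
  j <- germline_gene("Jl", "GGGGGGGGGGGGGGGG", end = "J_5prime")
  panel <- germline_panel(list(v), list(j))
  ok_x <- paste0(v$extended_sequence, j$extended_sequence)  # (-2,-2,0)
  # junction keeping a single V nucleotide: the only explanation would
  # trim fifteen from the V gene, beyond the fourteen-nt bound
  deep_x <- paste0("A", j$sequence)
  recs <- data.frame(
    sequence = c(ok_x, ok_x, ok_x, deep_x),
    v_gene = "Vl", j_gene = "Jl",
    productivity = c("nonproductive", "nonproductive", "productive",
                     "nonproductive"),
    n_insertions = c(0L, 2L, 0L, 0L))
  out <- suppressMessages(
    filter_records(recs, panel, q_keep = "nonproductive"))
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, ok_x)
  log <- attr(out, "filter_log")
  expect_equal(log$removed[log$criterion == "n_insertions"], 1L)
  expect_equal(log$removed[log$criterion == "productivity"], 1L)
  expect_equal(log$removed[log$criterion == "no_annotation_within_bounds"], 1L)
})

test_that("germline_mh_summary reports per-pair means and cross-pair medians", {
  # no shared characters anywhere (including P-extensions): medians (0, 1)
  vA <- germline_gene("vA", "AAAAAAAAAAAAAAAA", end = "V_3prime")
  jC <- germline_gene("jC", "CCCCCCCCCCCCCCCC", end = "J_5prime")
  s <- germline_mh_summary(list(gene_pair(vA, jC)))
  expect_equal(s$median_avg_mh, 0.0)
  expect_equal(s$median_n_ligation, 1.0)
  # toy pair over small bounds, cross-checked against direct averaging
  s2 <- germline_mh_summary(list(toy_pair()), trim_bounds = c(-2, 4))
  grid <- expand.grid(t_v = -2:4, t_j = -2:4)
  direct <- mean(mapply(function(a, b) average_mh(toy_pair(), a, b),
                        grid$t_v, grid$t_j))
  expect_equal(s2$per_pair$mean_avg_mh, direct)
  expect_gt(s2$median_n_ligation, 1.0)
})

test_that("annotate_records maps junctions to cells and honours skip_unexplainable", {
  w <- small_sim_world(301, n = 200)
  ds <- w$dataset
  expect_equal(ds$n_seq, 200L)
  # spot-check: per-record annotation sets match direct enumeration
  for (i in c(1L, 50L, 200L)) {
    pr_names <- c(ds$records$v_gene[i], ds$records$j_gene[i])
    pr <- gene_pair(w$panel$v[[pr_names[1]]], w$panel$j[[pr_names[2]]])
    direct <- enumerate_annotations(ds$records$sequence[i], pr)
    expect_equal(dataset_annotation_set(ds, i)$annotations,
                 direct$annotations)
  }
  # a junction foreign to its pair errors, or is dropped when asked
  bad <- w$records[1:3, ]
  bad$sequence[2] <- strrep("A", 40)
  expect_error(annotate_records(bad, w$panel), "unexplainable")
  expect_warning(ds2 <- annotate_records(bad, w$panel,
                                         skip_unexplainable = TRUE),
                 "unexplainable")
  expect_equal(ds2$n_seq, 2L)
})
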