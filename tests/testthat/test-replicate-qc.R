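test_that("Spearman concordance matches the rank-difference formula", {
  expect_equal(spearman_concordance(1:5, 1:5), 1)
  expect_equal(spearman_concordance(1:5, 5:1), -1)
  # hand computation: 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0,0,0,1,-1)
  expect_equal(spearman_concordance(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4)), 0.9)
  expect_true(is.na(spearman_concordance(rep(1, 5), 1:5)))
  expect_error(spearman_concordance(1:2, 1:2), "length")
})

test_that("control-gene z-scores use the sample SD over all pairs", {
  th <- qc_thresholds()
  res <- control_gene_check(c(0, 0, 0, 0, 1), th)
  expect_equal(res$z[5], (1 - 0.2) / sd(c(0, 0, 0, 0, 1)), tolerance = 1e-12)
  expect_equal(res$z[5], 1.7888544, tolerance = 1e-6)
  expect_true(all(res$pass))
  # a gross outlier (|z| > 2.3) fails; note |z| <= (n-1)/sqrt(n) with the
  # sample SD, so at least 8 pairs are needed for a failure to be possible
  d <- c(rep(0, 7), 9)
  r2 <- control_gene_check(d, th)
  expect_true(any(abs(r2$z) > th$z_max))
  expect_equal(r2$pass, abs(r2$z) <= 2.3)
  # degenerate: all equal -> SD 0 -> all pass
  r3 <- control_gene_check(rep(0.3, 4), th)
  expect_true(all(r3$pass))
  expect_warning(control_gene_check(0.5, th), "fewer than 2")
})

test_that("cluster adjacency passes tight pairs and fails scrambled ones", {
  set.seed(11)
  p <- sim_params(n_genes = 1000, n_case = 5, n_control = 5, n_diff = 0,
                  seed = 21)
  co <- generate_cohort(p)
  bad <- co$annot$subject_id[3]
  out <- add_replicates(co$matrix, co$annot, tau = 0.02,
                        corrupt_subjects = bad, scramble_fraction = 1,
                        seed = 22)
  ann <- out$annot
  pairs <- data.frame(
    subject_id = ann$subject_id[ann$replicate_role == "A"],
    A = ann$sample_id[ann$replicate_role == "A"],
    B = ann$sample_id[ann$replicate_role == "B"])
  res <- cluster_adjacency_check(out$matrix, pairs)
  expect_false(res[[bad]])
  expect_true(all(res[setdiff(names(res), bad)]))
  # brute-force mutual-nearest-neighbour scan agrees
  d <- 1 - cor(out$matrix)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$A[k]; b <- pairs$B[k]
    oth <- setdiff(colnames(out$matrix), c(a, b))
    expect_equal(unname(res[k]),
                 d[a, b] <= min(d[a, oth]) && d[a, b] <= min(d[b, oth]))
  }
  # an exactly duplicated pair (distance 0) passes
  m2 <- out$matrix
  dup_b <- pairs$B[1]
  m2[, dup_b] <- m2[, pairs$A[1]]
  expect_true(cluster_adjacency_check(m2, pairs)[[1]])
})

test_that("the drop decision is a pure 2-of-3 function of the check booleans", {
  p <- sim_params(n_genes = 800, n_case = 4, n_control = 4, n_diff = 0, seed = 31)
  co <- generate_cohort(p)
  out <- add_replicates(co$matrix, co$annot, tau = 0.02,
                        corrupt_subjects = co$annot$subject_id[1:2],
                        scramble_fraction = 1, seed = 32)
  for (fc in 1:3) {
    th <- qc_thresholds(fail_count_to_drop = fc)
    rep_ <- assess_replicates(out$matrix, out$annot, rownames(out$matrix)[1], th)
    expect_identical(rep_$decision == "drop_B", rep_$n_fail >= fc)
    expect_identical(
      rep_$n_fail,
      as.integer((!rep_$cluster_pass) + (!rep_$rho_pass) + (!rep_$control_pass)))
  }
})

test_that("corrupted replicates and only those are dropped, across seeds", {
  for (s in 1:10) {
    p <- sim_params(n_genes = 600, n_case = 5, n_control = 5, n_diff = 0,
                    tau = 0.03, seed = 500 + s)
    co <- generate_cohort(p)
    bad <- sample(co$annot$subject_id, 2)
    out <- add_replicates(co$matrix, co$annot, tau = 0.03,
                          corrupt_subjects = bad, scramble_fraction = 0.3,
                          seed = 600 + s)
    rep_ <- assess_replicates(out$matrix, out$annot, rownames(out$matrix)[1])
    dropped <- rep_$subject_id[rep_$decision == "drop_B"]
    expect_setequal(dropped, bad)
  }
})

test_that("a pair failing a single check keeps its B sample", {
  # clean cohort, then depress one pair's rho just below threshold while the
  # pair still clusters together and the control gene stays typical
  p <- sim_params(n_genes = 2000, n_case = 5, n_control = 5, n_diff = 0, seed = 71)
  co <- generate_cohort(p)
  out <- add_replicates(co$matrix, co$annot, tau = 0.01, seed = 72)
  subj <- out$annot$subject_id[1]
  b_id <- out$annot$sample_id[out$annot$subject_id == subj &
                                out$annot$replicate_role == "B"]
  # moderate extra noise on B: rho drops below 0.985 while the pair still
  # clusters together (noise well under the between-subject spread)
  set.seed(73)
  idx <- setdiff(seq_len(nrow(out$matrix)), 1L) # keep control gene intact
  out$matrix[idx, b_id] <- out$matrix[idx, b_id] + rnorm(length(idx), 0, 0.45)
  rep_ <- assess_replicates(out$matrix, out$annot, rownames(out$matrix)[1])
  row <- rep_[rep_$subject_id == subj, ]
  expect_false(row$rho_pass)
  expect_true(row$cluster_pass)
  expect_true(row$control_pass)
  expect_identical(row$decision, "keep_B")
  # and with a second failure the same pair is dropped
  th2 <- qc_thresholds(fail_count_to_drop = 1)
  rep2 <- assess_replicates(out$matrix, out$annot, rownames(out$matrix)[1], th2)
  expect_identical(rep2[rep2$subject_id == subj, ]$decision, "drop_B")
  # filtered annotation drops exactly the dropped B samples
  filt <- attr(rep2, "filtered_annot")
  gone <- setdiff(out$annot$sample_id, filt$sample_id)
  expect_setequal(
    gone,
    out$annot$sample_id[out$annot$subject_id %in%
                          rep2$subject_id[rep2$decision == "drop_B"] &
                          out$annot$replicate_role == "B"])
})

test_that("a missing control gene downgrades that check to an automatic pass", {
  p <- sim_params(n_genes = 300, n_case = 3, n_control = 3, n_diff = 0, seed = 81)
  co <- generate_cohort(p)
  out <- add_replicates(co$matrix, co$annot, tau = 0.02, seed = 82)
  expect_warning(rep_ <- assess_replicates(out$matrix, out$annot, "NOT_A_GENE"),
                 "not in matrix")
  expect_true(all(rep_$control_pass))
})
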