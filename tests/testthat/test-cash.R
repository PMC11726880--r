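test_that("preselection keeps exactly the genes below the cutoff", {
  sim <- generate_dataset(simulation_config(n_genes = 300, seed = 17))
  ds <- sim$dataset
  expect_identical(preselect_genes(ds, 1.0), rownames(ds$values))
  p <- welch_t(ds)$p
  expect_identical(preselect_genes(ds, 0.05), rownames(ds$values)[p < 0.05])
  # cutoff below the smallest raw p leaves nothing
  expect_length(preselect_genes(ds, min(p) * 0.99), 0L)
})

test_that("bootstrap p-values live on the +1-corrected grid", {
  set.seed(31)
  bc <- as_boolean(random_boolean_matrix(30, 6))
  bx <- as_boolean(random_boolean_matrix(30, 5))
  colnames(bx$values) <- paste0("c", 1:5)
  B <- 57
  boot <- bootstrap_pvalues(bc, bx, n_boot = B, seed = 2)
  expect_true(all(boot$p %in% ((1:(B + 1)) / (B + 1))))
  expect_true(all(boot$p > 0 & boot$p <= 1))
  # zero observed difference is never significant
  expect_true(all(boot$p[abs(boot$d) < 1e-15] == 1))
})

test_that("bootstrap is deterministic in the seed and shares resamples", {
  set.seed(8)
  bc <- as_boolean(random_boolean_matrix(25, 7))
  bx <- as_boolean(random_boolean_matrix(25, 6))
  colnames(bx$values) <- paste0("c", 1:6)
  a <- bootstrap_pvalues(bc, bx, 100, seed = 5)
  b <- bootstrap_pvalues(bc, bx, 100, seed = 5)
  expect_identical(a$p, b$p)
  d <- bootstrap_pvalues(bc, bx, 100, seed = 6)
  expect_false(identical(a$p, d$p))
  # identical Boolean rows get identical d and p (resamples shared)
  twin_case <- as_boolean(rbind(bc$values, bc$values[1, , drop = FALSE]))
  twin_ctrl <- as_boolean(rbind(bx$values, bx$values[1, , drop = FALSE]))
  rownames(twin_case$values)[26] <- rownames(twin_ctrl$values)[26] <- "twin"
  tw <- bootstrap_pvalues(twin_case, twin_ctrl, 100, seed = 5)
  expect_equal(tw$p[["g1"]], tw$p[["twin"]])
  expect_equal(tw$d[["g1"]], tw$d[["twin"]])
  expect_error(bootstrap_pvalues(bc, as_boolean(bx$values[1:10, ]), 10, 1),
               class = "cashr_validation_error")
})

test_that("direction combination follows the Bonferroni-2 rule", {
  got <- combine_directions(c(0.004, 0.5, 0.6), c(0.8, 0.5, 0.7),
                            delta = c(1, -1, 0))
  expect_equal(got$p, c(0.008, 1, 1))
  expect_equal(got$direction, c("up", "down", "up"))
})

test_that("fold changes use the signed 2^delta convention", {
  vals <- rbind(c(3, 3, 2, 2), c(1, 1, 3, 3), c(4, 4, 4, 4))
  ds <- toy_dataset(vals, 2, 2)
  fc <- fold_change(ds)
  expect_equal(fc$delta, c(1, -2, 0))
  expect_equal(fc$fold_change, c(2, -4, 1))
  # strict threshold: |FC| = 2 does not pass at threshold 2
  cfg <- cash_config()
  expect_false(abs(fc$delta[1]) > log2(cfg$fc_threshold))
  expect_true(abs(fc$delta[2]) > log2(cfg$fc_threshold))
})

test_that("the pipeline is deterministic and internally consistent", {
  ds <- load_fixture_dataset()
  cfg <- cash_config(n_boot = 100, seed = 42)
  res1 <- run_cash(ds, cfg)
  res2 <- run_cash(ds, cfg)
  expect_identical(res1, res2)
  expect_gt(nrow(res1), 0)
  # flags recomputable from stored numbers
  expect_identical(res1$sig_raw, pmin(res1$p_over, res1$p_under) < 0.05)
  expect_identical(res1$sig_fdr, res1$q_gene < 0.05)
  expect_identical(res1$passes_fc, abs(res1$delta) > 1)
  expect_identical(res1$p_gene, pmin(1, 2 * pmin(res1$p_over, res1$p_under)))
  expect_identical(res1$q_gene, bh_fdr(res1$p_gene))
  # direction reflects the firing side and the sign of its difference
  ov <- res1$p_over < res1$p_under
  un <- res1$p_under < res1$p_over
  expect_identical(res1$direction[ov], ifelse(res1$d_over[ov] < 0, "down", "up"))
  expect_identical(res1$direction[un], ifelse(res1$d_under[un] < 0, "up", "down"))
  # byte-identical table output across repeated runs
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_deg_table(as_deg_table(res1), p1)
  write_deg_table(as_deg_table(res2), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an empty preselection yields an empty, valid result", {
  sim <- generate_dataset(simulation_config(n_genes = 100, n_case = 5,
                                            n_control = 5, frac_de = 0,
                                            seed = 23))
  p_min <- min(welch_t(sim$dataset)$p)
  res <- run_cash(sim$dataset, cash_config(preselect_alpha = p_min * 0.9,
                                           n_boot = 50, seed = 1))
  expect_s3_class(res, "cash_result")
  expect_equal(nrow(res), 0)
})

test_that("data with no abnormal expression yields all p = 1 and no DEGs", {
  # every value stays inside the control mean +/- sd band: nothing is
  # ever flagged, whatever the group means do
  set.seed(6)
  n_genes <- 20
  ctrl <- matrix(rep(c(-1, 1, -1.05, 1.05), each = n_genes), n_genes, 4)
  case <- matrix(rnorm(n_genes * 4, 0.5, 0.01), n_genes, 4)
  ds <- toy_dataset(cbind(case, ctrl), 4, 4)
  ref <- control_reference(ds)
  expect_true(all(ds$values < ref$mean + ref$sd & ds$values >= ref$mean - ref$sd))
  res <- run_cash(ds, cash_config(preselect_alpha = 1, n_boot = 50, seed = 3))
  expect_gt(nrow(res), 0)  # preselection did fire
  expect_true(all(res$p_gene == 1))
  expect_true(all(!res$sig_raw & !res$sig_fdr))
})

test_that("configuration invariants are enforced", {
  expect_error(cash_config(preselect_alpha = 0), class = "cashr_validation_error")
  expect_error(cash_config(n_boot = 0), class = "cashr_validation_error")
  expect_error(cash_config(fc_threshold = 1), class = "cashr_validation_error")
  expect_error(cash_config(fdr_alpha = 1), class = "cashr_validation_error")
  cfg <- cash_config()
  expect_equal(cfg$preselect_alpha, 0.05)
  expect_equal(cfg$n_boot, 1000L)
  expect_equal(cfg$fc_threshold, 2)
  expect_equal(cfg$fdr_alpha, 0.05)
})
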