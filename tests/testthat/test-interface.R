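write_pipeline_inputs <- function(dir, with_survival = TRUE, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- make_dce_omics("e", seed = seed)
  meth <- make_dce_omics("m", seed = seed + 50)
  dump_omics <- function(om, tag) {
    write.table(data.frame(gene = om$gene_ids, om$values,
                           check.names = FALSE),
                file.path(dir, paste0(tag, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = om$sample_ids,
                           condition = om$condition),
                file.path(dir, paste0(tag, "_cond.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  dump_omics(expr, "expression")
  dump_omics(meth, "methylation")
  mod_genes <- function(prefix) {
    lapply(1:2, function(m) paste0(prefix, m, "_", 1:8))
  }
  within <- module_clique_edges(c(mod_genes("e"), mod_genes("m")))
  cross <- as.matrix(expand.grid(paste0("m1_", 1:8), paste0("e1_", 1:8),
                                 stringsAsFactors = FALSE))
  cross2 <- as.matrix(expand.grid(paste0("m2_", 1:8), paste0("e2_", 1:8),
                                  stringsAsFactors = FALSE))
  set.seed(seed)
  cross <- cross[runif(nrow(cross)) < 0.4, ]
  cross2 <- cross2[runif(nrow(cross2)) < 0.4, ]
  edges <- rbind(within, cross, cross2)
  write.table(edges, file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (with_survival) {
    set.seed(seed + 1)
    tum <- expr$sample_ids[expr$condition == "tumor"]
    tev <- stats::rexp(length(tum), 0.002)
    write.csv(data.frame(patient_id = tum, time_days = round(tev + 1),
                         event = rbinom(length(tum), 1, 0.7)),
              file.path(dir, "survival.csv"), row.names = FALSE)
  }
  dir
}

pipeline_config <- function(dir, out_dir, with_survival = TRUE) {
  cfg <- list(expression = file.path(dir, "expression.tsv"),
              expression_conditions = file.path(dir, "expression_cond.tsv"),
              methylation = file.path(dir, "methylation.tsv"),
              methylation_conditions = file.path(dir, "methylation_cond.tsv"),
              ppi = file.path(dir, "ppi.tsv"),
              out_dir = out_dir,
              k_grid = 2:4, B = 100, mu_grid = c(0, 1),
              max_subset_size = 2, seed = 11)
  if (with_survival) cfg$survival <- file.path(dir, "survival.csv")
  cfg
}

test_that("the end-to-end pipeline runs on simulated two-condition data", {
  dir <- write_pipeline_inputs(tempfile("pipe"))
  out <- tempfile("out")
  res <- suppressWarnings(run_pipeline(pipeline_config(dir, out)))
  expect_true(length(res$subnetworks) >= 1)
  expect_true(res$mu %in% c(0, 1))
  expect_true(all(file.exists(file.path(out,
    c("expression_diffnet.tsv", "methylation_diffnet.tsv",
      "expression_modules.tsv", "methylation_modules.tsv",
      "expression_eigengenes.tsv", "subnetworks.tsv",
      "subnetworks.json")))))
  # every planted module is dense and significant in its layer
  mods <- utils::read.delim(file.path(out, "expression_modules.tsv"))
  expect_gte(sum(unique(mods[, c("module_id", "significant")])$significant), 1)
  # stage outputs reload as inputs (format round trip)
  dn <- utils::read.delim(file.path(out, "expression_diffnet.tsv"))
  expect_true(all(c("geneA", "geneB", "Z", "weight", "p", "p_adj",
                    "significant") %in% names(dn)))
  # survival stage produced a table for kept subnetworks
  if (!is.null(res$survival)) {
    expect_true(all(c("cox_beta", "logrank_p") %in% names(res$survival)))
  }
})

test_that("pipeline runs are byte-identical under a fixed seed", {
  dir <- write_pipeline_inputs(tempfile("pipe"))
  out1 <- tempfile("out1"); out2 <- tempfile("out2")
  suppressWarnings(run_pipeline(pipeline_config(dir, out1,
                                                with_survival = FALSE)))
  suppressWarnings(run_pipeline(pipeline_config(dir, out2,
                                                with_survival = FALSE)))
  for (f in c("subnetworks.tsv", "expression_modules.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a missing survival table skips the stage with a notice", {
  dir <- write_pipeline_inputs(tempfile("pipe"), with_survival = FALSE)
  expect_message(
    res <- suppressWarnings(run_pipeline(pipeline_config(dir, tempfile(),
                                         with_survival = FALSE))),
    "survival stage skipped")
  expect_null(res$survival)
})

test_that("malformed input fails at load time naming the problem", {
  dir <- tempfile("bad")
  dir.create(dir)
  tab <- data.frame(gene = c("gA", "gA"), s1 = c(1, 2), s2 = c(3, 4),
                    s3 = c(1, 1), s4 = c(2, 0), s5 = 1:2, s6 = 2:3,
                    s7 = 0:1, s8 = c(5, 1))
  write.table(tab, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = paste0("s", 1:8),
                         condition = rep(c("tumor", "normal"), each = 4)),
              file.path(dir, "cond.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_omics_matrix(file.path(dir, "expression.tsv"),
                                 file.path(dir, "cond.tsv")),
               "gA")
})

test_that("recovery scoring mirrors the planted wiring", {
  mk_fit <- function(rid, preds, ps) {
    structure(list(response = rid,
                   fit = list(predictors = preds,
                              coef_p = stats::setNames(ps, preds))),
              class = "SubnetworkFit")
  }
  manifest <- list(wiring = list(y1 = "x1", y4 = character(0)))
  fits <- list(y1 = mk_fit("y1", "x1", 0.001),
               y4 = mk_fit("y4", "x3", 0.4))
  sc <- score_recovery(fits, manifest)
  expect_true(all(sc$correct))
  expect_equal(sc$fp, c(0, 1))
  # an extra selected predictor is a false positive
  fits2 <- list(y1 = mk_fit("y1", c("x1", "x2"), c(0.001, 0.01)))
  sc2 <- score_recovery(fits2, manifest)
  expect_false(sc2$correct)
  expect_equal(sc2$tp, 1)
  expect_equal(sc2$fp, 1)
  # a significant coefficient on a null response is an error, not a pass
  fits3 <- list(y4 = mk_fit("y4", "x3", 0.001))
  expect_false(score_recovery(fits3, manifest)$correct)
  expect_error(score_recovery(list(zz = mk_fit("zz", "x1", 0.1)), manifest),
               "unknown response")
})

test_that("simulated bundles flow through the reduced analysis path", {
  cfg <- sim_config(n = 60, p = 8, q = 8, a = 0.3, c_r = 0.5, seed = 8)
  ds <- generate_study(cfg)$dataset1
  an <- analyze_sim_dataset(ds, mu = 1, B = 49, seed = 9)
  expect_equal(nrow(an$recovery), 4)
  expect_true(all(c("correct", "tp", "fp") %in% names(an$recovery)))
  expect_equal(dim(an$r), c(4, 4))
})
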