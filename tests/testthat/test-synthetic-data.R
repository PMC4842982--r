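test_that("generator is deterministic given the seed", {
  a <- simulate_dataset(tiny_config(seed = 42L))
  b <- simulate_dataset(tiny_config(seed = 42L))
  expect_identical(SummarizedExperiment::assay(a$matrix),
                   SummarizedExperiment::assay(b$matrix))
  expect_identical(a$truth$cells, b$truth$cells)
  qa <- simulate_qpcr(a$truth, c(temporal_panel(), "Gapdh"))
  qb <- simulate_qpcr(b$truth, c(temporal_panel(), "Gapdh"))
  expect_identical(qa$ct, qb$ct)
  c2 <- simulate_dataset(tiny_config(seed = 43L))
  expect_false(identical(SummarizedExperiment::assay(a$matrix),
                         SummarizedExperiment::assay(c2$matrix)))
})

test_that("degenerate configuration gives constant non-spike genes", {
  cfg <- tiny_config(noise_sd = 0,
                     class_fractions = c(temporal = 0, differentiation = 0,
                                         cellcycle = 0))
  ds <- simulate_dataset(cfg)
  m <- SummarizedExperiment::assay(ds$matrix)
  g <- ds$truth$genes
  bg <- g$gene_id[g$class == "housekeeping" & !startsWith(g$gene_id, "spike")]
  expect_true(all(apply(m[bg, , drop = FALSE], 1L, function(x)
    diff(range(x)) == 0)))
})

test_that("config validation catches bad latent maps and proportions", {
  expect_error(sim_config(stages = c(E14 = 5L, E11 = 5L)), "monotone")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(spike_copies = c(20, -5)), "positive")
  tp <- matrix(c(0.5, 0.4, 0.2, 0.3, 0.2, 0.3), 2,
               dimnames = list(c("E11", "E14"),
                               c("AP", "IP", "neuron")))
  expect_error(sim_config(stages = c(E11 = 5L, E14 = 5L), type_props = tp),
               "sum to 1")
})

test_that("temporal shifts are parallel between AP and IP by construction", {
  ds <- simulate_dataset(tiny_config(seed = 3L))
  m <- log_signal(ds$matrix)
  cl <- ds$truth$cells
  g <- ds$truth$genes
  tg <- g$gene_id[g$class == "temporal"]
  shift <- function(type) {
    sel_a <- cl$stage == "E11" & cl$type == type
    sel_b <- cl$stage == "E14" & cl$type == type
    rowMeans(m[tg, sel_b, drop = FALSE]) - rowMeans(m[tg, sel_a, drop = FALSE])
  }
  # noiseless means share a_g, so expected signs agree; with noise compare
  # against the planted effect sign instead of between noisy subsets
  ds0 <- simulate_dataset(tiny_config(seed = 3L, noise_sd = 0))
  m <- log_signal(ds0$matrix)
  expect_identical(sign(shift("AP")), sign(shift("IP")))
  expect_identical(unname(sign(shift("AP"))),
                   sign(g$a[match(tg, g$gene_id)]) )
})

test_that("spike-in rows are independent of the latent time", {
  cfg <- sim_config(stages = c(E11 = 170L, E13 = 160L, E16 = 170L),
                    n_genes = 20L, seed = 5L)
  ds <- simulate_dataset(cfg)
  m <- log_signal(ds$matrix)
  tau <- ds$truth$cells$tau
  for (sp in c("spike_1000", "spike_100", "spike_20")) {
    ct <- suppressWarnings(stats::cor.test(m[sp, ], tau))
    expect_gt(ct$p.value, 0.01)
  }
})

test_that("qPCR readout follows the Ct model", {
  cfg <- tiny_config(qpcr_noise_sd = 0)
  tr <- simulate_truth(cfg)
  q <- simulate_qpcr(tr, c(temporal_panel(), "Gapdh"))
  # doubling the signal lowers Ct by exactly 1: bump every baseline by +1 log2
  tr2 <- tr
  tr2$genes$baseline <- tr$genes$baseline + 1
  q2 <- simulate_qpcr(tr2, c(temporal_panel(), "Gapdh"))
  det <- q$detected & q2$detected & q$ct > 0 & q2$ct > 0
  expect_equal(q2$ct[det], q$ct[det] - 1)
  # zero expected signal: markers off in the wrong cell type
  qm <- simulate_qpcr(tr, c("Eomes", "Gapdh"))
  ap <- tr$cells$type == "AP"
  expect_true(all(qm$ct["Eomes", ap] == 40))
  expect_true(all(!qm$detected["Eomes", ap]))
  expect_error(simulate_qpcr(tr, c("nope", "Gapdh")), "nope")
  expect_error(simulate_qpcr(tr, temporal_panel()), "Gapdh")
})

test_that("apply_arrest modes behave as documented", {
  cfg <- tiny_config()
  tr <- simulate_truth(cfg)
  e14_ap <- tr$cells$cell_id[tr$cells$stage == "E14" & tr$cells$type == "AP"]
  arr <- apply_arrest(tr, e14_ap, "NICD+p18")
  expect_true(all(!arr$cells$cycling[arr$cells$cell_id %in% e14_ap]))
  q <- simulate_qpcr(arr, c("Mki67", "Ttyh1", "Egfp", "Gapdh"))
  expect_true(all(!q$detected["Mki67", e14_ap]))
  expect_true(all(q$detected["Ttyh1", e14_ap]))
  expect_true(all(q$detected["Egfp", e14_ap]))
  # empty freeze set: latent temporal coordinates equal wild type
  frz <- apply_arrest(tr, e14_ap, "clonal-arrest", arrest_stage = "E11",
                      freeze_genes = character(0))
  expect_identical(frz$cells$tau, tr$cells$tau)
  expect_error(apply_arrest(tr, e14_ap, "p18-only"), "unknown mode")
  expect_error(apply_arrest(tr, "no_such_cell", "NICD"), "no_such_cell")
})

test_that("clonal arrest freezes the configured genes only", {
  cfg <- tiny_config(noise_sd = 0)
  tr <- simulate_truth(cfg)
  e14_ap <- tr$cells$cell_id[tr$cells$stage == "E14" & tr$cells$type == "AP"]
  e11_ap <- tr$cells$cell_id[tr$cells$stage == "E11" & tr$cells$type == "AP"]
  frz <- apply_arrest(tr, e14_ap, "clonal-arrest", arrest_stage = "E11",
                      freeze_genes = c("Zbtb20", "Rlbp1"))
  m <- log_signal(simulate_signals(frz, cfg))
  # frozen rising genes stay at their E11 value in arrested cells
  for (gid in c("Zbtb20", "Rlbp1"))
    expect_equal(unname(m[gid, e14_ap]),
                 rep(unname(m[gid, e11_ap[1]]), length(e14_ap)))
  # unfrozen declining genes still fall from E11 to E14
  for (gid in c("Dmrta1", "Dmrt3"))
    expect_lt(max(m[gid, e14_ap]), min(m[gid, e11_ap]))
})

test_that("dataset round-trips through the TSV writers", {
  ds <- simulate_dataset(tiny_config())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  se <- read_expression_tsv(file.path(dir, "matrix.tsv"),
                            probes_tsv = file.path(dir, "probes.tsv"),
                            cells_tsv = file.path(dir, "cells.tsv"))
  expect_equal(SummarizedExperiment::assay(se),
               SummarizedExperiment::assay(ds$matrix), tolerance = 1e-12)
  expect_equal(as.character(SummarizedExperiment::colData(se)$stage),
               ds$truth$cells$stage)
  q <- simulate_qpcr(ds$truth, c(temporal_panel(), "Gapdh"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_tsv(q, f)
  q2 <- read_qpcr_tsv(f)
  expect_equal(q2$ct, q$ct, tolerance = 1e-12)
})
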