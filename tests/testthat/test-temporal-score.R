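test_that("qpcr_normalize implements [40 - dCt] with censoring", {
  ct <- rbind(Gapdh = c(20, 22), geneA = c(20, 27), geneB = c(25, 40))
  colnames(ct) <- c("c1", "c2")
  nm <- qpcr_normalize(qpcr_table(ct))
  expect_equal(nm["geneA", "c1"], 40)     # Ct equal to reference
  expect_equal(nm["geneA", "c2"], 35)     # 40 - (27 - 22)
  expect_equal(nm["geneB", "c1"], 35)     # 40 - (25 - 20)
  # undetected floored to min detected - 1, flagged censored
  expect_equal(nm["geneB", "c2"], 34)
  expect_true(attr(nm, "censored")["geneB", "c2"])
  expect_false("Gapdh" %in% rownames(nm))
  # undetected reference excludes the cell with a warning
  ct2 <- ct; ct2["Gapdh", "c2"] <- 40
  expect_warning(nm2 <- qpcr_normalize(qpcr_table(ct2)), "excluding")
  expect_identical(colnames(nm2), "c1")
  expect_identical(attr(nm2, "excluded_cells"), "c2")
})

test_that("normalized values are invariant to a global Ct shift", {
  tr <- simulate_truth(tiny_config(seed = 18L))
  q <- simulate_qpcr(tr, c(temporal_panel(), "Gapdh"))
  shifted <- q
  shifted$ct <- pmin(q$ct + 1.5, 40)
  shifted$ct[q$ct == 40] <- 40           # keep undetected undetected
  shifted$detected <- shifted$ct < 40
  nm1 <- qpcr_normalize(q)
  nm2 <- qpcr_normalize(shifted)
  ok <- !attr(nm1, "censored") & !attr(nm2, "censored")
  expect_equal(nm1[ok], nm2[ok])
})

test_that("reference axis recovers latent time and projects exactly", {
  cfg <- sim_config(stages = c(E10 = 20L, E11 = 20L, E12 = 20L,
                               E13 = 20L, E14 = 22L),
                    noise_sd = 0.5, seed = 19L)
  tr <- simulate_truth(cfg)
  q <- simulate_qpcr(tr, c(temporal_panel(), "Gapdh"))
  nm <- qpcr_normalize(q)
  ap <- tr$cells$type == "AP"
  ax <- fit_reference_axis(nm[, ap], tr$cells$stage[ap])
  expect_equal(sum(ax$loading^2), 1, tolerance = 1e-12)
  expect_equal(mean(ax$scores), 0, tolerance = 1e-12)
  rho <- cor(ax$scores, tr$cells$tau[ap], method = "spearman")
  expect_gte(rho, 0.9)
  # training self-projection is exact
  sc <- project_cells(ax, nm[, ap])
  expect_lt(max(abs(sc - ax$scores)), 1e-10)
  # sign convention: latest stage highest median
  med <- tapply(sc, tr$cells$stage[ap], median)
  expect_gt(med[["E14"]], med[["E10"]])
  expect_error(project_cells(ax, nm[setdiff(rownames(nm), "Zbtb20"), ]),
               "Zbtb20")
})

test_that("projection is affine in the expression values", {
  tr <- simulate_truth(tiny_config(seed = 20L))
  q <- simulate_qpcr(tr, c(temporal_panel(), "Gapdh"))
  nm <- qpcr_normalize(q)
  ap <- tr$cells$type == "AP"
  ax <- fit_reference_axis(nm[, ap], tr$cells$stage[ap])
  x <- nm[ax$panel, 1]; y <- nm[ax$panel, 2]
  for (alpha in c(0.25, 0.5, 0.8)) {
    mix <- cbind(mixed = alpha * x + (1 - alpha) * y, a = x, b = y)
    sc <- project_cells(ax, mix)
    expect_equal(sc[["mixed"]], alpha * sc[["a"]] + (1 - alpha) * sc[["b"]],
                 tolerance = 1e-10)
  }
})

test_that("compare_scores: exact and approximate branches", {
  r <- compare_scores(1:5, 6:10)
  expect_identical(r$method, "exact")
  expect_equal(r$p, 2 / 252)
  expect_equal(r$U, 0)
  # identical multisets -> maximal p
  r2 <- compare_scores(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r2$p, 0.99)
  # agreement with the base-R oracle on random tie-free draws
  withr::with_seed(23, {
    for (i in 1:10) {
      a <- rnorm(7); b <- rnorm(9, mean = runif(1, -1, 1))
      ours <- compare_scores(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
    # large samples switch to the normal approximation
    a <- rnorm(30); b <- rnorm(30)
    big <- compare_scores(a, b)
    expect_identical(big$method, "normal-approx")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(big$p, ref$p.value, tolerance = 1e-6)
  })
  expect_error(compare_scores(numeric(0), 1:3), "non-empty")
})

test_that("detection_freq_test matches fisher.test", {
  r <- detection_freq_test(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(r$p, 2 / 252)
  expect_equal(detection_freq_test(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                     FALSE))$p, 1)
  withr::with_seed(29, {
    for (i in 1:10) {
      fa <- runif(8) < 0.6
      fb <- runif(12) < 0.3
      ours <- detection_freq_test(fa, fb)
      ref <- stats::fisher.test(ours$table)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    }
  })
  expect_error(detection_freq_test(logical(0), TRUE), "non-empty")
})

test_that("stage_dispersion flags the widest stage", {
  s <- stage_dispersion(rep(1, 10), rep(c("E10", "E12"), 5))
  expect_true(all(s$iqr == 0))
  # gradual-transition generator: widest spread at the middle stage
  hits <- vapply(1:20, function(i) {
    cfg <- sim_config(stages = c(E10 = 25L, E11 = 25L, E12 = 25L,
                                 E13 = 25L, E14 = 25L),
                      transition = list(t_star = 2, sd = 1, window = 0.5),
                      seed = 100L + i)
    tr <- simulate_truth(cfg)
    q <- simulate_qpcr(tr, c(temporal_panel(), "Gapdh"))
    nm <- qpcr_normalize(q)
    ap <- tr$cells$type == "AP"
    ax <- fit_reference_axis(nm[, ap], tr$cells$stage[ap])
    sd_tab <- stage_dispersion(ax$scores, tr$cells$stage[ap])
    sd_tab$stage[sd_tab$widest]
  }, "")
  expect_gte(mean(hits %in% c("E11", "E12", "E13")), 0.95)
})

test_that("arrest leaves the projected temporal trajectory intact", {
  cfg <- sim_config(stages = c(E10 = 20L, E11 = 20L, E12 = 20L,
                               E13 = 20L, E14 = 22L), seed = 33L)
  tr <- simulate_truth(cfg)
  cand <- tr$cells$cell_id[tr$cells$type == "AP" &
                             tr$cells$stage %in% c("E12", "E13", "E14")]
  arrest_me <- cand[seq_along(cand) %% 2 == 0]   # keep wild-type APs too
  arr <- apply_arrest(tr, arrest_me, "NICD+p18")
  q <- simulate_qpcr(arr, c(temporal_panel(), "Gapdh"))
  nm <- qpcr_normalize(q)
  wt_ap <- arr$cells$type == "AP" & arr$cells$condition == "wild-type"
  ax <- fit_reference_axis(nm[, wt_ap], arr$cells$stage[wt_ap])
  sc <- project_cells(ax, nm[, arr$cells$cell_id %in% arrest_me])
  st <- arr$cells$stage[match(names(sc), arr$cells$cell_id)]
  med <- tapply(sc, st, median)[c("E12", "E13", "E14")]
  expect_true(all(diff(med) > 0))
})
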