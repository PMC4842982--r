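# Synthetic single-cell expression and qPCR data with known latent
# coordinates.  The generative model on the log2 scale is
#   log2 signal(g, i) = baseline_g + a_g * tau_i + b_g * delta_i
#                       + cycle_g * cycling_i + eps,  eps ~ N(0, noise_sd^2)
# with linear signal 2^(log2 signal).  Marker genes are on/off by cell state;
# spike-in rows depend only on nominal copy number and the detection model.

#' Simulate ground truth (cells and gene effects)
#'
#' Draws the per-gene effect sizes and lays out the cell population (stage,
#' type, latent tau/delta, cycling flag, condition) without generating any
#' signal; signals are produced by [simulate_signals()] so that perturbations
#' ([apply_arrest()]) can be applied to the truth first.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_truth`: list with `cells` (data.frame:
#'   cell_id, stage, type, condition, tau, delta, cycling, tau_arrest),
#'   `genes` (data.frame: gene_id, class, a, b, cycle, baseline, marker_rule,
#'   spike_copies), `frozen_genes`, and the `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genes <- build_gene_table(config)
    cells <- build_cell_table(config)
  })
  out <- list(cells = cells, genes = genes,
              frozen_genes = character(0), config = config)
  class(out) <- "sim_truth"
  out
}

build_gene_table <- function(config) {
  n <- config$n_genes
  fr <- config$class_fractions
  n_t <- round(n * fr[["temporal"]])
  n_d <- round(n * fr[["differentiation"]])
  n_c <- round(n * fr[["cellcycle"]])
  n_h <- n - n_t - n_d - n_c
  cls <- rep(c("temporal", "differentiation", "cellcycle", "housekeeping"),
             c(n_t, n_d, n_c, n_h))
  runifr <- function(k, r) stats::runif(k, r[1], r[2])
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  a <- b <- cyc <- numeric(n)
  a[cls == "temporal"] <- sgn(n_t) * runifr(n_t, config$a_range)
  b[cls == "differentiation"] <- sgn(n_d) * runifr(n_d, config$b_range)
  cyc[cls == "cellcycle"] <- sgn(n_c) * runifr(n_c, config$cycle_range)
  bg <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    class = cls, a = a, b = b, cycle = cyc,
    baseline = runifr(n, config$baseline_range),
    marker_rule = NA_character_, spike_copies = NA_real_,
    stringsAsFactors = FALSE)
  spikes <- data.frame(
    gene_id = sprintf("spike_%d", config$spike_copies),
    class = "spike", a = 0, b = 0, cycle = 0, baseline = 0,
    marker_rule = NA_character_,
    spike_copies = as.numeric(config$spike_copies),
    stringsAsFactors = FALSE)
  out <- rbind(named_gene_table(), bg, spikes)
  rownames(out) <- NULL
  out
}

build_cell_table <- function(config) {
  rows <- lapply(names(config$stages), function(st) {
    n <- config$stages[[st]]
    if (n == 0L) return(NULL)
    # deterministic largest-remainder allocation of types
    p <- config$type_props[st, c("AP", "IP", "neuron")]
    cnt <- floor(p * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(p * n - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    type <- rep(c("AP", "IP", "neuron"), cnt)
    data.frame(
      cell_id = sprintf("%s_c%03d", st, seq_len(n)),
      stage = st, type = type, condition = "wild-type",
      tau = config$stage_tau[[st]],
      delta = unname(config$type_delta[type]),
      cycling = type != "neuron",
      tau_arrest = NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tr <- config$transition
  if (!is.null(tr)) {
    # gradual transition: per-cell switch time spreads the latent tau most
    # at stages near t_star
    t_i <- stats::rnorm(nrow(out), tr$t_star, tr$sd)
    rng <- range(config$stage_tau[names(config$stages)])
    out$tau <- rng[1] +
      diff(rng) * stats::pnorm((out$tau - t_i) / tr$window)
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$cells), "cells,", nrow(x$genes), "genes\n")
  print(table(x$cells$stage, x$cells$type))
  invisible(x)
}

#' Apply a cell-cycle / Notch perturbation to simulated cells
#'
#' Modes: `"NICD"` (constitutive Notch activation: transgene on, cycling
#' preserved), `"NICD+p18"` (arrest: transgene on, cycling off, cell-cycle
#' gene effects silenced via the cycling flag; the temporal clock tau keeps
#' advancing with stage), and `"clonal-arrest"` (as NICD+p18, but the genes in
#' `freeze_genes` are frozen at their value at `arrest_stage`, emulating
#' isolated one-cell clones deprived of tissue-derived cues).
#'
#' @param truth a `sim_truth`.
#' @param cells character cell ids (or logical/integer index into
#'   `truth$cells`) to perturb.
#' @param mode one of `"NICD"`, `"NICD+p18"`, `"clonal-arrest"`.
#' @param arrest_stage stage label whose tau is the freeze point (required for
#'   `"clonal-arrest"`).
#' @param freeze_genes genes frozen in clonal arrest; default
#'   [clonal_freeze_default()].  May be empty.
#' @return The modified `sim_truth`.
#' @export
apply_arrest <- function(truth, cells, mode,
                         arrest_stage = NULL,
                         freeze_genes = clonal_freeze_default()) {
  stopifnot(inherits(truth, "sim_truth"))
  modes <- c("NICD", "NICD+p18", "clonal-arrest")
  if (length(mode) != 1L || !mode %in% modes)
    stop("unknown mode '", mode, "'; expected one of ",
         paste(modes, collapse = ", "))
  idx <- if (is.character(cells)) match(cells, truth$cells$cell_id) else
    seq_len(nrow(truth$cells))[cells]
  if (anyNA(idx)) stop("unknown cell ids: ",
                       paste(cells[is.na(idx)], collapse = ", "))
  truth$cells$condition[idx] <- mode
  if (mode %in% c("NICD+p18", "clonal-arrest"))
    truth$cells$cycling[idx] <- FALSE
  if (mode == "clonal-arrest") {
    if (is.null(arrest_stage))
      stop("arrest_stage is required for clonal-arrest")
    if (!arrest_stage %in% names(truth$config$stage_tau))
      stop("unknown arrest_stage '", arrest_stage, "'")
    miss <- setdiff(freeze_genes, truth$genes$gene_id)
    if (length(miss))
      stop("freeze_genes not in gene table: ", paste(miss, collapse = ", "))
    truth$cells$tau_arrest[idx] <- truth$config$stage_tau[[arrest_stage]]
    truth$frozen_genes <- union(truth$frozen_genes, freeze_genes)
  }
  truth
}

# Noise-free log2 mean matrix (genes x cells); -Inf encodes "off" (zero
# linear signal).  Spike rows get their nominal proportional level here.
log2_mean_matrix <- function(truth) {
  g <- truth$genes
  cl <- truth$cells
  tau <- matrix(cl$tau, nrow(g), nrow(cl), byrow = TRUE)
  if (length(truth$frozen_genes) && any(!is.na(cl$tau_arrest))) {
    fg <- g$gene_id %in% truth$frozen_genes
    fc <- cl$condition == "clonal-arrest" & !is.na(cl$tau_arrest)
    tau[fg, fc] <- matrix(cl$tau_arrest[fc], sum(fg), sum(fc), byrow = TRUE)
  }
  mu <- g$baseline + g$a * tau +
    outer(g$b, cl$delta) + outer(g$cycle, as.numeric(cl$cycling))
  # marker genes: on-level baseline when the rule fires, off (-Inf) otherwise
  mk <- which(!is.na(g$marker_rule))
  for (j in mk) {
    on <- switch(g$marker_rule[j],
      AP = cl$type == "AP",
      IP_neuron = cl$type %in% c("IP", "neuron"),
      cycling = cl$cycling,
      transgene = cl$condition != "wild-type",
      stop("unknown marker rule ", g$marker_rule[j]))
    mu[j, ] <- ifelse(on, g$baseline[j], -Inf)
  }
  sp <- which(g$class == "spike")
  mu[sp, ] <- log2(g$spike_copies[sp] * truth$config$spike_gain)
  dimnames(mu) <- list(g$gene_id, cl$cell_id)
  mu
}

#' Generate the expression matrix for a simulated truth
#'
#' Adds log2-scale Gaussian noise to the noise-free means and exponentiates.
#' Spike-in rows below the proportional-detection copy number get inflated
#' noise (`spike_noise_mult` x) and Bernoulli dropout to zero; spike rows never
#' depend on tau or delta.  Deterministic given `config$seed`.
#'
#' @param truth a `sim_truth` (possibly after [apply_arrest()]).
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `signal` (linear scale), `rowData` probe annotations (class, effects,
#'   spike copies) and `colData` cell annotations (stage, type, condition,
#'   cycling, tau, delta).
#' @export
simulate_signals <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  mu <- log2_mean_matrix(truth)
  g <- truth$genes
  withr::with_seed(config$seed + 1L, {
    eps <- matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                  nrow(mu), ncol(mu))
    sub <- which(g$class == "spike" &
                   g$spike_copies < config$spike_detect_copies)
    if (length(sub)) {
      eps[sub, ] <- eps[sub, ] * config$spike_noise_mult
      drop <- matrix(stats::runif(length(sub) * ncol(mu)) <
                       config$spike_dropout_p, length(sub), ncol(mu))
    }
    sig <- 2^(mu + eps)
    if (length(sub)) sig[sub, ][drop] <- 0
  })
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig),
    rowData = S4Vectors::DataFrame(g[, c("class", "a", "b", "cycle",
                                         "baseline", "spike_copies")],
                                   row.names = g$gene_id),
    colData = S4Vectors::DataFrame(
      truth$cells[, c("stage", "type", "condition", "cycling",
                      "tau", "delta")],
      row.names = truth$cells$cell_id))
}

#' Simulate a full dataset (truth + expression matrix)
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (SummarizedExperiment) and `truth`
#'   (`sim_truth`).
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  list(matrix = simulate_signals(truth, config), truth = truth)
}

#' Simulate a qPCR readout (Ct table) for a gene panel
#'
#' Ct = C0 - log2(expected linear signal) + Gaussian noise, clipped to
#' \[0, 40\]; Ct = 40 is recorded as undetected.  The expected signal is the
#' noise-free generative mean, so qPCR and array readouts share latent
#' coordinates without sharing array noise.
#'
#' @param truth a `sim_truth`.
#' @param panel character vector of panel gene ids; must include `Gapdh` (the
#'   normalization reference).
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return An object of class `qpcr_table`: list with `ct` (genes x cells),
#'   `detected` (logical matrix), `c0`.
#' @export
simulate_qpcr <- function(truth, panel, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  miss <- setdiff(panel, truth$genes$gene_id)
  if (length(miss))
    stop("panel gene(s) absent from truth: ", paste(miss, collapse = ", "))
  if (!"Gapdh" %in% panel)
    stop("panel must include the reference gene Gapdh")
  mu <- log2_mean_matrix(truth)[panel, , drop = FALSE]
  withr::with_seed(config$seed + 2L, {
    ct <- config$qpcr_c0 - mu +
      matrix(stats::rnorm(length(mu), 0, config$qpcr_noise_sd),
             nrow(mu), ncol(mu))
  })
  ct <- pmin(pmax(ct, 0), 40)
  qpcr_table(ct, c0 = config$qpcr_c0)
}

#' Construct a qPCR Ct table
#'
#' @param ct numeric matrix of Ct values (genes x cells); 40 means undetected.
#' @param c0 optional calibration offset used to generate the table.
#' @return `qpcr_table` object.
#' @export
qpcr_table <- function(ct, c0 = NA_real_) {
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs gene row names and cell column names")
  if (any(ct < 0 | ct > 40)) stop("Ct values must lie in [0, 40]")
  structure(list(ct = ct, detected = ct < 40, c0 = c0),
            class = "qpcr_table")
}

#' @export
print.qpcr_table <- function(x, ...) {
  cat("qpcr_table:", nrow(x$ct), "genes x", ncol(x$ct), "cells; ",
      round(100 * mean(x$detected), 1), "% detected\n")
  invisible(x)
}
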