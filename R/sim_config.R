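#' Simulation configuration
#'
#' Describes the world the generator emulates: embryonic stages with per-stage
#' cell counts, a strictly monotone stage-to-time map tau, progenitor-type
#' mixing proportions, gene classes with per-gene effect sizes, spike-in
#' calibration transcripts at fixed nominal copy numbers, and a qPCR readout
#' model.
#'
#' Defaults mirror the study design the package targets: stages E11/E14/E16
#' with 30/70/28 cells, tau equally spaced per embryonic day (E10 = 0 ...
#' E16 = 6), spike-ins at 1000/100/20/5 copies per cell whose signal is
#' proportional to copy number at >= 20 copies and degraded (3x log-noise,
#' dropout) below, and an 18-gene temporal-axis qPCR panel plus marker and
#' housekeeping genes.
#'
#' @param stages named integer vector: per-stage cell counts, names are stage
#'   labels in developmental order (e.g. `c(E11 = 30, E14 = 70, E16 = 28)`).
#' @param stage_tau named numeric vector mapping every stage label to a latent
#'   time tau; must be strictly increasing in stage order.  Default parses
#'   embryonic-day labels (`"E14"` -> 4 with E10 = 0).
#' @param type_props matrix (stages x types `AP`,`IP`,`neuron`) of mixing
#'   proportions; rows must sum to 1.  Default proportions shift from
#'   AP-dominated early to mixed mid-neurogenic stages.
#' @param type_delta named numeric: latent differentiation coordinate delta per
#'   cell type (default AP = 0, IP = 1, neuron = 2).
#' @param n_genes integer: number of auto-generated background genes (named
#'   panel/marker/housekeeping genes and spike-ins are appended on top).
#' @param class_fractions named numeric: fractions of the background genes in
#'   classes `temporal`, `differentiation`, `cellcycle` (remainder is
#'   `housekeeping`, i.e. constant).
#' @param a_range,b_range,cycle_range numeric length-2: ranges of absolute
#'   effect sizes (log2 units per unit tau, per unit delta, and per cycling
#'   flag) for the corresponding gene classes; signs are random.
#' @param baseline_range numeric length-2: range of per-gene log2 baselines.
#' @param noise_sd log2-scale Gaussian noise standard deviation (>= 0).
#' @param spike_copies integer vector of nominal spike-in copy numbers.
#' @param spike_gain linear signal units per copy for spike-ins; the default
#'   43.51 puts the 20-copy spike median near 870 signal units.
#' @param spike_noise_mult noise-sd multiplier for spike-ins below
#'   `spike_detect_copies` copies.
#' @param spike_dropout_p dropout probability for spike-ins below
#'   `spike_detect_copies` copies.
#' @param spike_detect_copies copy number at/above which spike signal is
#'   proportional to copies (default 20).
#' @param qpcr_c0 qPCR calibration offset: Ct for one linear signal unit
#'   (default 38; any constant cancels under `[40 - Ct]` normalization).
#' @param qpcr_noise_sd Gaussian Ct noise (cycles).
#' @param transition optional gradual-transition model: a list with `t_star`
#'   (population mean switch time on the tau scale), `sd` (between-cell sd of
#'   the switch time) and `window` (within-cell transition steepness).  When
#'   set, each cell's latent tau becomes
#'   `tau_min + (tau_max - tau_min) * pnorm((stage_tau - t_star_i) / window)`
#'   with a per-cell switch time `t_star_i ~ N(t_star, sd)`, so cells at
#'   stages near `t_star` mix early- and late-type expression states and show
#'   the widest score dispersion.  Default `NULL` (tau constant per stage).
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(stages = c(E11 = 30L, E14 = 70L, E16 = 28L),
                       stage_tau = NULL,
                       type_props = NULL,
                       type_delta = c(AP = 0, IP = 1, neuron = 2),
                       n_genes = 1000L,
                       class_fractions = c(temporal = 0.15,
                                           differentiation = 0.15,
                                           cellcycle = 0.10),
                       a_range = c(0.5, 1.5),
                       b_range = c(1, 3),
                       cycle_range = c(0.5, 1.5),
                       baseline_range = c(6, 14),
                       noise_sd = 0.5,
                       spike_copies = c(1000L, 100L, 20L, 5L),
                       spike_gain = 43.51,
                       spike_noise_mult = 3,
                       spike_dropout_p = 0.5,
                       spike_detect_copies = 20,
                       qpcr_c0 = 38,
                       qpcr_noise_sd = 0.3,
                       transition = NULL,
                       seed = 1L) {
  if (is.null(names(stages)) || any(!nzchar(names(stages))))
    stop("'stages' must be a named vector of cell counts")
  if (any(stages < 0)) stop("stage cell counts must be non-negative")
  if (is.null(stage_tau)) {
    day <- suppressWarnings(as.numeric(sub("^E", "", names(stages))))
    if (anyNA(day))
      stop("stage_tau must be given when stage labels are not of the form 'E<day>'")
    stage_tau <- setNames(day - 10, names(stages))
  }
  if (!all(names(stages) %in% names(stage_tau)))
    stop("stage_tau missing stages: ",
         paste(setdiff(names(stages), names(stage_tau)), collapse = ", "))
  tau <- stage_tau[names(stages)]
  if (any(diff(tau) <= 0))
    stop("stage -> tau map must be strictly monotone increasing in stage order")
  if (is.null(type_props)) {
    type_props <- t(vapply(tau, function(t) {
      if (t <= 1) c(AP = 0.77, IP = 0.10, neuron = 0.13)
      else if (t >= 5) c(AP = 0.61, IP = 0.36, neuron = 0.03)
      else c(AP = 0.47, IP = 0.33, neuron = 0.20)
    }, numeric(3)))
    rownames(type_props) <- names(stages)
  }
  type_props <- as.matrix(type_props)
  if (!all(rownames(type_props) %in% names(stages)) ||
      !setequal(colnames(type_props), c("AP", "IP", "neuron")))
    stop("type_props must have stage rows and columns AP, IP, neuron")
  if (any(abs(rowSums(type_props) - 1) > 1e-8))
    stop("type mixing proportions must sum to 1 per stage")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(spike_copies <= 0)) stop("spike-in copy numbers must be positive")
  if (spike_dropout_p < 0 || spike_dropout_p > 1)
    stop("spike_dropout_p must be in [0, 1]")
  if (sum(class_fractions) > 1) stop("class fractions exceed 1")
  if (!is.null(transition) &&
      !all(c("t_star", "sd", "window") %in% names(transition)))
    stop("transition needs elements t_star, sd, window")

  cfg <- list(stages = stages, stage_tau = stage_tau,
              type_props = type_props[names(stages), , drop = FALSE],
              type_delta = type_delta,
              n_genes = as.integer(n_genes),
              class_fractions = class_fractions,
              a_range = a_range, b_range = b_range,
              cycle_range = cycle_range, baseline_range = baseline_range,
              noise_sd = noise_sd,
              spike_copies = spike_copies, spike_gain = spike_gain,
              spike_noise_mult = spike_noise_mult,
              spike_dropout_p = spike_dropout_p,
              spike_detect_copies = spike_detect_copies,
              qpcr_c0 = qpcr_c0, qpcr_noise_sd = qpcr_noise_sd,
              transition = transition,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sum(x$stages), "cells over stages",
      paste(sprintf("%s(%d)", names(x$stages), x$stages), collapse = " "),
      "\n  background genes:", x$n_genes,
      " noise_sd:", x$noise_sd,
      " seed:", x$seed, "\n")
  invisible(x)
}

# The named genes every simulated dataset carries: the 18-gene temporal-axis
# qPCR panel (9 declining E11-type, 9 rising E14-type), the gating markers
# (on/off by cell state), and four housekeeping genes.
named_gene_table <- function() {
  panel_dn <- c(Sulf2 = -1.0, Dmrta1 = -1.2, Dmrt3 = -1.1, Crabp2 = -0.9,
                Lrrn1 = -0.8, Fndc3c1 = -0.7, Sema5a = -0.9, Flrt3 = -1.0,
                Hmga2 = -1.3)
  base_dn <- c(12, 12.5, 12, 11.5, 11, 11, 11.5, 12, 12.5)
  panel_up <- c(Zbtb20 = 1.2, Rlbp1 = 1.1, Aldoc = 1.0, Ptn = 0.9,
                Pag1 = 0.8, Tgfb2 = 0.9, Fabp7 = 1.0, Tnc = 0.8,
                Slc1a3 = 1.1)
  base_up <- c(4, 4, 4.5, 5, 5, 4.5, 5, 4.5, 4)
  hk <- c(Gapdh = 13, Actb = 12.5, Aldoa = 12, Pabpn1 = 11.5)
  marker <- data.frame(
    gene_id = c("Ttyh1", "Eomes", "Mki67", "Egfp"),
    class = "marker", a = 0, b = 0, cycle = 0,
    baseline = c(13, 12, 12, 12),
    marker_rule = c("AP", "IP_neuron", "cycling", "transgene"),
    spike_copies = NA_real_, stringsAsFactors = FALSE)
  temporal <- data.frame(
    gene_id = c(names(panel_dn), names(panel_up)),
    class = "temporal",
    a = c(unname(panel_dn), unname(panel_up)), b = 0, cycle = 0,
    baseline = c(base_dn, base_up),
    marker_rule = NA_character_, spike_copies = NA_real_,
    stringsAsFactors = FALSE)
  house <- data.frame(
    gene_id = names(hk), class = "housekeeping",
    a = 0, b = 0, cycle = 0, baseline = unname(hk),
    marker_rule = NA_character_, spike_copies = NA_real_,
    stringsAsFactors = FALSE)
  rbind(temporal, marker, house)
}

#' Default 18-gene temporal-axis qPCR panel
#'
#' Gene symbols of the simulated temporal-axis panel: nine genes declining
#' and nine rising with developmental time.
#' @return Character vector of 18 gene ids.
#' @export
temporal_panel <- function() {
  tg <- named_gene_table()
  tg$gene_id[tg$class == "temporal"]
}

#' Default housekeeping gene set
#' @return Character vector: Gapdh, Actb, Aldoa, Pabpn1.
#' @export
housekeeping_genes <- function() c("Gapdh", "Actb", "Aldoa", "Pabpn1")

#' Temporal-axis genes frozen in clonal (isolated) arrested cells
#'
#' Default freeze set for `apply_arrest(mode = "clonal-arrest")`: the rising
#' genes whose induction requires a tissue environment plus the early gene
#' Sulf2 whose shutdown requires it, leaving the remaining panel genes free to
#' transition cell-intrinsically.
#' @return Character vector of gene ids.
#' @export
clonal_freeze_default <- function()
  c("Zbtb20", "Rlbp1", "Sulf2", "Tgfb2", "Fabp7", "Tnc", "Slc1a3")
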