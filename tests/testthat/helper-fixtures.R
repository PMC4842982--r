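# Small shared fixtures, generated in code.

tiny_config <- function(seed = 1L, ...) {
  sim_config(stages = c(E11 = 12L, E14 = 16L, E16 = 10L),
             n_genes = 60L, seed = seed, ...)
}

# deterministic toy matrix with named dims
toy_matrix <- function(values, nr, nc, rn = sprintf("p%02d", seq_len(nr)),
                       cn = sprintf("s%02d", seq_len(nc))) {
  matrix(values, nr, nc, dimnames = list(rn, cn))
}

default_spikes <- function()
  data.frame(probe_id = sprintf("spike_%d", c(1000L, 100L, 20L, 5L)),
             copies = c(1000, 100, 20, 5))

# Independent grid-search oracle for the rotation angle: 0.01-degree scan of
# the median-difference objective over [-90, 90], refined to 1e-4 degrees
# around every sign change.  Deliberately avoids the package's bisection path.
oracle_rotation <- function(sc, ai, bi) {
  eval_f <- function(deg) {
    th <- deg * pi / 180
    Ma <- cbind(sc[ai, 1], sc[ai, 2]) %*% rbind(cos(th), sin(th))
    Mb <- cbind(sc[bi, 1], sc[bi, 2]) %*% rbind(cos(th), sin(th))
    apply(Mb, 2L, stats::median) - apply(Ma, 2L, stats::median)
  }
  coarse <- seq(-90, 90, by = 0.01)
  fc <- eval_f(coarse)
  hits <- which(fc[-length(fc)] * fc[-1] < 0 | fc[-length(fc)] == 0)
  vapply(hits, function(i) {
    fine <- seq(coarse[i], coarse[i + 1], by = 1e-4)
    ff <- eval_f(fine)
    fine[which.min(abs(ff))]
  }, 0)
}

# Two point-symmetric score clouds with exact median offsets (dx, dy): the
# symmetric construction pins each group's medians analytically.
planted_scores <- function(n = 50, dx = 1, dy = 1, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    base <- cbind(rnorm(n, sd = sd), rnorm(n, sd = sd))
    a <- rbind(base, -base)
    b <- sweep(a, 2L, c(dx, dy), "+")
  })
  sc <- rbind(a, b)
  rownames(sc) <- sprintf("c%03d", seq_len(nrow(sc)))
  list(scores = sc, ai = seq_len(2 * n), bi = 2 * n + seq_len(2 * n))
}
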