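# Shared fixtures: small, fast parameter sets used across test files.
# (The package defaults model slow mammalian reporters; tests that probe
# mechanics rather than the default regimes use these quick variants.)

# a gene with no reactions at all
null_gene <- function() gene_params(0, 0, 0, 1, 0, 0, 0)

# mRNA-only birth-death: chromatin permanently open via clamp, one mRNA per
# burst, no translation
bd_mrna_gene <- function(k = 1, dm = 0.1) gene_params(0, 0, k, 1, 0, dm, 0)

# protein-only birth-death: constant production from a frozen mRNA pool
bd_protein_gene <- function(k_tl = 0.5, dp = 0.02) {
  gene_params(0, 0, 0, 1, k_tl, 0, dp)
}

# a fast-switching two-state gene for population mechanics
fast_gene <- function(k_open = 1 / 300, k_close = 1 / 200, k_burst = 0.5,
                      b = 2, k_tl = 0.5, dm = 0.05, dp = 0.01) {
  gene_params(k_open, k_close, k_burst, b, k_tl, dm, dp)
}

pair_of <- function(g) list(A = g, B = g)

no_division_cycle <- function() cell_cycle_params(T_div = 1e7)

# founder in the open state with both genes clamped open
clamped_open_state <- function(m = 0L, p = 0L, cycle_length = 1e7) {
  cell_state(chromatin = c(A = 1L, B = 1L),
             m = c(A = m, B = m), p = c(A = p, B = p),
             cycle_length = cycle_length, clamp = c(A = 1L, B = 1L))
}

# deterministic initial state at the open-chromatin stationary means
stationary_guess_open <- function(genes, cycle) {
  dil <- log(2) / cycle$T_div
  m <- vapply(genes, function(g)
    round(g$k_burst * g$burst_size_mean / (g$delta_m + dil)), numeric(1))
  p <- vapply(seq_along(genes), function(i)
    round(genes[[i]]$k_tl * m[i] / (genes[[i]]$delta_p + dil)), numeric(1))
  names(m) <- names(p) <- c("A", "B")
  cell_state(chromatin = c(A = 1L, B = 1L), m = m, p = p,
             cycle_length = cycle$T_div)
}

# Monte-Carlo standard error of the mean of an autocorrelated series,
# estimated by batch means (block size must exceed the correlation time)
batch_se <- function(x, n_blocks) {
  n <- length(x) - length(x) %% n_blocks
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_blocks))
  stats::sd(bm) / sqrt(n_blocks)
}

# identity measurement: readout equals the true molecule count
identity_measurement <- function() {
  measurement_model(noise_cv = 0, floor_mean = 0, floor_sd = 0, gain = 1)
}
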