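test_that("clone growth doubles the population at every synchronous division", {
  genes <- pair_of(fast_gene())
  cyc <- cell_cycle_params(300)   # cv 0: strictly regular divisions
  lin <- grow_clone(cell_state(cycle_length = 300), genes, cyc,
                    t_end = 3 * 300 + 50, snapshot_times = c(100, 650, 925),
                    seed = 17)
  expect_equal(sum(lin$sample_time == 100), 1)
  expect_equal(sum(lin$sample_time == 650), 4)   # after divisions at 300, 600
  expect_equal(sum(lin$sample_time == 925), 8)   # 2^3 live cells
  expect_true(validate_lineage(lin))
})

test_that("a passaging cap of one degenerates to single-line following", {
  genes <- pair_of(fast_gene())
  cyc <- cell_cycle_params(300)
  lin <- grow_clone(cell_state(cycle_length = 300), genes, cyc,
                    t_end = 1500, snapshot_times = seq(0, 1500, 150),
                    max_cells = 1, seed = 23)
  expect_true(all(table(lin$sample_time) == 1))
  expect_true(validate_lineage(lin))
})

test_that("a silent absorbing founder yields zero fluorescence forever", {
  g <- gene_params(0, 0.01, 5, 3, 1, 0.1, 0.01)  # k_open = 0
  founder <- cell_state(chromatin = c(A = 0L, B = 0L), cycle_length = 300)
  lin <- grow_clone(founder, pair_of(g), cell_cycle_params(300),
                    t_end = 1200, snapshot_times = c(300, 600, 900, 1200),
                    seed = 31)
  expect_true(all(lin$total_A == 0) && all(lin$total_B == 0))
})

test_that("snapshots outside the culture window are rejected", {
  expect_error(
    grow_clone(cell_state(cycle_length = 300), pair_of(null_gene()),
               cell_cycle_params(300), t_end = 500, snapshot_times = 600,
               seed = 1),
    class = "memsim_config")
  expect_error(validate_lineage(data.frame(cell_id = c(1, 3),
                                           parent_id = c(NA, 2),
                                           generation = c(0, 1))),
               class = "memsim_lineage")
})

test_that("founder selection respects class bands and fails on empty classes", {
  vals <- c(0.5, 0.8, 10, 12, 30, 60, 90, 150, 200, 400)
  thr <- 1
  expect_error(select_founders(vals[vals > thr], "NEGATIVE", thr),
               class = "memsim_selection")
  expect_equal(select_founders(5, "HIGH", 1), 1)
  set.seed(2)
  hi <- vals[select_founders(vals, "HIGH", thr)]
  lo <- vals[select_founders(vals, "LOW", thr)]
  expect_gt(hi, lo)
  expect_true(all(vals[select_founders(vals, "NEGATIVE", thr, n = 3)] <= thr))
})

test_that("silencing dilutes the clamped gene by halving across divisions", {
  # pure dilution: no degradation, no synthesis after the clamp
  g <- gene_params(0, 0, 0, 1, 0, 0, 0)
  init <- cell_state(p = c(A = 1024L, B = 1024L), cycle_length = 400)
  tr <- silencing_scenario(pair_of(g), cell_cycle_params(400), t_clamp = 0,
                           t_end = 3 * 400 + 100, dt = 10, seed = 5,
                           init = init)
  p <- trace_values(tr, "A", "protein")
  t <- sort(unique(tr$time_min))
  after_k <- function(k) p[match(k * 400, t)]
  for (k in 1:3) {
    expect_lte(abs(after_k(k) - 1024 / 2^k), k)
  }
  expect_error(silencing_scenario(pair_of(g), cell_cycle_params(400),
                                  t_clamp = 100, t_end = 50, seed = 1),
               class = "memsim_config")
})

test_that("silencing one gene leaves the other transcribing", {
  genes <- pair_of(fast_gene())
  init <- cell_state(cycle_length = 600)
  tr <- silencing_scenario(genes, cell_cycle_params(600), t_clamp = 0,
                           t_end = 1800, dt = 10, seed = 77, init = init)
  expect_true(all(trace_values(tr, "A", "mrna") == 0))
  expect_true(any(trace_values(tr, "B", "mrna") > 0))
  expect_true(all(trace_values(tr, "A", "chromatin") == "CLOSED"))
})

test_that("stable lineages pass expression memory to daughters, unstable lose it within a cycle", {
  cyc <- cell_cycle_params(2160)
  Tt <- 2160
  ngen <- 6
  snaps <- sort(c((1:ngen) * Tt - 1, (1:(ngen - 1)) * Tt + 1))
  genes_s <- default_genes("stable")
  founder_s <- stationary_guess_open(genes_s, cyc)
  founder_s$clamp <- c(A = 1L, B = 1L)
  lin_s <- grow_clone(founder_s, genes_s, cyc, ngen * Tt, snaps, seed = 303)
  genes_u <- default_genes("unstable")
  founder_u <- stationary_guess_open(genes_u, cyc)
  founder_u$clamp <- c(A = 1L, B = 1L)
  lin_u <- grow_clone(founder_u, genes_u, cyc, ngen * Tt, snaps, seed = 303)

  key <- function(id, tm) paste(id, round(tm))
  md_cor <- function(lin, lag_cycle) {
    pre <- lin[abs((lin$sample_time + 1) %% Tt) < 1e-6, ]
    post <- lin[abs((lin$sample_time - 1) %% Tt) < 1e-6, ]
    if (lag_cycle) {
      pre$par <- pre$norm_A[match(key(pre$parent_id, pre$sample_time - Tt),
                                  key(pre$cell_id, pre$sample_time))]
      d <- pre[!is.na(pre$par), ]
      cor(d$par, d$norm_A)
    } else {
      post$par <- pre$norm_A[match(key(post$parent_id, post$sample_time - 2),
                                   key(pre$cell_id, pre$sample_time))]
      d <- post[!is.na(post$par), ]
      cor(d$par, d$norm_A)
    }
  }
  # daughters start where the mother left off
  expect_gt(md_cor(lin_s, lag_cycle = FALSE), 0.9)
  # one full cycle later the unstable regime has forgotten the mother's level
  n_pairs <- 2^ngen - 2
  expect_lt(abs(md_cor(lin_u, lag_cycle = TRUE)), 3 / sqrt(n_pairs))
  # while the stable regime retains a positive echo
  expect_gt(md_cor(lin_s, lag_cycle = TRUE), md_cor(lin_u, lag_cycle = TRUE))
})

test_that("FRAP labels flag ongoing synthesis and only that", {
  # always-open gene: every bleached cell resynthesizes -> RECOVERING
  g_on <- gene_params(5, 0, 0.5, 2, 0.5, 0.02, 0.001)
  cyc <- cell_cycle_params(3000)
  fr_on <- frap_experiment(pair_of(g_on), cyc, n_cells = 8,
                           bleach_fraction = 0.2, observe = 200, dt = 10,
                           seed = 41, n_reference = 8)
  expect_true(all(fr_on$labels$label == "RECOVERING"))

  # translation blocked: nothing can recover
  fr_off <- frap_experiment(pair_of(g_on), cyc, n_cells = 8,
                            bleach_fraction = 0.2, observe = 200, dt = 10,
                            seed = 42, control = "NO_TRANSLATION",
                            n_reference = 8)
  expect_true(all(fr_off$labels$label == "FLAT"))

  expect_error(frap_experiment(pair_of(g_on), cyc, 4, bleach_fraction = 1.2,
                               seed = 1),
               class = "memsim_config")
})

test_that("reactivation appears in subclones only when opening is possible", {
  # absorbing silent gene: NEGATIVE-founder subclones stay dark
  g_dead <- gene_params(0, 0.05, 2, 2, 0.5, 0.05, 0.01)
  cyc <- cell_cycle_params(400)
  res <- subclone_experiment(pair_of(g_dead), cyc, n_per_class = 2,
                             duration = 2400,
                             snapshot_times = c(800, 1600, 2400),
                             seed = 51, max_cells = 16, n_parental = 40,
                             meas = NULL, classes = "NEGATIVE")
  expect_true(all(res$fraction_positive == 0))

  # with a reopening channel some subclone reactivates eventually
  g_live <- gene_params(1 / 800, 1 / 800, 2, 2, 0.5, 0.05, 0.01)
  res2 <- subclone_experiment(pair_of(g_live), cyc, n_per_class = 3,
                              duration = 4000,
                              snapshot_times = c(2000, 4000),
                              seed = 52, max_cells = 16, n_parental = 60,
                              meas = NULL, classes = "NEGATIVE")
  expect_true(any(res2$fraction_positive > 0))
})
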