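test_that("a reactionless system is frozen", {
  genes <- pair_of(null_gene())
  init <- cell_state(p = c(A = 100L, B = 50L), cycle_length = 1e7)
  tr <- simulate_cell(genes, no_division_cycle(), 500, dt = 10, seed = 1,
                      init = init)
  expect_true(all(trace_values(tr, "A", "protein") == 100))
  expect_true(all(trace_values(tr, "B", "protein") == 50))
  expect_true(all(trace_values(tr, "A", "mrna") == 0))
})

test_that("volume grows linearly from 1 to 2 over the cycle", {
  expect_equal(volume_at(0, 1200), 1.0)
  expect_equal(volume_at(1200, 1200), 2.0)
  expect_equal(volume_at(600, 1200), 1.5)
  expect_error(volume_at(1300, 1200), class = "memsim_precondition")
  expect_error(volume_at(-5, 1200), class = "memsim_precondition")
})

test_that("division conserves molecules and halves them within one", {
  cyc <- cell_cycle_params(1000)
  set.seed(7)
  for (mode in c("EQUAL", "BINOMIAL")) {
    for (rep in 1:40) {
      m <- c(A = rpois(1, 20), B = sample(0:5, 1))
      p <- c(A = rpois(1, 500), B = rpois(1, 3))
      mother <- cell_state(m = m, p = p, age = 1000, cycle_length = 1000,
                           cell_id = 9L, generation = 2L)
      d <- divide(mother, cyc, mode = mode, ids = c(10L, 11L))
      expect_equal(d[[1]]$m + d[[2]]$m, as.numeric(m))
      expect_equal(d[[1]]$p + d[[2]]$p, as.numeric(p))
      if (mode == "EQUAL") {
        expect_true(all(abs(d[[1]]$m - d[[2]]$m) <= 1))
        expect_true(all(abs(d[[1]]$p - d[[2]]$p) <= 1))
      }
      expect_equal(d[[1]]$chromatin, mother$chromatin)
      expect_equal(d[[1]]$generation, 3L)
      expect_equal(d[[1]]$parent_id, 9L)
      expect_equal(d[[1]]$age, 0)
    }
  }
})

test_that("even splits are deterministic and odd molecules go by fair coin", {
  cyc <- cell_cycle_params(1000)
  mother4 <- cell_state(m = c(A = 4L, B = 0L), age = 1000, cycle_length = 1000)
  d <- divide(mother4, cyc)
  expect_equal(c(d[[1]]$m[1], d[[2]]$m[1]), c(2, 2))

  mother5 <- cell_state(m = c(A = 5L, B = 0L), age = 1000, cycle_length = 1000)
  set.seed(3)
  firsts <- replicate(400, divide(mother5, cyc)[[1]]$m[1])
  expect_true(all(firsts %in% c(2, 3)))
  # fair coin: each outcome near half (3 SE of a Binomial(400, 1/2))
  expect_lt(abs(mean(firsts == 3) - 0.5), 3 * 0.5 / sqrt(400))

  empty <- cell_state(age = 1000, cycle_length = 1000)
  d0 <- divide(empty, cyc)
  expect_true(all(d0[[1]]$m == 0) && all(d0[[2]]$p == 0))

  young <- cell_state(age = 500, cycle_length = 1000)
  expect_error(divide(young, cyc), class = "memsim_precondition")
})

test_that("equal seeds give bit-identical traces", {
  genes <- pair_of(fast_gene())
  cyc <- cell_cycle_params(400)
  a <- simulate_cell(genes, cyc, 3000, dt = 10, seed = 99)
  b <- simulate_cell(genes, cyc, 3000, dt = 10, seed = 99)
  expect_identical(a, b)
  c <- simulate_cell(genes, cyc, 3000, dt = 10, seed = 100)
  expect_false(identical(a, c))
})

test_that("clamped-open single-mRNA bursting reaches the Poisson law", {
  # birth-death: k = 1/min, delta = 0.1/min -> stationary Poisson(10):
  # mean 10, NV 1/10
  genes <- pair_of(bd_mrna_gene(k = 1, dm = 0.1))
  init <- clamped_open_state()
  tr <- simulate_cell(genes, no_division_cycle(), 2e4, dt = 1, seed = 5,
                      init = init)
  m <- c(trace_values(tr, "A", "mrna")[-(1:200)],
         trace_values(tr, "B", "mrna")[-(1:200)])
  expect_lt(abs(mean(m) - 10), 3 * batch_se(m, 40))
  expect_lt(abs(normalized_variance(m) - 0.1), 0.02)
})

test_that("protein birth-death autocorrelation decays as exp(-delta tau)", {
  # frozen mRNA pool of 10, k_tl = 0.5 -> constant production 5/min;
  # delta_p = 0.02 -> OU-like stationary ACF exp(-0.02 tau)
  genes <- pair_of(bd_protein_gene(k_tl = 0.5, dp = 0.02))
  init <- cell_state(m = c(A = 10L, B = 10L), p = c(A = 250L, B = 250L),
                     cycle_length = 1e7)
  tr <- simulate_cell(genes, no_division_cycle(), 4e4, dt = 5, seed = 8,
                      init = init)
  x <- trace_values(tr, "A", "protein")[-(1:100)]
  ar <- autocorrelation(x, dt = 5, max_lag = 150)
  theo <- exp(-0.02 * ar$lags)
  expect_lt(max(abs(ar$acf - theo)), 0.1)
  th <- tau_half(ar)
  expect_false(th$censored)
  expect_lt(abs(th$tau_half - log(2) / 0.02), 10)
})

test_that("interventions bleach, clamp and release as specified", {
  st <- cell_state(p = c(A = 1000L, B = 300L), cycle_length = 1000)
  b <- apply_intervention(st, intervention("BLEACH", 0, "A",
                                           bleach_fraction = 0.2))
  expect_equal(b$p[[1]], 200)
  expect_equal(b$p[[2]], 300)   # only the targeted gene is bleached
  same <- apply_intervention(st, intervention("BLEACH", 0, "A",
                                              bleach_fraction = 1))
  expect_equal(same$p, st$p)

  expect_error(intervention("FREEZE", 0), class = "memsim_config")
  expect_error(intervention("BLEACH", 0, bleach_fraction = 0),
               class = "memsim_config")

  # a closed clamp dominates an arbitrarily high burst rate
  g <- gene_params(5, 0, 50, 4, 0, 0, 0)  # opens fast, never closes
  tr <- simulate_cell(pair_of(g), no_division_cycle(), 500, dt = 10,
                      seed = 2,
                      interventions = list(intervention("CLAMP_CLOSED", 0, "A")),
                      init = cell_state(cycle_length = 1e7))
  expect_true(all(trace_values(tr, "A", "mrna") == 0))
  expect_true(any(trace_values(tr, "B", "mrna") > 0))
})

test_that("stable-regime protein rises within cycles and halves at divisions", {
  genes <- default_genes("stable")
  cyc <- cell_cycle_params(2160)
  init <- stationary_guess_open(genes, cyc)
  tr <- simulate_cell(genes, cyc, 20 * 2160, dt = 10, seed = 13,
                      interventions = list(intervention("CLAMP_OPEN", 0, "A"),
                                           intervention("CLAMP_OPEN", 0, "B")),
                      init = init)
  p <- trace_values(tr, "A", "protein")
  t <- sort(unique(tr$time_min))
  divs <- attr(tr, "division_times")
  expect_length(divs, 19)

  # across each division the copy number drops to about half
  pre <- p[match(divs, t) - 1]
  post <- p[match(divs, t)]
  expect_true(all(post / pre > 0.4 & post / pre < 0.6))

  # within cycles the trend is a steady increase
  starts <- c(0, divs)
  ends <- c(divs, max(t))
  gain <- p[match(ends, t) - 1] - p[match(starts, t)]
  expect_true(mean(gain > 0) >= 0.9)
})

test_that("simulation rejects impossible time grids", {
  genes <- pair_of(null_gene())
  expect_error(simulate_cell(genes, no_division_cycle(), 5, dt = 10, seed = 1),
               class = "memsim_simulation")
})
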