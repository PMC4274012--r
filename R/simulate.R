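# internal: 7 x 2 parameter matrix consumed by the C++ SSA core
par_matrix <- function(genes) {
  stopifnot(length(genes) == 2)
  vapply(genes, function(g) {
    c(g$k_open, g$k_close, g$k_burst, 1 / g$burst_size_mean,
      g$k_tl, g$delta_m, g$delta_p)
  }, numeric(7))
}

# internal: simulate one cell (no division) from t0 to t1, applying
# interventions scheduled inside (t0, t1]; records grid points in
# [t0, t1) -- or [t0, t1] when `closed_end` -- by last-value-carried-forward.
# Returns the updated state and one sampled segment.
run_cell_segment <- function(state, genes, t0, t1, grid, interventions,
                             closed_end = FALSE) {
  pm <- par_matrix(genes)
  iv_times <- vapply(interventions, function(iv) iv$time, numeric(1))
  keep <- iv_times > t0 + 1e-9 & iv_times <= t1 + 1e-9
  ivs <- interventions[keep]
  bounds <- sort(unique(c(vapply(ivs, function(iv) iv$time, numeric(1)), t1)))

  times <- c(); chrom <- NULL; m <- NULL; p <- NULL
  a <- t0
  for (b in bounds) {
    last <- abs(b - t1) < 1e-9
    gsub <- if (last && closed_end) grid[grid >= a - 1e-9 & grid <= b + 1e-9]
            else grid[grid >= a - 1e-9 & grid < b - 1e-9]
    out <- .ssa_segment_cpp(state$chromatin, state$m, state$p, pm,
                            state$clamp, a, b, gsub)
    state$chromatin <- out$chrom_end
    state$m <- out$m_end
    state$p <- out$p_end
    times <- c(times, gsub)
    chrom <- cbind(chrom, out$chrom); m <- cbind(m, out$m); p <- cbind(p, out$p)
    for (iv in ivs) if (abs(iv$time - b) < 1e-9) state <- apply_intervention(state, iv)
    a <- b
  }
  state$age <- t1 - state$birth_time
  list(state = state,
       segment = list(times = times, chrom = chrom, m = m, p = p,
                      cell_id = state$cell_id, generation = state$generation,
                      birth_time = state$birth_time,
                      cycle_length = state$cycle_length))
}

# internal: assemble sampled segments into a long-format trace data frame
segments_to_trace <- function(segments, dt, division_times) {
  rows <- lapply(segments, function(s) {
    n <- length(s$times)
    if (n == 0) return(NULL)
    vol <- volume_at(s$times - s$birth_time, s$cycle_length)
    do.call(rbind, lapply(1:2, function(gi) {
      data.frame(time_min = s$times, gene = c("A", "B")[gi],
                 chromatin = ifelse(s$chrom[gi, ] == 1, "OPEN", "CLOSED"),
                 mrna = s$m[gi, ], protein = s$p[gi, ], volume = vol,
                 norm_level = s$p[gi, ] / vol,
                 cell_id = s$cell_id, generation = s$generation)
    }))
  })
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$gene, tr$time_min), ]
  rownames(tr) <- NULL
  structure(tr, dt = dt, division_times = division_times,
            class = c("msim_trace", "data.frame"))
}

#' Simulate a single followed cell line
#'
#' Runs the exact stochastic simulation of both reporter genes in one cell,
#' interleaving Gillespie reaction events with scheduled division events.
#' At each division the molecules are partitioned between two daughters and
#' one daughter, chosen by a fair coin, is followed further (the in-silico
#' analogue of tracking one line through a time-lapse movie). The trace is
#' sampled on a regular grid by last-value-carried-forward.
#'
#' Reproducibility: every cell along the line draws its reaction events from
#' its own RNG stream derived from the root seed via [child_seed()];
#' division coins and daughter cycle lengths are drawn from the mother's
#' stream. Identical seeds give bit-identical traces.
#'
#' @param genes list of two [gene_params()] (elements `A`, `B`).
#' @param cycle a [cell_cycle_params()].
#' @param t_end simulated duration, min.
#' @param dt sampling interval, min (default 10, the time-lapse frame
#'   spacing).
#' @param interventions list of [intervention()] objects.
#' @param seed root seed (integer); if `NULL` a seed is drawn from the
#'   current RNG state.
#' @param init a [cell_state()] or `"stationary-guess"` (default) to start
#'   near the long-run regime.
#' @param partition `"EQUAL"` or `"BINOMIAL"` division mode.
#' @return A long-format `data.frame` of class `msim_trace` with columns
#'   `time_min, gene, chromatin, mrna, protein, volume, norm_level,
#'   cell_id, generation`, and attributes `dt` and `division_times`.
#' @export
simulate_cell <- function(genes, cycle, t_end, dt = 10,
                          interventions = list(), seed = NULL,
                          init = "stationary-guess",
                          partition = c("EQUAL", "BINOMIAL")) {
  partition <- match.arg(partition)
  if (!is.finite(t_end) || t_end <= 0 || t_end < dt)
    msim_stop("t_end must be positive and at least one sampling interval",
              "simulation")
  root <- if (is.null(seed)) draw_root_seed() else seed

  set.seed(child_seed(root, 1L))
  state <- if (identical(init, "stationary-guess")) {
    stationary_guess(genes, cycle)
  } else {
    if (!inherits(init, "cell_state")) msim_stop("invalid init", "config")
    init
  }
  # interventions scheduled at t = 0 act on the initial state
  for (iv in interventions) if (iv$time <= 1e-9) state <- apply_intervention(state, iv)

  grid <- seq(0, t_end, by = dt)
  segments <- list()
  division_times <- numeric(0)
  seeded_id <- state$cell_id

  t_cur <- state$birth_time + state$age
  while (t_cur < t_end - 1e-9) {
    if (state$cell_id != seeded_id) {
      set.seed(child_seed(root, state$cell_id))
      seeded_id <- state$cell_id
    }
    next_div <- state$birth_time + state$cycle_length
    seg_stop <- min(next_div, t_end)
    res <- run_cell_segment(state, genes, t_cur, seg_stop, grid,
                            interventions, closed_end = FALSE)
    state <- res$state
    segments[[length(segments) + 1L]] <- res$segment
    t_cur <- seg_stop
    if (next_div <= t_end - 1e-9) {
      division_times <- c(division_times, next_div)
      daughters <- divide(state, cycle, mode = partition,
                          ids = state$cell_id + 1:2)
      state <- daughters[[rbinom(1, 1, 0.5) + 1L]]
      state$cell_id <- segments[[length(segments)]]$cell_id + 1L
    }
  }
  # remaining grid points (the final one, plus the post-division state when a
  # division falls exactly at t_end)
  recorded <- unlist(lapply(segments, `[[`, "times"))
  left <- setdiff(grid, recorded)
  if (length(left) > 0) {
    vol <- volume_at(pmin(left - state$birth_time, state$cycle_length),
                     state$cycle_length)
    segments[[length(segments) + 1L]] <-
      list(times = left,
           chrom = matrix(rep(state$chromatin, length(left)), nrow = 2),
           m = matrix(rep(state$m, length(left)), nrow = 2),
           p = matrix(rep(state$p, length(left)), nrow = 2),
           cell_id = state$cell_id, generation = state$generation,
           birth_time = state$birth_time, cycle_length = state$cycle_length)
  }
  segments_to_trace(segments, dt, division_times)
}

#' Extract one channel of a trace as a time-ordered numeric vector
#'
#' @param trace an `msim_trace` (or any trace-shaped data frame).
#' @param gene `"A"` or `"B"`.
#' @param value column to extract (default `"norm_level"`).
#' @return Numeric vector ordered by time.
#' @export
trace_values <- function(trace, gene = "A", value = "norm_level") {
  sel <- trace[trace$gene == gene, ]
  sel[[value]][order(sel$time_min)]
}
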