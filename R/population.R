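# Stream-splitting scheme for population runs: cell `id` draws its SSA
# events from stream 3*id, its division draws (partition coins, daughter
# cycle lengths) from stream 3*id + 1, and any passaging subsample decided
# at its division event from stream 3*id + 2. All streams derive from the
# root seed via child_seed(), so results are independent of scheduling order.

#' Grow a clonal population from a single founder
#'
#' Breadth-first growth of the full binary lineage tree from one founder
#' cell. When a division pushes the live population above `max_cells`, a
#' uniform random subsample of `max_cells` cells is retained (emulating
#' passaging of the culture). At every requested snapshot time the state of
#' every live cell is recorded.
#'
#' @param founder a [cell_state()] (its `age` may be > 0; the founder then
#'   completes its current cycle first).
#' @param genes list of two [gene_params()].
#' @param cycle a [cell_cycle_params()].
#' @param t_end culture duration, min.
#' @param snapshot_times times (min, within `[0, t_end]`) at which all live
#'   cells are recorded.
#' @param max_cells passaging cap on the live population (>= 1).
#' @param seed root seed.
#' @param partition division mode, `"EQUAL"` or `"BINOMIAL"`.
#' @return A `data.frame` lineage table: one row per live cell per snapshot
#'   time, with columns `cell_id, parent_id, generation, birth_time,
#'   sample_time, total_A, total_B, norm_A, norm_B, chromatin_A,
#'   chromatin_B`.
#' @export
grow_clone <- function(founder, genes, cycle, t_end, snapshot_times,
                       max_cells = Inf, seed = NULL,
                       partition = c("EQUAL", "BINOMIAL")) {
  partition <- match.arg(partition)
  if (max_cells < 1) msim_stop("max_cells must be >= 1", "config")
  if (any(snapshot_times > t_end + 1e-9) || any(snapshot_times < 0))
    msim_stop("snapshot times must lie within [0, t_end]", "config")
  root <- if (is.null(seed)) draw_root_seed() else seed
  snapshot_times <- sort(snapshot_times)

  founder$cell_id <- 1L
  founder$birth_time <- -founder$age

  # simulate one cell over [birth + age, min(division, t_end)], recording
  # snapshots; returns its record
  sim_life <- function(state) {
    set.seed(child_seed(root, 3 * state$cell_id))
    t0 <- state$birth_time + state$age
    t1 <- min(state$birth_time + state$cycle_length, t_end)
    lo <- if (state$cell_id == 1L) t0 - 1e-9 else t0 + 1e-9
    grid <- snapshot_times[snapshot_times > lo & snapshot_times <= t1 + 1e-9]
    res <- run_cell_segment(state, genes, t0, t1, grid, list(),
                            closed_end = TRUE)
    list(state = res$state, seg = res$segment,
         div_time = state$birth_time + state$cycle_length)
  }

  live <- list(sim_life(founder))
  records <- list()
  next_id <- 1L
  drop_time <- numeric(0)   # names = cell_id, value = time the cell was
                            # discarded at passaging

  repeat {
    div_times <- vapply(live, `[[`, numeric(1), "div_time")
    i <- which.min(div_times)
    if (div_times[i] > t_end - 1e-9) break
    mother <- live[[i]]
    records[[length(records) + 1L]] <- mother
    live[[i]] <- NULL

    set.seed(child_seed(root, 3 * mother$state$cell_id + 1))
    daughters <- divide(mother$state, cycle, mode = partition,
                        ids = next_id + 1:2)
    next_id <- next_id + 2L
    live <- c(live, lapply(daughters, sim_life))

    if (length(live) > max_cells) {
      set.seed(child_seed(root, 3 * mother$state$cell_id + 2))
      keep <- sort(sample.int(length(live), max_cells))
      dropped <- live[setdiff(seq_along(live), keep)]
      for (d in dropped) {
        records[[length(records) + 1L]] <- d
        drop_time[as.character(d$state$cell_id)] <- mother$div_time
      }
      live <- live[keep]
    }
  }
  records <- c(records, live)

  rows <- lapply(records, function(rec) {
    s <- rec$seg
    n <- length(s$times)
    if (n == 0) return(NULL)
    dt <- drop_time[as.character(s$cell_id)]
    keep <- if (!is.na(dt) && length(dt) == 1) s$times <= dt + 1e-9 else rep(TRUE, n)
    if (!any(keep)) return(NULL)
    vol <- volume_at(pmin(s$times[keep] - s$birth_time, s$cycle_length),
                     s$cycle_length)
    data.frame(cell_id = s$cell_id,
               parent_id = rec$state$parent_id,
               generation = s$generation, birth_time = s$birth_time,
               sample_time = s$times[keep], volume = vol,
               total_A = s$p[1, keep], total_B = s$p[2, keep],
               norm_A = s$p[1, keep] / vol, norm_B = s$p[2, keep] / vol,
               chromatin_A = ifelse(s$chrom[1, keep] == 1, "OPEN", "CLOSED"),
               chromatin_B = ifelse(s$chrom[2, keep] == 1, "OPEN", "CLOSED"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_time, out$cell_id), ]
  rownames(out) <- NULL
  # full pedigree (snapshot schedules may skip generations)
  ped <- do.call(rbind, lapply(records, function(rec) {
    data.frame(cell_id = rec$state$cell_id, parent_id = rec$state$parent_id,
               generation = rec$state$generation,
               birth_time = rec$state$birth_time)
  }))
  attr(out, "pedigree") <- ped[order(ped$cell_id), ]
  out
}

#' Check the structural integrity of a lineage table
#'
#' Verifies that every non-founder's parent appears in the record and that
#' generations increase by exactly one from parent to child. Tables built
#' by [grow_clone()] carry a full `pedigree` attribute which is used when
#' present; for plain tables (e.g. read back from TSV) the check runs on
#' the table rows themselves, which requires every generation to have been
#' sampled.
#'
#' @param lineage a lineage table from [grow_clone()].
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_lineage <- function(lineage) {
  ped <- attr(lineage, "pedigree")
  cells <- if (!is.null(ped)) ped else
    lineage[!duplicated(lineage$cell_id),
            c("cell_id", "parent_id", "generation")]
  nonfounder <- cells[!is.na(cells$parent_id), ]
  ok <- nonfounder$parent_id %in% cells$cell_id
  if (!all(ok))
    msim_stop("lineage table has orphan cells", "lineage")
  pg <- cells$generation[match(nonfounder$parent_id, cells$cell_id)]
  if (!all(nonfounder$generation == pg + 1))
    msim_stop("generation must increase by 1 from parent to child", "lineage")
  invisible(TRUE)
}

#' Select a founder cell of a given expression class
#'
#' `NEGATIVE` founders are drawn from cells at or below the positivity
#' threshold; `LOW` and `HIGH` founders from the bottom quartile and top
#' decile of the positive cells, respectively (the sorter gates of the
#' original experiment are not numerically specified; these quantile bands
#' stand in for them).
#'
#' @param values per-cell expression levels of the selection channel.
#' @param cls `"HIGH"`, `"LOW"` or `"NEGATIVE"`.
#' @param threshold positivity threshold (e.g. from
#'   [positivity_threshold()]).
#' @param n number of founders to draw (with replacement if the band is
#'   smaller than `n`).
#' @return Integer indices into `values`.
#' @export
select_founders <- function(values, cls = c("HIGH", "LOW", "NEGATIVE"),
                            threshold, n = 1) {
  cls <- match.arg(cls)
  if (length(values) < 1) msim_stop("empty snapshot", "selection")
  pos <- which(values > threshold)
  band <- switch(cls,
    NEGATIVE = which(values <= threshold),
    LOW = pos[values[pos] <= quantile(values[pos], 0.25)],
    HIGH = pos[values[pos] >= quantile(values[pos], 0.90)])
  if (cls != "NEGATIVE" && length(pos) == 0)
    msim_stop(sprintf("no cells available for class %s", cls), "selection")
  if (length(band) == 0)
    msim_stop(sprintf("no cells available for class %s", cls), "selection")
  band[sample.int(length(band), n, replace = length(band) < n)]
}

# internal: simulate n independent cells to the model's long-run regime,
# asynchronous in cycle phase. Returns a list of cell_state objects.
draw_longrun_states <- function(genes, cycle, n, root, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- burnin_duration(genes, cycle)
  lapply(seq_len(n), function(i) {
    set.seed(child_seed(root, 3 * i))
    state <- stationary_guess(genes, cycle)
    t_stop <- burn_in + runif(1) * cycle$T_div
    t_cur <- 0
    state$birth_time <- 0
    next_id <- 1L
    repeat {
      t_div <- state$birth_time + state$cycle_length
      t1 <- min(t_div, t_stop)
      res <- run_cell_segment(state, genes, t_cur, t1, numeric(0), list())
      state <- res$state
      t_cur <- t1
      if (t_div >= t_stop) break
      daughters <- divide(state, cycle, ids = next_id + 1:2)
      next_id <- next_id + 2L
      state <- daughters[[rbinom(1, 1, 0.5) + 1L]]
    }
    state$cell_id <- i
    state$parent_id <- NA_integer_
    state
  })
}

#' Default burn-in duration for long-run sampling
#'
#' `10 / min(k_open, k_close)` or 20 mean cell cycles, whichever is larger,
#' so that the slow chromatin chain approaches stationarity.
#'
#' @param genes list of two [gene_params()].
#' @param cycle a [cell_cycle_params()].
#' @return Burn-in duration in minutes.
#' @export
burnin_duration <- function(genes, cycle) {
  ks <- unlist(lapply(genes, function(g) c(g$k_open, g$k_close)))
  ks <- ks[ks > 0]
  chrom <- if (length(ks) > 0) 10 / min(ks) else 0
  max(chrom, 20 * cycle$T_div)
}

#' Subclone relaxation experiment
#'
#' Emulates the sorting-and-reculture experiment: founder cells of classes
#' HIGH / LOW / NEGATIVE are drawn from a burned-in parental population,
#' each founder is expanded into a subclone, and every subclone population
#' is summarized (median level, NV, fraction positive) at scheduled
#' snapshot times.
#'
#' @param genes,cycle model parameters.
#' @param n_per_class subclones per founder class.
#' @param duration culture duration, min.
#' @param snapshot_times snapshot schedule, min.
#' @param seed root seed.
#' @param max_cells passaging cap per subclone.
#' @param n_parental size of the parental population founders are sorted
#'   from.
#' @param meas a [measurement_model()] applied to the recorded levels (the
#'   sorter sees measured, not true, fluorescence); `NULL` for raw levels.
#' @param classes founder classes to include.
#' @return A `data.frame`, one row per subclone per snapshot: `subclone`,
#'   `class`, `time_min`, `median_level`, `nv`, `fraction_positive`,
#'   `n_cells`.
#' @export
subclone_experiment <- function(genes, cycle, n_per_class = 4,
                                duration, snapshot_times, seed = NULL,
                                max_cells = 100, n_parental = 300,
                                meas = measurement_model(),
                                classes = c("HIGH", "LOW", "NEGATIVE")) {
  if (any(snapshot_times > duration + 1e-9))
    msim_stop("snapshot schedule must lie within the culture duration",
              "config")
  root <- if (is.null(seed)) draw_root_seed() else seed

  parental <- draw_longrun_states(genes, cycle, n_parental,
                                  child_seed(root, 10L))
  norm <- vapply(parental, function(s) {
    s$p[1] / volume_at(min(s$age, s$cycle_length), s$cycle_length)
  }, numeric(1))
  set.seed(child_seed(root, 11L))
  measured <- if (is.null(meas)) norm else apply_measurement(norm, meas)
  thr <- if (is.null(meas)) 0 else positivity_threshold(sample_noise_floor(meas, 5000))

  out <- list()
  sub_i <- 0L
  for (cls in classes) {
    set.seed(child_seed(root, 12L + match(cls, c("HIGH", "LOW", "NEGATIVE"))))
    idx <- select_founders(measured, cls, thr, n = n_per_class)
    for (j in seq_len(n_per_class)) {
      sub_i <- sub_i + 1L
      founder <- parental[[idx[j]]]
      lin <- grow_clone(founder, genes, cycle, duration, snapshot_times,
                        max_cells = max_cells,
                        seed = child_seed(root, 100L + sub_i))
      set.seed(child_seed(root, 1000L + sub_i))
      rows <- lapply(split(lin, lin$sample_time), function(d) {
        lev <- if (is.null(meas)) d$norm_A else apply_measurement(d$norm_A, meas)
        data.frame(subclone = sub_i, class = cls,
                   time_min = d$sample_time[1],
                   median_level = median(lev),
                   nv = if (mean(lev) != 0) mean((lev - mean(lev))^2) / mean(lev)^2
                        else NA_real_,
                   fraction_positive = fraction_positive(lev, thr),
                   n_cells = nrow(d))
      })
      out[[sub_i]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' In-silico whole-cell photobleaching (FRAP) experiment
#'
#' Cells drawn from the model's long-run regime are bleached at t = 0
#' (protein count of the target gene reduced to `bleach_fraction`) and
#' followed for `observe` minutes. Each cell is labelled `RECOVERING` or
#' `FLAT` by comparing its recovery ratio (terminal / initial
#' volume-normalized level of the target gene) against a flat-reference
#' envelope; the label is `RECOVERING` when the ratio exceeds
#' `1 + 3 * envelope half-width`.
#'
#' For an untreated cohort the reference is an independent
#' translation-blocked simulation — the only treatment that is truly
#' synthesis-free over the window (a transcription block still permits
#' translation of pre-existing long-lived mRNAs, so it is not flat).
#' Inhibitor-treated cohorts are themselves the experiment's definition of
#' flatness, so their labels are computed against their own ratio
#' envelope.
#'
#' @param genes,cycle model parameters.
#' @param n_cells cohort size.
#' @param bleach_fraction retained protein fraction at the bleach (0 < f <
#'   1; the experimental bleach retained 20 percent).
#' @param observe observation window, min (default 300 = 5 h).
#' @param dt frame spacing, min.
#' @param seed root seed.
#' @param control `"NONE"`, `"NO_TRANSCRIPTION"` (burst rate set to 0 at
#'   the bleach) or `"NO_TRANSLATION"` (translation rate set to 0).
#' @param n_reference size of the internal reference cohort used to build
#'   the envelope.
#' @param min_initial minimum pre-bleach protein count of the target gene
#'   for a cell to enter the cohort (only fluorescent cells can be
#'   photobleached; default 1).
#' @return List with `traces` (`data.frame`: `cell_id, time_min,
#'   norm_level_target, norm_level_control`) and `labels` (`data.frame`:
#'   `cell_id, ratio, label`), plus the `threshold` used.
#' @export
frap_experiment <- function(genes, cycle, n_cells, bleach_fraction = 0.2,
                            observe = 300, dt = 10, seed = NULL,
                            control = c("NONE", "NO_TRANSCRIPTION",
                                        "NO_TRANSLATION"),
                            n_reference = 30, min_initial = 1) {
  control <- match.arg(control)
  if (!is.finite(bleach_fraction) || bleach_fraction <= 0 ||
      bleach_fraction >= 1)
    msim_stop("bleach_fraction must lie in (0, 1)", "config")
  root <- if (is.null(seed)) draw_root_seed() else seed

  block <- function(g, what) {
    if (what == "NO_TRANSCRIPTION") g$k_burst <- 0
    if (what == "NO_TRANSLATION") g$k_tl <- 0
    g
  }
  run_cohort <- function(n, what, stream) {
    states <- list()
    for (k in 0:4) {
      if (length(states) >= n) break
      batch <- draw_longrun_states(genes, cycle, n, child_seed(root, stream + k))
      states <- c(states, Filter(function(s) s$p[1] >= min_initial, batch))
    }
    if (length(states) < n)
      msim_stop("too few fluorescent cells to bleach; lower min_initial",
                "selection")
    states <- states[seq_len(n)]
    genes2 <- list(A = block(genes[[1]], what), B = genes[[2]])
    grid <- seq(0, observe, by = dt)
    res <- lapply(seq_len(n), function(i) {
      set.seed(child_seed(root, child_seed(stream, i)))
      st <- states[[i]]
      st <- apply_intervention(st, intervention("BLEACH", 0, "A",
                                                bleach_fraction = bleach_fraction))
      st$birth_time <- -st$age
      t_cur <- 0
      next_id <- st$cell_id
      segs <- list()
      while (t_cur < observe - 1e-9) {
        t_div <- st$birth_time + st$cycle_length
        t1 <- min(t_div, observe)
        out <- run_cell_segment(st, genes2, t_cur, t1,
                                grid[grid >= t_cur - 1e-9 &
                                     (grid < t1 - 1e-9 |
                                      (abs(t1 - observe) < 1e-9 & grid <= t1 + 1e-9))],
                                list(), closed_end = FALSE)
        st <- out$state
        segs[[length(segs) + 1L]] <- out$segment
        t_cur <- t1
        if (t_div <= observe - 1e-9) {
          daughters <- divide(st, cycle, ids = next_id + 1:2)
          next_id <- next_id + 2L
          st <- daughters[[rbinom(1, 1, 0.5) + 1L]]
        }
      }
      times <- unlist(lapply(segs, `[[`, "times"))
      normv <- function(gi) {
        unlist(lapply(segs, function(s) {
          s$p[gi, ] / volume_at(pmin(s$times - s$birth_time, s$cycle_length),
                                s$cycle_length)
        }))
      }
      o <- order(times)
      data.frame(cell_id = i, time_min = times[o],
                 norm_level_target = normv(1)[o],
                 norm_level_control = normv(2)[o])
    })
    do.call(rbind, res)
  }

  ratio_of <- function(traces) {
    vapply(split(traces, traces$cell_id), function(d) {
      d <- d[order(d$time_min), ]
      eps <- 1e-9
      (d$norm_level_target[nrow(d)] + eps) / (d$norm_level_target[1] + eps)
    }, numeric(1))
  }

  traces <- run_cohort(n_cells, control, 3000L)
  ratios <- ratio_of(traces)
  ref_ratios <- if (control == "NONE") {
    # independent synthesis-free reference
    ratio_of(run_cohort(n_reference, "NO_TRANSLATION", 2000L))
  } else {
    # an inhibitor-treated cohort is itself the definition of flatness
    ratios
  }
  half_width <- max((max(ref_ratios) - min(ref_ratios)) / 2, 0.02)
  threshold <- 1 + 3 * half_width
  labels <- data.frame(cell_id = as.integer(names(ratios)), ratio = ratios,
                       label = ifelse(ratios > threshold, "RECOVERING", "FLAT"))
  rownames(labels) <- NULL
  list(traces = traces, labels = labels, threshold = threshold)
}

#' Silencing-and-dilution scenario
#'
#' Clamps the chromatin of one gene closed at `t_clamp` and follows a
#' single cell line: the already synthesized proteins of the silenced gene
#' are then diluted by division (and degraded), while the other reporter is
#' unaffected.
#'
#' @param genes,cycle model parameters.
#' @param t_clamp silencing onset, min.
#' @param t_end simulated duration, min (> `t_clamp`).
#' @param gene gene to silence (`"A"` or `"B"`).
#' @param dt sampling interval, min.
#' @param seed root seed.
#' @param init initial state passed to [simulate_cell()].
#' @return An `msim_trace` (see [simulate_cell()]).
#' @export
silencing_scenario <- function(genes, cycle, t_clamp, t_end, gene = "A",
                               dt = 10, seed = NULL,
                               init = "stationary-guess") {
  if (t_clamp >= t_end)
    msim_stop("t_clamp must precede t_end", "config")
  simulate_cell(genes, cycle, t_end, dt = dt,
                interventions = list(intervention("CLAMP_CLOSED", t_clamp,
                                                  gene)),
                seed = seed, init = init)
}
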