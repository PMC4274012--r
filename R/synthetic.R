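#' Measurement model for synthetic microscopy / cytometry data
#'
#' Fluorescence readout of a true molecule count `p` is
#' `gain * p * L + F`, with `L` a mean-one multiplicative lognormal factor
#' of coefficient of variation `noise_cv` and `F` a Gaussian
#' autofluorescence floor. The floor is what produces the non-expressing
#' ("black") population in snapshots and dominates the readout of dim
#' reporters.
#'
#' @param noise_cv multiplicative measurement noise CV (>= 0).
#' @param floor_mean,floor_sd autofluorescence floor parameters,
#'   fluorescence units (>= 0).
#' @param gain fluorescence units per protein molecule (> 0).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(noise_cv = 0.05, floor_mean = 50,
                              floor_sd = 35, gain = 1) {
  if (noise_cv < 0 || floor_mean < 0 || floor_sd < 0 || gain <= 0)
    msim_stop("invalid measurement-model parameters", "invalid_parameter")
  structure(list(noise_cv = noise_cv, floor_mean = floor_mean,
                 floor_sd = floor_sd, gain = gain),
            class = "measurement_model")
}

#' Apply the measurement model to true levels
#'
#' @param values true levels (molecule counts or concentrations).
#' @param meas a [measurement_model()].
#' @return Measured fluorescence values.
#' @export
apply_measurement <- function(values, meas) {
  n <- length(values)
  mult <- if (meas$noise_cv > 0) {
    sdl <- sqrt(log(1 + meas$noise_cv^2))
    rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)
  floor <- if (meas$floor_sd > 0 || meas$floor_mean > 0) {
    rnorm(n, meas$floor_mean, meas$floor_sd)
  } else rep(0, n)
  meas$gain * values * mult + floor
}

#' Sample the zero-expression noise floor
#'
#' @param meas a [measurement_model()].
#' @param n sample size.
#' @return Fluorescence readouts of non-expressing cells.
#' @export
sample_noise_floor <- function(meas, n) {
  apply_measurement(rep(0, n), meas)
}

#' Positivity threshold from a noise-floor sample
#'
#' The 99th percentile of the supplied zero-expression readout sample;
#' cells above it are called expressing.
#'
#' @param floor_sample noise-floor readouts (n >= 100).
#' @return Threshold in fluorescence units.
#' @export
positivity_threshold <- function(floor_sample) {
  if (length(floor_sample) < 100)
    msim_stop("need at least 100 floor readouts", "insufficient_data")
  unname(quantile(floor_sample, 0.99))
}

#' Generate a synthetic time-lapse tracking table
#'
#' Emulates the per-cell output of image segmentation and tracking of a
#' fluorescence time-lapse movie: `n_founders` independent lineage trees
#' are simulated, and every live cell is measured at every frame
#' (fluorescence totals per channel through the measurement model, plus a
#' volume-derived area proxy).
#'
#' @param genes,cycle model parameters.
#' @param n_founders number of independent founder cells.
#' @param duration movie length, min.
#' @param frame_interval frame spacing, min (default 10).
#' @param meas a [measurement_model()].
#' @param seed root seed.
#' @param founders optional list of [cell_state()] founders; by default
#'   founders are drawn from the model's long-run regime, asynchronously in
#'   cycle phase.
#' @param burn_in burn-in used when drawing founders (default
#'   [burnin_duration()]).
#' @param shared_deg_cv coefficient of variation of an optional per-cell
#'   multiplicative factor applied to both genes' protein degradation rate
#'   (default 0 = off). A mean-one lognormal factor is drawn once per
#'   founder tree; it models degradation machinery shared by the two
#'   reporters and couples their per-cell kinetic statistics.
#' @return A `data.frame` with columns `root_id, cell_id, parent_id,
#'   frame, time_min, total_A, total_B, area_proxy`. Cell ids are unique
#'   within a `root_id` tree.
#' @export
generate_timelapse_table <- function(genes, cycle, n_founders, duration,
                                     frame_interval = 10,
                                     meas = measurement_model(),
                                     seed = NULL, founders = NULL,
                                     burn_in = NULL, shared_deg_cv = 0) {
  if (duration < frame_interval)
    msim_stop("duration must cover at least one frame", "config")
  root <- if (is.null(seed)) draw_root_seed() else seed
  frames <- seq(0, duration, by = frame_interval)

  deg_factor <- rep(1, n_founders)
  if (shared_deg_cv > 0) {
    set.seed(child_seed(root, 8L))
    sdl <- sqrt(log(1 + shared_deg_cv^2))
    deg_factor <- rlnorm(n_founders, -sdl^2 / 2, sdl)
  }
  scale_deg <- function(genes, s) {
    lapply(genes, function(g) { g$delta_p <- g$delta_p * s; g })
  }

  if (is.null(founders)) {
    founders <- lapply(seq_len(n_founders), function(f) {
      draw_longrun_states(scale_deg(genes, deg_factor[f]), cycle, 1,
                          child_seed(root, child_seed(7L, f)),
                          burn_in = burn_in)[[1]]
    })
  }
  trees <- lapply(seq_len(n_founders), function(f) {
    lin <- grow_clone(founders[[f]], scale_deg(genes, deg_factor[f]), cycle,
                      duration, frames, seed = child_seed(root, 50L + f))
    data.frame(root_id = f, cell_id = lin$cell_id,
               parent_id = lin$parent_id,
               frame = as.integer(round(lin$sample_time / frame_interval)),
               time_min = lin$sample_time,
               true_A = lin$total_A, true_B = lin$total_B,
               volume = lin$volume, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, trees)
  set.seed(child_seed(root, 9L))
  tab$total_A <- apply_measurement(tab$true_A, meas)
  tab$total_B <- apply_measurement(tab$true_B, meas)
  sdl <- sqrt(log(1 + meas$noise_cv^2))
  tab$area_proxy <- tab$volume *
    (if (meas$noise_cv > 0) rlnorm(nrow(tab), -sdl^2 / 2, sdl) else 1)
  rownames(tab) <- NULL
  tab[, c("root_id", "cell_id", "parent_id", "frame", "time_min",
          "total_A", "total_B", "area_proxy", "true_A", "true_B", "volume")]
}

#' Generate a cytometry-like two-channel snapshot
#'
#' Draws `n_cells` independent cells from the model's long-run regime
#' (burn-in at least ten mean dwell times of the slow chromatin chain or 20
#' cell cycles, whichever is larger), asynchronous in cycle phase, and
#' measures both channels through the measurement model.
#'
#' @param genes,cycle model parameters.
#' @param n_cells number of cells.
#' @param meas a [measurement_model()].
#' @param seed root seed.
#' @param burn_in burn-in duration, min (default [burnin_duration()]).
#' @return A `data.frame`, one row per cell: `cell_id, fl_A, fl_B` (measured
#'   totals), `p_A, p_B` (true protein counts), `norm_A, norm_B`
#'   (volume-normalized true levels), `volume`, `chromatin_A, chromatin_B`.
#' @export
generate_cytometry_snapshot <- function(genes, cycle, n_cells,
                                        meas = measurement_model(),
                                        seed = NULL, burn_in = NULL) {
  if (n_cells < 1) msim_stop("n_cells must be >= 1", "config")
  root <- if (is.null(seed)) draw_root_seed() else seed
  states <- draw_longrun_states(genes, cycle, n_cells, child_seed(root, 3L),
                                burn_in = burn_in)
  vol <- vapply(states, function(s)
    volume_at(min(s$age, s$cycle_length), s$cycle_length), numeric(1))
  pA <- vapply(states, function(s) s$p[1], numeric(1))
  pB <- vapply(states, function(s) s$p[2], numeric(1))
  chA <- vapply(states, function(s) s$chromatin[1], integer(1))
  chB <- vapply(states, function(s) s$chromatin[2], integer(1))
  set.seed(child_seed(root, 4L))
  data.frame(cell_id = seq_len(n_cells),
             fl_A = apply_measurement(pA, meas),
             fl_B = apply_measurement(pB, meas),
             p_A = pA, p_B = pB,
             norm_A = pA / vol, norm_B = pB / vol, volume = vol,
             chromatin_A = ifelse(chA == 1, "OPEN", "CLOSED"),
             chromatin_B = ifelse(chB == 1, "OPEN", "CLOSED"))
}
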