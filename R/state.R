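#' Instantaneous state of one cell
#'
#' Holds the chromatin state, molecule counts and clamp flags of both
#' reporter genes, plus the cell-cycle clock and lineage identifiers.
#' Chromatin and clamp vectors are indexed by gene (`"A"`, `"B"`).
#'
#' @param chromatin integer vector per gene: 1 = OPEN, 0 = CLOSED.
#' @param m,p integer vectors of mRNA / protein counts per gene.
#' @param age time since last division, min.
#' @param cycle_length this cycle's sampled length, min.
#' @param cell_id,parent_id,generation lineage identifiers.
#' @param birth_time absolute time of this cell's birth, min.
#' @param clamp integer vector per gene: 0 = free, 1 = clamped OPEN,
#'   2 = clamped CLOSED.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(chromatin = c(A = 1L, B = 1L),
                       m = c(A = 0L, B = 0L), p = c(A = 0L, B = 0L),
                       age = 0, cycle_length = 2160,
                       cell_id = 1L, parent_id = NA_integer_, generation = 0L,
                       birth_time = 0, clamp = c(A = 0L, B = 0L)) {
  if (any(m < 0) || any(p < 0))
    msim_stop("counts must be non-negative", "invalid_state")
  if (age < 0 || age > cycle_length + 1e-9)
    msim_stop("age must lie in [0, cycle_length]", "invalid_state")
  structure(list(chromatin = as.integer(chromatin), m = as.numeric(m),
                 p = as.numeric(p), age = age, cycle_length = cycle_length,
                 cell_id = cell_id, parent_id = parent_id,
                 generation = generation, birth_time = birth_time,
                 clamp = as.integer(clamp)),
            class = "cell_state")
}

#' Cell volume at a given cycle age
#'
#' Volume grows linearly from 1 at birth to 2 at division.
#'
#' @param age time since last division, min.
#' @param cycle_length cycle length, min.
#' @return Dimensionless volume in `[1, 2]`.
#' @export
volume_at <- function(age, cycle_length) {
  if (any(age < -1e-9) || any(age > cycle_length + 1e-9))
    msim_stop("age outside [0, cycle_length]", "precondition")
  1 + pmin(pmax(age / cycle_length, 0), 1)
}

#' Draw an initial cell state near the model's long-run regime
#'
#' Chromatin state is Bernoulli with the stationary open fraction
#' `k_open / (k_open + k_close)`; counts are set to the deterministic
#' conditional means of the open state (dilution by growth included) if
#' open, and to zero if closed.
#'
#' @param genes list of two [gene_params()] (elements `A`, `B`).
#' @param cycle a [cell_cycle_params()].
#' @param cycle_length optional pre-sampled first cycle length.
#' @return A [cell_state()].
#' @export
stationary_guess <- function(genes, cycle, cycle_length = NULL) {
  if (is.null(cycle_length)) cycle_length <- sample_cycle_length(cycle)
  dil <- log(2) / cycle$T_div
  chrom <- integer(2); m <- numeric(2); p <- numeric(2)
  for (i in 1:2) {
    g <- genes[[i]]
    f <- if (g$k_open + g$k_close > 0) g$k_open / (g$k_open + g$k_close) else 1
    open <- runif(1) < f
    chrom[i] <- as.integer(open)
    if (open) {
      gm <- g$delta_m + dil
      gp <- g$delta_p + dil
      m[i] <- if (gm > 0) round(g$k_burst * g$burst_size_mean / gm) else 0
      p[i] <- if (gp > 0) round(g$k_tl * m[i] / gp) else 0
    }
  }
  names(chrom) <- names(m) <- names(p) <- c("A", "B")
  cell_state(chromatin = chrom, m = m, p = p, cycle_length = cycle_length)
}

#' Divide a cell into two daughters
#'
#' Molecule counts of every species are conserved exactly. In `EQUAL` mode
#' each daughter receives half the molecules, with any odd molecule assigned
#' by a fair coin; in `BINOMIAL` mode daughter 1 receives a
#' `Binomial(n, 1/2)` share. Both daughters inherit the mother's chromatin
#' state and clamp flags, start at age 0 (volume 1), and receive a freshly
#' sampled cycle length.
#'
#' @param state mother [cell_state()] with `age == cycle_length`.
#' @param cycle a [cell_cycle_params()] used to sample daughter cycle
#'   lengths.
#' @param mode `"EQUAL"` (default) or `"BINOMIAL"`.
#' @param ids integer vector of two new cell ids.
#' @return List of two `cell_state` daughters.
#' @export
divide <- function(state, cycle, mode = c("EQUAL", "BINOMIAL"),
                   ids = c(NA_integer_, NA_integer_)) {
  mode <- match.arg(mode)
  if (abs(state$age - state$cycle_length) > 1e-6)
    msim_stop("divide() called before the end of the cycle", "precondition")
  split1 <- function(n) {
    if (mode == "BINOMIAL") return(rbinom(1, n, 0.5))
    floor(n / 2) + if (n %% 2 == 1) rbinom(1, 1, 0.5) else 0
  }
  m1 <- vapply(state$m, split1, numeric(1))
  p1 <- vapply(state$p, split1, numeric(1))
  birth <- state$birth_time + state$cycle_length
  mk <- function(m, p, id, cl) {
    cell_state(chromatin = state$chromatin, m = m, p = p, age = 0,
               cycle_length = cl, cell_id = id, parent_id = state$cell_id,
               generation = state$generation + 1L, birth_time = birth,
               clamp = state$clamp)
  }
  d1 <- mk(m1, p1, ids[1], sample_cycle_length(cycle))
  d2 <- mk(state$m - m1, state$p - p1, ids[2], sample_cycle_length(cycle))
  list(d1, d2)
}

#' Construct an intervention
#'
#' Interventions act on one gene of the simulated cell at a scheduled time:
#' `CLAMP_OPEN` / `CLAMP_CLOSED` fix the chromatin state from the onset
#' onwards (until a later clamp replaces it), `BLEACH` instantaneously
#' reduces the protein count to `bleach_fraction` of its value, and
#' `RELEASE` removes an active clamp.
#'
#' @param kind `"CLAMP_OPEN"`, `"CLAMP_CLOSED"`, `"BLEACH"` or `"RELEASE"`.
#' @param time onset, min.
#' @param gene `"A"` or `"B"`.
#' @param bleach_fraction retained fraction of the protein count
#'   (required for `BLEACH`, in (0, 1]).
#' @return An object of class `msim_intervention`.
#' @export
intervention <- function(kind, time, gene = "A", bleach_fraction = NULL) {
  kinds <- c("CLAMP_OPEN", "CLAMP_CLOSED", "BLEACH", "RELEASE")
  if (!kind %in% kinds)
    msim_stop(sprintf("unknown intervention kind '%s'", kind), "config")
  if (!gene %in% c("A", "B"))
    msim_stop("intervention gene must be 'A' or 'B'", "config")
  if (kind == "BLEACH") {
    if (is.null(bleach_fraction) || !is.finite(bleach_fraction) ||
        bleach_fraction <= 0 || bleach_fraction > 1)
      msim_stop("bleach_fraction must lie in (0, 1]", "config")
  }
  structure(list(kind = kind, time = time, gene = gene,
                 bleach_fraction = bleach_fraction),
            class = "msim_intervention")
}

#' Apply an intervention to a cell state
#'
#' @param state a [cell_state()].
#' @param iv an [intervention()].
#' @return The modified `cell_state`.
#' @export
apply_intervention <- function(state, iv) {
  gi <- match(iv$gene, c("A", "B"))
  switch(iv$kind,
    BLEACH = {
      state$p[gi] <- round(state$p[gi] * iv$bleach_fraction)
    },
    CLAMP_OPEN = {
      state$clamp[gi] <- 1L
      state$chromatin[gi] <- 1L
    },
    CLAMP_CLOSED = {
      state$clamp[gi] <- 2L
      state$chromatin[gi] <- 0L
    },
    RELEASE = {
      state$clamp[gi] <- 0L
    },
    msim_stop(sprintf("unknown intervention kind '%s'", iv$kind), "config")
  )
  state
}
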