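#' Convert a half-life to a first-order rate constant
#'
#' @param t_half half-life in minutes (> 0).
#' @return Rate constant in 1/min, `log(2) / t_half`.
#' @examples
#' half_life_to_rate(2580)  # 43 h protein half-life -> ~2.69e-4 /min
#' @export
half_life_to_rate <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    msim_stop("half-life must be a positive finite number", "invalid_parameter")
  log(2) / t_half
}

#' Convert a first-order rate constant to a half-life
#'
#' Inverse of [half_life_to_rate()].
#'
#' @param rate rate constant in 1/min (> 0).
#' @return Half-life in minutes.
#' @export
rate_to_half_life <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0))
    msim_stop("rate must be a positive finite number", "invalid_parameter")
  log(2) / rate
}

#' Kinetic parameters of one reporter gene
#'
#' The gene is a two-state (open/closed chromatin) promoter. While open,
#' transcription bursts fire at rate `k_burst`, each producing a shifted
#' geometric number of mRNAs with mean `burst_size_mean` (mean 1 degenerates
#' to the classic one-mRNA-per-event telegraph model). mRNAs are translated
#' at `k_tl` per mRNA and both species decay by first-order kinetics.
#'
#' @param k_open chromatin opening rate, 1/min.
#' @param k_close chromatin closing rate, 1/min.
#' @param k_burst burst initiation rate while chromatin is open, 1/min.
#' @param burst_size_mean mean mRNAs per burst (>= 1).
#' @param k_tl translation rate, proteins per mRNA per min.
#' @param delta_m mRNA degradation rate, 1/min.
#' @param delta_p protein degradation rate, 1/min.
#' @param name optional label (e.g. `"YFP"`).
#' @return An object of class `gene_params`.
#' @export
gene_params <- function(k_open, k_close, k_burst, burst_size_mean,
                        k_tl, delta_m, delta_p, name = "gene") {
  rates <- c(k_open = k_open, k_close = k_close, k_burst = k_burst,
             k_tl = k_tl, delta_m = delta_m, delta_p = delta_p)
  if (any(!is.finite(rates)) || any(rates < 0))
    msim_stop("all rates must be finite and >= 0", "invalid_parameter")
  if (!is.finite(burst_size_mean) || burst_size_mean < 1)
    msim_stop("burst_size_mean must be >= 1", "invalid_parameter")
  structure(list(k_open = k_open, k_close = k_close, k_burst = k_burst,
                 burst_size_mean = burst_size_mean, k_tl = k_tl,
                 delta_m = delta_m, delta_p = delta_p, name = name),
            class = "gene_params")
}

#' Cell-cycle parameters
#'
#' Cycle lengths are drawn from a normal distribution with mean `T_div` and
#' standard deviation `cv_div * T_div`, truncated below at `0.5 * T_div`.
#' The default `cv_div = 0` gives strictly regular divisions. Cell volume
#' grows linearly from 1 at birth to 2 at division.
#'
#' @param T_div mean cell-cycle length, minutes.
#' @param cv_div coefficient of variation of the cycle length (>= 0).
#' @return An object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(T_div = 2160, cv_div = 0) {
  if (!is.finite(T_div) || T_div <= 0)
    msim_stop("T_div must be > 0", "invalid_parameter")
  if (!is.finite(cv_div) || cv_div < 0)
    msim_stop("cv_div must be >= 0", "invalid_parameter")
  structure(list(T_div = T_div, cv_div = cv_div), class = "cell_cycle_params")
}

#' Sample one cell-cycle length
#'
#' @param cycle a [cell_cycle_params()] object.
#' @return Cycle length in minutes, truncated below at `0.5 * T_div`.
#' @export
sample_cycle_length <- function(cycle) {
  if (cycle$cv_div == 0) return(cycle$T_div)
  max(0.5 * cycle$T_div, rnorm(1, cycle$T_div, cycle$cv_div * cycle$T_div))
}

#' Reaction propensities of one gene in a given state
#'
#' Returns the five reaction rates of the telegraph model for one gene:
#' chromatin switch, burst initiation, mRNA decay, translation, protein
#' decay. Transcription-related channels are zero while chromatin is closed.
#'
#' @param chromatin `"OPEN"` or `"CLOSED"`.
#' @param m,p current mRNA and protein counts (integers >= 0).
#' @param params a [gene_params()] object.
#' @return Named numeric vector `c(switch, burst, mrna_decay, translation,
#'   protein_decay)`.
#' @export
propensities <- function(chromatin, m, p, params) {
  chromatin <- match.arg(chromatin, c("OPEN", "CLOSED"))
  if (m < 0 || p < 0 || m != round(m) || p != round(p))
    msim_stop("counts must be non-negative integers", "invalid_state")
  open <- chromatin == "OPEN"
  c(switch        = if (open) params$k_close else params$k_open,
    burst         = if (open) params$k_burst else 0,
    mrna_decay    = m * params$delta_m,
    translation   = m * params$k_tl,
    protein_decay = p * params$delta_p)
}

#' Sample a transcription-burst size
#'
#' Burst sizes follow a shifted geometric law on \{1, 2, ...\} with the given
#' mean; mean 1 is the degenerate single-mRNA burst.
#'
#' @param burst_size_mean mean burst size (>= 1).
#' @param n number of draws.
#' @return Integer vector of burst sizes, all >= 1.
#' @export
sample_burst_size <- function(burst_size_mean, n = 1) {
  if (!is.finite(burst_size_mean) || burst_size_mean < 1)
    msim_stop("burst_size_mean must be >= 1", "invalid_parameter")
  q <- 1 / burst_size_mean
  if (q >= 1) return(rep(1L, n))
  1L + rgeom(n, q)
}

#' Default reporter-gene parameter sets
#'
#' Two half-life regimes of the same promoter construct, each with a
#' YFP-like and a CFP-like reporter. The "stable" regime uses long-lived
#' gene products (mRNA half-life 3.5 h; protein half-lives 43 h and 29.5 h);
#' the "unstable" regime uses destabilized products (mRNA 1.5 h / 1.9 h;
#' protein 6 h 30 / 5 h 40). Chromatin switches are rare (mean closed dwell
#' 18 days, mean open dwell 12 days, open fraction 0.4). The burst rate and
#' effective translation rates were fixed once from the observable scales of
#' the system (clamped-open noise level of the stable reporter and the
#' roughly hundredfold lower mean expression of the destabilized clones);
#' see the package vignette for the calibration.
#'
#' @param regime `"stable"` or `"unstable"`.
#' @return List with elements `A` (YFP-like) and `B` (CFP-like), both
#'   [gene_params()] objects.
#' @export
default_genes <- function(regime = c("stable", "unstable")) {
  regime <- match.arg(regime)
  k_open <- 1 / 25920   # mean closed dwell 18 days
  k_close <- 1 / 17280  # mean open dwell 12 days
  if (regime == "stable") {
    list(
      A = gene_params(k_open, k_close, k_burst = 0.03, burst_size_mean = 3,
                      k_tl = 0.2, delta_m = half_life_to_rate(210),
                      delta_p = half_life_to_rate(2580), name = "YFP"),
      B = gene_params(k_open, k_close, k_burst = 0.03, burst_size_mean = 3,
                      k_tl = 0.2, delta_m = half_life_to_rate(210),
                      delta_p = half_life_to_rate(1770), name = "CFP"))
  } else {
    list(
      A = gene_params(k_open, k_close, k_burst = 0.03, burst_size_mean = 3,
                      k_tl = 0.016, delta_m = half_life_to_rate(90),
                      delta_p = half_life_to_rate(390), name = "YFP"),
      B = gene_params(k_open, k_close, k_burst = 0.03, burst_size_mean = 3,
                      k_tl = 0.016, delta_m = half_life_to_rate(114),
                      delta_p = half_life_to_rate(340), name = "CFP"))
  }
}
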