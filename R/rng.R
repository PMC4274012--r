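#' Derive a per-cell RNG child seed from a root seed
#'
#' Population runs give every cell its own reproducible RNG stream: all
#' randomness affecting cell `id` (its SSA trajectory, its division coins,
#' its sampled cycle length) is drawn after seeding with
#' `child_seed(root, id)`. The split is a fixed LCG-style mix modulo the
#' Mersenne prime 2^31 - 1, so results do not depend on the order in which
#' cells are scheduled.
#'
#' @param root root seed (integer).
#' @param id non-negative integer stream identifier (cell id, replicate
#'   index, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root, id) {
  if (any(id < 0)) msim_stop("stream id must be >= 0", "invalid_parameter")
  as.integer(((root %% 2147483647) * 16807 + id * 69621 + 12345) %% 2147483647)
}

# draw a fresh root seed from the current RNG state when none was supplied
draw_root_seed <- function() {
  sample.int(2147483646L, 1L)
}
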