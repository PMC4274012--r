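# minimal TOML reader for the flat subset used by run configs: [section],
# [section.sub], [[array-of-tables]], key = value with numeric, boolean,
# string and simple inline arrays. (No TOML parser ships with the
# environment's R stack; this covers the configuration grammar only.)
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  res <- list()
  ctx <- character(0)
  arr_ctx <- FALSE
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[", v)) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (trimws(inner) == "") return(list())
      return(lapply(strsplit(inner, ",")[[1]], parse_val))
    }
    if (v %in% c("true", "false")) return(v == "true")
    if (grepl('^".*"$', v)) return(sub('^"', "", sub('"$', "", v)))
    if (grepl("^'.*'$", v)) return(sub("^'", "", sub("'$", "", v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  get_at <- function(lst, path) {
    for (p in path) lst <- lst[[p]]
    lst
  }
  set_at <- function(lst, path, value) {
    if (length(path) == 0) return(value)
    key <- path[1]
    if (is.null(lst[[key]])) lst[[key]] <- list()
    lst[[key]] <- set_at(lst[[key]], path[-1], value)
    lst
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[\\[.*\\]\\]$", line)) {
      name <- trimws(gsub("^\\[\\[|\\]\\]$", "", line))
      ctx <- strsplit(name, ".", fixed = TRUE)[[1]]
      cur <- get_at(res, ctx)
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1L]] <- list()
      res <- set_at(res, ctx, cur)
      arr_ctx <- TRUE
    } else if (grepl("^\\[.*\\]$", line)) {
      name <- trimws(gsub("^\\[|\\]$", "", line))
      ctx <- strsplit(name, ".", fixed = TRUE)[[1]]
      if (is.null(get_at(res, ctx))) res <- set_at(res, ctx, list())
      arr_ctx <- FALSE
    } else if (grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- trimws(substr(line, 1, eq - 1))
      val <- parse_val(substr(line, eq + 1, nchar(line)))
      if (arr_ctx) {
        cur <- get_at(res, ctx)
        cur[[length(cur)]][[key]] <- val
        res <- set_at(res, ctx, cur)
      } else {
        res <- set_at(res, c(ctx, key), val)
      }
    } else {
      msim_stop(sprintf("cannot parse config line: '%s'", raw), "config")
    }
  }
  res
}

# allowed config keys
.gene_keys <- c("k_open", "k_close", "k_burst", "burst_size_mean", "k_tl",
                "delta_m", "delta_p", "mrna_half_life_h",
                "protein_half_life_h", "name")
.cycle_keys <- c("T_div_min", "T_div_h", "cv_div")
.meas_keys <- c("noise_cv", "floor_mean", "floor_sd", "gain")
.iv_keys <- c("kind", "time_min", "time_h", "gene", "bleach_fraction")
.top_keys <- c("scenario", "seed", "out_dir", "regime", "genes", "cycle",
               "measurement", "interventions", "options")
.opt_keys <- c("t_end_min", "t_end_h", "dt_min", "n_cells", "n_founders",
               "duration_min", "duration_h", "frame_interval_min",
               "snapshot_times_min", "snapshot_times_h", "n_per_class",
               "max_cells", "n_parental", "bleach_fraction", "observe_min",
               "observe_h", "control", "t_clamp_min", "t_clamp_h", "input",
               "max_lag_min", "partition", "n_reference")

check_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad) > 0)
    msim_stop(sprintf("unknown config key '%s' in %s", bad[1], where),
              "config")
}

resolve_gene <- function(block, default, where) {
  check_keys(block, .gene_keys, where)
  if (!is.null(block$mrna_half_life_h)) {
    block$delta_m <- half_life_to_rate(block$mrna_half_life_h * 60)
    block$mrna_half_life_h <- NULL
  }
  if (!is.null(block$protein_half_life_h)) {
    block$delta_p <- half_life_to_rate(block$protein_half_life_h * 60)
    block$protein_half_life_h <- NULL
  }
  merged <- modifyList(unclass(default), block)
  do.call(gene_params, merged)
}

#' Parse a run configuration file
#'
#' Accepts TOML, YAML or JSON (by file extension). All rates are
#' normalized to 1/min; `*_half_life_h`, `*_h` duration keys are converted
#' at parse time. Unknown keys are rejected by name. Gene blocks default to
#' the stable-regime parameter set (or the set named by `regime`).
#'
#' @param path configuration file.
#' @return An object of class `msim_config`: `scenario`, `seed`, `out_dir`,
#'   `genes`, `cycle`, `meas`, `interventions`, `options`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) msim_stop(sprintf("no such file: %s", path), "config")
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
    toml = parse_flat_toml(path),
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE),
    msim_stop(sprintf("unsupported config format '.%s'", ext), "config"))
  if (!is.list(raw)) msim_stop("config must be a key/value table", "config")
  check_keys(raw, .top_keys, "top level")

  scenario <- raw$scenario %||% "simulate"
  ok <- c("simulate", "subclone", "frap", "silencing", "synth", "analyze")
  if (!scenario %in% ok)
    msim_stop(sprintf("unknown scenario '%s'", scenario), "config")

  regime <- raw$regime %||% "stable"
  defaults <- default_genes(regime)
  genes <- defaults
  if (!is.null(raw$genes)) {
    check_keys(raw$genes, c("A", "B"), "genes")
    for (g in names(raw$genes)) {
      genes[[g]] <- resolve_gene(raw$genes[[g]], defaults[[g]],
                                 paste0("genes.", g))
    }
  }

  cyc <- raw$cycle %||% list()
  check_keys(cyc, .cycle_keys, "cycle")
  T_div <- cyc$T_div_min %||% (if (!is.null(cyc$T_div_h)) cyc$T_div_h * 60 else 2160)
  cycle <- cell_cycle_params(T_div = T_div, cv_div = cyc$cv_div %||% 0)

  mb <- raw$measurement %||% list()
  check_keys(mb, .meas_keys, "measurement")
  meas <- do.call(measurement_model, mb)

  ivs <- lapply(seq_along(raw$interventions %||% list()), function(i) {
    b <- raw$interventions[[i]]
    check_keys(b, .iv_keys, sprintf("interventions[%d]", i))
    tm <- b$time_min %||% (if (!is.null(b$time_h)) b$time_h * 60 else
      msim_stop("intervention needs time_min or time_h", "config"))
    intervention(b$kind %||% msim_stop("intervention needs a kind", "config"),
                 tm, gene = b$gene %||% "A",
                 bleach_fraction = b$bleach_fraction)
  })

  opts <- raw$options %||% list()
  check_keys(opts, .opt_keys, "options")
  h2m <- function(min_key, h_key, default = NULL) {
    opts[[min_key]] %||%
      (if (!is.null(opts[[h_key]])) opts[[h_key]] * 60 else default)
  }
  options <- list(
    t_end_min = h2m("t_end_min", "t_end_h", 7 * cycle$T_div),
    dt_min = opts$dt_min %||% 10,
    n_cells = opts$n_cells %||% 100,
    n_founders = opts$n_founders %||% 20,
    duration_min = h2m("duration_min", "duration_h", 7200),
    frame_interval_min = opts$frame_interval_min %||% 10,
    snapshot_times_min = opts$snapshot_times_min %||%
      (if (!is.null(opts$snapshot_times_h)) opts$snapshot_times_h * 60 else NULL),
    n_per_class = opts$n_per_class %||% 4,
    max_cells = opts$max_cells %||% 100,
    n_parental = opts$n_parental %||% 300,
    bleach_fraction = opts$bleach_fraction %||% 0.2,
    observe_min = h2m("observe_min", "observe_h", 300),
    control = opts$control %||% "NONE",
    t_clamp_min = h2m("t_clamp_min", "t_clamp_h", 0),
    input = opts$input,
    max_lag_min = opts$max_lag_min,
    partition = opts$partition %||% "EQUAL",
    n_reference = opts$n_reference %||% 30)

  structure(list(scenario = scenario, seed = raw$seed %||% 1L,
                 out_dir = raw$out_dir %||% ".", genes = genes,
                 cycle = cycle, meas = meas, interventions = ivs,
                 options = options),
            class = "msim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
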