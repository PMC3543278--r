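#' Read a declarative run configuration
#'
#' Configurations are YAML files with a versioned schema.  Every physical
#' parameter must be present explicitly; unknown keys are rejected (typo
#' safety) and missing keys fail loudly — there are no silent defaults for
#' physics.  See [makeFixtures()] for complete examples.
#'
#' @param path YAML file path.
#' @return named list with elements \code{unit} (\linkS4class{UnitParams}),
#'   \code{network} (\linkS4class{MemoryNetwork} or NULL),
#'   \code{schedule} (\linkS4class{ModulationSchedule} or NULL),
#'   \code{run} (solver/analysis settings) and \code{raw}.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configurations")
  cfg <- yaml::read_yaml(path)
  allowed_top <- c("schema", "unit", "patterns", "interunit", "schedule",
                   "run")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$schema) || cfg$schema != "qlandscape/1")
    stop("missing or unsupported schema (expected 'qlandscape/1')")

  need <- function(block, keys, where) {
    missing <- setdiff(keys, names(block))
    if (length(missing))
      stop("missing keys in ", where, ": ", paste(missing, collapse = ", "))
    extra <- setdiff(names(block), keys)
    if (length(extra))
      stop("unknown keys in ", where, ": ", paste(extra, collapse = ", "))
  }

  ukeys <- c("n_exc", "n_inh", "drive_exc", "drive_inh", "g_ee", "g_ei",
             "g_ie", "g_ii", "gap_strength", "kappa_exc", "kappa_inh",
             "noise_intensity")
  need(cfg$unit, ukeys, "unit")
  u <- cfg$unit
  unit <- UnitParams(nExc = u$n_exc, nInh = u$n_inh,
                     driveExc = u$drive_exc, driveInh = u$drive_inh,
                     gEE = u$g_ee, gEI = u$g_ei, gIE = u$g_ie,
                     gII = u$g_ii, gapStrength = u$gap_strength,
                     kappaExc = u$kappa_exc, kappaInh = u$kappa_inh,
                     noiseIntensity = u$noise_intensity)

  network <- NULL
  if (!is.null(cfg$patterns)) {
    pk <- c("matrix", "active_fraction")
    need(cfg$patterns, pk, "patterns")
    pm <- do.call(rbind, lapply(cfg$patterns$matrix, as.numeric))
    ps <- PatternSet(t(pm), cfg$patterns$active_fraction)
    ik <- c("intensity_ee", "intensity_ie", "intensity_ei",
            "regulation_x", "regulation_c")
    need(cfg$interunit, ik, "interunit")
    iu <- cfg$interunit
    network <- MemoryNetwork(unit, ps,
                             intensities = c(ee = iu$intensity_ee,
                                             ie = iu$intensity_ie,
                                             ei = iu$intensity_ei),
                             regulationX = iu$regulation_x,
                             regulationC = iu$regulation_c)
  }

  schedule <- NULL
  if (!is.null(cfg$schedule)) {
    sk <- c("ach_level", "ge_level", "ach_window", "ach_decay",
            "glu_units", "glu_increment", "glu_window")
    need(cfg$schedule, sk, "schedule")
    s <- cfg$schedule
    schedule <- ModulationSchedule(
      achLevel = s$ach_level, gELevel = s$ge_level,
      achWindow = as.numeric(s$ach_window),
      achDecay = if (identical(s$ach_decay, "inf")) Inf
                 else as.numeric(s$ach_decay),
      gluUnits = as.integer(unlist(s$glu_units)),
      gluIncrement = s$glu_increment,
      gluWindow = as.numeric(s$glu_window))
  }

  rkeys <- c("seed", "dt", "duration", "grid_size", "output_stride",
             "threshold", "kernel_width")
  need(cfg$run, rkeys, "run")
  list(unit = unit, network = network, schedule = schedule, run = cfg$run,
       raw = cfg)
}

#' Emit fixture configurations and constructed analytic fixtures
#'
#' Writes (a) a reduced-scale run configuration for every experiment
#' (M = 8 network, coarse grid, short horizons), (b) the full 16-unit
#' reference configuration, and (c) constructed analytic fixtures: a
#' square-wave overlap trace with known plateau widths and a linear
#' contraction benchmark for the Lyapunov estimator.  Golden values inside
#' the fixtures are regenerated from the constructions at write time,
#' never hand-typed.
#'
#' @param dir writable output directory.
#' @return character vector of written paths, invisibly.
#' @export
makeFixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configurations")
  paths <- character(0)
  unit_block <- function(p) list(
    n_exc = p@nExc, n_inh = p@nInh, drive_exc = p@driveExc,
    drive_inh = p@driveInh, g_ee = p@gEE, g_ei = p@gEI, g_ie = p@gIE,
    g_ii = p@gII, gap_strength = p@gapStrength, kappa_exc = p@kappaExc,
    kappa_inh = p@kappaInh, noise_intensity = p@noiseIntensity)
  net_blocks <- function(net) list(
    patterns = list(
      matrix = lapply(seq_len(ncol(net@patterns@patterns)), function(j)
        as.integer(net@patterns@patterns[, j])),
      active_fraction = net@patterns@activeFraction),
    interunit = list(
      intensity_ee = unname(net@weights@intensities[["ee"]]),
      intensity_ie = unname(net@weights@intensities[["ie"]]),
      intensity_ei = unname(net@weights@intensities[["ei"]]),
      regulation_x = net@weights@regulationX,
      regulation_c = net@weights@regulationC))
  run_block <- list(seed = 1, dt = 0.01, duration = 600, grid_size = 64,
                    output_stride = 0.25, threshold = 0.85,
                    kernel_width = 0.5)
  for (preset in c("reduced", "sixteen")) {
    net <- networkPreset(preset)
    cfg <- c(list(schema = "qlandscape/1",
                  unit = unit_block(net@unitParams)),
             net_blocks(net),
             list(schedule = list(ach_level = 0, ge_level = 0,
                                  ach_window = c(0, "inf"),
                                  ach_decay = "inf",
                                  glu_units = list(),
                                  glu_increment = 0,
                                  glu_window = c(0, 0)),
                  run = run_block))
    cfg$schedule$ach_window <- c(0, 1e9)
    f <- file.path(dir, paste0("ongoing-", preset, ".yaml"))
    yaml::write_yaml(cfg, f)
    paths <- c(paths, f)
  }
  # constructed square-wave overlap fixture: widths are the ground truth
  tt <- seq(0, 100, by = 0.1)
  sq <- ifelse(tt >= 10 & tt < 35, 0.95, ifelse(tt >= 50 & tt < 80, 0.92,
                                                0.1))
  f <- file.path(dir, "square-wave-overlap.tsv")
  utils::write.table(data.frame(time = tt, m1 = sq), f, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}
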