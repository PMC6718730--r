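#' The stability-coefficient sweep grid
#'
#' Grid index k maps to encoder parameters
#' \eqn{\gamma_k = 0.0133 k}, \eqn{\alpha_k = 1 - 0.005 k},
#' \eqn{\beta_k = \gamma_k (4 - 2\alpha_k)}, covering the stable fixed-point
#' range (\eqn{\gamma_{75} = 0.9975 < 1}).
#'
#' @param k integer grid indices in 1..75.
#' @return data.frame with columns \code{k}, \code{gamma}, \code{alpha},
#'   \code{beta}.
#' @examples
#' sweepGrid(25)   # alpha 0.875, beta 0.7481, gamma 0.3325
#' @export
sweepGrid <- function(k = 1:75) {
  stopifnot(all(k == round(k)), all(k >= 1), all(k <= 75))
  gamma <- 0.0133 * k
  alpha <- 1 - 0.005 * k
  data.frame(k = as.integer(k), gamma = gamma, alpha = alpha,
             beta = gamma * (4 - 2 * alpha))
}

# deterministic per-grid-point seed below 2^31, mixed from (seed, k)
deriveSeed <- function(seed, k) {
  as.integer((abs(as.double(seed)) * 1009 + as.double(k) * 7919 + 1) %%
               2147483647)
}

#' Monte-Carlo reliability sweep over the stability coefficient
#'
#' For each grid index k, runs \code{T} independent replicates of the full
#' single-neuron transfer experiment: a fresh gated sound-wave stimulus
#' (length \code{n}), the m-relay encoder--decoder chain at the grid-point
#' encoder parameters, and the propagation success rate of the c3-binarized
#' terminal output against the binarized stimulus.  Returns the per-point
#' mean (and sd) of the success rate.
#'
#' The whole sweep is deterministic given \code{seed}: each grid point uses
#' an RNG stream seeded from \code{(seed, k)}, so points can be recomputed
#' independently and in any order.
#'
#' @param kRange grid indices (1..75).
#' @param T replicates per grid point (10000 by default; use
#'   \code{pilot = TRUE} for a 500-replicate desk check).
#' @param m relay count (6 by default; 3000 for the long-chain variant).
#' @param n stimulus length (200 by default).
#' @param seed master seed, integer.
#' @param stimulusParams generator parameters of the sound-wave stimulus
#'   ([soundWaveParams()] by default; pass
#'   \code{soundWaveParams("printed")} for the alternate reading).
#' @param thresholds decoder thresholds, a [DecoderThresholds-class].
#' @param pilot when TRUE, overrides \code{T} to 500.
#' @return data.frame with one row per grid point: \code{k}, \code{gamma},
#'   \code{alpha}, \code{beta}, \code{m}, \code{n}, \code{T},
#'   \code{meanSuccess}, \code{sdSuccess}.
#' @examples
#' runSuccessSweep(kRange = 25, T = 50, m = 6, seed = 1)$meanSuccess
#' @export
runSuccessSweep <- function(kRange = 1:75, T = 10000, m = 6, n = 200,
                            seed = 1,
                            stimulusParams = soundWaveParams(),
                            thresholds = DecoderThresholds(),
                            pilot = FALSE) {
  stopifnot(T >= 1, m >= 1, n >= 2,
            is(stimulusParams, "NlariParams"),
            is(thresholds, "DecoderThresholds"))
  if (pilot) T <- 500L
  grid <- sweepGrid(kRange)
  grid$m <- as.integer(m)
  grid$n <- as.integer(n)
  grid$T <- as.integer(T)
  grid$meanSuccess <- NA_real_
  grid$sdSuccess <- NA_real_
  for (i in seq_len(nrow(grid))) {
    set.seed(deriveSeed(seed, grid$k[i]))
    rates <- cpp_sweep_point(as.integer(T), as.integer(n), as.integer(m),
                             grid$alpha[i], grid$beta[i],
                             stimulusParams@alpha, stimulusParams@beta,
                             stimulusParams@sigma,
                             thresholds@c1, thresholds@c2, thresholds@c3,
                             thresholds@sigma1)
    grid$meanSuccess[i] <- mean(rates)
    grid$sdSuccess[i] <- sd(rates)
  }
  grid
}

#' Read a membrane-potential trace from a text file
#'
#' Accepts either a headerless single-column file of values or a two-column
#' CSV with header \code{time_ms,value}.  For the CSV form the sampling step
#' is inferred from the time column (which must be uniform to within 1e-9);
#' otherwise it defaults to 2 ms.  Malformed rows are rejected with their
#' line numbers.
#'
#' @param path file path.
#' @param format \code{"single_column"} or \code{"time_value_csv"}; guessed
#'   from the first line by default.
#' @return a [PotentialTrace-class] with \code{scaleNote = "raw"}.
#' @export
readTrace <- function(path, format = c("guess", "single_column",
                                       "time_value_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty trace file: ", path)
  if (format == "guess")
    format <- if (grepl("^\\s*time_ms\\s*,", lines[1L], ignore.case = TRUE))
      "time_value_csv" else "single_column"
  bad <- function(i) stop("malformed row at line ", i, " of ", path)
  if (format == "time_value_csv") {
    if (!grepl("^\\s*time_ms\\s*,\\s*value\\s*$", lines[1L],
               ignore.case = TRUE))
      stop("expected header 'time_ms,value' in ", path)
    body <- lines[-1L]
    tm <- val <- numeric(length(body))
    for (i in seq_along(body)) {
      parts <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) bad(i + 1L)
      v <- suppressWarnings(as.numeric(parts))
      if (any(is.na(v))) bad(i + 1L)
      tm[i] <- v[1L]
      val[i] <- v[2L]
    }
    if (length(tm) >= 2L) {
      steps <- diff(tm)
      if (diff(range(steps)) > 1e-9)
        stop("non-uniform time steps in ", path)
      dt <- steps[1L]
    } else dt <- 2
    PotentialTrace(val, dt = dt, scaleNote = "raw")
  } else {
    vals <- numeric(length(lines))
    for (i in seq_along(lines)) {
      v <- suppressWarnings(as.numeric(trimws(lines[i])))
      if (length(v) != 1L || is.na(v)) bad(i)
      vals[i] <- v
    }
    PotentialTrace(vals, dt = 2, scaleNote = "raw")
  }
}

#' Run one of the canned relay experiments
#'
#' Reproducible drivers for the chain experiments:
#' \describe{
#'   \item{fig7}{nomodulation and all-or-none chains on a recorded trace
#'     (n = 600 points, relay counts 3, 10, 17, 18): demonstrates
#'     amplification without modulation and attenuation with it.}
#'   \item{fig8}{nomodulation encoder on a full recording (m = 1 and 4).}
#'   \item{fig9}{3000-relay encoder--decoder on the running-mean-centred
#'     recording; reports the propagation success rate.}
#'   \item{fig10}{fully synthetic: the gated sound-wave stimulus through the
#'     encoder--decoder (m = 1, 100, 3000), reporting per-stage traces and
#'     success rates.}
#' }
#' fig7--fig9 require a recording file (headerless single column or
#' \code{time_ms,value} CSV, raw mV scale); without one an explicit
#' data-required error is raised.  Outputs are display-scaled (x 1e5).
#'
#' @param name one of \code{"fig7"}, \code{"fig8"}, \code{"fig9"},
#'   \code{"fig10"}.
#' @param traceFile path to a recording (required for fig7--fig9).
#' @param params encoder parameters; by default alpha 0.71, beta 0.7
#'   (gamma 0.2713) for the recording experiments and the j = 25 grid point
#'   alpha 0.875, beta 0.7481 (gamma 0.3325) for the synthetic fig10 run.
#' @param thresholds decoder thresholds.
#' @param relays relay counts to run; defaults per experiment.
#' @param n number of points to use (defaults per experiment).
#' @param seed integer seed.
#' @param outDir optional directory; when given, [writeReport()] persists
#'   the metrics and config there.
#' @return an experiment report: list with \code{name}, \code{config},
#'   \code{metrics} (data.frame), \code{traces} (display-scaled terminal
#'   traces per relay count), and \code{files} when persisted.
#' @export
runFigureExperiment <- function(name = c("fig7", "fig8", "fig9", "fig10"),
                                traceFile = NULL, params = NULL,
                                thresholds = DecoderThresholds(),
                                relays = NULL, n = NULL, seed = 1,
                                outDir = NULL) {
  name <- match.arg(name)
  params <- params %||% if (name == "fig10")
    NlariParams(alpha = 0.875, beta = 0.748125)   # the j = 25 grid point
  else NlariParams(alpha = 0.71, beta = 0.7)
  needsData <- name %in% c("fig7", "fig8", "fig9")
  if (needsData && (is.null(traceFile) || !file.exists(traceFile %||% "")))
    stop("experiment '", name, "' needs a recorded trace file ",
         "(headerless single-column text or 'time_ms,value' CSV, raw mV ",
         "scale); none was supplied")
  defaults <- list(
    fig7 = list(relays = c(3L, 10L, 17L, 18L), n = 600L),
    fig8 = list(relays = c(1L, 4L), n = 20000L),
    fig9 = list(relays = 3000L, n = 20000L),
    fig10 = list(relays = c(1L, 100L, 3000L), n = 200L))
  relays <- relays %||% defaults[[name]]$relays
  n <- as.integer(n %||% defaults[[name]]$n)
  set.seed(seed)

  if (needsData) {
    raw <- traceValues(readTrace(traceFile))
    if (length(raw) < n) n <- length(raw)
    scaled <- preprocessScale(raw[seq_len(n)])
    stim <- if (name == "fig9") centerRunningMean(scaled) else scaled
  } else {
    stim <- generateSoundStimulus(n, thresholds = thresholds)$stimulus
  }

  mode <- if (name %in% c("fig7", "fig8")) "nomodulation" else
    "encoder_decoder"
  rows <- list()
  traces <- list()
  for (m in relays) {
    res <- propagateChain(stim, params, m = m, mode = mode,
                          thresholds = thresholds, keep = "last")
    fin <- finalTrace(res)
    rate <- successRate(binarize(stim, thresholds@c3),
                        binarize(fin, thresholds@c3))
    rows[[length(rows) + 1L]] <- data.frame(
      experiment = name, mode = mode, m = m, n = n,
      maxAbsOutput = max(abs(fin@values)),
      successRate = rate)
    traces[[as.character(m)]] <- displayScale(fin)
    if (name == "fig7") {   # also the all-or-none comparison branch
      resA <- propagateChain(stim, params, m = m, mode = "all_or_none",
                             thresholds = thresholds, keep = "last")
      finA <- finalTrace(resA)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = name, mode = "all_or_none", m = m, n = n,
        maxAbsOutput = max(abs(finA@values)),
        successRate = successRate(binarize(stim, thresholds@c3),
                                  binarize(finA, thresholds@c3)))
    }
  }
  report <- list(
    name = name,
    config = list(alpha = params@alpha, beta = params@beta,
                  gamma = stabilityCoefficient(params),
                  c1 = thresholds@c1, c2 = thresholds@c2,
                  c3 = thresholds@c3, sigma1 = thresholds@sigma1,
                  relays = relays, n = n, seed = seed,
                  traceFile = traceFile %||% "synthetic"),
    metrics = do.call(rbind, rows),
    traces = traces)
  if (!is.null(outDir)) report$files <- writeReport(report, outDir)
  report
}

#' Persist an experiment report
#'
#' Writes the metrics table as CSV and the configuration echo (including
#' seeds) as JSON into \code{outDir}.  Re-running the producing experiment
#' with the same seed yields byte-identical files.
#'
#' @param report a report list with elements \code{name}, \code{config} and
#'   \code{metrics} (e.g. from [runFigureExperiment()] or a
#'   [runSuccessSweep()] result wrapped via \code{list(name=, config=,
#'   metrics=)}).
#' @param outDir output directory, created if needed.
#' @return character vector of the files written.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(is.list(report), !is.null(report$name),
            is.data.frame(report$metrics))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  csv <- file.path(outDir, paste0(report$name, "_metrics.csv"))
  write.csv(report$metrics, csv, row.names = FALSE)
  files <- csv
  if (!is.null(report$config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the config echo requires the 'jsonlite' package")
    js <- file.path(outDir, paste0(report$name, "_config.json"))
    jsonlite::write_json(report$config, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, js)
  }
  files
}

`%||%` <- function(a, b) if (is.null(a)) b else a
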