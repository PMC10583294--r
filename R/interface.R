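#' Write a polarization time series as delimited text
#'
#' CSV with columns \code{time} and \code{signal}; acquisition metadata
#' (flip angle, TR, mode, scale, noise level, seed, time unit) is stored
#' in \code{#}-prefixed header comments so a file round-trips through
#' [read_timeseries()] without loss.
#'
#' @param ts A [pol_series()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "pol_series"))
  m <- series_meta(ts)
  hdr <- c(
    sprintf("# theta_deg: %.10g", m$theta),
    sprintf("# TR: %.10g", m$TR),
    sprintf("# mode: %s", m$mode),
    sprintf("# scale: %s", m$scale),
    sprintf("# noise_sigma: %.10g", m$noise_sigma),
    sprintf("# seed: %s", if (is.null(m$seed)) "NA" else
      format(m$seed)),
    sprintf("# time_unit: %s", m$time_unit),
    sprintf("# writer: dnpcorr %s", as.character(packageVersion("dnpcorr")))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time,signal", con)
  writeLines(sprintf("%.15g,%.15g", ts$time, ts$signal), con)
  invisible(path)
}

#' Read a polarization time series from delimited text
#'
#' Expects two columns (time, signal) in CSV or whitespace-delimited
#' text, with optional \code{# key: value} header comments carrying the
#' acquisition metadata.  Metadata supplied as arguments overrides the
#' header (command-line flags win over file headers).  Times must be
#' strictly increasing; uniformity of the spacing is checked against TR
#' with tolerance 1e-6 TR and recorded in the attribute \code{uniform}.
#'
#' @param path Input file.
#' @param theta,TR,mode,scale,noise_sigma,time_unit Metadata overrides;
#'   NULL means "use the file header".
#' @return A [pol_series()].
#' @export
read_timeseries <- function(path, theta = NULL, TR = NULL, mode = NULL,
                            scale = NULL, noise_sigma = NULL,
                            time_unit = NULL) {
  lines <- readLines(path)
  hdr_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    mm <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(mm) == 3) meta[[mm[2]]] <- trimws(mm[3])
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", body))) "," else ""
  first <- strsplit(trimws(body[1]), if (sep == ",") "," else "\\s+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  dat <- utils::read.table(text = paste(body, collapse = "\n"),
                           sep = sep, header = has_header,
                           strip.white = TRUE)
  if (ncol(dat) < 2)
    stop("expected two columns: time, signal", call. = FALSE)
  time <- as.numeric(dat[[1]])
  signal <- as.numeric(dat[[2]])
  if (any(is.na(time)) || any(is.na(signal)))
    stop("non-numeric values in time series", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("parse error: time column must be strictly increasing",
         call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  theta <- theta %||% num(meta$theta_deg) %||% num(meta$theta)
  TR <- TR %||% num(meta$TR)
  mode <- mode %||% meta$mode %||% "buildup"
  scale <- scale %||% meta$scale %||% "polarization"
  noise_sigma <- noise_sigma %||% num(meta$noise_sigma) %||% 0
  time_unit <- time_unit %||% meta$time_unit %||% "s"
  seed <- if (!is.null(meta$seed) && meta$seed != "NA")
    as.integer(meta$seed)
  if (is.null(theta) || is.null(TR))
    stop("missing metadata: flip angle (theta) and TR are required ",
         "(supply them in header comments or as arguments)",
         call. = FALSE)
  ts <- pol_series(time, signal, theta = theta, TR = TR, mode = mode,
                   scale = scale, noise_sigma = noise_sigma,
                   seed = seed, time_unit = time_unit)
  uniform <- length(time) < 2 ||
    all(abs(diff(time) - TR) <= 1e-6 * TR)
  attr(ts, "uniform") <- uniform
  ts
}

fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(model = fit$model, converged = fit$converged,
       estimate = as.list(fit$estimate),
       se = if (!is.null(fit$se)) as.list(fit$se),
       ci = if (!is.null(fit$ci))
         apply(fit$ci, 1, as.list, simplify = FALSE),
       sigma_resid = fit$sigma_resid, nobs = fit$nobs,
       with_offset = fit$with_offset,
       flags = as.list(fit$flags))
}

correction_to_list <- function(res) {
  list(method = res$method,
       corrected = list(P0 = res$P0, tau = res$tau),
       uncorrected = fit_to_list(res$uncorrected),
       rate_sum = res$rate_sum, iterations = res$iterations,
       converged = res$converged, flags = as.list(res$flags))
}

provenance <- function(config = NULL, seed = NULL) {
  list(package = "dnpcorr",
       version = as.character(packageVersion("dnpcorr")),
       seed = seed,
       config_hash = if (!is.null(config))
         sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                        digits = NA)) *
             seq_along(utf8ToInt(jsonlite::toJSON(config,
                                                  auto_unbox = TRUE,
                                                  digits = NA)))) %%
           2147483647)
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

cli_simulate <- function(args) {
  parser <- optparse::OptionParser(
    usage = "dnpcorr simulate [options]",
    option_list = list(
      optparse::make_option("--p0", type = "double", default = 0.3,
        help = "steady-state polarization (build-up) or initial polarization (decay) [default %default]"),
      optparse::make_option("--tau", type = "double", default = 50,
        help = "time constant without RF pulses [default %default]"),
      optparse::make_option("--capacity", type = "double", default = 1,
        help = "polarization capacity A [default %default]"),
      optparse::make_option("--theta", type = "double", default = 2.5,
        help = "flip angle in degrees [default %default]"),
      optparse::make_option("--tr", type = "double", default = 2,
        help = "repetition time [default %default]"),
      optparse::make_option("--duration", type = "double", default = NA,
        help = "total duration [default 6 apparent time constants]"),
      optparse::make_option("--mode", default = "buildup",
        help = "buildup or decay [default %default]"),
      optparse::make_option("--noise", type = "double", default = 0,
        help = "noise sd on the transverse signal [default %default]"),
      optparse::make_option("--seed", type = "integer", default = 1,
        help = "RNG seed [default %default]"),
      optparse::make_option("--time-unit", dest = "time_unit",
        default = "s", help = "time unit label [default %default]"),
      optparse::make_option("--out", default = "simulated.csv",
        help = "output CSV [default %default]"),
      optparse::make_option("--quiet", action = "store_true",
        default = FALSE, help = "suppress log messages")))
  opt <- optparse::parse_args(parser, args)
  mode <- match.arg(opt$mode, c("buildup", "decay"))
  params <- if (mode == "buildup")
    params_from_observables(opt$p0, opt$tau, opt$capacity)
  else rate_params(0, 1 / opt$tau, opt$capacity)
  tau_app <- apparent_params(
    if (mode == "buildup") params else
      params_from_observables(min(opt$p0, opt$capacity * 0.999) * 1e-9,
                              opt$tau, opt$capacity),
    opt$theta, opt$tr)$tau
  duration <- if (is.na(opt$duration)) 6 * tau_app else opt$duration
  scheme <- pulse_scheme(opt$theta, opt$tr, duration = duration)
  ts <- if (mode == "buildup")
    simulate_buildup(params, scheme, noise_sigma = opt$noise,
                     seed = opt$seed)
  else simulate_decay(params, scheme, P_init = opt$p0,
                      noise_sigma = opt$noise, seed = opt$seed)
  attr(ts, "time_unit") <- opt$time_unit
  write_timeseries(ts, opt$out)
  log_msg(!opt$quiet, "wrote %d samples to %s (seed %d)", nrow(ts),
          opt$out, opt$seed)
  0L
}

cli_correct <- function(args) {
  parser <- optparse::OptionParser(
    usage = "dnpcorr correct --in FILE [options]",
    option_list = list(
      optparse::make_option("--in", dest = "input",
        help = "input CSV (columns time, signal)"),
      optparse::make_option("--theta", type = "double", default = NULL,
        help = "flip angle in degrees (overrides file header)"),
      optparse::make_option("--tr", type = "double", default = NULL,
        help = "repetition time (overrides file header)"),
      optparse::make_option("--mode", default = NULL,
        help = "buildup or decay (overrides file header)"),
      optparse::make_option("--method", default = "all",
        help = "all, iterative, cc or cospower [default %default]"),
      optparse::make_option("--offset", action = "store_true",
        default = TRUE, help = "fit with an additive offset [default]"),
      optparse::make_option("--no-offset", action = "store_false",
        dest = "offset", help = "fit without an offset"),
      optparse::make_option("--peq", type = "double", default = NULL,
        help = "thermal equilibrium polarization: report signal amplitudes as enhancements and polarizations"),
      optparse::make_option("--out", default = NULL,
        help = "corrected series CSV (iterative/cospower methods)"),
      optparse::make_option("--json", default = NULL,
        help = "JSON parameter report path [default: stdout]"),
      optparse::make_option("--quiet", action = "store_true",
        default = FALSE, help = "suppress log messages")))
  opt <- optparse::parse_args(parser, args)
  if (is.null(opt$input))
    stop("correct: --in FILE is required", call. = FALSE)
  ts <- read_timeseries(opt$input, theta = opt$theta, TR = opt$tr,
                        mode = opt$mode)
  mode <- attr(ts, "mode")
  methods <- if (opt$method == "all") {
    if (mode == "decay") c("iterative", "cc", "cospower")
    else c("iterative", "cc")
  } else opt$method
  if (mode == "buildup" && "cospower" %in% methods)
    stop("the 1/cos^(n-1) correction is only applicable to decays",
         call. = FALSE)
  fit0 <- if (mode == "buildup") fit_buildup(ts, opt$offset)
          else fit_decay(ts, opt$offset)
  results <- lapply(methods, function(m) {
    correct_experiment(ts, method = m, with_offset = opt$offset)
  })
  names(results) <- methods
  for (m in methods) {
    if ("nonphysical_cc_correction" %in% results[[m]]$flags)
      warning(sprintf(
        "%s correction is non-physical for this series (RF depletion faster than the apparent rate)",
        m), call. = FALSE)
  }
  report <- list(
    input = opt$input,
    theta_deg = attr(ts, "theta"), TR = attr(ts, "TR"), mode = mode,
    time_unit = attr(ts, "time_unit"),
    uncorrected = fit_to_list(fit0),
    corrections = lapply(results, correction_to_list),
    provenance = provenance(config = opt))
  if (!is.null(opt$peq)) {
    report$P_eq <- opt$peq
    report$polarization <- lapply(results, function(r)
      list(P0 = enhancement_to_polarization(r$P0, opt$peq)))
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(opt$json)) cat(json, "\n") else writeLines(json, opt$json)
  if (!is.null(opt$out)) {
    written <- FALSE
    for (m in methods) {
      if (!written && !is.null(results[[m]]$series)) {
        write_timeseries(results[[m]]$series, opt$out)
        log_msg(!opt$quiet, "wrote corrected series (%s) to %s", m,
                opt$out)
        written <- TRUE
      }
    }
  }
  0L
}

cli_study <- function(args) {
  parser <- optparse::OptionParser(
    usage = "dnpcorr study --study NAME [options]",
    option_list = list(
      optparse::make_option("--study", default = "table1",
        help = "table1, accuracy or minsnr [default %default]"),
      optparse::make_option("--config", default = NULL,
        help = "YAML study-grid config (keys: theta, TR, P0, noise_sigma, n_rep, tau, A, mode)"),
      optparse::make_option("--replicates", type = "integer",
        default = NULL, help = "override the replicate count"),
      optparse::make_option("--seed", type = "integer", default = 1,
        help = "master seed [default %default]"),
      optparse::make_option("--out", default = "study.csv",
        help = "output CSV [default %default]"),
      optparse::make_option("--quiet", action = "store_true",
        default = FALSE, help = "suppress log messages")))
  opt <- optparse::parse_args(parser, args)
  grid_args <- list(seed = opt$seed)
  if (!is.null(opt$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for --config", call. = FALSE)
    grid_args <- modifyList(grid_args, yaml::read_yaml(opt$config))
  }
  if (!is.null(opt$replicates)) grid_args$n_rep <- opt$replicates
  out <- switch(opt$study,
    table1 = reproduce_table1(),
    accuracy = monte_carlo_accuracy(do.call(study_grid, grid_args)),
    minsnr = {
      defaults <- list(theta = c(2.5, 7, 25), TR = 2,
                       P0 = seq(0.01, 0.1, length.out = 10),
                       noise_sigma = exp(seq(log(3.2e-5), log(3.2e-3),
                                             length.out = 10)),
                       n_rep = 100)
      min_snr_map(do.call(study_grid, modifyList(defaults, grid_args)))
    },
    stop("unknown study: ", opt$study, call. = FALSE))
  utils::write.csv(out, opt$out, row.names = FALSE)
  log_msg(!opt$quiet, "wrote %s study (%d rows) to %s (seed %d)",
          opt$study, nrow(out), opt$out, opt$seed)
  0L
}

#' Command-line interface
#'
#' Entry point behind the \code{inst/cli/dnpcorr} script.  Subcommands:
#' \describe{
#'   \item{simulate}{simulate a pulsed build-up or decay and write it as
#'     CSV.}
#'   \item{correct}{read a measured series, apply the RF corrections and
#'     write a JSON parameter report (and optionally the corrected
#'     series).}
#'   \item{study}{run one of the packaged simulation studies (table1,
#'     accuracy, minsnr) and write its table as CSV.}
#' }
#' Run any subcommand with \code{--help} for its options.  Times are
#' assumed to be seconds unless a unit label says otherwise; labels are
#' carried through, never converted.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first); defaults to the process arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
dnp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: dnpcorr <simulate|correct|study> [options]\n")
    return(invisible(if (length(args) == 0) 1L else 0L))
  }
  sub <- args[1]
  rest <- args[-1]
  status <- switch(sub,
    simulate = cli_simulate(rest),
    correct = cli_correct(rest),
    study = cli_study(rest),
    stop("unknown subcommand: ", sub, call. = FALSE))
  invisible(status)
}
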