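# Readers and writers: light-regime and observation CSVs (comma-separated,
# '.' decimal, UTF-8, '#' comment lines) and the YAML run configuration.

read_csv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  line_no <- which(keep)
  if (length(line_no) < 2) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = raw[keep], stringsAsFactors = FALSE,
                        check.names = FALSE)
  data_lines <- line_no[-1]
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra))
    message("ignoring unrecognised column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  for (col in intersect(c(required, optional), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at line ",
             data_lines[bad[1]], " of ", path, call. = FALSE)
      df[[col]] <- vn
    }
  }
  tcol <- required[1]
  dt <- diff(df[[tcol]])
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1] + 1L
    stop(if (dt[i - 1L] == 0) "duplicated" else "non-increasing",
         " timestamp at line ", data_lines[i], " of ", path, call. = FALSE)
  }
  df[c(required, intersect(optional, names(df)))]
}

#' Read a light-regime CSV
#'
#' Expects columns `time_s` and `ppfd_umol_m2_s`; `#`-prefixed comment lines
#' are permitted and unrecognised extra columns are ignored with a notice.
#' Times must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @param Ca,T_leaf Constant cuvette conditions to pair with the regime.
#' @param interp Interpolation rule, see [environment_series()].
#' @return An [environment_series()].
#' @export
read_light_csv <- function(path, Ca = 400, T_leaf = 25,
                           interp = c("linear", "constant")) {
  df <- read_csv_checked(path, c("time_s", "ppfd_umol_m2_s"))
  environment_series(df$time_s, df$ppfd_umol_m2_s, Ca = Ca, T_leaf = T_leaf,
                     interp = match.arg(interp))
}

#' Read an observed gas-exchange CSV
#'
#' Expects columns `time_s`, `A_umol_m2_s` and `gs_mol_m2_s`; an optional
#' `ppfd_umol_m2_s` column overrides the light regime in `env`.
#'
#' @param path Path to the CSV file.
#' @param env An [environment_series()] spanning the observation times;
#'   may be omitted when the file carries its own `ppfd_umol_m2_s` column.
#' @param Ca,T_leaf Cuvette conditions used when the light is taken from the
#'   file.
#' @return An [observation_set()].
#' @export
read_observations_csv <- function(path, env = NULL, Ca = 400, T_leaf = 25) {
  df <- read_csv_checked(path, c("time_s", "A_umol_m2_s", "gs_mol_m2_s"),
                         optional = "ppfd_umol_m2_s")
  if ("ppfd_umol_m2_s" %in% names(df))
    env <- environment_series(df$time_s, df$ppfd_umol_m2_s,
                              Ca = Ca, T_leaf = T_leaf)
  if (is.null(env))
    stop("no light regime: supply env or a ppfd_umol_m2_s column", call. = FALSE)
  observation_set(df$time_s, df$A_umol_m2_s, df$gs_mol_m2_s, env)
}

#' Write a gas-exchange trajectory to CSV
#'
#' Writes one row per output time with the documented column names
#' (`time_s`, `ppfd_umol_m2_s`, `a_um2`, `as_um2`, `gs_mol_m2_s`,
#' `gt_mol_m2_s`, `ci_umol_mol`, `cc_umol_mol`, `L`, `ag_umol_m2_s`,
#' `a_umol_m2_s`, `wi_umol_mol`). The resolved configuration and seed, when
#' supplied, are embedded as `#`-prefixed JSON comment lines so that reruns
#' are reproducible from the file alone.
#'
#' @param x A `gas_exchange` data frame from [simulate_gas_exchange()].
#' @param path Output path.
#' @param config Optional resolved configuration list to embed.
#' @param seed Optional seed to embed.
#' @return `path`, invisibly.
#' @export
write_gas_exchange_csv <- function(x, path, config = NULL, seed = NULL) {
  stopifnot(inherits(x, "gas_exchange"))
  out <- data.frame(time_s = x$time, ppfd_umol_m2_s = x$ppfd, a_um2 = x$a,
                    as_um2 = x$a_s, gs_mol_m2_s = x$g_s, gt_mol_m2_s = x$g_t,
                    ci_umol_mol = x$C_i, cc_umol_mol = x$C_c, L = x$L,
                    ag_umol_m2_s = x$A_G, a_umol_m2_s = x$A,
                    wi_umol_mol = x$W_i)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config))
    writeLines(paste0("# config: ",
                      jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)),
               con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

config_sections <- c("parameters", "leaf_constants", "farquhar",
                     "environment", "solver", "inference", "experiment")

#' Read a run configuration
#'
#' Reads a YAML configuration with sections `parameters`, `leaf_constants`,
#' `farquhar`, `environment`, `solver`, `inference` and `experiment` (all
#' optional; omitted entries fall back to the package defaults). Unknown
#' sections or keys are rejected. The fully resolved configuration — defaults
#' merged with the file — is attached as attribute `resolved` for provenance
#' and is what [write_gas_exchange_csv()] embeds in outputs.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `params` ([model_parameters()]), `consts`
#'   ([leaf_constants()]), `fconsts` ([farquhar_constants()]), `environment`,
#'   `solver`, `inference` and `experiment` (lists of options), with the
#'   resolved configuration as attribute `resolved`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown key(s) in [", section, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    given
  }
  params <- do.call(model_parameters,
                    check_keys(cfg$parameters %||% list(),
                               names(formals(model_parameters)), "parameters"))
  consts <- do.call(leaf_constants,
                    check_keys(cfg$leaf_constants %||% list(),
                               names(formals(leaf_constants)), "leaf_constants"))
  fconsts <- do.call(farquhar_constants,
                     check_keys(cfg$farquhar %||% list(),
                                names(formals(farquhar_constants)), "farquhar"))
  envopts <- check_keys(cfg$environment %||% list(),
                        c("Ca", "T_leaf", "interp"), "environment")
  solver <- check_keys(cfg$solver %||% list(),
                       c("atol", "rtol", "max_retries", "method", "engine",
                         "net_assimilation"), "solver")
  inference <- check_keys(cfg$inference %||% list(),
                          c("iterations", "chains", "thin", "warmup_fraction",
                            "noise", "sigma_A", "sigma_gs", "seed",
                            "map_iterations"), "inference")
  experiment <- check_keys(cfg$experiment %||% list(),
                           c("fraction", "variants", "dt", "slope_window",
                             "wi_aggregation"), "experiment")
  resolved <- list(parameters = unclass(params),
                   leaf_constants = unclass(consts)[config_allowed_lc()],
                   farquhar = unclass(fconsts),
                   environment = utils::modifyList(
                     list(Ca = 400, T_leaf = 25, interp = "linear"), envopts),
                   solver = solver, inference = inference,
                   experiment = experiment)
  structure(list(params = params, consts = consts, fconsts = fconsts,
                 environment = resolved$environment, solver = solver,
                 inference = inference, experiment = experiment),
            resolved = resolved, class = "run_config")
}

config_allowed_lc <- function() names(formals(leaf_constants))

#' Resolved configuration of a run config
#'
#' @param x A `run_config` from [read_run_config()].
#' @return The fully resolved configuration list (defaults merged with the
#'   file), suitable for embedding in output files.
#' @export
resolved_config <- function(x) attr(x, "resolved")

`%||%` <- function(a, b) if (is.null(a)) b else a
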