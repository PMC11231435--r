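#' Write and read simulation traces as delimited text
#'
#' Traces are stored as tab-separated text (time column plus one column per
#' state variable) at full double precision, with a JSON sidecar
#' (\code{<path>.json}) recording the parameters and solver settings so a
#' run can be reproduced exactly.
#'
#' @param trace a \code{sin_trace}.
#' @param path output file path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns the \code{sin_trace}.
#' @export
write_trace <- function(trace, path) {
  m <- unclass(trace)
  attrs <- attributes(m)
  header <- paste(colnames(m), collapse = "\t")
  body <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(header, body), path)
  meta <- list(params = unclass(attr(trace, "params")),
               solver = unclass(attr(trace, "solver")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!"time" %in% header)
    stop("malformed trace file (line 1): missing 'time' column",
         call. = FALSE)
  n <- length(lines) - 1L
  m <- matrix(NA_real_, n, length(header),
              dimnames = list(NULL, header))
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(
      strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]))
    if (length(v) != length(header) || any(is.na(v)))
      stop("malformed trace file at line ", i + 1L, call. = FALSE)
    m[i, ] <- v
  }
  params <- solver <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    params <- structure(meta$params, class = "sin_params")
    solver <- structure(meta$solver, class = "solver_options")
  }
  new_trace(m, params, solver)
}

#' Save and load experiment configurations
#'
#' Experiments are described in YAML with a \code{kind} discriminator:
#' \describe{
#'   \item{cell}{fields \code{params} (overrides of
#'     \code{\link{sin_params}}), optional \code{init} (overrides of
#'     \code{\link{sin_state}}), \code{solver} (overrides of
#'     \code{\link{solver_options}}), and optional \code{protocol}
#'     (\code{type: pulse} with \code{g_syn}, \code{pulse_duration},
#'     \code{E_rev}).}
#'   \item{synapse}{fields \code{spec} (arguments of
#'     \code{\link{synapse_spec}}).}
#'   \item{network}{either \code{preset: <name>}, or explicit
#'     \code{cell1}, \code{cell2}, \code{syn12}, \code{syn21},
#'     \code{g_elec}, plus optional \code{solver}.}
#' }
#' Unknown keys are rejected with an error naming the offending key.
#'
#' @param path YAML file path.
#' @return \code{load_config} returns the validated experiment object: a
#'   list with the \code{kind} and constructed package objects.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$kind))
    stop("config must declare 'kind' (cell, synapse, or network)",
         call. = FALSE)
  kind <- match.arg(raw$kind, c("cell", "synapse", "network"))
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key '", bad[1], "' in ", where, call. = FALSE)
  }
  if (kind == "cell") {
    check_keys(raw, c("kind", "params", "init", "solver", "protocol"),
               "cell config")
    check_keys(raw$params, names(formals(sin_params)), "params")
    check_keys(raw$init, names(formals(sin_state)), "init")
    check_keys(raw$solver, names(formals(solver_options)), "solver")
    params <- do.call(sin_params, as.list(raw$params))
    init <- if (is.null(raw$init)) NULL else
      do.call(sin_state, c(as.list(raw$init), list(params = params)))
    solver <- do.call(solver_options, as.list(raw$solver))
    proto <- raw$protocol
    if (!is.null(proto))
      check_keys(proto, c("type", "g_syn", "pulse_duration", "E_rev"),
                 "protocol")
    list(kind = "cell", params = params, init = init, solver = solver,
         protocol = proto)
  } else if (kind == "synapse") {
    check_keys(raw, c("kind", "spec"), "synapse config")
    check_keys(raw$spec, names(formals(synapse_spec)), "spec")
    list(kind = "synapse", spec = do.call(synapse_spec, as.list(raw$spec)))
  } else {
    check_keys(raw, c("kind", "preset", "cell1", "cell2", "syn12",
                      "syn21", "g_elec", "solver"), "network config")
    if (!is.null(raw$preset)) {
      cfg <- preset(raw$preset)
    } else {
      for (nm in c("cell1", "cell2"))
        check_keys(raw[[nm]], names(formals(sin_params)), nm)
      for (nm in c("syn12", "syn21"))
        check_keys(raw[[nm]], names(formals(synapse_spec)), nm)
      cfg <- network_config(do.call(sin_params, as.list(raw$cell1)),
                            do.call(sin_params, as.list(raw$cell2)),
                            do.call(synapse_spec, as.list(raw$syn12)),
                            do.call(synapse_spec, as.list(raw$syn21)),
                            gap_junction_spec(raw$g_elec %||% 0))
    }
    if (!is.null(raw$solver)) {
      check_keys(raw$solver, names(formals(solver_options)), "solver")
      cfg$opts <- do.call(solver_options, as.list(raw$solver))
    }
    list(kind = "network", config = cfg)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config a list as returned by \code{load_config}, or a raw list
#'   in the same layout.
#' @export
save_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, c("sin_params", "sin_state", "synapse_spec",
                      "solver_options")))
      return(lapply(unclass(as.list(x)), strip))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Experiment records for exact replay
#'
#' Bundles everything needed to re-run an experiment bit-identically on
#' the same platform: the full configuration snapshot, the package
#' version, and the solver settings.
#'
#' @param config a \code{network_config}, or a list with \code{params} and
#'   \code{solver} for a single-cell run.
#' @return An object of class \code{experiment_record}.
#' @export
experiment_record <- function(config) {
  structure(list(config = config,
                 version = as.character(utils::packageVersion("sinet")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "experiment_record")
}

#' @rdname experiment_record
#' @param record an \code{experiment_record}.
#' @export
replay_experiment <- function(record) {
  cfg <- record$config
  if (inherits(cfg, "network_config")) return(simulate_network(cfg))
  simulate_cell(cfg$params, init = cfg$init %||% NULL,
                opts = cfg$solver %||% solver_options())
}
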