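# Session container and configuration. The native container is a plain-text
# session directory: meta.json, channels.csv, events.tsv and per-group CSV
# tables (dtofs in long form, irf, moments, truth.json). Every derived
# group records the configuration hash of the stage that produced it.

.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small stable polynomial hash; no external digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Create an in-memory session container
#'
#' @param meta named list of session metadata (seeds, config snapshot,
#'   software version are added automatically)
#' @param channels channel table ([enumerate_channels()] output)
#' @param dtofs optional named list of [dtof()] objects
#' @param irf optional IRF [dtof()]
#' @param moments optional data frame of moment time series (long form:
#'   `channel`, `t_s`, `N`, `m1_ps`, `V_ps2`)
#' @param events optional event table (`onset_s`, `duration_s`, `condition`)
#' @param truth optional list of simulation ground truth (synthetic only)
#' @export
session_container <- function(meta = list(), channels = NULL, dtofs = NULL,
                              irf = NULL, moments = NULL, events = NULL,
                              truth = NULL) {
  meta$software <- paste0("tdot ", as.character(utils::packageVersion("tdot")))
  meta$config_hash <- .config_hash(meta)
  structure(list(meta = meta, channels = channels, dtofs = dtofs, irf = irf,
                 moments = moments, events = events, truth = truth),
            class = "session_container")
}

.dtof_to_row <- function(name, d) {
  data.frame(name = name, bin = seq_along(d$counts), counts = d$counts,
             bin_width_ps = d$bin_width_ps, origin_ps = d$origin_ps,
             wavelength_nm = d$wavelength_nm,
             integration_time_ms = d$integration_time_ms)
}

.rows_to_dtof <- function(df) {
  df <- df[order(df$bin), ]
  dtof(df$counts, df$bin_width_ps[1], df$wavelength_nm[1],
       df$integration_time_ms[1], origin_ps = df$origin_ps[1])
}

#' Write a session container to a session directory
#'
#' @param x a [session_container()]
#' @param path directory (created if needed)
#' @return the path, invisibly
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "session_container"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(x$meta, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(path, "meta.json"))
  if (!is.null(x$channels))
    write.csv(x$channels, file.path(path, "channels.csv"), row.names = FALSE)
  if (!is.null(x$dtofs)) {
    nm <- names(x$dtofs)
    if (is.null(nm)) nm <- as.character(seq_along(x$dtofs))
    long <- do.call(rbind, Map(.dtof_to_row, nm, x$dtofs))
    write.csv(long, file.path(path, "dtofs.csv"), row.names = FALSE)
  }
  if (!is.null(x$irf)) {
    write.csv(.dtof_to_row("irf", x$irf), file.path(path, "irf.csv"),
              row.names = FALSE)
  }
  if (!is.null(x$moments))
    write.csv(x$moments, file.path(path, "moments.csv"), row.names = FALSE)
  if (!is.null(x$events))
    write.table(x$events, file.path(path, "events.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  if (!is.null(x$truth))
    writeLines(jsonlite::toJSON(x$truth, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE),
               file.path(path, "truth.json"))
  invisible(path)
}

#' Read a session directory written by [write_session()]
#'
#' Fails with an explicit error (and no partial state) when the directory
#' is missing its metadata or a table cannot be parsed.
#'
#' @param path session directory
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    stop("not a session directory (missing meta.json): ", path, call. = FALSE)
  meta <- tryCatch(jsonlite::fromJSON(mf, simplifyVector = TRUE),
                   error = function(e)
                     stop("corrupted session metadata: ", conditionMessage(e),
                          call. = FALSE))
  rd <- function(f) if (file.exists(file.path(path, f)))
    read.csv(file.path(path, f)) else NULL
  channels <- rd("channels.csv")
  moments <- rd("moments.csv")
  dl <- rd("dtofs.csv")
  dtofs <- if (!is.null(dl)) lapply(split(dl, dl$name), .rows_to_dtof)
  irfdf <- rd("irf.csv")
  irf <- if (!is.null(irfdf)) .rows_to_dtof(irfdf)
  events <- if (file.exists(file.path(path, "events.tsv")))
    read.delim(file.path(path, "events.tsv"))
  else NULL
  truth <- if (file.exists(file.path(path, "truth.json")))
    jsonlite::fromJSON(file.path(path, "truth.json"), simplifyVector = TRUE)
  else NULL
  out <- session_container(meta = list(), channels = channels, dtofs = dtofs,
                           irf = irf, moments = moments, events = events,
                           truth = truth)
  out$meta <- meta
  out
}

# ---------------------------------------------------------------------------
# Configuration

.config_schema <- c("geometry", "simulator", "selection", "pipeline",
                    "glm", "recon", "seed")

#' Read and validate a pipeline configuration (YAML)
#'
#' Top-level keys are restricted to the known schema (geometry, simulator,
#' selection, pipeline, glm, recon, seed); unknown keys are rejected.
#'
#' @param path YAML file
#' @return named list with attribute `config_hash`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_schema)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  attr(cfg, "config_hash") <- .config_hash(cfg)
  cfg
}

#' Append a structured log record (JSON lines)
#'
#' One record per pipeline stage: stage name, parameters, wall time.
#'
#' @param path log file (appended)
#' @param stage stage name
#' @param params named list of parameters
#' @param elapsed_s wall time in seconds
#' @export
log_stage_record <- function(path, stage, params = list(), elapsed_s = NA) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, params = params, elapsed_s = elapsed_s)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, force = TRUE),
      "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
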