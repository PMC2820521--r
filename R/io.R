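#' Load an experiment configuration
#'
#' YAML configuration with the documented keys; unknown keys are rejected
#' and defaults are applied for everything omitted. Recognized top-level
#' keys: `tables` (paths `concentrations`, `enzymatic`, `binding`),
#' `calcium` / `dopamine` (protocol fields), `experiment`
#' (`knockouts`, `ablations`, `clamps`, `eval_time`, `t_end`),
#' `grids` (`ca_amps`, `da_amps`), `solver` (`rtol`, `atol`),
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return A validated list of class `"experiment_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("tables", "calcium", "dopamine", "experiment", "grids",
             "solver", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  def <- list(
    tables = list(concentrations = spinesim_table("initial_concentrations.csv"),
                  enzymatic = spinesim_table("enzymatic_reactions.csv"),
                  binding = spinesim_table("binding_reactions.csv")),
    calcium = list(ca_basal = 0.06, ca_amp = 1, n_spikes = 8, isi = 0.01,
                   n_repeats = 6, repeat_interval = 10, tau = 0.3),
    dopamine = list(da_basal = 0.003, da_amp = 1, n_repeats = 6,
                    repeat_interval = 10, tau = 0.3, offset = 0),
    experiment = list(knockouts = character(0), ablations = character(0),
                      clamps = character(0), eval_time = 600, t_end = 600),
    grids = list(ca_amps = NULL, da_amps = NULL),
    solver = list(rtol = 1e-8, atol = 1e-12),
    output_dir = ".")
  cfg <- utils::modifyList(def, raw)
  for (sec in c("calcium", "dopamine", "experiment", "grids", "solver",
                "tables")) {
    extra <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(extra))
      stop("unknown keys in '", sec, "': ", paste(extra, collapse = ", "))
  }
  # normalize YAML list representations to the documented types
  for (k in c("knockouts", "ablations", "clamps"))
    cfg$experiment[[k]] <- as.character(unlist(cfg$experiment[[k]]))
  for (k in c("ca_amps", "da_amps"))
    if (!is.null(cfg$grids[[k]]))
      cfg$grids[[k]] <- as.numeric(unlist(cfg$grids[[k]]))
  if (cfg$solver$rtol <= 0 || cfg$solver$atol <= 0)
    stop("solver tolerances must be positive")
  with(cfg$calcium, stopifnot(ca_basal >= 0, ca_amp >= 0, tau > 0))
  with(cfg$dopamine, stopifnot(da_basal >= 0, da_amp >= 0, tau > 0))
  structure(cfg, class = "experiment_config")
}

#' Write an experiment configuration
#' @param cfg An `experiment_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# '#'-prefixed metadata header shared by all result writers
.result_header <- function(type, extra = character(0)) {
  ver <- tryCatch(as.character(utils::packageVersion("spinesim")),
                  error = function(e) "dev")
  prov <- tryCatch(parameter_provenance(), error = function(e) NULL)
  c(paste0("# spinesim result: ", type),
    paste0("# version: ", ver),
    if (!is.null(prov))
      paste0("# parameters: ", prov[["literature"]], " literature / ",
             prov[["tuned"]], " hand-tuned"),
    extra)
}

#' Parameter-provenance summary of the packaged model
#'
#' Counts rate parameters of the packaged tables by provenance label
#' (each rate group carries two constants; mixed groups contribute one to
#' each class).
#'
#' @param tables A [load_tables()] object.
#' @return Named integer vector `c(literature = ..., tuned = ...)`.
#' @export
parameter_provenance <- function(tables = load_tables()) {
  g <- rbind(
    data.frame(group = tables$binding$group,
               prov = tables$binding$provenance),
    data.frame(group = tables$enzymatic$group,
               prov = tables$enzymatic$provenance))
  g <- g[!duplicated(g$group), ]
  c(literature = sum(g$prov == "literature") * 2L +
      sum(g$prov == "literature/tuned"),
    tuned = sum(g$prov == "tuned") * 2L +
      sum(g$prov == "literature/tuned"))
}

#' Write a result to delimited text
#'
#' Tidy comma-separated output with a `#`-prefixed metadata header.
#' Numeric values are written at full (17 significant digit) precision so
#' that [read_results()] round-trips losslessly.
#'
#' @param x A `time_course`, `plasticity_map`, or data frame (e.g. a
#'   hysteresis table).
#' @param path Output path.
#' @param extra_header Additional header lines (each will be `#`-prefixed).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, extra_header = character(0)) {
  UseMethod("write_results")
}

.write_table <- function(df, path, type, extra) {
  hdr <- .result_header(type,
                        if (length(extra)) paste0("# ", extra)
                        else character(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.time_course <- function(x, path, extra_header = character(0)) {
  df <- data.frame(time = tc_times(x), unclass(x), check.names = FALSE)
  .write_table(df, path, "time_course", extra_header)
}

#' @export
write_results.plasticity_map <- function(x, path,
                                         extra_header = character(0)) {
  df <- expand.grid(ca_amp = x$ca_amps, da_amp = x$da_amps)
  df$ratio <- as.vector(x$ratio)
  .write_table(df, path, "plasticity_map", extra_header)
}

#' @export
write_results.data.frame <- function(x, path, extra_header = character(0)) {
  .write_table(x, path, "table", extra_header)
}

#' Read back a result written by [write_results()]
#'
#' @param path Path to the file.
#' @return A data frame; header metadata in attribute `"header"`.
#' @export
read_results <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  attr(df, "header") <- hdr
  df
}
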