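#' Load a simulation configuration from JSON
#'
#' The file is a nested mapping with the same structure as
#' [default_config()]; omitted keys take their documented defaults, unknown
#' keys are rejected with a named-field error.  An empty file (or `{}`)
#' yields the full default configuration (L = 200, dt = 1 h, psi = 0.7, ...).
#'
#' @param path JSON file path.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  over <- if (nzchar(trimws(txt)))
    jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  cfg <- default_config(overrides = over)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config a `sim_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# polynomial rolling hash of the canonical JSON serialization (stays inside
# 31 bits; no digest dependency)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write run outputs
#'
#' Writes, under `outdir`: `metrics.csv` (per-hour census), `agents.csv`
#' (full agent table), `vessel_edges.csv` (site_from, site_to, sprout,
#' birth hour), one `field_<name>_h<hour>.csv` matrix per field at the final
#' hour (the drug field only when treatment was on), `config.json`, and
#' `manifest.json` listing every file with the config hash and seed so the
#' run is reconstructible.
#'
#' @param result a [run_simulation()] result.
#' @param outdir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- result$state
  cfg <- state$config
  files <- character(0)
  wr <- function(x, name) {
    p <- file.path(outdir, name)
    write.csv(x, p, row.names = FALSE)
    files <<- c(files, name)
  }
  wr(result$metrics, "metrics.csv")
  pop <- state$pop
  wr(data.frame(id = seq_along(pop$i), i = pop$i, j = pop$j, age = pop$age,
                phenotype = pop$phen, alive = pop$alive, plc_rate = pop$plc),
     "agents.csv")
  wr(state$vessels$edges, "vessel_edges.csv")
  fnames <- c("glucose", "oxygen", "tgfa", "vegf", "fibronectin",
              if (isTRUE(cfg$treatment_on)) "tki")
  for (nm in fnames) {
    p <- file.path(outdir, sprintf("field_%s_h%d.csv", nm,
                                   as.integer(state$clock)))
    write.table(state$fields[[nm]]$grid, p, sep = ",", row.names = FALSE,
                col.names = FALSE)
    files <- c(files, basename(p))
  }
  save_config(cfg, file.path(outdir, "config.json"))
  files <- c(files, "config.json")
  manifest <- list(
    package = "glioabm",
    version = as.character(utils::packageVersion("glioabm")),
    seed = cfg$seed, config_hash = config_hash(cfg),
    start_hour = 0, end_hour = state$clock,
    treatment_on = cfg$treatment_on,
    files = c(files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, "manifest.json"))
}

#' Read back a field snapshot written by [write_outputs()]
#'
#' @param path CSV matrix path.
#' @return numeric matrix.
#' @export
read_field_snapshot <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
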