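#' Run configuration
#'
#' Assembles (and validates) every parameter group of a run: acquisition,
#' session design, BOLD and nuisance models for the simulator, spectral
#' filter, real-time chain, output directory and RNG seed. This is the
#' object behind the command-line interface; a flat YAML file with sections
#' named after the groups maps onto it via [read_run_config()].
#'
#' @param acquisition,design,bold,noise,filter,chain Parameter group
#'   objects; defaults are the standard 7 T session values (TR = 1 s,
#'   30-repetition blocks, alpha = 0.98, lambda = 4, 0.9 threshold
#'   coefficient, 1 percent floor, 10 discards).
#' @param output_dir Directory run commands write into.
#' @param seed Integer RNG seed.
#' @return A list with class `svps_run_config`.
#' @export
svps_run_config <- function(acquisition = svps_acquisition(),
                            design = svps_design(),
                            bold = svps_bold(),
                            noise = svps_noise(),
                            filter = svps_filter(),
                            chain = svps_chain(),
                            output_dir = "svps_run",
                            seed = 1L) {
  stopifnot(inherits(acquisition, "svps_acquisition"),
            inherits(design, "svps_design"),
            inherits(bold, "svps_bold"),
            inherits(noise, "svps_noise"),
            inherits(filter, "svps_filter"),
            inherits(chain, "svps_chain"))
  check_number(seed, "seed")
  if (!is.character(output_dir) || length(output_dir) != 1L) {
    svps_abort("`output_dir` must be a single path", class = "svps_config_error")
  }
  structure(list(acquisition = acquisition, design = design, bold = bold,
                 noise = noise, filter = filter, chain = chain,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "svps_run_config")
}

config_builders <- function() {
  list(acquisition = svps_acquisition, design = svps_design,
       bold = svps_bold, noise = svps_noise, filter = svps_filter,
       chain = svps_chain)
}

#' Read a run configuration from YAML
#'
#' The file holds top-level keys `seed`, `output_dir` and one section per
#' parameter group (`acquisition`, `design`, `bold`, `noise`, `filter`,
#' `chain`); omitted sections and keys take the package defaults. Unknown
#' sections or keys are rejected with an error naming the offender, so
#' typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `svps_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    svps_abort(sprintf("config file not found: %s", path),
               class = "svps_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  builders <- config_builders()
  allowed_top <- c(names(builders), "seed", "output_dir")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown) > 0) {
    svps_abort(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")),
               class = "svps_config_error")
  }
  groups <- list()
  for (g in names(builders)) {
    args <- raw[[g]] %||% list()
    allowed <- names(formals(builders[[g]]))
    bad <- setdiff(names(args), allowed)
    if (length(bad) > 0) {
      svps_abort(sprintf("unknown key(s) in section `%s`: %s", g,
                         paste(bad, collapse = ", ")),
                 class = "svps_config_error")
    }
    groups[[g]] <- do.call(builders[[g]], args)
  }
  svps_run_config(acquisition = groups$acquisition, design = groups$design,
                  bold = groups$bold, noise = groups$noise,
                  filter = groups$filter, chain = groups$chain,
                  output_dir = raw$output_dir %||% "svps_run",
                  seed = raw$seed %||% 1L)
}

# full provenance record: enough to reproduce the run exactly
write_provenance <- function(config, dir, command) {
  rec <- list(command = command,
              package = "fsvps",
              version = as.character(packageVersion("fsvps")),
              seed = config$seed,
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              config = list(acquisition = unclass(config$acquisition),
                            design = unclass(config$design),
                            bold = unclass(config$bold),
                            noise = unclass(config$noise),
                            filter = unclass(config$filter),
                            chain = unclass(config$chain),
                            output_dir = config$output_dir))
  jsonlite::write_json(rec, file.path(dir, paste0("provenance_", command,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec)
}
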