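KNOWN_TOP_KEYS <- c("config", "focal", "competitor", "experiment")

# YAML 1.1 resolves the bare scalars y/n/yes/no/on/off to booleans, which
# would silently turn the species key `n:` into a key named FALSE. Restrict
# boolean resolution to the spellings R writes (true/false and friends).
yaml_key_handlers <- function() {
  list("bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
       "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE)
}

PAPER_GRIDS <- list(
  n = c(16, 64, 256), mu = c(1e-3, 1e-4, 1e-5), rec = c(0.05, 0.5),
  d = c(0.1, 0.05, 0.01))

check_grid <- function(value, grid, what) {
  if (!is.null(value) && !value %in% grid)
    warning(sprintf("%s = %s is outside the default set {%s}", what,
                    format(value), paste(grid, collapse = ", ")),
            call. = FALSE)
  value
}

apply_fields <- function(defaults, overrides, what) {
  if (is.null(overrides)) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", what,
                 paste(unknown, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  defaults
}

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) file with optional top-level blocks `config`,
#' `focal`, `competitor` and `experiment`; any field not supplied takes its
#' default (an empty file yields the full default configuration, i.e. the
#' focal-species architecture and global constants). Unknown keys raise
#' descriptive errors; genetic-architecture or dispersal values outside the
#' default grids are accepted with a warning.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return list with elements `config` (a [sim_config()]), `focal` and
#'   `competitor` ([species_params()]; `competitor` is `NULL` unless
#'   configured), and `experiment` (replicates, master_seed, output_dir,
#'   keep_runs).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path, handlers = yaml_key_handlers())
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), KNOWN_TOP_KEYS)
  if (length(unknown))
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))

  cfg <- do.call(sim_config,
                 apply_fields(formals_defaults(sim_config), raw$config,
                              "config"))
  foc_def <- formals_defaults(species_params)
  foc_def$name <- "focal"; foc_def$start_patch <- 1L
  focal <- do.call(species_params, apply_fields(foc_def, raw$focal, "focal"))
  competitor <- NULL
  if (!is.null(raw$competitor)) {
    comp_def <- formals_defaults(species_params)
    comp_def$name <- "competitor"; comp_def$start_patch <- 2L
    competitor <- do.call(species_params,
                          apply_fields(comp_def, raw$competitor,
                                       "competitor"))
  }
  for (sp in Filter(Negate(is.null), list(focal, competitor))) {
    check_grid(sp$n, PAPER_GRIDS$n, paste0(sp$name, " n"))
    check_grid(sp$mu, PAPER_GRIDS$mu, paste0(sp$name, " mu"))
    check_grid(sp$rec, PAPER_GRIDS$rec, paste0(sp$name, " rec"))
    check_grid(sp$d, PAPER_GRIDS$d, paste0(sp$name, " d"))
  }
  exp_def <- list(replicates = 1L, master_seed = 1L, output_dir = "netcomm_out",
                  keep_runs = FALSE)
  experiment <- apply_fields(exp_def, raw$experiment, "experiment")
  list(config = cfg, focal = focal, competitor = competitor,
       experiment = experiment)
}

# evaluated default arguments of a function, as a named list
formals_defaults <- function(fn) {
  f <- formals(fn)
  f <- f[!vapply(f, function(x) is.symbol(x) && !nzchar(as.character(x)),
                 logical(1))]
  lapply(f, function(x) if (is.language(x)) eval(x) else x)
}

config_snapshot <- function(cfg, focal, competitor, experiment) {
  strip <- function(x) { x <- unclass(x); x[!vapply(x, is.null, logical(1))] }
  out <- list(config = strip(cfg), focal = strip(focal))
  if (!is.null(competitor)) out$competitor <- strip(competitor)
  out$experiment <- experiment
  out
}

#' Write experiment outputs
#'
#' Writes the experiment summary as CSV, one per-generation time-series CSV
#' per retained run, a YAML snapshot of the effective configuration (which
#' round-trips through [load_config()]), and a plain-text log of per-run
#' seeds and termination causes. Re-running with the same inputs overwrites
#' the same files deterministically.
#'
#' @param experiment an `nc_experiment` from [run_experiment()] or
#'   [run_metapopulation()].
#' @param dir output directory (created if needed).
#' @param focal,competitor optional [species_params()] echoed into the
#'   config snapshot.
#' @param experiment_spec optional experiment block (replicates, master_seed,
#'   ...) echoed into the snapshot.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(experiment, dir, focal = NULL, competitor = NULL,
                          experiment_spec = NULL) {
  stopifnot(inherits(experiment, "nc_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(dir, "summary.csv")
  utils::write.csv(experiment$summary, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(experiment$runs)) {
    run_dir <- file.path(dir, "runs")
    dir.create(run_dir, showWarnings = FALSE)
    for (k in seq_along(experiment$runs)) {
      rp <- file.path(run_dir, sprintf("run_%04d.csv", k))
      utils::write.csv(as.data.frame(experiment$runs[[k]]), rp,
                       row.names = FALSE)
      paths <- c(paths, rp)
    }
  }

  cp <- file.path(dir, "config.yaml")
  snap <- config_snapshot(experiment$config,
                          if (is.null(focal)) species_params() else focal,
                          competitor,
                          if (is.null(experiment_spec))
                            list(replicates = 1L,
                                 master_seed = experiment$master_seed,
                                 output_dir = dir, keep_runs = FALSE)
                          else experiment_spec)
  yaml::write_yaml(snap, cp)
  paths <- c(paths, cp)

  lp <- file.path(dir, "log.txt")
  s <- experiment$summary
  lines <- c(sprintf("netcomm experiment log (master seed %s, %d runs)",
                     format(experiment$master_seed), nrow(s)),
             sprintf("run %d: seed %d, %d generations, %s", seq_len(nrow(s)),
                     s$seed, s$generations,
                     ifelse(!is.na(s$coexist) & s$coexist,
                            "ran to completion (coexistence)",
                            ifelse(s$generations <
                                     experiment$config$generations,
                                   "terminated at first regional extinction",
                                   "ran to completion"))))
  writeLines(lines, lp)
  paths <- c(paths, lp)
  invisible(paths)
}
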