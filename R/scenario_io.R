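# Allowed keys per config model, with documented defaults (NA = required).
.config_schema <- list(
  ovulation = list(
    required = c("a", "b", "c", "d", "Rs"),
    optional = list(tol = 1e-8, n_grid = 201L, seed = 1L)
  ),
  prevalence = list(
    required = c("x"),
    optional = list(P = NULL, P_max = NULL, seed = 1L)
  ),
  geneculture = list(
    required = c("M", "gamma_cost", "alpha_share", "lambda_surv",
                 "beta", "delta"),
    optional = list(N_AQ = 0L, N_AQt = 0L, N_GQ = 0L, N_GQt = 0L,
                    generations = 100L, replicates = 1L, seed = 1L)
  )
)

#' Load and validate a scenario configuration
#'
#' Reads a flat YAML document describing one model run. The document must
#' carry a `model` key (`"ovulation"`, `"prevalence"` or `"geneculture"`);
#' remaining keys are the model's parameters. Unknown keys are rejected,
#' every cross-field invariant of the corresponding constructor is enforced,
#' and omitted optional keys receive their documented defaults (`N_*` counts
#' 0, `generations` 100, `replicates` 1, `seed` 1, partition `tol` 1e-8,
#' `n_grid` 201). A prevalence config supplies either `P` (a point query)
#' or `P_max` (a curve).
#'
#' @param path Path to a YAML scenario file.
#' @return A list of class `"gemino_config"` with elements `model` (string),
#'   `params` (the validated parameter object: an [ovulation_ecology()], a
#'   `gemino_scenario`, or a validated prevalence query list) and `run`
#'   (run settings: seed and, where applicable, generations/replicates/
#'   tol/n_grid/P_max).
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' writeLines(c("model: prevalence", "x: 0.028", "P: 5"), path)
#' cfg <- load_scenario(path)
#' mother_of_twins_probability(cfg$params$x, cfg$params$P)
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$model)) {
    stop("config must be a mapping with a `model` key", call. = FALSE)
  }
  model <- match.arg(raw$model, names(.config_schema))
  raw$model <- NULL
  schema <- .config_schema[[model]]
  known <- c(schema$required, names(schema$optional))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s) for model '", model, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(schema$required, names(raw))
  if (length(missing) > 0) {
    stop("missing required key(s) for model '", model, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (k in names(schema$optional)) {
    if (is.null(raw[[k]])) raw[[k]] <- schema$optional[[k]]
  }

  cfg <- switch(
    model,
    ovulation = list(
      params = ovulation_ecology(raw$a, raw$b, raw$c, raw$d, raw$Rs),
      run = list(tol = raw$tol, n_grid = raw$n_grid, seed = raw$seed)
    ),
    prevalence = {
      if (is.null(raw$P) && is.null(raw$P_max)) {
        stop("prevalence config needs `P` (point) or `P_max` (curve)",
             call. = FALSE)
      }
      if (!is.null(raw$P)) {
        invisible(mother_of_twins_probability(raw$x, raw$P))  # validates
      } else {
        invisible(prevalence_curves(raw$x, raw$P_max))  # validates
      }
      list(params = list(x = raw$x, P = raw$P),
           run = list(P_max = raw$P_max, seed = raw$seed))
    },
    geneculture = list(
      params = gemino_scenario(raw$M, raw$gamma_cost, raw$alpha_share,
                               raw$lambda_surv, raw$beta, raw$delta,
                               raw$N_AQ, raw$N_AQt, raw$N_GQ, raw$N_GQt),
      run = list(generations = as.integer(raw$generations),
                 replicates = as.integer(raw$replicates),
                 seed = as.integer(raw$seed))
    )
  )
  structure(c(list(model = model), cfg), class = "gemino_config")
}

#' Write a scenario configuration
#'
#' Serialises a loaded configuration (or the pieces to build one) back to a
#' flat YAML document; `load_scenario(write_scenario(cfg, path))` round-trips
#' to identical parameters.
#'
#' @param config A `"gemino_config"` from [load_scenario()], or a plain
#'   named list including a `model` key.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  flat <- if (inherits(config, "gemino_config")) {
    p <- config$params
    if (inherits(p, "ovulation_ecology")) p$E_star <- NULL
    if (inherits(p, "gemino_scenario")) p$N <- NULL
    run <- config$run[!vapply(config$run, is.null, logical(1))]
    c(list(model = config$model), unclass(p), run)
  } else {
    config
  }
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Generate the bundled scenario fixtures
#'
#' Writes ready-to-run YAML configs for the package's reference
#' parameterisations: the three worked twin-maternity prevalence queries
#' (global low-fertility `x = 0.013, P = 2`; Yoruba-like high-fertility
#' `x = 0.045, P = 10`; modern Benin `x = 0.028, P = 5`), a four-region
#' ovulation ecology, the invasion scenario of a community of 100
#' twin-supporters contributing about 1\% of net wealth, and a neutral
#' (`delta = 0`) drift control. Each fixture is checked at generation time
#' (the prevalence fixtures reproduce their reference percentages, the
#' ovulation fixture yields four regions, the invasion fixture satisfies the
#' invasion condition), and a run manifest is written alongside.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed recorded in the configs and manifest.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    prevalence_global = file.path(dir, "prevalence_global_low_fertility.yaml"),
    prevalence_yoruba = file.path(dir, "prevalence_high_fertility.yaml"),
    prevalence_benin = file.path(dir, "prevalence_benin.yaml"),
    ovulation_four_region = file.path(dir, "ovulation_four_region.yaml"),
    geneculture_invasion = file.path(dir, "geneculture_invasion.yaml"),
    geneculture_neutral = file.path(dir, "geneculture_neutral.yaml")
  )

  prev <- list(
    prevalence_global = list(x = 0.013, P = 2L),
    prevalence_yoruba = list(x = 0.045, P = 10L),
    prevalence_benin = list(x = 0.028, P = 5L)
  )
  ref_pct <- c(prevalence_global = 2.6, prevalence_yoruba = 37,
               prevalence_benin = 13.2)
  digits <- c(prevalence_global = 1, prevalence_yoruba = 0,
              prevalence_benin = 1)
  for (nm in names(prev)) {
    q <- prev[[nm]]
    got <- round(100 * mother_of_twins_probability(q$x, q$P), digits[[nm]])
    stopifnot(got == ref_pct[[nm]])
    write_scenario(c(list(model = "prevalence"), q, list(seed = seed)),
                   paths[[nm]])
  }

  eco <- list(a = 1.1, b = 0.02, c = 0.5, d = 0.55, Rs = 1)
  stopifnot(nrow(partition_resource_space(
    do.call(ovulation_ecology, eco))) == 4L)
  write_scenario(c(list(model = "ovulation"), eco, list(seed = seed)),
                 paths[["ovulation_four_region"]])

  inv <- list(M = 1, gamma_cost = 0.1, alpha_share = 0.01, lambda_surv = 2,
              beta = 0, delta = 1, N_GQ = 99L, N_GQt = 1L)
  stopifnot(invasion_condition(100, inv$M, inv$gamma_cost, inv$alpha_share,
                               inv$lambda_surv))
  write_scenario(c(list(model = "geneculture"), inv,
                   list(generations = 100L, replicates = 1L, seed = seed)),
                 paths[["geneculture_invasion"]])

  neutral <- list(M = 1, gamma_cost = 0.1, alpha_share = 0.05,
                  lambda_surv = 2, beta = 0.05, delta = 0,
                  N_GQ = 50L, N_GQt = 50L)
  write_scenario(c(list(model = "geneculture"), neutral,
                   list(generations = 50L, replicates = 500L, seed = seed)),
                 paths[["geneculture_neutral"]])

  write_manifest(dir, unname(paths), seed = seed)
  invisible(paths)
}

#' Write a run manifest
#'
#' Records, as JSON, what a run produced and how to reproduce it: package
#' version, root seed, timestamp, and an inventory of output files with MD5
#' content digests.
#'
#' @param dir Directory in which to write `manifest.json`.
#' @param files Character vector of output file paths to inventory.
#' @param seed Root seed of the run.
#' @param params Optional named list of scenario parameters to echo.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, files, seed, params = NULL) {
  inventory <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest <- list(
    package = "geminicoev",
    version = as.character(utils::packageVersion("geminicoev")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    files = inventory
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
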