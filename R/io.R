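plate_columns <- c("well", "strain", "glucose_g_l", "ph", "acetic_acid_mM",
                   "channel", "time_min", "value")
plate_channels <- c("OD620", "O2_saturation", "ratio_390_480")

validate_plate_table <- function(plate) {
  if (!is.data.frame(plate))
    stop("plate table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(plate_columns, names(plate))
  if (length(missing_cols))
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !plate$channel %in% plate_channels
  if (any(bad))
    stop("unknown channel(s): ",
         paste(unique(plate$channel[bad]), collapse = ", "),
         " (expected ", paste(plate_channels, collapse = ", "), ")",
         call. = FALSE)
  key <- paste(plate$well, plate$channel, plate$time_min)
  if (anyDuplicated(key))
    stop("duplicated (well, channel, time_min) rows at lines: ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  ord <- order(plate$well, plate$channel, plate$time_min)
  tt <- plate$time_min[ord]
  grp <- paste(plate$well, plate$channel)[ord]
  same <- grp[-1L] == grp[-length(grp)]
  if (any(same & diff(tt) <= 0))
    stop("times not strictly increasing within a (well, channel) series",
         call. = FALSE)
  invisible(plate)
}

#' Read a long-format plate table
#'
#' Reads the interchange CSV of the pipeline (one row per well, channel and
#' time point) with locale-independent numeric parsing, and validates the
#' schema: required columns, known channels, unique and strictly increasing
#' times per series. Lines starting with `#` (provenance headers written by
#' [write_plate_table()]) are skipped.
#'
#' @param path CSV file path.
#' @return Validated plate `data.frame` with columns
#'   `well, strain, glucose_g_l, ph, acetic_acid_mM, channel, time_min,
#'   value`.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  plate <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("glucose_g_l", "ph", "acetic_acid_mM", "time_min", "value")) {
    if (col %in% names(plate)) {
      v <- suppressWarnings(as.numeric(plate[[col]]))
      if (anyNA(v) && !anyNA(plate[[col]]))
        stop("non-numeric values in column '", col, "' near line(s) ",
             paste(utils::head(which(is.na(v)) + 1L, 5L), collapse = ", "),
             call. = FALSE)
      plate[[col]] <- v
    }
  }
  validate_plate_table(plate)
  plate
}

#' Write a table with a provenance header
#'
#' Writes a CSV preceded by `#`-comment lines recording the package
#' version, the master seed and a hash of the configuration, so every
#' artifact of a pipeline run documents how it was produced.
#'
#' @param x `data.frame` to write.
#' @param path Output path.
#' @param seed Master seed to record (optional).
#' @param config_hash Configuration hash to record (optional).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(x, path, seed = NULL, config_hash = NULL) {
  hdr <- c(sprintf("# acetox %s",
                   as.character(utils::packageVersion("acetox"))),
           if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
           if (!is.null(config_hash)) sprintf("# config: %s", config_hash))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# md5 of the canonical YAML serialization of a config list
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    design = list(n_points = 12L, candidate_pool = 500L,
                  strains = "wild-type"),
    factors = list(
      list(name = "glucose_g_l", lower = 0, upper = 40, scale = "log",
           offset = 1),
      list(name = "ph", lower = 2.5, upper = 7, scale = "linear"),
      list(name = "acetic_acid_mM", lower = 0, upper = 120,
           scale = "linear")),
    simulate = list(noise_sd = 0, channels = c("od", "o2")),
    kinetics = list(window = 5L, blank = 0, floor = 0.01),
    rsm = list(response = "od_integral", optimize = TRUE),
    toxicity = list(ph = c(3, 4, 5, 6), glucose_g_l = c(5, 20),
                    grid = 101L)
  )
}

stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) + h * 97561) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes design generation, plate simulation (or ingestion of a measured
#' plate table), per-well kinetics, response-surface fitting per strain,
#' and toxicity metrics, writing each stage's artifact as a CSV with a
#' provenance header when `out_dir` is set. Stage seeds are derived from
#' the master seed and the stage name, so results are reproducible
#' bit-for-bit under a fixed configuration and independent of stage-order
#' changes. Each stage logs its parameters, row counts and wall time via
#' `message()`; a stage failure halts the pipeline naming the stage, and
#' artifacts of completed stages remain on disk.
#'
#' @param config Nested configuration list (see
#'   `acetox:::default_pipeline_config()` for the full shape and defaults),
#'   or a path to a YAML file with the same structure. Unknown top-level
#'   keys are rejected. `config$plate` may name an existing plate CSV to
#'   analyse instead of simulating.
#' @param verbose Emit per-stage log messages (default `TRUE`).
#' @return Invisible list with `design`, `plate`, `kinetics`, `models`
#'   (one [gp_rsm()] per strain), `toxicity`, and the effective `config`.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), c(names(defaults), "plate"))
  if (length(unknown))
    stop("pipeline config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(bad) && nm != "factors")
        stop("pipeline config: unknown key(s) under '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  cfg <- defaults
  # validate before any computation
  factors <- lapply(cfg$factors, function(f)
    factor_spec(f$name, f$lower, f$upper, scale = f$scale,
                offset = if (is.null(f$offset)) 1 else f$offset))
  kin_cols <- c("mu_max_per_h", "t_mu_max_h", "yield_od", "od_integral",
                "o2_integral")
  resp_map <- c(mu_max = "mu_max_per_h", od_integral = "od_integral",
                o2_integral = "o2_integral", yield = "yield_od")
  if (!cfg$rsm$response %in% c(names(resp_map), kin_cols))
    stop("pipeline config: rsm response '", cfg$rsm$response,
         "' is not a kinetics column", call. = FALSE)
  resp_col <- if (cfg$rsm$response %in% names(resp_map))
    resp_map[[cfg$rsm$response]] else cfg$rsm$response
  chash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_stage <- function(stage, nrows, t0) {
    if (verbose)
      message(sprintf("[%s] %d rows, %.2f s", stage, nrows,
                      as.numeric(proc.time()[3L]) - t0))
  }
  emit <- function(x, name) {
    if (!is.null(out_dir))
      write_plate_table(x, file.path(out_dir, name), seed = cfg$seed,
                        config_hash = chash)
  }
  run_stage <- function(stage, f) {
    t0 <- as.numeric(proc.time()[3L])
    res <- tryCatch(f(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(res = res, t0 = t0)
  }

  st <- run_stage("design", function()
    space_filling_design(factors, cfg$design$n_points,
                         candidate_pool = cfg$design$candidate_pool,
                         seed = stage_seed(cfg$seed, "design"),
                         strains = cfg$design$strains))
  design <- st$res
  log_stage("design", nrow(design), st$t0)
  emit(design, "design.csv")

  if (!is.null(cfg$plate)) {
    st <- run_stage("ingest", function() read_plate_table(cfg$plate))
  } else {
    st <- run_stage("simulate", function()
      simulate_experiment(design,
                          params = sim_params(noise_sd = cfg$simulate$noise_sd),
                          channels = cfg$simulate$channels,
                          seed = stage_seed(cfg$seed, "simulate")))
  }
  plate <- st$res
  log_stage("plate", nrow(plate), st$t0)
  emit(plate, "plate.csv")

  st <- run_stage("kinetics", function()
    kinetics_table(plate, window = cfg$kinetics$window,
                   blank = cfg$kinetics$blank, floor = cfg$kinetics$floor))
  kin <- st$res
  log_stage("kinetics", nrow(kin), st$t0)
  emit(kin, "kinetics.csv")

  strains <- unique(kin$strain)
  form <- stats::as.formula(paste(
    resp_col, "~ glucose_g_l + ph + acetic_acid_mM"))
  models <- lapply(strains, function(s) {
    st <- run_stage(paste0("rsm:", s), function() {
      dat <- kin[kin$strain == s & !is.na(kin[[resp_col]]), ]
      gp_rsm(form, dat, factors = factors, optimize = cfg$rsm$optimize,
             seed = stage_seed(cfg$seed, paste0("rsm:", s)))
    })
    log_stage(paste0("rsm:", s), length(st$res$y), st$t0)
    st$res
  })
  names(models) <- strains

  direction <- if (resp_col == "o2_integral") "o2" else "od"
  st <- run_stage("toxicity", function() {
    tabs <- lapply(strains, function(s)
      toxicity_table(models[[s]], ph = cfg$toxicity$ph,
                     glucose_g_l = cfg$toxicity$glucose_g_l, strain = s,
                     channel = if (direction == "o2") "O2_saturation"
                               else "OD620",
                     direction = direction, grid = cfg$toxicity$grid))
    do.call(rbind, tabs)
  })
  tox <- st$res
  log_stage("toxicity", nrow(tox), st$t0)
  emit(tox, "toxicity.csv")

  invisible(list(design = design, plate = plate, kinetics = kin,
                 models = models, toxicity = tox, config = cfg))
}
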