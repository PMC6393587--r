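#' Default pipeline configuration
#'
#' A single declarative configuration for the end-to-end analysis.  Defaults
#' mirror the stated experimental protocol where one exists: fit window
#' 200-1000 us, Curie correction on, activation-energy anchor 6.01 kJ/mol,
#' 1-degree temperature grid, dead time 7 us.  Unknown keys are rejected,
#' so typos fail loudly.
#'
#' @param ... overrides of the default keys (see the returned list).
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    archetype = "folded",          # synthetic input when no FID dir given
    profile_overrides = list(),
    T_grid = seq(-80, -1, by = 1),
    ref_T_C = 5,
    acquisition = list(),          # overrides to acquisition_params()
    window = c(200, 1000),
    curie_correction = TRUE,
    slope_frac = 0.05,
    min_width_Tfn = 0.02,
    onset_frac = 0.10,
    f_max = 0.6,
    u_min = 0.95,
    masses = NULL,                 # list(m_water=, m_protein=) or NULL
    seed = 1L,
    out_dir = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, ov, keep.null = TRUE)
  if (cfg$slope_frac <= 0 || cfg$slope_frac >= 1)
    stop("slope_frac must lie in (0, 1)")
  if (cfg$min_width_Tfn <= 0) stop("min_width_Tfn must be positive")
  if (!(cfg$f_max < cfg$u_min)) stop("need f_max < u_min")
  class(cfg) <- "run_config"
  cfg
}

# tiny FNV-1a hash so reports can embed a config fingerprint without
# external digest dependencies; output paths are excluded so the same
# analysis written to two places shares a fingerprint
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # h * 16777619 mod 2^32, split so every intermediate stays exact
    h <- ((h %% 256) * 16777216 + (h * 403) %% 4294967296) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0L) # fingerprint, 31 bits
}

#' Run the full melting-diagram pipeline
#'
#' Composes the whole analysis: synthesize (or load) a per-temperature FID
#' series, fit the slow component of every record, build the melting
#' diagram, differentiate it on the fundamental-temperature scale, detect
#' the plateau, compute HeR, and classify the fold state.  Deterministic
#' given the config seed.
#'
#' @param config a [default_config()] object.
#' @param fid_dir optional directory of FID CSV files (dialect of
#'   [read_fid_csv()]); when `NULL`, a synthetic series is generated from
#'   `config$archetype`.
#' @return list of class `pipeline_report` with the diagram, plateau
#'   result, `HeR`, `state`, the config and its hash.  When
#'   `config$out_dir` is set, writes `diagram.tsv` and `report.json` there.
#' @examples
#' rep <- run_pipeline(default_config(archetype = "disordered",
#'                                    T_grid = seq(-70, -1, by = 2)))
#' rep$HeR
#' @export
run_pipeline <- function(config = default_config(), fid_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done (%.2f s)", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  series <- stage("ingest", {
    if (is.null(fid_dir)) {
      profile <- make_melting_profile(config$archetype,
                                      config$profile_overrides,
                                      seed = config$seed)
      acq <- do.call(acquisition_params, config$acquisition)
      synthesize_series(profile, config$T_grid, acq, seed = config$seed,
                        ref_T_C = config$ref_T_C)
    } else {
      files <- list.files(fid_dir, pattern = "\\.csv$", full.names = TRUE)
      if (!length(files)) stop("no .csv FID files in ", fid_dir)
      sigs <- lapply(sort(files), read_fid_csv)
      is_ref <- vapply(sigs, function(s) s$is_reference, logical(1))
      if (sum(is_ref) != 1)
        stop("expected exactly one reference record, found ", sum(is_ref))
      list(signals = sigs[!is_ref], reference = sigs[is_ref][[1]])
    }
  })
  diagram <- stage("diagram", build_melting_diagram(
    series$signals, series$reference, masses = config$masses,
    window = config$window, curie_correction = config$curie_correction))
  diagram <- stage("derivative", derivative_melting(diagram))
  plateau <- stage("plateau", detect_plateau(
    diagram, slope_frac = config$slope_frac,
    min_width_Tfn = config$min_width_Tfn, onset_frac = config$onset_frac))
  plateau <- stage("her", heterogeneity_ratio(plateau))
  state <- stage("classify", classify_state(plateau, config$f_max, config$u_min))
  report <- structure(list(
    package = "hydromelt",
    version = as.character(utils::packageVersion("hydromelt")),
    config_hash = config_hash(config),
    config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    n_temperatures = nrow(diagram),
    plateau = unclass(plateau),
    HeR = plateau$HeR,
    state = state,
    diagram = diagram), class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_melting_tsv(diagram, file.path(config$out_dir, "diagram.tsv"),
                      comments = c(paste0("hydromelt ", report$version),
                                   paste0("config_hash ", report$config_hash)))
    jsonlite::write_json(report[setdiff(names(report), "diagram")],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("hydromelt pipeline report (%d temperatures)\n",
              x$n_temperatures))
  print(structure(x$plateau, class = "plateau_result"))
  cat("state:", x$state, "\n")
  invisible(x)
}
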