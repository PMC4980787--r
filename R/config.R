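# Flat key-value run configuration. Keys follow the field's customary
# parameter names (probLS, rho, w1, th_n, MAX_ITER, PS, ...) so a config
# file reads like a published parameter table; they are mapped onto
# mabc_params() arguments here. The key `uph` is accepted for
# compatibility and ignored.

config_key_map <- c(
  probLS = "prob_ls", rho = "rho", w = "w", w1 = "w1", th_n = "th_n",
  sahc_iter = "sahc_iter", sahc_tweak = "sahc_tweak", sa_iter = "sa_iter",
  hc_iter = "hc_iter", t = "t", schedule = "schedule", tmax = "tmax0",
  tmin = "tmin", c0 = "c0", MAX_ITER = "max_iter", limit = "limit",
  nd = "nd", PS = "ps", r4 = "r4", ls_e = "ls_e", ls_o = "ls_o",
  selection = "selection", kernel = "kernel", wt = "wt_rule",
  prefilter = "prefilter", uph = NA, C = "cost", gamma = "gamma",
  init_alpha = "init_alpha", sa_temperature = "sa_temperature",
  seed = NA, preset = NA, n_runs = NA, dataset = NA, format = NA,
  label_column = NA, output = NA, ablation = NA
)

normalize_config_values <- function(vals) {
  sel_map <- c(`tournament selection` = "tournament", tournament = "tournament",
               `fitness proportionate selection` = "fps", fps = "fps",
               `stochastic universal sampling` = "sus", sus = "sus")
  if (!is.null(vals$selection)) {
    key <- tolower(vals$selection)
    if (!key %in% names(sel_map)) {
      stop("unknown selection method '", vals$selection, "'", call. = FALSE)
    }
    vals$selection <- unname(sel_map[key])
  }
  for (nm in c("ls_e", "ls_o")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- toupper(vals[[nm]])
  }
  if (!is.null(vals$kernel)) vals$kernel <- tolower(vals$kernel)
  if (!is.null(vals$prefilter)) {
    vals$prefilter <- gsub("[ -]", "_", tolower(vals$prefilter))
  }
  if (!is.null(vals$wt_rule)) {
    wt <- tolower(as.character(vals$wt_rule))
    vals$wt_rule <- if (wt %in% c("random", "eq6", "6")) "random"
                    else if (wt %in% c("decay", "eq5", "5")) "decay"
                    else stop("unknown wt rule '", wt, "'", call. = FALSE)
  }
  vals
}

#' Resolve a run configuration into search parameters
#'
#' Accepts a named list, or a path to a YAML/JSON file of flat key-value
#' pairs using the customary parameter names (`probLS`, `rho`, `w1`,
#' `th_n`, `MAX_ITER`, `limit`, `nd`, `PS`, `r4`, `t`, `schedule`,
#' `tmax`, `tmin`, `c0`, `sahc_iter`, `sahc_tweak`, `sa_iter`, `hc_iter`,
#' `ls_e`, `ls_o`, `selection`, `kernel`, `wt`, `prefilter`, `C`,
#' `gamma`). A `preset` key selects a [mabc_preset()] base; the remaining
#' keys override it. Unknown keys are rejected (except the documented,
#' ignored `uph`). Run-level keys (`dataset`, `seed`, `n_runs`, `output`,
#' `label_column`, `format`, `ablation`) pass through unchanged.
#'
#' @param config named list or file path.
#' @return A list with `params` (a `mabc_params`) and `run` (the run-level
#'   keys).
#' @export
resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(config_key_map))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  run_keys <- c("seed", "n_runs", "dataset", "format", "label_column",
                "output", "ablation")
  run <- config[intersect(names(config), run_keys)]
  mapped <- list()
  for (nm in names(config)) {
    target <- config_key_map[[nm]]
    if (!is.na(target)) {
      mapped[[target]] <- config[[nm]]
    }
  }
  mapped <- normalize_config_values(mapped)
  preset <- if (is.null(config$preset)) "first" else config$preset
  params <- do.call(mabc_preset, c(list(name = preset), mapped))
  list(params = params, run = run)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' Serialize resolved parameters back to config keys
#'
#' Inverse of the parameter mapping in [resolve_run_config()]; resolving
#' the serialized form reproduces the same parameters (round trip).
#'
#' @param params a `mabc_params` object.
#' @return A named list using config-file key names.
#' @export
serialize_params <- function(params) {
  stopifnot(inherits(params, "mabc_params"))
  inv <- names(config_key_map)[!is.na(config_key_map)]
  names(inv) <- config_key_map[!is.na(config_key_map)]
  out <- list()
  for (nm in names(params)) {
    if (nm %in% names(inv)) {
      out[[inv[[nm]]]] <- params[[nm]]
    }
  }
  out$wt <- if (identical(params$wt_rule, "random")) "random" else "decay"
  out
}
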