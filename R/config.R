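# Pipeline configuration: one validated list drives every stage, read from
# YAML for the CLI or built directly in R.

#' Build and validate a pipeline configuration
#'
#' @param scenario name of a built-in scenario preset
#'   (`"regeneration_7dpa"`, `"gastrulation_videoS1"`) to simulate, or
#'   `NULL` when an input stack is supplied.
#' @param seed integer seed used for every source of randomness.
#' @param input path to an input TIFF stack (alternative to `scenario`).
#' @param k_bg background threshold factor: threshold = level +
#'   `k_bg` * spread.
#' @param min_size_px smallest component kept, in pixels.
#' @param membrane_guided split touching nuclei by membrane watershed.
#' @param k_min,k_max range of mixture sizes scored by BIC.
#' @param k force the component count (e.g. 3) instead of BIC selection.
#' @param restarts EM restarts per mixture size.
#' @param halving_constrained fit the geometric-halving constrained mixture.
#' @param division_set division counts for the constrained fit.
#' @param gate_um tracking gate: maximum centroid displacement per frame.
#' @param direction tracking direction, `"forward"` or `"backward"`.
#' @param n_perm permutation-null replicates (>= 99).
#' @param bright_rule `"component"` (top mixture component) or
#'   `"quantile:<q>"` for an intensity-quantile rule.
#' @param r_low colocalization ratio below which a bright nucleus is called
#'   non-divided.
#' @param out_dir where `run_pipeline()` writes artifacts.
#' @param scenario_overrides named list forwarded to [photo_scenario()].
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "regeneration_7dpa", seed = 0L,
                            input = NULL, k_bg = 3, min_size_px = 20L,
                            membrane_guided = FALSE, k_min = 1L, k_max = 6L,
                            k = NULL, restarts = 20L,
                            halving_constrained = FALSE,
                            division_set = c(0L, 2L, 5L), gate_um = 15,
                            direction = c("forward", "backward"),
                            n_perm = 199L, bright_rule = "component",
                            r_low = 0.2, out_dir = tempfile("photolineage_"),
                            scenario_overrides = list()) {
  cfg <- list(scenario = scenario, seed = as.integer(seed), input = input,
              k_bg = k_bg, min_size_px = as.integer(min_size_px),
              membrane_guided = isTRUE(membrane_guided),
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              k = if (is.null(k)) NULL else as.integer(k),
              restarts = as.integer(restarts),
              halving_constrained = isTRUE(halving_constrained),
              division_set = as.integer(division_set), gate_um = gate_um,
              direction = match.arg(direction), n_perm = as.integer(n_perm),
              bright_rule = bright_rule, r_low = r_low, out_dir = out_dir,
              scenario_overrides = scenario_overrides)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$scenario) && is.null(cfg$input))
    pl_stop("config", "either a scenario name or an input stack is required")
  if (cfg$k_min < 1L) pl_stop("config", "k_min must be >= 1")
  if (cfg$k_min > cfg$k_max) pl_stop("config", "k_min must be <= k_max")
  if (cfg$restarts < 1L) pl_stop("config", "restarts must be >= 1")
  if (cfg$gate_um <= 0) pl_stop("config", "gate_um must be > 0")
  if (cfg$n_perm < 99L) pl_stop("config", "n_perm must be >= 99")
  if (cfg$k_bg <= 0) pl_stop("config", "k_bg must be > 0")
  if (cfg$min_size_px < 1L) pl_stop("config", "min_size_px must be >= 1")
  if (!(cfg$r_low > 0 && cfg$r_low < 1))
    pl_stop("config", "r_low must be in (0, 1)")
  if (!identical(cfg$bright_rule, "component") &&
      !grepl("^quantile:0?\\.[0-9]+$", cfg$bright_rule))
    pl_stop("config", "bright_rule must be 'component' or 'quantile:<q>'")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return validated `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(flat))
    cat(sprintf("  %-18s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  invisible(x)
}
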