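# The weighting scheme: ten real-valued weights, one per scored target
# attribute. Two built-in presets cover the common use cases — "default"
# favors late-stage, heavily validated targets (drug repurposing), "novel"
# up-weights early-phase trial activity to surface less developed targets.

.weight_keys <- c(
  "pathways", "tractability", "approved", "safety", "unique_drugs",
  "diseases", "phase1", "phase2", "phase3", "phase4"
)

.weight_presets <- list(
  default = c(
    pathways = 1, tractability = 1, approved = 1, safety = -2,
    unique_drugs = 1, diseases = 1, phase1 = 0.5, phase2 = 1,
    phase3 = 1.5, phase4 = 2
  ),
  novel = c(
    pathways = 0.5, tractability = 0.5, approved = 0.5, safety = -2,
    unique_drugs = 0.5, diseases = 0.01, phase1 = 10, phase2 = 4,
    phase3 = 0.5, phase4 = 0.01
  )
)

#' Build a target-attribute weight scheme
#'
#' Starts from a named preset and applies any overrides. Weights are arbitrary
#' finite reals; no normalization is applied. A negative weight penalizes an
#' attribute — the presets penalize safety liabilities (weight -2) and reward
#' everything else.
#'
#' The ten keys are `pathways` (number of significant pathways containing the
#' target), `tractability` (tractability bucket count), `approved` (approved
#' therapeutics), `safety` (safety liabilities), `unique_drugs`, `diseases`
#' (associated disease count) and `phase1`..`phase4` (therapeutics whose
#' maximum clinical phase is 1..4).
#'
#' @param preset `"default"` or `"novel"`.
#' @param ... Named overrides, e.g. `safety = -5`. Unknown names error.
#' @return A named numeric vector of class `tr_weights`.
#' @export
#' @examples
#' weight_scheme("default")
#' weight_scheme("novel", phase1 = 20)
weight_scheme <- function(preset = c("default", "novel"), ...) {
  preset <- rlang::arg_match(preset)
  w <- .weight_presets[[preset]]
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("Weight overrides must be named.", class = "targetrank_usage_error")
    }
    bad <- setdiff(names(overrides), .weight_keys)
    if (length(bad) > 0) {
      abort(paste0("Unknown weight key(s): ", paste(bad, collapse = ", "),
                   ". Valid keys: ", paste(.weight_keys, collapse = ", ")),
            class = "targetrank_usage_error")
    }
    vals <- unlist(overrides)
    if (!is.numeric(vals) || any(!is.finite(vals))) {
      abort("Weights must be finite numbers.", class = "targetrank_usage_error")
    }
    w[names(overrides)] <- vals
  }
  structure(w, class = "tr_weights", preset = preset)
}

#' Read a weight scheme from a YAML file
#'
#' The file may contain a `preset` key (`default`/`novel`) and any subset of
#' the ten weight keys as overrides; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `tr_weights` vector.
#' @export
read_weight_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Weight file not found: ", path),
          class = "targetrank_io_error")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    abort("Weight file must be a YAML mapping.",
          class = "targetrank_format_error")
  }
  preset <- cfg$preset %||% "default"
  cfg$preset <- NULL
  bad <- setdiff(names(cfg), .weight_keys)
  if (length(bad) > 0) {
    abort(paste0("Unknown weight key(s) in ", path, ": ",
                 paste(bad, collapse = ", ")),
          class = "targetrank_usage_error")
  }
  rlang::exec(weight_scheme, preset = preset, !!!cfg)
}

#' @export
print.tr_weights <- function(x, ...) {
  cat("<tr_weights> preset:", attr(x, "preset") %||% "custom",
      " hash:", scheme_hash(x), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

as_weights <- function(weights) {
  if (inherits(weights, "tr_weights")) return(weights)
  if (is.character(weights) && length(weights) == 1) {
    if (weights %in% names(.weight_presets)) return(weight_scheme(weights))
    return(read_weight_scheme(weights))
  }
  abort("`weights` must be a tr_weights object, a preset name, or a YAML path.",
        class = "targetrank_usage_error")
}
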