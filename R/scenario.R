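#' Describe a choice scenario
#'
#' A scenario fixes everything about a single choice episode that is not
#' part of the structure itself: which alternatives are on offer, which
#' nodes are clamped active (cues are always clamped during evaluation;
#' an owned alternative or a revealed decoy can be clamped in addition),
#' which unavailable decoys still take part in the dynamics without being
#' choosable, where the process starts, which trigger stops it, and
#' whether the first Metropolis step is forced even when the start
#' configuration already satisfies a choice condition (the endowment
#' protocol).
#'
#' @param available Character vector of choosable alternative ids
#'   (non-empty).
#' @param initial Either the string `"resting"` (start from the resting
#'   Boltzmann distribution of the induced network, cue states
#'   marginalised out), a named 0/1 vector over the mutable alternatives
#'   (a known configuration), or a numeric probability vector over the
#'   `2^m` canonical alternative configurations.
#' @param clamped_active Node ids clamped active in addition to cue-role
#'   nodes. Must be disjoint from `available`.
#' @param unavailable_decoys Alternative ids that are sampled and flipped
#'   during evaluation but cannot be chosen (phantom decoys known to be
#'   unavailable upfront).
#' @param trigger One of `"first_passage"`, `"converged"`,
#'   `"k_visit_proportional"`, `"k_visit_first"`.
#' @param forced_first_step Logical; when `TRUE`, a start in a choice
#'   condition does not trigger immediately: one Metropolis step is always
#'   executed, and re-absorption counts as choosing the start alternative.
#' @return An object of class `choice_scenario`.
#' @export
choice_scenario <- function(available,
                            initial = "resting",
                            clamped_active = character(0),
                            unavailable_decoys = character(0),
                            trigger = c("first_passage", "converged",
                                        "k_visit_proportional",
                                        "k_visit_first"),
                            forced_first_step = FALSE) {
  if (length(available) == 0L)
    stop("`available` must be non-empty", call. = FALSE)
  if (length(intersect(available, clamped_active)))
    stop("`available` and `clamped_active` must be disjoint", call. = FALSE)
  if (length(intersect(available, unavailable_decoys)))
    stop("a decoy cannot also be available", call. = FALSE)
  trigger <- match.arg(trigger)
  structure(
    list(available = as.character(available),
         initial = initial,
         clamped_active = as.character(clamped_active),
         unavailable_decoys = as.character(unavailable_decoys),
         trigger = trigger,
         forced_first_step = isTRUE(forced_first_step)),
    class = "choice_scenario"
  )
}

#' @export
print.choice_scenario <- function(x, ...) {
  cat("Choice scenario\n")
  cat("  available:", paste(x$available, collapse = ", "), "\n")
  if (length(x$unavailable_decoys))
    cat("  unavailable decoys:", paste(x$unavailable_decoys, collapse = ", "),
        "\n")
  if (length(x$clamped_active))
    cat("  clamped active:", paste(x$clamped_active, collapse = ", "), "\n")
  ini <- if (identical(x$initial, "resting")) "resting distribution"
         else "known/explicit start"
  cat("  initial:", ini, "\n")
  cat("  trigger:", x$trigger,
      if (x$forced_first_step) "(forced first step)" else "", "\n")
  invisible(x)
}

# Mutable (proposable) alternative nodes of a scenario, in structure order.
scenario_mutable <- function(structure, scenario) {
  ids <- c(scenario$available, scenario$unavailable_decoys)
  miss <- setdiff(ids, structure$nodes)
  if (length(miss))
    stop("scenario references unknown node id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- ids[structure$roles[ids] != "alternative"]
  if (length(bad))
    stop("not alternative nodes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure$nodes[structure$nodes %in% ids]
}

# Nodes clamped active during evaluation: every cue plus explicit clamps.
scenario_clamped <- function(structure, scenario) {
  union(cue_ids(structure), scenario$clamped_active)
}

# Induced network a scenario evaluates: clamped nodes plus mutable
# alternatives; alternatives not on offer are absent (equivalently clamped
# inactive, contributing nothing to any energy).
scenario_structure <- function(structure, scenario) {
  keep <- union(scenario_clamped(structure, scenario),
                scenario_mutable(structure, scenario))
  restrict_structure(structure, keep)
}

# Start distribution over the canonical 2^m alternative configurations.
scenario_start_distribution <- function(structure, scenario) {
  sub <- scenario_structure(structure, scenario)
  mutable <- scenario_mutable(structure, scenario)
  m <- length(mutable)
  ini <- scenario$initial
  if (identical(ini, "resting")) {
    return(resting_alternative_distribution(
      sub, alternatives = mutable,
      clamped_active = intersect(scenario$clamped_active, sub$nodes),
      available = scenario$available))
  }
  if (is.numeric(ini) && length(ini) == m &&
      all(ini %in% c(0, 1)) && !is.null(names(ini))) {
    x <- ini[mutable]
    if (anyNA(x))
      stop("known configuration must name every mutable alternative",
           call. = FALSE)
    probs <- numeric(2^m)
    probs[config_index(as.numeric(x))] <- 1
    return(state_distribution(enumerate_configurations(m, mutable), probs,
                              mutable, scenario$available))
  }
  if (is.numeric(ini) && length(ini) == 2^m) {
    if (any(ini < 0) || abs(sum(ini) - 1) > 1e-10)
      stop("explicit start distribution must be a probability vector",
           call. = FALSE)
    return(state_distribution(enumerate_configurations(m, mutable),
                              ini / sum(ini), mutable, scenario$available))
  }
  stop("`initial` must be \"resting\", a named 0/1 configuration over the ",
       "mutable alternatives, or a probability vector of length 2^m",
       call. = FALSE)
}
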