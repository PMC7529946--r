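# JSON structure documents, result documents, and tabular writers.

STRUCTURE_SCHEMA_VERSION <- "1.0"

#' Write a choice structure to JSON
#'
#' Serialises a structure as a versioned JSON document: a node list
#' (`id`, `role`, `appeal`), an undirected edge list (each pair stored
#' once with `source` < `target` lexicographically), and the scaling
#' constants. Numbers are written at full precision.
#'
#' @param structure A [choice_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  nz <- which(upper.tri(structure$coupling) & structure$coupling != 0,
              arr.ind = TRUE)
  edges <- if (nrow(nz)) {
    src <- structure$nodes[nz[, 1]]; tgt <- structure$nodes[nz[, 2]]
    swap <- src > tgt
    tmp <- src[swap]; src[swap] <- tgt[swap]; tgt[swap] <- tmp
    data.frame(source = src, target = tgt,
               weight = structure$coupling[nz], stringsAsFactors = FALSE)
  } else data.frame(source = character(0), target = character(0),
                    weight = numeric(0))
  doc <- list(
    schema_version = STRUCTURE_SCHEMA_VERSION,
    nodes = data.frame(id = structure$nodes,
                       role = unname(structure$roles),
                       appeal = unname(structure$appeal),
                       stringsAsFactors = FALSE),
    edges = edges,
    beta = structure$beta,
    mu = structure$mu)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a choice structure from JSON
#'
#' Parses and validates a structure document written by
#' [write_structure()] (or by hand against the schema shipped in
#' `inst/schema/`). Validation is strict: unknown roles, duplicate node
#' ids, edges referencing unknown ids, duplicate undirected edges
#' (including asymmetric re-statements of the same pair) and a negative
#' `beta` are all rejected with a message naming the offending field.
#'
#' @param path Path to a JSON structure document.
#' @return A validated [choice_structure()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  for (field in c("nodes", "beta", "mu"))
    if (is.null(doc[[field]]))
      stop("structure document missing required field '", field, "'",
           call. = FALSE)
  nodes <- as.data.frame(doc$nodes)
  for (field in c("id", "role"))
    if (is.null(nodes[[field]]))
      stop("every node needs an '", field, "' field", call. = FALSE)
  if (is.null(nodes$appeal)) nodes$appeal <- 0
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(nodes$role), c("cue", "alternative"))
  if (length(bad_role))
    stop("unknown node role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(doc$beta) || doc$beta < 0)
    stop("field 'beta' must be a non-negative number", call. = FALSE)
  edges <- doc$edges
  A <- matrix(0, nrow(nodes), nrow(nodes),
              dimnames = list(nodes$id, nodes$id))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.data.frame(edges)
    for (field in c("source", "target", "weight"))
      if (is.null(edges[[field]]))
        stop("every edge needs a '", field, "' field", call. = FALSE)
    seen <- character(0)
    for (r in seq_len(nrow(edges))) {
      src <- edges$source[r]; tgt <- edges$target[r]
      for (id in c(src, tgt))
        if (!(id %in% nodes$id))
          stop("edge ", r, " references unknown node id '", id, "'",
               call. = FALSE)
      if (src == tgt)
        stop("edge ", r, " is a self-edge on '", src, "'", call. = FALSE)
      key <- paste(sort(c(src, tgt)), collapse = "\r")
      if (key %in% seen)
        stop("duplicate undirected edge between '", src, "' and '", tgt,
             "' (edge ", r, "); each pair may be stated once",
             call. = FALSE)
      seen <- c(seen, key)
      A[src, tgt] <- edges$weight[r]
      A[tgt, src] <- edges$weight[r]
    }
  }
  choice_structure(nodes = nodes$id, roles = nodes$role,
                   appeal = nodes$appeal, coupling = A,
                   beta = doc$beta, mu = doc$mu)
}

#' Write a self-contained result document
#'
#' Serialises a solved or simulated outcome together with an echo of the
#' inputs that produced it (structure, scenario, seed, tool version), so
#' the result can be reproduced from the document alone.
#'
#' @param outcome A `choice_outcome` or `simulation_summary`.
#' @param structure The [choice_structure()] used.
#' @param scenario The [choice_scenario()] used.
#' @param path Output JSON path.
#' @param seed Seed echoed for simulated results (optional).
#' @return `path`, invisibly.
#' @export
write_result <- function(outcome, structure, scenario, path, seed = NULL) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_structure(structure, tmp)
  doc <- list(
    tool = "netchoice",
    version = as.character(utils::packageVersion("netchoice")),
    structure = jsonlite::read_json(tmp, simplifyVector = TRUE),
    scenario = list(
      available = scenario$available,
      clamped_active = scenario$clamped_active,
      unavailable_decoys = scenario$unavailable_decoys,
      trigger = scenario$trigger,
      forced_first_step = scenario$forced_first_step,
      initial = if (identical(scenario$initial, "resting")) "resting"
                else scenario$initial),
    seed = seed)
  if (inherits(outcome, "choice_outcome")) {
    doc$probabilities <- as.list(outcome$probabilities)
    if (!is.null(outcome$expected_iterations))
      doc$expected_iterations <- as.list(outcome$expected_iterations)
    doc$overall_expected_iterations <- outcome$overall_expected_iterations
    doc$condition_warning <- outcome$condition_warning
  } else if (inherits(outcome, "simulation_summary")) {
    doc$n_trials <- outcome$n_trials
    doc$probabilities <- as.list(outcome$empirical_probs)
    doc$prob_standard_errors <- as.list(outcome$prob_standard_errors)
    doc$mean_iterations <- outcome$mean_iterations
  } else stop("unsupported outcome object", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pairwise table from JSON
#'
#' Reads a document with fields `alternatives`, `pairs` (list of
#' `{x, y, p}` giving the probability of choosing `x` from the pair) and
#' optionally `subsets` (list of named probability maps).
#'
#' @param path Path to a JSON pairwise-table document.
#' @return A [pairwise_table()].
#' @export
read_pairwise_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  alts <- unlist(doc$alternatives)
  if (is.null(alts))
    stop("pairwise table document needs an 'alternatives' field",
         call. = FALSE)
  p <- matrix(NA_real_, length(alts), length(alts),
              dimnames = list(alts, alts))
  for (pr in doc$pairs) {
    p[pr$x, pr$y] <- pr$p
    p[pr$y, pr$x] <- 1 - pr$p
  }
  subset_probs <- NULL
  if (!is.null(doc$subsets))
    subset_probs <- lapply(doc$subsets, function(s) unlist(s))
  pairwise_table(alts, p, subset_probs)
}

#' Write a phase grid as long-format CSV
#'
#' One row per (beta, mu) cell with the per-alternative probabilities,
#' the log mean iteration count and the phase label.
#'
#' @param grid A `phase_grid` from [phase_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
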