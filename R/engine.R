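#' @name simulation_engine
#' @title Replicated message-condition experiment protocol
#'
#' @description
#' Each experimental condition injects one single message into a freshly
#' generated population, observes the evacuation decision of every agent,
#' and repeats this for a fixed number of replications under seeds derived
#' deterministically from the condition's seed. Agent state is discarded
#' between replications and between conditions (memory reset), so results
#' are invariant to condition order and to which other conditions run.
#' What varies across replications is the population redraw (attribute
#' sampling and belief-initialization noise); the decision step itself is
#' deterministic.
NULL

#' Construct one condition specification
#'
#' @param condition_id Message id (must exist in the catalog used to run).
#' @param n_agents Positive number of agents per replication.
#' @param n_replications Number of replications (>= 1).
#' @param seed Integer seed; replication seeds are derived from it with
#'   [seed_combine()].
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(condition_id, n_agents, n_replications = 10,
                           seed = 1) {
  stopifnot(n_agents > 0, n_replications >= 1)
  structure(list(condition_id = as.character(condition_id),
                 n_agents = as.integer(n_agents),
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed)),
            class = c("condition_spec", "list"))
}

#' The default sixteen-condition experiment design
#'
#' One condition per bundled catalog message, 222 agents per condition
#' except the third fear+efficacy+norm condition with 220, ten replications
#' each — 3,550 agent-observations per aggregated experiment in total.
#'
#' @param master_seed Integer master seed shared by all conditions;
#'   per-replication seeds are derived from (seed, condition id,
#'   replication index).
#' @param n_replications Replications per condition.
#' @return List of [condition_spec()] objects.
#' @export
default_design <- function(master_seed = 1, n_replications = 10) {
  ids <- c("C1", "F1", "F2", "F3", "E1", "E2", "E3", "M1", "M2", "M3",
           "T1", "T2", "T3", "FEN1", "FEN2", "FEN3")
  lapply(ids, function(id) {
    condition_spec(id, n_agents = if (id == "FEN3") 220L else 222L,
                   n_replications = n_replications, seed = master_seed)
  })
}

#' Read an experiment design from YAML
#'
#' The design file lists conditions with fields `condition_id` (a message
#' id), `n_agents`, `n_replications` and `seed`.
#'
#' @param path Path to a YAML design file with a top-level `conditions` list
#'   (and optionally a shared `seed` / `n_replications` default).
#' @return List of [condition_spec()] objects.
#' @export
read_design <- function(path) {
  stopifnot(file.exists(path))
  doc <- yaml::read_yaml(path)
  conds <- doc$conditions %||% doc
  lapply(conds, function(cn) {
    condition_spec(cn$condition_id %||% cn$message_id,
                   n_agents = cn$n_agents,
                   n_replications = cn$n_replications %||%
                     (doc$n_replications %||% 10),
                   seed = cn$seed %||% (doc$seed %||% 1))
  })
}

#' Run one message condition
#'
#' For each replication r, a child seed is derived from (condition seed,
#' condition id, r); a fresh population of `spec$n_agents` agents is
#' generated, beliefs are initialized, the condition's message is applied
#' once to every agent, and each agent decides. One record per (replication,
#' agent) is emitted. Nothing persists between replications.
#'
#' @param spec A [condition_spec()].
#' @param pop_config Population configuration (its `n_agents` and `seed` are
#'   overridden per replication).
#' @param weights A [decision_weights()] object.
#' @param catalog Message catalog containing `spec$condition_id`.
#' @param init Belief-initialization settings.
#' @param constraint_weights Constraint weights.
#' @return Data frame of run records: `condition_id`, `replication`,
#'   `agent_id`, `evacuated`.
#' @export
run_condition <- function(spec, pop_config = default_population_config(),
                          weights = default_weights(),
                          catalog = default_catalog(),
                          init = default_belief_init(),
                          constraint_weights = default_constraint_weights()) {
  msg <- catalog_message(catalog, spec$condition_id)
  reps <- lapply(seq_len(spec$n_replications), function(r) {
    cfg <- pop_config
    cfg$n_agents <- spec$n_agents
    cfg$seed <- seed_combine(spec$seed, spec$condition_id, r)
    pop <- generate_population(cfg)
    beliefs <- initialize_beliefs(pop, init)   # continues the seeded stream
    beliefs <- apply_message(beliefs, msg)
    cs <- constraint_score(pop, constraint_weights)
    action <- decide(beliefs, cs, weights)
    data.frame(condition_id = spec$condition_id, replication = r,
               agent_id = pop$agent_id, evacuated = action == "evacuate",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reps)
}

#' Run a full multi-condition experiment
#'
#' Executes every condition independently (memory reset between conditions)
#' and aggregates evacuated counts across replications.
#'
#' @param design List of [condition_spec()] objects with distinct ids.
#' @inheritParams run_condition
#' @return An `experiment_result` list with elements `records` (all run
#'   records) and `per_condition_counts` (see [aggregate_records()]).
#' @export
run_experiment <- function(design, pop_config = default_population_config(),
                           weights = default_weights(),
                           catalog = default_catalog(),
                           init = default_belief_init(),
                           constraint_weights = default_constraint_weights()) {
  ids <- vapply(design, function(s) s$condition_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate condition id '%s' in design", dup[1]), call. = FALSE)
  }
  if (length(design) == 0) {
    empty <- data.frame(condition_id = character(0), replication = integer(0),
                        agent_id = character(0), evacuated = logical(0))
    return(structure(list(records = empty,
                          per_condition_counts = aggregate_records(empty)),
                     class = c("experiment_result", "list")))
  }
  records <- do.call(rbind, lapply(design, run_condition,
                                   pop_config = pop_config, weights = weights,
                                   catalog = catalog, init = init,
                                   constraint_weights = constraint_weights))
  structure(list(records = records,
                 per_condition_counts = aggregate_records(records, ids)),
            class = c("experiment_result", "list"))
}

#' Aggregate run records into per-condition counts
#'
#' Per condition, the evacuated count is the mean over replications of the
#' per-replication evacuated counts, rounded half-up to an integer;
#' `not_evacuated` is the complement so that counts always sum to the
#' per-condition population size.
#'
#' @param records Run-record data frame from [run_condition()].
#' @param condition_order Optional character vector fixing row order;
#'   defaults to first appearance in `records`.
#' @return Data frame with columns `condition_id`, `n_agents`, `evacuated`,
#'   `not_evacuated`, `pct_evacuated`.
#' @export
aggregate_records <- function(records, condition_order = NULL) {
  if (nrow(records) == 0) {
    return(data.frame(condition_id = character(0), n_agents = integer(0),
                      evacuated = integer(0), not_evacuated = integer(0),
                      pct_evacuated = numeric(0), stringsAsFactors = FALSE))
  }
  ids <- condition_order %||% unique(records$condition_id)
  rows <- lapply(ids, function(id) {
    rec <- records[records$condition_id == id, , drop = FALSE]
    per_rep <- tapply(rec$evacuated, rec$replication, sum)
    n_agents <- nrow(rec) / length(per_rep)
    stopifnot(n_agents == round(n_agents))
    ev <- as.integer(round_half_up(mean(per_rep)))
    data.frame(condition_id = id, n_agents = as.integer(n_agents),
               evacuated = ev, not_evacuated = as.integer(n_agents) - ev,
               pct_evacuated = 100 * ev / n_agents, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
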