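# Iterative score-gated particle selection.
#
# Each round: the in-flight particles are 2D-classified by a pluggable
# backend, every resulting class is scored, and its member particles are
# dispositioned by the class score:
#   score <= good_cutoff   : a seeded random 70% of the class moves to the
#                            accepted pool, 30% stays in flight
#   between the cutoffs    : the class stays in flight for re-classification
#   score >= accept_cutoff : the class is discarded
# After the planned rounds, in-flight particles whose last class scored
# below accept_cutoff join the pool; the pool is classified once more and
# split into three nested batches at the final thresholds.

#' Plan the number of classification rounds from the extraction box
#'
#' The extraction-box side is an indirect measure of particle size: small
#' particles (noisier classes) get more rounds. Boxes below 200 px run 5
#' rounds, 200-300 px (inclusive) run 3, above 300 px run 2.
#'
#' @param box_px Extraction box side in pixels (> 0).
#' @return Integer number of rounds (5, 3 or 2).
#' @examples
#' plan_iterations(150)  # 5
#' plan_iterations(250)  # 3
#' plan_iterations(350)  # 2
#' @export
plan_iterations <- function(box_px) {
  if (!is.numeric(box_px) || length(box_px) != 1L || !is.finite(box_px) || box_px <= 0)
    stop("box_px must be a single positive number")
  if (box_px < 200) 5L else if (box_px <= 300) 3L else 2L
}

#' Build an iteration plan
#'
#' @param box_px Extraction box side in pixels.
#' @param accept_cutoff Classes scoring at or above this are discarded
#'   (default 4.5).
#' @param good_cutoff Classes scoring at or below this trigger the
#'   set-aside split (default 2.5).
#' @param setaside_fraction Fraction of a good class pooled per round
#'   (default 0.70, round-half-up on the count).
#' @param final_thresholds Strictly increasing score thresholds for the
#'   three nested final batches (default 2.5, 3.5, 4.5).
#' @param n_iterations Override for the round count; default derives from
#'   `box_px` via [plan_iterations()].
#' @param seed Integer seed driving every random set-aside draw.
#' @param pool_setaside If `TRUE` (default) the set-aside 70% of a good
#'   class joins the accepted pool; if `FALSE` it is removed outright.
#' @return An `iteration_plan` list.
#' @export
iteration_plan <- function(box_px, accept_cutoff = 4.5, good_cutoff = 2.5,
                           setaside_fraction = 0.70,
                           final_thresholds = c(2.5, 3.5, 4.5),
                           n_iterations = NULL, seed = 1L,
                           pool_setaside = TRUE) {
  if (good_cutoff >= accept_cutoff) stop("good_cutoff must be below accept_cutoff")
  if (is.unsorted(final_thresholds, strictly = TRUE))
    stop("final_thresholds must be strictly increasing")
  stopifnot(setaside_fraction >= 0, setaside_fraction <= 1)
  n_it <- if (is.null(n_iterations)) plan_iterations(box_px) else as.integer(n_iterations)
  structure(list(box_px = box_px, n_iterations = n_it,
                 accept_cutoff = accept_cutoff, good_cutoff = good_cutoff,
                 setaside_fraction = setaside_fraction,
                 final_thresholds = final_thresholds,
                 seed = as.integer(seed), pool_setaside = isTRUE(pool_setaside)),
            class = "iteration_plan")
}

# Deterministic per-(seed, iteration, class) RNG substream, independent of
# the global RNG state and of cutoff settings, so reruns and resumed runs
# reproduce the same draws and cutoff changes do not reshuffle them.
.class_seed <- function(seed, iteration, class_index) {
  as.integer((as.double(seed) * 1000003 + iteration * 10007 +
                class_index * 101) %% 2147483647)
}

# The set-aside draw ranks particles by a per-(seed, iteration, particle)
# hash key and takes the smallest `size` keys: the exact per-class count is
# honored, while whether a given particle sorts early does not depend on
# which other particles share its class, so resumed runs, re-enumerated
# classes and cutoff changes keep the draws aligned.
.id_key <- function(ids, seed, iteration) {
  v <- if (is.character(ids)) vapply(ids, function(s) sum(utf8ToInt(s)), numeric(1))
       else as.numeric(ids)
  (as.double(seed) * 1000003 + iteration * 10007 + v * 2654435761) %% 2147483647
}

.seeded_sample <- function(x, size, seed, iteration) {
  x[order(.id_key(x, seed, iteration), x)][seq_len(size)]
}

round_half_up <- function(x) floor(x + 0.5)

#' Initialize a selection state
#'
#' @param particles Vector of particle ids (integer or character).
#' @return A `selection_state` with all particles in flight.
#' @export
selection_state <- function(particles) {
  particles <- unique(particles)
  structure(list(pooled = particles[0], in_flight = particles,
                 rejected = particles[0], iteration = 0L,
                 last_score = stats::setNames(numeric(0), character(0)),
                 initial_n = length(particles), finished = FALSE,
                 final_scores = NULL, final_membership = NULL, batches = NULL,
                 audit = .empty_audit()), class = "selection_state")
}

.empty_audit <- function() {
  data.frame(iteration = integer(), class_index = integer(), score = numeric(),
             disposition = character(), n_members = integer(),
             n_pooled = integer(), n_rejected = integer(), n_retained = integer(),
             stringsAsFactors = FALSE)
}

.check_state <- function(state) {
  if (anyDuplicated(c(state$pooled, state$in_flight, state$rejected)))
    stop("selection-state invariant violated: pooled/in-flight/rejected overlap")
  n <- length(state$pooled) + length(state$in_flight) + length(state$rejected)
  if (n != state$initial_n)
    stop(sprintf("particle conservation violated: %d tracked vs %d initial",
                 n, state$initial_n))
  invisible(state)
}

#' Disposition classified particles by class score
#'
#' Applies the threshold semantics per class: score <= `good_cutoff` splits
#' the class (a seeded random `setaside_fraction` to the pool, remainder
#' stays in flight, set-aside count rounded half-up); scores strictly
#' between the cutoffs stay in flight; score >= `accept_cutoff` rejects the
#' class. Every class action is appended to the audit log.
#'
#' @param state A `selection_state`.
#' @param result A classification result: list of classes, each a list with
#'   at least `members` (particle ids); classes must partition the in-flight
#'   set.
#' @param scores Numeric vector, one score per class.
#' @param plan An [iteration_plan()].
#' @param iteration Round number used for seeding and the audit log.
#' @return The updated `selection_state`.
#' @export
disposition_classes <- function(state, result, scores, plan, iteration) {
  stopifnot(inherits(state, "selection_state"), inherits(plan, "iteration_plan"))
  members <- lapply(result, `[[`, "members")
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("classification result is inconsistent: particle(s) appear in more than one class")
  if (length(scores) != length(result))
    stop("need exactly one score per class")
  if (!all(all_members %in% state$in_flight))
    stop("classification result contains particles that are not in flight")

  for (k in seq_along(result)) {
    ids <- members[[k]]
    s <- scores[k]
    n_m <- length(ids)
    state$last_score[as.character(ids)] <- s
    if (s >= plan$accept_cutoff) {
      state$rejected <- c(state$rejected, ids)
      state$in_flight <- setdiff(state$in_flight, ids)
      row <- list(disposition = "rejected", n_pooled = 0L,
                  n_rejected = n_m, n_retained = 0L)
    } else if (s <= plan$good_cutoff) {
      n_aside <- round_half_up(plan$setaside_fraction * n_m)
      aside <- .seeded_sample(ids, n_aside, plan$seed, iteration)
      if (plan$pool_setaside) state$pooled <- c(state$pooled, aside)
      else state$rejected <- c(state$rejected, aside)
      state$in_flight <- setdiff(state$in_flight, aside)
      row <- list(disposition = if (plan$pool_setaside) "split_pooled" else "split_removed",
                  n_pooled = if (plan$pool_setaside) length(aside) else 0L,
                  n_rejected = if (plan$pool_setaside) 0L else length(aside),
                  n_retained = n_m - length(aside))
    } else {
      row <- list(disposition = "retained", n_pooled = 0L, n_rejected = 0L,
                  n_retained = n_m)
    }
    state$audit <- rbind(state$audit, data.frame(
      iteration = as.integer(iteration), class_index = k, score = s,
      disposition = row$disposition, n_members = n_m, n_pooled = row$n_pooled,
      n_rejected = row$n_rejected, n_retained = row$n_retained,
      stringsAsFactors = FALSE))
  }
  .check_state(state)
}

#' Split the final classification into three nested particle batches
#'
#' Batch k contains every particle whose final class score is at or below
#' `thresholds[k]`, so the batches are nested by construction
#' (batch 1 within batch 2 within batch 3).
#'
#' @param scores Numeric score per final class.
#' @param membership List of particle-id vectors, one per final class.
#' @param thresholds Strictly increasing thresholds (default 2.5, 3.5, 4.5).
#' @return List of three id vectors, nested.
#' @export
final_batches <- function(scores, membership, thresholds = c(2.5, 3.5, 4.5)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  stopifnot(length(scores) == length(membership))
  batches <- lapply(thresholds, function(th)
    unlist(membership[scores <= th], use.names = FALSE))
  for (k in seq_along(batches)[-1])
    if (!all(batches[[k - 1]] %in% batches[[k]]))
      stop("internal error: final batches are not nested")
  names(batches) <- sprintf("le_%g", thresholds)
  batches
}

#' Run the iterative selection workflow
#'
#' Executes `plan$n_iterations` rounds of classify-score-disposition over the
#' in-flight set, flushes surviving in-flight particles whose last class
#' scored below `accept_cutoff` into the pool (others are rejected), runs one
#' final classification over the pool, and splits it into three nested
#' batches at `plan$final_thresholds`. Particle conservation and batch
#' nesting are asserted at every step; identical seeds give identical final
#' states and audit logs.
#'
#' The backend contract: `backend(particle_ids, iteration, seed)` returns a
#' list of classes, each `list(members = ids, image = matrix or NULL,
#' record = list or NULL)`, the members exactly partitioning `particle_ids`.
#' The scorer contract: `scorer(classes, iteration)` returns one numeric
#' score per class. Both must be deterministic in their arguments; the
#' workflow assumes nothing else about how classes are formed.
#'
#' @param particles Vector of particle ids.
#' @param backend Classification backend function (see Details).
#' @param scorer Class-scoring function (see Details).
#' @param plan An [iteration_plan()].
#' @param state Optional `selection_state` to resume from (e.g. a snapshot
#'   loaded with [read_workflow_snapshot()]).
#' @param stop_after Stop after this round and return the partial state
#'   (for snapshot/resume); `Inf` runs to completion.
#' @return The final `selection_state`, with `batches`, `final_scores`,
#'   `final_membership` and the full `audit` log.
#' @export
run_workflow <- function(particles, backend, scorer, plan,
                         state = NULL, stop_after = Inf) {
  stopifnot(inherits(plan, "iteration_plan"))
  if (is.null(state)) state <- selection_state(particles)
  if (state$finished) return(state)

  it <- state$iteration + 1L
  while (it <= plan$n_iterations) {
    if (it > stop_after) return(state)
    if (!length(state$in_flight)) {
      warning("in-flight set empty after round ", it - 1L,
              "; terminating iteration early")
      break
    }
    result <- backend(state$in_flight, it, plan$seed)
    .check_partition(result, state$in_flight)
    scores <- scorer(result, it)
    state <- disposition_classes(state, result, scores, plan, it)
    state$iteration <- it
    it <- it + 1L
  }

  # flush: surviving in-flight particles whose last class scored below the
  # accept cutoff join the pool (by construction all survivors qualify)
  if (length(state$in_flight)) {
    ls <- state$last_score[as.character(state$in_flight)]
    ok <- is.na(ls) | ls < plan$accept_cutoff
    state$pooled <- c(state$pooled, state$in_flight[ok])
    state$rejected <- c(state$rejected, state$in_flight[!ok])
    state$audit <- rbind(state$audit, data.frame(
      iteration = state$iteration + 1L, class_index = NA_integer_,
      score = NA_real_, disposition = "flush",
      n_members = length(state$in_flight), n_pooled = sum(ok),
      n_rejected = sum(!ok), n_retained = 0L, stringsAsFactors = FALSE))
    state$in_flight <- state$in_flight[0]
  }
  .check_state(state)

  # final classification of the pooled set, then the nested threshold split
  if (length(state$pooled)) {
    final_it <- plan$n_iterations + 1L
    result <- backend(state$pooled, final_it, plan$seed)
    .check_partition(result, state$pooled)
    scores <- scorer(result, final_it)
    membership <- lapply(result, `[[`, "members")
    state$final_scores <- scores
    state$final_membership <- membership
    state$batches <- final_batches(scores, membership, plan$final_thresholds)
    state$audit <- rbind(state$audit, data.frame(
      iteration = final_it, class_index = seq_along(result), score = scores,
      disposition = "final", n_members = lengths(membership),
      n_pooled = 0L, n_rejected = 0L, n_retained = lengths(membership),
      stringsAsFactors = FALSE))
  } else {
    state$batches <- stats::setNames(
      rep(list(particles[0]), length(plan$final_thresholds)),
      sprintf("le_%g", plan$final_thresholds))
  }
  state$finished <- TRUE
  .check_state(state)
  state
}

.check_partition <- function(result, ids) {
  members <- unlist(lapply(result, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, ids))
    stop("backend contract violated: classes must exactly partition their input")
  invisible(TRUE)
}

#' Write a workflow state snapshot
#'
#' JSON snapshot sufficient to resume an interrupted run with
#' [run_workflow()]; resuming reproduces the uninterrupted result exactly
#' because every random draw is keyed by (seed, round, class), not by global
#' RNG state.
#'
#' @param state A `selection_state`.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_workflow_snapshot <- function(state, path) {
  payload <- list(format = "cryograder-state-v1",
                  pooled = state$pooled, in_flight = state$in_flight,
                  rejected = state$rejected, iteration = state$iteration,
                  last_score_ids = names(state$last_score),
                  last_score = unname(state$last_score),
                  initial_n = state$initial_n, finished = state$finished,
                  audit = state$audit)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a workflow state snapshot
#'
#' @param path Path written by [write_workflow_snapshot()].
#' @return A `selection_state`.
#' @export
read_workflow_snapshot <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cryograder-state-v1"))
    stop("not a cryograder workflow snapshot: ", path)
  as_ids <- function(v) if (is.null(v)) integer(0) else v
  audit <- if (is.data.frame(p$audit) && nrow(p$audit)) p$audit else .empty_audit()
  structure(list(pooled = as_ids(p$pooled), in_flight = as_ids(p$in_flight),
                 rejected = as_ids(p$rejected), iteration = as.integer(p$iteration),
                 last_score = stats::setNames(as.numeric(p$last_score),
                                              as.character(p$last_score_ids)),
                 initial_n = as.integer(p$initial_n), finished = isTRUE(p$finished),
                 final_scores = NULL, final_membership = NULL, batches = NULL,
                 audit = audit), class = "selection_state")
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("<selection_state> round %d%s | pooled %d | in flight %d | rejected %d of %d\n",
              x$iteration, if (x$finished) " (finished)" else "",
              length(x$pooled), length(x$in_flight), length(x$rejected), x$initial_n))
  invisible(x)
}
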