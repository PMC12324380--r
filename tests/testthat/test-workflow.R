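# Iterative score-gated selection: schedule, disposition semantics,
# conservation, determinism, resume.

make_classes <- function(sizes, ids = seq_len(sum(sizes))) {
  stopifnot(length(ids) == sum(sizes))
  split_ids <- split(ids, rep(seq_along(sizes), sizes))
  lapply(split_ids, function(m) list(members = m))
}

test_that("the iteration schedule follows the box-size tiers", {
  expect_identical(plan_iterations(150), 5L)
  expect_identical(plan_iterations(250), 3L)
  expect_identical(plan_iterations(350), 2L)
  expect_identical(plan_iterations(199), 5L)
  expect_identical(plan_iterations(200), 3L)   # boundary -> middle tier
  expect_identical(plan_iterations(300), 3L)
  expect_identical(plan_iterations(301), 2L)
  expect_error(plan_iterations(0), "positive")
  expect_error(plan_iterations(-10), "positive")
})

test_that("disposition reproduces the three-class bookkeeping example", {
  classes <- make_classes(c(1000, 500, 200))
  plan <- iteration_plan(box_px = 350, seed = 1)
  st <- selection_state(1:1700)
  st <- disposition_classes(st, classes, c(2.0, 3.0, 4.8), plan, iteration = 1)
  expect_length(st$pooled, 700)      # 70% of the 1000 @ 2.0
  expect_length(st$in_flight, 800)   # 300 remainder + 500 middle class
  expect_length(st$rejected, 200)
  expect_identical(length(st$pooled) + length(st$in_flight) + length(st$rejected), 1700L)
})

test_that("threshold boundaries: exactly 4.5 rejects, exactly 2.5 splits", {
  plan <- iteration_plan(box_px = 350, seed = 3)
  st <- disposition_classes(selection_state(1:100), make_classes(100),
                            4.5, plan, 1)
  expect_length(st$rejected, 100)
  st2 <- disposition_classes(selection_state(1:100), make_classes(100),
                             2.5, plan, 1)
  expect_length(st2$pooled, 70)
  expect_length(st2$in_flight, 30)
  # strictly between the cutoffs: nothing moves
  st3 <- disposition_classes(selection_state(1:100), make_classes(100),
                             3.7, plan, 1)
  expect_length(st3$in_flight, 100)
})

test_that("the set-aside count rounds half up per class", {
  plan <- iteration_plan(box_px = 350, seed = 4)
  # 5 particles: 0.7*5 = 3.5 -> 4 pooled
  st <- disposition_classes(selection_state(1:5), make_classes(5), 2.0, plan, 1)
  expect_length(st$pooled, 4)
  # 3 particles: 2.1 -> 2
  st2 <- disposition_classes(selection_state(1:3), make_classes(3), 2.0, plan, 1)
  expect_length(st2$pooled, 2)
})

test_that("particles are conserved across randomized disposition scenarios", {
  set.seed(77)
  for (rep in 1:200) {
    k <- sample(1:6, 1)
    sizes <- sample(1:60, k, replace = TRUE)
    scores <- runif(k, 1, 6)
    n <- sum(sizes)
    plan <- iteration_plan(box_px = sample(c(100, 250, 400), 1), seed = rep)
    st <- disposition_classes(selection_state(seq_len(n)), make_classes(sizes),
                              scores, plan, iteration = sample(1:5, 1))
    expect_identical(
      length(st$pooled) + length(st$in_flight) + length(st$rejected), n)
    expect_identical(anyDuplicated(c(st$pooled, st$in_flight, st$rejected)), 0L)
  }
})

test_that("a particle claimed by two classes is a consistency error", {
  plan <- iteration_plan(box_px = 350, seed = 1)
  classes <- list(list(members = 1:10), list(members = 10:20))
  expect_error(disposition_classes(selection_state(1:20), classes,
                                   c(2, 3), plan, 1), "more than one class")
})

test_that("an always-bad backend rejects everything in round one", {
  plan <- iteration_plan(box_px = 350, seed = 2)   # N = 2
  backend <- function(ids, iteration, seed) list(list(members = ids))
  expect_warning(
    st <- run_workflow(1:500, backend, scripted_scorer(list(5.0)), plan),
    "empty")
  expect_length(st$rejected, 500)
  expect_length(st$pooled, 0)
  expect_true(all(lengths(st$batches) == 0))
})

test_that("an always-good backend pools everything via the geometric 70% cascade", {
  plan <- iteration_plan(box_px = 350, seed = 8)   # N = 2
  backend <- function(ids, iteration, seed) list(list(members = ids))
  st <- run_workflow(1:1000, backend, scripted_scorer(list(1.0)), plan)
  aud <- st$audit
  expect_identical(aud$n_pooled[aud$iteration == 1 & aud$disposition == "split_pooled"], 700L)
  expect_identical(aud$n_pooled[aud$iteration == 2 & aud$disposition == "split_pooled"], 210L)
  # remaining 90 flushed, then all 1000 classified once more as the final pool
  expect_length(st$pooled, 1000)
  expect_length(st$rejected, 0)
  expect_length(st$batches[[1]], 1000)
})

test_that("identical seeds give identical audit logs, byte for byte", {
  plan <- iteration_plan(box_px = 150, seed = 31)  # N = 5
  backend <- mock_backend(4)
  scorer <- scripted_scorer(list(c(2.0, 3.0, 4.8, 2.4), c(2.2, 4.6, 3.3, 1.9),
                                 c(2.5, 4.5, 3.5, 2.0)))
  s1 <- run_workflow(1:400, backend, scorer, plan)
  s2 <- run_workflow(1:400, backend, scorer, plan)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  utils::write.csv(s1$audit, f1, row.names = FALSE)
  utils::write.csv(s2$audit, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(s1$batches, s2$batches)
  # a different seed reshuffles the random set-aside draws
  plan2 <- iteration_plan(box_px = 150, seed = 32)
  s3 <- run_workflow(1:400, backend, scorer, plan2)
  expect_false(identical(sort(s1$pooled), sort(s3$pooled)) &&
               identical(s1$audit, s3$audit))
})

test_that("final batches are nested and use <= threshold semantics", {
  b <- final_batches(c(2.0, 3.0, 4.0), make_classes(c(10, 10, 10)) |>
                       lapply(`[[`, "members"))
  expect_identical(lengths(b), c(le_2.5 = 10L, le_3.5 = 20L, le_4.5 = 30L))
  expect_true(all(b[[1]] %in% b[[2]]) && all(b[[2]] %in% b[[3]]))

  b2 <- final_batches(rep(5, 3), make_classes(c(5, 5, 5)) |> lapply(`[[`, "members"))
  expect_true(all(lengths(b2) == 0))

  b3 <- final_batches(3.5, list(1:7))
  expect_identical(lengths(b3), c(le_2.5 = 0L, le_3.5 = 7L, le_4.5 = 7L))

  expect_error(final_batches(1, list(1:2), thresholds = c(3, 2, 4)), "increasing")
})

test_that("lowering the accept cutoff never grows the pool at fixed seed", {
  backend <- mock_backend(5)
  scorer <- function(classes, iteration)
    vapply(classes, function(cl) 1 + (cl$class_id * 17 + iteration * 7) %% 40 / 10,
           numeric(1))
  sizes <- sapply(c(4.5, 4.0, 3.5, 3.0), function(cut) {
    plan <- iteration_plan(box_px = 250, accept_cutoff = cut, good_cutoff = 2.5,
                           seed = 5)
    length(run_workflow(1:600, backend, scorer, plan)$pooled)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("resuming from a snapshot reproduces the uninterrupted run", {
  plan <- iteration_plan(box_px = 250, seed = 12)  # N = 3
  backend <- mock_backend(3)
  scorer <- scripted_scorer(list(c(2.0, 3.4, 4.7), c(2.5, 3.0, 4.5),
                                 c(1.5, 2.6, 4.9), c(2.0, 3.0, 4.0)))
  full <- run_workflow(1:300, backend, scorer, plan)

  partial <- run_workflow(1:300, backend, scorer, plan, stop_after = 1)
  expect_false(partial$finished)
  snap <- withr::local_tempfile(fileext = ".json")
  write_workflow_snapshot(partial, snap)
  resumed <- run_workflow(NULL, backend, scorer, plan,
                          state = read_workflow_snapshot(snap))
  expect_identical(sort(resumed$pooled), sort(full$pooled))
  expect_identical(sort(resumed$rejected), sort(full$rejected))
  expect_identical(resumed$batches, full$batches)
  expect_identical(resumed$audit, full$audit)
})

test_that("the workflow only relies on the backend contract, not the grouping rule", {
  plan <- iteration_plan(box_px = 350, seed = 9)
  scorer <- scripted_scorer(list(c(2.0, 4.8), c(3.0, 2.0), c(2.2, 3.1)))
  # two structurally different partitions: id-hash classes vs contiguous halves
  b1 <- mock_backend(2)
  b2 <- function(ids, iteration, seed) {
    half <- ceiling(length(ids) / 2)
    list(list(members = ids[seq_len(half)]),
         list(members = ids[setdiff(seq_along(ids), seq_len(half))]))
  }
  for (bk in list(b1, b2)) {
    st <- run_workflow(1:200, bk, scorer, plan)
    expect_identical(length(st$pooled) + length(st$rejected), 200L)
    expect_true(all(st$batches[[1]] %in% st$batches[[2]]) &&
                all(st$batches[[2]] %in% st$batches[[3]]))
  }
  # a backend dropping particles violates the contract loudly
  bad <- function(ids, iteration, seed) list(list(members = ids[-1]))
  expect_error(run_workflow(1:50, bad, scorer, plan), "partition")
})
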