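test_that("fire_times follows the timer semantics", {
  im <- timeline_step("A", "imaging", 0, 300, 60)
  expect_equal(fire_times(im), c(0, 60, 120, 180, 240, 300))  # inclusive end
  un <- timeline_step("A", "uncaging", 600)
  expect_equal(fire_times(un), 600)
  expect_equal(fire_times(timeline_step("A", "imaging", 10, 0, 60)), 10)
  expect_error(timeline_step("A", "imaging", 0, 10), "period_s")
})

test_that("queue activation ticks and pauses reproduce the hand simulation", {
  pl <- session_plan(list(timeline_step("A", "uncaging", 0),
                          timeline_step("B", "uncaging", 0)))
  log <- run_queue(pl, function(a) 1)
  expect_equal(log$start_t, c(0.1, 1.2))
  expect_equal(log$end_t, c(1.1, 2.2))
  expect_equal(log$position_id, c("A", "B"))
  # empty plan handled by dropping every position
  expect_equal(nrow(run_queue(pl, drop = c("A", "B"))), 0)
})

test_that("staggered uncaging events see an idle queue", {
  steps <- list()
  for (i in 1:5) {
    id <- paste0("P", i)
    steps[[length(steps) + 1]] <- timeline_step(id, "imaging", 0, 240, 60)
    # uncaging staggered clear of imaging bursts and of each other
    steps[[length(steps) + 1]] <- timeline_step(id, "uncaging", 270 + (i - 1) * 31)
  }
  pl <- session_plan(steps)
  log <- run_queue(pl, function(a) if (a$kind == "uncaging") 30 else 0.5)
  unc <- log[log$action == "uncaging", ]
  expect_equal(nrow(unc), 5)
  # each uncaging starts within one tick of its firing (idle queue by design)
  expect_true(all(unc$start_t - unc$enqueue_t <= 0.1 + 1e-9))
})

test_that("rotation admits positions as capacity frees up", {
  steps <- lapply(1:5, function(i)
    timeline_step(paste0("P", i), "imaging", 0, 600, 60))
  pl <- session_plan(steps)
  adm <- rotate_positions(pl, capacity = 3)
  expect_equal(adm$admit_s[1:3], c(0, 0, 0))
  adm1 <- rotate_positions(pl, capacity = 1)
  expect_equal(adm1$admit_s, c(0, 600.1, 1200.2, 1800.3, 2400.4),
               tolerance = 1e-9)
  # deleted-before-admission positions never appear
  log <- run_queue(pl, capacity = 1, drop = "P4")
  expect_false("P4" %in% log$position_id)
  expect_true(all(paste0("P", c(1, 2, 3, 5)) %in% log$position_id))
})

test_that("mutual exclusion, FIFO, single-fire and determinism hold on random plans", {
  set.seed(77)
  for (rep in 1:40) {
    n_pos <- sample(1:4, 1)
    steps <- list()
    for (i in seq_len(n_pos)) {
      id <- paste0("P", i)
      steps[[length(steps) + 1]] <- timeline_step(
        id, "imaging", start_s = sample(0:30, 1),
        duration_s = sample(c(0, 60, 120), 1), period_s = sample(c(20, 30), 1))
      if (runif(1) < 0.7)
        steps[[length(steps) + 1]] <- timeline_step(id, "uncaging",
                                                    sample(0:120, 1))
    }
    pl <- session_plan(steps, capacity = sample(1:3, 1))
    exec <- function(a) if (a$kind == "uncaging") 3 else runif(1, 0, 0) + 0.7
    log <- run_queue(pl, exec)
    # every firing executed exactly once
    expect_equal(nrow(log), sum(vapply(steps, function(s)
      length(fire_times(s)), numeric(1))))
    # uncaging fires once per uncaging step
    expect_equal(sum(log$action == "uncaging"),
                 sum(vapply(steps, function(s) s$kind == "uncaging", logical(1))))
    # mutual exclusion: intervals do not overlap
    o <- order(log$start_t)
    expect_true(all(diff(log$start_t[o]) >= 0))
    expect_true(all(log$end_t[o][-nrow(log)] <= log$start_t[o][-1] + 1e-9))
    # FIFO: execution order respects enqueue order
    expect_false(is.unsorted(log$enqueue_t))
    expect_equal(log$start_t, sort(log$start_t))
    # no starvation: everything enqueued eventually started
    expect_true(all(is.finite(log$start_t)))
    # determinism: bit-identical on repeat
    expect_identical(log, run_queue(pl, exec))
  }
})
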