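md5s_n <- function(n) sprintf("%032d", seq_len(n))

test_that("planning chunks sequences and derives instance dependencies", {
  j <- job_def("lib", list(
    step_def("scan", "run_analyzer_scan", chunkable = TRUE),
    step_def("persist", "persist_matches", depends_on = "scan")))
  inst <- plan_instances(j, md5s_n(10), chunk_size = 4L)
  scans <- Filter(function(i) i$step == "scan", inst)
  expect_length(scans, 3L)
  expect_equal(lengths(lapply(scans, `[[`, "md5_list")), c(4L, 4L, 2L))
  persist <- Filter(function(i) i$step == "persist", inst)[[1]]
  expect_setequal(persist$deps, vapply(scans, `[[`, character(1), "id"))

  # chunk-aligned edges between chunkable steps
  j2 <- job_def("lib", list(
    step_def("a", chunkable = TRUE),
    step_def("b", depends_on = "a", chunkable = TRUE)))
  inst2 <- plan_instances(j2, md5s_n(5), 2L)
  b2 <- Filter(function(i) i$step == "b" & i$chunk_index == 2L, inst2)[[1]]
  expect_equal(b2$deps, "lib/a#2")
})

test_that("cyclic step dependencies abort planning with the cycle named", {
  expect_error(
    plan_instances(job_def("j", list(step_def("A", depends_on = "B"),
                                     step_def("B", depends_on = "A"))),
                   md5s_n(2), 1L),
    "cyclic step dependencies.*A.*B")
})

test_that("no instance dispatches before its dependencies complete", {
  # diamond A -> {B, C} -> D over 3 chunks
  j <- job_def("dia", list(
    step_def("A", chunkable = TRUE),
    step_def("B", depends_on = "A", chunkable = TRUE),
    step_def("C", depends_on = "A", chunkable = TRUE),
    step_def("D", depends_on = c("B", "C"))))
  inst <- plan_instances(j, md5s_n(6), 2L)
  for (mode in c("serial", "multiprocess")) {
    rep <- run_master(inst, worker_policy(), mode = mode, max_workers = 3L)
    expect_true(rep$success)
    tr <- rep$trace
    done_seq <- stats::setNames(
      tr$seq[tr$event == "done"], tr$instance[tr$event == "done"])
    for (i in inst) {
      disp <- min(tr$seq[tr$instance == i$id & tr$event == "dispatch"])
      expect_true(all(done_seq[i$deps] < disp),
                  label = sprintf("%s dispatch after deps (%s)", i$id, mode))
    }
    expect_true(max(done_seq) == done_seq[["dia/D#0"]])
  }
})

test_that("serial execution order is deterministic", {
  j <- job_def("lib", list(step_def("s", chunkable = TRUE),
                           step_def("p", depends_on = "s")))
  inst <- plan_instances(j, md5s_n(7), 3L)
  t1 <- run_master(inst, worker_policy(), "serial")$trace$instance
  t2 <- run_master(inst, worker_policy(), "serial")$trace$instance
  expect_identical(t1, t2)
})

test_that("worker attachment respects the direct-connection limit and tiers", {
  pol <- worker_policy(max_direct_workers = 2L)
  topo <- data.frame(worker = integer(), parent = integer(),
                     tier = integer())
  for (i in 1:5) {
    slot <- spawn_worker(topo, pol)
    topo <- rbind(topo, data.frame(worker = slot$worker,
                                   parent = slot$parent, tier = slot$tier))
  }
  expect_equal(sum(topo$parent == 0L), 2L)   # master holds two children
  expect_equal(sort(unique(topo$tier)), c(1L, 2L))
  expect_true(all(topo$parent[topo$tier == 2L] %in%
                    topo$worker[topo$tier == 1L]))

  # demand 1: a single tier
  t1 <- spawn_worker(topo[0, ], pol)
  expect_equal(t1$tier, 1L)
})

test_that("a failing step retries and a killed worker does not corrupt results", {
  workdir <- tempfile("eng")
  dir.create(workdir)
  fails <- new.env(); fails$left <- 1L
  j <- job_def("lib", list(
    step_def("write", chunkable = TRUE, fn = function(ctx, inst) {
      out <- file.path(ctx$workdir, sprintf("c%d.txt", inst$chunk_index))
      tmp <- paste0(out, ".tmp"); writeLines(inst$md5_list, tmp)
      file.rename(tmp, out)
    }),
    step_def("gather", depends_on = "write", fn = function(ctx, inst) {
      files <- sort(list.files(ctx$workdir, "^c\\d+\\.txt$",
                               full.names = TRUE))
      writeLines(unlist(lapply(files, readLines)),
                 file.path(ctx$workdir, "all.txt"))
    })))
  inst <- plan_instances(j, md5s_n(6), 2L)
  pol <- worker_policy(retry_limit = 3L,
                       fault_hook = function(id, attempt) {
                         id == "lib/write#2" && attempt == 1L
                       })
  rep <- run_master(inst, pol, "serial",
                    context = list(workdir = workdir))
  expect_true(rep$success)
  tr <- rep$trace
  expect_equal(sum(tr$event == "failed"), 1L)
  expect_equal(readLines(file.path(workdir, "all.txt")), md5s_n(6))

  # retry exhaustion aborts with the failing instance named
  pol2 <- worker_policy(retry_limit = 2L,
                        fault_hook = function(id, attempt) id == "lib/write#1")
  rep2 <- run_master(inst, pol2, "serial",
                     context = list(workdir = tempfile("eng2")))
  expect_false(rep2$success)
  expect_equal(rep2$aborted$instance, "lib/write#1")
})

test_that("spawn failures are tolerated and the run still completes", {
  j <- job_def("lib", list(step_def("s", chunkable = TRUE,
                                    fn = function(ctx, inst) TRUE)))
  inst <- plan_instances(j, md5s_n(6), 1L)
  # a worker tree limited to a single slot cannot satisfy demand 6; the
  # extra spawn attempts fail and are logged, one worker does all the work
  pol <- worker_policy(max_direct_workers = 1L, max_tiers = 1L)
  rep <- run_master(inst, pol, "multiprocess", max_workers = 4L)
  expect_true(rep$success)
  expect_gt(length(rep$spawn_failures), 0L)
  expect_equal(nrow(rep$topology), 1L)
  expect_equal(sum(rep$trace$event == "done"), 6L)
})
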