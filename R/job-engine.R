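# Dependency-driven job engine.
#
# An analysis is declared as a job made of steps wired by dependencies
# (merging and branching both allowed). Planning binds chunkable steps to
# chunks of the deduplicated sequence set, producing step instances whose
# dependency edges are chunk-aligned (chunkable -> chunkable), fan-in
# (chunkable -> non-chunkable) or fan-out (non-chunkable -> chunkable).
# A master process dispatches ready instances to workers over a FIFO
# request-queue contract; workers attach to the master until a direct
# connection limit is reached, after which new workers hang off existing
# ones, forming tiers. Steps are idempotent (instance-scoped temp paths,
# atomic rename), so at-least-once delivery and retries are safe.

STEP_KINDS <- c("write_fasta", "run_analyzer_scan", "run_postprocess",
                "persist_matches", "generic")

#' Declare a step of a job
#'
#' @param name Step name, unique within its job.
#' @param kind One of `write_fasta`, `run_analyzer_scan`,
#'   `run_postprocess`, `persist_matches`, `generic`.
#' @param depends_on Character vector of step names this step waits for.
#' @param chunkable Whether the step runs once per sequence chunk.
#' @param fn `function(context, instance)` executing the step. May be
#'   omitted for pure planning tests.
#' @return A `step_def`.
#' @export
step_def <- function(name, kind = "generic", depends_on = character(),
                     chunkable = FALSE, fn = NULL) {
  kind <- match.arg(kind, STEP_KINDS)
  structure(list(name = name, kind = kind, depends_on = depends_on,
                 chunkable = isTRUE(chunkable), fn = fn),
            class = "step_def")
}

#' Declare a job (one analysis)
#'
#' @param name Job name (typically a signature library).
#' @param steps List of [step_def()]s; names must be unique and dependency
#'   references must resolve within the job.
#' @return A `job_def`.
#' @export
job_def <- function(name, steps) {
  nms <- vapply(steps, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate step names in job", call. = FALSE)
  for (s in steps) {
    missing <- setdiff(s$depends_on, nms)
    if (length(missing) > 0L) {
      stop(sprintf("step '%s' depends on unknown step '%s'",
                   s$name, missing[1L]), call. = FALSE)
    }
  }
  structure(list(name = name, steps = stats::setNames(steps, nms)),
            class = "job_def")
}

#' Worker policy
#'
#' @param max_direct_workers Maximum workers attached to one parent before
#'   new workers are delegated to the next tier (default 4).
#' @param max_tiers Depth limit on the worker tree.
#' @param worker_lifetime Idle seconds before a worker expires.
#' @param retry_limit Maximum executions per step instance (default 2, i.e.
#'   one retry).
#' @param backlog_threshold Ready-queue length above the live worker count
#'   that triggers spawning.
#' @param fault_hook Optional `function(instance_id, attempt)` returning
#'   TRUE to kill the executing worker (fault-injection for robustness
#'   tests).
#' @return A `worker_policy`.
#' @export
worker_policy <- function(max_direct_workers = 4L, max_tiers = 10L,
                          worker_lifetime = 30, retry_limit = 2L,
                          backlog_threshold = 0L, fault_hook = NULL) {
  stopifnot(max_direct_workers >= 1L, max_tiers >= 1L,
            worker_lifetime > 0, retry_limit >= 1L)
  structure(list(max_direct_workers = as.integer(max_direct_workers),
                 max_tiers = as.integer(max_tiers),
                 worker_lifetime = worker_lifetime,
                 retry_limit = as.integer(retry_limit),
                 backlog_threshold = as.integer(backlog_threshold),
                 fault_hook = fault_hook),
            class = "worker_policy")
}

# Kahn topological check; returns step names in order or stops naming a cycle.
topo_order_steps <- function(job) {
  nms <- names(job$steps)
  indeg <- vapply(job$steps, function(s) length(s$depends_on), integer(1))
  order_out <- character()
  avail <- sort(nms[indeg == 0L])
  indeg <- stats::setNames(indeg, nms)
  while (length(avail) > 0L) {
    n <- avail[1L]; avail <- avail[-1L]
    order_out <- c(order_out, n)
    for (m in nms) {
      if (n %in% job$steps[[m]]$depends_on) {
        indeg[m] <- indeg[m] - 1L
        if (indeg[m] == 0L) avail <- sort(c(avail, m))
      }
    }
  }
  if (length(order_out) < length(nms)) {
    cyc <- setdiff(nms, order_out)
    stop(sprintf("cyclic step dependencies in job '%s' involving: %s",
                 job$name, paste(sort(cyc), collapse = " -> ")),
         call. = FALSE)
  }
  order_out
}

#' Split checksums into chunks
#'
#' All chunks but the last hold exactly `chunk_size` checksums; together
#' they partition the input in order.
#'
#' @param md5s Ordered character vector of distinct protein checksums.
#' @param chunk_size Positive chunk size.
#' @return List of character vectors.
#' @export
chunk_md5s <- function(md5s, chunk_size) {
  stopifnot(chunk_size >= 1L)
  n <- length(md5s)
  if (n == 0L) return(list())
  split(md5s, ceiling(seq_len(n) / chunk_size))
}

instance_id <- function(job, step, chunk) {
  sprintf("%s/%s#%d", job, step, chunk)
}

#' Plan step instances for a set of jobs over a sequence set
#'
#' Chunkable steps yield one instance per chunk (`ceil(n / chunk_size)`
#' instances), non-chunkable steps one instance. Instance dependency edges
#' derive from step dependencies: chunk-aligned between chunkable steps,
#' fan-in into non-chunkable steps, fan-out from non-chunkable steps.
#' Cyclic step dependencies abort planning with the cycle named.
#'
#' @param jobs List of [job_def()]s.
#' @param md5s Ordered distinct checksums of the deduplicated sequence set.
#' @param chunk_size Positive integer (default 1000).
#' @return List of step instances (`id`, `job`, `step`, `kind`,
#'   `chunk_index`, `md5_list`, `deps`, `state`, `attempts`, `fn`).
#' @export
plan_instances <- function(jobs, md5s, chunk_size = 1000L) {
  stopifnot(chunk_size >= 1L)
  if (inherits(jobs, "job_def")) jobs <- list(jobs)
  chunks <- chunk_md5s(md5s, chunk_size)
  n_chunks <- length(chunks)
  instances <- list()
  for (job in jobs) {
    topo <- topo_order_steps(job)
    for (sn in topo) {
      s <- job$steps[[sn]]
      my_chunks <- if (s$chunkable) seq_len(n_chunks) else 0L
      for (c in my_chunks) {
        deps <- character()
        for (d in s$depends_on) {
          dstep <- job$steps[[d]]
          deps <- c(deps, if (dstep$chunkable && s$chunkable) {
            instance_id(job$name, d, c)
          } else if (dstep$chunkable) {
            vapply(seq_len(n_chunks),
                   function(i) instance_id(job$name, d, i), character(1))
          } else {
            instance_id(job$name, d, 0L)
          })
        }
        instances[[length(instances) + 1L]] <- list(
          id = instance_id(job$name, sn, c),
          job = job$name, step = sn, kind = s$kind,
          chunkable = s$chunkable, chunk_index = c,
          md5_list = if (s$chunkable) chunks[[c]] else character(),
          deps = deps, state = "pending", attempts = 0L, fn = s$fn)
      }
    }
  }
  instances
}

#' Choose an attachment point for a new worker
#'
#' Workers attach directly to the master until `max_direct_workers`
#' children exist; afterwards spawning is delegated to an existing worker
#' (the least-loaded lowest-tier one), creating the next tier.
#'
#' @param topology Data frame with columns `worker`, `parent`, `tier`
#'   (master is worker 0, tier 0).
#' @param policy A [worker_policy()].
#' @return List `worker` (new id), `parent`, `tier`.
#' @export
spawn_worker <- function(topology, policy) {
  new_id <- if (nrow(topology) == 0L) 1L else max(topology$worker) + 1L
  candidates <- rbind(data.frame(worker = 0L, parent = NA_integer_,
                                 tier = 0L),
                      topology)
  n_children <- vapply(candidates$worker, function(w) {
    sum(topology$parent == w)
  }, integer(1))
  open <- candidates[n_children < policy$max_direct_workers &
                       candidates$tier < policy$max_tiers, , drop = FALSE]
  if (nrow(open) == 0L) {
    stop("no attachment point: worker tree is full", call. = FALSE)
  }
  open <- open[order(open$tier, open$worker), , drop = FALSE]
  parent <- open$worker[1L]
  list(worker = new_id, parent = parent,
       tier = open$tier[1L] + 1L)
}

new_report <- function() {
  env <- new.env(parent = emptyenv())
  env$trace <- list()
  env$seq <- 0L
  env$topology <- data.frame(worker = integer(), parent = integer(),
                             tier = integer())
  env$spawn_failures <- character()
  env
}

record <- function(rep, instance, event, attempt, worker = 0L) {
  rep$seq <- rep$seq + 1L
  rep$trace[[rep$seq]] <- data.frame(
    seq = rep$seq, instance = instance, event = event,
    attempt = attempt, worker = worker, time = as.numeric(Sys.time()),
    stringsAsFactors = FALSE)
}

finish_report <- function(rep, success, aborted = NULL) {
  structure(list(success = success,
                 trace = do.call(rbind, rep$trace),
                 topology = rep$topology,
                 spawn_failures = rep$spawn_failures,
                 aborted = aborted),
            class = "execution_report")
}

# Deterministic dispatch order among ready instances.
order_ready <- function(instances, ids) {
  info <- instances[ids]
  ord <- order(vapply(info, `[[`, character(1), "job"),
               vapply(info, `[[`, character(1), "step"),
               vapply(info, `[[`, integer(1), "chunk_index"))
  ids[ord]
}

#' Execute a plan under the master
#'
#' Dispatches step instances in dependency order. Serial mode runs every
#' instance in the master process in a deterministic topological order
#' (ties broken by job name, step name, chunk index), so output is
#' byte-identical across runs. Multiprocess mode forks worker processes
#' (an in-process realization of the request-queue contract) and spawns
#' them on demand up to `max_workers`, attaching past
#' `max_direct_workers` to existing workers as a new tier. Failed
#' instances re-enter the ready queue until the retry limit is exhausted,
#' after which the run aborts with the failing instance and its
#' diagnostics captured in the report.
#'
#' @param instances Output of [plan_instances()].
#' @param policy A [worker_policy()].
#' @param mode `"serial"` or `"multiprocess"`.
#' @param context Shared, read-only state handed to step functions (the
#'   shared-filesystem assumption: large artifacts pass by path).
#' @param max_workers Worker-count cap in multiprocess mode.
#' @return An `execution_report` with the full dispatch/completion trace,
#'   the worker topology, spawn failures and a success flag.
#' @export
run_master <- function(instances, policy = worker_policy(),
                       mode = c("serial", "multiprocess"),
                       context = list(), max_workers = 4L) {
  mode <- match.arg(mode)
  rep <- new_report()
  names(instances) <- vapply(instances, `[[`, character(1), "id")
  state <- stats::setNames(rep("pending", length(instances)),
                           names(instances))
  attempts <- stats::setNames(rep(0L, length(instances)), names(instances))

  exec_one <- function(inst, attempt) {
    # returns TRUE on success, a condition message string on failure
    if (!is.null(policy$fault_hook) &&
        isTRUE(policy$fault_hook(inst$id, attempt))) {
      return("worker killed during execution")
    }
    if (is.null(inst$fn)) return(TRUE)
    res <- tryCatch({ inst$fn(context, inst); TRUE },
                    error = function(e) conditionMessage(e))
    res
  }

  ready_ids <- function() {
    ids <- names(instances)[state == "pending"]
    ids[vapply(ids, function(i) {
      all(state[instances[[i]]$deps] == "done")
    }, logical(1))]
  }

  if (mode == "serial") {
    while (any(state != "done")) {
      ready <- order_ready(instances, ready_ids())
      if (length(ready) == 0L) {
        stop("no runnable instance but plan incomplete (broken dependencies)",
             call. = FALSE)
      }
      id <- ready[1L]
      attempts[id] <- attempts[id] + 1L
      record(rep, id, "dispatch", attempts[id])
      res <- exec_one(instances[[id]], attempts[id])
      if (isTRUE(res)) {
        state[id] <- "done"
        record(rep, id, "done", attempts[id])
      } else {
        record(rep, id, "failed", attempts[id])
        if (attempts[id] >= policy$retry_limit) {
          return(finish_report(rep, FALSE,
                               aborted = list(instance = id,
                                              diagnostics = res)))
        }
        # re-enters the ready queue
      }
    }
    return(finish_report(rep, TRUE))
  }

  # multiprocess: forked workers over the in-process queue backend
  workers <- data.frame(worker = integer(), parent = integer(),
                        tier = integer(), busy = logical(),
                        instance = character(), idle_since = numeric(),
                        stringsAsFactors = FALSE)
  handles <- list()  # worker id (character) -> mcparallel job
  launcher <- function(expr_fun) parallel::mcparallel(expr_fun())

  repeat {
    if (all(state == "done")) break
    ready <- order_ready(instances, ready_ids())
    running <- sum(workers$busy)
    if (length(ready) == 0L && running == 0L) {
      stop("no runnable instance but plan incomplete (broken dependencies)",
           call. = FALSE)
    }
    # demand-driven spawning
    backlog <- length(ready)
    while (backlog > sum(!workers$busy) + policy$backlog_threshold &&
           nrow(workers) < max_workers) {
      slot <- tryCatch(spawn_worker(workers[, c("worker", "parent", "tier")],
                                    policy),
                       error = function(e) conditionMessage(e))
      if (is.character(slot)) {
        rep$spawn_failures <- c(rep$spawn_failures, slot)
        break
      }
      workers <- rbind(workers, data.frame(
        worker = slot$worker, parent = slot$parent, tier = slot$tier,
        busy = FALSE, instance = "", idle_since = as.numeric(Sys.time()),
        stringsAsFactors = FALSE))
      rep$topology <- rbind(rep$topology,
                            data.frame(worker = slot$worker,
                                       parent = slot$parent,
                                       tier = slot$tier))
    }
    # dispatch ready instances to idle workers
    for (id in ready) {
      idle <- which(!workers$busy)
      if (length(idle) == 0L) break
      w <- idle[1L]
      inst <- instances[[id]]
      attempts[id] <- attempts[id] + 1L
      att <- attempts[id]
      state[id] <- "dispatched"
      record(rep, id, "dispatch", att, workers$worker[w])
      fh <- policy$fault_hook
      h <- tryCatch(
        launcher(function() {
          if (!is.null(fh) && isTRUE(fh(inst$id, att))) {
            # simulate a killed worker: the child dies without replying
            tools::pskill(Sys.getpid())
            Sys.sleep(5)
          }
          if (!is.null(inst$fn)) inst$fn(context, inst)
          TRUE
        }),
        error = function(e) NULL)
      if (is.null(h)) {
        # could not fork: treat as an immediate failure of this attempt
        state[id] <- "pending"
        record(rep, id, "failed", att, workers$worker[w])
        if (att >= policy$retry_limit) {
          return(finish_report(rep, FALSE,
                               aborted = list(instance = id,
                                              diagnostics = "fork failure")))
        }
        next
      }
      workers$busy[w] <- TRUE
      workers$instance[w] <- id
      handles[[as.character(workers$worker[w])]] <- h
    }
    # collect completions
    busy_idx <- which(workers$busy)
    if (length(busy_idx) > 0L) {
      hs <- handles[as.character(workers$worker[busy_idx])]
      res <- suppressWarnings(
        parallel::mccollect(jobs = hs, wait = FALSE, timeout = 0.05))
      if (!is.null(res)) {
        for (nm in names(res)) {
          # mccollect names results by pid; map back via handle pids
          widx <- busy_idx[vapply(hs, function(h) {
            as.character(h$pid) == nm
          }, logical(1))]
          if (length(widx) != 1L) next
          r <- res[[nm]]
          id <- workers$instance[widx]
          att <- attempts[id]
          ok <- !is.null(r) && !inherits(r, "try-error")
          if (ok) {
            state[id] <- "done"
            record(rep, id, "done", att, workers$worker[widx])
          } else {
            state[id] <- "pending"
            record(rep, id, "failed", att, workers$worker[widx])
            if (att >= policy$retry_limit) {
              parallel::mccollect(wait = TRUE)  # reap remaining children
              return(finish_report(rep, FALSE,
                                   aborted = list(
                                     instance = id,
                                     diagnostics = if (is.null(r))
                                       "worker died without completing"
                                     else as.character(r))))
            }
          }
          workers$busy[widx] <- FALSE
          workers$instance[widx] <- ""
          workers$idle_since[widx] <- as.numeric(Sys.time())
          handles[[as.character(workers$worker[widx])]] <- NULL
        }
      }
      # dead children that mccollect(wait=FALSE) never reports: poll pids
      for (widx in which(workers$busy)) {
        h <- handles[[as.character(workers$worker[widx])]]
        if (is.null(h)) next
        alive <- tryCatch(
          { tools::pskill(h$pid, 0L) },
          error = function(e) FALSE)
        if (!isTRUE(alive)) {
          got <- suppressWarnings(
            parallel::mccollect(jobs = list(h), wait = TRUE, timeout = 1))
          r <- if (is.null(got)) NULL else got[[1L]]
          id <- workers$instance[widx]
          att <- attempts[id]
          ok <- !is.null(r) && !inherits(r, "try-error")
          if (ok) {
            state[id] <- "done"
            record(rep, id, "done", att, workers$worker[widx])
          } else {
            state[id] <- "pending"
            record(rep, id, "failed", att, workers$worker[widx])
            if (att >= policy$retry_limit) {
              return(finish_report(rep, FALSE,
                                   aborted = list(
                                     instance = id,
                                     diagnostics = "worker died without completing")))
            }
          }
          workers$busy[widx] <- FALSE
          workers$instance[widx] <- ""
          workers$idle_since[widx] <- as.numeric(Sys.time())
          handles[[as.character(workers$worker[widx])]] <- NULL
        }
      }
    }
    # expire idle workers past their lifetime (frees resources)
    now <- as.numeric(Sys.time())
    expired <- !workers$busy &
      (now - workers$idle_since) > policy$worker_lifetime
    if (any(expired)) workers <- workers[!expired, , drop = FALSE]
  }
  finish_report(rep, TRUE)
}
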