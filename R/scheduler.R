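# Dynamic dataflow scheduling.
#
# A single event loop emulates the FBP model of independently running
# processes: every process owns one packet queue per connected in-port;
# whenever each queue holds at least one packet, one packet is popped from
# each and combined positionally into a concrete task (zip semantics — when
# any upstream closes after n packets the process emits min-over-ports
# tasks and closes). Formed tasks are launched asynchronously, capped at
# max_tasks simultaneously running external commands; finished tasks
# deliver their output packets downstream, which lets new tasks form
# continually during the run ("dynamic scheduling"). Parameter values
# travel the same way but only through memory, never to disk.

port_key <- function(port) {
  paste0(if (port$kind %in% c("file-in", "file-out")) "f:" else "p:", port$name)
}

schedule_run <- function(wf, targets = NULL, hook = NULL) {
  wf$validate()
  work_dir <- wf$work_dir
  if (!dir.exists(work_dir)) dir.create(work_dir, recursive = TRUE)

  active <- if (is.null(targets)) names(wf$processes) else wf$upstream_closure(targets)

  states <- new.env(parent = emptyenv())
  for (pn in active) {
    proc <- wf$processes[[pn]]
    st <- new.env(parent = emptyenv())
    st$queues <- list()
    st$closed <- list()
    for (ip in c(proc$in_ports, proc$param_in_ports)) {
      key <- port_key(ip)
      st$queues[[key]] <- list()
      st$closed[[key]] <- FALSE
    }
    st$fired <- FALSE          # for source processes that fire exactly once
    st$emitted <- FALSE        # for param/file sources and collectors
    st$done_forming <- FALSE
    st$closed_out <- FALSE
    st$unfinished <- 0L        # tasks formed but not yet done/cached
    assign(pn, st, envir = states)
  }

  pending <- list()
  running <- list()
  events <- list()
  aborting <- FALSE
  failure <- NULL
  t0 <- Sys.time()
  progress <- TRUE

  deliver <- function(out_port, packet) {
    for (rem in out_port$remotes) {
      pn <- rem$process$name
      if (!pn %in% active) next
      st <- get(pn, envir = states)
      key <- port_key(rem)
      st$queues[[key]] <- c(st$queues[[key]], list(packet))
    }
  }

  close_downstream <- function(proc) {
    for (op in c(proc$out_ports, proc$param_out_ports)) {
      for (rem in op$remotes) {
        pn <- rem$process$name
        if (!pn %in% active) next
        st <- get(pn, envir = states)
        st$closed[[port_key(rem)]] <- TRUE
      }
    }
  }

  log_event <- function(event, task) {
    events[[length(events) + 1L]] <<- list(
      event = event, process = task$proc_name, task_id = task$id,
      command = task$command %||% "",
      start_ns = task$start_ns %||% NA_real_, end_ns = task$end_ns %||% NA_real_)
  }

  deliver_outputs <- function(task, include_streamed = FALSE) {
    proc <- task$proc
    for (nm in names(proc$out_ports)) {
      streamed <- nm %in% task$streamed
      if (streamed && !include_streamed) next
      if (!streamed && include_streamed) next
      deliver(proc$out_ports[[nm]],
              file_ip(task$outputs[[nm]], audit = task$audit, stream = streamed))
    }
  }

  form_for_proc <- function(proc, st) {
    formed <- FALSE
    if (proc$type == "param_source") {
      if (!st$emitted) {
        n <- length(proc$values[[1]])
        for (i in seq_len(n)) {
          for (nm in names(proc$param_out_ports)) {
            deliver(proc$param_out_ports[[nm]], list(value = proc$values[[nm]][i]))
          }
        }
        st$emitted <- TRUE
        st$done_forming <- TRUE
        formed <- TRUE
      }
    } else if (proc$type == "file_source") {
      if (!st$emitted) {
        for (path in proc$values[["out"]]) {
          audit <- load_audit(file.path(work_dir, path), quiet = TRUE)
          deliver(proc$out_ports[["out"]], file_ip(path, audit = audit))
        }
        st$emitted <- TRUE
        st$done_forming <- TRUE
        formed <- TRUE
      }
    } else if (proc$type == "collect") {
      if (!st$emitted && all(unlist(st$closed))) {
        packets <- list()
        for (nm in names(proc$in_ports)) {
          packets[[nm]] <- st$queues[[paste0("f:", nm)]]
        }
        res <- proc$fn(packets)
        if (!is.list(res) || is.null(names(res)) ||
            !setequal(names(res), names(proc$param_out_ports))) {
          stop(flow_error(sprintf(
            "collector '%s' must return a named list covering its parameter out-ports (%s)",
            proc$name, paste(names(proc$param_out_ports), collapse = ", ")),
            "flow_exec_error"))
        }
        lens <- lengths(res)
        if (length(unique(lens)) != 1L) {
          stop(flow_error(sprintf(
            "collector '%s' returned parameter streams of unequal length", proc$name),
            "flow_exec_error"))
        }
        for (i in seq_len(lens[1])) {
          for (nm in names(res)) {
            deliver(proc$param_out_ports[[nm]], list(value = as.character(res[[nm]][i])))
          }
        }
        st$emitted <- TRUE
        st$done_forming <- TRUE
        formed <- TRUE
      }
    } else {  # shell
      keys_file <- vapply(proc$in_ports, port_key, "")
      keys_param <- vapply(proc$param_in_ports, port_key, "")
      keys <- c(keys_file, keys_param)
      if (!length(keys)) {
        if (!st$fired) {
          task <- form_task(proc)
          st$fired <- TRUE
          st$done_forming <- TRUE
          st$unfinished <- st$unfinished + 1L
          pending[[length(pending) + 1L]] <<- task
          formed <- TRUE
        }
      } else {
        repeat {
          if (!all(vapply(keys, function(k) length(st$queues[[k]]) > 0L, TRUE))) break
          inputs <- list()
          for (nm in names(proc$in_ports)) {
            k <- paste0("f:", nm)
            inputs[[nm]] <- st$queues[[k]][[1]]
            st$queues[[k]] <- st$queues[[k]][-1]
          }
          params <- list()
          for (nm in names(proc$param_in_ports)) {
            k <- paste0("p:", nm)
            params[[nm]] <- st$queues[[k]][[1]]$value
            st$queues[[k]] <- st$queues[[k]][-1]
          }
          task <- form_task(proc, inputs, params)
          st$unfinished <- st$unfinished + 1L
          pending[[length(pending) + 1L]] <<- task
          formed <- TRUE
        }
        starved <- any(vapply(keys, function(k) {
          isTRUE(st$closed[[k]]) && length(st$queues[[k]]) == 0L
        }, TRUE))
        if (starved) st$done_forming <- TRUE
      }
    }
    formed
  }

  repeat {
    checkpoint(hook, "tick", NA_character_)
    progress <- FALSE

    # 1. form new tasks from available packets
    if (!aborting) {
      for (pn in active) {
        st <- get(pn, envir = states)
        if (st$done_forming) next
        if (form_for_proc(wf$processes[[pn]], st)) progress <- TRUE
      }
    }

    # 2. launch pending tasks up to the concurrency cap
    while (!aborting && length(pending) > 0L && length(running) < wf$max_tasks) {
      task <- pending[[1]]
      pending <- pending[-1]
      checkpoint(hook, "pre_launch", task$id)
      st <- get(task$proc_name, envir = states)
      if (should_skip(task, work_dir)) {
        mark_cached(task, work_dir)
        task$start_ns <- task$end_ns <- now_ns()
        log_event("cached", task)
        deliver_outputs(task)
        st$unfinished <- st$unfinished - 1L
      } else {
        launch_task(task, work_dir)
        running[[length(running) + 1L]] <- task
        # streamed outputs are live as soon as the producer starts
        deliver_outputs(task, include_streamed = TRUE)
      }
      progress <- TRUE
    }

    # 3. poll running commands
    if (length(running)) {
      still <- list()
      for (task in running) {
        if (task$px$is_alive()) {
          still[[length(still) + 1L]] <- task
          next
        }
        task$end_ns <- now_ns()
        exit <- task$px$get_exit_status()
        st <- get(task$proc_name, envir = states)
        if (identical(exit, 0L)) {
          finalize_task(task, work_dir, hook)
          log_event("done", task)
          deliver_outputs(task)
        } else {
          task$status <- "failed"
          log_event("failed", task)
          if (is.null(failure)) {
            failure <- list(process = task$proc_name, command = task$command,
                            exit = exit, stderr = task_stderr(task, work_dir),
                            sandbox = task$sandbox)
          }
          aborting <- TRUE
        }
        st$unfinished <- st$unfinished - 1L
        progress <- TRUE
      }
      running <- still
    }

    # 4. close out-ports of exhausted processes
    for (pn in active) {
      st <- get(pn, envir = states)
      if (!st$closed_out && st$done_forming && st$unfinished == 0L) {
        st$closed_out <- TRUE
        close_downstream(wf$processes[[pn]])
        progress <- TRUE
      }
    }

    all_closed <- all(vapply(active, function(pn) get(pn, envir = states)$closed_out, TRUE))

    if (aborting && length(running) == 0L) {
      wf$run_log <- c(wf$run_log, events)
      stop(flow_task_failure(failure))
    }
    if (all_closed && length(running) == 0L && length(pending) == 0L) break

    if (!progress) {
      if (length(running) == 0L) {
        stop(flow_error("scheduler stalled: no runnable task and no running command",
                        "flow_internal_error"))
      }
      Sys.sleep(0.002)
    }
  }

  wf$run_log <- c(wf$run_log, events)
  ev <- events_tibble(events)
  structure(list(
    workflow = wf$name,
    events = ev,
    n_executed = sum(ev$event == "done"),
    n_cached = sum(ev$event == "cached"),
    processes = active,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "flow_run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

events_tibble <- function(events) {
  tibble::tibble(
    event = vapply(events, `[[`, "", "event"),
    process = vapply(events, `[[`, "", "process"),
    task_id = vapply(events, `[[`, "", "task_id"),
    command = vapply(events, `[[`, "", "command"),
    start_ns = vapply(events, `[[`, 0, "start_ns"),
    end_ns = vapply(events, `[[`, 0, "end_ns"))
}

flow_task_failure <- function(failure) {
  msg <- sprintf(
    "task of process '%s' failed with exit code %d\n  command: %s\n  sandbox retained at: %s%s",
    failure$process, failure$exit, failure$command, failure$sandbox,
    if (nzchar(failure$stderr)) paste0("\n  stderr: ", failure$stderr) else "")
  structure(class = c("flow_task_error", "flow_error", "error", "condition"),
            list(message = msg, call = NULL, process = failure$process,
                 command = failure$command, exit = failure$exit,
                 stderr = failure$stderr))
}

#' @export
print.flow_run_report <- function(x, ...) {
  cat(sprintf("Workflow '%s': %d task(s) executed, %d cached, %.2f s\n",
              x$workflow, x$n_executed, x$n_cached, x$elapsed_s))
  invisible(x)
}

#' Maximum number of simultaneously running commands in a run report
#'
#' Computed from the recorded start/finish timestamps of executed tasks;
#' cached tasks do not count.
#'
#' @param report A run report from [run()].
#' @return Integer maximum overlap.
#' @export
max_concurrency <- function(report) {
  ev <- report$events[report$events$event == "done", ]
  if (nrow(ev) == 0L) return(0L)
  pts <- rbind(data.frame(t = ev$start_ns, d = 1L),
               data.frame(t = ev$end_ns, d = -1L))
  pts <- pts[order(pts$t, pts$d), ]   # finish before start at equal stamps
  max(cummax(cumsum(pts$d)))
}
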