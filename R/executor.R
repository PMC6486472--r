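# Task-level execution: cache check, sandbox creation, asynchronous shell
# execution (processx), atomic finalization, streaming via named pipes.
#
# Atomicity contract: a task runs inside a sandbox directory created
# directly under the workflow directory; nothing is visible in the final
# area until the command has exited 0. Finalization then renames, for each
# declared output, first its audit sidecar and then the data file, so at no
# instant can a finished-looking output exist without its complete audit.
# Undeclared files the command created in the sandbox are moved afterwards.

ENGINE_FILE_PREFIX <- "._flowpipe_"

#' Information packet: a file path plus its provenance attachment
#'
#' @param path Final file path, relative to the workflow directory.
#' @param audit An audit record ([new_audit()]) or `NULL`.
#' @param stream Whether the path is a named pipe being streamed.
#' @return A `flow_file_ip` list with fields `path`, `audit`, `stream`.
#' @export
file_ip <- function(path, audit = NULL, stream = FALSE) {
  structure(list(path = path, audit = audit, stream = stream),
            class = "flow_file_ip")
}

#' Sandbox-side path of an information packet
#'
#' @param ip A [file_ip()].
#' @param sandbox Sandbox directory path.
#' @return The path of the same file inside the sandbox.
#' @export
ip_sandbox_path <- function(ip, sandbox) file.path(sandbox, ip$path)

now_ns <- function() as.numeric(Sys.time()) * 1e9

new_task_id <- function() {
  paste(sprintf("%08x", as.integer(floor(stats::runif(4) * 2^31))), collapse = "")
}

# Form one concrete task for `proc` from one packet per connected in-port.
# `inputs`: named list of flow_file_ip; `params`: named list of values.
form_task <- function(proc, inputs = list(), params = list()) {
  input_paths <- vapply(inputs, function(ip) ip$path, "")
  params <- lapply(params, as.character)
  outputs <- list()
  for (nm in names(proc$out_ports)) {
    fmt <- proc$formatters[[nm]]
    path <- if (!is.null(fmt)) {
      fmt(as.list(input_paths), params)
    } else {
      default_path(proc$name, nm, proc$command_pattern, params, input_paths)
    }
    if (nm %in% proc$streamed) path <- paste0(path, ".fifo")
    outputs[[nm]] <- path
  }
  command <- resolve_command(proc$command_pattern, as.list(input_paths), outputs,
                             params, streamed = proc$streamed,
                             prepend = proc$prepend)
  sig <- task_signature(proc$command_pattern, params, input_paths)
  task <- new.env(parent = emptyenv())
  task$id <- new_task_id()
  task$proc <- proc
  task$proc_name <- proc$name
  task$command <- command
  task$inputs <- inputs
  task$params <- params
  task$outputs <- outputs
  task$streamed <- proc$streamed
  task$sandbox <- paste0("_tmp.", sanitize_name(proc$name), ".", sig_digest(sig))
  task$audit <- new_audit(
    id = task$id, process_name = proc$name, command = command,
    params = params,
    tags = if (length(proc$streamed)) list(stream = "true") else list(),
    upstream = upstream_from_inputs(inputs))
  task$status <- "formed"
  task
}

upstream_from_inputs <- function(inputs) {
  up <- list()
  for (ip in inputs) {
    up[[ip$path]] <- if (!is.null(ip$audit)) ip$audit else external_audit_stub(ip$path)
  }
  up
}

#' Decide whether a task can be skipped as cached
#'
#' A task is a cache hit iff every declared output's final file *and* its
#' `.audit.json` sidecar exist. An output without its audit is treated as
#' unfinished and re-executed. Tasks touching streams (FIFO outputs or
#' inputs) are never skipped: a consumed stream cannot be replayed.
#'
#' @param task A task (internal), as produced during scheduling.
#' @param work_dir Workflow working directory.
#' @return `TRUE` if the task should be skipped.
#' @keywords internal
should_skip <- function(task, work_dir) {
  if (length(task$streamed)) return(FALSE)
  if (any(vapply(task$inputs, function(ip) isTRUE(ip$stream), TRUE))) return(FALSE)
  if (!length(task$outputs)) return(FALSE)
  for (path in unlist(task$outputs)) {
    final <- file.path(work_dir, path)
    if (!file.exists(final) || !file.exists(paste0(final, ".audit.json"))) {
      return(FALSE)
    }
  }
  TRUE
}

# Mark a task as cached: reuse the provenance stored in the existing audit
# sidecars instead of the freshly generated one.
mark_cached <- function(task, work_dir) {
  first <- unlist(task$outputs)[1]
  task$audit <- load_audit(file.path(work_dir, first))
  task$status <- "cached"
  task
}

# Launch a task asynchronously. Creates the sandbox (wiping any stale one
# left by an aborted run), pre-creates output subdirectories, materializes
# FIFOs for streamed outputs at their final paths, and starts the command
# through bash with `set -euo pipefail` from inside the sandbox.
launch_task <- function(task, work_dir) {
  sandbox <- file.path(work_dir, task$sandbox)
  if (dir.exists(sandbox)) unlink(sandbox, recursive = TRUE)
  dir.create(sandbox, recursive = TRUE)
  for (nm in names(task$outputs)) {
    rel <- task$outputs[[nm]]
    if (nm %in% task$streamed) {
      fifo <- file.path(work_dir, rel)
      if (file.exists(fifo)) unlink(fifo)
      status <- system2("mkfifo", shQuote(fifo))
      if (status != 0L) {
        stop(flow_error(sprintf("could not create named pipe at '%s'", fifo),
                        "flow_exec_error"))
      }
    } else if (dirname(rel) != ".") {
      dir.create(file.path(sandbox, dirname(rel)), recursive = TRUE, showWarnings = FALSE)
    }
  }
  task$start_ns <- now_ns()
  task$px <- processx::process$new(
    "bash", c("-c", paste0("set -euo pipefail\n", task$command)),
    wd = sandbox,
    stdout = file.path(sandbox, paste0(ENGINE_FILE_PREFIX, "stdout")),
    stderr = file.path(sandbox, paste0(ENGINE_FILE_PREFIX, "stderr")))
  task$status <- "running"
  task
}

task_stderr <- function(task, work_dir) {
  p <- file.path(work_dir, task$sandbox, paste0(ENGINE_FILE_PREFIX, "stderr"))
  if (file.exists(p)) paste(readLines(p, warn = FALSE), collapse = "\n") else ""
}

# Atomic move with cross-device fallback.
move_file <- function(from, to) {
  if (!dir.exists(dirname(to))) dir.create(dirname(to), recursive = TRUE)
  if (!suppressWarnings(file.rename(from, to))) {
    tmp <- paste0(to, ".", ENGINE_FILE_PREFIX, "mv")
    if (!file.copy(from, tmp, overwrite = TRUE)) {
      stop(flow_error(sprintf("could not move '%s' to '%s'", from, to),
                      "flow_exec_error"))
    }
    file.rename(tmp, to)
    unlink(from)
  }
  invisible(TRUE)
}

# Finalize a successfully exited task. For every declared output (in sorted
# port order) the audit sidecar is renamed into the final area before the
# data file; undeclared sandbox files are moved afterwards; the sandbox is
# removed last. `hook` is the fault-injection checkpoint callback.
finalize_task <- function(task, work_dir, hook = NULL) {
  sandbox <- file.path(work_dir, task$sandbox)
  checkpoint(hook, "pre_finalize", task$id)
  task$audit$StartTime <- task$start_ns
  task$audit$ExecTimeNS <- round(task$end_ns - task$start_ns)
  declared <- character(0)
  for (nm in sort(names(task$outputs))) {
    rel <- task$outputs[[nm]]
    streamed <- nm %in% task$streamed
    if (!streamed) {
      src <- file.path(sandbox, rel)
      if (!file.exists(src)) {
        stop(flow_error(sprintf(
          "process '%s': declared output '%s' (port '%s') was not created by command: %s",
          task$proc_name, rel, nm, task$command), "flow_exec_error"))
      }
      declared <- c(declared, rel)
    }
    audit_tmp <- file.path(sandbox, paste0(ENGINE_FILE_PREFIX, "audit_", sanitize_name(nm)))
    writeLines(audit_to_json(task$audit), audit_tmp)
    move_file(audit_tmp, file.path(work_dir, paste0(rel, ".audit.json")))
    checkpoint(hook, "finalize_audit", task$id)
    if (!streamed) {
      move_file(file.path(sandbox, rel), file.path(work_dir, rel))
      checkpoint(hook, "finalize_file", task$id)
    }
  }
  # undeclared-output capture: everything else the command left behind
  all_files <- list.files(sandbox, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  extras <- setdiff(all_files[!startsWith(basename(all_files), ENGINE_FILE_PREFIX)],
                    declared)
  for (rel in extras) {
    move_file(file.path(sandbox, rel), file.path(work_dir, rel))
  }
  unlink(sandbox, recursive = TRUE)
  checkpoint(hook, "post_finalize", task$id)
  task$status <- "done"
  task
}

checkpoint <- function(hook, point, task_id) {
  if (!is.null(hook)) hook(point, task_id)
  invisible(NULL)
}
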