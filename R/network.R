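# Process network: workflows, processes, ports, connections.
#
# The network layer follows the flow-based programming model: processes own
# named ports; the dependency graph is defined purely by connecting an
# in-port to an out-port (InPort$from(OutPort)), never by shared variables.
# Execution is handled by the scheduler (scheduler.R).

#' @importFrom R6 R6Class
NULL

PORT_KINDS <- c("file-in", "file-out", "param-in", "param-out")

#' Port: a named attachment point on a process
#'
#' Ports are created automatically from the placeholders of a process's
#' command pattern (or declared explicitly for parameter sources and
#' collector processes). Connections are made with `in_port$from(out_port)`
#' or [connect()]. Only complementary kinds connect: `file-out` feeds
#' `file-in`, `param-out` feeds `param-in`. An out-port may feed several
#' in-ports (each packet is broadcast); a connected in-port has exactly one
#' upstream out-port.
#'
#' @export
Port <- R6::R6Class("Port",
  public = list(
    #' @field name Port name (placeholder name).
    name = NULL,
    #' @field kind One of `"file-in"`, `"file-out"`, `"param-in"`, `"param-out"`.
    kind = NULL,
    #' @field process The owning [Process].
    process = NULL,
    #' @field remotes List of connected peer ports.
    remotes = NULL,

    #' @description Create a port (used internally by [Process]).
    #' @param name,kind,process See fields.
    initialize = function(name, kind, process) {
      stopifnot(kind %in% PORT_KINDS)
      self$name <- name
      self$kind <- kind
      self$process <- process
      self$remotes <- list()
    },

    #' @description Connect this in-port to an upstream out-port.
    #' @param out_port A `file-out` or `param-out` [Port].
    from = function(out_port) {
      connect(self, out_port)
      invisible(self)
    },

    #' @description Human-readable identification.
    print = function() {
      cat(sprintf("<Port %s:%s (%s), %d connection(s)>\n",
                  self$process$name, self$name, self$kind, length(self$remotes)))
      invisible(self)
    }
  )
)

#' Connect an in-port to an upstream out-port
#'
#' Registers a dependency edge: packets emitted on `out_port` are delivered
#' to `in_port` during the run. File ports connect only to file ports and
#' parameter ports only to parameter ports; a file or parameter in-port may
#' have a single upstream producer, while an out-port may broadcast to any
#' number of consumers.
#'
#' @param in_port A `file-in` or `param-in` [Port].
#' @param out_port The complementary out-port.
#' @return Invisibly, `in_port`.
#' @export
connect <- function(in_port, out_port) {
  stopifnot(inherits(in_port, "Port"), inherits(out_port, "Port"))
  expected <- c("file-in" = "file-out", "param-in" = "param-out")
  if (!in_port$kind %in% names(expected)) {
    stop(flow_error(sprintf("cannot connect: '%s' on process '%s' is not an in-port",
                            in_port$name, in_port$process$name),
         "flow_definition_error"))
  }
  if (out_port$kind != expected[[in_port$kind]]) {
    stop(flow_error(sprintf(
      "port kind mismatch: %s-port '%s' (process '%s') cannot receive from %s-port '%s' (process '%s')",
      in_port$kind, in_port$name, in_port$process$name,
      out_port$kind, out_port$name, out_port$process$name),
      "flow_definition_error"))
  }
  if (length(in_port$remotes) > 0L) {
    stop(flow_error(sprintf(
      "in-port '%s' of process '%s' is already connected; an in-port has exactly one upstream producer",
      in_port$name, in_port$process$name), "flow_definition_error"))
  }
  in_port$remotes <- c(in_port$remotes, list(out_port))
  out_port$remotes <- c(out_port$remotes, list(in_port))
  invisible(in_port)
}

#' Process: a workflow component defined by a shell-command pattern
#'
#' Created with [new_proc()]. Ports are derived from the command pattern's
#' placeholders: every distinct `{i:NAME}` becomes a file in-port, every
#' `{o:NAME}` a file out-port, and every `{p:NAME}` a parameter in-port.
#' Output paths are registered with `$set_out()`; `$stream_out()` turns an
#' out-port into a named-pipe stream.
#'
#' @export
Process <- R6::R6Class("Process",
  public = list(
    #' @field workflow Owning [Workflow].
    workflow = NULL,
    #' @field name Process name, unique within the workflow.
    name = NULL,
    #' @field type `"shell"`, `"param_source"` or `"collect"`.
    type = "shell",
    #' @field command_pattern The command template (shell processes).
    command_pattern = NULL,
    #' @field prepend Text prefixed to every executed command (e.g. a
    #'   resource-manager allocation call such as `salloc -n 1`).
    prepend = "",
    #' @field in_ports,out_ports,param_in_ports,param_out_ports Named lists of [Port]s.
    in_ports = NULL,
    #' @field out_ports See `in_ports`.
    out_ports = NULL,
    #' @field param_in_ports See `in_ports`.
    param_in_ports = NULL,
    #' @field param_out_ports See `in_ports`.
    param_out_ports = NULL,
    #' @field formatters Named list of compiled path formatters per out-port.
    formatters = NULL,
    #' @field streamed Character vector of out-port names that stream via FIFO.
    streamed = character(),
    #' @field values Parameter streams (parameter-source processes only).
    values = NULL,
    #' @field fn Collector function (collector processes only).
    fn = NULL,

    #' @description Create a process; use [new_proc()] instead.
    #' @param workflow,name,command_pattern,type,values,fn,in_port_names,param_out_names
    #'   Internal constructor arguments.
    initialize = function(workflow, name, command_pattern = NULL, type = "shell",
                          values = NULL, fn = NULL,
                          in_port_names = character(), param_out_names = character()) {
      self$workflow <- workflow
      self$name <- name
      self$type <- type
      self$in_ports <- list()
      self$out_ports <- list()
      self$param_in_ports <- list()
      self$param_out_ports <- list()
      self$formatters <- list()
      if (type == "shell") {
        ph <- parse_pattern(command_pattern)
        self$command_pattern <- command_pattern
        for (k in seq_len(nrow(ph))) {
          kind <- ph$kind[k]; nm <- ph$name[k]
          if (kind == "input" && is.null(self$in_ports[[nm]])) {
            self$in_ports[[nm]] <- Port$new(nm, "file-in", self)
          } else if (kind == "output" && is.null(self$out_ports[[nm]])) {
            self$out_ports[[nm]] <- Port$new(nm, "file-out", self)
          } else if (kind == "param" && is.null(self$param_in_ports[[nm]])) {
            self$param_in_ports[[nm]] <- Port$new(nm, "param-in", self)
          }
        }
      } else if (type == "param_source") {
        stopifnot(is.list(values), length(values) >= 1L, !is.null(names(values)))
        lens <- lengths(values)
        if (length(unique(lens)) != 1L) {
          stop(flow_error("parameter streams of a parameter source must have equal length",
                          "flow_definition_error"))
        }
        self$values <- lapply(values, as.character)
        for (nm in names(values)) {
          self$param_out_ports[[nm]] <- Port$new(nm, "param-out", self)
        }
      } else if (type == "file_source") {
        self$values <- lapply(values, as.character)
        self$out_ports[["out"]] <- Port$new("out", "file-out", self)
      } else if (type == "collect") {
        stopifnot(is.function(fn))
        self$fn <- fn
        for (nm in in_port_names) self$in_ports[[nm]] <- Port$new(nm, "file-in", self)
        for (nm in param_out_names) self$param_out_ports[[nm]] <- Port$new(nm, "param-out", self)
      } else {
        stop(flow_error("unknown process type", "flow_definition_error"))
      }
    },

    #' @description Access a file in-port by name.
    #' @param name Port name.
    in_port = function(name) {
      p <- self$in_ports[[name]]
      if (is.null(p)) stop(flow_error(sprintf("process '%s' has no in-port '%s'", self$name, name),
                                      "flow_definition_error"))
      p
    },

    #' @description Access a file out-port by name.
    #' @param name Port name.
    out_port = function(name) {
      p <- self$out_ports[[name]]
      if (is.null(p)) stop(flow_error(sprintf("process '%s' has no out-port '%s'", self$name, name),
                                      "flow_definition_error"))
      p
    },

    #' @description Access a parameter in-port by name.
    #' @param name Port name.
    param_in_port = function(name) {
      p <- self$param_in_ports[[name]]
      if (is.null(p)) stop(flow_error(sprintf("process '%s' has no parameter in-port '%s'",
                                              self$name, name), "flow_definition_error"))
      p
    },

    #' @description Access a parameter out-port by name.
    #' @param name Port name.
    param_out_port = function(name) {
      p <- self$param_out_ports[[name]]
      if (is.null(p)) stop(flow_error(sprintf("process '%s' has no parameter out-port '%s'",
                                              self$name, name), "flow_definition_error"))
      p
    },

    #' @description Register the output path pattern for an out-port. The
    #'   pattern may contain literal text, `{i:port}` / `{p:param}`
    #'   references and the trim modifier `{i:port|%.suffix}`; alternatively
    #'   a function `function(inputs, params) -> path` may be supplied.
    #' @param port Out-port name.
    #' @param pattern Path pattern string or formatter function.
    set_out = function(port, pattern) {
      if (is.null(self$out_ports[[port]])) {
        stop(flow_error(sprintf("process '%s' has no out-port '%s'", self$name, port),
                        "flow_definition_error"))
      }
      self$formatters[[port]] <- compile_formatter(
        pattern, self$name,
        in_ports = names(self$in_ports), params = names(self$param_in_ports))
      invisible(self)
    },

    #' @description Mark an out-port as streamed: its output is materialized
    #'   as a named pipe (FIFO) and producer and consumer run concurrently.
    #'   A streamed port must have exactly one consumer.
    #' @param port Out-port name.
    stream_out = function(port) {
      if (is.null(self$out_ports[[port]])) {
        stop(flow_error(sprintf("process '%s' has no out-port '%s'", self$name, port),
                        "flow_definition_error"))
      }
      self$streamed <- union(self$streamed, port)
      invisible(self)
    },

    #' @description Print a short description.
    print = function() {
      cat(sprintf("<Process '%s' (%s): %d file-in, %d file-out, %d param-in, %d param-out>\n",
                  self$name, self$type, length(self$in_ports), length(self$out_ports),
                  length(self$param_in_ports), length(self$param_out_ports)))
      invisible(self)
    }
  )
)

#' Workflow: a named network of processes
#'
#' Create with [new_workflow()], add processes with [new_proc()] (and
#' [new_param_source()] / [new_collect_proc()] for dynamic parametrization),
#' connect ports, then call [run()] or [run_to()].
#'
#' @export
Workflow <- R6::R6Class("Workflow",
  public = list(
    #' @field name Workflow name.
    name = NULL,
    #' @field max_tasks Maximum number of external commands running at once.
    max_tasks = NULL,
    #' @field work_dir Directory under which all task sandboxes and outputs live.
    work_dir = NULL,
    #' @field processes Named list of [Process] objects.
    processes = NULL,
    #' @field run_log Append-only list of task events from the last run.
    run_log = NULL,

    #' @description Create a workflow; use [new_workflow()] instead.
    #' @param name,max_tasks,work_dir See fields.
    initialize = function(name, max_tasks, work_dir = ".") {
      if (!is.numeric(max_tasks) || length(max_tasks) != 1L || is.na(max_tasks) ||
          max_tasks < 1) {
        stop(flow_error("max_tasks must be a positive integer (>= 1)",
                        "flow_config_error"))
      }
      self$name <- name
      self$max_tasks <- as.integer(max_tasks)
      self$work_dir <- work_dir
      self$processes <- list()
      self$run_log <- list()
    },

    #' @description Add a shell-command process. See [new_proc()].
    #' @param name Unique process name.
    #' @param command_pattern Command template with placeholders.
    add_proc = function(name, command_pattern) {
      private$check_name(name)
      p <- Process$new(self, name, command_pattern)
      self$processes[[name]] <- p
      p
    },

    #' @description Add a parameter source emitting fixed value streams.
    #' @param name Unique process name.
    #' @param values Named list; one parameter out-port per element, all
    #'   streams of equal length, emitted zipped.
    add_param_source = function(name, values) {
      private$check_name(name)
      p <- Process$new(self, name, type = "param_source", values = values)
      self$processes[[name]] <- p
      p
    },

    #' @description Add a file source: emits one packet per existing file
    #'   path on its out-port `"out"`, loading any `.audit.json` sidecar so
    #'   provenance chains across separately executed workflow scripts. A
    #'   file without a sidecar gets a stub audit flagged external.
    #' @param name Unique process name.
    #' @param paths Character vector of file paths (relative to the
    #'   workflow directory).
    add_file_source = function(name, paths) {
      private$check_name(name)
      p <- Process$new(self, name, type = "file_source",
                       values = list(out = paths))
      self$processes[[name]] <- p
      p
    },

    #' @description Add a collector process: waits for its file in-ports to
    #'   close, then calls `fn(packets)` (named list of in-port name ->
    #'   list of file packets, each with `$path` and `$audit`) and emits the
    #'   returned named character vectors on its parameter out-ports.
    #' @param name Unique process name.
    #' @param in_ports Character vector of file in-port names.
    #' @param param_outs Character vector of parameter out-port names.
    #' @param fn Collector function.
    add_collect_proc = function(name, in_ports, param_outs, fn) {
      private$check_name(name)
      p <- Process$new(self, name, type = "collect", fn = fn,
                       in_port_names = in_ports, param_out_names = param_outs)
      self$processes[[name]] <- p
      p
    },

    #' @description Enumerate all connections as a data frame (one row per
    #'   edge) with columns `from_proc`, `from_port`, `to_proc`, `to_port`,
    #'   `kind` (`"file"` or `"param"`).
    connections = function() {
      rows <- list()
      for (p in self$processes) {
        for (op in c(p$out_ports, p$param_out_ports)) {
          for (rem in op$remotes) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              from_proc = p$name, from_port = op$name,
              to_proc = rem$process$name, to_port = rem$name,
              kind = if (op$kind == "file-out") "file" else "param")
          }
        }
      }
      if (!length(rows)) {
        return(tibble::tibble(from_proc = character(), from_port = character(),
                              to_proc = character(), to_port = character(),
                              kind = character()))
      }
      do.call(rbind, rows)
    },

    #' @description Validate the network: every connected in-port has
    #'   exactly one producer, no in-port is left unconnected, the process
    #'   graph is acyclic, and streamed ports have exactly one consumer.
    #'   Called automatically by [run()].
    validate = function() {
      for (p in self$processes) {
        for (ip in c(p$in_ports, p$param_in_ports)) {
          if (length(ip$remotes) == 0L) {
            stop(flow_error(sprintf(
              "in-port '%s' of process '%s' is not connected", ip$name, p$name),
              "flow_validation_error"))
          }
          if (length(ip$remotes) > 1L) {
            stop(flow_error(sprintf(
              "in-port '%s' of process '%s' has multiple producers", ip$name, p$name),
              "flow_validation_error"))
          }
        }
        for (nm in p$streamed) {
          ncons <- length(p$out_ports[[nm]]$remotes)
          if (ncons != 1L) {
            stop(flow_error(sprintf(
              "streamed out-port '%s' of process '%s' must have exactly one consumer (has %d)",
              nm, p$name, ncons), "flow_config_error"))
          }
        }
      }
      edges <- self$connections()
      if (nrow(edges) > 0L) {
        g <- igraph::graph_from_data_frame(
          unique(edges[, c("from_proc", "to_proc")]),
          vertices = names(self$processes))
        if (!igraph::is_dag(g)) {
          stop(flow_error("the process dependency graph contains a cycle",
                          "flow_validation_error"))
        }
      }
      invisible(TRUE)
    },

    #' @description Reverse-reachability closure: all processes upstream of,
    #'   and including, the targets (over file and parameter edges).
    #' @param targets Character vector of process names.
    upstream_closure = function(targets) {
      unknown <- setdiff(targets, names(self$processes))
      if (length(unknown)) {
        stop(flow_error(sprintf("unknown target process(es): %s",
                                paste(unknown, collapse = ", ")),
             "flow_definition_error"))
      }
      edges <- self$connections()
      g <- igraph::graph_from_data_frame(
        unique(edges[, c("from_proc", "to_proc")]),
        vertices = names(self$processes))
      res <- character(0)
      for (t in targets) {
        res <- union(res, names(igraph::subcomponent(g, t, mode = "in")))
      }
      res
    },

    #' @description Run the workflow to completion. See [run()].
    #' @param targets Optional character vector of target process names; if
    #'   given, only their upstream closure executes.
    #' @param hook Optional fault-injection hook `function(point)` invoked
    #'   at internal checkpoints (used by the atomicity tests).
    run = function(targets = NULL, hook = NULL) {
      schedule_run(self, targets = targets, hook = hook)
    },

    #' @description Print a short description.
    print = function() {
      cat(sprintf("<Workflow '%s': %d process(es), max_tasks=%d, dir=%s>\n",
                  self$name, length(self$processes), self$max_tasks, self$work_dir))
      invisible(self)
    }
  ),
  private = list(
    check_name = function(name) {
      stopifnot(is.character(name), length(name) == 1L, nzchar(name))
      if (!is.null(self$processes[[name]])) {
        stop(flow_error(sprintf("a process named '%s' already exists in workflow '%s'",
                                name, self$name), "flow_definition_error"))
      }
    }
  )
)

# ---- functional API ---------------------------------------------------------

#' Create a new workflow
#'
#' A workflow is initiated with a name and the maximum number of external
#' shell commands the engine may have running at once.
#'
#' @param name Workflow name.
#' @param max_tasks Positive integer cap on concurrently running commands.
#' @param work_dir Working directory for outputs and task sandboxes
#'   (created on demand; default: current directory).
#' @return A [Workflow] object.
#' @examples
#' wf <- new_workflow("wf", max_tasks = 4, work_dir = tempfile())
#' @export
new_workflow <- function(name, max_tasks, work_dir = ".") {
  Workflow$new(name, max_tasks, work_dir)
}

#' Add a shell-command process to a workflow
#'
#' The command pattern is ordinary shell text in which concrete file names
#' are replaced by placeholders: `{i:NAME}` (input file), `{o:NAME}`
#' (output file) and `{p:NAME}` (parameter value). One port is created per
#' distinct placeholder name per kind.
#'
#' @param wf A [Workflow].
#' @param name Unique process name.
#' @param command_pattern Command template.
#' @return The new [Process].
#' @examples
#' wf <- new_workflow("demo", 1, work_dir = tempfile())
#' p <- new_proc(wf, "hello", "echo hello > {o:out}")
#' set_out(p, "out", "hello.txt")
#' @export
new_proc <- function(wf, name, command_pattern) {
  stopifnot(inherits(wf, "Workflow"))
  wf$add_proc(name, command_pattern)
}

#' Add a parameter source emitting fixed value streams
#'
#' Each named element becomes a parameter out-port; the value vectors must
#' have equal length and are emitted zipped (the i-th values together
#' parametrize the i-th downstream task).
#'
#' @param wf A [Workflow].
#' @param name Unique process name.
#' @param ... Named vectors of parameter values.
#' @return The new [Process].
#' @export
new_param_source <- function(wf, name, ...) {
  stopifnot(inherits(wf, "Workflow"))
  wf$add_param_source(name, list(...))
}

#' Add a file source emitting packets for existing files
#'
#' Brings files created outside the current workflow (by hand, by an
#' external tool, or by a previously executed workflow script) into the
#' network. If a file has an `.audit.json` sidecar it is loaded and merged
#' into downstream provenance, so a chain of processing split across
#' several workflow scripts keeps its full audit trail; files without a
#' sidecar get a stub audit entry flagged as external.
#'
#' @param wf A [Workflow].
#' @param name Unique process name.
#' @param paths Character vector of file paths relative to the workflow
#'   directory, emitted in order on the out-port `"out"`.
#' @return The new [Process].
#' @export
new_file_source <- function(wf, name, paths) {
  stopifnot(inherits(wf, "Workflow"))
  wf$add_file_source(name, paths)
}

#' Add a collector process for run-time dynamic parametrization
#'
#' A collector waits until its file in-ports have received their complete
#' streams, then computes parameter values from the collected packets and
#' emits them on parameter out-ports — enabling downstream tasks to be
#' parametrized by values that only exist once part of the workflow has run
#' (e.g. the best hyper-parameter found by a sweep).
#'
#' @param wf A [Workflow].
#' @param name Unique process name.
#' @param in_ports Character vector of file in-port names.
#' @param param_outs Character vector of parameter out-port names.
#' @param fn `function(packets)` where `packets` maps in-port name to the
#'   list of received file packets (`$path`, `$audit`); must return a named
#'   list of equal-length character vectors, one per parameter out-port.
#' @return The new [Process].
#' @export
new_collect_proc <- function(wf, name, in_ports, param_outs, fn) {
  stopifnot(inherits(wf, "Workflow"))
  wf$add_collect_proc(name, in_ports, param_outs, fn)
}

#' Register an output path pattern for a process out-port
#'
#' @param proc A [Process].
#' @param port Out-port name.
#' @param pattern Path pattern (literals, `{i:port}`, `{p:param}`, trim
#'   modifier `{i:port|%.suffix}`) or a formatter function.
#' @return Invisibly, `proc`.
#' @export
set_out <- function(proc, port, pattern) {
  stopifnot(inherits(proc, "Process"))
  proc$set_out(port, pattern)
}

#' Stream an out-port through a named pipe
#'
#' The output is materialized as a FIFO at `<path>.fifo`; the producer and
#' its (single) consumer run concurrently and the data never touches disk.
#' Streamed outputs are not cacheable and are re-executed on every run.
#'
#' @param proc A [Process].
#' @param port Out-port name.
#' @return Invisibly, `proc`.
#' @export
stream_out <- function(proc, port) {
  stopifnot(inherits(proc, "Process"))
  proc$stream_out(port)
}

#' Run a workflow
#'
#' Validates the network and executes it: tasks are formed dynamically as
#' packets arrive on in-ports, launched concurrently up to `max_tasks`,
#' executed in per-task sandboxes, finalized atomically, and skipped when
#' their outputs and audit sidecars already exist.
#'
#' @param wf A [Workflow].
#' @param hook Optional fault-injection hook (internal/testing).
#' @return A run report (class `flow_run_report`) with the event log as a
#'   tibble and executed/cached task counts.
#' @export
run <- function(wf, hook = NULL) {
  stopifnot(inherits(wf, "Workflow"))
  wf$run(hook = hook)
}

#' Run a workflow up to (and including) target processes
#'
#' Executes exactly the reverse-reachability closure of the targets: every
#' process upstream of, and including, a target. Downstream processes are
#' not scheduled at all.
#'
#' @param wf A [Workflow].
#' @param targets Character vector of process names.
#' @param hook Optional fault-injection hook (internal/testing).
#' @return A run report, as for [run()].
#' @export
run_to <- function(wf, targets, hook = NULL) {
  stopifnot(inherits(wf, "Workflow"), is.character(targets), length(targets) >= 1L)
  wf$run(targets = targets, hook = hook)
}
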