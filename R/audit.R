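# Hierarchical per-output provenance records.
#
# Every output file gets a sidecar "<path>.audit.json" describing the task
# that produced it: unique task ID, process name, the exact resolved shell
# command (with "../"-prefixed input paths, reflecting sandbox execution),
# parameters, tags, start time and execution time in nanoseconds, and an
# Upstream map keyed by input file path whose values are the full audit
# records of the producing tasks. Audit records are reference objects
# (environments) so a task shared by several downstream branches appears as
# one node with one ID, which converters use to deduplicate.

AUDIT_FIELDS <- c("ID", "ProcessName", "Command", "Params", "Tags",
                  "StartTime", "ExecTimeNS", "Upstream")

#' Create an audit record
#'
#' Usually created by the engine, one per output file of a finished task.
#'
#' @param id Globally unique task ID (32 hex characters).
#' @param process_name Name of the producing process.
#' @param command The resolved shell command.
#' @param params Named list of parameter values.
#' @param tags Named list of free-form tags.
#' @param start_time Start instant in nanoseconds since the epoch (numeric),
#'   or an RFC 3339 string when reloaded from disk.
#' @param exec_time_ns Execution time in nanoseconds.
#' @param upstream Named list mapping input file path to the upstream
#'   audit record.
#' @return An environment of class `flow_audit` with fields `ID`,
#'   `ProcessName`, `Command`, `Params`, `Tags`, `StartTime`, `ExecTimeNS`
#'   and `Upstream`.
#' @export
new_audit <- function(id, process_name, command, params = list(), tags = list(),
                      start_time = NA_real_, exec_time_ns = NA_real_,
                      upstream = list()) {
  a <- new.env(parent = emptyenv())
  a$ID <- id
  a$ProcessName <- process_name
  a$Command <- command
  a$Params <- params
  a$Tags <- tags
  a$StartTime <- start_time
  a$ExecTimeNS <- exec_time_ns
  a$Upstream <- upstream
  class(a) <- "flow_audit"
  a
}

external_audit_stub <- function(path) {
  new_audit(id = paste0("external-", sig_digest(path)),
            process_name = "<external>",
            command = "",
            tags = list(external = "true"),
            start_time = "",
            exec_time_ns = 0)
}

format_rfc3339_ns <- function(ns) {
  if (is.character(ns)) return(ns)
  if (is.na(ns)) return("")
  secs <- floor(ns / 1e9)
  frac <- max(0, round(ns - secs * 1e9))
  base <- format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S")
  sprintf("%s.%09.0fZ", base, frac)
}

parse_rfc3339_ns <- function(x) {
  if (is.numeric(x)) return(x)
  if (!nzchar(x)) return(NA_real_)
  t <- as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  as.numeric(t) * 1e9
}

audit_start_ns <- function(a) parse_rfc3339_ns(a$StartTime)

named_or_empty <- function(x) {
  if (length(x) == 0L) structure(list(), names = character(0)) else x
}

audit_to_list <- function(a) {
  list(
    ID = a$ID,
    ProcessName = a$ProcessName,
    Command = a$Command,
    Params = named_or_empty(lapply(a$Params, as.character)),
    Tags = named_or_empty(lapply(a$Tags, as.character)),
    StartTime = format_rfc3339_ns(a$StartTime),
    ExecTimeNS = if (is.na(a$ExecTimeNS)) 0 else round(a$ExecTimeNS),
    Upstream = named_or_empty(lapply(a$Upstream, audit_to_list)))
}

audit_to_json <- function(a) {
  as.character(jsonlite::toJSON(audit_to_list(a), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA))
}

#' Write an audit record as a JSON sidecar
#'
#' @param audit A `flow_audit` record.
#' @param path Path of the data file the audit describes; the sidecar is
#'   written to `paste0(path, ".audit.json")`.
#' @return Invisibly, the sidecar path.
#' @export
write_audit <- function(audit, path) {
  sidecar <- paste0(path, ".audit.json")
  writeLines(audit_to_json(audit), sidecar)
  invisible(sidecar)
}

#' Load the audit record attached to a file
#'
#' Reads `<path>.audit.json` and reconstructs the full provenance tree.
#' Upstream entries sharing a task ID are rebuilt as one shared record.
#' A missing or unparsable sidecar yields a stub record tagged
#' `external = "true"` (with a warning unless `quiet`), so files produced
#' outside the engine can still flow through a workflow.
#'
#' @param path Path of the data file (not of the sidecar).
#' @param quiet Suppress the missing/corrupt-sidecar warning.
#' @param label Path recorded in the stub when the sidecar is absent
#'   (defaults to `path`; the engine passes workflow-relative paths).
#' @return A `flow_audit` record.
#' @export
load_audit <- function(path, quiet = FALSE, label = path) {
  sidecar <- paste0(path, ".audit.json")
  if (!file.exists(sidecar)) {
    if (!quiet) warning(sprintf("no audit sidecar for '%s'; treating as external input", path),
                        call. = FALSE)
    return(external_audit_stub(label))
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(sidecar, simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed$ID)) {
    if (!quiet) warning(sprintf("corrupt audit sidecar '%s'; treating as external input", sidecar),
                        call. = FALSE)
    return(external_audit_stub(label))
  }
  seen <- new.env(parent = emptyenv())
  rebuild_audit(parsed, seen)
}

rebuild_audit <- function(x, seen) {
  id <- x$ID
  if (!is.null(id) && exists(id, envir = seen, inherits = FALSE)) {
    return(get(id, envir = seen, inherits = FALSE))
  }
  up <- list()
  for (k in names(x$Upstream %||% list())) {
    up[[k]] <- rebuild_audit(x$Upstream[[k]], seen)
  }
  a <- new_audit(
    id = x$ID %||% "",
    process_name = x$ProcessName %||% "",
    command = x$Command %||% "",
    params = lapply(x$Params %||% list(), as.character),
    tags = lapply(x$Tags %||% list(), as.character),
    start_time = x$StartTime %||% "",
    exec_time_ns = as.numeric(x$ExecTimeNS %||% 0),
    upstream = up)
  if (!is.null(id)) assign(id, a, envir = seen)
  a
}

# Unique task records of an audit tree in upstream-first (topological)
# order; each ID appears once. External stubs are excluded unless asked for.
collect_audit_tasks <- function(audit, include_external = FALSE) {
  out <- list()
  seen <- new.env(parent = emptyenv())
  visit <- function(a) {
    if (exists(a$ID, envir = seen, inherits = FALSE)) return(invisible())
    assign(a$ID, TRUE, envir = seen)
    for (k in sort(names(a$Upstream))) visit(a$Upstream[[k]])
    if (include_external || !identical(a$Tags$external, "true")) {
      out[[length(out) + 1L]] <<- a
    }
    invisible()
  }
  visit(audit)
  out
}

#' Convert an audit trail into an executable Bash replay script
#'
#' Emits the unique commands of the provenance tree in topological
#' (upstream-first) order, one command per task; duplicated subtrees are
#' deduplicated by task ID so a shared ancestor appears once. The `../`
#' sandbox prefixes of the recorded commands are stripped so the script
#' runs in a single flat directory: executing it in a clean directory
#' reproduces the target file for deterministic commands.
#'
#' @param audit A `flow_audit` record (e.g. from [load_audit()]).
#' @return The script as a single character string.
#' @export
audit2bash <- function(audit) {
  tasks <- collect_audit_tasks(audit)
  lines <- c("#!/bin/bash",
             "# Replay script generated from an audit trail",
             "set -euo pipefail", "")
  for (a in tasks) {
    cmd <- gsub("../", "", a$Command, fixed = TRUE)
    lines <- c(lines, sprintf("# Process: %s (task %s)", a$ProcessName, a$ID), cmd, "")
  }
  paste(lines, collapse = "\n")
}

report_task_table <- function(tasks) {
  start <- vapply(tasks, audit_start_ns, 0)
  execn <- vapply(tasks, function(a) as.numeric(a$ExecTimeNS), 0)
  ord <- order(ifelse(is.na(start), Inf, start),
               vapply(tasks, `[[`, "", "ID"))
  tasks <- tasks[ord]
  start <- start[ord]
  execn <- execn[ord]
  t0 <- suppressWarnings(min(start, na.rm = TRUE))
  if (!is.finite(t0)) t0 <- 0
  data.frame(
    id = vapply(tasks, `[[`, "", "ID"),
    process = vapply(tasks, `[[`, "", "ProcessName"),
    command = vapply(tasks, `[[`, "", "Command"),
    start_time = vapply(tasks, function(a) format_rfc3339_ns(a$StartTime), ""),
    offset_ns = ifelse(is.na(start), 0, start - t0),
    exec_ns = ifelse(is.na(execn), 0, execn),
    params = vapply(tasks, function(a) {
      if (!length(a$Params)) "" else
        paste(sprintf("%s=%s", names(a$Params), unlist(a$Params)), collapse = ", ")
    }, ""),
    stringsAsFactors = FALSE)
}

REPORT_PALETTE <- c("#4e79a7", "#f28e2b", "#59a14f", "#e15759", "#76b7b2",
                    "#edc948", "#b07aa1", "#ff9da7", "#9c755f", "#bab0ac")

#' Convert an audit trail into an HTML or TeX report
#'
#' The report carries a header with the engine version and total execution
#' time, a Gantt-style execution timeline with one bar per unique task
#' (ordered by start time; ties broken by task ID), and one detail table
#' per task, color-keyed consistently with the timeline.
#'
#' @param audit A `flow_audit` record.
#' @param format `"html"` or `"tex"`.
#' @return Document text as a single character string. The TeX variant is
#'   a standalone document compilable with an external `pdflatex`.
#' @export
audit2report <- function(audit, format = c("html", "tex")) {
  format <- match.arg(format)
  tab <- report_task_table(collect_audit_tasks(audit))
  total_ns <- if (nrow(tab)) max(tab$offset_ns + tab$exec_ns) else 0
  version <- as.character(utils::packageVersion("flowpipe"))
  colors <- REPORT_PALETTE[(seq_len(nrow(tab)) - 1L) %% length(REPORT_PALETTE) + 1L]
  if (format == "html") {
    render_html_report(tab, total_ns, version, colors)
  } else {
    render_tex_report(tab, total_ns, version, colors)
  }
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_html_report <- function(tab, total_ns, version, colors) {
  span <- max(total_ns, 1)
  bars <- character(0)
  for (i in seq_len(nrow(tab))) {
    left <- 100 * tab$offset_ns[i] / span
    width <- max(100 * tab$exec_ns[i] / span, 0.5)
    bars <- c(bars, sprintf(
      '<div class="row"><span class="lbl">%s</span><div class="lane"><div class="bar" style="margin-left:%.2f%%;width:%.2f%%;background:%s"></div></div></div>',
      html_escape(tab$process[i]), left, width, colors[i]))
  }
  tables <- character(0)
  for (i in seq_len(nrow(tab))) {
    tables <- c(tables, sprintf(paste0(
      '<table class="task" style="border-left:8px solid %s">',
      "<tr><th>Process</th><td>%s</td></tr>",
      "<tr><th>Task ID</th><td>%s</td></tr>",
      "<tr><th>Command</th><td><code>%s</code></td></tr>",
      "<tr><th>Parameters</th><td>%s</td></tr>",
      "<tr><th>Start time</th><td>%s</td></tr>",
      "<tr><th>Execution time</th><td>%s ns</td></tr></table>"),
      colors[i], html_escape(tab$process[i]), tab$id[i],
      html_escape(tab$command[i]), html_escape(tab$params[i]),
      tab$start_time[i], format(tab$exec_ns[i], scientific = FALSE)))
  }
  paste(c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>Audit report</title>", "<style>",
    "body{font-family:sans-serif;margin:2em}",
    ".row{display:flex;align-items:center;margin:2px 0}",
    ".lbl{width:14em;font-size:90%}",
    ".lane{flex:1;background:#eee;height:14px}",
    ".bar{height:14px}",
    "table.task{border-collapse:collapse;margin:1em 0;padding-left:4px}",
    "table.task th{text-align:left;padding:2px 8px;vertical-align:top}",
    "table.task td{padding:2px 8px}",
    "</style></head><body>",
    "<h1>Audit report</h1>",
    sprintf("<p>flowpipe version %s &mdash; total execution time: %s ns</p>",
            version, format(total_ns, scientific = FALSE)),
    "<h2>Execution timeline</h2>", bars,
    "<h2>Tasks</h2>", tables,
    "</body></html>"), collapse = "\n")
}

tex_escape <- function(x) {
  x <- gsub("\\", "\\textbackslash{}", x, fixed = TRUE)
  for (ch in c("&", "%", "$", "#", "_", "{", "}")) {
    x <- gsub(ch, paste0("\\", ch), x, fixed = TRUE)
  }
  x <- gsub("~", "\\textasciitilde{}", x, fixed = TRUE)
  gsub("^", "\\textasciicircum{}", x, fixed = TRUE)
}

render_tex_report <- function(tab, total_ns, version, colors) {
  span <- max(total_ns, 1)
  defs <- sprintf("\\definecolor{task%d}{HTML}{%s}",
                  seq_len(nrow(tab)), toupper(sub("#", "", colors)))
  bars <- character(0)
  for (i in seq_len(nrow(tab))) {
    off <- 100 * tab$offset_ns[i] / span
    len <- max(100 * tab$exec_ns[i] / span, 0.5)
    bars <- c(bars, sprintf(
      "%s & \\hspace{%.2fmm}{\\color{task%d}\\rule{%.2fmm}{2.5mm}} \\\\",
      tex_escape(tab$process[i]), off, i, len))
  }
  tables <- character(0)
  for (i in seq_len(nrow(tab))) {
    tables <- c(tables, sprintf(paste0(
      "\\noindent{\\color{task%d}\\rule{2mm}{1em}}\\hspace{1mm}%%\n",
      "\\begin{tabular}[t]{ll}\n",
      "Process & %s \\\\\n",
      "Task ID & \\texttt{%s} \\\\\n",
      "Command & \\texttt{%s} \\\\\n",
      "Parameters & %s \\\\\n",
      "Start time & %s \\\\\n",
      "Execution time & %s ns \\\\\n",
      "\\end{tabular}\\par\\vspace{1em}"),
      i, tex_escape(tab$process[i]), tab$id[i], tex_escape(tab$command[i]),
      tex_escape(tab$params[i]), tex_escape(tab$start_time[i]),
      format(tab$exec_ns[i], scientific = FALSE)))
  }
  paste(c(
    "\\documentclass{article}",
    "\\usepackage[margin=2.5cm]{geometry}",
    "\\usepackage{xcolor}",
    "\\begin{document}",
    "\\section*{Audit report}",
    sprintf("flowpipe version %s --- total execution time: %s ns\\par\\vspace{1em}",
            version, format(total_ns, scientific = FALSE)),
    "\\subsection*{Execution timeline}",
    defs,
    "\\begin{tabular}{lp{10cm}}",
    bars,
    "\\end{tabular}",
    "\\subsection*{Tasks}",
    tables,
    "\\end{document}"), collapse = "\n")
}
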