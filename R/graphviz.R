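# Graphviz DOT export of the process network.

#' Export a workflow's process network as Graphviz DOT text
#'
#' One box node per process, one directed edge per port connection. The
#' edge tail is labelled with the out-port name and the head with the
#' in-port name. Dependencies via files are drawn solid; dependencies via
#' parameters (transmitted only through memory) are drawn dashed.
#' Processes and edges are emitted in name-sorted order so the output is
#' deterministic and diffable; rendering to an image is delegated to the
#' external `dot` tool.
#'
#' @param wf A [Workflow].
#' @return DOT source as a single character string.
#' @examples
#' wf <- new_workflow("demo", 1, work_dir = tempfile())
#' a <- new_proc(wf, "A", "echo hi > {o:x}")
#' b <- new_proc(wf, "B", "cat {i:y} > {o:z}")
#' b$in_port("y")$from(a$out_port("x"))
#' cat(to_dot(wf))
#' @export
to_dot <- function(wf) {
  stopifnot(inherits(wf, "Workflow"))
  dq <- function(x) paste0('"', gsub('"', '\\"', x, fixed = TRUE), '"')
  lines <- c(sprintf("digraph %s {", dq(wf$name)),
             "  rankdir=TB;",
             "  node [shape=box];")
  for (nm in sort(names(wf$processes))) {
    lines <- c(lines, sprintf("  %s;", dq(nm)))
  }
  edges <- wf$connections()
  if (nrow(edges)) {
    ord <- order(edges$from_proc, edges$to_proc, edges$from_port, edges$to_port)
    edges <- edges[ord, ]
    for (i in seq_len(nrow(edges))) {
      style <- if (edges$kind[i] == "param") "dashed" else "solid"
      lines <- c(lines, sprintf(
        "  %s -> %s [taillabel=%s, headlabel=%s, style=%s];",
        dq(edges$from_proc[i]), dq(edges$to_proc[i]),
        dq(edges$from_port[i]), dq(edges$to_port[i]), style))
    }
  }
  paste(c(lines, "}", ""), collapse = "\n")
}
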