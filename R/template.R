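# Command-pattern and path-pattern parsing/resolution.
#
# Placeholder grammar: {i:NAME}, {o:NAME}, {p:NAME} with NAME = [A-Za-z0-9_]+.
# Brace groups whose content does not look like a placeholder ("<letter>:")
# are left as literal text, so shell/awk constructs like `awk 'BEGIN{...}'`
# survive inside command patterns. A brace group that *does* start with a
# single letter and a colon must be a valid placeholder, otherwise parsing
# fails with the column of the offending token.

PLACEHOLDER_KINDS <- c(i = "input", o = "output", p = "param")

#' Parse a command or path pattern into its placeholders
#'
#' Scans `text` for placeholder tokens of the form `{i:NAME}`, `{o:NAME}` or
#' `{p:NAME}` and returns them in order of appearance. Duplicate occurrences
#' are preserved. Literal text outside (and non-placeholder braces inside)
#' the pattern is ignored by this function and kept verbatim at resolution
#' time.
#'
#' @param text A single character string, the pattern.
#' @param allow_trim Allow the `{i:NAME|%.suffix}` trim modifier (used in
#'   output-path patterns, not in command patterns).
#' @return A [tibble][tibble::tibble] with one row per placeholder and
#'   columns `kind` (`"input"`, `"output"` or `"param"`), `name`, `trim`
#'   (the suffix to strip, or `NA`), and `start`/`end` (character offsets of
#'   the token in `text`, 1-based, inclusive).
#' @examples
#' parse_pattern("cat {i:in} | rev > {o:rev}")
#' parse_pattern("echo hello")          # no placeholders
#' @export
parse_pattern <- function(text, allow_trim = FALSE) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] == "{") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "}") { close <- j; break }
        if (chars[j] == "{") break   # nested open: outer brace is literal
        j <- j + 1L
      }
      if (is.na(close)) {
        rest_text <- substr(text, i + 1L, nchar(text))
        if (grepl("^[A-Za-z]:", rest_text)) {
          stop(flow_parse_error(sprintf(
            "unbalanced braces: placeholder opened at column %d is never closed in pattern: %s",
            i, text)))
        }
        i <- i + 1L
        next
      }
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (grepl("^[A-Za-z]:", body)) {
        kind_letter <- substr(body, 1L, 1L)
        rest <- substr(body, 3L, nchar(body))
        if (!kind_letter %in% names(PLACEHOLDER_KINDS)) {
          stop(flow_parse_error(sprintf(
            "unknown placeholder kind '%s' at column %d in pattern: %s",
            kind_letter, i, text)))
        }
        trim <- NA_character_
        if (grepl("|", rest, fixed = TRUE)) {
          if (!allow_trim) {
            stop(flow_parse_error(sprintf(
              "modifier not allowed in this pattern at column %d: {%s}", i, body)))
          }
          parts <- strsplit(rest, "|", fixed = TRUE)[[1]]
          if (length(parts) != 2L || !grepl("^%", parts[2]) || nchar(parts[2]) < 2L) {
            stop(flow_parse_error(sprintf(
              "malformed trim modifier at column %d: {%s}", i, body)))
          }
          rest <- parts[1]
          trim <- substr(parts[2], 2L, nchar(parts[2]))
        }
        if (!grepl("^[A-Za-z0-9_]+$", rest)) {
          stop(flow_parse_error(sprintf(
            "empty or invalid placeholder name at column %d: {%s}", i, body)))
        }
        if (!is.na(trim) && kind_letter != "i") {
          stop(flow_parse_error(sprintf(
            "trim modifier only applies to {i:...} at column %d: {%s}", i, body)))
        }
        out[[length(out) + 1L]] <- list(
          kind = unname(PLACEHOLDER_KINDS[kind_letter]), name = rest,
          trim = trim, start = i, end = close)
        i <- close + 1L
        next
      }
      # not placeholder-shaped: literal braces
      i <- i + 1L
      next
    }
    i <- i + 1L
  }
  tibble::tibble(
    kind  = vapply(out, `[[`, "", "kind"),
    name  = vapply(out, `[[`, "", "name"),
    trim  = vapply(out, `[[`, "", "trim"),
    start = vapply(out, `[[`, 0L, "start"),
    end   = vapply(out, `[[`, 0L, "end"))
}

flow_parse_error <- function(msg) {
  structure(class = c("flow_parse_error", "flow_error", "error", "condition"),
            list(message = msg, call = NULL))
}

flow_error <- function(msg, class = "flow_error") {
  structure(class = c(class, "flow_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Strip a suffix from a path if present
#'
#' Implements the `%` trim modifier of output-path patterns: the suffix is
#' removed only when it terminates the string; otherwise the path is
#' returned unchanged with a warning.
#'
#' @param x Character string.
#' @param suffix Suffix to strip (e.g. `".txt"`).
#' @return `x` without `suffix`, or `x` unchanged.
#' @export
trim_suffix <- function(x, suffix) {
  if (nchar(suffix) > 0L && endsWith(x, suffix)) {
    substr(x, 1L, nchar(x) - nchar(suffix))
  } else {
    warning(sprintf("trim modifier '%%%s' did not match end of '%s'; path left unchanged",
                    suffix, x), call. = FALSE)
    x
  }
}

# Compile a path pattern into a formatter closure: function(inputs, params)
# -> path, where inputs/params are named character vectors of final input
# paths and parameter values. A function passed instead of a string is used
# as-is (caller-supplied formatter escape hatch).
compile_formatter <- function(pattern, proc_name = "?",
                              in_ports = character(), params = character()) {
  if (is.function(pattern)) return(pattern)
  ph <- parse_pattern(pattern, allow_trim = TRUE)
  if (any(ph$kind == "output")) {
    stop(flow_error(sprintf("output placeholders are not allowed in path patterns (process '%s')",
                            proc_name), "flow_definition_error"))
  }
  bad_in <- setdiff(ph$name[ph$kind == "input"], in_ports)
  if (length(bad_in)) {
    stop(flow_error(sprintf("path pattern for process '%s' references unknown in-port(s): %s",
                            proc_name, paste(bad_in, collapse = ", ")),
         "flow_definition_error"))
  }
  bad_p <- setdiff(ph$name[ph$kind == "param"], params)
  if (length(bad_p)) {
    stop(flow_error(sprintf("path pattern for process '%s' references unknown parameter(s): %s",
                            proc_name, paste(bad_p, collapse = ", ")),
         "flow_definition_error"))
  }
  force(pattern); force(ph)
  function(inputs, params) {
    substitute_placeholders(pattern, ph, function(row) {
      if (row$kind == "input") {
        val <- inputs[[row$name]]
        if (is.null(val)) stop(flow_error(sprintf("missing input '%s' for path pattern", row$name)))
        if (!is.na(row$trim)) val <- trim_suffix(val, row$trim)
        val
      } else {
        val <- params[[row$name]]
        if (is.null(val)) stop(flow_error(sprintf("missing parameter '%s' for path pattern", row$name)))
        val
      }
    })
  }
}

# Replace each placeholder row in `ph` within `pattern` using resolve(row).
substitute_placeholders <- function(pattern, ph, resolve) {
  if (nrow(ph) == 0L) return(pattern)
  pieces <- character(0)
  cursor <- 1L
  for (k in seq_len(nrow(ph))) {
    row <- ph[k, ]
    if (row$start > cursor) {
      pieces <- c(pieces, substr(pattern, cursor, row$start - 1L))
    }
    pieces <- c(pieces, resolve(row))
    cursor <- row$end + 1L
  }
  if (cursor <= nchar(pattern)) pieces <- c(pieces, substr(pattern, cursor, nchar(pattern)))
  paste(pieces, collapse = "")
}

# Canonical signature of a task for default path naming and sandbox naming:
# command pattern, sorted param name=value pairs, sorted inport=path pairs.
task_signature <- function(command_pattern, params, input_paths) {
  p <- if (length(params)) {
    o <- order(names(params))
    paste(sprintf("%s=%s", names(params)[o], unlist(params)[o]), collapse = ",")
  } else ""
  i <- if (length(input_paths)) {
    o <- order(names(input_paths))
    paste(sprintf("%s=%s", names(input_paths)[o], unlist(input_paths)[o]), collapse = ",")
  } else ""
  paste(command_pattern, p, i, sep = "|")
}

sig_digest <- function(signature, n = 12L) {
  substr(digest::digest(signature, algo = "sha256", serialize = FALSE), 1L, n)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Default output path for a task port
#'
#' When no explicit path pattern was registered for an out-port, the engine
#' derives `"<process>.<digest>.<port>"` where the 12-hex-character digest is
#' taken over the canonical task signature (command pattern plus sorted
#' parameters plus sorted input paths). Two tasks with the same signature
#' always map to the same path (cache reuse); tasks differing in any
#' parameter or input get distinct paths.
#'
#' @param process_name,port Process and out-port names.
#' @param command_pattern The process's command pattern.
#' @param params Named character vector/list of parameter values.
#' @param input_paths Named character vector/list of final input paths.
#' @return A relative file path.
#' @export
default_path <- function(process_name, port, command_pattern,
                         params = character(), input_paths = character()) {
  sig <- task_signature(command_pattern, params, input_paths)
  paste0(sanitize_name(process_name), ".", sig_digest(sig), ".", sanitize_name(port))
}

# Resolve a command pattern into concrete shell text for a task.
#   {i:x} -> "../" + final input path (task sandboxes sit directly under the
#            workflow dir, so inputs are one level up)
#   {o:x} -> the output path relative to the sandbox (same relative path as
#            final), or "../<path>" for streamed outputs written in place
#   {p:x} -> parameter value
# `prepend`, when non-empty, is prefixed with a single space separator.
resolve_command <- function(pattern, inputs, outputs, params,
                            streamed = character(), prepend = "") {
  ph <- parse_pattern(pattern)
  cmd <- substitute_placeholders(pattern, ph, function(row) {
    switch(row$kind,
      input = {
        val <- inputs[[row$name]]
        if (is.null(val)) stop(flow_error(sprintf("unresolved input placeholder {i:%s}", row$name)))
        paste0("../", val)
      },
      output = {
        val <- outputs[[row$name]]
        if (is.null(val)) stop(flow_error(sprintf("unresolved output placeholder {o:%s}", row$name)))
        if (row$name %in% streamed) paste0("../", val) else val
      },
      param = {
        val <- params[[row$name]]
        if (is.null(val)) stop(flow_error(sprintf("unresolved param placeholder {p:%s}", row$name)))
        as.character(val)
      })
  })
  if (nzchar(prepend)) paste(prepend, cmd) else cmd
}
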