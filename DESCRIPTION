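Package: flowpipe
Title: Flow-Based Scientific Workflow Engine with Per-File Provenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A library for writing scientific pipelines as networks of
    shell-command processes connected through named ports, in the
    flow-based programming style. Processes are declared with command
    templates containing {i:...}, {o:...} and {p:...} placeholders; the
    engine schedules concrete tasks dynamically during the run, executes
    each task in a per-task sandbox directory with atomic finalization,
    caches finished outputs, and writes a hierarchical JSON audit trail
    next to every output file. Includes optional streaming between tasks
    via named pipes, partial runs up to a target process, Graphviz DOT
    export of the process network, and converters that turn audit trails
    into executable Bash replay scripts or HTML/TeX reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    processx,
    jsonlite,
    digest,
    igraph,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
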