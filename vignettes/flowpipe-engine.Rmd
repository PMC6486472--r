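---
title: "The flowpipe execution model: dataflow scheduling, atomic tasks, and per-file provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flowpipe execution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowpipe)
```

## The problem

Scientific pipelines — bioinformatics alignments, variant calling, machine
learning sweeps — are chains and fan-outs of shell commands whose outputs
feed later commands. Three practical failure modes dominate day-to-day
work with ad-hoc scripts: half-written files being mistaken for finished
ones after a crash; no record of which exact commands produced a given
result file; and schedules fixed before the run starts, which cannot
express "train the final model with whatever parameter value the sweep
selects". flowpipe addresses all three with a small flow-based programming
(FBP) engine: processes own named ports, the network is defined purely by
port connections, and concrete tasks are created dynamically while the
workflow runs.

## The model

A **workflow** is a named set of **processes** plus a concurrency cap
(`max_tasks`) and a working directory. A shell process is declared with a
command *pattern* in which file names are replaced by placeholders:

```
cat {i:in} | rev > {o:rev}
```

Each distinct `{i:NAME}` becomes a file in-port, each `{o:NAME}` a file
out-port, and each `{p:NAME}` a parameter in-port. Placeholder names match
`[A-Za-z0-9_]+`. A brace group that does not look like a placeholder
(i.e. does not start with a single letter and a colon) is kept as literal
text, so `awk 'BEGIN{...}'` is legal inside a pattern; a group that *does*
start that way must be a valid placeholder or parsing fails with the
offending column.

Dependencies are declared only through ports, `in_port$from(out_port)`,
never through shared variables — processes stay self-contained and
re-connectable. File out-ports connect to file in-ports and parameter
out-ports to parameter in-ports; an in-port has exactly one producer,
while an out-port may broadcast to any number of consumers. Cycles are
rejected at validation.

### Task formation (zip semantics)

During a run, each process pops one packet from every connected in-port
and combines them positionally into one **task** — a concrete command with
all placeholders resolved. When any upstream closes after *n* packets the
process emits exactly `min` over its ports of the packet counts, then
closes its own out-ports. We chose zip over a cross product because it is
the FBP one-packet-per-firing model; fan-outs are built explicitly with a
parameter source that emits pre-expanded, aligned value streams (see the
sweep demo, where `expand.grid()` produces the cross product before the
run starts).

### Dynamic parametrization

A **collector process** (`new_collect_proc()`) waits until its in-port
streams close, computes values from everything it received — it can read
both the files and their audit attachments — and emits those values on
parameter out-ports. Downstream tasks are therefore parametrized by
numbers that did not exist when the run began. The bundled sweep demo
selects the cost with the lowest mean cross-validation error and feeds it
to the final training stage over a parameter (dashed) edge.

## Execution

### Sandboxes and atomic writes

Every task runs via `bash -c` with `set -euo pipefail` from inside a
sandbox directory `_tmp.<process>.<digest>` created directly under the
workflow directory. Input placeholders resolve to `../<path>` (one level
up, out of the sandbox); output placeholders resolve to sandbox-relative
paths. On exit 0 the engine renames, for each declared output, first the
audit sidecar and then the data file into the final area, then moves
*every remaining file the command created* (undeclared outputs, like the
five companion files of a FASTA indexer) and removes the sandbox. The
ordering guarantees the invariant the atomicity tests check: at no instant
does a final-area file exist without its complete audit. A failed command
finalizes nothing and its sandbox is kept for inspection; the sandbox name
is deterministic, so a later run wipes and retries it cleanly.

On failure the engine stops launching new tasks, lets already-running
commands finish, and then raises an error carrying the process name,
resolved command, exit code and captured stderr. In-flight commands are
not killed; their sandboxes simply never finalize.

### Caching

A task is skipped when every declared output *and* its `.audit.json`
sidecar already exist — presence-based, no checksums, which is exactly the
reuse criterion the default path naming is built for. An output missing
its sidecar counts as unfinished and re-executes. Cache hits reuse the
stored audit (and its task ID) rather than minting a new one.

### File naming

Output paths come from `set_out()` patterns (literals, `{i:port}`,
`{p:param}`, and the trim modifier `{i:port|%.txt}` which strips the
suffix only when present, warning otherwise — so re-deriving
`dna.compl.txt` from `dna.txt` is one expression). Without a pattern the
engine derives `<process>.<digest>.<port>`, where the digest is the first
12 hex characters of a SHA-256 over the canonical task signature (command
pattern, sorted parameters, sorted input paths): equal signatures reuse
the same cached path, any differing parameter or input changes it.
Process names are sanitized (`[^A-Za-z0-9_.-]` becomes `_`) because
resolved commands embed paths unquoted.

### Concurrency

R is single-threaded, so the "independently running processes" of FBP are
emulated by one event loop that forms tasks, launches external commands
asynchronously (via processx) and polls them. The observable semantics
are preserved: tasks form as packets arrive, at most `max_tasks` external
commands are alive at any instant (engine bookkeeping is unbounded), and
a task starts only after all packets it consumes exist. Timestamps are
taken from R's clock (microsecond resolution) and recorded in nanoseconds
for dialect compatibility; trailing digits beyond the clock's resolution
carry no information.

### Streaming

`stream_out(proc, port)` materializes an output as a named pipe at
`<path>.fifo` instead of a file: the producer writes into the FIFO in the
final area while its single consumer reads it, so both run concurrently
and the data never lands on disk. Streamed tasks (producer and consumer
alike) are never cache-skipped — a consumed stream has no persistent
content to reuse — which also makes the "streaming into a cached
consumer" deadlock unreachable. A streamed port must have exactly one
consumer (FIFOs are single-reader here), and a streamed pair needs
`max_tasks >= 2` to overlap.

## Provenance

Every output file gets `"<path>.audit.json"`: task ID (random 128-bit hex,
minted per execution, reused on cache hits), process name, the exact
resolved command (inputs carrying their `../` prefixes, bit-exact for
replay), parameters, tags, RFC 3339 start time, execution time in
nanoseconds, and an `Upstream` map keyed by input path holding the full
audit record of each producer. Audits are reference objects, so a task
feeding two branches of a diamond appears under both keys with one shared
ID — which is what lets converters deduplicate. When a workflow consumes a
file produced by an earlier, separately executed script, the existing
sidecar is loaded and merged, so provenance survives across runs and
scripts; a file with no sidecar becomes a stub entry tagged
`external = "true"` rather than an error.

`audit2bash()` walks the tree upstream-first, emits each unique task once,
and strips the `../` prefixes so the script replays in one flat clean
directory; for deterministic commands the regenerated target is
byte-identical. `audit2report()` renders an HTML or standalone TeX
document (header with engine version and total execution time, a
Gantt-style timeline ordered by start time with ties broken by ID, and one
color-keyed table per task); PDF conversion is left to an external
`pdflatex`. `to_dot()` exports the network as deterministic, diffable DOT
(solid file edges, dashed parameter edges, port names as edge labels).

## What the fixtures emulate — and what they do not

The demos use only standard UNIX text tools. The reverse-base-complement
chain exercises the whole stack end to end in well under a second. The
sweep demo mirrors a real hyper-parameter search — by default 15 cost
values × 10 folds per training-set size, and five sizes (500–8000), i.e.
150 evaluation tasks per size — but its "learner" is a deterministic awk
one-liner with error `(cost − 0.75)² + fold/10⁵`, chosen so the per-size
argmin is unique and the selected value is predictable; it exercises
dynamic scheduling, not statistics. `make_random_dag()` generates seeded
random acyclic `cat` networks (each process fires once) for scheduler
property tests. Passing tests therefore demonstrate the engine's
scheduling, atomicity, caching and provenance guarantees on fast,
deterministic commands; they say nothing about long-running tools,
multi-gigabyte intermediates, cluster schedulers beyond the `prepend`
string, or commands that are themselves nondeterministic (replay fidelity
is only meaningful for deterministic commands).

Problem sizes in the test and acceptance suites — 100 random DAGs of up to
12 processes, 50 injected kill-points on a 5-stage chain, 20 quarter-second
sleepers against a cap of 4, one full-grid sweep per size configuration —
were chosen as the smallest batteries that exercise every guarantee while
keeping a full run in the tens of seconds.

## Numerical and design choices

* **Fault injection.** The atomicity battery kills the engine via a hook
  that aborts at randomized internal checkpoints, including between the
  two renames of an output's finalization; this reaches the same
  filesystem-visible states as killing the OS process at a random instant
  and keeps the battery fast.
* **Zip, not merge.** An in-port accepts a single upstream producer;
  merging several producers onto one port would need an ordering rule the
  FBP model does not supply, so fan-in is expressed with multi-input
  commands or collectors instead.
* **Abort policy.** First failure stops new launches but lets running
  commands finish — finished files stay cleanly separated from unfinished
  ones, and nothing is partially finalized.
* **Degenerate inputs.** An empty workflow validates and runs to an empty
  report; a process with no connected in-ports fires exactly once; a
  collector receiving zero packets still fires (its function sees empty
  lists) once its upstream closes.
* **Tie-breaks.** Report rows with equal start times sort by task ID;
  DOT nodes and edges sort by name; a collector argmin tie breaks to the
  numerically smallest value (the bundled sweep never ties).

## Known limitations

Single-machine execution only (the `prepend` field is the extent of HPC
integration); presence-based cache validity (a corrupted but present
output is trusted); FIFO streaming requires a platform with named pipes
and a consumer that reads to EOF (a consumer that closes early SIGPIPEs
the producer, which is then treated as a failure); in-engine R code
(collector functions) is not captured in audits — only shell commands
are.
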