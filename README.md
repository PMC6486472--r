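# flowpipe

A flow-based workflow engine for scientific shell pipelines, as an R
library. Pipelines are networks of **processes** declared by shell-command
templates with named **ports**; the engine schedules concrete tasks
dynamically while the workflow runs, executes each task atomically in a
per-task sandbox, caches finished outputs, and writes a hierarchical JSON
**audit trail next to every output file** — so any result can be traced,
replayed, or reported on its own.

It is aimed at people who today glue bioinformatics or machine-learning
tools together with shell scripts or Makefiles and want, with little
ceremony: crash-safe (atomic) outputs, make-like caching, concurrency with
a cap, provenance per file rather than per run, and schedules that can
depend on values computed mid-run (e.g. a hyper-parameter picked by a
sweep).

## The model in one paragraph

A process is declared from a command pattern such as
`cat {i:in} | rev > {o:rev}`: `{i:...}` placeholders become file in-ports,
`{o:...}` file out-ports, `{p:...}` parameter in-ports. The dependency
graph is defined only by connecting ports (`in_port$from(out_port)`), in
the flow-based programming style. At run time each process zips one packet
per connected in-port into a task; tasks run concurrently up to
`max_tasks`, each inside a sandbox directory, with inputs addressed as
`../<path>`. On success, outputs (declared or not) are renamed into the
final area — audit sidecar first, data file second, so a finished-looking
file without provenance cannot exist. A task whose outputs and sidecars
already exist is skipped. Outputs can optionally stream to their consumer
through a named pipe instead of touching disk.

## Worked example

The bundled demo computes the reverse base complement of a DNA string with
standard UNIX tools — three processes connected in a chain:

```r
library(flowpipe)

wf <- new_workflow("DNA Base Complement Workflow", max_tasks = 4,
                   work_dir = "demo")

make_dna <- new_proc(wf, "Make DNA", "echo AAAGCCCGTGGGGGACCTGTTC > {o:dna}")
set_out(make_dna, "dna", "dna.txt")

complement <- new_proc(wf, "Base Complement",
                       "cat {i:in} | tr ATCG TAGC > {o:complement}")
set_out(complement, "complement", "{i:in|%.txt}.compl.txt")

reverse <- new_proc(wf, "Reverse", "cat {i:in} | rev > {o:rev}")
set_out(reverse, "rev", "{i:in|%.txt}.rev.txt")

complement$in_port("in")$from(make_dna$out_port("dna"))
reverse$in_port("in")$from(complement$out_port("complement"))

run(wf)
#> Workflow 'DNA Base Complement Workflow': 3 task(s) executed, 0 cached, 0.25 s
```

(The same network is available as `make_revcomp_demo()`.) The run leaves
six files in `demo/` — each output with its audit sidecar:

```
dna.txt                     dna.txt.audit.json
dna.compl.txt               dna.compl.txt.audit.json
dna.compl.rev.txt           dna.compl.rev.txt.audit.json
```

`dna.txt` contains `AAAGCCCGTGGGGGACCTGTTC` and `dna.compl.rev.txt`
contains `GAACAGGTCCCCCACGGGCTTT`, its reverse base complement. Running
`run(wf)` again executes 0 commands — everything is cached. The final
audit nests the complete history (abridged):

```json
{
  "ProcessName": "Reverse",
  "Command": "cat ../dna.compl.txt | rev > dna.compl.rev.txt",
  "ExecTimeNS": 10342144,
  "Upstream": {
    "dna.compl.txt": {
      "ProcessName": "Base Complement",
      "Command": "cat ../dna.txt | tr ATCG TAGC > dna.compl.txt",
      "Upstream": { "dna.txt": { "ProcessName": "Make DNA", "..." : "..." } }
    }
  }
}
```

From that one file you can regenerate the result or report on it:

```r
a <- load_audit("demo/dna.compl.rev.txt")
cat(audit2bash(a))            # 3-command Bash script that reproduces the file
cat(audit2report(a, "tex"))   # standalone TeX report (timeline + task tables)
cat(to_dot(wf))               # Graphviz DOT of the process network
```

Partial runs (`run_to(wf, "Base Complement")`) execute only a target
process and everything upstream of it. Dynamic parametrization is shown by
`make_sweep_demo()`: 15 cost values × 10 folds per training-set size fan
out, a collector picks the best cost per size at run time, and one final
training task per size is parametrized with it over a parameter
connection.

A command-line helper wrapping the converters is installed at
`inst/cli/flowpipe-helper`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","flowpipe-helper",package="flowpipe"))') \
    audit2bash demo/dna.compl.rev.txt.audit.json -o replay.sh
```

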