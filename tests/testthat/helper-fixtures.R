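# Shared fixtures and independent oracles for the engine tests.
# Everything is generated in code at test time; no stored data files.

fresh_dir <- function() {
  d <- tempfile("flowtest_")
  dir.create(d)
  d
}

# Run the reverse-base-complement demo in a fresh directory and return the
# directory and run report.
run_revcomp <- function() {
  d <- fresh_dir()
  wf <- make_revcomp_demo(d)
  rep <- run(wf)
  list(dir = d, wf = wf, report = rep)
}

REVCOMP_DNA <- "AAAGCCCGTGGGGGACCTGTTC"
REVCOMP_FINAL <- "GAACAGGTCCCCCACGGGCTTT"

# Independent oracle for port creation: count distinct (kind, name) pairs
# via a plain regex scan of the pattern.
regex_port_counts <- function(pattern) {
  m <- regmatches(pattern, gregexpr("\\{[iop]:[A-Za-z0-9_]+(\\|%[^}]*)?\\}", pattern))[[1]]
  kind <- substr(m, 2, 2)
  name <- sub("^\\{[iop]:([A-Za-z0-9_]+).*\\}$", "\\1", m)
  pairs <- unique(paste(kind, name))
  table(factor(substr(pairs, 1, 1), levels = c("i", "o", "p")))
}

# Independent reverse-reachability oracle: plain BFS over the reversed
# edge list (no igraph).
reverse_bfs <- function(edges_from, edges_to, targets) {
  seen <- unique(targets)
  frontier <- seen
  while (length(frontier)) {
    preds <- unique(edges_from[edges_to %in% frontier])
    frontier <- setdiff(preds, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

# Independent concurrency oracle: for each task interval, count how many
# intervals cover its start instant (different algorithm from
# max_concurrency's sweep).
overlap_at_starts <- function(start_ns, end_ns) {
  if (!length(start_ns)) return(0L)
  max(vapply(seq_along(start_ns), function(i) {
    sum(start_ns <= start_ns[i] & end_ns > start_ns[i])
  }, 0L))
}

# A linear chain of n cat processes for atomicity/kill tests.
make_chain <- function(n, work_dir, max_tasks = 2) {
  wf <- new_workflow(sprintf("chain%d", n), max_tasks, work_dir)
  p <- new_proc(wf, "c1", "echo chain-payload > {o:out}")
  set_out(p, "out", "k1.txt")
  prev <- p
  for (i in seq_len(n - 1) + 1) {
    q <- new_proc(wf, sprintf("c%d", i), "cat {i:in} {i:in} > {o:out}")
    set_out(q, "out", sprintf("k%d.txt", i))
    q$in_port("in")$from(prev$out_port("out"))
    prev <- q
  }
  wf
}

# Hook that simulates a hard engine death at the k-th internal checkpoint.
kill_hook_at <- function(k) {
  count <- 0L
  function(point, task_id) {
    count <<- count + 1L
    if (count == k) {
      stop(structure(class = c("flow_engine_killed", "error", "condition"),
                     list(message = sprintf("injected kill at checkpoint %d (%s)", k, point),
                          call = NULL)))
    }
  }
}

# Atomicity invariant: every regular file in the final area (top level,
# audits and engine sandboxes excluded) has its complete audit sidecar.
final_files_without_audit <- function(dir) {
  entries <- list.files(dir)
  if (!length(entries)) return(character(0))
  files <- entries[!dir.exists(file.path(dir, entries))]
  data_files <- files[!grepl("\\.audit\\.json$", files)]
  if (!length(data_files)) return(character(0))
  data_files[!file.exists(file.path(dir, paste0(data_files, ".audit.json")))]
}

# Streamed/unstreamed producer-consumer pair.
make_seq_pair <- function(work_dir, streamed) {
  wf <- new_workflow("seqpair", 4, work_dir)
  p <- new_proc(wf, "producer", "seq 1 5 > {o:s}")
  set_out(p, "s", "s.txt")
  if (streamed) stream_out(p, "s")
  q <- new_proc(wf, "consumer", "wc -l < {i:s} | tr -d ' ' > {o:n}")
  set_out(q, "n", "n.txt")
  q$in_port("s")$from(p$out_port("s"))
  wf
}

# Check that every task starts only after all tasks of its producer
# processes have finished (valid for networks where each process fires
# once, as in make_random_dag).
order_violations <- function(wf, report) {
  ev <- report$events[report$events$event == "done", ]
  edges <- wf$connections()
  bad <- 0L
  for (i in seq_len(nrow(edges))) {
    up <- ev[ev$process == edges$from_proc[i], ]
    down <- ev[ev$process == edges$to_proc[i], ]
    if (nrow(up) && nrow(down) && any(down$start_ns < max(up$end_ns))) {
      bad <- bad + 1L
    }
  }
  bad
}
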