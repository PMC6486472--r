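# Sandboxed execution: caching, atomic finalization, undeclared-output
# capture, failure handling, idempotence, streaming.

test_that("caching skips only tasks whose outputs AND audits exist", {
  r <- run_revcomp()

  # immediate rerun: everything cached, nothing executed, mtimes unchanged
  before <- file.mtime(list.files(r$dir, full.names = TRUE))
  rep2 <- run(r$wf)
  expect_equal(rep2$n_executed, 0L)
  expect_equal(rep2$n_cached, 3L)
  expect_identical(file.mtime(list.files(r$dir, full.names = TRUE)), before)

  # output present but audit missing -> treated unfinished, re-executed
  unlink(file.path(r$dir, "dna.compl.txt.audit.json"))
  rep3 <- run(r$wf)
  expect_equal(rep3$n_executed, 1L)
  expect_equal(rep3$events$process[rep3$events$event == "done"], "Base Complement")
  expect_true(file.exists(file.path(r$dir, "dna.compl.txt.audit.json")))

  # audit present but output missing -> re-executed
  unlink(file.path(r$dir, "dna.txt"))
  rep4 <- run(r$wf)
  expect_equal(rep4$events$process[rep4$events$event == "done"], "Make DNA")
})

test_that("every file created in the sandbox is captured, declared or not", {
  d <- fresh_dir()
  wf <- new_workflow("idx", 1, d)
  # bwa-index-like toy: one declared output, five undeclared companions
  p <- new_proc(wf, "index",
                "touch {o:fa} r.fa.bwt r.fa.pac r.fa.ann r.fa.amb r.fa.sa")
  set_out(p, "fa", "r.fa")
  run(wf)
  expect_true(all(file.exists(file.path(
    d, c("r.fa", "r.fa.bwt", "r.fa.pac", "r.fa.ann", "r.fa.amb", "r.fa.sa")))))
  # sandbox removed after finalization
  expect_length(list.files(d, pattern = "^_tmp\\."), 0)
})

test_that("a failing command finalizes nothing and retains its sandbox", {
  d <- fresh_dir()
  wf <- new_workflow("fail", 1, d)
  p <- new_proc(wf, "boom", "echo x > {o:out}; exit 1")
  set_out(p, "out", "out.txt")
  err <- tryCatch(run(wf), error = function(e) e)
  expect_s3_class(err, "flow_task_error")
  expect_equal(err$exit, 1L)
  expect_equal(err$process, "boom")
  expect_match(err$command, "exit 1")
  expect_false(file.exists(file.path(d, "out.txt")))
  expect_false(file.exists(file.path(d, "out.txt.audit.json")))
  expect_length(list.files(d, pattern = "^_tmp\\."), 1)

  # the failure is recoverable: a later run re-executes and succeeds
  wf2 <- new_workflow("fixed", 1, d)
  p2 <- new_proc(wf2, "boom", "echo x > {o:out}")
  set_out(p2, "out", "out.txt")
  run(wf2)
  expect_true(file.exists(file.path(d, "out.txt")))
})

test_that("a mid-chain failure stops downstream scheduling", {
  d <- fresh_dir()
  wf <- new_workflow("chainfail", 2, d)
  a <- new_proc(wf, "a", "echo ok > {o:out}")
  set_out(a, "out", "a.txt")
  b <- new_proc(wf, "b", "cat {i:in} > {o:out} && false")
  set_out(b, "out", "b.txt")
  c3 <- new_proc(wf, "c", "cat {i:in} > {o:out}")
  set_out(c3, "out", "c.txt")
  b$in_port("in")$from(a$out_port("out"))
  c3$in_port("in")$from(b$out_port("out"))
  expect_error(run(wf), "exit code 1")
  expect_true(file.exists(file.path(d, "a.txt")))    # finished upstream kept
  expect_false(file.exists(file.path(d, "b.txt")))
  expect_false(file.exists(file.path(d, "c.txt")))
})

test_that("injected engine death never leaves an output without its audit", {
  ref_dir <- fresh_dir()
  run(make_chain(4, ref_dir))
  ref <- lapply(sprintf("k%d.txt", 1:4),
                function(f) readLines(file.path(ref_dir, f)))

  for (k in c(3L, 9L, 15L, 21L, 27L)) {
    d <- fresh_dir()
    res <- tryCatch(run(make_chain(4, d), hook = kill_hook_at(k)),
                    flow_engine_killed = function(e) "killed")
    expect_length(final_files_without_audit(d), 0)
    # resuming completes the workflow with results identical to a clean run
    run(make_chain(4, d))
    got <- lapply(sprintf("k%d.txt", 1:4),
                  function(f) readLines(file.path(d, f)))
    expect_identical(got, ref)
  }
})

test_that("streaming materializes a FIFO and overlaps producer and consumer", {
  plain_dir <- fresh_dir()
  run(make_seq_pair(plain_dir, streamed = FALSE))
  streamed_dir <- fresh_dir()
  rep <- run(make_seq_pair(streamed_dir, streamed = TRUE))

  # identical result, no regular file ever at the s path
  expect_identical(readLines(file.path(streamed_dir, "n.txt")),
                   readLines(file.path(plain_dir, "n.txt")))
  expect_equal(readLines(file.path(streamed_dir, "n.txt")), "5")
  expect_false(file.exists(file.path(streamed_dir, "s.txt")))
  fifo <- file.path(streamed_dir, "s.txt.fifo")
  expect_identical(unname(system2("test", c("-p", fifo))), 0L)

  # consumer starts before the producer finishes
  ev <- rep$events[rep$events$event == "done", ]
  expect_lt(ev$start_ns[ev$process == "consumer"],
            ev$end_ns[ev$process == "producer"])

  # stream non-cacheability: both sides re-execute on a second run
  rep2 <- run(make_seq_pair(streamed_dir, streamed = TRUE))
  expect_equal(rep2$n_executed, 2L)
  # the streamed audit is tagged
  a <- load_audit(file.path(streamed_dir, "n.txt"))
  expect_identical(a$Upstream[["s.txt.fifo"]]$Tags$stream, "true")
})

test_that("a streamed port with two consumers is a configuration error", {
  d <- fresh_dir()
  wf <- new_workflow("s2", 4, d)
  p <- new_proc(wf, "producer", "seq 1 5 > {o:s}")
  set_out(p, "s", "s.txt")
  stream_out(p, "s")
  for (cn in c("c1", "c2")) {
    q <- new_proc(wf, cn, "cat {i:s} > {o:n}")
    set_out(q, "n", paste0(cn, ".txt"))
    q$in_port("s")$from(p$out_port("s"))
  }
  expect_error(run(wf), "exactly one consumer")
})

test_that("prepend text is prefixed to the executed command and audited", {
  d <- fresh_dir()
  wf <- new_workflow("pre", 1, d)
  p <- new_proc(wf, "hello", "echo ok > {o:out}")
  set_out(p, "out", "out.txt")
  p$prepend <- "env"   # stand-in for e.g. "salloc -n 1"
  run(wf)
  expect_equal(readLines(file.path(d, "out.txt")), "ok")
  a <- load_audit(file.path(d, "out.txt"))
  expect_identical(a$Command, "env echo ok > out.txt")
})

test_that("concurrency never exceeds max_tasks", {
  d <- fresh_dir()
  wf <- new_workflow("sleepers", 4, d)
  src <- new_param_source(wf, "ids", i = as.character(1:12))
  p <- new_proc(wf, "sleeper", "sleep 0.2 && echo {p:i} > {o:out}")
  set_out(p, "out", "sleep_{p:i}.txt")
  p$param_in_port("i")$from(src$param_out_port("i"))
  rep <- run(wf)
  expect_equal(rep$n_executed, 12L)
  expect_lte(max_concurrency(rep), 4L)
  ev <- rep$events[rep$events$event == "done", ]
  expect_lte(overlap_at_starts(ev$start_ns, ev$end_ns), 4L)
  # and the cap is actually used: some overlap must occur
  expect_gte(max_concurrency(rep), 2L)
})
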