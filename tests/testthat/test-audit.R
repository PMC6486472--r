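# Audit trail construction, serialization, merging across runs, and the
# Bash/HTML/TeX converters.

test_that("the final audit nests the full upstream hierarchy", {
  r <- run_revcomp()
  a <- load_audit(file.path(r$dir, "dna.compl.rev.txt"))
  expect_s3_class(a, "flow_audit")
  expect_equal(a$ProcessName, "Reverse")
  expect_match(a$Command, "^cat \\.\\./dna\\.compl\\.txt")

  compl <- a$Upstream[["dna.compl.txt"]]
  expect_equal(compl$ProcessName, "Base Complement")
  mk <- compl$Upstream[["dna.txt"]]
  expect_equal(mk$ProcessName, "Make DNA")
  expect_length(mk$Upstream, 0)

  # IDs are unique across the trace; times are recorded in nanoseconds
  ids <- vapply(flowpipe:::collect_audit_tasks(a), `[[`, "", "ID")
  expect_length(unique(ids), 3L)
  expect_true(all(grepl("^[0-9a-f]{32}$", ids)))
  expect_gt(a$ExecTimeNS, 0)
  expect_match(flowpipe:::format_rfc3339_ns(a$StartTime),
               "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}\\.\\d{9}Z$")
})

test_that("audit serialization round-trips byte-stably", {
  r <- run_revcomp()
  sidecar <- file.path(r$dir, "dna.compl.rev.txt.audit.json")
  original <- readLines(sidecar)
  a <- load_audit(file.path(r$dir, "dna.compl.rev.txt"))
  rewritten <- strsplit(flowpipe:::audit_to_json(a), "\n")[[1]]
  expect_identical(rewritten, original)
})

test_that("two inputs from one upstream task share a single audit identity", {
  d <- fresh_dir()
  wf <- new_workflow("diamond", 2, d)
  root <- new_proc(wf, "root", "echo seed > {o:out}")
  set_out(root, "out", "root.txt")
  left <- new_proc(wf, "left", "tr a-z A-Z < {i:in} > {o:out}")
  set_out(left, "out", "left.txt")
  right <- new_proc(wf, "right", "rev < {i:in} > {o:out}")
  set_out(right, "out", "right.txt")
  left$in_port("in")$from(root$out_port("out"))
  right$in_port("in")$from(root$out_port("out"))
  join <- new_proc(wf, "join", "cat {i:a} {i:b} > {o:out}")
  set_out(join, "out", "join.txt")
  join$in_port("a")$from(left$out_port("out"))
  join$in_port("b")$from(right$out_port("out"))
  run(wf)

  a <- load_audit(file.path(d, "join.txt"))
  id_via_left <- a$Upstream[["left.txt"]]$Upstream[["root.txt"]]$ID
  id_via_right <- a$Upstream[["right.txt"]]$Upstream[["root.txt"]]$ID
  expect_identical(id_via_left, id_via_right)

  # the shared root command appears exactly once in the replay script
  script <- audit2bash(a)
  expect_equal(length(gregexpr("echo seed > root.txt", script, fixed = TRUE)[[1]]), 1L)
  # one command per unique task: 4 task blocks
  expect_equal(sum(grepl("^# Process:", strsplit(script, "\n")[[1]])), 4L)
})

test_that("audit2bash replays deterministic workflows byte-identically", {
  r <- run_revcomp()
  script <- audit2bash(load_audit(file.path(r$dir, "dna.compl.rev.txt")))
  lines <- strsplit(script, "\n")[[1]]
  expect_equal(sum(grepl("^# Process:", lines)), 3L)

  replay <- fresh_dir()
  writeLines(script, file.path(replay, "replay.sh"))
  status <- withr::with_dir(replay,
    system2("bash", "replay.sh", stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  expect_identical(readLines(file.path(replay, "dna.compl.rev.txt")),
                   readLines(file.path(r$dir, "dna.compl.rev.txt")))
})

test_that("externally created inputs become stub entries, not failures", {
  d <- fresh_dir()
  writeLines("made by hand", file.path(d, "external.txt"))
  wf <- new_workflow("ext", 1, d)
  src <- new_file_source(wf, "inputs", "external.txt")
  p <- new_proc(wf, "copy", "cat {i:in} > {o:out}")
  set_out(p, "out", "copy.txt")
  p$in_port("in")$from(src$out_port("out"))
  run(wf)

  a <- load_audit(file.path(d, "copy.txt"))
  stub <- a$Upstream[["external.txt"]]
  expect_identical(stub$Tags$external, "true")
  expect_identical(stub$Command, "")

  # direct loads warn about the absent sidecar
  expect_warning(load_audit(file.path(d, "external.txt")), "external")
  # corrupt sidecars degrade to a stub too
  writeLines("not json{", file.path(d, "external.txt.audit.json"))
  expect_warning(b <- load_audit(file.path(d, "external.txt")), "corrupt")
  expect_identical(b$Tags$external, "true")
})

test_that("provenance chains across separately executed workflow scripts", {
  d <- fresh_dir()
  wf1 <- new_workflow("first script", 1, d)
  a <- new_proc(wf1, "stage one", "echo payload > {o:out}")
  set_out(a, "out", "stage1.txt")
  run(wf1)

  # a completely separate workflow picks the file up later
  wf2 <- new_workflow("second script", 1, d)
  src <- new_file_source(wf2, "handoff", "stage1.txt")
  b <- new_proc(wf2, "stage two", "rev < {i:in} > {o:out}")
  set_out(b, "out", "stage2.txt")
  b$in_port("in")$from(src$out_port("out"))
  run(wf2)

  final <- load_audit(file.path(d, "stage2.txt"))
  expect_equal(final$Upstream[["stage1.txt"]]$ProcessName, "stage one")
  expect_match(final$Upstream[["stage1.txt"]]$Command, "echo payload")
})

test_that("reports carry version, total time, timeline and per-task tables", {
  r <- run_revcomp()
  a <- load_audit(file.path(r$dir, "dna.compl.rev.txt"))

  html <- audit2report(a, "html")
  expect_match(html, "flowpipe version")
  expect_match(html, "total execution time")
  expect_equal(length(gregexpr('<table class="task"', html, fixed = TRUE)[[1]]), 3L)
  # timeline bars ordered by start time: Make DNA first
  bar_pos <- regexpr("Make DNA", html, fixed = TRUE)
  expect_lt(bar_pos, regexpr("Base Complement", html, fixed = TRUE))

  tex <- audit2report(a, "tex")
  expect_match(tex, "\\\\documentclass\\{article\\}")
  expect_match(tex, "\\\\end\\{document\\}")
  expect_equal(sum(grepl("Task ID", strsplit(tex, "\n")[[1]])), 3L)

  # single task -> one bar spanning the whole duration
  solo <- audit2report(load_audit(file.path(r$dir, "dna.txt")), "html")
  expect_equal(length(gregexpr('class="bar"', solo, fixed = TRUE)[[1]]), 1L)

  # equal start times render in deterministic id-sorted order
  t1 <- new_audit("aaa", "P1", "c1", start_time = 1e9, exec_time_ns = 10)
  t2 <- new_audit("bbb", "P2", "c2", start_time = 1e9, exec_time_ns = 10,
                  upstream = list(x = t1))
  tab <- flowpipe:::report_task_table(flowpipe:::collect_audit_tasks(t2))
  expect_equal(tab$id, c("aaa", "bbb"))
})
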