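# Workflow/process/port definition, connection rules, validation, and the
# packet-combination (zip) semantics of task formation.

test_that("workflow construction enforces the concurrency setting", {
  wf <- new_workflow("wf", 4, work_dir = fresh_dir())
  expect_length(wf$processes, 0)
  expect_error(new_workflow("wf", 0), "positive integer")
  expect_error(new_workflow("wf", -3), "positive integer")
})

test_that("processes derive one port per distinct placeholder name and kind", {
  wf <- new_workflow("wf", 1, work_dir = fresh_dir())
  p1 <- new_proc(wf, "mk", "echo AAAGCCCGTGGGGGACCTGTTC > {o:dna}")
  expect_length(p1$in_ports, 0)
  expect_equal(names(p1$out_ports), "dna")

  p2 <- new_proc(wf, "cp", "cat {i:in} > {o:out}")
  expect_equal(names(p2$in_ports), "in")
  expect_equal(names(p2$out_ports), "out")

  # repeated placeholder still yields a single port; oracle = regex scan
  pats <- c("f {i:a} {i:a} {o:b}",
            "g {i:x} {p:v} {p:v} {o:y} {o:y}",
            "h {i:a} {i:b} {o:c} {p:q}")
  for (k in seq_along(pats)) {
    p <- new_proc(wf, paste0("r", k), pats[k])
    counts <- regex_port_counts(pats[k])
    expect_length(p$in_ports, counts[["i"]])
    expect_length(p$out_ports, counts[["o"]])
    expect_length(p$param_in_ports, counts[["p"]])
  }

  expect_error(new_proc(wf, "mk", "echo x > {o:y}"), "already exists")
  expect_error(new_proc(wf, "bad", "oops {q:z}"), "unknown placeholder kind")
})

test_that("connections pair complementary kinds and forbid double producers", {
  wf <- new_workflow("wf", 1, work_dir = fresh_dir())
  a <- new_proc(wf, "a", "echo x > {o:out}")
  b <- new_proc(wf, "b", "cat {i:in} {p:v} > {o:out}")
  s <- new_param_source(wf, "params", v = c("1", "2"))

  expect_error(b$param_in_port("v")$from(a$out_port("out")), "kind mismatch")
  expect_error(connect(a$out_port("out"), b$in_port("in")), "not an in-port")

  b$in_port("in")$from(a$out_port("out"))
  expect_error(b$in_port("in")$from(a$out_port("out")), "already connected")
  b$param_in_port("v")$from(s$param_out_port("v"))
  expect_silent(wf$validate())
})

test_that("validation rejects unconnected in-ports and cyclic graphs", {
  wf <- new_workflow("wf", 1, work_dir = fresh_dir())
  new_proc(wf, "a", "cat {i:in} > {o:out}")
  expect_error(run(wf), "not connected")

  wf2 <- new_workflow("wf2", 1, work_dir = fresh_dir())
  a <- new_proc(wf2, "a", "cat {i:x} > {o:y}")
  b <- new_proc(wf2, "b", "cat {i:y} > {o:x}")
  a$in_port("x")$from(b$out_port("x"))
  b$in_port("y")$from(a$out_port("y"))
  expect_error(wf2$validate(), "cycle")
})

test_that("an out-port broadcasts every packet to all its consumers", {
  d <- fresh_dir()
  wf <- new_workflow("bcast", 4, d)
  src <- new_param_source(wf, "vals", v = as.character(1:3))
  prod <- new_proc(wf, "prod", "echo {p:v} > {o:out}")
  set_out(prod, "out", "b{p:v}.txt")
  prod$param_in_port("v")$from(src$param_out_port("v"))
  for (cn in c("left", "right")) {
    cons <- new_proc(wf, cn, "cat {i:in} > {o:out}")
    set_out(cons, "out", paste0(cn, "_{i:in}"))
    cons$in_port("in")$from(prod$out_port("out"))
  }
  rep <- run(wf)
  ev <- rep$events
  # oracle: each consumer executes once per producer packet
  n_prod <- sum(ev$process == "prod" & ev$event == "done")
  expect_equal(n_prod, 3L)
  expect_equal(sum(ev$process == "left" & ev$event == "done"), n_prod)
  expect_equal(sum(ev$process == "right" & ev$event == "done"), n_prod)
})

test_that("multi-port task formation zips packets positionally", {
  # equal streams: i-th pairs with i-th (oracle = explicit zip)
  d <- fresh_dir()
  wf <- new_workflow("zip", 2, d)
  sa <- new_param_source(wf, "as", a = c("1", "2", "3"))
  sb <- new_param_source(wf, "bs", b = c("x", "y", "z"))
  p <- new_proc(wf, "pair", "echo {p:a}-{p:b} > {o:out}")
  set_out(p, "out", "pair_{p:a}{p:b}.txt")
  p$param_in_port("a")$from(sa$param_out_port("a"))
  p$param_in_port("b")$from(sb$param_out_port("b"))
  rep <- run(wf)
  expect_equal(rep$n_executed, 3L)
  zipped <- mapply(paste0, c("1", "2", "3"), c("x", "y", "z"))
  expect_true(all(file.exists(file.path(d, sprintf("pair_%s.txt", zipped)))))

  # unequal streams: min-length zip
  d2 <- fresh_dir()
  wf2 <- new_workflow("zipmin", 2, d2)
  sa2 <- new_param_source(wf2, "as", a = as.character(1:3))
  sb2 <- new_param_source(wf2, "bs", b = as.character(1:2))
  p2 <- new_proc(wf2, "pair", "echo {p:a}-{p:b} > {o:out}")
  set_out(p2, "out", "p_{p:a}_{p:b}.txt")
  p2$param_in_port("a")$from(sa2$param_out_port("a"))
  p2$param_in_port("b")$from(sb2$param_out_port("b"))
  rep2 <- run(wf2)
  expect_equal(rep2$n_executed, min(3L, 2L))
})

test_that("run_to executes exactly the reverse-reachability closure", {
  # three-node chain: target the middle process
  r <- list(dir = fresh_dir())
  wf <- make_revcomp_demo(r$dir)
  rep <- run_to(wf, "Base Complement")
  expect_setequal(rep$events$process, c("Make DNA", "Base Complement"))
  expect_false(file.exists(file.path(r$dir, "dna.compl.rev.txt")))

  # diamond: target one mid-branch; oracle = independent reverse BFS
  d <- fresh_dir()
  wf2 <- new_workflow("diamond", 2, d)
  root <- new_proc(wf2, "root", "echo seed > {o:out}")
  set_out(root, "out", "root.txt")
  for (br in c("left", "right")) {
    p <- new_proc(wf2, br, "cat {i:in} > {o:out}")
    set_out(p, "out", paste0(br, ".txt"))
    p$in_port("in")$from(root$out_port("out"))
  }
  join <- new_proc(wf2, "join", "cat {i:a} {i:b} > {o:out}")
  set_out(join, "out", "join.txt")
  join$in_port("a")$from(wf2$processes$left$out_port("out"))
  join$in_port("b")$from(wf2$processes$right$out_port("out"))

  edges <- wf2$connections()
  oracle <- reverse_bfs(edges$from_proc, edges$to_proc, "left")
  rep2 <- run_to(wf2, "left")
  expect_setequal(rep2$events$process, oracle)
  expect_setequal(oracle, c("left", "root"))

  # target = sink behaves like run()
  rep3 <- run_to(wf2, "join")
  expect_setequal(rep3$processes, names(wf2$processes))
  expect_true(file.exists(file.path(d, "join.txt")))

  expect_error(run_to(wf2, "nope"), "unknown target")
})

test_that("the final task's packets flow through the whole chain", {
  r <- run_revcomp()
  expect_equal(r$report$n_executed, 3L)
  expect_equal(readLines(file.path(r$dir, "dna.txt")), REVCOMP_DNA)
  expect_equal(readLines(file.path(r$dir, "dna.compl.txt")), "TTTCGGGCACCCCCTGGACAAG")
  expect_equal(readLines(file.path(r$dir, "dna.compl.rev.txt")), REVCOMP_FINAL)
})
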