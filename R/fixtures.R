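# Self-contained demo workflows and randomized test networks. All fixtures
# use only standard UNIX text tools (echo/tr/rev/cat/awk/touch/sleep) and
# never touch the network, so every part of the engine is exercisable on a
# bare machine.

#' Demo: reverse base complement of a DNA string
#'
#' A three-process chain built from standard UNIX tools: "Make DNA" writes
#' a fixed DNA string to a file, "Base Complement" maps each base to its
#' complementary base (A<->T, C<->G) with `tr`, and "Reverse" reverses the
#' string with `rev`. Running it produces `dna.txt`, `dna.compl.txt` and
#' `dna.compl.rev.txt`, each with its audit sidecar.
#'
#' @param work_dir Workflow working directory.
#' @param max_tasks Concurrency cap (default 4).
#' @return A [Workflow], ready to [run()].
#' @examples
#' \donttest{
#' wf <- make_revcomp_demo(tempfile())
#' run(wf)
#' readLines(file.path(wf$work_dir, "dna.compl.rev.txt"))
#' }
#' @export
make_revcomp_demo <- function(work_dir = ".", max_tasks = 4) {
  wf <- new_workflow("DNA Base Complement Workflow", max_tasks, work_dir)

  make_dna <- new_proc(wf, "Make DNA", "echo AAAGCCCGTGGGGGACCTGTTC > {o:dna}")
  set_out(make_dna, "dna", "dna.txt")

  complement <- new_proc(wf, "Base Complement",
                         "cat {i:in} | tr ATCG TAGC > {o:complement}")
  set_out(complement, "complement", "{i:in|%.txt}.compl.txt")

  reverse <- new_proc(wf, "Reverse", "cat {i:in} | rev > {o:rev}")
  set_out(reverse, "rev", "{i:in|%.txt}.rev.txt")

  complement$in_port("in")$from(make_dna$out_port("dna"))
  reverse$in_port("in")$from(complement$out_port("complement"))
  wf
}

#' Demo: cross-validated parameter sweep with dynamic parametrization
#'
#' Emulates a hyper-parameter search: a parameter source fans out one
#' "Train Eval" task per (size, cost, fold) combination; a collector
#' ("Select Best") waits for all fold results, picks the cost with the
#' lowest mean error per training-set size, and emits it as a parameter;
#' a final "Train Final" task per size is parametrized by that value —
#' which only exists once part of the workflow has already run, exercising
#' dynamic scheduling through a parameter (dashed-edge) connection.
#'
#' The toy "learner" is a deterministic awk one-liner whose error is
#' `(cost - 0.75)^2` plus a small fold-dependent offset, so the per-size
#' argmin over costs is unique (0.75 with the default grid).
#'
#' @param sizes Training-set sizes (default: 500, 1000, 2000, 4000, 8000).
#' @param costs Cost grid (default: the 15-value grid
#'   0.0001 ... 5).
#' @param folds Cross-validation fold indices (default 1:10).
#' @param work_dir Workflow working directory.
#' @param max_tasks Concurrency cap (default 4).
#' @return A [Workflow].
#' @export
make_sweep_demo <- function(sizes = c(500, 1000, 2000, 4000, 8000),
                            costs = c(0.0001, 0.0005, 0.001, 0.005, 0.01,
                                      0.05, 0.1, 0.25, 0.5, 0.75, 1, 2, 3, 4, 5),
                            folds = 1:10,
                            work_dir = ".", max_tasks = 4) {
  stopifnot(length(sizes) >= 1L, length(costs) >= 1L, length(folds) >= 1L)
  wf <- new_workflow("Parameter Sweep Workflow", max_tasks, work_dir)

  grid <- expand.grid(fold = folds, cost = costs, size = sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gen <- new_param_source(wf, "Param Gen",
                          size = as.character(grid$size),
                          cost = as.character(grid$cost),
                          fold = as.character(grid$fold))

  sweep <- new_proc(wf, "Train Eval",
    "awk -v s={p:size} -v c={p:cost} -v f={p:fold} 'BEGIN{printf \"%.8f\\n\", (c-0.75)^2 + f/100000 + 0*s}' > {o:err}")
  set_out(sweep, "err", "sweep_s{p:size}_c{p:cost}_f{p:fold}.err.txt")
  sweep$param_in_port("size")$from(gen$param_out_port("size"))
  sweep$param_in_port("cost")$from(gen$param_out_port("cost"))
  sweep$param_in_port("fold")$from(gen$param_out_port("fold"))

  size_order <- as.character(sizes)
  best <- new_collect_proc(wf, "Select Best",
    in_ports = "errs", param_outs = c("size", "cost"),
    fn = function(packets) {
      errs <- packets$errs
      size <- vapply(errs, function(ip) ip$audit$Params$size, "")
      cost <- vapply(errs, function(ip) ip$audit$Params$cost, "")
      val <- vapply(errs, function(ip) {
        as.numeric(readLines(file.path(work_dir, ip$path), warn = FALSE)[1])
      }, 0)
      best_cost <- vapply(size_order, function(s) {
        sel <- size == s
        means <- tapply(val[sel], cost[sel], mean)
        # unique argmin by construction; ties would break to lowest cost
        names(means)[order(means, as.numeric(names(means)))][1]
      }, "")
      list(size = size_order, cost = unname(best_cost))
    })
  best$in_port("errs")$from(sweep$out_port("err"))

  final <- new_proc(wf, "Train Final",
                    "echo \"model trained: size={p:size} cost={p:cost}\" > {o:model}")
  set_out(final, "model", "model_s{p:size}.txt")
  final$param_in_port("size")$from(best$param_out_port("size"))
  final$param_in_port("cost")$from(best$param_out_port("cost"))
  wf
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Seeded random DAG of file-copying processes
#'
#' Builds a reproducible random acyclic network of `touch`/`cat` processes
#' for scheduler property tests: the same `(n_procs, seed)` pair always
#' yields an identical network (identical DOT output). Process `p1` is a
#' source; every later process concatenates one or two outputs of earlier
#' processes, so the file dependency graph is acyclic by construction.
#'
#' @param n_procs Number of processes (>= 1).
#' @param seed Integer seed.
#' @param work_dir Workflow working directory.
#' @param max_tasks Concurrency cap (default 4).
#' @return A [Workflow].
#' @export
make_random_dag <- function(n_procs, seed, work_dir = ".", max_tasks = 4) {
  stopifnot(n_procs >= 1L)
  with_preserved_rng(seed, {
    wf <- new_workflow(sprintf("Random DAG n=%d seed=%d", n_procs, seed),
                       max_tasks, work_dir)
    procs <- list()
    p1 <- new_proc(wf, "p1", sprintf("echo seed%d > {o:out}", seed))
    set_out(p1, "out", sprintf("rnd%d_p1.txt", seed))
    procs[[1]] <- p1
    if (n_procs > 1L) {
      for (i in 2:n_procs) {
        k <- sample(seq_len(min(2L, i - 1L)), 1L)
        ups <- sample(seq_len(i - 1L), k)
        pattern <- if (k == 1L) "cat {i:in1} > {o:out}" else "cat {i:in1} {i:in2} > {o:out}"
        p <- new_proc(wf, sprintf("p%d", i), pattern)
        set_out(p, "out", sprintf("rnd%d_p%d.txt", seed, i))
        for (j in seq_len(k)) {
          p$in_port(paste0("in", j))$from(procs[[ups[j]]]$out_port("out"))
        }
        procs[[i]] <- p
      }
    }
    wf
  })
}
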