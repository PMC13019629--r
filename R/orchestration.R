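#' Batch execution configuration
#'
#' @param B Number of independent batch runs (default 8); the lowest
#'   pseudovariance representative of each state across batches is kept.
#' @param N States per parity chain (default 4: deep enough to reach the
#'   high-lying Hermitian parent of the second resonance in this model).
#' @param dedup_tol Squared-overlap tolerance above which two states found
#'   within one run are considered duplicates (default 0.8).
#' @param workers Local worker processes for DAG execution.
#' @param seed Master seed; every task derives its own substream from it,
#'   so results do not depend on the worker count.
#' @return Object of class `batch_config`.
#' @export
batch_config <- function(B = 8, N = 4, dedup_tol = 0.8, workers = 1,
                         seed = 1) {
  stopifnot(B >= 1, N >= 1, dedup_tol > 0, dedup_tol <= 1, workers >= 1)
  structure(list(B = as.integer(B), N = as.integer(N),
                 dedup_tol = dedup_tol, workers = as.integer(workers),
                 seed = as.integer(seed)),
            class = "batch_config")
}

# Deterministic per-task seed from the master seed and the task id.
task_seed <- function(master, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

#' Build the arborescence task graph of one batched run
#'
#' Each (batch, parity) component is a chain of `N` Hermitian-deflation
#' nodes; every chain node additionally spawns a childless pseudovariance
#' refinement leaf, so a parent always has one child of its own kind and
#' one terminal child. Refinement leaves feed a per-component pool node,
#' and all pools feed one final sort node.
#'
#' @param cfg A [batch_config()].
#' @param parities Character vector among `"even"`, `"odd"`.
#' @return Object of class `dag_plan` with `nodes` and `edges` data frames.
#' @export
build_dag <- function(cfg = batch_config(), parities = c("even", "odd")) {
  stopifnot(all(parities %in% c("even", "odd")))
  nodes <- list(); edges <- list()
  add_node <- function(id, type, batch = NA, parity = NA, index = NA)
    nodes[[length(nodes) + 1]] <<- data.frame(
      id = id, type = type, batch = batch, parity = parity, index = index,
      stringsAsFactors = FALSE)
  add_edge <- function(from, to)
    edges[[length(edges) + 1]] <<- data.frame(from = from, to = to,
                                              stringsAsFactors = FALSE)
  for (b in seq_len(cfg$B)) {
    for (par in parities) {
      pool_id <- sprintf("b%d.%s.pool", b, par)
      for (i in seq_len(cfg$N)) {
        h_id <- sprintf("b%d.%s.h%d", b, par, i)
        r_id <- sprintf("b%d.%s.r%d", b, par, i)
        add_node(h_id, "hermitian", b, par, i)
        add_node(r_id, "refine", b, par, i)
        if (i > 1) add_edge(sprintf("b%d.%s.h%d", b, par, i - 1), h_id)
        add_edge(h_id, r_id)
        add_edge(r_id, pool_id)
      }
      add_node(pool_id, "pool", b, par)
      add_edge(pool_id, "sort")
    }
  }
  add_node("sort", "sort")
  structure(list(nodes = do.call(rbind, nodes),
                 edges = do.call(rbind, edges), cfg = cfg,
                 parities = parities),
            class = "dag_plan")
}

#' @export
print.dag_plan <- function(x, ...) {
  cat(sprintf("Task DAG: %d nodes, %d edges (%d batches x {%s}, chains of %d)\n",
              nrow(x$nodes), nrow(x$edges), x$cfg$B,
              paste(x$parities, collapse = ", "), x$cfg$N))
  invisible(x)
}

#' Export a task graph in DOT format
#'
#' The textual node/edge list can be handed to an external metascheduler or
#' rendered with graphviz.
#'
#' @param plan A [build_dag()] result.
#' @param file Optional path; when `NULL` the DOT text is returned.
#' @return The DOT lines, invisibly when written to a file.
#' @export
dag_to_dot <- function(plan, file = NULL) {
  lines <- c("digraph resonance_run {",
             sprintf("  \"%s\" [label=\"%s\"];", plan$nodes$id,
                     plan$nodes$type),
             sprintf("  \"%s\" -> \"%s\";", plan$edges$from, plan$edges$to),
             "}")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

# Topological order of a dag_plan (also validates acyclicity).
topological_order <- function(plan) {
  ids <- plan$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (to in plan$edges$to) indeg[to] <- indeg[to] + 1L
  order <- character(0)
  ready <- ids[indeg == 0]
  while (length(ready)) {
    n <- ready[1]; ready <- ready[-1]
    order <- c(order, n)
    for (to in plan$edges$to[plan$edges$from == n]) {
      indeg[to] <- indeg[to] - 1L
      if (indeg[to] == 0L) ready <- c(ready, to)
    }
  }
  if (length(order) != length(ids)) stop("task graph has a cycle")
  order
}

# Execute one task. `inputs` is a named list of parent results.
run_task <- function(node, inputs, ctx) {
  seed <- task_seed(ctx$master_seed, node$id)
  set.seed(seed)
  t0 <- Sys.time()
  res <- switch(
    node$type,
    hermitian = {
      priors <- if (node$index > 1) inputs[[1]]$priors else list()
      st <- hermitian_chain_step(ctx$ansatz, priors, ctx$ms[[node$parity]],
                                 ctx$deflation, ctx$backend)
      list(priors = c(priors, list(st$theta)), state = st)
    },
    refine = {
      st <- inputs[[1]]$state
      r <- refine_resonance(st$theta, ctx$ansatz, ctx$ms[[node$parity]],
                            ctx$refinement, ctx$backend)
      # final cross-batch comparison uses an extra order of magnitude of shots
      if (ctx$backend$mode != "exact") {
        r$sigma2 <- pseudovariance(ctx$ansatz, r$phi, ctx$ms[[node$parity]],
                                   ctx$backend, shots = ctx$backend$final_shots)
        r$energy <- energy_estimate(ctx$ansatz, r$phi, ctx$ms[[node$parity]],
                                    ctx$backend, shots = ctx$backend$final_shots)
      }
      rec <- data.frame(batch = node$batch, parity = node$parity,
                        index = node$index, E = r$energy$E,
                        sigma2 = r$sigma2, warning = r$warning,
                        hermitian_energy = inputs[[1]]$state$energy,
                        stringsAsFactors = FALSE)
      rec$phi <- I(list(r$phi))
      rec
    },
    pool = {
      recs <- do.call(rbind, unname(inputs))
      if (is.null(recs)) NULL
      else dedup_run(recs, ctx$ansatz, ctx$plan$cfg$dedup_tol)
    },
    sort = {
      pool_records(do.call(rbind, unname(inputs)), ctx$ansatz,
                   ctx$plan$cfg$dedup_tol)
    })
  list(value = res, start = t0, end = Sys.time(), seed = seed)
}

#' Execute a task graph on local workers
#'
#' Runs every task after its parents, either sequentially or on forked
#' worker processes. Each task draws its randomness from a seed derived
#' deterministically from the master seed and the task id, so the records
#' are identical for any worker count. A failing task skips only its own
#' descendants of the same kind (the rest of its chain); pool and sort
#' nodes always run on whichever parents succeeded.
#'
#' @param plan A [build_dag()] result.
#' @param ctx Execution context as assembled by [resonance_search()]: list
#'   with `ansatz`, `ms` (one [measurement_set()] per parity), `deflation`,
#'   `refinement`, `backend`, `master_seed`.
#' @param workers Number of local processes (forked; 1 = sequential).
#' @param fail_ids Task ids forced to fail (fault-injection testing).
#' @return List with `records` (pooled, sorted data frame), `pools`,
#'   `schedule` (per-task status and timestamps), and `failed` ids.
#' @export
execute_dag <- function(plan, ctx, workers = 1, fail_ids = character(0)) {
  ctx$plan <- plan
  nodes <- plan$nodes
  rownames(nodes) <- nodes$id
  parents_of <- split(plan$edges$from, plan$edges$to)
  status <- stats::setNames(rep("pending", nrow(nodes)), nodes$id)
  results <- list()
  sched <- list()
  terminal <- c("done", "failed", "skipped")

  runnable <- function(id) {
    ps <- parents_of[[id]]
    if (is.null(ps)) return(TRUE)
    all(status[ps] %in% terminal)
  }
  launch <- function(id) {
    node <- nodes[id, ]
    ps <- parents_of[[id]]
    ok_parents <- ps[status[ps] == "done"]
    if (node$type %in% c("hermitian", "refine") &&
        length(ok_parents) < length(ps)) return(list(skip = TRUE))
    if (id %in% fail_ids) stop("injected failure in ", id)
    run_task(node, results[ok_parents], ctx)
  }

  repeat {
    ready <- names(status)[status == "pending" &
                             vapply(names(status), runnable, logical(1))]
    if (length(ready) == 0) break
    if (workers == 1 || length(ready) == 1) {
      batch_ids <- ready[1]
      outs <- list(tryCatch(launch(batch_ids), error = function(e) e))
    } else {
      batch_ids <- utils::head(ready, workers)
      jobs <- lapply(batch_ids, function(id)
        parallel::mcparallel(tryCatch(launch(id), error = function(e) e)))
      outs <- parallel::mccollect(jobs, wait = TRUE)
    }
    for (k in seq_along(batch_ids)) {
      id <- batch_ids[k]; out <- outs[[k]]
      if (inherits(out, "error")) {
        status[id] <- "failed"
        sched[[id]] <- data.frame(id = id, status = "failed",
                                  start = NA, end = NA)
      } else if (isTRUE(out$skip)) {
        status[id] <- "skipped"
        sched[[id]] <- data.frame(id = id, status = "skipped",
                                  start = NA, end = NA)
      } else {
        status[id] <- "done"
        results[[id]] <- out$value
        sched[[id]] <- data.frame(id = id, status = "done",
                                  start = as.numeric(out$start),
                                  end = as.numeric(out$end))
      }
    }
  }
  list(records = results[["sort"]], pools = results[nodes$id[nodes$type == "pool"]],
       schedule = do.call(rbind, sched),
       failed = names(status)[status %in% c("failed", "skipped")])
}

# Within-run duplicate removal: a later state whose squared overlap with an
# earlier kept state exceeds the tolerance is dropped. Overlaps are taken
# between the simulated statevectors of the stored parameters.
dedup_run <- function(recs, ansatz, tol) {
  if (is.null(recs) || nrow(recs) <= 1) return(recs)
  recs <- recs[order(recs$index), , drop = FALSE]
  states <- lapply(recs$phi, prepare_state, ansatz = ansatz)
  keep <- logical(nrow(recs))
  for (k in seq_len(nrow(recs))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (Mod(sum(Conj(states[[j]]) * states[[k]]))^2 > tol) {
        dup <- TRUE; break
      }
    }
    keep[k] <- !dup
  }
  recs[keep, , drop = FALSE]
}

# Across batches: records approximating the same eigenstate of H_N are
# grouped (same parity, squared overlap of their statevectors above the
# duplicate tolerance) and the minimum-pseudovariance member represents the
# group. Grouping is greedy in ascending pseudovariance, so the best
# converged record seeds each group; chain indices need not agree across
# batches, since different runs can reach the same state at different
# deflation depths. The pooled list is sorted by Re(E).
pool_records <- function(recs, ansatz, tol = 0.8) {
  if (is.null(recs) || nrow(recs) == 0) return(recs)
  recs <- recs[order(recs$sigma2), , drop = FALSE]
  states <- lapply(recs$phi, prepare_state, ansatz = ansatz)
  n <- nrow(recs)
  assigned <- logical(n)
  keep <- integer(0)
  for (k in seq_len(n)) {
    if (assigned[k]) next
    keep <- c(keep, k)
    assigned[k] <- TRUE
    for (j in seq_len(n)) {
      if (!assigned[j] && recs$parity[j] == recs$parity[k] &&
          Mod(sum(Conj(states[[k]]) * states[[j]]))^2 > tol)
        assigned[j] <- TRUE
    }
  }
  out <- recs[keep, , drop = FALSE]
  out[order(Re(out$E)), , drop = FALSE]
}

#' Deduplicate within runs and pool across batches
#'
#' @param records Data frame of refinement records (as produced by
#'   [execute_dag()] pools) with columns `batch`, `parity`, `index`, `E`,
#'   `sigma2` and a `phi` list column.
#' @param ansatz The [ansatz_spec()] the parameters refer to.
#' @param dedup_tol Squared-overlap duplicate tolerance within a run.
#' @return Pooled data frame sorted by `Re(E)`.
#' @export
dedup_and_pool <- function(records, ansatz, dedup_tol = 0.8) {
  if (is.null(records) || nrow(records) == 0) return(records)
  parts <- split(records, paste(records$batch, records$parity))
  dd <- do.call(rbind, lapply(parts, dedup_run, ansatz = ansatz,
                              tol = dedup_tol))
  pool_records(dd, ansatz, dedup_tol)
}

#' Filter configuration for spurious-state classification
#'
#' CAP calculations produce, besides genuine bound and resonance states,
#' artifacts: nonresonant states living in the absorbing region, diverging
#' states, and states indifferent to the CAP strength. The thresholds here
#' classify each record from its CAP-region occupancy
#' \eqn{\int_{|x|>x_0} |\psi|^2 dx}, its convergence status and its
#' sensitivity to doubling the CAP prefactor.
#'
#' @param nonresonant_occupancy Occupancy above which a state is classified
#'   spurious-nonresonant (default 0.5).
#' @param indifferent_occupancy Occupancy above which CAP-insensitivity
#'   marks a state spurious-indifferent (default 0.25).
#' @param indifferent_rel_change Relative energy change under CAP doubling
#'   below which a state counts as insensitive (default 1e-3).
#' @param bound_im_tol `|Im E|` below which a non-spurious, well-localized
#'   state is classified bound (default 1e-6).
#' @param bound_occupancy Maximum CAP-region occupancy of a bound state
#'   (default 0.05).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(nonresonant_occupancy = 0.5,
                          indifferent_occupancy = 0.25,
                          indifferent_rel_change = 1e-3,
                          bound_im_tol = 1e-6,
                          bound_occupancy = 0.05) {
  structure(list(nonresonant_occupancy = nonresonant_occupancy,
                 indifferent_occupancy = indifferent_occupancy,
                 indifferent_rel_change = indifferent_rel_change,
                 bound_im_tol = bound_im_tol,
                 bound_occupancy = bound_occupancy),
            class = "filter_config")
}

#' Classify records and drop spurious CAP artifacts
#'
#' @param records Pooled record data frame with `E`, `sigma2`, `warning`,
#'   `parity` and `phi` columns.
#' @param ansatz An [ansatz_spec()].
#' @param spec A [model_spec()].
#' @param cfg A [filter_config()].
#' @return The records with a `classification` column (`bound`,
#'   `resonance`, `spurious-nonresonant`, `spurious-diverging`,
#'   `spurious-indifferent`) and an `occupancy` column; the headline list
#'   is the subset with classification `bound` or `resonance`.
#' @export
filter_spurious <- function(records, ansatz, spec = model_spec(),
                            cfg = filter_config()) {
  if (is.null(records) || nrow(records) == 0) {
    if (!is.null(records)) records$classification <- character(0)
    return(records)
  }
  cap_depth <- (spec$x_max - spec$x0)^2 / 2
  cls <- character(nrow(records))
  occ <- numeric(nrow(records))
  for (k in seq_len(nrow(records))) {
    basis <- basis_spec(records$parity[k], ansatz$q)
    coef <- prepare_state(ansatz, records$phi[[k]])
    occ[k] <- cap_occupancy(coef, spec, basis)
    E <- records$E[k]
    w <- Im(E)
    E2 <- complex(real = Re(E), imaginary = 2 * w)  # doubled CAP prefactor
    rel_change <- Mod(E2 - E) / Mod(E)
    cls[k] <- if (occ[k] > cfg$nonresonant_occupancy) {
      "spurious-nonresonant"
    } else if (records$warning[k] && abs(w) > cap_depth) {
      "spurious-diverging"
    } else if (rel_change < cfg$indifferent_rel_change &&
               occ[k] > cfg$indifferent_occupancy) {
      "spurious-indifferent"
    } else if (abs(w) < cfg$bound_im_tol && occ[k] < cfg$bound_occupancy) {
      "bound"
    } else "resonance"
  }
  records$occupancy <- occ
  records$classification <- cls
  records
}

#' Search for bound and resonance states of the CAP Hamiltonian
#'
#' Full batched pipeline: per parity, project the model onto the sine
#' basis; run `B` independent batch runs, each a Hermitian deflation chain
#' of `N` states whose members seed pseudovariance refinements; pool by
#' minimum pseudovariance across batches after in-run deduplication; and
#' classify/filter spurious CAP artifacts.
#'
#' @param q Qubit count (basis holds `2^q` states per parity).
#' @param parities Parities to run (default both).
#' @param spec A [model_spec()].
#' @param batch A [batch_config()] (holds the master seed).
#' @param deflation A [deflation_config()].
#' @param refinement A [refinement_config()].
#' @param backend A [backend_config()].
#' @param filter A [filter_config()].
#' @param workers Worker processes for the DAG executor.
#' @return Object of class `resonance_result`: list with `states` (headline
#'   bound/resonance records), `diagnostics` (all pooled records with
#'   classification), `plan`, `schedule`, `failed`.
#' @export
resonance_search <- function(q, parities = c("even", "odd"),
                             spec = model_spec(), batch = batch_config(),
                             deflation = deflation_config(),
                             refinement = refinement_config(),
                             backend = backend_config(),
                             filter = filter_config(),
                             workers = batch$workers) {
  ansatz <- ansatz_spec(q)
  ms <- lapply(stats::setNames(parities, parities), function(par)
    measurement_set(project_operators(spec, basis_spec(par, q))))
  plan <- build_dag(batch, parities)
  ctx <- list(ansatz = ansatz, ms = ms, deflation = deflation,
              refinement = refinement, backend = backend,
              master_seed = batch$seed)
  ex <- execute_dag(plan, ctx, workers = workers)
  recs <- filter_spurious(ex$records, ansatz, spec, filter)
  headline <- recs[recs$classification %in% c("bound", "resonance"), ,
                   drop = FALSE]
  structure(list(states = headline, diagnostics = recs, plan = plan,
                 schedule = ex$schedule, failed = ex$failed,
                 ansatz = ansatz, spec = spec, ms = ms),
            class = "resonance_result")
}

#' @export
print.resonance_result <- function(x, ...) {
  cat(sprintf("Resonance search: %d state(s) after filtering (%d candidate records)\n",
              nrow(x$states), nrow(x$diagnostics)))
  if (nrow(x$states)) {
    df <- x$states
    cat(sprintf("  %-6s %-5s Re(E)=%.4f  Im(E)=%+.3e  sigma2=%.2e  [%s]\n",
                df$parity, df$index, Re(df$E), Im(df$E), df$sigma2,
                df$classification))
  }
  invisible(x)
}
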