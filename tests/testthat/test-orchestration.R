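test_that("the task graph is an arborescence with the expected shape", {
  plan <- build_dag(batch_config(B = 1, N = 3), parities = "even")
  # 3 chain nodes + 3 refinement leaves + 1 pool + 1 sort
  expect_equal(nrow(plan$nodes), 8)
  types <- table(plan$nodes$type)
  expect_equal(as.vector(types[c("hermitian", "refine", "pool", "sort")]),
               c(3L, 3L, 1L, 1L))
  # every non-terminal chain node has exactly two children: the next chain
  # node and a childless refinement leaf
  for (i in 1:2) {
    kids <- plan$edges$to[plan$edges$from == sprintf("b1.even.h%d", i)]
    expect_setequal(kids, c(sprintf("b1.even.h%d", i + 1),
                            sprintf("b1.even.r%d", i)))
  }
  refine_children <- plan$edges$to[startsWith(plan$edges$from, "b1.even.r")]
  expect_true(all(refine_children == "b1.even.pool"))
  # acyclic: a topological order exists
  expect_silent(siegertq:::topological_order(plan))
})

test_that("parity splitting yields two isomorphic component graphs", {
  plan <- build_dag(batch_config(B = 2, N = 2), parities = c("even", "odd"))
  even_nodes <- plan$nodes[grepl("even", plan$nodes$id), ]
  odd_nodes <- plan$nodes[grepl("odd", plan$nodes$id), ]
  expect_equal(nrow(even_nodes), nrow(odd_nodes))
  expect_equal(table(even_nodes$type), table(odd_nodes$type))
  # edge sets map onto each other under the parity renaming
  ren <- function(x) gsub("even", "odd", x)
  even_edges <- plan$edges[grepl("even", plan$edges$from) |
                             grepl("even", plan$edges$to), ]
  expect_setequal(paste(ren(even_edges$from), ren(even_edges$to)),
                  paste(plan$edges$from, plan$edges$to)[
                    grepl("odd", plan$edges$from) |
                      grepl("odd", plan$edges$to)])
  # DOT export mentions every node
  dot <- dag_to_dot(plan)
  expect_true(all(vapply(plan$nodes$id, function(id)
    any(grepl(id, dot, fixed = TRUE)), logical(1))))
})

make_ctx <- function(q = 2, seed = 99, cfgs = list()) {
  spec <- small_spec()
  ms <- lapply(stats::setNames(c("even", "odd"), c("even", "odd")),
               function(par)
                 measurement_set(project_operators(spec, basis_spec(par, q))))
  list(ansatz = ansatz_spec(q), ms = ms,
       deflation = deflation_config(max_iter = 128),
       refinement = refinement_config(f_max = 128),
       backend = backend_config("exact"), master_seed = seed)
}

test_that("records are identical for any worker count", {
  plan <- build_dag(batch_config(B = 2, N = 2, seed = 99),
                    parities = "even")
  ctx <- make_ctx()
  r1 <- suppressWarnings(execute_dag(plan, ctx, workers = 1))
  r2 <- suppressWarnings(execute_dag(plan, ctx, workers = 4))
  expect_equal(r1$records$E, r2$records$E)
  expect_equal(r1$records$sigma2, r2$records$sigma2)
  expect_equal(r1$records$phi, r2$records$phi)
})

test_that("the scheduler respects parent-child ordering", {
  plan <- build_dag(batch_config(B = 1, N = 2, seed = 5), parities = "even")
  ctx <- make_ctx(seed = 5)
  ex <- suppressWarnings(execute_dag(plan, ctx, workers = 1))
  sched <- ex$schedule
  rownames(sched) <- sched$id
  for (k in seq_len(nrow(plan$edges))) {
    from <- plan$edges$from[k]; to <- plan$edges$to[k]
    expect_lte(sched[from, "end"], sched[to, "start"])
  }
})

test_that("a poisoned task aborts only its own chain descendants", {
  plan <- build_dag(batch_config(B = 2, N = 3, seed = 31),
                    parities = "even")
  ctx <- make_ctx(seed = 31)
  ex <- suppressWarnings(execute_dag(plan, ctx, workers = 1,
                                     fail_ids = "b1.even.h2"))
  expect_setequal(ex$failed,
                  c("b1.even.h2", "b1.even.h3", "b1.even.r2", "b1.even.r3"))
  # batch 1 still contributed its first state; batch 2 is complete
  recs <- ex$records
  expect_true(any(recs$batch == 1 & recs$index == 1))
  expect_true(any(recs$batch == 2))
  # batch 2's pool is present with its post-deduplication states
  expect_gte(nrow(ex$pools[["b2.even.pool"]]), 2)
  expect_false(any(startsWith(ex$failed, "b2.")))
})

test_that("within-run deduplication drops repeated states, pooling keeps the best", {
  a <- ansatz_spec(2)
  set.seed(7)
  th <- random_parameters(a)
  th_dup <- th + 1e-6            # numerically the same prepared state
  th_other <- random_parameters(a)
  mk <- function(batch, index, theta, sigma2) {
    r <- data.frame(batch = batch, parity = "even", index = index,
                    E = complex(real = index, imaginary = -0.01 * index),
                    sigma2 = sigma2, warning = FALSE,
                    hermitian_energy = index, stringsAsFactors = FALSE)
    r$phi <- I(list(theta))
    r
  }
  # one run with a duplicate pair: the later duplicate is dropped
  run <- rbind(mk(1, 1, th, 0.3), mk(1, 2, th_dup, 0.1),
               mk(1, 3, th_other, 0.2))
  dd <- siegertq:::dedup_run(run, a, tol = 0.8)
  expect_equal(dd$index, c(1, 3))
  # across batches the lowest-sigma2 representative of a state wins
  recs <- rbind(mk(1, 1, th, 0.3), mk(2, 1, th_dup, 0.01),
                mk(3, 1, th, 0.2), mk(1, 2, th_other, 0.5))
  pooled <- dedup_and_pool(recs, a, dedup_tol = 0.8)
  expect_equal(nrow(pooled), 2)
  expect_equal(pooled$sigma2[pooled$batch == 2], 0.01)
  # ordering by Re(E)
  expect_true(!is.unsorted(Re(pooled$E)))
  # empty input passes through
  expect_null(dedup_and_pool(NULL, a))
})

test_that("spurious-state classification follows the occupancy rules", {
  spec <- model_spec()
  q <- 2
  a <- ansatz_spec(q)
  ms <- measurement_set(project_operators(spec, basis_spec("even", q)))
  mk_rec <- function(phi, E, sigma2 = 1e-10, warning = FALSE) {
    rec <- data.frame(batch = 1, parity = "even", index = 1, E = E,
                      sigma2 = sigma2, warning = warning,
                      hermitian_energy = Re(E), stringsAsFactors = FALSE)
    rec$phi <- I(list(phi))
    rec
  }
  # a well-converged bound-like state: refine down to the lowest eigenstate
  set.seed(3)
  ch <- suppressWarnings(solve_hermitian_chain(1, a, ms,
                                               deflation_config(),
                                               backend_config()))
  r <- refine_resonance(ch[[1]]$theta, a, ms, refinement_config(),
                        backend_config())
  # at q = 2 the lowest state keeps a finite CAP-induced width, so it is
  # classified resonance; with a negligible width the same density profile
  # is classified bound
  out <- filter_spurious(mk_rec(r$phi, r$energy$E, r$sigma2), a, spec)
  expect_lt(out$occupancy, 0.05)
  expect_equal(out$classification, "resonance")
  out_b <- filter_spurious(mk_rec(r$phi,
                                  complex(real = 0.62, imaginary = -1e-8),
                                  r$sigma2), a, spec)
  expect_equal(out_b$classification, "bound")
  # a delocalized state (uniform over all even modes) has substantial
  # CAP-region occupancy; tightening the threshold flags it nonresonant
  th_mix <- rep(pi / 2, a$m)
  occ_mix <- filter_spurious(mk_rec(th_mix,
                                    complex(real = 1.5, imaginary = -0.1)),
                             a, spec)$occupancy
  strict <- filter_config(nonresonant_occupancy = occ_mix / 2)
  out2 <- filter_spurious(mk_rec(th_mix,
                                 complex(real = 1.5, imaginary = -0.1)),
                          a, spec, strict)
  expect_equal(out2$classification, "spurious-nonresonant")
  # an unconverged record with huge width is spurious-diverging
  out3 <- filter_spurious(mk_rec(r$phi,
                                 complex(real = 1, imaginary = -5),
                                 sigma2 = 1, warning = TRUE), a, spec)
  expect_equal(out3$classification, "spurious-diverging")
  # a CAP-insensitive state with moderate occupancy is spurious-indifferent
  loose <- filter_config(indifferent_occupancy = occ_mix / 2)
  out4 <- filter_spurious(mk_rec(th_mix,
                                 complex(real = 1.5, imaginary = -1e-4)),
                          a, spec, loose)
  expect_equal(out4$classification, "spurious-indifferent")
  # empty input passes through with zero rows
  expect_equal(nrow(filter_spurious(out[0, , drop = FALSE], a, spec)), 0)
})

test_that("pipeline output is reproducible from configuration and master seed", {
  cfg <- batch_config(B = 2, N = 2, seed = 12)
  r1 <- suppressWarnings(resonance_search(2, parities = "even",
                                          batch = cfg))
  r2 <- suppressWarnings(resonance_search(2, parities = "even",
                                          batch = cfg))
  expect_equal(r1$states$E, r2$states$E)
  expect_equal(r1$states$sigma2, r2$states$sigma2)
})

test_that("refinement leaves and next chain states can run concurrently", {
  # with >= 2 workers, refine-state i overlaps hermitian-state i+1 of the
  # same chain in the logged schedule
  plan <- build_dag(batch_config(B = 1, N = 3, seed = 77),
                    parities = "even")
  ctx <- make_ctx(seed = 77)
  ex <- suppressWarnings(execute_dag(plan, ctx, workers = 2))
  sched <- ex$schedule
  rownames(sched) <- sched$id
  overlaps <- vapply(1:2, function(i) {
    r <- sched[sprintf("b1.even.r%d", i), ]
    h <- sched[sprintf("b1.even.h%d", i + 1), ]
    r$start < h$end && h$start < r$end
  }, logical(1))
  expect_true(any(overlaps))
})
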