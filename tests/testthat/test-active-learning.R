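# Hamiltonian-distance selection and the active-learning loop.

toy_provider <- function(dim = 3, seed_base = 100) {
  ## deterministic pseudo-random integral features per geometry, keyed by
  ## the first coordinate -- a stand-in for real integrals in pure
  ## selection-logic tests
  function(g) {
    set.seed(seed_base + round(1e4 * g$coordinates[1, 1]))
    list(h1 = matrix(stats::rnorm(dim^2), dim),
         eri = array(stats::rnorm(dim^4), c(dim, dim, dim, dim)))
  }
}

test_that("hamiltonian_distance is a symmetric premetric with SAO invariances", {
  g1 <- h_chain(4, 1.7)
  g2 <- h_chain(4, 1.9)
  f1 <- evcont:::sao_features(g1, "sto-6g")
  f2 <- evcont:::sao_features(g2, "sto-6g")
  expect_equal(hamiltonian_distance(f1, f1), 0, tolerance = 1e-14)
  d12 <- hamiltonian_distance(f1, f2)
  expect_gt(d12, 0)
  expect_equal(d12, hamiltonian_distance(f2, f1), tolerance = 1e-12)
  ## rigid translation of one geometry alone leaves the distance unchanged
  g1t <- translate_geometry(g1, c(0.7, -1.1, 0.4))
  f1t <- evcont:::sao_features(g1t, "sto-6g")
  expect_equal(hamiltonian_distance(f1t, f2), d12, tolerance = 1e-8)
  expect_lt(hamiltonian_distance(f1t, f1), 1e-16)
})

test_that("select_next_geometry implements the argmax-min rule", {
  ## brute-force double loop on a randomized toy instance
  cand <- lapply(c(0.001, 0.002, 0.003, 0.004, 0.005),
                 function(x) geometry(c(1L, 1L), rbind(c(x, 0, 0), c(5, 0, 0))))
  train <- lapply(c(0.011, 0.012, 0.013),
                  function(x) geometry(c(1L, 1L), rbind(c(x, 0, 0), c(5, 0, 0))))
  prov <- toy_provider()
  sel <- select_next_geometry(cand, train, integral_provider = prov)
  cf <- lapply(cand, prov); tf <- lapply(train, prov)
  brute <- vapply(cf, function(c1) {
    min(vapply(tf, function(t1) hamiltonian_distance(c1, t1), 0))
  }, 0)
  expect_equal(sel$index, which.max(brute))
  expect_equal(sel$distance, max(brute), tolerance = 1e-12)
  expect_false(sel$converged)

  ## training point among candidates: its min-distance is zero
  sel2 <- select_next_geometry(c(train[1], cand[1]), train,
                               integral_provider = prov)
  expect_equal(sel2$index, 2L)

  ## all candidates equal to training points: converged flag, earliest index
  sel3 <- select_next_geometry(train, train, integral_provider = prov)
  expect_equal(sel3$index, 1L)
  expect_equal(sel3$distance, 0)
  expect_true(sel3$converged)
  expect_error(select_next_geometry(list(), train, integral_provider = prov),
               "empty")
})

test_that("batch_select returns top-scoring, deduplicated geometries", {
  prov <- toy_provider()
  pool <- lapply(seq(0.001, 0.009, by = 0.001),
                 function(x) geometry(c(1L, 1L), rbind(c(x, 0, 0), c(5, 0, 0))))
  train <- pool[1:2]
  sel <- batch_select(list(pool), train, batch_size = 3,
                      integral_provider = prov)
  expect_length(sel, 3L)
  scores <- attr(sel, "scores")
  expect_true(all(diff(scores) <= 1e-12))  # descending
  ## selected geometries are pairwise distinct under the dedup threshold
  sf <- lapply(sel, prov)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(hamiltonian_distance(sf[[i]], sf[[j]]), 1e-8)
  }
  ## batch of 1 reduces to select_next_geometry on the pool
  s1 <- batch_select(list(pool), train, batch_size = 1,
                     integral_provider = prov)
  sn <- select_next_geometry(pool, train, integral_provider = prov)
  expect_equal(s1[[1]]$coordinates, pool[[sn$index]]$coordinates)
  expect_error(batch_select(list(pool), train, batch_size = 99,
                            integral_provider = prov), "exceeds")
})

test_that("convergence_check applies the tolerance/patience rule", {
  cfg <- al_config(energy_tol = 1e-3, patience = 2)
  e0 <- c(-1.0, -1.1, -1.2)
  ## identical arrays count toward patience
  c1 <- convergence_check(e0, e0, cfg)
  expect_false(c1$converged)
  expect_equal(c1$max_lowering, 0)
  c2 <- convergence_check(e0, e0, cfg, history = c1$history)
  expect_true(c2$converged)
  ## lowerings 5e-4 then 8e-4 with tol 1e-3, patience 2: converged
  h <- convergence_check(e0, e0 - 5e-4, cfg)$history
  expect_true(convergence_check(e0, e0 - 8e-4, cfg, history = h)$converged)
  ## a 2e-3 lowering resets the count
  h2 <- convergence_check(e0, e0 - 2e-3, cfg)$history
  expect_false(convergence_check(e0, e0 - 5e-4, cfg, history = h2)$converged)
  ## variationality violation is a hard error
  expect_error(convergence_check(e0, e0 + 1e-6, cfg), "variationality")
  expect_error(convergence_check(e0, e0[1:2], cfg), "length")
})

test_that("the H2 active-learning loop converges with few training points", {
  out <- active_learn_loop(
    h_chain(2, 1.8), "sto-6g",
    md = list(dt = 10, steps = 30),
    config = al_config(energy_tol = 1e-3, patience = 2, max_training = 5),
    audit_path = withr::local_tempfile(fileext = ".jsonl"),
    verbose = FALSE)
  expect_true(out$converged)
  expect_lte(evcont:::n_training(out$training), 4L)
  ## audit log records every iteration
  expect_s3_class(out$audit, "data.frame")
  expect_true(all(c("iteration", "distance", "max_lowering") %in% names(out$audit)))
  ## lowering history obeys the variational guarantee by construction:
  ## re-evaluating with the final model never rises above earlier models
  frames <- trajectory_geometries(out$trajectory)
  e_final <- vapply(frames[seq(1, length(frames), by = 6)], function(g) {
    continuation_energy(out$training, g)
  }, 0)
  tr1 <- train_continuation(out$training$geometries[1], "sto-6g")
  e_first <- vapply(frames[seq(1, length(frames), by = 6)], function(g) {
    continuation_energy(tr1, g)
  }, 0)
  expect_true(all(e_final <= e_first + 1e-8))
  ## determinism: NVE loop reruns identically
  out2 <- active_learn_loop(
    h_chain(2, 1.8), "sto-6g",
    md = list(dt = 10, steps = 30),
    config = al_config(energy_tol = 1e-3, patience = 2, max_training = 5))
  expect_equal(out2$training$energies, out$training$energies, tolerance = 1e-12)
  expect_equal(out2$trajectory$epot, out$trajectory$epot, tolerance = 1e-12)
})
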