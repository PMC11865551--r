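## Active learning of training geometries. New training points are picked
## where the SAO-basis Hamiltonian has moved furthest (least squares) from
## every Hamiltonian already in the training set — since the ground state is
## uniquely determined by the Hamiltonian, this is a faithful, invariance-
## respecting novelty measure. Convergence is monitored through the
## variational guarantee: enlarging the training set can only lower the
## inferred surface.

#' Active-learning configuration
#'
#' @param energy_tol convergence tolerance on the maximum trajectory-energy
#'   lowering per iteration (hartree, default 1e-3)
#' @param patience consecutive below-tolerance iterations required (default 2)
#' @param batch_size geometries added per selection round (default 1)
#' @param subsample trajectories subsampled in ensemble batch selection
#' @param max_training hard cap on training-set size
#' @return list of class `al_config`
#' @export
al_config <- function(energy_tol = 1e-3, patience = 2L, batch_size = 1L,
                      subsample = NULL, max_training = 12L) {
  if (energy_tol <= 0) stop("energy_tol must be positive")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(energy_tol = energy_tol, patience = as.integer(patience),
                 batch_size = as.integer(batch_size), subsample = subsample,
                 max_training = as.integer(max_training)),
            class = "al_config")
}

## SAO-basis integral features of a geometry, for the distance metric.
sao_features <- function(geom, basis_name) {
  ao <- compute_ao_integrals(geom, basis_name)
  sao <- rotate_to_sao(ao, lowdin_transform(ao$overlap), with_k = FALSE)
  list(h1 = sao$h1_sao, eri = sao$eri_sao)
}

.as_features <- function(x) {
  if (inherits(x, "sao_integrals")) list(h1 = x$h1_sao, eri = x$eri_sao) else x
}

#' Hamiltonian distance between two geometries
#'
#' `D = sum_ij |h1_ij(R) - h1_ij(R')|^2 + 1/2 sum_ijkl |h2(R) - h2(R')|^2`
#' evaluated on SAO-basis integrals, so the measure inherits the translation
#' and rotation invariance of the continuation itself.
#'
#' @param ints_a,ints_b `sao_integrals` objects (or `list(h1, eri)` features)
#'   expressed in their own geometries' SAO bases with identical ordering
#' @return non-negative distance
#' @export
hamiltonian_distance <- function(ints_a, ints_b) {
  a <- .as_features(ints_a); b <- .as_features(ints_b)
  if (!all(dim(a$h1) == dim(b$h1))) stop("basis size mismatch")
  sum((a$h1 - b$h1)^2) + 0.5 * sum((a$eri - b$eri)^2)
}

## distance of every candidate to its closest training point
.min_distances <- function(cand_feats, train_feats) {
  vapply(cand_feats, function(cf) {
    min(vapply(train_feats, function(tf) hamiltonian_distance(cf, tf), 0))
  }, 0)
}

#' Select the next training geometry from a trajectory
#'
#' Returns the candidate maximizing the distance to its closest training
#' configuration (argmax-min rule); ties break to the earliest frame.
#'
#' @param trajectory_geometries list of candidate [geometry()]
#' @param training_geometries list of current training [geometry()]
#' @param integral_provider `function(geometry) -> sao_integrals` or feature
#'   list; defaults require `basis_name`
#' @param basis_name basis for the default provider
#' @return list with `index` (1-based), `distance`, and `converged` (TRUE
#'   when every candidate coincides with a training point, distance 0)
#' @export
select_next_geometry <- function(trajectory_geometries, training_geometries,
                                 integral_provider = NULL, basis_name = NULL) {
  if (length(trajectory_geometries) == 0) stop("empty candidate list")
  if (length(training_geometries) == 0) stop("empty training list")
  if (is.null(integral_provider)) {
    if (is.null(basis_name)) stop("need integral_provider or basis_name")
    integral_provider <- function(g) sao_features(g, basis_name)
  }
  cf <- lapply(trajectory_geometries, integral_provider)
  tf <- lapply(training_geometries, integral_provider)
  d <- .min_distances(cf, tf)
  idx <- which.max(d)  # which.max takes the earliest maximizer
  list(index = idx, distance = d[idx], converged = d[idx] <= 0)
}

#' Batched selection over an ensemble of trajectories
#'
#' Subsamples `subsample` trajectories, scores every frame by its minimum
#' Hamiltonian distance to the training set, and returns the top
#' `batch_size` frames, skipping candidates closer than `dedup_threshold`
#' to an already-selected frame.
#'
#' @param ensemble_trajectories list of `trajectory` objects (or lists of
#'   geometries)
#' @param training_geometries list of training [geometry()]
#' @param batch_size number of geometries to return (>= 1)
#' @param subsample number of trajectories to subsample (NULL = all)
#' @param seed subsampling seed
#' @param integral_provider,basis_name as in [select_next_geometry()]
#' @param dedup_threshold Hamiltonian-distance below which two candidates
#'   count as identical (default 1e-8)
#' @return list of selected [geometry()], attribute `scores`
#' @export
batch_select <- function(ensemble_trajectories, training_geometries,
                         batch_size, subsample = NULL, seed = 1L,
                         integral_provider = NULL, basis_name = NULL,
                         dedup_threshold = 1e-8) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (is.null(integral_provider)) {
    if (is.null(basis_name)) stop("need integral_provider or basis_name")
    integral_provider <- function(g) sao_features(g, basis_name)
  }
  trajs <- ensemble_trajectories
  if (!is.null(subsample) && subsample < length(trajs)) {
    set.seed(as.integer(seed))
    trajs <- trajs[sort(sample.int(length(trajs), subsample))]
  }
  pool <- list()
  for (tr in trajs) {
    gs <- if (inherits(tr, "trajectory")) trajectory_geometries(tr) else tr
    pool <- c(pool, gs)
  }
  if (batch_size > length(pool)) {
    stop("batch_size (", batch_size, ") exceeds candidate pool (",
         length(pool), ")")
  }
  cf <- lapply(pool, integral_provider)
  tf <- lapply(training_geometries, integral_provider)
  scores <- .min_distances(cf, tf)
  ord <- order(-scores)
  sel <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in sel) {
      if (hamiltonian_distance(cf[[i]], cf[[j]]) < dedup_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) sel <- c(sel, i)
    if (length(sel) == batch_size) break
  }
  out <- pool[sel]
  attr(out, "scores") <- scores[sel]
  out
}

#' Convergence check on the variational lowering of a trajectory PES
#'
#' Compares inferred energies from the previous (smaller) and current
#' (larger) training sets at identical geometries. The variational guarantee
#' means the newer energies can only be lower; a rise beyond 1e-8 hartree
#' signals an implementation bug and raises an error. Convergence is
#' declared when the maximum lowering stays below `config$energy_tol` for
#' `config$patience` consecutive iterations.
#'
#' @param pes_prev,pes_new equal-length energy vectors along one trajectory
#' @param config an [al_config()]
#' @param history numeric vector of previous max-lowerings
#' @return list with `converged`, `max_lowering`, updated `history`
#' @export
convergence_check <- function(pes_prev, pes_new, config, history = numeric(0)) {
  if (length(pes_prev) != length(pes_new)) stop("energy arrays differ in length")
  rise <- max(pes_new - pes_prev)
  if (rise > 1e-8) {
    stop("variationality violation: inferred energy rose by ",
         format(rise), " hartree with a larger training set")
  }
  max_lowering <- max(pes_prev - pes_new)
  history <- c(history, max_lowering)
  n <- length(history)
  converged <- n >= config$patience &&
    all(history[(n - config$patience + 1L):n] < config$energy_tol)
  list(converged = converged, max_lowering = max_lowering, history = history)
}

#' Active-learning loop for molecular dynamics training sets
#'
#' Train at the initial geometry, run MD on the inferred surface, add the
#' trajectory geometry whose SAO Hamiltonian is furthest from the training
#' set, re-train, and repeat until the surface stops improving (per
#' [convergence_check()]) or `max_training` is reached.
#'
#' @param initial starting [geometry()]
#' @param basis_name built-in basis
#' @param md list of [run_bomd()] arguments (dt, steps, ensemble, ...)
#' @param config an [al_config()]
#' @param solver_tol Davidson tolerance for training solves
#' @param audit_path optional path for a JSON-lines audit log
#' @param verbose print progress
#' @return list with `training` (`training_set`), `trajectory` (final),
#'   `audit` (data.frame), `converged`
#' @export
active_learn_loop <- function(initial, basis_name, md = list(),
                              config = al_config(), solver_tol = 1e-9,
                              audit_path = NULL, verbose = FALSE) {
  md_args <- utils::modifyList(list(dt = 5, steps = 100L, ensemble = "NVE"), md)
  fs <- fci_training_state(initial, basis_name, tol = solver_tol)
  training <- add_training_state(training_set(), fs$state, initial, fs$energy,
                                 basis_name = basis_name)
  prev_training <- NULL
  history <- numeric(0)
  audit <- list()
  traj <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pes <- continuation_pes(training)
    traj <- do.call(run_bomd, c(list(initial = initial, pes = pes), md_args))
    frames <- trajectory_geometries(traj)
    ## one SAO build per frame serves the convergence comparison, the
    ## selection metric and the current-model energies alike
    saos <- lapply(frames, function(g) {
      ao <- compute_ao_integrals(g, basis_name)
      rotate_to_sao(ao, lowdin_transform(ao$overlap),
                    n_elec = training$n_elec)
    })
    e_new <- vapply(saos, function(s) infer_state(training, s)$energy, 0)
    max_lowering <- NA_real_
    if (!is.null(prev_training)) {
      e_prev <- vapply(saos, function(s) infer_state(prev_training, s)$energy, 0)
      chk <- convergence_check(e_prev, e_new, config, history)
      history <- chk$history
      max_lowering <- chk$max_lowering
      converged <- chk$converged
    }
    sel <- select_next_geometry(frames, training$geometries,
                                integral_provider = .as_features_provider(saos, frames, basis_name))
    rec <- list(iteration = iter, n_training = n_training(training),
                selected_frame = sel$index, distance = sel$distance,
                max_lowering = max_lowering, converged = converged)
    audit[[iter]] <- rec
    if (!is.null(audit_path)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = audit_path, append = iter > 1L)
    }
    if (verbose) {
      message(sprintf("AL iter %d: N = %d, max_lowering = %s, next frame %d (D = %.3e)",
                      iter, n_training(training),
                      ifelse(is.na(max_lowering), "-", format(max_lowering, digits = 3)),
                      sel$index, sel$distance))
    }
    if (converged || n_training(training) >= config$max_training) break
    ## solve the selected geometry; on failure fall back to the next-ranked
    gsel <- frames[[sel$index]]
    prev_training <- training
    newstate <- tryCatch(
      fci_training_state(gsel, basis_name, tol = solver_tol,
                         guess = continuation_guess(training,
                                                    saos[[sel$index]])),
      error = function(e) NULL)
    if (is.null(newstate)) {
      warning("training solve failed at selected geometry; trying next-ranked")
      d <- .min_distances(lapply(saos, .as_features),
                          lapply(training$geometries,
                                 function(g) sao_features(g, basis_name)))
      for (i in order(-d)) {
        if (i == sel$index) next
        newstate <- tryCatch(
          fci_training_state(frames[[i]], basis_name, tol = solver_tol),
          error = function(e) NULL)
        if (!is.null(newstate)) { gsel <- frames[[i]]; break }
      }
      if (is.null(newstate)) stop("no selectable geometry could be solved")
    }
    training <- add_training_state(training, newstate$state, gsel,
                                   newstate$energy, basis_name = basis_name)
  }
  audit_df <- do.call(rbind, lapply(audit, function(r) {
    data.frame(iteration = r$iteration, n_training = r$n_training,
               selected_frame = r$selected_frame, distance = r$distance,
               max_lowering = r$max_lowering, converged = r$converged)
  }))
  ## the RDM workspace can be large (Nd x L^2); hand the memory back
  release_fci_workspace()
  gc(verbose = FALSE)
  list(training = training, trajectory = traj, audit = audit_df,
       converged = converged)
}

## provider that reuses precomputed per-frame SAO integrals and falls back
## to a fresh build for geometries outside the frame cache
.as_features_provider <- function(saos, frames, basis_name) {
  key <- vapply(frames, function(g) paste(signif(g$coordinates, 15), collapse = ","), "")
  function(g) {
    k <- paste(signif(g$coordinates, 15), collapse = ",")
    i <- match(k, key)
    if (!is.na(i)) return(.as_features(saos[[i]]))
    sao_features(g, basis_name)
  }
}
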