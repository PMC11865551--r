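## Versioned JSON persistence of continuation models. Everything needed for
## inference (Gamma tensors, overlaps, energies, geometries, metadata) round
## trips losslessly; CI amplitudes are deliberately not serialized, so a
## loaded model can be used for inference but not extended.

.MODEL_SCHEMA_VERSION <- 1L

#' Save a continuation model to disk
#'
#' @param training a `training_set`
#' @param path output path (JSON)
#' @export
save_model <- function(training, path) {
  N <- n_training(training)
  if (N < 1) stop("refusing to save an empty training set")
  L <- training$L
  payload <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    basis_name = training$basis_name,
    L = training$L, n_elec = training$n_elec,
    n_alpha = training$n_alpha, n_beta = training$n_beta,
    n_states = N,
    energies = training$energies,
    overlap = as.numeric(training$overlap),
    gamma1 = lapply(training$gamma1, as.numeric),
    gamma2 = lapply(training$gamma2, as.numeric),
    geometries = lapply(training$geometries, function(g) list(
      atomic_numbers = g$atomic_numbers,
      coordinates = as.numeric(g$coordinates),
      charge = g$charge, masses = g$masses
    ))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a continuation model from disk
#'
#' @param path JSON file written by [save_model()]
#' @return a `training_set` (inference-ready; cannot be extended because CI
#'   amplitudes are not stored on disk)
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  stop("failed to read model file (no partial model loaded): ",
                       conditionMessage(e))
                })
  need <- c("schema_version", "L", "n_states", "overlap", "gamma2", "energies")
  if (!all(need %in% names(p))) {
    stop("model file is incomplete (no partial model loaded); missing: ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  if (p$schema_version != .MODEL_SCHEMA_VERSION) {
    stop("model schema version ", p$schema_version, " does not match ",
         .MODEL_SCHEMA_VERSION, "; explicit migration required")
  }
  N <- p$n_states
  L <- p$L
  ts <- training_set()
  ts$basis_name <- p$basis_name
  ts$L <- as.integer(L)
  ts$n_elec <- as.integer(p$n_elec)
  ts$n_alpha <- as.integer(p$n_alpha)
  ts$n_beta <- as.integer(p$n_beta)
  ts$energies <- as.numeric(p$energies)
  ts$overlap <- matrix(as.numeric(p$overlap), N, N)
  ts$gamma1 <- lapply(p$gamma1, function(v) matrix(as.numeric(v), L, L))
  ts$gamma2 <- lapply(p$gamma2, function(v) array(as.numeric(v), c(L, L, L, L)))
  if (length(ts$gamma2) != N * N) {
    stop("model file is truncated (no partial model loaded)")
  }
  ts$geometries <- lapply(seq_len(N), function(i) {
    g <- if (is.data.frame(p$geometries)) {
      lapply(p$geometries, `[[`, i)
    } else {
      p$geometries[[i]]
    }
    geometry(unlist(g$atomic_numbers),
             matrix(unlist(g$coordinates), ncol = 3),
             charge = if (is.null(g$charge)) 0L else unlist(g$charge)[1],
             masses = unlist(g$masses))
  })
  ts$ci <- list()
  ts
}
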