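# RNG-state bookkeeping: seeded functions restore the caller's stream so a
# call with an explicit seed never perturbs surrounding code.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# One global seed fans out to per-stage seeds by fixed offsets, keeping each
# stage independently reproducible. Offsets are arbitrary but frozen.
.stage_offsets <- c(graph = 0L, gcn = 101L, deepwalk = 211L,
                    negatives = 307L, cv = 401L, classifier = 503L,
                    synth = 601L)

stage_seed <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) + off) %% .Machine$integer.max)
}
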