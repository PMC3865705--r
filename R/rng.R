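# Named RNG substreams derived from a session seed.
#
# Each generator component (trajectory, unit assignment, spiking) draws from
# its own substream so that, e.g., changing the number of units never perturbs
# the trajectories. Substream seeds are drawn once from the master seed in a
# fixed order; per-trial / per-unit seeds are small deterministic offsets kept
# below 2^31 - 1.

.opm_streams <- c("trajectory", "units", "spikes", "behavior")

stream_seeds <- function(seed) {
  local_seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(.opm_streams))
  names(s) <- .opm_streams
  s
}

substream_seed <- function(stream_seed, index) {
  as.integer((as.double(stream_seed) + as.double(index) * 1000003) %%
               (.Machine$integer.max - 1)) + 1L
}

# Set the RNG state for the calling frame, restoring the previous state when
# that frame exits.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (is.null(.opm_old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", .opm_old_seed, envir = globalenv())
  }), add = TRUE), envir = envir)
  assign(".opm_old_seed", old, envir = envir)
  set.seed(seed)
  invisible(seed)
}
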