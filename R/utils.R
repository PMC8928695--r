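# internal: run `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb user randomness
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal: binary VolumeGrid from a logical array on a reference grid
maskVolume <- function(like, logicalArray) {
  withData(like, array(as.double(logicalArray), dim(like@data)))
}

# internal: logical array from a binary VolumeGrid
asMaskArray <- function(v) v@data > 0.5

# internal: bounding box (lo, hi) of a logical array; NULL if empty
boundingBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}
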