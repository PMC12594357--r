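# internal helpers

# run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream so placement helpers don't perturb user simulations
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("poreskel_config_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("poreskel_numeric_error", "error")))
}

# coords (n x 3 matrix, 1-based) of TRUE voxels, in lexicographic (i,j,k) order
voxel_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("i", "j", "k")
  w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
}

# order labels 1..n by the lexicographic (i,j,k) minimum voxel of each label
relabel_lexicographic <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(lab)
  d <- dim(lab)
  idx <- which(lab > 0L)
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  key <- (as.double(i) * (d[2] + 1) + j) * (d[3] + 1) + k
  minkey <- rep(Inf, n)
  l <- lab[idx]
  o <- order(key)
  firsts <- o[!duplicated(l[o])]        # first (lexicographically smallest) voxel per label
  minkey[l[firsts]] <- key[firsts]
  perm <- integer(n)
  perm[order(minkey)] <- seq_len(n)
  out <- lab
  out[idx] <- perm[l]
  out
}
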