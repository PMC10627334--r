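# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Rounded percentage as printed in reports (nearest integer).
.percent <- function(count, total) as.integer(round(100 * count / total))

# Row-standardize a matrix: center each row and scale to unit Euclidean norm.
# Rows with zero spread come back as all-zero (flagged by the caller if needed).
.row_unit <- function(m) {
  ctr <- m - rowMeans(m)
  nrm <- sqrt(rowSums(ctr^2))
  ok <- nrm > 0
  ctr[ok, ] <- ctr[ok, , drop = FALSE] / nrm[ok]
  ctr[!ok, ] <- 0
  list(z = ctr, ok = ok)
}

# Filter features by fraction of non-missing values and impute the remaining
# missing cells with the feature's own mean (the row-mean imputation used by
# the PLS and clustering steps). Returns the imputed matrix and the kept index.
.filter_impute_rows <- function(values, valid_fraction) {
  frac <- rowMeans(!is.na(values))
  keep <- which(frac >= valid_fraction & frac > 0)
  v <- values[keep, , drop = FALSE]
  if (anyNA(v)) {
    rm_ <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm_[idx[, 1]]
  }
  list(values = v, keep = keep)
}
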