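# Internal numerical helpers shared across modules.

# Sliding-window box sum of a numeric matrix using an integral image.
# Window of side `k` (odd) centered at each pixel, clipped at the image border
# (pixels outside the image contribute zero). Exact for integer-valued input.
box_sum <- function(m, k) {
  stopifnot(is.matrix(m), k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(m)
  h <- k %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  s <- matrix(0, nr + 1L, nc + 1L)
  s[-1L, -1L] <- apply(m, 2L, cumsum)
  s[-1L, ] <- t(apply(s[-1L, , drop = FALSE], 1L, cumsum))
  r2 <- pmin(seq_len(nr) + h, nr)
  r1 <- pmax(seq_len(nr) - h, 1L)
  c2 <- pmin(seq_len(nc) + h, nc)
  c1 <- pmax(seq_len(nc) - h, 1L)
  s[r2 + 1L, c2 + 1L, drop = FALSE] - s[r1, c2 + 1L, drop = FALSE] -
    s[r2 + 1L, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

# Gaussian smoothing of a plain matrix; sigma in pixels, sigma = 0 is identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions must lie within [1, nrow] x [1, ncol]; returns NA outside.
bilinear_interp <- function(m, row, col) {
  nr <- nrow(m)
  nc <- ncol(m)
  inside <- row >= 1 & row <= nr & col >= 1 & col <= nc & is.finite(row) & is.finite(col)
  out <- rep(NA_real_, length(row))
  if (!any(inside)) return(out)
  r <- row[inside]
  c <- col[inside]
  r0 <- pmin(floor(r), nr - 1)
  c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0
  fc <- c - c0
  i00 <- cbind(r0, c0)
  i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1)
  i11 <- cbind(r0 + 1, c0 + 1)
  out[inside] <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i10] +
    (1 - fr) * fc * m[i01] + fr * fc * m[i11]
  out
}

# Matrix -> long tibble (row, col, value), used by the autoplot methods.
matrix_to_tibble <- function(m, value_name = "value") {
  idx <- which(!is.na(m) | is.na(m))  # all cells
  out <- tibble::tibble(
    row = as.integer((idx - 1L) %% nrow(m) + 1L),
    col = as.integer((idx - 1L) %/% nrow(m) + 1L)
  )
  out[[value_name]] <- as.vector(m)
  out
}
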