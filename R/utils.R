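#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr` and
#' restores the previous state, so library functions never perturb a user's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Separable Gaussian blur of a matrix
#'
#' Convolution is performed per dimension with a row-normalized band matrix,
#' which keeps constants exactly invariant at image borders (equivalent to
#' replicate-style boundary handling) and remains well defined when the
#' kernel support exceeds the image, as it routinely does for the
#' large-sigma background estimation used on cropped CT stacks.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return blurred matrix of the same shape.
#' @export
gauss_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (!all(is.finite(img))) stop("gauss_blur: input contains non-finite values")
  blur_1d <- function(n) {
    # n x n operator: row i holds the truncated, renormalized kernel centred at i
    half <- min(n - 1L, as.integer(ceiling(3 * sigma)))
    offs <- (-half):half
    k <- exp(-offs^2 / (2 * sigma^2))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + offs
      keep <- j >= 1L & j <= n
      M[i, j[keep]] <- k[keep] / sum(k[keep])
    }
    M
  }
  Mr <- blur_1d(nrow(img))
  Mc <- blur_1d(ncol(img))
  Mr %*% img %*% t(Mc)
}

#' Draw from a symmetric truncated normal
#'
#' Resamples until all draws fall within `mean +/- trunc_sd * sd` and above
#' `lower`. Used for object size laws, where unbounded tails would produce
#' non-physical objects.
#' @keywords internal
rnorm_trunc <- function(n, mean, sd, trunc_sd = 2, lower = 0) {
  lo <- max(lower, mean - trunc_sd * sd)
  hi <- mean + trunc_sd * sd
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
    guard <- guard + 1L
    if (guard > 1000L) stop("rnorm_trunc: truncation bounds reject all draws")
  }
  out[seq_len(n)]
}

# rotation matrix about a single axis of the (z, y, x) frame, angle in degrees
rot3 <- function(axis = c("z", "y", "x"), deg) {
  axis <- match.arg(axis)
  th <- deg * pi / 180
  c3 <- cos(th); s3 <- sin(th)
  # coordinates ordered (z, y, x)
  switch(axis,
    z = matrix(c(1, 0, 0,  0, c3, -s3,  0, s3, c3), 3, 3, byrow = TRUE),
    y = matrix(c(c3, 0, s3,  0, 1, 0,  -s3, 0, c3), 3, 3, byrow = TRUE),
    x = matrix(c(c3, -s3, 0,  s3, c3, 0,  0, 0, 1), 3, 3, byrow = TRUE))
}

# uniformly random 3D rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
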