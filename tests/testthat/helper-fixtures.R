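## in-code fixtures shared across the suite

## horizontal bar mask (h x w px) at an offset inside an n x n frame
barMask <- function(n = 60, rows = 30:32, cols = 5:54) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

## Y-shaped mask: one horizontal arm plus two diagonal arms
yMask <- function(n = 80) {
  m <- matrix(FALSE, n, n)
  m[40:41, 10:40] <- TRUE
  for (i in 0:25) {
    m[40 - i, 40 + i] <- TRUE; m[41 - i, 40 + i] <- TRUE
    m[40 + i, 40 + i] <- TRUE; m[41 + i, 40 + i] <- TRUE
  }
  m
}

## brute-force flood fill labeling (oracle for labelComponents)
floodLabel <- function(mask, connectivity = 8) {
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (r in seq_len(nrow(mask))) for (cl in seq_len(ncol(mask))) {
    if (!mask[r, cl] || lab[r, cl] > 0L) next
    k <- k + 1L
    queue <- list(c(r, cl))
    lab[r, cl] <- k
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(offs))) {
        nr <- cur[1] + offs[i, 1]; nc <- cur[2] + offs[i, 2]
        if (nr >= 1 && nr <= nrow(mask) && nc >= 1 && nc <= ncol(mask) &&
            mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- k
          queue[[length(queue) + 1]] <- c(nr, nc)
        }
      }
    }
  }
  lab
}

## brute-force constriction scan (oracle for callConstrictions): every local
## minimum, reference peak = larger of the nearest flanking maxima
## (endpoints count when they rise above their neighbour)
bruteConstrictions <- function(y, arc = seq_along(y) - 1, thr = 0.40) {
  n <- length(y)
  maxima <- integer(0)
  if (y[1] > y[2]) maxima <- c(maxima, 1L)
  for (i in 2:(n - 1)) if (y[i] > y[i - 1] && y[i] >= y[i + 1])
    maxima <- c(maxima, i)
  if (y[n] > y[n - 1]) maxima <- c(maxima, n)
  out <- data.frame(positionUm = numeric(), dipFraction = numeric())
  for (i in 2:(n - 1)) {
    if (!(y[i] < y[i - 1] && y[i] <= y[i + 1])) next
    left <- maxima[maxima < i]; right <- maxima[maxima > i]
    if (length(left) == 0 && length(right) == 0) next
    peak <- max(c(if (length(left)) y[max(left)],
                  if (length(right)) y[min(right)]))
    if (peak <= 0) next
    dip <- 1 - y[i] / peak
    if (dip >= thr)
      out[nrow(out) + 1L, ] <- list(arc[i], dip)
  }
  out
}

## smoothed random intensity profile (for oracle-equivalence checks)
randomSmoothProfile <- function(n = 60) {
  raw <- 100 + 80 * sin(seq(0, runif(1, 2, 9), length.out = n) +
                        runif(1, 0, 6)) + rnorm(n, 0, 25)
  y <- stats::filter(pmax(raw, 5), rep(1 / 5, 5), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- y[!is.na(y)][c(1, sum(!is.na(y)))][c(1, 1, 2, 2)][seq_len(sum(is.na(y)))]
  pmax(y, 1)
}

## PunctaSet built directly from micrometre coordinates
punctaAt <- function(x, y, cal = Calibration(), nFrames = 24L,
                     role = "puncta") {
  px <- cal@pixelSize
  pu <- data.frame(id = seq_along(x), role = rep(role, length(x)),
                   row = y / px + 0.5, col = x / px + 0.5,
                   persistence = rep(1, length(x)),
                   nFrames = rep(nFrames, length(x)),
                   xUm = x, yUm = y)
  new("PunctaSet", puncta = pu, tracks = list(),
      nFramesMovie = as.integer(nFrames), calibration = cal)
}
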