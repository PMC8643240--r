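# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive nested loops and base set
# operations, and share no code with the package internals.

# Exhaustive cross-correlation, valid padding, stride 1.
# x: (H, W, Cin) array; kernels: (kh, kw, Cin, Cout); bias: length Cout.
convOracle <- function(x, kernels, bias = NULL) {
  kd <- dim(kernels)
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- H - kd[1] + 1L; Wo <- W - kd[2] + 1L
  out <- array(0, c(Ho, Wo, kd[4]))
  for (p in seq_len(kd[4])) for (r in seq_len(Ho)) for (cc in seq_len(Wo)) {
    acc <- 0
    for (b in seq_len(kd[3])) for (dh in seq_len(kd[1]))
      for (dw in seq_len(kd[2]))
        acc <- acc + kernels[dh, dw, b, p] * x[r + dh - 1L, cc + dw - 1L, b]
    out[r, cc, p] <- acc + if (is.null(bias)) 0 else bias[p]
  }
  out
}

# Explicit window-mean pooling on a (H, W) matrix.
poolOracle <- function(x, w) {
  Ho <- nrow(x) %/% w; Wo <- ncol(x) %/% w
  out <- matrix(0, Ho, Wo)
  for (r in seq_len(Ho)) for (cc in seq_len(Wo))
    out[r, cc] <- mean(x[(r - 1L) * w + seq_len(w),
                         (cc - 1L) * w + seq_len(w)])
  out
}

# Set-arithmetic Dice on coordinate matrices.
diceOracle <- function(M, N) {
  kM <- unique(complex(real = M[, 1], imaginary = M[, 2]))
  kN <- unique(complex(real = N[, 1], imaginary = N[, 2]))
  2 * length(intersect(kM, kN)) / (length(kM) + length(kN))
}

# O(|A||B|) double-loop directed Hausdorff.
directedHausdorffOracle <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

hausdorffOracle <- function(M, N) {
  max(directedHausdorffOracle(M, N), directedHausdorffOracle(N, M))
}

# Pearson chi-square by explicit O/E loops.
chisqOracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    stat <- stat + (tab[i, j] - E[i, j])^2 / E[i, j]
  stat
}

# Random pixel set of up to maxN distinct points on a grid.
randomPixelSet <- function(n, extent = 40L) {
  idx <- sample.int(extent * extent, n)
  cbind(row = (idx - 1L) %/% extent + 1L, col = (idx - 1L) %% extent + 1L)
}

# Small lesion-free phantom batch for network tests.
makePhantomBatch <- function(n, params = PhantomParams(), seedBase = 1L) {
  ph <- lapply(seq_len(n),
               function(i) generatePhantom(params, deriveSeed(seedBase, i)))
  list(images = lapply(ph, `[[`, "image"),
       masks = lapply(ph, `[[`, "mask"))
}
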