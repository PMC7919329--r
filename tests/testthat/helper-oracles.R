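# Brute-force oracles and small fixture builders shared across tests.

# Per-pixel double-loop confusion tally (the independent oracle for the
# vectorized metrics).
loopConfusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1
      else if (p == 0 && t == 0) tn <- tn + 1
      else if (p == 1 && t == 0) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

randomMask <- function(h, w, p = 0.3) {
  matrix((runif(h * w) < p) * 1, h, w)
}

# Small stack of phantom slices with the requested target masks.
phantomStack <- function(n, size = 32, seed = 1,
                         target = c("liver", "tumor"),
                         tumorProbability = 1) {
  target <- match.arg(target)
  set.seed(seed)
  cfg <- phantomConfig(imageSize = size,
                       tumorProbability = tumorProbability)
  imgs <- array(0, c(size, size, n))
  msks <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    sl <- generateSlice(cfg)
    imgs[, , i] <- sl$image
    msks[, , i] <- if (target == "liver") sl$liverMask else sl$tumorMask
  }
  list(images = imgs, masks = msks)
}

# Layer-by-layer parameter census from first principles: the independent
# oracle for countParameters(). conv = k^2*cin*f + f; BN = 2f;
# up-convolution = 2*2*cin*f + f.
censusParameters <- function(depth, base, k = 3, inCh = 1, outCh = 1,
                             bottleneckDouble = TRUE) {
  convP <- function(k, cin, f) k * k * cin * f + f
  total <- 0
  cin <- inCh
  filt <- base * 2^(0:(depth - 1))
  for (i in seq_len(depth)) {
    f <- filt[i]
    total <- total + convP(k, cin, f) + 2 * f + convP(k, f, f) + 2 * f
    cin <- f
  }
  fb <- if (bottleneckDouble) base * 2^depth else base * 2^(depth - 1)
  total <- total + convP(k, cin, fb) + 2 * fb + convP(k, fb, fb) + 2 * fb
  cin <- fb
  for (i in rev(seq_len(depth))) {
    f <- filt[i]
    total <- total + convP(2, cin, f) +          # transposed conv
      convP(k, 2 * f, f) + 2 * f + convP(k, f, f) + 2 * f
    cin <- f
  }
  total + convP(1, cin, outCh)
}
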