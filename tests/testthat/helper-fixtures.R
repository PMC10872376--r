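# shared fixtures built in code

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digital disk mask of radius r centered in a (2r+21)^2 image
diskMask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  matrix((idx$i - c0)^2 + (idx$j - c0)^2 <= r^2, n, n)
}

# one-gland slide spec: circular lumen radius r, ring thickness t
oneGlandSpec <- function(r = 50, t = 20, mpp = 1, margin = 25, seed = 1,
                         class = "G3", noiseSd = 0) {
  side <- 2 * (r + t) + 2 * margin + 40
  ctr <- (side + 1) / 2
  syntheticSlideSpec(side, side, micronsPerPixel = mpp,
                     glands = list(glandSpec(c(ctr, ctr), c(r, r), t,
                                             annotationClass = class)),
                     backgroundMargin = margin, seed = seed, noiseSd = noiseSd)
}

# independent product-limit oracle (censored subjects leave risk set after
# tied event times)
kmOracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (k in seq_along(ut)) {
    atRisk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / atRisk)
    out$survival[k] <- s
  }
  out
}

# brute-force AUC over all positive-negative pairs (ties count 1/2)
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# step-up BH oracle by direct enumeration of the rejection rule
bhOracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}
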