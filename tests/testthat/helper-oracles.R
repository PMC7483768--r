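# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately use plain elementwise loops so they share no
# code with the implementation they check.

# naive per-pixel summation of the weighted soft Dice loss
naive_dice <- function(y, yhat, w, eps) {
  d <- dim(y)
  P <- if (length(d) == 4) d[4] else 1
  K <- if (length(d) == 4) d[3] else d[length(d)]
  y <- array(y, dim = c(prod(d) / (K * P), K, P))
  yhat <- array(yhat, dim = dim(y))
  total <- 0
  for (p in seq_len(P)) {
    for (l in seq_len(K)) {
      num <- 0
      den <- eps
      for (i in seq_len(dim(y)[1])) {
        num <- num + 2 * y[i, l, p] * yhat[i, l, p]
        den <- den + y[i, l, p] + yhat[i, l, p]
      }
      total <- total + w[l] * num / den
    }
  }
  -total / P
}

naive_specificity <- function(y, yhat, w, eps) {
  d <- dim(y)
  P <- if (length(d) == 4) d[4] else 1
  K <- if (length(d) == 4) d[3] else d[length(d)]
  y <- array(y, dim = c(prod(d) / (K * P), K, P))
  yhat <- array(yhat, dim = dim(y))
  total <- 0
  for (p in seq_len(P)) {
    for (l in seq_len(K)) {
      num <- 0
      den <- eps
      for (i in seq_len(dim(y)[1])) {
        num <- num + (1 - y[i, l, p]) * (1 - yhat[i, l, p])
        den <- den + 1 - yhat[i, l, p]
      }
      total <- total + w[l] * num / den
    }
  }
  -total / P
}

# random soft probability tensors (yhat a softmax, y one-hot)
random_loss_pair <- function(npx = 24, K = 3, P = 2) {
  z <- array(rnorm(npx * K * P), dim = c(npx, K, P))
  yhat <- apply(z, c(1, 3), function(v) exp(v) / sum(exp(v)))
  yhat <- aperm(yhat, c(2, 1, 3))
  y <- array(0, dim = c(npx, K, P))
  for (p in seq_len(P)) {
    cls <- sample(K, npx, replace = TRUE)
    y[cbind(seq_len(npx), cls, p)] <- 1
  }
  # canonical (H, W, K, P) layout with a single-column spatial grid
  dim(y) <- c(npx, 1, K, P)
  dim(yhat) <- c(npx, 1, K, P)
  list(y = y, yhat = yhat)
}

# probability map made of separated smooth bumps: superlevel sets of each
# component stay connected at every threshold, the shape detection maps have
# in practice
bump_map <- function(H = 40, W = 60, n_bumps = 3, radius = c(3, 6)) {
  out <- matrix(0, H, W)
  placed <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(placed) < n_bumps && tries < 200) {
    tries <- tries + 1
    r <- runif(1, radius[1], radius[2])
    cr <- runif(1, r + 1, H - r - 1)
    cc <- runif(1, r + 1, W - r - 1)
    if (nrow(placed) > 0 &&
        any(sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2) <
            placed[, 3] + r + 3)) next
    placed <- rbind(placed, c(cr, cc, r))
    h <- runif(1, 0.3, 1)
    rows <- matrix(seq_len(H) - 1, H, W)
    cols <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    d2 <- (rows - cr)^2 + (cols - cc)^2
    out <- pmax(out, h * exp(-d2 / (2 * (r / 2)^2)) * (d2 < r^2))
  }
  attr(out, "centers") <- placed[, 1:2, drop = FALSE]
  out
}

# square annotation polygon covering rows/cols [a, b] (pixel centres)
square_polygon <- function(a, b) {
  cbind(row = c(a, a, b, b), col = c(a, b, b, a))
}

# small-canvas archetype mix (halved radii) for fast generator tests
small_archetypes <- function() {
  list(
    `G3` = archetype_spec("G3", c(1L, 2L), c(14, 20), c(1L, 1L), 0, 10,
                          prevalence = 0.95),
    `G4 fused` = archetype_spec("G4 fused", c(1L, 1L), c(24, 34),
                                c(2L, 3L), 0.7, 9, prevalence = 0.45),
    `G4 ill-defined` = archetype_spec("G4 ill-defined", c(1L, 1L),
                                      c(20, 30), c(0L, 0L), 0, 9,
                                      prevalence = 0.55),
    `G4 complex fused` = archetype_spec("G4 complex fused", c(1L, 1L),
                                        c(28, 40), c(4L, 6L), 0.85, 9,
                                        prevalence = 0.15),
    `G4 glomeruloid` = archetype_spec("G4 glomeruloid", c(1L, 1L),
                                      c(20, 28), c(1L, 1L), 0, 9,
                                      prevalence = 0.25),
    `G4 cribriform` = archetype_spec("G4 cribriform", c(1L, 1L),
                                     c(28, 42), c(6L, 12L), 0, 11,
                                     prevalence = 0.35)
  )
}

small_synth_config <- function(seed = 1L, ...) {
  synthesis_config(seed = seed, canvas_px = c(320L, 960L),
                   archetypes = small_archetypes(), ...)
}

desk_net_config <- function() {
  network_config(n_blocks = 3L, base_features = 4L, se_ratio = 4L,
                 input_size = 256L)
}

desk_synth_config <- function(seed = 1L, ...) {
  synthesis_config(seed = seed, canvas_px = c(512L, 1536L), ...)
}
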