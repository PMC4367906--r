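## Independent oracles used across the suite. Deliberately written from
## first principles (sorting, enumeration, flood fill) rather than through
## the code paths they check.

## sorting-based median: average of middle two for even n
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_mad <- function(x, constant = 1.4826) {
  constant * oracle_median(abs(x - oracle_median(x)))
}

## brute-force median +/- k*MAD hit rule, element by element
oracle_call_hits <- function(x, k = 2, constant = 1.4826) {
  med <- oracle_median(x)
  s <- oracle_mad(x, constant)
  ifelse(x > med + k * s, "high", ifelse(x < med - k * s, "low", "none"))
}

## exhaustive subset enumeration: P(at least k of the n drawn genes are
## among the K annotated ones) out of a universe of N
oracle_hypergeom_enum <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K carry the annotation
  mean(hits >= k)
}

## closed-form counting over the drawing space (exact in doubles for N <= 20)
oracle_hypergeom_choose <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## two-sided Fisher p by enumeration over all tables with fixed margins
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  avals <- max(0, c1 - r2):min(r1, c1)
  probs <- sapply(avals, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  })
  p_obs <- probs[avals == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## 4-neighborhood flood-fill component count of a binary mask
oracle_flood_fill_count <- function(mask) {
  mask <- as.matrix(mask)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  sizes <- integer()
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && !seen[i, j]) {
      count <- count + 1L
      size <- 0L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask)) next
        if (!mask[p[1], p[2]] || seen[p[1], p[2]]) next
        seen[p[1], p[2]] <- TRUE
        size <- size + 1L
        stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                               c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
      }
      sizes <- c(sizes, size)
    }
  }
  list(count = count, sizes = sizes)
}

## tiny 2-plate screen used by several io/normalization tests
tiny_screen <- function(seed = 11) {
  generate_screen(
    screen_config(n_genes = 40, n_low_hits = 3, low_effect = 0.2,
                  n_high_hits = 4, high_effect = 3),
    seed = seed
  )
}
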