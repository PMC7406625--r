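# Independent brute-force re-implementations used as oracles. These are
# deliberately written with plain loops, recounting everything from
# scratch, and share no code with the package internals.

oracle_window_calls <- function(calls, cfg = bin_call_config()) {
  n <- length(calls)
  if (n < cfg$window) {
    starts <- 1L
    width <- n
  } else {
    starts <- seq.int(1L, n - cfg$window + 1L, by = cfg$step)
    width <- cfg$window
  }
  out <- character(length(starts))
  for (w in seq_along(starts)) {
    win <- calls[starts[w]:(starts[w] + width - 1L)]
    a <- 0L
    b <- 0L
    for (g in win) {
      if (g == "A") a <- a + 1L
      if (g == "B") b <- b + 1L
    }
    if (a + b < min(cfg$min_informative, width)) {
      out[w] <- "U"
    } else if (a / (a + b) >= cfg$a_threshold / cfg$window) {
      out[w] <- "A"
    } else if (a / (a + b) <= cfg$b_threshold / cfg$window) {
      out[w] <- "B"
    } else {
      out[w] <- "U"
    }
  }
  attr(out, "starts") <- as.integer(starts)
  attr(out, "width") <- as.integer(width)
  out
}

oracle_collapse <- function(wc, pos, chrom_len, cfg = bin_call_config()) {
  n <- length(pos)
  starts <- attr(wc, "starts")
  width <- attr(wc, "width")
  mcall <- character(n)
  for (i in seq_len(n)) {
    cA <- 0L
    cB <- 0L
    for (w in seq_along(starts)) {
      if (starts[w] <= i && i <= starts[w] + width - 1L) {
        if (wc[w] == "A") cA <- cA + 1L
        if (wc[w] == "B") cB <- cB + 1L
      }
    }
    mcall[i] <- if (cA > cB) "A" else if (cB > cA) "B" else "U"
  }
  det <- which(mcall != "U")
  if (length(det) == 0L) {
    return(list(blocks = data.frame(genotype = "undetermined", start = 0,
                                    end = chrom_len,
                                    stringsAsFactors = FALSE),
                breakpoints = numeric(0)))
  }
  geno <- character(0)
  first_det <- integer(0)
  last_det <- integer(0)
  for (i in det) {
    g <- mcall[i]
    if (length(geno) > 0 && geno[length(geno)] == g) {
      last_det[length(geno)] <- i
    } else {
      geno <- c(geno, g)
      first_det <- c(first_det, i)
      last_det <- c(last_det, i)
    }
  }
  bps <- numeric(0)
  if (length(geno) > 1L) {
    for (k in seq_len(length(geno) - 1L)) {
      bps <- c(bps, (pos[last_det[k]] + pos[first_det[k + 1L]]) / 2)
    }
  }
  bounds <- c(0, bps, chrom_len)
  list(blocks = data.frame(genotype = geno,
                           start = bounds[-length(bounds)],
                           end = bounds[-1L], stringsAsFactors = FALSE),
       breakpoints = bps)
}

# all-orderings LMG average, feasible for a handful of predictors
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

oracle_lmg <- function(X, y) {
  p <- ncol(X)
  r2 <- function(cols) {
    if (length(cols) == 0L) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- all_perms(seq_len(p))
  shares <- numeric(p)
  for (ord in perms) {
    prev <- 0
    for (k in seq_len(p)) {
      cur <- r2(ord[seq_len(k)])
      shares[ord[k]] <- shares[ord[k]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(perms)
}
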