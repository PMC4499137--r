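# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (all-pairs loops, per-bin recounts) so they cannot share
# a bug with the sweep implementations they check.

# all-pairs nearest edge gap, looping over every interval pair
brute_nearest <- function(A, B) {
  da <- A$intervals; db <- B$intervals
  out <- rep(Inf, nrow(da))
  for (i in seq_len(nrow(da))) {
    for (j in seq_len(nrow(db))) {
      if (da$chrom[i] != db$chrom[j]) next
      g <- max(0, da$start[i] - db$end[j], db$start[j] - da$end[i])
      if (g < out[i]) out[i] <- g
    }
  }
  out
}

# per-bin recount of reads in the centered moving-average window
brute_window_counts <- function(positions, L, step, window) {
  nb <- ceiling(L / step)
  vapply(seq_len(nb) - 1, function(i) {
    center <- i * step + step / 2
    sum(positions >= center - window / 2 & positions < center + window / 2)
  }, 0)
}

# per-anchor, per-offset recount of track values
brute_signal_profile <- function(track, anchors, flank) {
  step <- track$step
  k <- floor(flank / step)
  koff <- (-k):k
  sums <- numeric(length(koff)); nval <- numeric(length(koff))
  adf <- anchors$intervals
  for (r in seq_len(nrow(adf))) {
    v <- track$values[[adf$chrom[r]]]
    b0 <- ((adf$start[r] + adf$end[r]) / 2) %/% step
    for (ki in seq_along(koff)) {
      idx <- b0 + koff[ki]
      if (idx >= 0 && idx < length(v)) {
        sums[ki] <- sums[ki] + v[idx + 1]
        nval[ki] <- nval[ki] + 1
      }
    }
  }
  sums / ifelse(nval == 0, NA, nval)
}

# uniform random peak set built directly from runif, independent of
# simulate_peaks' placement logic
rand_peaks <- function(genome, n, seed, max_len = 1000, label = "R") {
  set.seed(seed)
  ci <- sample.int(length(genome$chrom), n, replace = TRUE,
                   prob = genome$length)
  len <- sample(50:max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[ci] - len))
  peak_set(data.frame(chrom = genome$chrom[ci], start = start,
                      end = start + len), genome, label)
}

# uniform random read set built directly from runif
rand_reads <- function(genome, n, seed, total_mapped = n) {
  set.seed(seed)
  ci <- sample.int(length(genome$chrom), n, replace = TRUE,
                   prob = genome$length)
  pos <- floor(runif(n) * genome$length[ci])
  read_set(split(pos, factor(genome$chrom[ci], levels = genome$chrom)),
           genome, total_mapped)
}
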