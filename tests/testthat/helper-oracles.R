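# Independent step-integration AUPRC oracle: sweep every unique score as a
# threshold, collect (recall, precision) points, integrate stepwise.
auprc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t_ in ths) {
    called <- scores >= t_
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / npos
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

# Brute-force best-hit: enumerate every window on both strands.
scan_oracle <- function(pwm, sequence) {
  lo <- pwm$log_odds
  W <- ncol(lo)
  best <- -Inf
  for (s in c(sequence, reverse_complement(sequence))) {
    chars <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (w in seq_len(nchar(s) - W + 1)) {
      best <- max(best, sum(lo[cbind(chars[w:(w + W - 1)], seq_len(W))]))
    }
  }
  best
}

fps_oracle <- function(similarity, k) {
  dist <- 1 - similarity
  n <- ncol(similarity)
  ids <- colnames(similarity)
  picked <- which.max(rowSums(dist) / (n - 1))
  while (length(picked) < k) {
    cand <- setdiff(seq_len(n), picked)
    score <- vapply(cand, function(j) min(dist[j, picked]), numeric(1))
    picked <- c(picked, cand[which.max(score)])
  }
  ids[picked]
}
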