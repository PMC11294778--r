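# Brute-force oracles, kept independent of the implementations they check.

roc_auc_brute <- function(scores, labels) {
  y <- labels > 0.5
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

pr_auc_brute <- function(scores, labels) {
  y <- labels > 0.5
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & y)
    prec <- tp / sum(pred)
    rec <- tp / sum(y)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
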