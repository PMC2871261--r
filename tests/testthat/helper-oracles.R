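# Independent brute-force reference implementations used as oracles.
# They deliberately use the most literal formulation of each definition and
# share no code with the package internals.

bh_brute <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    # step-up: the adjusted value of p_i is the smallest n*p_j/rank_j over
    # all j whose p-value is >= p_i, capped at 1
    best <- Inf
    for (j in seq_len(n)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        best <- min(best, n * p[j] / rank_j)
      }
    }
    adj[i] <- min(1, best)
  }
  adj
}

mad_summary_brute <- function(v, k = 3) {
  med <- sort(v)[ceiling(length(v) / 2)]
  if (length(v) %% 2 == 0) {
    s <- sort(v)
    med <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  }
  dev <- abs(v - med)
  sdev <- sort(dev)
  mad0 <- if (length(dev) %% 2 == 1) {
    sdev[(length(dev) + 1) / 2]
  } else {
    (sdev[length(dev) / 2] + sdev[length(dev) / 2 + 1]) / 2
  }
  keep <- logical(length(v))
  for (i in seq_along(v)) {
    keep[i] <- if (mad0 > 0) dev[i] <= k * mad0 else TRUE
  }
  list(mean = sum(v[keep]) / sum(keep), n_removed = sum(!keep))
}

pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

auc_brute <- function(scores, labels) {
  tp <- scores[labels == "true_positive"]
  tn <- scores[labels == "true_negative"]
  total <- 0
  for (a in tp) {
    for (b in tn) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(tp) * length(tn))
}

# All genotypes producible by one allele from each parent.
mendel_children_brute <- function(mother, father) {
  pair <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  out <- character(0)
  for (x in pair[[mother]]) {
    for (y in pair[[father]]) {
      out <- c(out, paste0(sort(c(x, y)), collapse = ""))
    }
  }
  unique(out)
}
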