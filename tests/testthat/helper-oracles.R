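# Independent oracles, written naively from the definitions so they share
# no code path with the package implementation.

# Benjamini-Hochberg step-up, literal: sort, p_(i) * m / i, running min
# from the largest rank down, cap at 1, map back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# HWE goodness of fit, spelled out step by step
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p_A <- (n_AA + n_Aa / 2) / n
  if (p_A == 0 || p_A == 1) return(list(chisq = 0, p = 1))
  e <- n * c(p_A^2, 2 * p_A * (1 - p_A), (1 - p_A)^2)
  o <- c(n_AA, n_Aa, n_aa)
  chisq <- sum((o - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Sentinel/pruning/conditional selection from the rule definitions, all
# fits through stats::lm, no shared helpers with the package.
selection_oracle <- function(y, G, variants, age, sex, threshold,
                             r2_max = 0.1, window = 1e6, cond_p = 0.01) {
  sex01 <- as.numeric(sex == "male")
  marg <- lapply(colnames(G), function(v) {
    fit <- summary(stats::lm(y ~ G[, v] + age + sex01))
    co <- fit$coefficients
    if (!"G[, v]" %in% rownames(co)) return(NULL)
    data.frame(variant_id = v, p = co["G[, v]", 4])
  })
  marg <- do.call(rbind, marg)
  marg <- merge(marg, variants, by = "variant_id")
  cand <- marg[marg$p < threshold, ]
  sentinels <- character(0)
  picked <- list()
  cand$current_p <- cand$p
  while (nrow(cand) > 0) {
    cand <- cand[order(cand$current_p, cand$chrom, cand$pos), ]
    s <- cand[1, ]
    picked[[length(picked) + 1]] <- data.frame(
      variant_id = s$variant_id,
      conditional_p = if (length(sentinels) == 0) NA_real_ else s$current_p
    )
    sentinels <- c(sentinels, s$variant_id)
    cand <- cand[-1, ]
    if (nrow(cand) == 0) break
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$chrom[i] == s$chrom && abs(cand$pos[i] - s$pos) <= window) {
        r2 <- stats::cor(G[, cand$variant_id[i]], G[, s$variant_id])^2
        if (!is.na(r2) && r2 > r2_max) keep[i] <- FALSE
      }
    }
    cand <- cand[keep, ]
    if (nrow(cand) == 0) break
    new_p <- rep(NA_real_, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      Xs <- G[, sentinels, drop = FALSE]
      fit <- summary(stats::lm(y ~ G[, cand$variant_id[i]] + Xs + age + sex01))
      co <- fit$coefficients
      row <- "G[, cand$variant_id[i]]"
      if (row %in% rownames(co)) new_p[i] <- co[row, 4]
    }
    cand$current_p <- new_p
    cand <- cand[!is.na(cand$current_p) & cand$current_p < cond_p, ]
  }
  do.call(rbind, picked)
}
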