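# shared fixtures: build harmonized-pair and GWAS tables directly in code

make_pairs <- function(bx, by, sy, sx = rep(1e-6, length(bx)),
                       ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(variant_id = ids, effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = sx, eaf_exposure = 0.3,
             beta_outcome = by, se_outcome = sy, eaf_outcome = 0.3,
             status = "kept", stringsAsFactors = FALSE)
}

gwas_row <- function(id, ea = "A", oa = "G", beta = 0.1, se = 0.01,
                     eaf = 0.3, chromosome = "1", position = 1000,
                     pvalue = 1e-9, n = 1e5) {
  data.frame(variant_id = id, chromosome = chromosome, position = position,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se, pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

gwas_table <- function(...) do.call(rbind, list(...))

# independent brute-force greedy clumping oracle, written directly from the
# procedure definition (no shared code with clump())
oracle_clump <- function(records, ld, r2, window_kb = 10000) {
  remaining <- records[order(records$pvalue, records$variant_id), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$variant_id)
    drop <- logical(nrow(remaining)); drop[1] <- TRUE
    for (i in seq_len(nrow(remaining))[-1]) {
      v <- remaining[i, ]
      if (ld[top$variant_id, v$variant_id] >= r2 &&
          abs(v$position - top$position) <= window_kb * 1000) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, ]
  }
  sort(kept)
}

# independent step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# independent interpolated weighted-median oracle via stats::approx on the
# cumulative-midpoint curve
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5)$y
}
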