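# Shared small fixtures and independent oracles.

# O(n^2) pairwise concordance oracle for Somers' D.
somers_d_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  conc <- 0
  disc <- 0
  for (a in pos) {
    conc <- conc + sum(a > neg)
    disc <- disc + sum(a < neg)
  }
  (conc - disc) / (length(pos) * length(neg))
}

# Rank-then-Pearson oracle for Spearman's rho (mid-rank ties).
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Independent BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Complete-enumeration Fisher's exact two-sided p for a 2x2 table
# (row sums and a-cell hypergeometric).
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small deterministic expression fixture with one strong planted regulator.
planted_expression <- function(n = 300, n_tf = 5, beta = 2, noise_sd = 0.3,
                               seed = 42) {
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  x <- matrix(rlnorm(n_tf * n, 0, 0.5), n_tf, n,
              dimnames = list(tfs, sprintf("c%03d", seq_len(n))))
  y <- beta * x[1, ] + rlnorm(n, 0, noise_sd) * 0.5
  expr <- rbind(x, target = y)
  rownames(expr) <- c(tfs, "target")
  attr(expr, "normalized") <- TRUE
  expr
}

tiny_regions <- function() {
  tibble::tibble(
    region_id = c("r1", "r2", "r3"),
    chrom = "chr1",
    start = c(100L, 9500L, 20100L),
    end = c(200L, 9700L, 20200L)
  )
}

tiny_tss <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1",
    tss = c(150L, 10000L),
    strand = c("+", "-")
  )
}

edge_keys <- function(d) paste(d$tf_id, d$target_id)
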