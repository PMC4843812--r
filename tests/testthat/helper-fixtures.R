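# shared fixtures and independent oracles

genes_table1 <- c("GAPDH", "ACT", "UBC", "EF1-alpha", "alpha-TUB",
                  "beta-TUB", "PP2A", "EXP1", "PTBP1", "EXP2",
                  "TIP41", "CYP1", "CYP2", "YLS8")

table2_path <- function() {
  system.file("extdata", "table2_rankings.csv", package = "refstab")
}

table1_path <- function() {
  system.file("extdata", "table1_primers.csv", package = "refstab")
}

# small Ct table: genes x samples matrix with annotations
make_ct <- function(m, ...) {
  if (is.null(rownames(m)))
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  ct_table(m, ...)
}

random_q <- function(k, n, sd = 1) {
  m <- 2^-abs(matrix(stats::rnorm(k * n, sd = sd), k, n))
  rownames(m) <- paste0("g", seq_len(k))
  sweep(m, 1, apply(m, 1, max), "/")
}

# --- independent geNorm oracle: plain double loops, recomputed from
# scratch at every elimination round ---------------------------------------
oracle_m <- function(q, gene_set) {
  sapply(gene_set, function(g) {
    vs <- sapply(setdiff(gene_set, g), function(h) {
      r <- log2(q[g, ] / q[h, ])
      sqrt(sum((r - mean(r))^2) / (length(r) - 1))
    })
    mean(vs)
  })
}

oracle_genorm <- function(q) {
  surviving <- rownames(q)
  elim <- character(0)
  while (length(surviving) > 2) {
    m <- oracle_m(q, surviving)
    worst <- surviving[max(which(m == max(m)))]
    elim <- c(elim, worst)
    surviving <- setdiff(surviving, worst)
  }
  list(elimination_order = elim, final_pair = surviving,
       ranked = c(surviving, rev(elim)))
}

oracle_v_series <- function(q, ranked) {
  k <- length(ranked)
  nf <- function(n) {
    apply(q[ranked[1:n], , drop = FALSE], 2, function(col)
      prod(col)^(1 / n))
  }
  v <- sapply(2:(k - 1), function(n) {
    r <- log2(nf(n) / nf(n + 1))
    sqrt(sum((r - mean(r))^2) / (length(r) - 1))
  })
  names(v) <- 2:(k - 1)
  v
}
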