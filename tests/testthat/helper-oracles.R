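# Independent oracles used across the suite. Each is a straight-line
# transcription of the defining formula, deliberately sharing no code with
# the package implementation.

# mid-ranks computed from first principles (sort positions averaged over ties)
midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    tied <- sum(x == x[i])
    r[i] <- less + (tied + 1) / 2
  }
  r
}

# Kruskal-Wallis H by the textbook formula with tie correction
kw_oracle_H <- function(values, groups) {
  r <- midranks(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(r[idx])^2 / sum(idx)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tie <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie <- tie + t^3 - t
  }
  cc <- 1 - tie / (n^3 - n)
  if (cc == 0) return(0)
  h / cc
}

# exact two-group permutation distribution of H: enumerate every assignment
# of n_a observations to group a and return the tail probability of h_obs
kw_perm_p_oracle <- function(values, n_a, h_obs) {
  n <- length(values)
  splits <- utils::combn(n, n_a)
  hs <- apply(splits, 2L, function(ia) {
    g <- rep("b", n)
    g[ia] <- "a"
    kw_oracle_H(values, g)
  })
  mean(hs >= h_obs - 1e-10)
}

# brute-force weighted-KS running sum, looped exactly as defined
es_oracle <- function(hit, metric, weight) {
  n <- length(hit)
  nh <- sum(hit)
  denom_hit <- sum(abs(metric[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (denom_hit == 0) 1 / nh else abs(metric[i])^weight / denom_hit
    } else {
      cur <- cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  best <- which.max(abs(running))
  running[best]
}

# brute-force Venn partition: per taxon, collect the cohorts where it is
# significant, then check direction agreement
partition_oracle <- function(tables) {
  cohorts <- names(tables)
  taxa <- tables[[1L]]$taxon
  assign <- list()
  discordant <- character(0)
  for (tx in taxa) {
    s <- character(0)
    d <- character(0)
    for (co in cohorts) {
      tb <- tables[[co]]
      i <- which(tb$taxon == tx)
      if (tb$significant[i]) {
        s <- c(s, co)
        d <- c(d, tb$direction[i])
      }
    }
    if (!length(s)) next
    if (length(unique(d)) == 1L) {
      assign[[tx]] <- s
    } else {
      discordant <- c(discordant, tx)
    }
  }
  list(assign = assign, discordant = discordant)
}

# random DA tables for partition property tests
random_da_table <- function(taxa, cohort) {
  sig <- runif(length(taxa)) < 0.4
  structure(
    data.frame(
      taxon = taxa, domain = "fungal", H = 1, p_raw = 0.5, p_adj = 0.5,
      logFC = 0, direction = sample(c("over_in_a", "over_in_b"),
                                    length(taxa), replace = TRUE),
      significant = sig, stringsAsFactors = FALSE
    ),
    class = c("da_table", "data.frame"), cohort = cohort
  )
}
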