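# Independent oracles used across tests. These deliberately avoid the code
# paths they check: exact binomial-coefficient enumeration instead of
# phyper, naive substring scanning instead of the vectorized scanner.

# Exact hypergeometric upper tail P[X >= k], X ~ Hyper(N, K, n).
# For pooled N <= 40 every choose() term and partial sum is an exact
# integer below 2^53, so this is exact rational arithmetic up to one final
# division.
oracle_hyper_tail <- function(k, K, N, n) {
  jj <- seq.int(max(k, 0, n - (N - K)), min(K, n))
  if (length(jj) == 0) return(0)
  sum(choose(K, jj) * choose(N - K, n - jj)) / choose(N, n)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), NULL)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive occurrence finder: test every position on both strands.
oracle_scan <- function(seq, core = "TGTC") {
  L <- nchar(seq)
  core_rc <- oracle_revcomp(core)
  res <- list()
  for (off in 0:(L - 6)) {
    foot <- substr(seq, off + 1, off + 6)
    if (substr(foot, 1, 4) == core) {
      res[[length(res) + 1]] <- list(offset = off, strand = "+",
                                     hexamer = foot)
    }
    if (substr(foot, 3, 6) == core_rc) {
      res[[length(res) + 1]] <- list(offset = off, strand = "-",
                                     hexamer = oracle_revcomp(foot))
    }
  }
  if (length(res) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      hexamer = character(), stringsAsFactors = FALSE))
  }
  data.frame(offset = vapply(res, `[[`, integer(1), "offset"),
             strand = vapply(res, `[[`, character(1), "strand"),
             hexamer = vapply(res, `[[`, character(1), "hexamer"),
             stringsAsFactors = FALSE)
}

# Quadratic all-pairs repeat-config brute force on one sequence.
oracle_configs <- function(seq, min_spacer = 0, max_spacer = 25) {
  occ <- oracle_scan(seq)
  cfg <- character(0)
  n <- nrow(occ)
  if (n >= 2) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        spacer <- occ$offset[b] - (occ$offset[a] + 6)
        if (spacer < min_spacer || spacer > max_spacer) next
        ori <- if (occ$strand[a] == occ$strand[b]) "DR" else
          if (occ$strand[a] == "+") "IR" else "ER"
        cfg <- c(cfg, paste0(ori, "_", spacer))
      }
    }
  }
  sort(unique(cfg))
}

# sorted "<orientation>_<spacer>" keys of a config data.frame
config_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste0(df$orientation, "_", df$spacer))
}

random_dna <- function(len, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
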