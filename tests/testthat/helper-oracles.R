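# Independent oracles used across test files.

# Grid search of the binomial likelihood-ratio condition
# {p : 2[l(k/n) - l(p)] <= chisq_1(level)} at fixed resolution.
grid_wilks <- function(k, n, level = 0.95, res = 1e-5) {
  crit <- qchisq(level, 1)
  p <- seq(res, 1 - res, by = res)
  lhat <- (if (k > 0) k * log(k / n) else 0) +
    (if (k < n) (n - k) * log(1 - k / n) else 0)
  lp <- ifelse(rep(k > 0, length(p)), k * log(p), 0) +
    ifelse(rep(k < n, length(p)), (n - k) * log1p(-p), 0)
  keep <- 2 * (lhat - lp) <= crit
  c(lo = if (k == 0) 0 else min(p[keep]),
    hi = if (k == n) 1 else max(p[keep]))
}

# Generic least-squares solution of the 2x2 system with design
# X = [[1,-1],[1,+1]] and error propagation for the slope.
ls_oracle <- function(v_ctrl, sd_ctrl, v_as, sd_as) {
  X <- matrix(c(1, 1, -1, 1), nrow = 2)
  A <- solve(t(X) %*% X) %*% t(X)
  b <- A %*% c(v_ctrl, v_as)
  sd_b1 <- sqrt(sum(A[2, ]^2 * c(sd_ctrl, sd_as)^2))
  list(b0 = b[1], b1 = b[2], sd_b1 = sd_b1,
       z = if (sd_b1 > 0) b[2] / sd_b1 else 0)
}

# Explicit run enumeration over flagged sites of one pair: walk each
# chromosome and direction, cut where the distance between successive
# flagged sites exceeds max_gap, keep runs with enough sites.
segment_oracle <- function(flagged, max_gap, min_sites) {
  sig <- flagged[!is.na(flagged$flag), ]
  out <- list()
  for (pr in unique(sig$pair)) for (ch in unique(sig$chrom)) {
    for (dir in c("hyper", "hypo")) {
      s <- sig[sig$pair == pr & sig$chrom == ch & sig$flag == dir, ]
      if (nrow(s) == 0) next
      s <- s[order(s$pos), ]
      run_start <- 1
      for (i in seq_len(nrow(s))) {
        last <- i == nrow(s)
        brk <- if (last) TRUE else (s$pos[i + 1] - s$pos[i]) > max_gap
        if (brk) {
          idx <- run_start:i
          if (length(idx) >= min_sites) {
            out[[length(out) + 1]] <- data.frame(
              pair = pr, chrom = ch,
              start = min(s$pos[idx]) - 1, end = max(s$pos[idx]),
              direction = dir, n_sites = length(idx),
              region_z = sum(s$z[idx]) / sqrt(length(idx))
            )
          }
          run_start <- i + 1
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$pair, res$chrom, res$start), ]
}

# A small simulated data set shared by several tests.
tiny_config <- function(...) {
  defaults <- list(n_chromosomes = 1, chrom_length = 3e5, n_genes = 20,
                   gene_length_range = c(2000L, 6000L), seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

make_contrasts <- function(pos, z, pair = "male", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = pos, strand = "+", pair = pair,
                 f_ctrl = 0.5, f_as = 0.5, v_ctrl = 0, v_as = 0,
                 b0 = 0, b1 = z, sd_b1 = 1, z = z)
}
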