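# Independent brute-force oracles. These deliberately avoid the package's
# code paths: per-base position sets for interval work, direct enumeration
# for rank statistics, triple loops for connectivity.

# per-base union of peaks, then close gaps <= merge_gap
oracle_merge <- function(peaks, merge_gap) {
  out <- NULL
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, ]
    pos <- sort(unique(unlist(mapply(function(s, e) seq(s, e - 1), p$start,
                                     p$end, SIMPLIFY = FALSE))))
    # runs of covered positions
    brk <- c(0, which(diff(pos) > 1), length(pos))
    runs <- data.frame(start = pos[brk[-length(brk)] + 1],
                       end = pos[brk[-1]] + 1)
    # close gaps
    i <- 1
    while (i < nrow(runs)) {
      if (runs$start[i + 1] - runs$end[i] <= merge_gap) {
        runs$end[i] <- runs$end[i + 1]
        runs <- runs[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    out <- rbind(out, data.frame(chrom = ch, start = runs$start,
                                 end = runs$end))
  }
  rownames(out) <- NULL
  out
}

# position-set overlap test between two single intervals
oracle_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1))) > 0
}

# which genes are marked, via explicit position sets
oracle_mark <- function(domains, genes, extension) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(vapply(seq_len(nrow(domains)), function(j) {
      oracle_overlaps(genes$chrom[i], max(0, genes$start[i] - extension),
                      genes$end[i] + extension,
                      domains$chrom[j], domains$start[j], domains$end[j])
    }, TRUE))
  }, TRUE)
}

# connectivity by triple loop over loops x domain pairs
oracle_connectivity <- function(doms, loops) {
  n <- nrow(doms)
  connected <- logical(n)
  hit <- function(dc, ds, de, ch, s, e) dc == ch && ds < e && de > s
  for (l in seq_len(nrow(loops))) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      i1 <- hit(doms$chrom[i], doms$start[i], doms$end[i],
                loops$chrom1[l], loops$start1[l], loops$end1[l])
      j2 <- hit(doms$chrom[j], doms$start[j], doms$end[j],
                loops$chrom2[l], loops$start2[l], loops$end2[l])
      i2 <- hit(doms$chrom[i], doms$start[i], doms$end[i],
                loops$chrom2[l], loops$start2[l], loops$end2[l])
      j1 <- hit(doms$chrom[j], doms$start[j], doms$end[j],
                loops$chrom1[l], loops$start1[l], loops$end1[l])
      if ((i1 && j2) || (i2 && j1)) connected[c(i, j)] <- TRUE
    }
  }
  connected
}

# Mann-Whitney p by direct enumeration of label assignments, computing U
# from pairwise comparisons (not ranks)
oracle_mw_p <- function(x, y, alternative = "two-sided") {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  cmb <- utils::combn(length(pool), n1)
  us <- apply(cmb, 2, function(ix) u_of(pool[ix], pool[-ix]))
  switch(alternative,
         "two-sided" = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
         "greater" = mean(us >= u_obs - 1e-9),
         "less" = mean(us <= u_obs + 1e-9))
}

# midranks by hand, then explicit Pearson formula
oracle_spearman_r <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small deterministic track builder
toy_track <- function(..., total_mapped = 1e7, value_bounds = NULL) {
  runs <- data.frame(...)
  coverage_track(runs, total_mapped = total_mapped,
                 value_bounds = value_bounds)
}

# tiny genome of random peaks for property tests
random_peaks <- function(n, chroms = c("chrA", "chrB"), span = 10000) {
  s <- sample.int(span - 50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample(10:400, n, replace = TRUE))
}
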