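# Fixtures are built in code at test time.

make_pool <- function(chrom, pos, strand, meth, unmeth, label = "P",
                      destranded = FALSE) {
  pool_methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                            meth = meth, unmeth = unmeth,
                            stringsAsFactors = FALSE),
                 label = label, destranded = destranded)
}

# Desk-scale study for module tests: ~4000 CpG dyads, 40 islands, 4 planted.
tiny_study <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_planted = 4,
         depth_means = c(H = 10, DFS = 10, MBC = 17),
         genome_args = list(chrom_length = 4e5, n_islands = 40,
                            n_genes = 20)),
    list(...))
  suppressWarnings(suppressMessages(do.call(simulate_study, args)))
}

# Independent brute-force oracle for the two-sided Fisher exact test:
# enumerate the conditional distribution over the fixed margins directly
# from binomial coefficients (no dhyper).
fisher_oracle <- function(ma, ua, mb, ub) {
  ra <- ma + ua; rb <- mb + ub; cm <- ma + mb; n <- ra + rb
  k <- max(0, cm - rb):min(ra, cm)
  logp <- lchoose(ra, k) + lchoose(rb, cm - k) - lchoose(n, cm)
  p <- exp(logp)
  p_obs <- p[match(ma, k)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Naive quadratic hotspot scan (every island x every DML), the oracle for
# the interval-indexed implementation.
hotspot_oracle <- function(records, islands, params) {
  iv <- islands$intervals
  out <- character(0)
  for (i in seq_len(nrow(iv))) {
    inside <- records$chrom == iv$chrom[i] & records$pos >= iv$start[i] &
      records$pos <= iv$end[i]
    qual <- inside & records$dmv >= params$min_dmv &
      (!params$require_hyper | records$direction == "hyper")
    if (sum(qual) >= params$min_dml) out <- c(out, iv$name[i])
  }
  sort(out)
}

quiet_dml <- function(...) suppressWarnings(suppressMessages(call_dml(...)))
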