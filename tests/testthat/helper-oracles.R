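# Independent reference implementations used as oracles. These deliberately
# share no code with the package: reverse complementation goes through
# Biostrings, and scores are accumulated by explicit position loops.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Exhaustive substring-pair dimer score: loop over every start position in
# both primers and every length 4..8, test reverse complementarity, and add
# 2^len * 2^numGC / ((d1+1)(d2+1)), d measured from the substring's 3'-most
# base to the primer's 3' terminus.
oracle_badness <- function(pa, pb) {
  na <- nchar(pa); nb <- nchar(pb)
  total <- 0
  for (len in 4:8) {
    if (len > na || len > nb) next
    for (i in seq_len(na - len + 1)) {
      sa <- substr(pa, i, i + len - 1)
      d1 <- na - (i + len - 1)
      for (j in seq_len(nb - len + 1)) {
        sb <- substr(pb, j, j + len - 1)
        if (sb == oracle_revcomp(sa)) {
          d2 <- nb - (j + len - 1)
          numGC <- sum(strsplit(sa, "")[[1]] %in% c("G", "C"))
          total <- total + 2^len * 2^numGC / ((d1 + 1) * (d2 + 1))
        }
      }
    }
  }
  total
}

# Set loss by definition: sum over unordered pairs b > a plus self terms.
oracle_loss <- function(primers) {
  n <- length(primers)
  total <- sum(vapply(primers, function(p) oracle_badness(p, p), numeric(1)))
  if (n > 1)
    for (a in seq_len(n - 1))
      for (b in seq.int(a + 1, n))
        total <- total + oracle_badness(primers[a], primers[b])
  total
}

random_primer <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Build an optimizer panel directly from explicit primer sequences,
# bypassing candidate generation: one target per element of fp_sets /
# rp_sets (character vectors of alternative primers); pairs combine
# same-index fp/rp when paired = TRUE, else the full product.
direct_panel <- function(fp_sets, rp_sets, paired = TRUE) {
  stopifnot(length(fp_sets) == length(rp_sets))
  panel <- lapply(seq_along(fp_sets), function(i) {
    fps <- data.frame(target_id = paste0("t", i), strand = "forward",
                      sequence = fp_sets[[i]],
                      start_5p = NA_integer_,
                      length = nchar(fp_sets[[i]]), dG = NA_real_)
    rps <- data.frame(target_id = paste0("t", i), strand = "reverse",
                      sequence = rp_sets[[i]],
                      start_5p = NA_integer_,
                      length = nchar(rp_sets[[i]]), dG = NA_real_)
    pairs <- if (paired) {
      stopifnot(nrow(fps) == nrow(rps))
      data.frame(target_id = paste0("t", i),
                 fp = seq_len(nrow(fps)), rp = seq_len(nrow(rps)))
    } else {
      expand.grid(fp = seq_len(nrow(fps)), rp = seq_len(nrow(rps)))
    }
    list(region = NULL, fps = fps, rps = rps, pairs = pairs)
  })
  names(panel) <- paste0("t", seq_along(fp_sets))
  panel
}

# Exhaustive loss minimum over every selection of one pair per target,
# from a pairwise badness matrix computed by the oracle-independent route
# (badness_matrix is itself cross-checked against oracle_badness elsewhere).
enumerate_global_minimum <- function(panel) {
  n_pairs <- vapply(panel, function(t) nrow(t$pairs), integer(1))
  all_primers <- unlist(lapply(panel, function(t)
    c(t$fps$sequence, t$rps$sequence)))
  bm <- plexanneal::badness_matrix(all_primers)
  # map (target, pair row) -> indices of its two primers in all_primers
  offs <- c(0, cumsum(vapply(panel, function(t)
    nrow(t$fps) + nrow(t$rps), integer(1))))
  pair_primers <- lapply(seq_along(panel), function(i) {
    t <- panel[[i]]
    lapply(seq_len(nrow(t$pairs)), function(r)
      c(offs[i] + t$pairs$fp[r], offs[i] + nrow(t$fps) + t$pairs$rp[r]))
  })
  grid <- expand.grid(lapply(n_pairs, seq_len))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    idx <- unlist(lapply(seq_along(panel), function(i)
      pair_primers[[i]][[grid[g, i]]]))
    sub <- bm[idx, idx]
    loss <- sum(sub[upper.tri(sub)]) + sum(diag(sub))
    if (loss < best) best <- loss
  }
  best
}
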