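# Read classification and tabulation.

toy_panel <- function(seed = 1, n = 4, plen = 12, amp_extra = 30) {
  set.seed(seed)
  fp <- replicate(n, random_primer(plen))
  rp <- replicate(n, random_primer(plen))
  amps <- vapply(seq_len(n), function(i)
    paste0(fp[i], random_primer(amp_extra), oracle_revcomp(rp[i])),
    character(1))
  primer_panel(fp, rp, amps)
}

test_that("panel construction validates amplicon/primer consistency", {
  p <- toy_panel()
  expect_equal(length(p$primers), 8)
  expect_error(primer_panel("ACGTACGTACGT", "ACGTACGTACGT", "GGGG"),
               "expected ends")
})

test_that("the insert-length boundary separates dimer from non-specific", {
  p <- toy_panel()
  fp1 <- p$primers[1]
  rp1 <- p$primers[5]
  # insert 5 nt longer than the two primers combined -> non-specific
  long_read <- paste0(fp1, "ACGTA", revcomp(rp1))
  rec <- classify_read(long_read, p, max_mismatch = 0)
  expect_equal(rec$class, "nonspecific")
  expect_equal(rec$fp_index, 1)
  expect_equal(rec$rp_index, 5)
  # 3'-overlapped join shorter than the two primers combined -> dimer
  short_read <- paste0(fp1, substr(revcomp(rp1), 3, nchar(rp1)))
  rec2 <- classify_read(short_read, p, max_mismatch = 0)
  expect_equal(rec2$class, "dimer")
  expect_lt(rec2$insert_len, nchar(fp1) + nchar(rp1))
  # an exact amplicon copy is on-target
  rec3 <- classify_read(p$amplicons[2], p, max_mismatch = 0)
  expect_equal(rec3$class, "on_target")
  expect_equal(rec3$target, 2)
})

test_that("forward-forward dimers are matched against the merged primer list", {
  p <- toy_panel(seed = 3)
  read <- paste0(p$primers[2], substr(revcomp(p$primers[3]), 2, 12))
  rec <- classify_read(read, p, max_mismatch = 0)
  expect_equal(rec$class, "dimer")
  expect_equal(unname(c(rec$fp_index, rec$rp_index)), c(2, 3))
})

test_that("reads matching no primer at both ends are unassigned", {
  p <- toy_panel()
  set.seed(9)
  rec <- classify_read(random_primer(60), p, max_mismatch = 0)
  expect_equal(rec$class, "unassigned")
  expect_equal(classify_read("", p)$class, "unassigned")
})

test_that("mismatch tolerance rescues near-matching reads", {
  p <- toy_panel()
  amp <- p$amplicons[1]
  mutated <- paste0("T", substr(amp, 2, nchar(amp)))  # 1 edit
  expect_equal(classify_read(mutated, p, max_mismatch = 0)$class,
               "unassigned")
  expect_equal(classify_read(mutated, p, max_mismatch = 2)$class,
               "on_target")
})

test_that("classification is deterministic and order-independent", {
  p <- toy_panel(seed = 5)
  reads <- simulate_reads(p, n_reads = 200, seed = 6)
  r1 <- classify_reads(reads$sequence, p, max_mismatch = 0)
  perm <- sample(nrow(reads))
  r2 <- classify_reads(reads$sequence[perm], p, max_mismatch = 0)
  expect_equal(r1$class[perm], r2$class)
})

test_that("tabulation computes fractions, dimer matrix and totals", {
  p <- toy_panel()
  records <- data.frame(
    read_id = 1:10,
    class = c(rep("dimer", 9), "on_target"),
    target = c(rep(NA, 9), 1),
    fp_index = c(rep(1, 9), NA), rp_index = c(rep(5, 9), NA),
    insert_len = 20)
  tab <- tabulate_reads(records, p)
  expect_equal(unname(tab$fractions["dimer"]), 0.9)
  expect_equal(tab$dimer_matrix[1, 5], 9)
  expect_equal(sum(tab$dimer_matrix), 9)
  expect_equal(tab$on_target_counts, c(1, 0, 0, 0))
  # per-million normalization
  tab2 <- tabulate_reads(records, p, per_million = TRUE)
  expect_equal(tab2$dimer_matrix[1, 5], 9e5)
  # empty input warns and reports zero fractions
  expect_warning(empty <- tabulate_reads(records[0, ], p), "no classified")
  expect_equal(unname(empty$fractions), c(0, 0, 0))
})

test_that("simulated class mixes are recovered within multinomial error", {
  p <- toy_panel(seed = 11, n = 6, plen = 14)
  mix <- c(on_target = 0.7, dimer = 0.2, nonspecific = 0.1)
  n <- 2000
  reads <- simulate_reads(p, mix = mix, n_reads = n, seed = 12)
  rec <- classify_reads(reads$sequence, p, max_mismatch = 0)
  tab <- tabulate_reads(rec, p)
  expect_equal(tab$n_classified, n)  # nothing unassigned
  for (cl in names(mix)) {
    tol <- 3 * sqrt(mix[[cl]] * (1 - mix[[cl]]) / n)
    expect_lt(abs(tab$fractions[[cl]] - mix[[cl]]), tol)
  }
})

test_that("the confusion matrix is diagonal at zero mismatch tolerance", {
  p <- toy_panel(seed = 21, n = 5, plen = 13)
  reads <- simulate_reads(p, n_reads = 600, seed = 22)
  rec <- classify_reads(reads$sequence, p, max_mismatch = 0)
  expect_equal(rec$class, reads$true_class)
  # simulated primer indices are recovered for non-on-target reads
  off <- reads$true_class != "on_target"
  expect_equal(rec$fp_index[off], reads$fp_index[off])
  expect_equal(rec$rp_index[off], reads$rp_index[off])
  expect_equal(rec$target[!off], reads$target[!off])
})

test_that("degenerate simulated mixes classify uniformly", {
  p <- toy_panel(seed = 31)
  all_on <- simulate_reads(p, mix = c(on_target = 1, dimer = 0, nonspecific = 0),
                           n_reads = 50, seed = 1)
  rec <- classify_reads(all_on$sequence, p, max_mismatch = 0)
  expect_true(all(rec$class == "on_target"))
  all_dimer <- simulate_reads(p, mix = c(on_target = 0, dimer = 1, nonspecific = 0),
                              n_reads = 50, seed = 2)
  rec2 <- classify_reads(all_dimer$sequence, p, max_mismatch = 0)
  tab <- tabulate_reads(rec2, p)
  expect_equal(unname(tab$fractions["dimer"]), 1)
})
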