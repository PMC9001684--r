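# Synthetic data generation.
#
# The target generator emulates a panel of exon-sized genomic targets:
# random-composition templates of configurable length and G/C content with
# a centered pivot interval that the amplicon insert must contain. The
# adversarial mode plants, across pairs of targets, forward-primer
# candidates whose 3' termini carry a motif and its reverse complement, so
# that a naive selection can be driven into a strong predicted dimer while
# a clean alternative always exists; this exercises the optimizer.
#
# The read simulator synthesizes a library from a classification panel:
# on-target reads are exact amplicon copies, dimer reads join a primer to a
# second primer's reverse complement through a 3' overlap (total length
# below the two primer lengths combined, by construction), and non-specific
# reads flank a random insert longer than that sum. Real libraries differ
# in ways the simulator does not model: sequencing errors, adapter
# read-through, and off-panel genomic amplicons.

.random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Extend `motif` 5'-ward with A/T bases until its duplex free energy enters
# the window. A/T steps change the energy by at most ~1.05 kcal/mol, less
# than the window width, so the walk cannot step over the window.
.tune_into_window <- function(motif, window, params) {
  p <- motif
  while (duplex_dg(p, params) > window[2L]) {
    p <- paste0(sample(c("A", "T"), 1L), p)
    if (nchar(p) > 60L)
      stop("failed to tune planted primer into the free-energy window",
           call. = FALSE)
  }
  if (duplex_dg(p, params) < window[1L])
    stop("planted motif overshot the free-energy window", call. = FALSE)
  p
}

#' Generate synthetic target regions
#'
#' Seeded random templates with a centered pivot interval. With
#' `adversarial = TRUE`, consecutive targets are paired and each pair is
#' planted with forward-primer candidates terminating in `motif` and its
#' reverse complement at the 3' end, guaranteeing a selectable candidate
#' pair with badness at least `2^len * 2^numGC`.
#'
#' @param n_targets number of targets.
#' @param template_len template length (nt).
#' @param gc mean G/C content of the random templates.
#' @param pivot_width width of the pivot interval (nt), centered.
#' @param seed RNG seed; identical arguments give identical targets.
#' @param max_amplicon_len per-target amplicon cap (nt).
#' @param adversarial plant complementary 3'-end motifs (see above).
#' @param motif planted motif (used when `adversarial`); its reverse
#'   complement goes into the partner target.
#' @param config [design_config()] used to tune planted candidates into the
#'   free-energy window.
#' @return list of class `target_fixture`: `regions` (list of
#'   [target_region()]), `planted` (data.frame of planted candidate
#'   sequences, empty unless adversarial), `seed`.
#' @export
make_targets <- function(n_targets = 96L, template_len = 250L, gc = 0.5,
                         pivot_width = 2L, seed = 1L,
                         max_amplicon_len = 150L,
                         adversarial = FALSE, motif = "GCAGTC",
                         config = design_config()) {
  stopifnot(n_targets >= 1L, pivot_width >= 1L)
  pivot_start <- (template_len - pivot_width) %/% 2L
  if (pivot_start < config$proto_min_len ||
      template_len - (pivot_start + pivot_width) < config$proto_min_len)
    stop("template too short to place proto-primers on both sides of the pivot",
         call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  planted <- data.frame(target_id = character(), strand = character(),
                        sequence = character())
  regions <- vector("list", n_targets)
  for (i in seq_len(n_targets)) {
    template <- .random_dna(template_len, gc)
    tid <- sprintf("t%03d", i)
    if (adversarial) {
      m <- if (i %% 2L == 1L) motif else revcomp(motif)
      p <- .tune_into_window(m, config$dg_window, config$params)
      # place p so the proto of length L (5' start pivot - L) trims to it,
      # leaving its motif at the candidate's 3' terminus
      L <- config$proto_min_len
      lp <- nchar(p)
      if (lp > L) stop("planted candidate longer than the proto", call. = FALSE)
      substr(template, pivot_start - L + 1L, pivot_start - L + lp) <- p
      planted <- rbind(planted,
                       data.frame(target_id = tid, strand = "forward",
                                  sequence = p))
    }
    regions[[i]] <- target_region(tid, template, pivot_start,
                                  pivot_start + pivot_width,
                                  max_amplicon_len = max_amplicon_len)
  }
  structure(list(regions = regions, planted = planted, seed = seed),
            class = "target_fixture")
}

#' Simulate an amplicon sequencing library
#'
#' Draws a class per read from `mix` and synthesizes its sequence from the
#' panel: on-target reads copy a random expected amplicon; dimer reads join
#' a random ordered primer pair through a 3' overlap so their length falls
#' below the summed primer lengths; non-specific reads place a random
#' insert longer than that sum between a primer and another primer's
#' reverse complement.
#'
#' @param panel a [primer_panel()].
#' @param mix named numeric, proportions for `on_target`, `dimer`,
#'   `nonspecific`; must sum to 1.
#' @param n_reads number of reads.
#' @param seed RNG seed.
#' @param max_overlap largest 3' overlap used for dimer reads.
#' @param min_suffix_match shortest surviving suffix-primer image; keep at
#'   or above the classifier's `min_anchor_match`.
#' @param nonspec_insert_range range of extra insert lengths for
#'   non-specific reads.
#' @return data.frame: `read_id`, `sequence`, `true_class`, `fp_index`,
#'   `rp_index` (simulated primer indices, NA for on-target), `target`
#'   (amplicon index, NA otherwise).
#' @export
simulate_reads <- function(panel,
                           mix = c(on_target = 0.7, dimer = 0.2,
                                   nonspecific = 0.1),
                           n_reads = 1000L, seed = 1L,
                           max_overlap = 8L, min_suffix_match = 8L,
                           nonspec_insert_range = 10:60) {
  stopifnot(abs(sum(mix) - 1) < 1e-8,
            all(names(mix) %in% c("on_target", "dimer", "nonspecific")))
  set.seed(seed %% .Machine$integer.max)
  n2 <- length(panel$primers)
  plen <- nchar(panel$primers)
  classes <- sample(names(mix), n_reads, replace = TRUE, prob = mix)
  seqs <- character(n_reads)
  fp_i <- rp_i <- tgt <- rep(NA_integer_, n_reads)
  for (r in seq_len(n_reads)) {
    if (classes[r] == "on_target") {
      tgt[r] <- sample.int(panel$n_targets, 1L)
      seqs[r] <- panel$amplicons[tgt[r]]
    } else {
      i <- sample.int(n2, 1L)
      if (classes[r] == "dimer") {
        # the 3' overlap shortens the suffix primer's image in the read by o
        # bases; draw the suffix primer long enough that the image stays at
        # or above the classifier's matching floor
        eligible <- which(plen > min_suffix_match)
        if (length(eligible) == 0L)
          stop("no primer long enough to leave a matchable dimer suffix",
               call. = FALSE)
        j <- eligible[sample.int(length(eligible), 1L)]
        fp_i[r] <- i
        rp_i[r] <- j
        o_max <- min(max_overlap, plen[j] - min_suffix_match)
        o <- sample.int(o_max, 1L)
        seqs[r] <- paste0(panel$primers[i],
                          substr(revcomp(panel$primers[j]), o + 1L, plen[j]))
      } else {
        j <- sample.int(n2, 1L)
        fp_i[r] <- i
        rp_i[r] <- j
        ins <- sample(nonspec_insert_range, 1L)
        seqs[r] <- paste0(panel$primers[i], .random_dna(ins),
                          revcomp(panel$primers[j]))
      }
    }
  }
  data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
             sequence = seqs, true_class = classes,
             fp_index = fp_i, rp_index = rp_i, target = tgt)
}
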