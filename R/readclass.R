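# Classification of amplicon sequencing reads.
#
# Adapter-trimmed reads are classified in two stages. Stage 1 matches each
# read against the panel's expected amplicon sequences within a bounded edit
# distance (on-target). Stage 2 matches the remaining reads' first bases
# against the merged primer list and their last bases against the primers'
# reverse complements -- forward primers can dimerize with other forward
# primers, so both read ends are matched against all 2N primers. A read
# whose total length (the insert) is shorter than the sum of its two
# matched primers' lengths is a dimer; longer is non-specific; reads
# without a primer match at both ends are unassigned.
#
# The 3' overlap that joins the two primers of a dimer consumes part of the
# suffix primer's image in the read, so suffix matching walks a truncation
# ladder: the last k bases of the read are compared against the last k of
# each primer's reverse complement, k descending from the full anchor down
# to a minimum match length, preferring the longest match, then the lowest
# edit distance, then the lowest primer index.

#' Assemble a primer panel for read classification
#'
#' @param fp,rp character vectors of forward / reverse primer sequences
#'   (equal length N); the merged indexing is fPs 1..N, rPs N+1..2N.
#' @param amplicons character vector of the N expected amplicon sequences
#'   (top strand). Each must start with its fP and end with revcomp(rP).
#' @param target_ids optional target identifiers.
#' @return a list of class `primer_panel`.
#' @export
primer_panel <- function(fp, rp, amplicons, target_ids = NULL) {
  stopifnot(length(fp) == length(rp), length(fp) == length(amplicons))
  n <- length(fp)
  ok <- startsWith(amplicons, fp) & endsWith(amplicons, revcomp(rp))
  if (!all(ok))
    stop("amplicon(s) ", paste(which(!ok), collapse = ", "),
         " do not contain their primers at the expected ends", call. = FALSE)
  structure(list(primers = c(fp, rp), n_targets = n,
                 amplicons = amplicons,
                 target_ids = target_ids %||% paste0("t", seq_len(n))),
            class = "primer_panel")
}

#' Build a classification panel from a designed primer set
#'
#' @param set_table output of [primer_set_table()].
#' @param regions the list of [target_region()] objects the set was
#'   designed for (same order).
#' @return a [primer_panel()].
#' @export
panel_from_design <- function(set_table, regions) {
  amps <- vapply(seq_len(nrow(set_table)), function(i) {
    substring(regions[[i]]$template,
              set_table$fp_start_5p[i] + 1L, set_table$rp_start_5p[i] + 1L)
  }, character(1L))
  primer_panel(set_table$fp_seq, set_table$rp_seq, amps,
               target_ids = set_table$target_id)
}

# Match one end of each read against every primer. side = "prefix" compares
# read starts to primer starts; side = "suffix" compares read ends to the
# ends of primer reverse complements, over truncation lengths k from the
# anchor down to min_match. Returns list(index, primer_len) with NA where
# no primer matched.
.match_end <- function(reads, primers, side, max_mismatch, anchor_len,
                       min_match) {
  n_reads <- length(reads)
  idx <- rep(NA_integer_, n_reads)
  plen <- vapply(primers, nchar, integer(1L), USE.NAMES = FALSE)
  rlen <- nchar(reads)
  rc_primers <- if (side == "suffix") revcomp(primers) else NULL

  k_max <- min(anchor_len, max(plen))
  for (k in seq.int(k_max, min_match)) {
    open <- is.na(idx) & rlen >= k
    if (!any(open)) break
    for (j in seq_along(primers)) {
      if (k > min(plen[j], anchor_len)) next
      probe <- if (side == "prefix") substr(primers[j], 1L, k)
               else substr(rc_primers[j], plen[j] - k + 1L, plen[j])
      hit <- open & (if (side == "prefix") startsWith(reads, probe)
                     else endsWith(reads, probe))
      idx[hit] <- j
      open <- open & !hit
    }
    # full-length anchors get a fuzzy pass before shorter exact ones
    if (max_mismatch > 0L) {
      for (j in seq_along(primers)) {
        if (k != min(plen[j], anchor_len)) next
        who <- which(open)
        if (length(who) == 0L) next
        probe <- if (side == "prefix") substr(primers[j], 1L, k)
                 else substr(rc_primers[j], plen[j] - k + 1L, plen[j])
        frag <- if (side == "prefix") substr(reads[who], 1L, k)
                else substr(reads[who], rlen[who] - k + 1L, rlen[who])
        ed <- drop(utils::adist(frag, probe))
        hit <- who[ed <= max_mismatch]
        idx[hit] <- j
        open[hit] <- FALSE
      }
    }
  }
  list(index = idx, primer_len = ifelse(is.na(idx), NA_integer_, plen[idx]))
}

#' Classify reads as on-target, dimer, non-specific or unassigned
#'
#' @param reads character vector of adapter-trimmed read sequences.
#' @param panel a [primer_panel()].
#' @param max_mismatch edit-distance tolerance: per 100 nt of amplicon in
#'   stage 1, per anchor in stage 2. `0` demands exact matches.
#' @param anchor_len how many bases of each read end are matched against
#'   primers (default 25).
#' @param min_anchor_match shortest truncated suffix/prefix match accepted.
#' @return data.frame with one row per read: `read_id`, `class`, `target`
#'   (stage-1 amplicon index or NA), `fp_index`, `rp_index` (merged primer
#'   indices or NA) and `insert_len`.
#' @export
classify_reads <- function(reads, panel, max_mismatch = 2L,
                           anchor_len = 25L, min_anchor_match = 8L) {
  n <- length(reads)
  cls <- rep("unassigned", n)
  target <- rep(NA_integer_, n)
  insert_len <- nchar(reads)

  # stage 1: on-target
  target <- match(reads, panel$amplicons)
  if (max_mismatch > 0L) {
    open <- which(is.na(target) & insert_len > 0L)
    if (length(open) > 0L) {
      amp_len <- nchar(panel$amplicons)
      allowed <- ceiling(max_mismatch * amp_len / 100)
      ed <- utils::adist(reads[open], panel$amplicons)
      ed[!sweep(ed, 2L, allowed, `<=`)] <- Inf
      best <- apply(ed, 1L, which.min)
      hit <- is.finite(ed[cbind(seq_along(open), best)])
      target[open[hit]] <- best[hit]
    }
  }
  cls[!is.na(target)] <- "on_target"

  # stage 2: primer-end matching of the remainder
  rest <- which(is.na(target) & insert_len >= min_anchor_match)
  fp_index <- rp_index <- rep(NA_integer_, n)
  if (length(rest) > 0L) {
    pre <- .match_end(reads[rest], panel$primers, "prefix",
                      max_mismatch, anchor_len, min_anchor_match)
    suf <- .match_end(reads[rest], panel$primers, "suffix",
                      max_mismatch, anchor_len, min_anchor_match)
    fp_index[rest] <- pre$index
    rp_index[rest] <- suf$index
    both <- rest[!is.na(pre$index) & !is.na(suf$index)]
    if (length(both) > 0L) {
      sum_len <- pre$primer_len[match(both, rest)] +
        suf$primer_len[match(both, rest)]
      cls[both] <- ifelse(insert_len[both] < sum_len, "dimer", "nonspecific")
    }
  }
  data.frame(read_id = if (is.null(names(reads))) seq_len(n) else names(reads),
             class = cls, target = target,
             fp_index = fp_index, rp_index = rp_index,
             insert_len = insert_len, row.names = NULL)
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read one read sequence.
#' @return a one-row data.frame as from [classify_reads()].
#' @export
classify_read <- function(read, panel, max_mismatch = 2L,
                          anchor_len = 25L, min_anchor_match = 8L) {
  classify_reads(read, panel, max_mismatch, anchor_len, min_anchor_match)
}

#' Tabulate classified reads
#'
#' Computes class fractions over classified (non-unassigned) reads, the
#' ordered per-primer-pair dimer read count matrix over the merged 2N-primer
#' indexing, and per-target on-target counts.
#'
#' @param records data.frame from [classify_reads()].
#' @param panel the [primer_panel()] the records were classified against.
#' @param per_million if `TRUE`, scale counts to reads per million
#'   classified reads.
#' @return a list of class `read_tabulation`: `fractions` (named numeric
#'   over on_target/dimer/nonspecific), `counts` (all four classes),
#'   `dimer_matrix` (2N x 2N, rows = prefix primer, cols = suffix primer),
#'   `on_target_counts` (per target), `n_classified`, `n_total`.
#' @export
tabulate_reads <- function(records, panel, per_million = FALSE) {
  n2 <- 2L * panel$n_targets
  counts <- c(on_target = sum(records$class == "on_target"),
              dimer = sum(records$class == "dimer"),
              nonspecific = sum(records$class == "nonspecific"),
              unassigned = sum(records$class == "unassigned"))
  n_classified <- sum(counts[c("on_target", "dimer", "nonspecific")])
  if (n_classified == 0L) {
    warning("no classified reads; fractions reported as 0", call. = FALSE)
    fractions <- c(on_target = 0, dimer = 0, nonspecific = 0)
  } else {
    fractions <- counts[c("on_target", "dimer", "nonspecific")] / n_classified
  }
  dm <- matrix(0, n2, n2)
  dimers <- records[records$class == "dimer", , drop = FALSE]
  if (nrow(dimers) > 0L) {
    tab <- table(factor(dimers$fp_index, levels = seq_len(n2)),
                 factor(dimers$rp_index, levels = seq_len(n2)))
    dm <- unclass(tab)
    dimnames(dm) <- NULL
  }
  ot <- tabulate(records$target[records$class == "on_target"],
                 nbins = panel$n_targets)
  scale <- if (per_million && n_classified > 0L) 1e6 / n_classified else 1
  structure(list(fractions = fractions, counts = counts,
                 dimer_matrix = dm * scale, on_target_counts = ot * scale,
                 n_classified = n_classified, n_total = nrow(records)),
            class = "read_tabulation")
}
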