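# Primer candidate generation.
#
# For each target a set of "pivot" nucleotides must be contained in the
# amplicon insert. Proto-primers are enumerated with their 3' end abutting
# the pivot on either side and a range of 5' starts, then trimmed from the
# 3' end until the duplex free energy falls inside a configured window.
# Surviving truncations are filtered on G/C content, deduplicated, and
# combined combinatorially into admissible forward/reverse pairs.
#
# Coordinates are 0-based, half-open on the top (template) strand; reverse
# strand oligos are stored 5'->3' as synthesized, with `start_5p` the
# template coordinate of the 5'-most template base they cover (their
# rightmost base on the top strand).

#' Describe a target region
#'
#' @param target_id identifier for the target.
#' @param template top-strand template sequence, 5'->3'.
#' @param pivot_start,pivot_end 0-based half-open interval of template
#'   positions that must lie inside the amplicon insert.
#' @param min_amplicon_len,max_amplicon_len amplicon length bounds in nt.
#'   `min_amplicon_len = NA` applies the per-pair default
#'   `len(fP) + len(rP) + pivot width + 10`.
#' @return an object of class `target_region`.
#' @export
target_region <- function(target_id, template, pivot_start, pivot_end,
                          min_amplicon_len = NA_integer_,
                          max_amplicon_len = 150L) {
  template <- check_dna(template, min_len = 2L, what = "template")
  stopifnot(pivot_start >= 0, pivot_start < pivot_end,
            pivot_end <= nchar(template))
  if (!is.na(min_amplicon_len) && min_amplicon_len > max_amplicon_len)
    stop("min_amplicon_len exceeds max_amplicon_len", call. = FALSE)
  structure(
    list(target_id = as.character(target_id), template = template,
         pivot_start = as.integer(pivot_start),
         pivot_end = as.integer(pivot_end),
         min_amplicon_len = as.integer(min_amplicon_len),
         max_amplicon_len = as.integer(max_amplicon_len)),
    class = "target_region")
}

#' Design configuration
#'
#' Tunables for candidate generation. The free-energy window and G/C bounds
#' default to the design criteria used throughout the package; both are
#' boundary-inclusive.
#'
#' @param dg_window numeric length-2, `c(lo, hi)` in kcal/mol; candidates
#'   must satisfy `lo <= dG <= hi`.
#' @param gc_min,gc_max inclusive G/C-fraction bounds.
#' @param proto_min_len,proto_max_len proto-primer length range (nt).
#' @param min_primer_len shortest candidate retained after trimming (nt).
#' @param params an [nn_params()] thermodynamic parameter set.
#' @return a list of class `design_config`.
#' @export
design_config <- function(dg_window = c(-12.5, -10.5),
                          gc_min = 0.25, gc_max = 0.75,
                          proto_min_len = 18L, proto_max_len = 45L,
                          min_primer_len = 8L,
                          params = nn_params()) {
  stopifnot(length(dg_window) == 2L, dg_window[1L] <= dg_window[2L],
            gc_min <= gc_max, proto_min_len <= proto_max_len,
            min_primer_len >= 4L)
  structure(list(dg_window = as.numeric(dg_window),
                 gc_min = gc_min, gc_max = gc_max,
                 proto_min_len = as.integer(proto_min_len),
                 proto_max_len = as.integer(proto_max_len),
                 min_primer_len = as.integer(min_primer_len),
                 params = params),
            class = "design_config")
}

#' Enumerate proto-primers for one side of the pivot
#'
#' Proto-primers have their 3' terminal base abutting the pivot interval:
#' forward protos end at template position `pivot_start - 1`, reverse protos
#' (stored as bottom-strand oligos, 5'->3') end at `pivot_end`. One proto is
#' produced per admissible 5' start, lengths spanning `min_len:max_len`.
#'
#' @param region a [target_region()].
#' @param strand `"forward"` or `"reverse"`.
#' @param min_len,max_len proto length range (nt).
#' @return data.frame with columns `start_5p`, `length`, `sequence`. Empty
#'   (with a warning naming the target) when the template is too short on
#'   that side.
#' @export
generate_proto_primers <- function(region, strand = c("forward", "reverse"),
                                   min_len = 18L, max_len = 45L) {
  strand <- match.arg(strand)
  avail <- if (strand == "forward") region$pivot_start
           else nchar(region$template) - region$pivot_end
  lens <- seq.int(min_len, max_len)
  lens <- lens[lens <= avail]
  if (length(lens) == 0L) {
    warning("target ", region$target_id, ": template too short on the ",
            strand, " side of the pivot; no proto-primers", call. = FALSE)
    return(data.frame(start_5p = integer(), length = integer(),
                      sequence = character()))
  }
  if (strand == "forward") {
    # covers [pivot_start - L, pivot_start), 0-based half-open
    from <- region$pivot_start - lens            # 0-based start
    seqs <- substring(region$template, from + 1L, region$pivot_start)
    data.frame(start_5p = from, length = lens, sequence = seqs)
  } else {
    # covers [pivot_end, pivot_end + L); oligo is the bottom strand
    to <- region$pivot_end + lens                # 0-based exclusive end
    seqs <- revcomp(substring(region$template, region$pivot_end + 1L, to))
    data.frame(start_5p = to - 1L, length = lens, sequence = seqs)
  }
}

#' Trim a proto-primer into the free-energy window
#'
#' Starting from the full proto, bases are removed one at a time from the 3'
#' end. Every truncation whose duplex free energy lies inside the window is
#' emitted; trimming stops at the first truncation less stable than the
#' window's upper bound (the free energy is monotone in length under the
#' default table) or when the minimum primer length is reached. Because base
#' stacks are coarse-grained, one proto can yield zero, one or several
#' candidates.
#'
#' @param proto proto-primer sequence, 5'->3'.
#' @param window `c(lo, hi)` free-energy window in kcal/mol, inclusive.
#' @param params an [nn_params()] parameter set.
#' @param min_len shortest truncation considered.
#' @return data.frame with columns `length`, `dG` (possibly zero rows),
#'   lengths in decreasing order.
#' @export
trim_to_window <- function(proto, window = c(-12.5, -10.5),
                           params = nn_params(), min_len = 8L) {
  proto <- check_dna(proto, min_len = max(2L, min_len), what = "proto-primer")
  dgs <- .prefix_dgs(proto, params)   # dG of prefixes length 2..n
  keep_len <- integer()
  keep_dg <- numeric()
  for (k in seq.int(nchar(proto), min_len)) {
    dg <- dgs[k - 1L]
    if (dg > window[2L]) break
    if (dg >= window[1L]) {
      keep_len <- c(keep_len, k)
      keep_dg <- c(keep_dg, dg)
    }
  }
  data.frame(length = keep_len, dG = keep_dg)
}

#' Filter candidates on G/C content
#'
#' Retains candidates with `lo <= gc <= hi` (boundary-inclusive).
#'
#' @param cands candidate data.frame with a `gc` column.
#' @param lo,hi inclusive bounds on the G/C fraction.
#' @return the filtered data.frame.
#' @export
filter_gc <- function(cands, lo = 0.25, hi = 0.75) {
  cands[cands$gc >= lo & cands$gc <= hi, , drop = FALSE]
}

#' Generate all primer candidates for a target
#'
#' Runs proto-primer enumeration, 3'-end trimming into the free-energy
#' window and the G/C filter for both strands, deduplicating candidates with
#' identical (strand, sequence) and keeping the first coordinates seen.
#'
#' @param region a [target_region()].
#' @param config a [design_config()].
#' @return data.frame with one row per candidate: `target_id`, `strand`,
#'   `sequence`, `start_5p`, `length`, `dG`, `gc`, `self_badness`.
#' @export
generate_candidates <- function(region, config = design_config()) {
  one_strand <- function(strand) {
    protos <- generate_proto_primers(region, strand,
                                     config$proto_min_len,
                                     config$proto_max_len)
    if (nrow(protos) == 0L)
      return(NULL)
    out <- lapply(seq_len(nrow(protos)), function(i) {
      tr <- trim_to_window(protos$sequence[i], config$dg_window,
                           config$params, config$min_primer_len)
      if (nrow(tr) == 0L) return(NULL)
      seqs <- substring(protos$sequence[i], 1L, tr$length)
      data.frame(target_id = region$target_id, strand = strand,
                 sequence = seqs, start_5p = protos$start_5p[i],
                 length = tr$length, dG = tr$dG)
    })
    do.call(rbind, out)
  }
  cands <- rbind(one_strand("forward"), one_strand("reverse"))
  if (is.null(cands) || nrow(cands) == 0L)
    return(data.frame(target_id = character(), strand = character(),
                      sequence = character(), start_5p = integer(),
                      length = integer(), dG = numeric(), gc = numeric(),
                      self_badness = numeric()))
  cands <- cands[!duplicated(cands[c("strand", "sequence")]), , drop = FALSE]
  cands$gc <- gc_fraction(cands$sequence)
  cands <- filter_gc(cands, config$gc_min, config$gc_max)
  cands$self_badness <- vapply(cands$sequence,
                               function(s) badness_pair(s, s), numeric(1L),
                               USE.NAMES = FALSE)
  rownames(cands) <- NULL
  cands
}

# 0-based template coordinate of a candidate's 3' terminal base.
.end3_coord <- function(cand) {
  ifelse(cand$strand == "forward",
         cand$start_5p + cand$length - 1L,
         cand$start_5p - cand$length + 1L)
}

#' Enumerate admissible forward/reverse candidate pairs
#'
#' Takes the Cartesian product of forward and reverse candidates and keeps
#' pairs whose amplicon length lies within the target's bounds and whose
#' insert (the region strictly between the two 3' ends) contains the whole
#' pivot interval. The amplicon spans from the forward primer's 5' start to
#' the reverse primer's 5' start, inclusive.
#'
#' @param region a [target_region()].
#' @param fps,rps forward / reverse candidate data.frames as produced by
#'   [generate_candidates()] (rows with the matching strand).
#' @return data.frame with columns `target_id`, `fp` and `rp` (row indices
#'   into `fps` / `rps`), `amplicon_len`, `insert_len`.
#' @export
enumerate_pairs <- function(region, fps, rps) {
  if (nrow(fps) == 0L || nrow(rps) == 0L)
    stop("target ", region$target_id,
         ": undesignable (no candidates on one side)", call. = FALSE)
  grid <- expand.grid(fp = seq_len(nrow(fps)), rp = seq_len(nrow(rps)))
  f <- fps[grid$fp, ]
  r <- rps[grid$rp, ]
  amplicon_len <- r$start_5p - f$start_5p + 1L
  f3 <- f$start_5p + f$length - 1L
  r3 <- r$start_5p - r$length + 1L
  insert_len <- r3 - f3 - 1L
  min_amp <- if (is.na(region$min_amplicon_len))
    f$length + r$length + (region$pivot_end - region$pivot_start) + 10L
  else region$min_amplicon_len
  ok <- amplicon_len >= min_amp &
    amplicon_len <= region$max_amplicon_len &
    f3 < region$pivot_start & r3 >= region$pivot_end &
    insert_len >= (region$pivot_end - region$pivot_start)
  if (!any(ok))
    stop("target ", region$target_id, ": undesignable (no admissible pairs)",
         call. = FALSE)
  data.frame(target_id = region$target_id,
             fp = grid$fp[ok], rp = grid$rp[ok],
             amplicon_len = amplicon_len[ok], insert_len = insert_len[ok],
             row.names = NULL)
}

#' Build the per-target candidate-pair lists for a panel
#'
#' Convenience wrapper running [generate_candidates()] and
#' [enumerate_pairs()] over a list of targets. The result is the input
#' expected by the annealing optimizer.
#'
#' @param regions list of [target_region()] objects.
#' @param config a [design_config()].
#' @return named list (by target_id); each element holds `region`, `fps`,
#'   `rps` (candidate data.frames) and `pairs` (admissible pair table).
#' @export
panel_candidates <- function(regions, config = design_config()) {
  out <- lapply(regions, function(region) {
    cands <- generate_candidates(region, config)
    fps <- cands[cands$strand == "forward", , drop = FALSE]
    rps <- cands[cands$strand == "reverse", , drop = FALSE]
    rownames(fps) <- rownames(rps) <- NULL
    pairs <- enumerate_pairs(region, fps, rps)
    list(region = region, fps = fps, rps = rps, pairs = pairs)
  })
  names(out) <- vapply(regions, `[[`, character(1L), "target_id")
  out
}

#' Expected amplicon sequence of a candidate pair
#'
#' @param region a [target_region()].
#' @param fp,rp single-row candidate data.frames (forward / reverse).
#' @return the top-strand amplicon sequence from the forward primer's 5'
#'   start through the reverse primer's 5' start.
#' @export
amplicon_sequence <- function(region, fp, rp) {
  substring(region$template, fp$start_5p + 1L, rp$start_5p + 1L)
}
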