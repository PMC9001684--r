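# Mutable primer-set state for the optimizer.
#
# A primer set holds one forward/reverse candidate pair per target together
# with cached loss state: the subsequence hash table over all selected
# primers, the ordered-pair cross sum, and the pre-computed self-badness
# sum. Swapping one target's pair touches only the four affected primers'
# subsequences, so a swap costs O(P) hash edits instead of a full O(N*P)
# re-evaluation.

# Attach primer_profile objects to every candidate of a panel (idempotent).
prepare_panel <- function(panel) {
  lapply(panel, function(tgt) {
    if (!is.null(tgt$fp_profiles)) return(tgt)
    tgt$fp_profiles <- lapply(tgt$fps$sequence, primer_profile)
    tgt$rp_profiles <- lapply(tgt$rps$sequence, primer_profile)
    tgt
  })
}

.pair_profiles <- function(tgt, pair_row) {
  list(fp = tgt$fp_profiles[[tgt$pairs$fp[pair_row]]],
       rp = tgt$rp_profiles[[tgt$pairs$rp[pair_row]]])
}

#' Create a primer set from an explicit selection
#'
#' @param panel per-target candidate structure from [panel_candidates()].
#' @param selection named integer vector: for every target, the selected row
#'   of that target's `pairs` table.
#' @return an environment of class `primer_set` with fields `panel`,
#'   `selection`, `H` (subsequence hash), `cross` (ordered-pair double sum),
#'   `sum_self`. Query the loss with [set_loss()].
#' @export
new_primer_set <- function(panel, selection) {
  panel <- prepare_panel(panel)
  targets <- names(panel)
  if (!setequal(names(selection), targets) || anyNA(selection))
    stop("selection must name exactly one pair row per target", call. = FALSE)
  set <- new.env(parent = emptyenv())
  set$panel <- panel
  set$selection <- selection[targets]
  profs <- unlist(lapply(targets, function(t)
    .pair_profiles(panel[[t]], selection[[t]])), recursive = FALSE)
  set$H <- build_hash(profs)
  set$sum_self <- sum(vapply(profs, `[[`, numeric(1L), "self"))
  set$cross <- sum(vapply(profs, .score_against_hash, numeric(1L),
                          H = set$H))
  class(set) <- "primer_set"
  set
}

#' Current loss of a primer set
#'
#' @param set a `primer_set`.
#' @return `cross/2 + sum_self/2`, the set's dimer-likelihood loss.
#' @export
set_loss <- function(set) set$cross / 2 + set$sum_self / 2

# Recompute `cross` from the hash table (O(N*P)); called periodically during
# long optimizations to cap floating-point drift from incremental updates.
refresh_cross <- function(set) {
  profs <- selected_profiles(set)
  set$cross <- sum(vapply(profs, .score_against_hash, numeric(1L),
                          H = set$H))
  invisible(set_loss(set))
}

selected_profiles <- function(set) {
  unlist(lapply(names(set$panel), function(t)
    .pair_profiles(set$panel[[t]], set$selection[[t]])), recursive = FALSE)
}

#' Selected primer sequences of a set
#'
#' @param set a `primer_set`.
#' @return character vector of the 2N selected primer sequences.
#' @export
selected_primers <- function(set) {
  vapply(selected_profiles(set), `[[`, character(1L), "seq")
}

.remove_primer <- function(set, prof) {
  sc <- .score_against_hash(prof, set$H)
  set$cross <- set$cross - (2 * sc - prof$self)
  set$sum_self <- set$sum_self - prof$self
  hash_add(set$H, prof$keys, prof$w, sign = -1)
}

.add_primer <- function(set, prof) {
  hash_add(set$H, prof$keys, prof$w, sign = 1)
  sc <- .score_against_hash(prof, set$H)
  set$cross <- set$cross + (2 * sc - prof$self)
  set$sum_self <- set$sum_self + prof$self
}

#' Swap one target's primer pair, updating the loss incrementally
#'
#' Removes the incumbent pair's subsequence weights from the hash table,
#' inserts the replacement's, and corrects the cached cross and self sums.
#' The updated loss equals a from-scratch re-evaluation up to floating-point
#' error. Swapping a pair for itself leaves the loss unchanged exactly;
#' swapping and swapping back restores it.
#'
#' @param set a `primer_set` (modified in place).
#' @param target_id the target whose pair is replaced.
#' @param pair_row row of that target's `pairs` table to select.
#' @return the new loss, invisibly.
#' @export
swap_update <- function(set, target_id, pair_row) {
  tgt <- set$panel[[target_id]]
  if (is.null(tgt))
    stop("unknown target: ", target_id, call. = FALSE)
  old_row <- set$selection[[target_id]]
  if (pair_row == old_row)
    return(invisible(set_loss(set)))
  old <- .pair_profiles(tgt, old_row)
  new <- .pair_profiles(tgt, pair_row)
  .remove_primer(set, old$fp)
  .remove_primer(set, old$rp)
  .add_primer(set, new$fp)
  .add_primer(set, new$rp)
  set$selection[[target_id]] <- pair_row
  invisible(set_loss(set))
}

#' Tabulate a primer set's selected pairs
#'
#' @param set a `primer_set`, or a `panel` plus explicit `selection`.
#' @param panel,selection alternative to `set`: the candidate structure and
#'   a named pair-row vector.
#' @return data.frame with one row per target: primer sequences,
#'   coordinates (0-based), free energies and amplicon geometry.
#' @export
primer_set_table <- function(set = NULL, panel = NULL, selection = NULL) {
  if (!is.null(set)) {
    panel <- set$panel
    selection <- set$selection
  }
  rows <- lapply(names(panel), function(t) {
    tgt <- panel[[t]]
    i <- selection[[t]]
    fp <- tgt$fps[tgt$pairs$fp[i], ]
    rp <- tgt$rps[tgt$pairs$rp[i], ]
    data.frame(target_id = t,
               fp_seq = fp$sequence, fp_start_5p = fp$start_5p,
               fp_len = fp$length, fp_dG = fp$dG,
               rp_seq = rp$sequence, rp_start_5p = rp$start_5p,
               rp_len = rp$length, rp_dG = rp$dG,
               amplicon_len = tgt$pairs$amplicon_len[i],
               insert_len = tgt$pairs$insert_len[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
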