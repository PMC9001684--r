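# Dimer-likelihood scoring.
#
# The pairwise score ("badness") of two primers sums, over every pair of
# positions at which a subsequence of one primer (length 4-8) is the reverse
# complement of a subsequence of the other,
#
#     2^len * 2^numGC / ((d1 + 1) * (d2 + 1))
#
# where len is the subsequence length, numGC its G/C count, and d1, d2 the
# distances of the two hits to their primers' 3' ends (d = 0 when the hit
# includes the 3' terminal base). All substrings of length 4-8 contribute,
# not only maximal complementary runs: a 6-nt complement also scores its
# internal 4- and 5-mers. The exponential terms crudely mirror a duplex
# partition function with G/C pairs twice as strong as A/T; the distance
# attenuation encodes that 3'-proximal complementarity is what seeds primer
# extension.
#
# The set-level loss L(S) = sum over unordered primer pairs (self-pairs
# included once) equals
#
#     1/2 * sum_{a,b} Badness(p_a, p_b)  +  1/2 * sum_a Badness(p_a, p_a)
#
# and the ordered double sum factorises through a hash table H mapping each
# subsequence s to sum 1/(d+1) over its occurrences in the set, giving the
# O(N*P) evaluation  sum_s (2^len * 2^numGC)/(d+1) * H[revcomp(s)]  and O(P)
# incremental updates when one primer pair is swapped.

BADNESS_MIN_LEN <- 4L
BADNESS_MAX_LEN <- 8L

# Enumerate all substrings of length 4-8 of one primer. Returns per-occurrence
# vectors: the substring, its 3'-distance weight 1/(d+1), and the coefficient
# 2^len * 2^numGC (a function of the substring only).
.subseq_occurrences <- function(p) {
  n <- nchar(p)
  sub <- character()
  w <- numeric()
  for (len in BADNESS_MIN_LEN:min(BADNESS_MAX_LEN, n)) {
    i <- seq_len(n - len + 1L)
    sub <- c(sub, substring(p, i, i + len - 1L))
    d <- n - (i + len - 1L)          # 0 when the hit ends at the 3' terminus
    w <- c(w, 1 / (d + 1))
  }
  list(sub = sub, w = w)
}

#' Per-primer subsequence profile
#'
#' Aggregates a primer's substring occurrences (lengths 4-8) by subsequence:
#' `w[k]` is the summed 1/(d+1) positional weight of subsequence `keys[k]`,
#' `coef[k]` its `2^len * 2^numGC` factor, and `rc[k]` its reverse
#' complement (the hash key it must be looked up under). `self` caches the
#' primer's badness against itself. Profiles are the unit of work for hash
#' construction, loss evaluation and swap updates.
#'
#' @param p primer sequence (A/C/G/T, length >= 4).
#' @return a list of class `primer_profile`.
#' @export
primer_profile <- function(p) {
  p <- check_dna(p, min_len = BADNESS_MIN_LEN, what = "primer")
  occ <- .subseq_occurrences(p)
  w <- vapply(split(occ$w, occ$sub), sum, numeric(1L))
  keys <- names(w)
  coef <- 2^nchar(keys) * 2^(stringi::stri_count_charclass(keys, "[GC]"))
  prof <- list(seq = p, keys = keys, w = unname(w), coef = unname(coef),
               rc = revcomp(keys))
  # self-badness via the aggregated identity: ordered position pairs within
  # the same sequence, so a palindromic self-hit at two positions counts in
  # both orders.
  m <- match(prof$rc, prof$keys)
  hit <- !is.na(m)
  prof$self <- sum(prof$coef[hit] * prof$w[hit] * prof$w[m[hit]])
  class(prof) <- "primer_profile"
  prof
}

#' Pairwise dimer-likelihood score of two primers
#'
#' Sums `2^len * 2^numGC / ((d1+1)(d2+1))` over every ordered pair of
#' positions at which a length-4..8 substring of `pa` is the reverse
#' complement of a substring of `pb`. Symmetric in its arguments; zero when
#' the primers share no complementary 4-mer (up to 3 nt of 3'-end
#' complementarity is deliberately ignored, as it does not seed appreciable
#' dimer formation).
#'
#' @param pa,pb primer sequences (A/C/G/T, length >= 4), or
#'   `primer_profile` objects.
#' @return non-negative numeric score.
#' @export
#' @examples
#' badness_pair("GGGGACGT", "CCCCACGT")  # 74.24
#' badness_pair("AAAAAAAA", "AAAAAAAA")  # 0: A-runs are self-incompatible
badness_pair <- function(pa, pb) {
  a <- if (inherits(pa, "primer_profile")) pa else primer_profile(pa)
  b <- if (inherits(pb, "primer_profile")) pb else primer_profile(pb)
  m <- match(a$rc, b$keys)
  hit <- !is.na(m)
  sum(a$coef[hit] * a$w[hit] * b$w[m[hit]])
}

#' Set loss by direct pairwise summation
#'
#' Evaluates the loss as the sum of [badness_pair()] over all unordered
#' primer pairs plus each primer's self term, in O(N^2 P^2) time. This is
#' the reference evaluation; [loss_hash()] must agree with it and is what
#' production code uses.
#'
#' @param primers character vector of primer sequences, or a list of
#'   [primer_profile()] objects.
#' @return the loss (non-negative numeric).
#' @export
loss_brute_force <- function(primers) {
  profs <- lapply(primers, function(p)
    if (inherits(p, "primer_profile")) p else primer_profile(p))
  n <- length(profs)
  total <- sum(vapply(profs, `[[`, numeric(1L), "self"))
  if (n > 1L) {
    for (a in seq_len(n - 1L))
      for (b in seq.int(a + 1L, n))
        total <- total + badness_pair(profs[[a]], profs[[b]])
  }
  total
}

# --- subsequence hash table -------------------------------------------------

#' Build the subsequence hash table for a primer multiset
#'
#' Maps every subsequence `s` (length 4-8) occurring in any primer to
#' `sum 1/(d+1)` over all occurrences, `d` being each occurrence's distance
#' to its primer's 3' end. Stored as an environment so incremental updates
#' are cheap.
#'
#' @param primers character vector of sequences or list of profiles.
#' @return an environment of class `subseq_hash`.
#' @export
build_hash <- function(primers) {
  H <- new.env(parent = emptyenv(), size = 4096L)
  class(H) <- "subseq_hash"
  for (p in primers) {
    prof <- if (inherits(p, "primer_profile")) p else primer_profile(p)
    hash_add(H, prof$keys, prof$w)
  }
  H
}

#' Add (or subtract) subsequence weights in a hash table
#'
#' @param H a `subseq_hash` environment.
#' @param keys character vector of subsequences (unique within the call).
#' @param w numeric weights to add.
#' @param sign `+1` to insert, `-1` to remove.
#' @return `H`, invisibly.
#' @export
hash_add <- function(H, keys, w, sign = 1) {
  cur <- unlist(mget(keys, envir = H, ifnotfound = 0), use.names = FALSE)
  val <- cur + sign * w
  for (k in seq_along(keys))
    assign(keys[k], val[k], envir = H)
  invisible(H)
}

# sum_q Badness(p, q) over the multiset the hash was built from (q includes
# p itself whenever p's own weights are in H).
.score_against_hash <- function(prof, H) {
  hv <- unlist(mget(prof$rc, envir = H, ifnotfound = 0), use.names = FALSE)
  sum(prof$coef * prof$w * hv)
}

#' Set loss via the subsequence hash table
#'
#' Computes the ordered double sum `sum_{a,b} Badness(p_a, p_b)` by scoring
#' each primer's subsequences against `H[revcomp(s)]`, halves it, and adds
#' half the pre-computed self-term sum. Agrees with [loss_brute_force()] to
#' within floating-point error on any input.
#'
#' @param primers sequences or profiles; the multiset `H` was built over.
#' @param H hash table from [build_hash()].
#' @param sum_self `sum_a Badness(p_a, p_a)`; computed from the profiles
#'   when omitted.
#' @return the loss.
#' @export
loss_hash <- function(primers, H, sum_self = NULL) {
  profs <- lapply(primers, function(p)
    if (inherits(p, "primer_profile")) p else primer_profile(p))
  if (is.null(sum_self))
    sum_self <- sum(vapply(profs, `[[`, numeric(1L), "self"))
  cross <- sum(vapply(profs, .score_against_hash, numeric(1L), H = H))
  cross / 2 + sum_self / 2
}
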