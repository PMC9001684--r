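# Nearest-neighbor duplex free energy.
#
# Candidate generation trims primers until their hybridization free energy
# to the perfect complement falls in a configured window, so only relative
# consistency of the parameter table matters; no salt or temperature
# correction is applied.

# Unified nearest-neighbor ΔG°37 stack values (kcal/mol), keyed by the
# top-strand dinucleotide step read 5'->3'.
.UNIFIED_STACK_DG <- c(
  AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
  CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
  GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
  TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00
)

#' Nearest-neighbor parameter set
#'
#' Bundles dinucleotide stack free energies with duplex initiation penalties.
#' The default is the unified nearest-neighbor ΔG°37 table with per-end
#' initiation penalties (0.98 kcal/mol for a terminal G·C, 1.03 kcal/mol for
#' a terminal A·T). Alternative conditions are a data change: supply your own
#' table here or load one with [read_nn_params()].
#'
#' @param stack_dG named numeric vector of length 16: stack free energy
#'   (kcal/mol) for every dinucleotide step, names `"AA"`, `"AC"`, ...,
#'   top strand 5'->3'.
#' @param init_GC,init_AT duplex initiation penalty (kcal/mol) applied once
#'   per duplex end with a terminal G·C (resp. A·T) pair.
#' @param source_label free-text identifier of the parameter table.
#' @return an object of class `nn_params`.
#' @export
#' @examples
#' p <- nn_params()
#' duplex_dg("ACGTACGTACGT", p)
nn_params <- function(stack_dG = .UNIFIED_STACK_DG,
                      init_GC = 0.98, init_AT = 1.03,
                      source_label = "unified_dG37") {
  steps <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, 4L))
  if (!all(steps %in% names(stack_dG)))
    stop("stack_dG must name all 16 dinucleotide steps", call. = FALSE)
  stack_dG <- stack_dG[steps]
  if (any(!is.finite(stack_dG)))
    stop("all stack_dG values must be finite", call. = FALSE)
  structure(
    list(stack_dG = stack_dG,
         init_terms = c(init_GC = init_GC, init_AT = init_AT),
         source_label = source_label),
    class = "nn_params")
}

#' Load nearest-neighbor parameters from a TSV file
#'
#' The file must be tab-separated with a header and columns `step` and `dG`
#' listing all 16 dinucleotide steps; optional rows with step `init_GC` /
#' `init_AT` override the initiation penalties.
#'
#' @param path path to the TSV file.
#' @param source_label identifier stored in the returned object.
#' @return an `nn_params` object.
#' @export
read_nn_params <- function(path, source_label = basename(path)) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("step", "dG") %in% names(tab)))
    stop("parameter TSV needs columns 'step' and 'dG'", call. = FALSE)
  vals <- setNames(tab$dG, tab$step)
  init_GC <- if ("init_GC" %in% names(vals)) unname(vals[["init_GC"]]) else 0.98
  init_AT <- if ("init_AT" %in% names(vals)) unname(vals[["init_AT"]]) else 1.03
  nn_params(vals[!names(vals) %in% c("init_GC", "init_AT")],
            init_GC = init_GC, init_AT = init_AT,
            source_label = source_label)
}

.end_penalty <- function(base, params) {
  ifelse(base %in% c("G", "C"),
         params$init_terms[["init_GC"]], params$init_terms[["init_AT"]])
}

#' Standard free energy of a primer bound to its perfect complement
#'
#' Sums nearest-neighbor dinucleotide stack terms over the sequence and adds
#' the two end initiation penalties. More negative values mean a more stable
#' duplex. Used as the trimming criterion during primer candidate generation.
#'
#' @param sequence DNA string, 5'->3', alphabet A/C/G/T, length >= 2.
#' @param params an [nn_params()] parameter set.
#' @return free energy in kcal/mol (scalar).
#' @export
#' @examples
#' duplex_dg("ACGTACGTACGTACGTACGT")
duplex_dg <- function(sequence, params = nn_params()) {
  sequence <- check_dna(sequence, min_len = 2L, what = "primer sequence")
  n <- nchar(sequence)
  steps <- substring(sequence, seq_len(n - 1L), 2:n)
  sum(params$stack_dG[steps]) +
    .end_penalty(substr(sequence, 1L, 1L), params) +
    .end_penalty(substr(sequence, n, n), params)
}

# Free energies of all 5'-anchored prefixes of a proto-primer, lengths
# 2..nchar(proto), computed in one pass. Row k of the returned vector is the
# dG of proto[1..k+1]. Used by the 3'-trimming loop.
.prefix_dgs <- function(proto, params) {
  n <- nchar(proto)
  bases <- substring(proto, seq_len(n), seq_len(n))
  steps <- paste0(bases[-n], bases[-1L])
  first_pen <- .end_penalty(bases[1L], params)
  cumsum(unname(params$stack_dG[steps])) + first_pen +
    .end_penalty(bases[-1L], params)
}
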