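# Simulated-annealing optimization of the primer set.
#
# Starting from a uniformly random selection of one candidate pair per
# target, each generation proposes replacing the pair of one (or k) randomly
# chosen target(s) with a different pair from that target's candidate list.
# Improvements are always kept; detrimental moves are kept with probability
# exp((L(S) - L(T)) / C(g)) while g < g_t, and never once g >= g_t, at which
# point the search degenerates to stochastic descent. The tolerance C(g)
# decays monotonically from C0 to C_end over [0, g_t).

#' Annealing configuration
#'
#' @param g_t generation at which annealing ends and strict descent begins.
#' @param total_generations total generations to run; defaults to
#'   `ceiling(1.5 * g_t)` so the descent tail can settle into a local
#'   minimum.
#' @param C0 initial tolerance (loss units); `NA` (default) resolves at run
#'   time to `L(S0) / 20`.
#' @param C_end tolerance approached at `g_t`; `NA` resolves to `C0 / 1000`.
#' @param schedule `"exponential"` (geometric decay from `C0` to `C_end`)
#'   or `"linear"`.
#' @param n_mutations_per_step number of target pairs replaced per proposal
#'   (1 recommended; simultaneous multi-pair mutation tends to slow
#'   convergence).
#' @param loss_threshold optional early-stop loss `L_t`.
#' @param seed integer RNG seed; each restart folds its index into it.
#' @param n_restarts independent optimization runs; the best final set wins.
#' @return a list of class `anneal_config`.
#' @export
anneal_config <- function(g_t, total_generations = ceiling(1.5 * g_t),
                          C0 = NA_real_, C_end = NA_real_,
                          schedule = c("exponential", "linear"),
                          n_mutations_per_step = 1L,
                          loss_threshold = NA_real_,
                          seed = 1L, n_restarts = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(g_t >= 0, total_generations >= g_t,
            n_mutations_per_step >= 1L, n_restarts >= 1L)
  structure(list(g_t = as.integer(g_t),
                 total_generations = as.integer(total_generations),
                 C0 = C0, C_end = C_end, schedule = schedule,
                 n_mutations_per_step = as.integer(n_mutations_per_step),
                 loss_threshold = loss_threshold,
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "anneal_config")
}

# Tolerance C(g): positive and non-increasing on [0, g_t).
cooling_tolerance <- function(g, g_t, C0, C_end, schedule = "exponential") {
  frac <- if (g_t > 0) g / g_t else 0
  if (schedule == "exponential") C0 * (C_end / C0)^frac
  else C0 + (C_end - C0) * frac
}

#' Probability of accepting a proposed set
#'
#' Improvements (`L_T <= L_S`) are always accepted. Detrimental moves are
#' accepted with probability `exp((L_S - L_T)/C(g))` before generation
#' `g_t`, and never afterwards.
#'
#' @param L_S,L_T loss of the current and the proposed set.
#' @param g current generation.
#' @param cfg an [anneal_config()] with numeric `C0`/`C_end` (resolved).
#' @return a probability in `[0, 1]`.
#' @export
accept_probability <- function(L_S, L_T, g, cfg) {
  if (L_T <= L_S) return(1)
  if (g >= cfg$g_t) return(0)
  if (!is.finite(cfg$C0) || !is.finite(cfg$C_end))
    stop("C0/C_end must be resolved to numbers before calling", call. = FALSE)
  C <- cooling_tolerance(g, cfg$g_t, cfg$C0, cfg$C_end, cfg$schedule)
  exp((L_S - L_T) / C)
}

#' Draw a uniformly random initial primer set
#'
#' One candidate pair is drawn uniformly per target. Uses R's RNG; seed it
#' for reproducibility.
#'
#' @param panel candidate structure from [panel_candidates()].
#' @return a [new_primer_set()] object.
#' @export
init_set <- function(panel) {
  n_pairs <- vapply(panel, function(t) nrow(t$pairs), integer(1L))
  if (any(n_pairs == 0L))
    stop("undesignable target(s): ",
         paste(names(panel)[n_pairs == 0L], collapse = ", "), call. = FALSE)
  selection <- vapply(n_pairs, function(n) sample.int(n, 1L), integer(1L))
  names(selection) <- names(panel)
  new_primer_set(panel, selection)
}

#' Propose a mutation of the current set
#'
#' Chooses `k` distinct targets with at least two candidate pairs and, for
#' each, a replacement pair different from the incumbent, both uniformly at
#' random. The proposal is returned as a plan (applied with
#' [swap_update()]), so the temporary set differs from the current one in
#' exactly `k` targets.
#'
#' @param set a `primer_set`.
#' @param k number of pairs to replace.
#' @return data.frame with columns `target_id`, `old_row`, `new_row`.
#' @export
propose <- function(set, k = 1L) {
  n_pairs <- vapply(set$panel, function(t) nrow(t$pairs), integer(1L))
  eligible <- names(set$panel)[n_pairs >= 2L]
  if (length(eligible) == 0L)
    stop("no target has an alternative candidate pair; optimization is a no-op",
         call. = FALSE)
  k <- min(k, length(eligible))
  targets <- if (length(eligible) == 1L) eligible
             else sample(eligible, k)
  old <- unname(set$selection[targets])
  new <- vapply(seq_along(targets), function(i) {
    others <- setdiff(seq_len(n_pairs[[targets[i]]]), old[i])
    if (length(others) == 1L) others else sample(others, 1L)
  }, integer(1L))
  data.frame(target_id = targets, old_row = old, new_row = new)
}

.apply_plan <- function(set, plan, forward = TRUE) {
  loss <- set_loss(set)
  if (forward) {
    for (i in seq_len(nrow(plan)))
      loss <- swap_update(set, plan$target_id[i], plan$new_row[i])
  } else {
    for (i in rev(seq_len(nrow(plan))))
      loss <- swap_update(set, plan$target_id[i], plan$old_row[i])
  }
  loss
}

#' Optimize a multiplex primer panel by simulated annealing
#'
#' Runs `n_restarts` independent annealing runs and returns the one whose
#' final set has the lowest loss, together with the best-seen set of that
#' run, the full loss trace, and optional checkpoint selections so any
#' intermediate generation's set can be recovered. Over-fitting an imperfect
#' dimer-likelihood score is a real risk, so inspecting intermediate sets
#' rather than blindly taking the last generation is recommended.
#'
#' @param panel candidate structure from [panel_candidates()].
#' @param cfg an [anneal_config()].
#' @param checkpoint_generations integer vector of generations at which to
#'   snapshot the selection.
#' @param debug_check_every if positive, assert the incremental loss against
#'   [loss_brute_force()] every that-many generations (slow; testing aid).
#' @return a list of class `anneal_result`: `set` (final `primer_set` of
#'   the winning restart), `final_loss`, `best` (`selection`, `loss`,
#'   `generation`), `trace` (per-generation data.frame), `checkpoints`,
#'   `restart_losses`, resolved `config`.
#' @export
optimize_panel <- function(panel, cfg,
                           checkpoint_generations = integer(),
                           debug_check_every = 0L) {
  panel <- prepare_panel(panel)
  best_overall <- NULL
  traces <- vector("list", cfg$n_restarts)
  restart_losses <- numeric(cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    res <- .anneal_once(panel, cfg, restart = r,
                        checkpoint_generations = checkpoint_generations,
                        debug_check_every = debug_check_every)
    traces[[r]] <- res$trace
    restart_losses[r] <- res$final_loss
    if (is.null(best_overall) || res$final_loss < best_overall$final_loss)
      best_overall <- res
  }
  best_overall$trace <- do.call(rbind, traces)
  best_overall$restart_losses <- restart_losses
  best_overall$config <- cfg
  class(best_overall) <- "anneal_result"
  best_overall
}

.anneal_once <- function(panel, cfg, restart, checkpoint_generations,
                         debug_check_every) {
  set.seed((cfg$seed + 7919L * (restart - 1L)) %% .Machine$integer.max)
  set <- init_set(panel)
  loss <- set_loss(set)
  C0 <- if (is.finite(cfg$C0)) cfg$C0 else max(loss / 20, 1e-9)
  C_end <- if (is.finite(cfg$C_end)) cfg$C_end else C0 / 1000
  rcfg <- cfg
  rcfg$C0 <- C0
  rcfg$C_end <- C_end

  n_g <- cfg$total_generations
  tr_loss <- numeric(n_g + 1L)
  tr_acc <- logical(n_g + 1L)
  tr_tgt <- character(n_g + 1L)
  tr_loss[1L] <- loss
  tr_tgt[1L] <- NA_character_
  best <- list(selection = set$selection, loss = loss, generation = 0L)
  checkpoints <- list()
  if (0L %in% checkpoint_generations)
    checkpoints[["0"]] <- set$selection

  g <- 0L
  while (g < n_g) {
    plan <- propose(set, cfg$n_mutations_per_step)
    L_S <- loss
    L_T <- .apply_plan(set, plan, forward = TRUE)
    if (L_T <= L_S ||
        (g < cfg$g_t && runif(1L) < accept_probability(L_S, L_T, g, rcfg))) {
      loss <- L_T
      accepted <- TRUE
    } else {
      .apply_plan(set, plan, forward = FALSE)
      accepted <- FALSE
    }
    g <- g + 1L
    tr_loss[g + 1L] <- loss
    tr_acc[g + 1L] <- accepted
    tr_tgt[g + 1L] <- plan$target_id[1L]
    if (loss < best$loss)
      best <- list(selection = set$selection, loss = loss, generation = g)
    if (g %in% checkpoint_generations)
      checkpoints[[as.character(g)]] <- set$selection
    if (g %% 2000L == 0L)
      loss <- refresh_cross(set)
    if (debug_check_every > 0L && g %% debug_check_every == 0L) {
      ref <- loss_brute_force(selected_profiles(set))
      if (abs(loss - ref) > 1e-6 * max(1, abs(ref)))
        stop("incremental loss drifted from reference: ", loss, " vs ", ref,
             call. = FALSE)
    }
    if (is.finite(cfg$loss_threshold) && loss <= cfg$loss_threshold)
      break
  }
  n_rec <- g + 1L
  list(set = set, final_loss = loss, best = best,
       trace = data.frame(restart = restart, generation = 0:(n_rec - 1L),
                          loss = tr_loss[seq_len(n_rec)],
                          accepted = tr_acc[seq_len(n_rec)],
                          target_id = tr_tgt[seq_len(n_rec)]),
       checkpoints = checkpoints, restart = restart)
}
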