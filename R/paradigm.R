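#' Generate a pseudo-randomized stimulus sequence for one trial
#'
#' One trial of the six-class auditory speller presents each of the \code{K}
#' stimuli exactly once per iteration, for \code{J} iterations, in
#' pseudo-random order (an independent uniform permutation per iteration
#' block). At the defaults \code{K = 6}, \code{J = 15} this yields 90 tone
#' presentations lasting \code{K * J * soa} = 15.75 s.
#'
#' @param K number of distinct stimuli (>= 2).
#' @param J number of iterations, i.e. repetitions of each stimulus (>= 1).
#' @param seed integer seed; the sequence is deterministic given it.
#' @param soa stimulus onset asynchrony in seconds.
#' @param stimulus_duration tone duration in seconds.
#' @param trial_index index of the trial the sequence belongs to.
#' @param permute_hook optional \code{function(K, j)} returning the
#'   permutation of \code{1:K} used for iteration \code{j}; overrides the
#'   default uniform draw (e.g. to forbid repeats at iteration seams).
#' @return a \code{stim_sequence}: list with \code{presentations} (integer
#'   vector of stimulus ids in \code{1..K}), \code{K}, \code{J}, \code{soa},
#'   \code{stimulus_duration}, \code{trial_index}.
#' @export
generate_sequence <- function(K = 6, J = 15, seed = NULL, soa = 0.175,
                              stimulus_duration = 0.040, trial_index = 1L,
                              permute_hook = NULL) {
  if (!is.numeric(K) || length(K) != 1 || K < 2 || K != round(K))
    stop("K must be an integer >= 2", call. = FALSE)
  if (!is.numeric(J) || length(J) != 1 || J < 1 || J != round(J))
    stop("J must be an integer >= 1", call. = FALSE)
  draw <- function() {
    pres <- integer(K * J)
    for (j in seq_len(J)) {
      p <- if (is.null(permute_hook)) sample.int(K) else permute_hook(K, j)
      pres[((j - 1) * K + 1):(j * K)] <- p
    }
    pres
  }
  presentations <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(presentations = presentations, K = as.integer(K),
                 J = as.integer(J), soa = soa,
                 stimulus_duration = stimulus_duration,
                 trial_index = as.integer(trial_index)),
            class = "stim_sequence")
}

#' Target / non-target label of one stimulus presentation
#'
#' A presentation is a target exactly when the presented stimulus is the one
#' the user attends; every other presentation is a non-target. Over a full
#' trial this partitions the \code{K * J} presentations into \code{J} targets
#' and \code{(K - 1) * J} non-targets.
#'
#' @param attended attended stimulus id (scalar) in \code{1..K}.
#' @param presented presented stimulus id(s) in \code{1..K}; vectorized.
#' @param K number of stimuli, for validation.
#' @return a character vector in \code{c("target", "nontarget")}.
#' @export
label_function <- function(attended, presented, K = 6) {
  if (length(attended) != 1 || attended < 1 || attended > K ||
      attended != round(attended))
    stop("attended must be a single stimulus id in 1..K", call. = FALSE)
  if (any(presented < 1 | presented > K | presented != round(presented)))
    stop("presented ids must lie in 1..K", call. = FALSE)
  ifelse(presented == attended, "target", "nontarget")
}

#' Duration of a trial's stimulation sequence
#'
#' @param sequence a \code{stim_sequence}.
#' @return duration in seconds: number of presentations times the SOA.
#' @export
trial_duration <- function(sequence) {
  stopifnot(inherits(sequence, "stim_sequence"))
  length(sequence$presentations) * sequence$soa
}

#' The default 6 x 6 symbol grid
#'
#' Thirty-six spellable symbols arranged in six groups of six: the 26 letters,
#' the German umlauts, punctuation and an underscore for white space. The
#' first selection trial picks a group, the second picks a symbol within it.
#'
#' @param groups optional list of six character vectors of six symbols each,
#'   to override the shipped layout.
#' @return a \code{symbol_grid}: list of six ordered groups of six symbols.
#' @export
symbol_grid <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      c("A", "B", "C", "D", "E", "F"),
      c("G", "H", "I", "J", "K", "L"),
      c("M", "N", "O", "P", "Q", "R"),
      c("S", "T", "U", "V", "W", "X"),
      c("Y", "Z", "Ä", "Ö", "Ü", "_"),
      c(".", ",", "!", "?", "<", ">")
    )
  }
  if (length(groups) != 6 || !all(vapply(groups, length, 1L) == 6))
    stop("symbol grid must have 6 groups of 6 symbols", call. = FALSE)
  syms <- unlist(groups)
  if (length(unique(syms)) != 36)
    stop("symbol grid must contain 36 distinct symbols", call. = FALSE)
  structure(list(groups = groups), class = "symbol_grid")
}

#' Map a pair of one-out-of-six selections to a spelled symbol
#'
#' @param first_selection group id in \code{1..6} (first trial's decision).
#' @param second_selection within-group id in \code{1..6} (second trial's).
#' @param grid a \code{symbol_grid}.
#' @return the spelled symbol (single character string).
#' @export
decode_symbol <- function(first_selection, second_selection,
                          grid = symbol_grid()) {
  if (!inherits(grid, "symbol_grid"))
    stop("grid must be a symbol_grid", call. = FALSE)
  if (first_selection < 1 || first_selection > 6 ||
      second_selection < 1 || second_selection > 6)
    stop("selections must lie in 1..6", call. = FALSE)
  grid$groups[[first_selection]][[second_selection]]
}

#' Check the structural invariants of a stimulus sequence
#'
#' @param sequence a \code{stim_sequence}.
#' @return TRUE, or an error describing the violated invariant.
#' @export
validate_sequence <- function(sequence) {
  stopifnot(inherits(sequence, "stim_sequence"))
  p <- sequence$presentations
  K <- sequence$K; J <- sequence$J
  if (length(p) != K * J)
    stop("sequence must have K*J presentations", call. = FALSE)
  if (!all(tabulate(p, K) == J))
    stop("each stimulus must appear exactly J times", call. = FALSE)
  for (j in seq_len(J)) {
    blk <- p[((j - 1) * K + 1):(j * K)]
    if (!setequal(blk, seq_len(K)))
      stop("iteration block ", j, " is not a permutation of 1..K",
           call. = FALSE)
  }
  TRUE
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence> trial %d: %d presentations (K=%d, J=%d), SOA %.3f s, %.2f s total\n",
              x$trial_index, length(x$presentations), x$K, x$J, x$soa,
              trial_duration(x)))
  invisible(x)
}
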