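#' Derive a child RNG seed from a root seed and a stage label
#'
#' All stochastic stages draw their own seed deterministically from one root
#' seed and a text label, so stages are reproducible in isolation and adding a
#' stage never perturbs the streams of the others.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) %% 1000003L) * 2017L + (h %% 999983L)) %% 2147483646L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Inverse-logit
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @keywords internal
inv_logit <- function(x) stats::plogis(x)
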