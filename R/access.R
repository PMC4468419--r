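#' Competition model
#'
#' Parameterizes how often two agents contest the same resource and who wins
#' a mixed contest. The per-step pairwise contest probability grows with
#' population size, either linearly with a cap (`min(1, kappa * (N - 1))`,
#' the default) or as the saturating form `1 - (1 - kappa)^(N - 1)`. When an
#' automatic act meets a controlled act over one resource, the automatic
#' side wins with probability `w_auto` (1 in the baseline model: the faster
#' habit always grabs the packet); same-mode contests split the packet
#' randomly.
#'
#' @param kappa Contest-rate constant (`>= 0`); scales how fast contests
#'   become likely as `N` grows.
#' @param w_auto Probability the automatic agent wins a mixed contest, in
#'   `(0.5, 1]`.
#' @param form `"linear"` (capped) or `"saturating"` contest probability.
#' @return An object of class `competition_model`.
#' @export
competition_model <- function(kappa = 0.01, w_auto = 1,
                              form = c("linear", "saturating")) {
  form <- match.arg(form)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
            is.numeric(w_auto), length(w_auto) == 1L)
  if (w_auto <= 0.5 || w_auto > 1)
    stop("'w_auto' must lie in (0.5, 1]", call. = FALSE)
  if (form == "saturating" && kappa > 1)
    stop("'kappa' must be <= 1 for the saturating form", call. = FALSE)
  structure(list(kappa = kappa, w_auto = w_auto, form = form),
            class = "competition_model")
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Competition: kappa =", x$kappa, ", w_auto =", x$w_auto,
      ", form =", x$form, "\n")
  invisible(x)
}

#' Per-mode resource-access probabilities
#'
#' Folds competition into the two per-step acquisition probabilities an
#' agent faces depending on its current mode. With contest probability
#' `p_contest` and a focal encounter (probability `R`), an uncontested
#' packet is always acquired; a contested one is won according to the
#' opponent's mode (drawn from the population's automatic share) and the
#' contest rules:
#'
#' * `p_auto = R * ((1 - p_contest) + p_contest * (share * 0.5 + (1 - share) * w_auto))`
#' * `p_ctrl = R * ((1 - p_contest) + p_contest * ((1 - share) * 0.5 + share * (1 - w_auto)))`
#'
#' where `share` is the population mean of `1 - C` (per-step probability an
#' opponent acts automatically). For `w_auto > 0.5` the controlled mode
#' never out-accesses the automatic mode.
#'
#' @param R Environmental richness (encounter probability).
#' @param N Population size (`>= 1`).
#' @param mean_auto_share Population mean of `1 - C`, in `[0, 1]`.
#' @param comp A [competition_model()].
#' @return An object of class `access_probabilities` with fields `p_auto`,
#'   `p_ctrl`, `p_contest`.
#' @export
access_probabilities <- function(R, N, mean_auto_share,
                                 comp = competition_model()) {
  stopifnot(is.numeric(R), R >= 0, R <= 1,
            is.numeric(mean_auto_share),
            mean_auto_share >= 0, mean_auto_share <= 1)
  if (!is.numeric(N) || N < 1) stop("'N' must be >= 1", call. = FALSE)
  p_contest <- switch(comp$form,
    linear = min(1, comp$kappa * (N - 1)),
    saturating = 1 - (1 - comp$kappa)^(N - 1)
  )
  s <- mean_auto_share
  w <- comp$w_auto
  p_auto <- R * ((1 - p_contest) + p_contest * (s * 0.5 + (1 - s) * w))
  p_ctrl <- R * ((1 - p_contest) + p_contest * ((1 - s) * 0.5 + s * (1 - w)))
  structure(list(p_auto = p_auto, p_ctrl = p_ctrl, p_contest = p_contest),
            class = "access_probabilities")
}

#' @export
print.access_probabilities <- function(x, ...) {
  cat("Access: p_auto =", format(x$p_auto), ", p_ctrl =", format(x$p_ctrl),
      ", p_contest =", format(x$p_contest), "\n")
  invisible(x)
}
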