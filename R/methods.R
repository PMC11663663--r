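#' Coefficients of a fit summary
#'
#' @param object A `fit_summary`.
#' @param ... Unused.
#' @return Named numeric vector of point estimates.
#' @export
coef.fit_summary <- function(object, ...) {
  stats::setNames(object$estimate, object$term)
}

#' Plot learning curves from a trial table
#'
#' Mean accuracy per block, one line per problem type, averaged over
#' participants (and over the capacity grid for BR-DIVA rows).
#'
#' @param x An `shj_trials` table.
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted accuracy matrix (blocks x types), invisibly.
#' @export
plot.shj_trials <- function(x, ...) {
  agg <- aggregate_accuracy(x, by = c("type", "block"))
  types <- sort(unique(agg$type))
  blocks <- sort(unique(agg$block))
  m <- vapply(types, function(ty) {
    agg$accuracy[agg$type == ty][order(agg$block[agg$type == ty])]
  }, numeric(length(blocks)))
  graphics::matplot(blocks, m, type = "l", lty = 1, lwd = 2,
                    xlab = "Block", ylab = "Mean accuracy",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = paste("Type", types),
                   col = seq_along(types), lty = 1, lwd = 2, bty = "n")
  invisible(m)
}

#' Simulate responses from a trained model
#'
#' Classifies the full stimulus set `nsim` times without any learning:
#' deterministic repeats for DIVA, fresh latent noise per pass for BR-DIVA.
#'
#' @param object A `diva` or `brdiva` model.
#' @param nsim Number of passes through the eight stimuli.
#' @param seed Optional seed for the latent noise and tie-breaks.
#' @param ... Unused.
#' @return An 8 x `nsim` integer matrix of category responses, rows named by
#'   stimulus.
#' @export
simulate.diva <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stim <- shj_stimuli()
  out <- vapply(seq_len(nsim), function(i) {
    apply(stim, 1L, function(x) classify(diva_forward(object, x)$channel_errors))
  }, integer(8L))
  rownames(out) <- rownames(stim)
  out
}

#' @rdname simulate.diva
#' @export
simulate.brdiva <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stim <- shj_stimuli()
  out <- vapply(seq_len(nsim), function(i) {
    apply(stim, 1L, function(x) classify(brdiva_forward(object, x)$channel_errors))
  }, integer(8L))
  rownames(out) <- rownames(stim)
  out
}
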