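# Grouped means that tolerate NA in grouping columns (the DIVA rows carry
# beta = NA); NA is treated as its own level and restored afterwards.
.group_mean <- function(df, by, value = "correct", out_name = "accuracy") {
  g <- df[by]
  na_cols <- vapply(g, anyNA, logical(1))
  for (cn in names(g)[na_cols]) {
    g[[cn]] <- ifelse(is.na(g[[cn]]), "<NA>", as.character(g[[cn]]))
  }
  agg <- stats::aggregate(df[[value]], by = g, FUN = mean)
  names(agg)[ncol(agg)] <- out_name
  for (cn in names(g)[na_cols]) {
    orig <- df[[cn]]
    v <- agg[[cn]]
    restored <- rep(NA, length(v))
    restored[v != "<NA>"] <- as.numeric(v[v != "<NA>"])
    agg[[cn]] <- restored
  }
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Aggregate accuracy over a trial table
#'
#' Mean proportion correct (and its complement, the error rate) for every
#' combination of the grouping keys.
#'
#' @param trials A trial table (from [run_experiment()] or read back from CSV).
#' @param by Character vector of grouping column names.
#' @return A data.frame with the grouping keys, `accuracy` and `error_rate`.
#' @export
aggregate_accuracy <- function(trials, by) {
  if (length(by) < 1L) stop("`by` must name at least one grouping column", call. = FALSE)
  missing_cols <- setdiff(c(by, "correct"), names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  agg <- .group_mean(trials, by)
  agg$error_rate <- 1 - agg$accuracy
  rownames(agg) <- NULL
  agg
}

#' Per-participant accuracy, optionally pooling the capacity grid
#'
#' One accuracy per participant (within the given grouping), with BR-DIVA
#' rows first averaged within each beta and then across the beta grid, so a
#' "participant" contributes one number regardless of how many beta values
#' were simulated. This is the unit of analysis for the model-vs-model
#' t-tests and regressions, where the capacity parameter is treated as a
#' secondary manipulation.
#'
#' @param trials Trial table containing one or both models.
#' @param by Extra grouping keys besides `model`, `type`, `participant`
#'   (e.g. `"block"`).
#' @param pool_beta Average BR-DIVA across beta values (default `TRUE`).
#' @return A data.frame with `model`, `type`, `participant`, the extra keys
#'   and `accuracy`.
#' @export
subject_accuracy <- function(trials, by = character(0), pool_beta = TRUE) {
  keys <- c("model", "type", "participant", by)
  if (pool_beta) {
    per_beta <- .group_mean(trials, c(keys, "beta"))
    out <- .group_mean(per_beta, keys, value = "accuracy", out_name = "accuracy")
  } else {
    out <- .group_mean(trials, c(keys, "beta"))
  }
  rownames(out) <- NULL
  out
}

#' Ordinary least squares with explicit reference levels
#'
#' Thin wrapper around [stats::lm()] that dummy-codes the named factors
#' against stated reference levels and returns a tidy coefficient table.
#' Rank-deficient fits are an error naming the collinear terms rather than
#' silently dropped coefficients.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param ref Named character vector mapping factor column names to their
#'   reference level, e.g. `c(type = "1")`. The named columns are converted
#'   to factors and releveled before fitting.
#' @return An object of class `fit_summary`: a data.frame with columns
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`; attributes
#'   `n_obs`, `reference_levels` and `fit` (the underlying `lm`).
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
#' fit_ols(y ~ g, d, ref = c(g = "a"))
#' @export
fit_ols <- function(formula, data, ref = NULL) {
  data <- as.data.frame(data)
  if (!is.null(ref)) {
    for (cn in names(ref)) {
      if (!cn %in% names(data)) stop("no column `", cn, "` to relevel", call. = FALSE)
      f <- factor(data[[cn]])
      if (!ref[[cn]] %in% levels(f)) {
        stop("reference level `", ref[[cn]], "` not present in `", cn, "`",
             call. = FALSE)
      }
      data[[cn]] <- stats::relevel(f, ref = ref[[cn]])
    }
  }
  fit <- stats::lm(formula, data = data)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient fit; collinear terms: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  sm <- stats::coef(summary(fit))
  out <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                    std_error = sm[, 2L], statistic = sm[, 3L],
                    p_value = sm[, 4L], row.names = NULL)
  structure(out, class = c("fit_summary", "data.frame"),
            n_obs = stats::nobs(fit), reference_levels = ref, fit = fit)
}

#' @export
print.fit_summary <- function(x, digits = 4, ...) {
  cat(sprintf("OLS fit on %d observations\n", attr(x, "n_obs")))
  ref <- attr(x, "reference_levels")
  if (!is.null(ref)) {
    cat("  reference levels:",
        paste(sprintf("%s = %s", names(ref), ref), collapse = ", "), "\n")
  }
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Extract one coefficient from a fit summary
#'
#' @param fit A `fit_summary`.
#' @param term Coefficient name as it appears in the table.
#' @return The point estimate.
#' @export
ols_coef <- function(fit, term) {
  i <- match(term, fit$term)
  if (is.na(i)) {
    stop("no term `", term, "`; available: ", paste(fit$term, collapse = ", "),
         call. = FALSE)
  }
  fit$estimate[i]
}

#' Paired-samples t-test
#'
#' Classical paired t on per-subject value pairs; `df = n - 1`.
#'
#' @param a,b Numeric vectors of equal length (>= 2), matched by position.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("`a` and `b` must be equal-length vectors with n >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; the paired t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t; `df = n_a + n_b - 2`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("both samples have zero variance; the t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Learning curves
#'
#' Mean accuracy per model x type x beta x block, block order preserved.
#'
#' @param trials Trial table.
#' @return A data.frame with the four keys plus `accuracy` and `error_rate`.
#' @export
learning_curves <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  agg <- aggregate_accuracy(trials, by = c("model", "type", "beta", "block"))
  agg[order(agg$model, agg$type, agg$beta, agg$block), , drop = FALSE]
}

#' Hidden-layer geometry of a trained model
#'
#' Maps each of the eight stimuli to its 2-d hidden coordinates (sigmoid
#' hidden activations for DIVA; the deterministic posterior means `mu` for
#' BR-DIVA) and, for the rule-plus-exception structures (Types 3-5),
#' computes the mean within-category Euclidean distance from each category's
#' exception stimulus to its three rule-followers, averaged over the two
#' categories.
#'
#' @param model A trained `diva` or `brdiva` object.
#' @param problem An `shj_problem` (see [shj_assignment()]).
#' @return A list of class `hidden_geometry` with `coordinates` (8 x
#'   `n_hidden` matrix, rows named by stimulus), `type_id` and
#'   `exception_distance` (`NA` for Types 1, 2 and 6, which have no unique
#'   exception).
#' @export
hidden_geometry <- function(model, problem) {
  stopifnot(inherits(problem, "shj_problem"))
  stim <- shj_stimuli()
  coords <- if (inherits(model, "brdiva")) {
    t(apply(stim, 1L, function(x) brdiva_encode(model, x)$mu))
  } else if (inherits(model, "diva")) {
    t(apply(stim, 1L, function(x) diva_forward(model, x)$hidden))
  } else stop("`model` must be a diva or brdiva object", call. = FALSE)
  rownames(coords) <- rownames(stim)
  exc_dist <- NA_real_
  if (problem$type_id %in% 3:5) {
    exc <- shj_exception(problem$type_id)$exceptions
    per_cat <- vapply(exc, function(e) {
      mates <- setdiff(which(problem$assignment == problem$assignment[e]), e)
      mean(vapply(mates, function(m) sqrt(sum((coords[e, ] - coords[m, ])^2)),
                  numeric(1)))
    }, numeric(1))
    exc_dist <- mean(per_cat)
  }
  structure(list(coordinates = coords, type_id = problem$type_id,
                 exception_distance = exc_dist),
            class = "hidden_geometry")
}

#' @export
print.hidden_geometry <- function(x, ...) {
  cat(sprintf("Hidden-layer geometry, Type %d\n", x$type_id))
  print(round(x$coordinates, 4))
  if (!is.na(x$exception_distance)) {
    cat(sprintf("mean exception-to-rule-follower distance: %.4f\n",
                x$exception_distance))
  }
  invisible(x)
}

#' Rule versus exception error curves
#'
#' Splits a rule-plus-exception problem's trials into rule-following and
#' exception stimuli and returns the per-block error rate of each group.
#' The attribute `"convergence_block"` gives the first block at which the
#' exception error rate no longer exceeds the rule-follower error rate
#' (`NA` if it never catches up).
#'
#' @param trials Trial table containing a single problem type in 3..5 (rows
#'   of other types are an error).
#' @param type_id The problem type of the trials, in 3..5.
#' @return A data.frame with `block`, `rule_error`, `exception_error`.
#' @export
rule_exception_curves <- function(trials, type_id) {
  if (!type_id %in% 3:5) {
    stop("rule/exception curves are defined for Types 3-5 only", call. = FALSE)
  }
  trials <- trials[trials$type == type_id, , drop = FALSE]
  if (nrow(trials) == 0L) stop("no trials of the requested type", call. = FALSE)
  exc <- shj_exception(type_id)$exceptions
  is_exc <- trials$stimulus %in% exc
  blocks <- sort(unique(trials$block))
  rule_err <- vapply(blocks, function(b) {
    1 - mean(trials$correct[!is_exc & trials$block == b])
  }, numeric(1))
  exc_err <- vapply(blocks, function(b) {
    1 - mean(trials$correct[is_exc & trials$block == b])
  }, numeric(1))
  conv <- which(exc_err <= rule_err)
  structure(
    data.frame(block = blocks, rule_error = rule_err, exception_error = exc_err),
    convergence_block = if (length(conv)) blocks[min(conv)] else NA_integer_
  )
}

# ---- headline regression recipes -------------------------------------------

#' Order-of-difficulty regression
#'
#' Aggregates BR-DIVA accuracy to one cell mean per (type, beta) and fits
#' `accuracy ~ type + beta` with Type 1 as the reference category, so the
#' type coefficients are each type's aggregate accuracy deficit relative to
#' the one-dimensional rule problem.
#'
#' @param trials BR-DIVA trial table covering several types.
#' @return A `fit_summary`.
#' @export
fit_difficulty <- function(trials) {
  trials <- trials[trials$model == "BRDIVA", , drop = FALSE]
  cells <- aggregate_accuracy(trials, by = c("type", "beta"))
  fit_ols(accuracy ~ type + beta, cells, ref = c(type = "1"))
}

#' Block-by-model regression for one problem type
#'
#' Per-(model, participant, block) accuracy -- BR-DIVA pooled across the
#' capacity grid -- regressed on `block * model` with DIVA as the reference
#' model. The `block` coefficient is the reference model's learning slope;
#' the `model` coefficient the BR-DIVA minus DIVA accuracy difference.
#'
#' @param trials Trial table containing both models.
#' @param type_id Problem type to analyse.
#' @return A `fit_summary`.
#' @export
fit_block_model <- function(trials, type_id) {
  trials <- trials[trials$type == type_id, , drop = FALSE]
  subj <- subject_accuracy(trials, by = "block", pool_beta = TRUE)
  subj$block <- as.numeric(subj$block)
  fit_ols(accuracy ~ block * model, subj, ref = c(model = "DIVA"))
}

#' Full-interaction regression over the rule-plus-exception types
#'
#' BR-DIVA accuracy for Types 3-5, aggregated to per-(type, beta, block)
#' means, regressed on `block * type * beta` with Type 5 as the reference
#' group (uncentered block 1-20, so type main effects are block-0
#' extrapolations). Positive type coefficients mean higher accuracy than
#' Type 5.
#'
#' @param trials BR-DIVA trial table containing Types 3-5.
#' @return A `fit_summary`.
#' @export
fit_exception_types <- function(trials) {
  trials <- trials[trials$model == "BRDIVA" & trials$type %in% 3:5, , drop = FALSE]
  cells <- aggregate_accuracy(trials, by = c("type", "beta", "block"))
  cells$block <- as.numeric(cells$block)
  fit_ols(accuracy ~ block * type * beta, cells, ref = c(type = "5"))
}
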