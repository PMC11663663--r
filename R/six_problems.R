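#' The eight binary three-feature stimuli
#'
#' Enumerates the full stimulus set of the six-problems benchmark: all
#' binary triples over three abstract feature dimensions, in lexicographic
#' order `000, 001, ..., 111`.
#'
#' @return An 8 x 3 integer matrix with columns `f1`, `f2`, `f3` and row
#'   names giving the bit pattern of each stimulus. Row order is
#'   lexicographic, so row 1 is `(0,0,0)` and row 8 is `(1,1,1)`.
#' @examples
#' shj_stimuli()
#' @export
shj_stimuli <- function() {
  m <- as.matrix(expand.grid(f3 = 0:1, f2 = 0:1, f1 = 0:1))[, c("f1", "f2", "f3")]
  m <- matrix(as.integer(m), 8L, 3L, dimnames = list(NULL, c("f1", "f2", "f3")))
  rownames(m) <- apply(m, 1L, paste, collapse = "")
  m
}

# Category-A member sets of the canonical representative of each structural
# class, as bit strings over (f1, f2, f3). Any member of a class is
# behaviourally equivalent for a model with dimension-symmetric random
# initialisation; one fixed representative per class keeps everything
# deterministic and testable.
.shj_category_a <- list(
  `1` = c("000", "001", "010", "011"),
  `2` = c("000", "001", "110", "111"),
  `3` = c("000", "001", "010", "110"),
  `4` = c("000", "001", "010", "100"),
  `5` = c("000", "001", "010", "111"),
  `6` = c("000", "011", "101", "110")
)

#' Canonical category assignment for one of the six problems
#'
#' Returns the canonical representative of one of the six structurally
#' distinct ways of splitting the eight stimuli into two equal categories.
#' Type 1 is a one-dimensional rule (first feature), Type 2 an exclusive-or
#' on the first two features, Types 3-5 rule-plus-exception structures, and
#' Type 6 the parity problem with no within-category similarity structure.
#'
#' @param type_id Integer problem type, 1 through 6.
#' @return An object of class `shj_problem`: a list with `type_id`,
#'   `assignment` (integer vector over the 8 stimuli in lexicographic order;
#'   1 = category A, 2 = category B) and `labels` (`c("A", "B")`).
#' @examples
#' p <- shj_assignment(2)
#' p$assignment  # XOR of the first two features
#' @export
shj_assignment <- function(type_id) {
  if (length(type_id) != 1L || !is.numeric(type_id) || is.na(type_id) ||
      type_id != as.integer(type_id) || type_id < 1L || type_id > 6L) {
    stop("`type_id` must be a single integer in 1..6", call. = FALSE)
  }
  stim <- shj_stimuli()
  a <- ifelse(rownames(stim) %in% .shj_category_a[[as.character(type_id)]], 1L, 2L)
  structure(
    list(type_id = as.integer(type_id), assignment = a, labels = c("A", "B")),
    class = "shj_problem"
  )
}

#' @export
print.shj_problem <- function(x, ...) {
  stim <- shj_stimuli()
  cat("Six-problems category structure, Type", x$type_id, "\n")
  cat("  A:", paste(rownames(stim)[x$assignment == 1L], collapse = " "), "\n")
  cat("  B:", paste(rownames(stim)[x$assignment == 2L], collapse = " "), "\n")
  invisible(x)
}

#' Stimulus/assignment table for export
#'
#' Long-format table of the canonical assignments, one row per
#' (type, stimulus), suitable for writing to CSV.
#'
#' @param types Integer vector of problem types to include.
#' @return A data.frame with columns `type`, `f1`, `f2`, `f3`, `category`.
#' @export
shj_problem_table <- function(types = 1:6) {
  stim <- shj_stimuli()
  do.call(rbind, lapply(types, function(ty) {
    p <- shj_assignment(ty)
    data.frame(
      type = ty,
      f1 = stim[, 1L], f2 = stim[, 2L], f3 = stim[, 3L],
      category = p$labels[p$assignment],
      row.names = NULL
    )
  }))
}

# Best single-dimension rule for a problem: the (dimension, polarity) whose
# one-feature classifier misclassifies the fewest stimuli. Ties broken by
# lowest dimension index so the choice is deterministic.
.best_unidimensional_rule <- function(problem) {
  stim <- shj_stimuli()
  best <- NULL
  for (d in 1:3) for (pol in 0:1) {
    pred <- ifelse(stim[, d] == pol, 1L, 2L)
    acc <- mean(pred == problem$assignment)
    if (is.null(best) || acc > best$accuracy + 1e-12) {
      best <- list(dimension = d, a_value = pol, accuracy = acc)
    }
  }
  best
}

#' Exception stimuli of a rule-plus-exception problem
#'
#' For Types 3-5, identifies the single member of each category that
#' violates the best one-dimensional rule for that structure. The rule and
#' the exceptions are computed, not hard-coded.
#'
#' @param type_id Integer problem type in 3..5.
#' @return A list with `rule` (dimension, A-side value, rule accuracy) and
#'   `exceptions` (integer stimulus indices, one per category, named by the
#'   category label).
#' @export
shj_exception <- function(type_id) {
  if (length(type_id) != 1L || !type_id %in% 3:5) {
    stop("`type_id` must be 3, 4 or 5; Types 1, 2 and 6 have no unique exception",
         call. = FALSE)
  }
  p <- shj_assignment(type_id)
  stim <- shj_stimuli()
  rule <- .best_unidimensional_rule(p)
  pred <- ifelse(stim[, rule$dimension] == rule$a_value, 1L, 2L)
  wrong <- which(pred != p$assignment)
  stopifnot(length(wrong) == 2L, p$assignment[wrong[1L]] != p$assignment[wrong[2L]])
  names(wrong) <- p$labels[p$assignment[wrong]]
  list(rule = rule, exceptions = wrong[order(names(wrong))])
}

#' Input-space distance from exception to rule-followers
#'
#' Mean Hamming distance from a category's exception stimulus to its three
#' rule-following category mates, computed per category and averaged across
#' the two categories. By construction of the canonical representatives the
#' two categories give the same value. Orders the rule-plus-exception
#' structures as Type 4 (5/3) < Type 3 (2) < Type 5 (7/3): Type 4's
#' exception sits closest to its own category, Type 5's furthest.
#'
#' @param type_id Integer problem type in 3..5.
#' @return A single nonnegative number.
#' @examples
#' exception_distance_profile(4)  # 5/3
#' @export
exception_distance_profile <- function(type_id) {
  exc <- shj_exception(type_id)
  p <- shj_assignment(type_id)
  stim <- shj_stimuli()
  per_cat <- vapply(exc$exceptions, function(e) {
    mates <- setdiff(which(p$assignment == p$assignment[e]), e)
    mean(vapply(mates, function(m) sum(stim[e, ] != stim[m, ]), numeric(1)))
  }, numeric(1))
  mean(per_cat)
}
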