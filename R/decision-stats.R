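direction_levels <- function() c("left", "centre", "right")

#' Label the three fitted clusters as left / centre / right
#'
#' The centre ("no decision") cluster is the component whose mean is
#' closest to the origin. The decision axis is the feature axis with the
#' largest absolute separation between the two remaining cluster means.
#' Those two clusters are mapped to left/right so as to maximise the
#' agreement between predicted class and speaker side over the training
#' trials assigned to them; an exact tie is broken by the sign
#' convention (negative decision-axis coordinate = left).
#'
#' @param model A fitted [gmm3_model()].
#' @param x Training points (n x 2) used for the fit.
#' @param sides Character vector (`"left"`/`"right"`) of speaker sides
#'   for the training trials.
#' @return Object of class `cluster_labelling`: `classes` (length-3
#'   character, class of each cluster index), `decision_axis` (1 or 2).
#' @export
label_clusters <- function(model, x, sides) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_input("labelling requires at least 1 training point")
  if (nrow(x) != length(sides)) stop_input("'x' and 'sides' lengths differ")
  norms <- sqrt(rowSums(model$means^2))
  ord <- order(norms)
  if (abs(norms[ord[1L]] - norms[ord[2L]]) < 1e-9) {
    stop_input("two clusters tied for centre (mean norms within 1e-9)")
  }
  centre <- ord[1L]
  others <- setdiff(1:3, centre)
  sep <- abs(model$means[others[1L], ] - model$means[others[2L], ])
  axis <- which.max(sep)

  assign <- max.col(gmm3_posterior(model, x), ties.method = "first")
  agree <- function(cl_left, cl_right) {
    sum(assign == cl_left & sides == "left") +
      sum(assign == cl_right & sides == "right")
  }
  a1 <- agree(others[1L], others[2L])
  a2 <- agree(others[2L], others[1L])
  if (a1 > a2) {
    left <- others[1L]
  } else if (a2 > a1) {
    left <- others[2L]
  } else {
    # tie: the cluster on the negative side of the decision axis is left
    left <- others[which.min(model$means[others, axis])]
  }
  right <- setdiff(others, left)
  classes <- character(3L)
  classes[centre] <- "centre"
  classes[left] <- "left"
  classes[right] <- "right"
  structure(list(classes = classes, decision_axis = axis),
            class = "cluster_labelling")
}

#' Predict reaction direction for new points
#'
#' Each point is assigned the class of its maximum-responsibility
#' cluster.
#'
#' @param model A fitted `gmm3` model.
#' @param labelling A [label_clusters()] result.
#' @param x Numeric matrix (n x 2) of points.
#' @return Factor with levels left, centre, right.
#' @export
predict_direction <- function(model, labelling, x) {
  x <- as.matrix(x)
  k <- max.col(gmm3_posterior(model, x), ties.method = "first")
  factor(labelling$classes[k], levels = direction_levels())
}

#' Build a 3 x 2 direction contingency table
#'
#' Counts predictions (left/centre/right) against the speaker side
#' (left/right) for one feature set and data split.
#'
#' @param predictions Factor or character of predicted classes.
#' @param sides Character vector of speaker sides, same length.
#' @param split Split label (e.g. `"training"`, `"validation_toddler"`,
#'   `"validation_infant"`).
#' @param feature_set Feature-set label (see [feature_sets()]).
#' @return Integer matrix of class `direction_table` (rows = predicted
#'   class, columns = speaker side) with `split` and `feature_set`
#'   attributes.
#' @export
direction_table <- function(predictions, sides, split = "training",
                            feature_set = "head_rot") {
  if (length(predictions) != length(sides)) {
    stop_input("'predictions' and 'sides' lengths differ")
  }
  counts <- table(
    factor(as.character(predictions), levels = direction_levels()),
    factor(as.character(sides), levels = c("left", "right"))
  )
  out <- matrix(as.integer(counts), 3L, 2L,
                dimnames = list(class = direction_levels(),
                                side = c("left", "right")))
  structure(out, split = split, feature_set = feature_set,
            class = c("direction_table", class(out)))
}

#' Decision counts and the correct-decision rate ("specificity")
#'
#' A decision is a non-centre prediction. The correct-decision rate --
#' reported as "specificity" in behavioural-audiometry usage -- is the
#' fraction of decisions whose direction matches the speaker side:
#' `(counts[left, left] + counts[right, right]) / n_decisions`. When no
#' decision was made the rate is undefined and `NA` is returned.
#'
#' @param table A [direction_table()].
#' @return `n_decisions()`, `n_correct()`: integer counts.
#'   `correct_decision_rate()`: fraction in \[0, 1\] or `NA`.
#'   `decision_rate()`: decisions / all trials in the table.
#' @export
correct_decision_rate <- function(table) {
  nd <- n_decisions(table)
  if (nd == 0L) return(NA_real_)
  n_correct(table) / nd
}

#' @rdname correct_decision_rate
#' @export
n_decisions <- function(table) {
  as.integer(sum(table[c("left", "right"), ]))
}

#' @rdname correct_decision_rate
#' @export
n_correct <- function(table) {
  as.integer(table["left", "left"] + table["right", "right"])
}

#' @rdname correct_decision_rate
#' @export
decision_rate <- function(table) {
  tot <- sum(table)
  if (tot == 0L) return(NA_real_)
  n_decisions(table) / tot
}

#' Exact one-sided binomial test for correct decisions
#'
#' Upper-tail probability `P(X >= k | n, p0)` under the binomial law:
#' the probability of at least `k` correct directions among `n`
#' decisions when guessing at rate `p0`.
#'
#' @param k Number of correct decisions (0 <= k <= n).
#' @param n Number of decisions (>= 1).
#' @param p0 Chance rate under the null (default 0.5).
#' @return Exact one-sided p-value.
#' @examples
#' binom_p_one_sided(16, 20) # 0.0059...
#' @export
binom_p_one_sided <- function(k, n, p0 = 0.5) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop_input("require integers 0 <= k <= n with n >= 1")
  }
  if (p0 < 0 || p0 > 1) stop_input("'p0' must be in [0, 1]")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Average correct-decision rate across the four feature sets
#'
#' Unweighted mean of the per-feature-set correct-decision rates for one
#' split, as a percentage rounded to the nearest integer. Feature sets
#' with no decisions are excluded with a warning.
#'
#' @param tables List of [direction_table()]s from one split.
#' @return Integer percentage, or `NA` if every table is undefined.
#' @export
average_correct_rate <- function(tables) {
  rates <- vapply(tables, correct_decision_rate, numeric(1L))
  if (anyNA(rates)) {
    warning(sum(is.na(rates)), " feature set(s) with no decisions excluded",
            call. = FALSE)
    rates <- rates[!is.na(rates)]
  }
  if (!length(rates)) return(NA_real_)
  round(mean(rates) * 100)
}

#' Combine head-based and gaze-based direction decisions
#'
#' Per trial: if only one source makes a (non-centre) decision, that
#' decision is used; if both agree, the shared class; if they conflict,
#' the `conflict` policy decides (default `"gaze"`: the gaze-based
#' prediction wins). Combination can only add decisions, never remove
#' them.
#'
#' @param pred_head,pred_gaze Aligned prediction vectors
#'   (left/centre/right).
#' @param conflict Conflict policy: `"gaze"`, `"head"` or `"centre"`.
#' @return List with `predictions` (factor) and `stats`
#'   (`n_decisions_combined`, `n_both`, `n_agree`, `n_conflict`).
#' @export
combine_decisions <- function(pred_head, pred_gaze,
                              conflict = c("gaze", "head", "centre")) {
  conflict <- match.arg(conflict)
  h <- as.character(pred_head)
  g <- as.character(pred_gaze)
  if (length(h) != length(g)) stop_input("prediction lengths differ")
  out <- character(length(h))
  both <- h != "centre" & g != "centre"
  agree <- both & h == g
  confl <- both & h != g
  out[h == "centre" & g == "centre"] <- "centre"
  out[h != "centre" & g == "centre"] <- h[h != "centre" & g == "centre"]
  out[h == "centre" & g != "centre"] <- g[h == "centre" & g != "centre"]
  out[agree] <- h[agree]
  out[confl] <- switch(conflict, gaze = g[confl], head = h[confl],
                       centre = "centre")
  preds <- factor(out, levels = direction_levels())
  list(
    predictions = preds,
    stats = list(
      n_decisions_combined = sum(preds != "centre"),
      n_both = sum(both),
      n_agree = sum(agree),
      n_conflict = sum(confl)
    )
  )
}

#' @export
print.direction_table <- function(x, ...) {
  cat(sprintf("direction table [%s, %s]\n",
              attr(x, "feature_set"), attr(x, "split")))
  print(unclass(x)[, , drop = FALSE])
  sp <- correct_decision_rate(x)
  cat(sprintf("decisions: %d, correct: %d, rate: %s\n",
              n_decisions(x), n_correct(x),
              if (is.na(sp)) "no decision" else sprintf("%.1f%%", 100 * sp)))
  invisible(x)
}
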