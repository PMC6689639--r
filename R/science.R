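#' Hypothesis, investigation and communication draws
#'
#' The elementary random events of the Science stage. A hypothesis is
#' true with probability `b` (the base rate). A true hypothesis yields a
#' positive result with probability `W` (power); a false one with
#' probability `alpha` (the lab's false positive rate).
#'
#' All three functions are vectorized; `draw_hypothesis` and
#' `investigate` consume one uniform draw per element from R's global
#' RNG, `publication_probability` is deterministic.
#'
#' @param b Base rate of true hypotheses, in \[0, 1\].
#' @param n Number of independent draws.
#' @param hypothesis_true Logical: true epistemic state of the
#'   hypothesis.
#' @param alpha False positive rate of the investigating lab.
#' @param W Statistical power.
#' @return `draw_hypothesis` and `investigate` return logical vectors;
#'   `publication_probability` returns probabilities.
#' @examples
#' publication_probability(TRUE, TRUE, p = 0.3, r = 0.5)   # always 1
#' publication_probability(TRUE, FALSE, p = 0.4, r = 0.25) # 0.4 * 0.75
#' @export
draw_hypothesis <- function(b, n = 1L) {
  stopifnot(b >= 0, b <= 1)
  runif(n) < b
}

#' @rdname draw_hypothesis
#' @export
investigate <- function(hypothesis_true, alpha, W) {
  stopifnot(all(alpha >= 0 & alpha <= 1), all(W >= 0 & W <= 1))
  prob <- ifelse(hypothesis_true, W, alpha)
  runif(length(prob)) < prob
}

#' @rdname draw_hypothesis
#' @param result_positive Logical: observed result of the investigation.
#' @param p Probability that a negative result is publishable.
#' @param r Probability that an erroneous result (incongruent with the
#'   hypothesis's truth) is blocked by peer review.
#' @details The two publication filters act independently, so the
#'   probability that a result is published is the product of the
#'   negative-result factor (1 for positive results, `p` for negative)
#'   and the peer-review factor (1 for congruent results, `1 - r` for
#'   erroneous ones): (T,+) 1; (F,+) 1-r; (F,-) p; (T,-) p(1-r).
#' @export
publication_probability <- function(hypothesis_true, result_positive, p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  erroneous <- hypothesis_true != result_positive
  ifelse(result_positive, 1, p) * ifelse(erroneous, 1 - r, 1)
}

#' Run one Science stage
#'
#' Visits every lab in a fresh uniformly random order. Each lab with at
#' least one fund spends exactly one fund and performs one
#' investigation: a hypothesis is drawn, investigated, and submitted for
#' publication through the publication-bias and peer-review filters.
#' Labs with zero funds are untouched.
#'
#' @param labs A lab data frame (see [init_labs()]).
#' @param params A validated [lab_params()] object.
#' @return A list with elements `labs` (updated), `stats` (per-step
#'   tallies: investigations, publications, erroneous_publications,
#'   true_hypotheses, positive_results), and `investigations` (one row
#'   per investigation: lab_id, hypothesis_true, result_positive,
#'   published, erroneous).
#' @export
run_science_step <- function(labs, params) {
  n <- nrow(labs)
  order_idx <- sample_index(n, n)
  lab_id <- integer(0); hyp <- logical(0); pos <- logical(0)
  pub <- logical(0); err <- logical(0)
  for (i in order_idx) {
    if (labs$funds[i] >= 1L) {
      labs$funds[i] <- labs$funds[i] - 1L
      h <- draw_hypothesis(params$b)
      s <- investigate(h, labs$alpha[i], params$W)
      e <- h != s
      q <- publication_probability(h, s, params$p, params$r)
      published <- runif(1L) < q
      if (published) {
        labs$publications[i] <- labs$publications[i] + 1L
        if (e) {
          labs$erroneous_publications[i] <- labs$erroneous_publications[i] + 1L
        }
      }
      lab_id <- c(lab_id, labs$id[i]); hyp <- c(hyp, h); pos <- c(pos, s)
      pub <- c(pub, published); err <- c(err, e)
    }
  }
  investigations <- data.frame(
    lab_id = lab_id, hypothesis_true = hyp, result_positive = pos,
    published = pub, erroneous = err
  )
  stats <- list(
    investigations = length(lab_id),
    publications = sum(pub),
    erroneous_publications = sum(pub & err),
    true_hypotheses = sum(hyp),
    positive_results = sum(pos)
  )
  list(labs = labs, stats = stats, investigations = investigations)
}
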