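#' Closed-form expectations for a static, fully funded population
#'
#' Ground truth for Monte Carlo validation: with evolution and funding
#' frozen and every lab funded every iteration, investigation outcomes
#' are i.i.d. draws from a four-cell distribution over (hypothesis
#' truth, result sign). `outcome_table` enumerates the cells:
#' occurrence mass (T,+) `b*W`; (T,-) `b*(1-W)`; (F,+) `(1-b)*alpha`;
#' (F,-) `(1-b)*(1-alpha)`, each with its publication probability and
#' erroneous flag.
#'
#' @param alpha False positive rate.
#' @param b Base rate of true hypotheses.
#' @param W Statistical power.
#' @param p Negative-result publication rate.
#' @param r Peer-review efficacy.
#' @return A data frame with one row per (truth, result) cell:
#'   `hypothesis_true`, `result_positive`, `occurrence`,
#'   `pub_probability`, `erroneous`.
#' @examples
#' outcome_table(0.05, 0.1, 0.8, 0, 0)
#' static_fdr(0.05, 0.1, 0.8, 0, 0)  # 0.045 / 0.125 = 0.36
#' @export
outcome_table <- function(alpha, b, W, p, r) {
  stopifnot(all(c(alpha, b, W, p, r) >= 0), all(c(alpha, b, W, p, r) <= 1))
  hypothesis_true <- c(TRUE, TRUE, FALSE, FALSE)
  result_positive <- c(TRUE, FALSE, TRUE, FALSE)
  occurrence <- c(b * W, b * (1 - W), (1 - b) * alpha, (1 - b) * (1 - alpha))
  data.frame(
    hypothesis_true = hypothesis_true,
    result_positive = result_positive,
    occurrence = occurrence,
    pub_probability = publication_probability(hypothesis_true,
                                              result_positive, p, r),
    erroneous = hypothesis_true != result_positive
  )
}

#' @rdname outcome_table
#' @details `static_fdr` is the expected false discovery rate of the
#'   published literature in the static population: the published
#'   erroneous mass divided by the total published mass,
#'   \deqn{F = \frac{(1-b)\alpha(1-r) + b(1-W)p(1-r)}{bW + (1-b)(1-\alpha)p
#'   + (1-b)\alpha(1-r) + b(1-W)p(1-r)},}
#'   `NA` when nothing is publishable (zero denominator).
#' @export
static_fdr <- function(alpha, b, W, p, r) {
  tab <- outcome_table(alpha, b, W, p, r)
  published <- tab$occurrence * tab$pub_probability
  denom <- sum(published)
  if (denom <= 0) return(NA_real_)
  sum(published[tab$erroneous]) / denom
}

#' @rdname outcome_table
#' @details `expected_publications_per_investigation` is the marginal
#'   probability that one investigation ends in a publication.
#' @export
expected_publications_per_investigation <- function(alpha, b, W, p, r) {
  tab <- outcome_table(alpha, b, W, p, r)
  sum(tab$occurrence * tab$pub_probability)
}
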