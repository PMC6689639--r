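#' Grant application and award
#'
#' The Grant-Seeking stage: a uniformly random group of `d` labs applies
#' for one grant of size `G`, and the winner is chosen by the funding
#' strategy. Funding status and current funds do not affect
#' eligibility.
#'
#' Strategies: `PH` awards the applicant with the most publications
#' (ties uniform); `MI` the applicant with the lowest false positive
#' rate (ties uniform); `RA` a uniformly random applicant; `MS` applies
#' MI with probability `X` and RA otherwise (one coin flip per award,
#' recorded in `strategy_used`); `ML` awards uniformly among qualified
#' applicants with `alpha <= A`, and awards nothing when no applicant
#' qualifies. With `A = 1` every applicant qualifies and ML consumes the
#' same single draw as RA, so the two are draw-for-draw identical.
#'
#' @param labs A lab data frame.
#' @param d Number of applicants to sample.
#' @return `select_applicants` returns applicant lab ids in sampled
#'   order.
#' @export
select_applicants <- function(labs, d) {
  n <- nrow(labs)
  labs$id[sample_index(n, min(d, n))]
}

#' @rdname select_applicants
#' @param applicant_ids Lab ids of the applicants, in sampled order.
#' @param params A validated [lab_params()] object.
#' @return `award_grant` returns a list with `labs` (updated: the
#'   winner's funds increased by `G`) and `award` (`applicant_ids`,
#'   `winner_id` — `NA` when no award — and `strategy_used`).
#' @export
award_grant <- function(labs, applicant_ids, params) {
  if (length(applicant_ids) == 0L) stop("empty applicant set")
  rows <- match(applicant_ids, labs$id)
  strategy <- params$strategy
  used <- strategy
  pick_ph <- function() {
    pubs <- labs$publications[rows]
    pick_uniform(rows[pubs == max(pubs)])
  }
  pick_mi <- function() {
    al <- labs$alpha[rows]
    pick_uniform(rows[al == min(al)])
  }
  pick_ra <- function() rows[unif_index(length(rows))]
  win_row <- switch(strategy,
    PH = pick_ph(),
    MI = pick_mi(),
    RA = pick_ra(),
    MS = {
      if (runif(1L) < params$X) {
        used <- "MI"; pick_mi()
      } else {
        used <- "RA"; pick_ra()
      }
    },
    ML = {
      qualified <- rows[labs$alpha[rows] <= params$A]
      if (length(qualified) > 0L) pick_uniform(qualified) else NA_integer_
    }
  )
  winner_id <- NA_integer_
  if (!is.na(win_row)) {
    labs$funds[win_row] <- labs$funds[win_row] + params$G
    winner_id <- labs$id[win_row]
  }
  list(labs = labs,
       award = list(applicant_ids = applicant_ids, winner_id = winner_id,
                    strategy_used = used))
}

#' Run one Grant-Seeking stage
#'
#' Samples the applicant pool and awards (at most) one grant under the
#' configured strategy.
#'
#' @inheritParams award_grant
#' @return As [award_grant()].
#' @export
run_funding_step <- function(labs, params) {
  applicants <- select_applicants(labs, params$d)
  award_grant(labs, applicants, params)
}
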