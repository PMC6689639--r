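#' Death, parent selection and mutation
#'
#' The Evolution stage removes one lab and creates one new lab per
#' iteration. Death: the oldest lab of a uniformly random `d`-sample
#' dies, ties broken uniformly at random. Birth: under `"strong"`
#' selection the most-published lab of a fresh `d`-sample of the
#' remaining population is the parent (ties uniform); under
#' `"proportional"` selection every extant lab can be parent with
#' probability proportional to its publication count (uniform fallback
#' when no lab has published).
#'
#' @param labs A lab data frame (see [init_labs()]).
#' @param d Sample size for the death or birth event.
#' @param mode `"strong"` or `"proportional"` parent selection.
#' @return `select_death` and `select_parent` return a lab `id`.
#' @export
select_death <- function(labs, d) {
  n <- nrow(labs)
  if (n == 0L) stop("empty population")
  idx <- sample_index(n, min(d, n))
  ages <- labs$age[idx]
  ties <- idx[ages == max(ages)]
  labs$id[pick_uniform(ties)]
}

#' @rdname select_death
#' @export
select_parent <- function(labs, d, mode = c("strong", "proportional")) {
  mode <- match.arg(mode)
  m <- nrow(labs)
  if (m == 0L) stop("empty population")
  if (mode == "strong") {
    idx <- sample_index(m, min(d, m))
    pubs <- labs$publications[idx]
    ties <- idx[pubs == max(pubs)]
    labs$id[pick_uniform(ties)]
  } else {
    w <- as.numeric(labs$publications)
    total <- sum(w)
    u <- runif(1L)
    if (total <= 0) {
      row <- 1L + min(as.integer(floor(u * m)), m - 1L)
    } else {
      row <- which(u * total < cumsum(w))[1L]
    }
    labs$id[row]
  }
}

#' @rdname select_death
#' @param parent_alpha False positive rate of the parent lab.
#' @param epsilon Mutation standard deviation.
#' @details `mutate_alpha` adds a zero-mean Gaussian deviate with
#'   standard deviation `epsilon` to the inherited rate and truncates
#'   the result to \[0, 1\]. One normal draw is consumed per element even
#'   when `epsilon = 0`, keeping the RNG stream aligned with the
#'   compiled engine.
#' @export
mutate_alpha <- function(parent_alpha, epsilon) {
  stopifnot(all(parent_alpha >= 0 & parent_alpha <= 1), epsilon >= 0)
  pmin(1, pmax(0, parent_alpha + epsilon * rnorm(length(parent_alpha))))
}

#' Run one Evolution stage
#'
#' Applies one death-birth event: the dying lab is selected and removed,
#' a parent is selected among the remaining labs, and a new lab with age
#' 0, zero publications and startup funds `G0` is created in the dying
#' lab's place, inheriting the parent's false positive rate with
#' mutation. Age increments happen once per iteration at the engine
#' level, not here.
#'
#' @param labs A lab data frame.
#' @param params A validated [lab_params()] object.
#' @return A list with `labs` (updated, same number of rows) and `event`
#'   (`dead_id`, `parent_id`, `child_id`, `child_alpha`).
#' @export
run_evolution_step <- function(labs, params) {
  child_id <- max(labs$id) + 1L
  dead_id <- select_death(labs, params$d)
  dead_row <- match(dead_id, labs$id)
  survivors <- labs[-dead_row, , drop = FALSE]
  parent_id <- select_parent(survivors, params$d, params$selection_mode)
  parent_alpha <- survivors$alpha[match(parent_id, survivors$id)]
  child_alpha <- mutate_alpha(parent_alpha, params$epsilon)
  dead_funds <- labs$funds[dead_row]
  labs$id[dead_row] <- child_id
  labs$alpha[dead_row] <- child_alpha
  labs$funds[dead_row] <- params$G0
  labs$age[dead_row] <- 0L
  labs$publications[dead_row] <- 0L
  labs$erroneous_publications[dead_row] <- 0L
  list(labs = labs,
       event = list(dead_id = dead_id, parent_id = parent_id,
                    child_id = child_id, child_alpha = child_alpha,
                    dead_funds = dead_funds))
}
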