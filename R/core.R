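# Best-response movement rule, IFD predicate, and congestion potential.
# All three see a patch only through intake_rate(Q, n), so any response
# strictly increasing in Q/n induces the same dynamics.

# hot-path: target patch for a consumer currently on patch p, or NA if no
# strictly improving patch exists; ties among maximisers broken uniformly
# with the run's RNG stream
.best_target <- function(quality, count, p, response) {
  w <- .intake(response, quality[p], count[p])
  v <- .intake(response, quality, count + 1L)
  v[p] <- -Inf
  m <- max(v)
  if (m > w) {
    cand <- which(v == m)
    if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
  } else {
    NA_integer_
  }
}

# hot-path IFD predicate on raw vectors: every consumer on every occupied
# patch already earns at least what it would earn anywhere else after
# joining (n_q + 1)
.ifd_counts <- function(quality, count, response) {
  occ <- count >= 1L
  if (!any(occ)) return(TRUE)
  v <- .intake(response, quality, count + 1L)
  w <- .intake(response, quality[occ], count[occ])
  top1 <- max(v)
  if (sum(v == top1) > 1L || length(v) == 1L) {
    # best alternative is top1 for everyone (or no alternative at all)
    if (length(v) == 1L) return(TRUE)
    return(all(w >= top1))
  }
  top2 <- max(v[-which.max(v)])
  vm <- v[occ]
  all(w >= ifelse(vm == top1, top2, top1))
}

#' Best-response move for one consumer
#'
#' Evaluates the focal consumer's current intake
#' `intake_rate(Q_p, n_p)` against its prospective intake
#' `intake_rate(Q_q, n_q + 1)` on every other patch `q` — the consumer
#' counts itself at the destination but not twice at the origin. Returns
#' the index of a patch attaining the maximal prospective intake if that
#' maximum strictly exceeds the current intake (ties among maximisers
#' broken uniformly at random), and `NA` if staying is already optimal.
#'
#' @param state An `ifd_state`.
#' @param i Consumer index.
#' @param response A [functional_response()].
#' @return Integer patch index, or `NA_integer_` for "no move".
#' @export
best_move <- function(state, i, response) {
  stopifnot(inherits(state, "ifd_state"))
  L <- state$landscape
  if (i < 1L || i > length(state$patch)) stop("consumer index out of range")
  .best_target(L$quality, L$count, state$patch[i], response)
}

#' Move a consumer to a target patch
#'
#' Pure bookkeeping: decrements the origin count, increments the target
#' count and the consumer's cumulative move counter. Population size is
#' conserved. (Run functions record the move in their event log.)
#'
#' @param state An `ifd_state`.
#' @param i Consumer index.
#' @param target Destination patch index, different from the consumer's
#'   current patch.
#' @return The updated `ifd_state`.
#' @export
apply_move <- function(state, i, target) {
  stopifnot(inherits(state, "ifd_state"))
  P <- length(state$landscape$quality)
  target <- as.integer(target)
  if (is.na(target) || target < 1L || target > P)
    stop("move target out of range")
  p <- state$patch[i]
  if (target == p) stop("move target equals the consumer's current patch")
  state$landscape$count[p] <- state$landscape$count[p] - 1L
  state$landscape$count[target] <- state$landscape$count[target] + 1L
  state$patch[i] <- target
  state$moves[i] <- state$moves[i] + 1L
  state
}

#' Exact ideal-free-distribution predicate
#'
#' `TRUE` iff no consumer has a strictly improving move: for every
#' occupied patch `p`, `intake_rate(Q_p, n_p) >= intake_rate(Q_q, n_q + 1)`
#' for all `q != p`. Empty patches are valid move targets but are not
#' tested as sources (they host no consumer).
#'
#' @param x An `ifd_state` or `patch_landscape` (with counts).
#' @param response A [functional_response()].
#' @return Logical scalar.
#' @examples
#' is_ifd(patch_landscape(c(12, 6), count = c(2, 1)), functional_response("type_I"))
#' @export
is_ifd <- function(x, response) {
  L <- as_landscape(x)
  .ifd_counts(L$quality, L$count, response)
}

#' Congestion potential of a state
#'
#' Rosenthal-style potential `Phi = sum_p sum_{k=1..n_p} intake_rate(Q_p, k)`.
#' A single accepted best-response move changes `Phi` by exactly the
#' mover's intake gain (new intake minus old intake), which is strictly
#' positive; since `Phi` is bounded above on a fixed landscape, sequential
#' best-response dynamics terminate in finitely many moves.
#'
#' @inheritParams is_ifd
#' @return Numeric scalar; 0 for an empty population.
#' @export
potential <- function(x, response) {
  L <- as_landscape(x)
  tot <- 0
  for (p in which(L$count >= 1L)) {
    tot <- tot + sum(.intake(response, L$quality[p], seq_len(L$count[p])))
  }
  tot
}
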