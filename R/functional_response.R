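#' Ratio-dependent functional response
#'
#' Constructs the per-capita intake model used throughout the simulator.
#' Intake on a patch depends on resource input rate `Q` and occupancy `n`
#' only through the ratio `Q/n`:
#' * `type_I` — linear, intake = `Q/n` (equal division of the input rate);
#' * `type_II` — saturating Arditi–Ginzburg ratio-dependent Holling
#'   disc form, intake = `a (Q/n) / (1 + a h (Q/n))` with attack rate `a`
#'   and handling time `h`.
#'
#' Both forms are strictly increasing in `Q/n`, so they rank patches
#' identically; best-response movement dynamics are therefore the same
#' under either response (see the package vignette).
#'
#' @param kind `"type_I"` or `"type_II"`.
#' @param attack_rate Attack rate `a > 0` (type II only; intake per unit
#'   resource-per-capita at low density).
#' @param handling_time Handling time `h >= 0` per resource unit (type II
#'   only; `h = 0` reduces type II to `a Q/n`).
#' @return An object of class `functional_response`.
#' @examples
#' fr1 <- functional_response("type_I")
#' fr2 <- functional_response("type_II", attack_rate = 1, handling_time = 1)
#' intake_rate(fr1, quality = 10, n = 2)  # 5
#' intake_rate(fr2, quality = 10, n = 2)  # 5/6
#' @export
functional_response <- function(kind = c("type_I", "type_II"),
                                attack_rate = 1, handling_time = 1) {
  kind <- match.arg(kind)
  if (kind == "type_II") {
    if (!is.numeric(attack_rate) || length(attack_rate) != 1L || attack_rate <= 0)
      stop("`attack_rate` must be a single positive number")
    if (!is.numeric(handling_time) || length(handling_time) != 1L || handling_time < 0)
      stop("`handling_time` must be a single non-negative number")
  }
  structure(
    list(kind = kind, attack_rate = attack_rate, handling_time = handling_time),
    class = "functional_response"
  )
}

#' @export
print.functional_response <- function(x, ...) {
  if (x$kind == "type_I") {
    cat("Ratio-dependent functional response: type I, intake = Q/n\n")
  } else {
    cat(sprintf(
      "Ratio-dependent functional response: type II, intake = a(Q/n)/(1 + a h (Q/n)), a = %g, h = %g\n",
      x$attack_rate, x$handling_time
    ))
  }
  invisible(x)
}

# hot-path intake on precomputed Q and n (no validation); vectorised
.intake <- function(response, quality, n) {
  x <- quality / n
  if (response$kind == "type_I") {
    x
  } else {
    a <- response$attack_rate
    a * x / (1 + a * response$handling_time * x)
  }
}

#' Per-capita intake rate on a patch
#'
#' Realised intake of one consumer on a patch with resource input rate
#' `quality` shared among `n` consumers (the focal consumer included).
#' Vectorised over `quality` and `n`.
#'
#' @param response A [functional_response()].
#' @param quality Patch resource input rate(s), positive.
#' @param n Patch consumer count(s), at least 1; intake is undefined on an
#'   empty patch (prospective evaluations always use `n + 1 >= 1`).
#' @return Numeric vector of intake rates; strictly increasing in
#'   `quality/n` and strictly decreasing in `n` for fixed `quality`.
#' @export
intake_rate <- function(response, quality, n) {
  stopifnot(inherits(response, "functional_response"))
  if (any(n < 1)) stop("intake rate is undefined on an empty patch (n >= 1 required)")
  if (any(quality <= 0)) stop("patch quality must be positive")
  .intake(response, quality, n)
}
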