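#' Learning state
#'
#' Holds the Rescorla-Wagner associative strengths of the two prey
#' signature odors: `Vh` (appetitive association of the hermi odor) and
#' `Vf` (aversive association of the flab odor), both in `[0, lambda]`.
#'
#' @param Vh,Vf initial associative strengths.
#' @param enabled logical; when `FALSE`, [on_consumption()] leaves the
#'   state untouched.
#' @return A list of class `cs_learning_state`.
#' @export
learning_state <- function(Vh = 0, Vf = 0, enabled = TRUE) {
  stopifnot(Vh >= 0, Vf >= 0)
  structure(list(Vh = Vh, Vf = Vf, enabled = isTRUE(enabled)),
            class = "cs_learning_state")
}

#' One Rescorla-Wagner update
#'
#' `V' = V + alpha * beta * (lambda - V)`: the associative strength moves a
#' fixed fraction of the remaining distance toward the asymptote, so
#' repeated training converges geometrically to `lambda` and never
#' overshoots it.
#'
#' @param V current associative strength.
#' @param alpha CS salience in \code{[0, 1]}.
#' @param beta US associability rate in \code{[0, 1]}.
#' @param lambda asymptotic associative strength of the US.
#' @return Updated strength.
#' @examples
#' rw_update(0, 0.5, 1, 1)   # 0.5
#' rw_update(0.5, 0.5, 1, 1) # 0.75
#' @export
rw_update <- function(V, alpha = 0.5, beta = 1, lambda = 1) {
  .cpp_rw_update(V, alpha, beta, lambda)
}

#' Apply the learning consequence of a consumption event
#'
#' Consuming a hermi drives `Vh` toward `lambda` (reward association);
#' consuming a flab drives `Vf` toward `lambda` (punishment association).
#' Consuming the Batesian mimic fauxflab -- Flab's odor with Hermi's
#' rewarding consequences -- applies an extinction-style update driving
#' `Vf` toward 0, the package's rendering of an appetitive
#' counter-association bound to the flab odor channel.
#'
#' @param state a [learning_state()].
#' @param species one of "flab", "hermi", "fauxflab".
#' @param constants a [cs_constants()].
#' @return The updated learning state.
#' @examples
#' on_consumption(learning_state(), "hermi")$Vh # 0.5
#' @export
on_consumption <- function(state, species, constants = cs_constants()) {
  stopifnot(inherits(state, "cs_learning_state"))
  if (!species %in% PREY_SPECIES) {
    stop("unknown prey species: ", species, call. = FALSE)
  }
  if (!state$enabled) return(state)
  a <- constants$alpha; b <- constants$beta; lam <- constants$lambda
  if (species == "hermi") {
    state$Vh <- rw_update(state$Vh, a, b, lam)
  } else if (species == "flab") {
    state$Vf <- rw_update(state$Vf, a, b, lam)
  } else {
    state$Vf <- rw_update(state$Vf, a, b, 0)
  }
  state
}
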