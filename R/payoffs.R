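#' Prisoner's dilemma payoff matrix
#'
#' Bundles the four payoffs of the one-shot prisoner's dilemma: the temptation
#' `T` earned by a defector meeting a cooperator, the reward `R` for mutual
#' cooperation, the punishment `P` for mutual defection, and the sucker payoff
#' `S` of a cooperator meeting a defector.  The constructor enforces the
#' dilemma ordering `T > R > P > S` together with `2R > T + S`, the condition
#' under which cooperation retains a non-null chance of persisting.
#'
#' @param T Temptation payoff (defect against cooperate).
#' @param R Reward payoff (mutual cooperation).
#' @param P Punishment payoff (mutual defection).
#' @param S Sucker payoff (cooperate against defect).
#'
#' @return An object of class `payoff_matrix`: a named list with elements
#'   `T`, `R`, `P`, `S`.
#'
#' @examples
#' payoff_matrix()                  # default T=1.5, R=1, P=0.1, S=0
#' payoff_matrix(T = 1.8, R = 1, P = 0.1, S = 0)
#' @export
payoff_matrix <- function(T = 1.5, R = 1, P = 0.1, S = 0) {
  vals <- c(T = T, R = R, P = P, S = S)
  if (!all(is.finite(vals))) {
    stop("all payoffs must be finite numbers", call. = FALSE)
  }
  if (!(T > R && R > P && P > S)) {
    stop("payoff ordering violated: need T > R > P > S (got T=", T,
         ", R=", R, ", P=", P, ", S=", S, ")", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("need 2R > T + S so cooperation has a non-null chance (got 2R=",
         2 * R, ", T+S=", T + S, ")", call. = FALSE)
  }
  structure(list(T = T, R = R, P = P, S = S), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("<payoff_matrix>  T =", x$T, " R =", x$R, " P =", x$P, " S =", x$S, "\n")
  invisible(x)
}

#' Payoffs for one prisoner's dilemma round
#'
#' Returns the payoff earned by each member of a pair given their strategies:
#' (C,C) -> (R,R), (D,D) -> (P,P), (C,D) -> (S,T), (D,C) -> (T,S).
#' Vectorised over pairs.
#'
#' @param a,b Character vectors of strategies, `"C"` or `"D"`.
#' @param payoffs A [payoff_matrix()].
#'
#' @return A tibble with columns `a`, `b`, `payoff_a`, `payoff_b`, one row per
#'   pair.
#'
#' @examples
#' payoff_pair("C", "D", payoff_matrix())
#' @export
payoff_pair <- function(a, b, payoffs = payoff_matrix()) {
  stopifnot(length(a) == length(b))
  a_c <- as_strategy(a)
  b_c <- as_strategy(b)
  pa <- ifelse(a_c == 1L,
               ifelse(b_c == 1L, payoffs$R, payoffs$S),
               ifelse(b_c == 1L, payoffs$T, payoffs$P))
  pb <- ifelse(b_c == 1L,
               ifelse(a_c == 1L, payoffs$R, payoffs$S),
               ifelse(a_c == 1L, payoffs$T, payoffs$P))
  tibble::tibble(a = strategy_label(a_c), b = strategy_label(b_c),
                 payoff_a = pa, payoff_b = pb)
}

# Internal strategy coding: 1L = cooperate, 0L = defect.
as_strategy <- function(x) {
  if (is.numeric(x)) {
    s <- as.integer(x)
  } else {
    s <- ifelse(toupper(as.character(x)) %in% c("C", "COOPERATE"), 1L,
         ifelse(toupper(as.character(x)) %in% c("D", "DEFECT"), 0L, NA_integer_))
  }
  if (anyNA(s) || !all(s %in% c(0L, 1L))) {
    stop("strategies must be \"C\"/\"D\" (or 1/0)", call. = FALSE)
  }
  s
}

strategy_label <- function(s) c("D", "C")[s + 1L]

# Payoff earned by strategy s against opponent strategy o (integer-coded).
payoff_of <- function(s, o, payoffs) {
  ifelse(s == 1L,
         ifelse(o == 1L, payoffs$R, payoffs$S),
         ifelse(o == 1L, payoffs$T, payoffs$P))
}
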