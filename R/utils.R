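## internal helpers shared across modules

# deterministic half-up rounding (round() is banker's): 1.5 -> 2, 2.5 -> 3
round_half_up <- function(x) floor(x + 0.5)

# percentage on a stated denominator, reported at 2 dp
pct <- function(k, n) round(100 * k / n, 2)

stop_hetexpr <- function(msg, class) {
  abort(msg, class = c(class, "hetexpr_error"))
}

check_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop_hetexpr(
      sprintf("`%s` must lie in [0, 1]", name),
      "hetexpr_invalid_probability"
    )
  }
  invisible(x)
}

# slack factor when comparing point probabilities in probability-ordering
# two-sided tests; guards against floating-point ties
.prob_order_eps <- 1e-7
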